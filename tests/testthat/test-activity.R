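# independent brute-force oracles over raw sequences
oracle_dff <- function(trace, onset) {
  f <- sum(trace[(onset - 20):(onset - 11)]) / 10
  (trace - f) / f
}

oracle_kinetics <- function(dff, window) {
  peak <- -Inf
  peak_frame <- NA
  for (i in window) if (dff[i] > peak) { peak <- dff[i]; peak_frame <- i }
  thr <- 0.1 * peak
  on <- dff >= thr
  runs <- rle(on)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  k <- which(runs$values & starts <= peak_frame & ends >= peak_frame)
  list(peak = peak, peak_frame = peak_frame,
       activation_frame = starts[k], duration = runs$lengths[k],
       censored = ends[k] == length(dff) && runs$values[k])
}

test_that("delta-F/F uses the 10-frame baseline and is scale invariant", {
  trace <- rep(100, 60)
  expect_equal(as.numeric(delta_f_over_f(trace, 30)), rep(0, 60))
  trace[40] <- 250
  d <- delta_f_over_f(trace, 30)
  expect_equal(d[[40]], 1.5)
  expect_equal(attr(d, "baseline"), 100)
  # scaling the raw trace leaves delta-F/F unchanged
  expect_equal(as.numeric(delta_f_over_f(3.7 * trace, 30)), as.numeric(d))
  # baseline window boundary: frames onset-20 .. onset-11 only
  t2 <- rep(100, 60)
  t2[30 - 21] <- 1e6   # just before the window
  t2[30 - 10] <- 1e6   # just after the window
  expect_equal(attr(delta_f_over_f(t2, 30), "baseline"), 100)
  expect_error(delta_f_over_f(rep(100, 60), 20), ">= 21")
  expect_error(delta_f_over_f(rep(0, 60), 30), "baseline")
})

test_that("responder call is strict and windowed, monotone in threshold", {
  dff <- rep(0, 100)
  dff[50] <- 1.5
  expect_true(is_responsive(dff, 45:60))
  expect_false(is_responsive(dff, 60:80))   # peak outside window
  dff[50] <- 1.0
  expect_false(is_responsive(dff, 45:60))   # exactly 100% above baseline
  set.seed(5)
  for (i in 1:50) {
    d <- rnorm(80, 0.5, 0.6)
    w <- 30:60
    thr <- sort(runif(2, 0, 2))
    expect_true(is_responsive(d, w, thr[1]) >= is_responsive(d, w, thr[2]))
  }
})

test_that("activation kinetics match the brute-force scan oracle", {
  # symmetric triangular pulse 0 -> 1 -> 0 over 21 frames
  dff <- c(rep(0, 40), seq(0, 1, length.out = 11)[-1],
           seq(1, 0, length.out = 11)[-1], rep(0, 40))
  window <- 41:70
  m <- activation_metrics(dff, window)
  o <- oracle_kinetics(dff, window)
  expect_equal(m$peak, 1)
  expect_equal(m$activation_frame, o$activation_frame)
  expect_equal(m$activation_duration, o$duration)
  expect_false(m$censored)
  # rectangular pulse of height 2 lasting 10 frames
  dff <- rep(0, 100); dff[51:60] <- 2
  m <- activation_metrics(dff, 45:70)
  expect_equal(m$activation_duration, 10)
  expect_equal(m$activation_frame, 51)
  # monotone rise without decay is censored at the trace end
  dff <- seq(0, 2, length.out = 60)
  m <- activation_metrics(dff, 30:60)
  expect_true(m$censored)
  expect_error(activation_metrics(rep(-1, 50), 30:40), "not responsive")
})

test_that("kinetics agree with the oracle on many random traces", {
  set.seed(21)
  for (i in 1:300) {
    n <- 120
    base <- runif(1, 50, 200)
    onset <- sample(25:60, 1)
    width <- sample(3:40, 1)
    amp <- runif(1, 1.2, 4)
    shape <- sample(c("rect", "tri", "decay"), 1)
    dfft <- numeric(n)
    idx <- onset:min(onset + width, n)
    dfft[idx] <- switch(shape,
      rect = amp,
      tri = amp * (1 - abs(seq(-1, 1, length.out = length(idx)))),
      decay = amp * exp(-(seq_along(idx) - 1) / 5))
    trace <- base * (1 + dfft) + rnorm(n, 0, base * 0.002)
    d <- delta_f_over_f(trace, onset)
    expect_equal(as.numeric(d), oracle_dff(trace, onset), tolerance = 1e-12)
    w <- onset:min(onset + 40, n)
    resp <- is_responsive(d, w)
    expect_identical(resp, max(oracle_dff(trace, onset)[w]) > 1)
    if (resp) {
      m <- activation_metrics(d, w)
      o <- oracle_kinetics(as.numeric(d), w)
      expect_equal(m$peak_frame, o$peak_frame)
      expect_equal(m$activation_frame, o$activation_frame)
      expect_equal(m$activation_duration, o$duration)
      expect_identical(m$censored, o$censored)
    }
  }
})

test_that("alignment is shift equivariant and centres activation at 0", {
  base <- c(rep(0, 30), seq(0, 2, length.out = 6), rep(2, 10),
            seq(2, 0, length.out = 6), rep(0, 48))
  shifted <- c(rep(0, 7), base)[1:length(base)]
  m <- align_at_activation(list(a = base, b = shifted), window = 25:60)
  common <- !is.na(m[1, ]) & !is.na(m[2, ])
  expect_equal(m[1, common], m[2, common])
  expect_equal(unname(m[, "0"]),
               c(base[activation_metrics(base, 25:60)$activation_frame],
                 shifted[activation_metrics(shifted, 25:60)$activation_frame]))
  # identical traces align identically
  m2 <- align_at_activation(list(base, base), window = 25:60)
  expect_equal(m2[1, ], m2[2, ])
})

test_that("marker rules call subpopulations in listing order", {
  panel <- default_marker_panel()
  blank <- setNames(rep(FALSE, length(panel)), panel)
  hit <- function(...) { p <- blank; p[c(...)] <- TRUE; p }
  expect_equal(classify_subpopulation(hit("Gpr65")), "F")
  expect_equal(classify_subpopulation(hit("Gabra1")), "B")
  expect_equal(classify_subpopulation(blank), "X")
  # A: mechanoreceptor markers without Tmc3
  expect_equal(classify_subpopulation(hit("Runx3")), "A")
  expect_equal(classify_subpopulation(hit("Piezo2", "P2ry1")), "A")
  # D: Tmc3+ without Trpv1 (single Tmc3 hit falls through C)
  expect_equal(classify_subpopulation(hit("Tmc3")), "D")
  # C: multiple hits, Trpv1- and P2ry1-
  expect_equal(classify_subpopulation(hit("Slit2", "Ddc", "Tmc3")), "C")
  # H: Trpv1+, Tmc3-, Trpa1+
  expect_equal(classify_subpopulation(hit("Trpv1", "Trpa1")), "H")
  # K needs Kcng1 on top of H's markers plus Calca, but H fires first
  expect_equal(classify_subpopulation(
    hit("Trpa1", "Kcng1", "Trpv1", "Calca")), "H")
  # I: gut mechanosensor markers with Trpv1+ so D and H stay silent
  expect_equal(classify_subpopulation(hit("Car8", "Cckar", "Trpv1")), "I")
  # L: P2ry1 alone (Piezo2- keeps A silent, Trpv1- keeps J silent)
  expect_equal(classify_subpopulation(hit("P2ry1")), "L")
  expect_error(classify_subpopulation(blank[-1]), "unmeasured")
})
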