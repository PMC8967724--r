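toy_labels <- function() {
  data.frame(cluster = c("fixA", "fixB", "fixC", "fixD", "J1", "J2"),
             single = c(4, 5, 6, 3, 4, 2),
             dual_4 = c(8, 1, 2, 0.5, 8, 2),
             dual_6 = c(2, 3, 1, 1, 4, 4),
             dual_7 = c(1, 2, 5, 2, 1, 1),
             dual_8 = c(0.5, 4, 3, 6, 2, 3),
             stringsAsFactors = FALSE)
}

test_that("innervation intensity and fold changes follow their ratios", {
  expect_equal(innervation_intensity(10, 100), 0.1)
  expect_equal(innervation_intensity(5, 50), 0.1)   # IGLE count basis
  expect_equal(innervation_intensity(0, 10), 0)
  expect_error(innervation_intensity(1, 0), "positive")
  intens <- matrix(c(2, 0, 1, 1), 2, 2,
                   dimnames = list(c("ME", "IGLE"), c("4", "6")))
  af <- anatomical_fold_change(intens, c(ME = 1, IGLE = 1))
  expect_equal(af["ME", "4"], 2)
  expect_equal(af["ME", "6"], 1)
  expect_equal(af["IGLE", "4"], 0)
  af2 <- anatomical_fold_change(intens, c(ME = 1, IGLE = 0))
  expect_true(all(is.na(af2["IGLE", ])))
  expect_equal(normalized_innervation(1, 2), 0.5)
  expect_equal(normalized_innervation(0, 2), 0)
  expect_error(normalized_innervation(1, 0), "positive")
})

test_that("projection fold change is a ratio of sums", {
  labels <- data.frame(cluster = c("c1", "c2"), single = c(1, 2),
                       dual_4 = c(2, 4))
  sf <- projection_fold_change(setNames(c("ME", "ME"), c("c1", "c2")),
                               labels, regions = "4", types = "ME")
  expect_equal(sf["ME", "4"], 6 / 3)     # summed duals over summed singles
  sf1 <- projection_fold_change(c(c1 = "ME"), labels,
                                regions = "4", types = c("ME", "IGLE"))
  expect_equal(sf1["ME", "4"], 2)
  expect_true(is.na(sf1["IGLE", "4"]))   # no cluster assigned
  expect_error(projection_fold_change(c(zz = "ME"), labels,
                                      regions = "4", types = "ME"),
               "unknown cluster")
})

test_that("assignment variance equals a direct double-loop oracle", {
  labels <- toy_labels()
  fixed <- setNames(ending_types(), paste0("fix", LETTERS[1:4]))
  assign1 <- c(fixed, J1 = "ME", J2 = "cIMA")
  af <- matrix(runif(16, 0, 2), 4, 4,
               dimnames = list(ending_types(), stomach_regions()))
  got <- assignment_variance(assign1, af, labels)
  sf <- projection_fold_change(assign1, labels)
  oracle <- 0
  for (ty in ending_types()) for (rg in stomach_regions()) {
    oracle <- oracle + (sf[ty, rg] - af[ty, rg])^2
  }
  expect_equal(got, oracle)
  # SF == AF gives zero
  expect_equal(assignment_variance(assign1, sf, labels), 0)
  # a single half-unit discrepancy contributes 0.25
  af2 <- sf; af2["ME", "4"] <- af2["ME", "4"] + 0.5
  expect_equal(assignment_variance(assign1, af2, labels), 0.25)
})

test_that("enumeration is exhaustive, distinct and lexicographic", {
  e1 <- enumerate_assignments("c1")
  expect_equal(nrow(e1), 4)
  expect_equal(as.vector(e1), ending_types())
  e2 <- enumerate_assignments(c("c1", "c2"), types = c("a", "b", "c"))
  expect_equal(nrow(e2), 9)
  expect_equal(nrow(unique(e2)), 9)
  # first cluster varies slowest
  expect_equal(e2[1:3, "c1"], rep("a", 3))
  expect_equal(e2[1:3, "c2"], c("a", "b", "c"))
  e7 <- enumerate_assignments(paste0("f", 1:7))
  expect_equal(nrow(e7), 16384)
  expect_equal(nrow(unique(e7)), 16384)
  e0 <- enumerate_assignments(character(0))
  expect_equal(dim(e0), c(1L, 0L))
})

test_that("best assignment minimises the brute-force objective with ties lexicographic", {
  labels <- toy_labels()
  fixed <- setNames(ending_types(), paste0("fix", LETTERS[1:4]))
  free <- c("J1", "J2")
  truth <- c(J1 = "pIMA", J2 = "IGLE")
  sim <- simulate_ending_tables(truth, seed = 31)
  best <- best_assignment(sim$af, sim$labels, names(truth), sim$fixed_map)
  expect_equal(best$free, truth)
  expect_equal(best$variance, 0, tolerance = 1e-18)
  # oracle: independent enumeration in shuffled order via assignment_variance
  af <- matrix(runif(16, 0, 2), 4, 4,
               dimnames = list(ending_types(), stomach_regions()))
  best2 <- best_assignment(af, labels, free, fixed)
  enum <- enumerate_assignments(free)
  vars <- apply(enum[sample(nrow(enum)), , drop = FALSE], 1, function(row)
    assignment_variance(c(fixed, setNames(row, free)), af, labels))
  expect_equal(best2$variance, min(vars), tolerance = 1e-12)
  # exact tie: identical label rows for J1/J2 make (ME, pIMA) and
  # (pIMA, ME) score identically; the lexicographically first wins
  labels_tie <- labels
  labels_tie[labels_tie$cluster == "J2", -1] <-
    labels_tie[labels_tie$cluster == "J1", -1]
  af_tie <- projection_fold_change(c(fixed, J1 = "ME", J2 = "pIMA"),
                                   labels_tie)
  swapped <- c(fixed, J1 = "pIMA", J2 = "ME")
  expect_equal(assignment_variance(swapped, af_tie, labels_tie), 0)
  best_tie <- best_assignment(af_tie, labels_tie, free, fixed)
  expect_equal(unname(best_tie$variance), 0)
  expect_equal(best_tie$free, c(J1 = "ME", J2 = "pIMA"))
  # all clusters fixed: k = 0 returns the fixed map
  best0 <- best_assignment(af, labels, character(0), fixed)
  expect_equal(best0$assignment, fixed)
  expect_equal(best0$n_evaluated, 1)
})

test_that("noisy tables still recover the true assignment near zero noise", {
  truth <- setNames(c("cIMA", "IGLE", "ME"), paste0("J", 1:3))
  hits <- vapply(1:20, function(s) {
    sim <- simulate_ending_tables(truth, noise_sd = 0.01, seed = s)
    best <- best_assignment(sim$af, sim$labels, names(truth), sim$fixed_map)
    identical(best$free, truth)
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("enriched-cluster rules apply threshold and margin", {
  shares <- data.frame(cluster = c("a", "b", "c"),
                       single = c(5, 3.9, 4.0))
  expect_equal(identify_enriched_clusters(shares, "single"), "a")
  dual <- data.frame(cluster = c("a", "b", "c"),
                     dual = c(10, 10, 3),
                     single_1 = c(4, 6, 0), single_2 = c(4.5, 4, 0))
  # a: 10 > 4 and 10 >= 4+5 and 10 >= 4.5+5 -> enriched
  # b: fails the margin against single_1 = 6
  expect_equal(identify_enriched_clusters(dual, "dual"), "a")
  r5 <- data.frame(cluster = c("a", "b"), single = c(12, 12),
                   dual_1 = c(2, 8), dual_2 = c(1, 1),
                   dual_3 = c(0, 0), dual_4 = c(7, 7))
  expect_equal(identify_enriched_clusters(r5, "region5"), "a")
})
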