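random_rotation <- function() {
  rotation_about_axis(runif(1, -pi, pi), "z") %*%
    rotation_about_axis(runif(1, -pi, pi), "x")
}

test_that("rigid transform constructor enforces its invariants", {
  expect_error(rigid_transform(matrix(1, 3, 3)), "orthonormal")
  expect_error(rigid_transform(diag(c(1, 1, -1))), "determinant")
  expect_error(rigid_transform(diag(3), c(0, 0, 0), scale = 0), "scale")
  tf <- rigid_transform(rotation_about_axis(pi / 2), c(1, 0, 0))
  expect_equal(apply_transform(tf, rbind(c(1, 0, 0))),
               rbind(c(1, 1, 0)), tolerance = 1e-12)
})

test_that("transform estimation recovers known parameters exactly", {
  set.seed(13)
  pts <- matrix(runif(30, 0, 100), 10, 3)
  # identity
  tf0 <- estimate_transform(pts, pts)
  expect_equal(tf0$rotation, diag(3), tolerance = 1e-9)
  expect_equal(tf0$translation, c(0, 0, 0), tolerance = 1e-9)
  expect_lt(attr(tf0, "rmsd"), 1e-9)
  # known 30-degree rotation plus translation
  truth <- rigid_transform(rotation_about_axis(pi / 6), c(12, -3, 7))
  est <- estimate_transform(pts, apply_transform(truth, pts))
  expect_lt(max(abs(est$rotation - truth$rotation)), 1e-6)
  expect_lt(max(abs(est$translation - truth$translation)), 1e-6)
  # estimate-then-apply round trip is the identity
  for (i in 1:10) {
    truth <- rigid_transform(random_rotation(), runif(3, -50, 50))
    est <- estimate_transform(pts, apply_transform(truth, pts))
    back <- apply_transform(est, pts)
    expect_lt(max(abs(back - apply_transform(truth, pts))), 1e-9)
  }
  # similarity transform recovers isotropic scale
  truth <- rigid_transform(rotation_about_axis(0.4), c(1, 2, 3), scale = 0.8)
  est <- estimate_transform(pts, apply_transform(truth, pts),
                            allow_scale = TRUE)
  expect_equal(est$scale, 0.8, tolerance = 1e-9)
  # reflected targets still yield a proper rotation (det +1)
  refl <- pts %*% diag(c(-1, 1, 1))
  est <- estimate_transform(pts, refl)
  expect_equal(det(est$rotation), 1, tolerance = 1e-9)
  expect_gt(attr(est, "rmsd"), 1)
  expect_error(estimate_transform(cbind(1:5, 0, 0), cbind(1:5, 0, 0)),
               "collinear")
})

test_that("mutual-nearest-neighbour landmark matching gates outliers", {
  set.seed(2)
  a <- matrix(runif(15, 0, 100), 5, 3)
  pairs <- match_landmarks(a, a)
  expect_equal(pairs[, "invivo"], pairs[, "section"])
  # an outlier beyond the gate radius is excluded
  b <- rbind(a, c(1e4, 1e4, 1e4))
  pairs <- match_landmarks(a, b, gate_radius = 50)
  expect_false(6 %in% pairs[, "section"])
  expect_error(match_landmarks(a[1:2, ], a[1:2, ]), "at least 3")
})

test_that("virtual plane fit matches the closed-form eigen solution", {
  # coplanar points: exact plane z = 3
  set.seed(4)
  flat <- cbind(runif(12, 0, 10), runif(12, 0, 10), 3)
  fit <- fit_virtual_plane(flat)
  expect_equal(abs(fit$normal[3]), 1, tolerance = 1e-12)
  expect_equal(fit$residual, 0, tolerance = 1e-18)
  # noisy points: compare against the eigen decomposition oracle
  pts <- flat + matrix(rnorm(36, 0, 0.3), 12, 3)
  fit <- fit_virtual_plane(pts)
  cen <- sweep(pts, 2, colMeans(pts))
  ev <- eigen(crossprod(cen))
  oracle_normal <- ev$vectors[, 3]
  oracle_res <- ev$values[3]
  expect_equal(abs(sum(fit$normal * oracle_normal)), 1, tolerance = 1e-9)
  expect_equal(fit$residual, oracle_res, tolerance = 1e-9)
  # invariant to point order and to rigid motion of the whole set
  expect_equal(fit_virtual_plane(pts[sample(12), ])$residual, fit$residual)
  tf <- rigid_transform(rotation_about_axis(1.1, "x"), c(5, -2, 9))
  expect_equal(fit_virtual_plane(apply_transform(tf, pts))$residual,
               fit$residual, tolerance = 1e-9)
  expect_error(fit_virtual_plane(cbind(1:5, 2 * (1:5), 3 * (1:5))),
               "collinear")
})

test_that("non-landmark registration applies the ambiguity gate", {
  cand <- rbind(c(0, 0, 0), c(100, 0, 0))
  expect_equal(register_nonlandmark(c(1, 0, 0), cand)$status, "registered")
  expect_equal(register_nonlandmark(c(1, 0, 0), cand)$match, 1)
  expect_equal(register_nonlandmark(c(50, 0, 0), cand, r = 60)$status,
               "ambiguous")
  expect_equal(register_nonlandmark(c(0, 40, 0), cand)$status, "unmatched")
  expect_error(register_nonlandmark(c(0, 0, 0), cand[0, , drop = FALSE]),
               "no candidates")
})

test_that("zero-noise scenes register fully and match ground truth", {
  tf <- rigid_transform(rotation_about_axis(pi / 6), c(20, -10, 5))
  scene <- simulate_landmark_scene(tf, n_landmarks = 8, n_cells = 30,
                                   noise_sd = 0, seed = 6)
  reg <- register_scene(scene)
  expect_equal(registration_rate(reg$outcomes), 1)
  expect_equal(reg$outcomes$invivo_id,
               unname(scene$correspondence[reg$outcomes$section_id]))
  expect_lt(max(abs(reg$transform$rotation - tf$rotation)), 1e-6)
  expect_lt(max(abs(reg$transform$translation - tf$translation)), 1e-6)
  # status is invariant to cell id relabelling
  scene2 <- scene
  scene2$invivo$cell_id <- paste0("cell", rev(seq_len(nrow(scene$invivo))))
  scene2$section$cell_id <- paste0("s_", scene2$invivo$cell_id)
  reg2 <- register_scene(scene2)
  expect_equal(sort(reg2$outcomes$status), sort(reg$outcomes$status))
})

test_that("registration rate arithmetic", {
  expect_equal(registration_rate(rep("registered", 5)), 1)
  expect_equal(registration_rate(c(rep("registered", 349),
                                   rep("ambiguous", 607 - 349))), 0.575,
               tolerance = 1e-4)
  expect_equal(registration_rate(rep("unmatched", 3)), 0)
  expect_error(registration_rate(character(0)), "no outcomes")
})
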