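test_that("principal angles match closed forms and reject bad bases", {
  e <- diag(3)
  expect_equal(principal_angles(e[, 1, drop = FALSE], e[, 1, drop = FALSE]), 0)
  expect_equal(principal_angles(e[, 1, drop = FALSE], e[, 2, drop = FALSE]), 90)
  v45 <- cbind(c(1, 1, 0) / sqrt(2))
  expect_equal(principal_angles(e[, 1, drop = FALSE], v45), 45,
               tolerance = 1e-10)
  expect_error(principal_angles(cbind(c(1, 1, 0)), e[, 1, drop = FALSE]),
               "orthonormal")
  # invariance to a rotation of either basis
  set.seed(1)
  bx <- qr.Q(qr(matrix(rnorm(40), 10, 4)))
  by <- qr.Q(qr(matrix(rnorm(30), 10, 3)))
  rot <- qr.Q(qr(matrix(rnorm(16), 4)))
  expect_equal(principal_angles(bx %*% rot, by), principal_angles(bx, by),
               tolerance = 1e-8)
  expect_true(all(diff(principal_angles(bx, by)) >= 0))
})

test_that("principal angles agree with the projector-eigenvalue oracle", {
  set.seed(2)
  for (i in 1:100) {
    bx <- qr.Q(qr(matrix(rnorm(3 * 2), 3)))
    by <- qr.Q(qr(matrix(rnorm(3 * 2), 3)))
    ang <- principal_angles(bx, by)
    # independent route: cos^2(theta) are eigenvalues of Px Py
    ev <- sort(Re(eigen(tcrossprod(bx) %*% tcrossprod(by),
                        only.values = TRUE)$values), decreasing = TRUE)[1:2]
    oracle <- sort(acos(pmin(1, sqrt(pmax(ev, 0)))) * 180 / pi)
    expect_lt(max(abs(ang - oracle)), 1e-4)
  }
})

test_that("random-subspace nulls calibrate significance", {
  set.seed(3)
  y <- build_subspace(matrix(rnorm(30 * 3), 30))
  null <- random_subspace_null(30, y, d_random = 3, n = 200, seed = 4)
  expect_equal(dim(null), c(200L, 3L))
  # the subspace is trivially closer to itself than to chance
  expect_true(all(angles_below_chance(principal_angles(y, y), null)))
  # an independent random subspace is not
  z <- build_subspace(matrix(rnorm(30 * 3), 30))
  expect_false(all(angles_below_chance(principal_angles(z$basis, y), null)))
})

test_that("1-d angles to a fixed line in 2-d are uniform on [0, 90]", {
  y <- build_subspace(cbind(c(1, 0)))
  null <- random_subspace_null(2, y, 1, n = 2000, seed = 5)
  q <- stats::quantile(null[, 1], c(0.25, 0.5, 0.75))
  expect_lt(max(abs(q - c(22.5, 45, 67.5))), 4)
})

test_that("inter/intra cluster ratio matches hand computation and scaling", {
  pts <- rbind(c(0, 0), c(0, 2), c(10, 0), c(10, 2))
  lab <- c("a", "a", "b", "b")
  cm <- inter_intra_ratio(pts, lab, n_boot = 50, n_per_cluster = 2, seed = 6)
  expect_equal(cm$inter, 10)
  expect_equal(cm$intra, 2)
  expect_equal(cm$ratio, 5)
  cm2 <- inter_intra_ratio(2 * pts, lab, n_boot = 50, n_per_cluster = 2,
                           seed = 6)
  expect_equal(cm2$ratio, 5)
  expect_error(inter_intra_ratio(rbind(c(0, 0), c(5, 5)), c("a", "b"),
                                 n_boot = 5),
               "fewer than 2")
  expect_error(
    inter_intra_ratio(rbind(c(0, 0), c(0, 0), c(5, 5), c(5, 5)),
                      c("a", "a", "b", "b"), n_boot = 5),
    "zero")
})

test_that("loading weights are row norms with the documented normalization", {
  s1 <- build_subspace(cbind(c(1, 0)))
  s2 <- build_subspace(cbind(c(0, 1)))
  lw <- loading_weights(s1, s2, n_perm = 50, seed = 7)
  expect_equal(lw$w_memory, c(1, 0))
  expect_equal(lw$w_preparation, c(0, 1))
  set.seed(8)
  b <- build_subspace(matrix(rnorm(226 * 7), 226))
  w <- sqrt(rowSums(b$basis^2))
  expect_equal(sum(w^2), 7, tolerance = 1e-10)
  expect_true(all(w <= 1 + 1e-12))
})

test_that("shared neuron participation yields a significant weight correlation", {
  set.seed(9)
  gain <- runif(80, 0.2, 2)          # common per-neuron participation
  m <- gain * matrix(rnorm(80 * 5), 80)
  p <- gain * matrix(rnorm(80 * 5), 80)
  lw <- loading_weights(build_subspace(m), build_subspace(p),
                        n_perm = 200, seed = 10)
  expect_gt(lw$correlation, lw$null_q95)
  expect_true(lw$significant)
})

test_that("axis clustering statistic behaves at its extremes", {
  diag45 <- list(w_memory = rep(0.5, 40), w_preparation = rep(0.5, 40))
  out <- axis_clustering_test(diag45, n_boot = 50, seed = 11)
  expect_equal(unname(out$near_axis_ci), c(0, 0))
  on_axis <- list(w_memory = c(rep(1, 20), rep(0, 20)),
                  w_preparation = c(rep(0, 20), rep(1, 20)))
  out2 <- axis_clustering_test(on_axis, n_boot = 50, seed = 12)
  expect_equal(unname(out2$near_axis_ci), c(1, 1))
  # isotropic positive-quadrant weights: 45/90 of angle mass is near-axis
  set.seed(13)
  th <- runif(4000, 0, pi / 2)
  iso <- list(w_memory = sin(th), w_preparation = cos(th))
  out3 <- axis_clustering_test(iso, n_boot = 100, seed = 14)
  expect_lt(abs(mean(out3$near_axis_boot) - 0.5), 0.05)
})

test_that("projection magnitude timecourse tracks subspace content", {
  t1 <- matrix(rnorm(8 * 4, sd = 3), 8)
  d <- toy_dataset(n_per_cond = 6, n_neurons = 8, n_cond = 4, t1 = t1)
  s <- build_subspace(t1)
  tc <- projection_magnitude_timecourse(d, s)
  expect_equal(max(tc$magnitude_norm), 1)
  d1_bins <- tc$time >= 800 & tc$time < 1300
  fix_bins <- tc$time < 0
  expect_gt(min(tc$magnitude[d1_bins]), 10 * max(tc$magnitude[fix_bins]))
  # activity orthogonal to the subspace projects to nothing
  northo <- null_space_projection(s)
  tco <- projection_magnitude_timecourse(d, northo)
  expect_lt(max(tco$magnitude[d1_bins]) / max(tc$magnitude[d1_bins]), 1e-8)
})

test_that("effective dimensionality counts the occupied components", {
  set.seed(15)
  flat <- matrix(rnorm(100 * 3), 100) %*% matrix(rnorm(3 * 9), 3) +
    rep(1, 100) %o% rnorm(9)
  expect_equal(effective_dimensionality(flat, 0.999), 3)
  iso <- matrix(rnorm(400 * 7), 400)
  expect_equal(effective_dimensionality(iso, 0.95), 7)
  # 7 equidistant condition means (regular simplex): mean-centred rank is 6
  # with equal spread along every direction
  centers <- 4 * (diag(7) - 1 / 7)
  trials <- centers[rep(1:7, each = 40), ] + matrix(rnorm(280 * 7, 0, 0.05), 280)
  expect_equal(effective_dimensionality(trials, 0.95), 6)
})

test_that("variance explained is a proper fraction with analytic cases", {
  set.seed(16)
  b <- qr.Q(qr(matrix(rnorm(20 * 3), 20)))
  inside <- matrix(rnorm(100 * 3), 100) %*% t(b)
  s <- build_subspace(b)
  expect_equal(variance_explained(inside, s), 1, tolerance = 1e-10)
  outside <- matrix(rnorm(100 * 17), 100) %*%
    t(null_space_projection(s)$basis)
  expect_lt(variance_explained(outside, s), 1e-10)
  iso <- matrix(rnorm(3000 * 20), 3000)
  expect_lt(abs(variance_explained(iso, s) - 3 / 20), 0.02)
  # complementary subspaces account for everything together
  expect_equal(variance_explained(iso, s) +
               variance_explained(iso, null_space_projection(s)), 1,
               tolerance = 1e-10)
  expect_error(variance_explained(matrix(1, 5, 20), s), "zero")
})

test_that("null space projection returns the orthogonal complement", {
  e <- diag(3)
  ns <- null_space_projection(build_subspace(e[, 1, drop = FALSE]))
  expect_equal(ns$d, 2)
  expect_lt(max(abs(crossprod(ns$basis, e[, 1]))), 1e-12)
  expect_error(null_space_projection(build_subspace(diag(3))), "empty")
})

test_that("element correlations flag shared structure with calibrated strength", {
  set.seed(17)
  e1 <- matrix(rnorm(226 * 7), 226)
  expect_equal(element_correlation(e1, 2 * e1)$r, 1)
  indep <- matrix(rnorm(226 * 7), 226)
  expect_lt(abs(element_correlation(e1, indep)$r), 0.06)
  # attenuation: E2 = 0.6 E1 + noise with total variance 1 gives r ~ 0.6
  e2 <- 0.6 * e1 + matrix(rnorm(226 * 7, 0, 0.8), 226)
  expect_lt(abs(element_correlation(e1, e2)$r - 0.6), 0.1)
  expect_error(element_correlation(e1 * 0, e1), "zero-variance")
})

test_that("per-cell tuning correlations separate shared-tuning populations", {
  set.seed(18)
  n <- 60
  ea <- matrix(rnorm(n * 7, sd = 2), n)
  # identical tuning: every cell significantly correlated
  out_same <- per_cell_tuning_correlation(ea, ea + matrix(rnorm(n * 7, 0, 0.1), n),
                                          n_shuffles = 100, seed = 19)
  expect_gt(out_same$fraction_significant, 0.95)
  # half the cells share tuning: fraction near one half, above the band
  eb <- matrix(rnorm(n * 7, sd = 2), n)
  eb[1:30, ] <- ea[1:30, ] + matrix(rnorm(30 * 7, 0, 0.3), 30)
  out_half <- per_cell_tuning_correlation(ea, eb, n_shuffles = 200, seed = 20)
  expect_lt(abs(out_half$fraction_significant - 0.5), 0.18)
  expect_gt(out_half$fraction_significant, out_half$chance_band[2])
  expect_error(per_cell_tuning_correlation(ea[, 1:2], eb[, 1:2]),
               "3 conditions")
})
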