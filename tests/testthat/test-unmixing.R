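test_that("Sturges' rule bin counts", {
  expect_equal(sturges_bins(1), 1L)
  expect_equal(sturges_bins(1000), 11L)   # ceil(1 + 9.97)
  expect_equal(sturges_bins(1582), 12L)   # ceil(1 + 10.63)
  expect_error(sturges_bins(0), "n >= 1")
})

test_that("histogram MI matches closed forms on discrete toys", {
  # uniform joint = product of marginals
  expect_equal(mutual_information(c(1, 1, 2, 2), c(1, 2, 1, 2)), 0)
  # identical two-level arrays: H(X) = 1 bit
  expect_equal(mutual_information(c(1, 1, 2, 2), c(1, 1, 2, 2)), 1)
  # four equiprobable levels falling in distinct bins: 2 bits
  x <- rep(1:4, each = 25)
  expect_equal(mutual_information(x, x), 2)
})

test_that("MI estimator is symmetric, scale-invariant and non-negative", {
  set.seed(8)
  x <- rnorm(300); y <- 0.5 * x + rnorm(300)
  expect_equal(mutual_information(x, y), mutual_information(y, x))
  expect_equal(mutual_information(2 * x + 3, y), mutual_information(x, y))
  expect_equal(mutual_information(x, -5 * y), mutual_information(x, y))
  for (i in 1:5) {
    a <- rnorm(100); b <- rnorm(100)
    expect_gte(mutual_information(a, b), 0)
  }
  expect_warning(mi0 <- mutual_information(rep(1, 10), rnorm(10)), "constant")
  expect_equal(mi0, 0)
  expect_error(mutual_information(1:3, 1:4), "equal length")
})

test_that("unmix_pair inverts the 2x2 mixing model", {
  set.seed(3)
  M <- matrix(rnorm(50), 10); P <- matrix(rnorm(50), 10)
  el <- unmix_pair(M + 0.12 * P, 0.65 * M + P, 0.12, 0.65)
  expect_equal(el$m, M, tolerance = 1e-12)
  expect_equal(el$p, P, tolerance = 1e-12)
  el0 <- unmix_pair(M, P, 0, 0)
  expect_equal(el0$m, M)
  expect_equal(el0$p, P)
  expect_error(unmix_pair(M, P, 2, 0.5), "singular")
})

test_that("remixing unmixed elements reproduces the inputs (100 draws)", {
  set.seed(4)
  d1 <- matrix(rnorm(60), 12); d2 <- matrix(rnorm(60), 12)
  for (i in 1:100) {
    repeat {
      a <- runif(1, -1, 1.5); b <- runif(1, -1, 1.5)
      if (abs(1 - a * b) > 0.05) break
    }
    el <- unmix_pair(d1, d2, a, b)
    r1 <- el$m + a * el$p
    r2 <- b * el$m + el$p
    expect_lt(sqrt(sum((r1 - d1)^2) / sum(d1^2)), 1e-12)
    expect_lt(sqrt(sum((r2 - d2)^2) / sum(d2^2)), 1e-12)
  }
})

test_that("MI minimization recovers planted mixing coefficients", {
  gt <- parametric_ground_truth(a = 0.2, b = 0.5, n_per_condition = 2)
  pd <- generate_parametric_dataset(gt, seed = 5)
  sol <- fit_mixing(pd$d1bar, pd$d2bar, n_restarts = 30, seed = 6)
  expect_lt(abs(sol$a - 0.2), 0.05)
  expect_lt(abs(sol$b - 0.5), 0.05)
  expect_lte(sol$mi_min, sol$mi_original)
  expect_true(sol$improved)
  expect_equal(nrow(sol$restarts), 31)    # grid seed + 30 random starts
  expect_equal(sol$a_round, round(sol$a, 2))
})

test_that("degenerate identical inputs yield no spurious unmixing", {
  set.seed(9)
  d1 <- matrix(rnorm(60), 12)
  sol <- fit_mixing(d1, d1, n_restarts = 10, seed = 10, grid_step = 0.25)
  expect_false(sol$improved)
  expect_equal(c(sol$a, sol$b), c(0, 0))
  expect_equal(sol$mi_min, sol$mi_original)
})

test_that("build_subspace returns an orthonormal basis of the column space", {
  set.seed(12)
  el <- matrix(rnorm(226 * 7), 226)
  s <- build_subspace(el)
  expect_equal(s$d, 7)
  expect_lt(max(abs(crossprod(s$basis) - diag(7))), 1e-10)
  # projector equality against an SVD oracle
  pr1 <- tcrossprod(s$basis)
  u <- svd(el)$u
  expect_lt(max(abs(pr1 - tcrossprod(u))), 1e-10)
  # rank detection on a rank-3 element with 7 columns
  low <- matrix(rnorm(60), 20, 3) %*% matrix(rnorm(21), 3, 7)
  expect_equal(build_subspace(low)$d, 3)
  expect_error(build_subspace(matrix(0, 5, 3)), "zero")
})

test_that("single-trial unmixing follows the label-matched algebra", {
  set.seed(14)
  k <- 4; n <- 8
  M <- matrix(rnorm(n * k), n); P <- matrix(rnorm(n * k), n)
  a <- 0.2; b <- 0.6
  labels <- rep(1:k, each = 3)
  D1 <- (M + a * P)[, labels]
  D2 <- (b * M + P)[, labels]
  st <- unmix_single_trials(D1, D2, M, P, a, b, labels)
  # noise-free condition-mean trials: M2 = b M[, c], P1 = a P[, c]
  expect_equal(st$m2, (b * M)[, labels], tolerance = 1e-12)
  expect_equal(st$p1, (a * P)[, labels], tolerance = 1e-12)
  expect_equal(st$m1, M[, labels], tolerance = 1e-12)
  expect_equal(st$p2, P[, labels], tolerance = 1e-12)
  # a = 0 leaves D1 untouched as the memory estimate
  st0 <- unmix_single_trials(D1, D2, M, P, 0, b, labels)
  expect_equal(st0$m1, D1)
  expect_error(unmix_single_trials(D1, D2, M, P, a, b, rep(9, ncol(D1))),
               "matching element column")
  # error-trial variant is the same algebra on the supplied activity
  ste <- unmix_error_trials(D1, D2, M, P, a, b, labels)
  expect_equal(ste$m2, st$m2)
})

test_that("pre-saccade unmixing recovers a preparation-like element", {
  set.seed(15)
  # skewed elements: MI identifies the coefficients (Gaussian ones do not)
  M <- matrix(rexp(226 * 7) - 1, 226); P <- matrix(rexp(226 * 7) - 1, 226)
  d1 <- M + 0.05 * P
  ds <- 0.7 * M + P + matrix(rnorm(226 * 7, 0, 0.1), 226)
  out <- unmix_presaccade(d1, ds, n_restarts = 20, seed = 16)
  expect_s3_class(out$solution, "mixing_solution")
  expect_gt(element_correlation(out$s, P)$r, 0.9)
  expect_gt(element_correlation(out$m_prime, M)$r, 0.9)
})

test_that("uncorrelated-label unmixing reduces to the paired model", {
  set.seed(17)
  k <- 5; n <- 120
  L <- matrix(rexp(n * k) - 1, n); C <- matrix(rexp(n * k) - 1, n)
  a <- 0.1; b <- 0.6
  # one-to-one mapping: joint counts on a permutation support
  perm <- c(2, 3, 4, 5, 1)
  J <- matrix(0, k, k); J[cbind(1:k, perm)] <- 10
  G1 <- L + a * C[, perm]
  G2 <- C + b * L[, order(perm)]
  out <- unmix_uncorrelated(G1, G2, J, n_restarts = 20, seed = 18)
  expect_false(out$skipped)
  expect_lt(abs(out$a - a), 0.07)
  expect_lt(abs(out$b - b), 0.07)
  pair <- unmix_pair(G1, G2[, perm], out$a, out$b)
  expect_lt(max(abs(out$l - pair$m)), 1e-6)
  expect_lt(max(abs(out$c[, perm] - pair$p)), 1e-6)
})

test_that("vanishing conditional expectations skip the optimization", {
  set.seed(19)
  n <- 30
  L <- matrix(rnorm(n * 2), n); L <- L - rowMeans(L)
  C <- matrix(rnorm(n * 3), n); C <- C - rowMeans(C)
  J <- matrix(6, 2, 3)          # fully crossed, uniform
  out <- unmix_uncorrelated(L, C, J)
  expect_true(out$skipped)
  expect_equal(out$l, L)
  expect_equal(out$c, C)
  expect_error(unmix_uncorrelated(L, C, matrix(c(1, 0, 0, 0, 0, 0), 2, 3)),
               "non-overlapping")
})

test_that("Gram-Schmidt subspaces are exactly orthogonal", {
  set.seed(20)
  d1 <- matrix(rnorm(40 * 4), 40)
  d2 <- matrix(rnorm(40 * 4), 40)
  gs <- gram_schmidt_subspaces(d1, d2)
  ang <- principal_angles(gs$first, gs$second)
  expect_true(all(abs(ang - 90) < 1e-8))
  # already-orthogonal D2 spans itself
  q <- qr.Q(qr(cbind(gs$first$basis, matrix(rnorm(40 * 4), 40))))
  d2o <- q[, 5:8] %*% matrix(rnorm(16), 4)
  gs2 <- gram_schmidt_subspaces(d1, d2o)
  expect_lt(max(principal_angles(gs2$second, build_subspace(d2o))), 1e-5)
  expect_error(gram_schmidt_subspaces(d1, d1 %*% matrix(rnorm(16), 4)),
               "inside")
})

test_that("memory and preparation span all decodable condition structure", {
  # the orthogonal complement of span(M, P) annihilates both delay matrices
  gt <- parametric_ground_truth(n_per_condition = 2)
  pd <- generate_parametric_dataset(gt, seed = 21)
  el <- unmix_pair(pd$d1bar, pd$d2bar, 0.3, 0.4)   # any non-singular pair
  ns <- null_space_projection(list(build_subspace(el$m),
                                   build_subspace(el$p)))
  r1 <- sqrt(sum(crossprod(ns$basis, unclass(pd$d1bar))^2) /
             sum(unclass(pd$d1bar)^2))
  r2 <- sqrt(sum(crossprod(ns$basis, unclass(pd$d2bar))^2) /
             sum(unclass(pd$d2bar)^2))
  expect_lt(r1, 1e-8)
  expect_lt(r2, 1e-8)
})
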