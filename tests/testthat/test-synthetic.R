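test_that("activation is the stated piecewise function, continuous at knots", {
  expect_equal(phi(-0.5), 0)
  expect_equal(phi(0.5), 0.25)
  expect_equal(phi(1), 1)                      # x^2 branch at the knot
  expect_equal(phi(1 + 1e-12, upper = "linear"), 1, tolerance = 1e-9)
  expect_equal(phi(1 + 1e-12, upper = "sqrt"), 1, tolerance = 1e-9)
  expect_equal(phi(2, upper = "linear"), 5)
  expect_equal(phi(2, upper = "sqrt"), sqrt(5))
  expect_equal(phi(0), 0)
  m <- phi(matrix(c(-1, 0.5, 3), 1))
  expect_equal(dim(m), c(1L, 3L))
})

test_that("divisive normalization restores the baseline mean exactly", {
  expect_equal(divisive_normalize(c(2, 4), 1), c(2 / 3, 4 / 3))
  expect_equal(mean(divisive_normalize(c(2, 4), 1)), 1)
  r <- matrix(runif(40, 0.1, 3), 8)
  rn <- divisive_normalize(r, 0.7)
  expect_equal(colMeans(rn), rep(0.7, 5))
  expect_error(divisive_normalize(c(0, 0), 1), "zero")
})

test_that("one attractor step preserves fixed points and the population mean", {
  cfg <- attractor_config(noise_sd = 0, normalize = FALSE)
  W <- matrix(0, 4, 4)
  # r = 0 is a fixed point of the noise-free dynamics
  expect_equal(step_attractor(rep(0, 4), W, 0, cfg, r0_mean = 1), rep(0, 4))
  # with normalization on, the mean returns to mean(r0) to machine precision
  cfgN <- attractor_config(noise_sd = 0, normalize = TRUE)
  r <- c(0.1, 0.5, 0.9, 0.2)
  r1 <- step_attractor(r, diag(4) * 0.3, rep(0.2, 4), cfgN, r0_mean = 0.4)
  expect_equal(mean(r1), 0.4, tolerance = 1e-14)
})

test_that("bump attractor without input or normalization decays to rest", {
  cfg <- attractor_config(noise_sd = 0, normalize = FALSE)
  W <- mdsubspace:::ring_kernel(80, cfg$w_plus, cfg$w_minus, cfg$half_width)
  r <- rep(cfg$baseline_rate, 80)
  for (i in 1:400) r <- step_attractor(r, W, 0, cfg, r0_mean = 1)
  expect_lt(max(r), 1e-3)
})

test_that("bump attractor population size follows the overlap ratio", {
  set.seed(1)
  n0 <- mdsubspace:::build_attractor_network(attractor_config(overlap_ratio = 0))$n
  n1 <- mdsubspace:::build_attractor_network(attractor_config(overlap_ratio = 1))$n
  nh <- mdsubspace:::build_attractor_network(attractor_config(overlap_ratio = 0.5))$n
  expect_equal(n0, 160)
  expect_equal(n1, 80)
  expect_equal(nh, 120)
})

test_that("bump simulator is deterministic and satisfies dataset invariants", {
  cfg <- attractor_config()
  d1 <- simulate_bump_attractor(cfg, 2, seed = 9)
  d2 <- simulate_bump_attractor(cfg, 2, seed = 9)
  expect_identical(d1$counts, d2$counts)
  expect_identical(d1$trials, d2$trials)
  expect_s3_class(validate_dataset(d1), "population_dataset")
  expect_true(all(d1$trials$distractor_location != d1$trials$target_location))
})

test_that("divisive normalization pins the population-mean rate in every bin", {
  cfg <- attractor_config(output = "rates")
  d <- simulate_bump_attractor(cfg, 2, seed = 9)
  pm <- apply(d$counts, c(1, 3), mean)    # trial x bin population means
  expect_lt(max(abs(pm - cfg$baseline_rate)), 1e-10)
})

test_that("a localized input ignites a bump that stays put through the delays", {
  cfg <- attractor_config(output = "rates", noise_sd = 0.03)
  d <- simulate_bump_attractor(cfg, 1, seed = 9)
  net <- attr(d, "network")
  left <- d$t_start + (seq_len(dim(d$counts)[3]) - 1) * d$bin_width
  mem <- d$counts[1, net$mem_idx, ]
  loading <- which(net$win_mem[net$mem_idx, d$trials$target_location[1]] > 0)
  ring_dist <- function(i, j, n = 80) pmin(abs(i - j), n - abs(i - j))
  d1_bins <- which(left >= 800 & left < 1300)
  d2_bins <- which(left >= 2000 & left < 2500)
  peak_d1 <- which.max(rowMeans(mem[, d1_bins]))
  expect_lte(min(ring_dist(peak_d1, loading)), 2)
  # peak drifts by at most 2 units across the second delay
  peaks <- vapply(d2_bins, function(b) which.max(mem[, b]), integer(1))
  expect_lte(max(ring_dist(peaks, peak_d1)), 2)
  # the memory bump persists, and the preparation ring carries a bump at
  # its (target-linked) loading in the second delay; any Delay-1 activity
  # in the preparation ring is a noise-positioned spontaneous bump, so only
  # the Delay-2 bump is checked against the input loading
  h1 <- max(rowMeans(mem[, d1_bins]))
  h2 <- max(rowMeans(mem[, d2_bins]))
  expect_gt(h2, 0.3 * h1)
  prep <- d$counts[1, net$prep_idx, ]
  loading_p <- which(net$win_prep[net$prep_idx,
                                  d$trials$target_location[1]] > 0)
  peak_p <- which.max(rowMeans(prep[, d2_bins]))
  expect_lte(min(ring_dist(peak_p, loading_p)), 2)
})

test_that("linear network has exactly 17 unit eigenvalues", {
  set.seed(4)
  net <- make_linear_network(linear_model_config())
  ev <- eigen(net$W, only.values = TRUE)$values
  expect_equal(sum(abs(ev - 1) < 1e-6), 17)
  expect_true(all(Re(ev) < 1 + 1e-6))
})

test_that("unit-eigenvalue directions persist after input offset", {
  cfg <- linear_model_config(noise_sd = 0, normalize = FALSE)
  d <- simulate_linear_model(cfg, 1, seed = 6)
  net <- attr(d, "network")
  left <- d$t_start + (seq_len(dim(d$counts)[3]) - 1) * d$bin_width
  r <- d$counts[1, , ]
  # projection of the state onto the trial's memory eigenvector, via the
  # dual basis rows of Q^-1
  dual <- solve(net$Q)
  coef_mem <- dual[net$memory_cols[d$trials$target_location[1]], ] %*% r
  d1_bins <- which(left >= 800 & left < 1300)
  d2_bins <- which(left >= 2000 & left < 2500)
  c1 <- mean(coef_mem[d1_bins]); c2 <- mean(coef_mem[d2_bins])
  expect_gt(abs(c1), 0.1)                 # input deposited a component
  expect_lt(abs(c2 - c1) / abs(c1), 0.02) # and it persisted
})

test_that("normalization makes memory decoding decrease from Delay 1 to 2", {
  cfg <- linear_model_config(noise_sd = 0.05)
  d <- simulate_linear_model(cfg, 30, seed = 6)
  net <- attr(d, "network")
  # decode in the generative memory subspace (known eigenvectors)
  sub <- build_subspace(net$Q[, net$memory_cols])
  bins <- c(mdsubspace:::bins_in_window(d, c(800, 1300)),
            mdsubspace:::bins_in_window(d, c(2000, 2500)))
  g <- cross_temporal_decode(d, sub, bins = bins, n_per_condition = 50,
                             n_repeats = 2, seed = 7)
  a1 <- grid_window_mean(g, "delay1")
  a2 <- grid_window_mean(g, "delay2")
  expect_gt(a1, 100 / 8 + chance_ci(400, 8))
  expect_lt(a2, a1)
})

test_that("parametric generator realises the mixing model exactly", {
  gt <- parametric_ground_truth(n_neurons = 30, n_conditions = 5,
                                a = 0.3, b = 0.6, noise_sd = 0,
                                n_per_condition = 4)
  pd <- generate_parametric_dataset(gt, seed = 2)
  expect_lt(max(abs(unclass(pd$d1bar) - (pd$truth$M + 0.3 * pd$truth$P))),
            1e-12)
  expect_lt(max(abs(unclass(pd$d2bar) - (0.6 * pd$truth$M + pd$truth$P))),
            1e-12)
  # zero noise: single trials sit exactly on the condition means
  expect_equal(pd$pseudo_d1$train[, 1], unclass(pd$d1bar)[, 1],
               ignore_attr = TRUE)

  gt0 <- parametric_ground_truth(n_neurons = 10, n_conditions = 3,
                                 a = 0, b = 0, noise_sd = 0,
                                 n_per_condition = 2)
  pd0 <- generate_parametric_dataset(gt0, seed = 3)
  expect_lt(max(abs(unclass(pd0$d1bar) - pd0$truth$M)), 1e-12)
  expect_lt(max(abs(unclass(pd0$d2bar) - pd0$truth$P)), 1e-12)
  expect_error(parametric_ground_truth(a = 2, b = 0.5), "singular")
})
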