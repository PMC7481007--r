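# Shared synthetic fixtures, built in code at test time.

# A small rate-mode recording on the task timeline (31 bins of 100 ms from
# -500 to 2600 ms). `t1` / `t2` are neurons x conditions tuning matrices
# injected over the Delay 1 (800-1300 ms) and late-delay (2000-2600 ms)
# windows on top of a constant baseline rate.
toy_dataset <- function(n_per_cond = 8, n_neurons = 12, n_cond = 4,
                        base = 5, t1 = NULL, t2 = NULL, td = NULL,
                        noise_sd = 0, seed = 1, n_error_per_cond = 0,
                        saccade = NA_real_, unit = "rate") {
  set.seed(seed)
  if (is.null(t1)) t1 <- matrix(0, n_neurons, n_cond)
  if (is.null(t2)) t2 <- matrix(0, n_neurons, n_cond)
  if (is.null(td)) td <- matrix(0, n_neurons, n_cond)
  n_tr <- (n_per_cond + n_error_per_cond) * n_cond
  tgt <- rep(seq_len(n_cond), each = n_per_cond + n_error_per_cond)
  outcome <- rep(c(rep("correct", n_per_cond), rep("error", n_error_per_cond)),
                 n_cond)
  nb <- 31L
  t_start <- -500
  counts <- array(base, dim = c(n_tr, n_neurons, nb))
  left <- t_start + (seq_len(nb) - 1L) * 100
  b_d1 <- which(left >= 800 & left < 1300)
  b_d2 <- which(left >= 2000 & left < 2600)
  b_dis <- which(left >= 1300 & left < 1600)
  dis <- (tgt %% n_cond) + 1L
  for (k in seq_len(n_tr)) {
    counts[k, , b_d1] <- counts[k, , b_d1] + t1[, tgt[k]]
    counts[k, , b_d2] <- counts[k, , b_d2] + t2[, tgt[k]]
    counts[k, , b_dis] <- counts[k, , b_dis] + td[, dis[k]]
  }
  if (noise_sd > 0)
    counts <- counts + array(rnorm(length(counts), 0, noise_sd), dim(counts))
  trials <- data.frame(
    trial_id = seq_len(n_tr), session_id = 1L,
    target_location = tgt, distractor_location = dis,
    outcome = outcome, saccade_onset_ms = saccade)
  population_dataset(counts, 100, t_start, trials, unit = unit)
}

# Rate-mode dataset realising the parametric mixing model on the task
# timeline: Delay-1 bins carry (M + aP)[, c] + noise, late-delay bins carry
# (bM + P)[, c] + noise, fixation at baseline 0.
mixing_dataset <- function(gt, seed = 1, base = 0) {
  set.seed(seed)
  n <- gt$n_neurons; k <- gt$n_conditions
  M <- matrix(rnorm(n * k), n, k)
  P <- matrix(rnorm(n * k), n, k)
  d <- toy_dataset(n_per_cond = gt$n_per_condition, n_neurons = n,
                   n_cond = k, base = base,
                   t1 = M + gt$a * P, t2 = gt$b * M + P,
                   noise_sd = 0, seed = seed + 1)
  # per-trial noise, constant within each delay window (trial-level noise,
  # not bin-level), as the mixing model assumes
  nb <- dim(d$counts)[3]
  left <- d$t_start + (seq_len(nb) - 1L) * 100
  b_d1 <- which(left >= 800 & left < 1300)
  b_d2 <- which(left >= 2000 & left < 2600)
  for (k2 in seq_len(dim(d$counts)[1])) {
    d$counts[k2, , b_d1] <- d$counts[k2, , b_d1] +
      rnorm(n, 0, gt$noise_sd)
    d$counts[k2, , b_d2] <- d$counts[k2, , b_d2] +
      rnorm(n, 0, gt$noise_sd)
  }
  attr(d, "truth") <- list(M = M, P = P, a = gt$a, b = gt$b)
  d
}

# chance band half-width (percentage points) for an accuracy estimated from
# n trials at chance level p, z standard errors wide
chance_ci <- function(n, n_classes, z = 3) {
  p <- 1 / n_classes
  100 * z * sqrt(p * (1 - p) / n)
}
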