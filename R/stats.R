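#' Bootstrap-overlap p-value
#'
#' Estimated p-value `(1 + X) / (N + 1)` for the comparison of two
#' bootstrap distributions of equal length `N`, where `X` counts the
#' overlapping points. With the default `"extremes"` rule and the higher
#' distribution called `dist1`, `X` is the number of `dist1` points at or
#' below `max(dist2)` plus the number of `dist2` points at or above
#' `min(dist1)` (capped at `N`); distributions with no overlap therefore
#' give `p = 1/(N+1) < 0.001` at `N = 1000`, and an overlap of `x%` of the
#' points gives `p ~ x/100`. A threshold-free `"paired"` variant counts the
#' fraction of index-paired draws whose order reverses.
#'
#' @param dist1,dist2 equal-length bootstrap distributions.
#' @param method `"extremes"` (default) or `"paired"`.
#' @return p-value in (0, 1], with the overlap count `X` and the counting
#'   rule attached as attributes.
#' @export
bootstrap_pvalue <- function(dist1, dist2, method = c("extremes", "paired")) {
  method <- match.arg(method)
  n <- length(dist1)
  if (n == 0 || length(dist2) != n)
    stop("dist1 and dist2 must be non-empty and of equal length")
  if (mean(dist1) < mean(dist2)) { tmp <- dist1; dist1 <- dist2; dist2 <- tmp }
  x <- if (method == "extremes")
    sum(dist1 <= max(dist2)) + sum(dist2 >= min(dist1))
  else
    sum(dist1 <= dist2)
  x <- min(x, n)
  structure((1 + x) / (n + 1), overlap = x, method = method)
}

#' Hedges' g effect size
#'
#' Bias-corrected standardised mean difference:
#' `g = (1 - 3 / (4 (n1 + n2) - 9)) * (mean1 - mean2) / s'` with
#' `s' = sqrt(((n1-1) s1^2 + (n2-1) s2^2) / (n1 + n2 - 2))` the pooled SD.
#'
#' @param dist1,dist2 numeric samples (each of length >= 2).
#' @return Hedges' g (antisymmetric in its arguments, scale-invariant).
#' @export
hedges_g <- function(dist1, dist2) {
  n1 <- length(dist1); n2 <- length(dist2)
  if (n1 < 2 || n2 < 2) stop("need at least 2 points per sample")
  s_pooled <- sqrt(((n1 - 1) * stats::var(dist1) +
                    (n2 - 1) * stats::var(dist2)) / (n1 + n2 - 2))
  if (s_pooled == 0) stop("zero pooled variance")
  (1 - 3 / (4 * (n1 + n2) - 9)) * (mean(dist1) - mean(dist2)) / s_pooled
}

#' ANOVA-based selectivity classification of neurons
#'
#' Per neuron, trial-mean firing rates in the two selectivity windows
#' (Delay 1: 800-1300 ms; Delay 2: 2100-2600 ms) enter a two-way ANOVA with
#' factors target location x task epoch (type-II sums of squares), plus two
#' one-way location ANOVAs (one per delay). Classes, applied in order of
#' precedence at level `alpha`:
#' \describe{
#'   \item{pure_preparation}{one-way location effect significant in Delay 2
#'     but not in Delay 1 (tuning appears only after the distractor; takes
#'     precedence because such cells also trip the two-way interaction).}
#'   \item{mixed}{significant location and epoch main effects and a
#'     significant interaction (tuning changes between the delays).}
#'   \item{pure_memory}{significant location main effect without an
#'     interaction (stable tuning, with or without an epoch offset).}
#'   \item{none}{everything else.}
#' }
#'
#' @param data a `population_dataset` (correct trials are used).
#' @param alpha significance level (0.05).
#' @param epochs epoch list supplying `selectivity_delay1` and
#'   `selectivity_delay2`.
#' @return data.frame with one row per neuron: `class`, `p_location`,
#'   `p_epoch`, `p_interaction`, `p_delay1`, `p_delay2`.
#' @export
classify_selectivity <- function(data, alpha = 0.05,
                                 epochs = default_epochs()) {
  tr <- select_trials(data, "correct")
  loc <- factor(data$trials$target_location[tr])
  if (min(table(loc)) < 2)
    stop("every location needs at least 2 correct trials")
  r1 <- window_mean_rate(data, "selectivity_delay1", epochs, tr)
  r2 <- window_mean_rate(data, "selectivity_delay2", epochs, tr)
  n_neurons <- dim(data$counts)[2]
  out <- data.frame(neuron = seq_len(n_neurons), class = NA_character_,
                    p_location = NA_real_, p_epoch = NA_real_,
                    p_interaction = NA_real_, p_delay1 = NA_real_,
                    p_delay2 = NA_real_)
  epoch_f <- factor(rep(c("delay1", "delay2"), each = length(tr)))
  loc2 <- rep(loc, 2)
  for (ni in seq_len(n_neurons)) {
    y <- c(r1[, ni], r2[, ni])
    p <- if (stats::sd(y) == 0) c(1, 1, 1) else {
      aa <- car::Anova(stats::lm(y ~ loc2 * epoch_f), type = 2)
      aa[["Pr(>F)"]][1:3]
    }
    p1 <- if (stats::sd(r1[, ni]) == 0) 1 else
      stats::anova(stats::lm(r1[, ni] ~ loc))[["Pr(>F)"]][1]
    p2 <- if (stats::sd(r2[, ni]) == 0) 1 else
      stats::anova(stats::lm(r2[, ni] ~ loc))[["Pr(>F)"]][1]
    cls <- if (p2 < alpha && p1 >= alpha) "pure_preparation"
    else if (p[1] < alpha && p[2] < alpha && p[3] < alpha) "mixed"
    else if (p[1] < alpha && p[3] >= alpha) "pure_memory"
    else "none"
    out[ni, -1] <- list(cls, p[1], p[2], p[3], p1, p2)
  }
  out
}

#' Shuffle-null significance of an arbitrary statistic
#'
#' Computes the observed statistic, re-computes it on `n_shuffles` permuted
#' copies of the data, and reports the observed value's percentile in the
#' null distribution (significance at the 95th percentile, one-sided, by
#' convention). Built-in schemes permute the label vector
#' (`scheme = "labels"`, permutes `data$labels`) or the row assignment of a
#' matrix (`scheme = "rows"`, permutes rows of `data$y`); any other design
#' is expressed through `shuffle_fn`.
#'
#' @param statistic function of `data` returning a scalar.
#' @param data a list holding whatever `statistic` needs.
#' @param n_shuffles permutations (1000 by default).
#' @param scheme `"labels"` or `"rows"` (ignored when `shuffle_fn` given).
#' @param seed integer seed.
#' @param shuffle_fn optional `function(data)` returning a permuted copy.
#' @return list with `observed`, `null`, `percentile`, `significant`
#'   (observed above the 95th percentile).
#' @export
shuffle_null <- function(statistic, data, n_shuffles = 1000,
                         scheme = c("labels", "rows"), seed = NULL,
                         shuffle_fn = NULL) {
  scheme <- match.arg(scheme)
  if (is.null(shuffle_fn)) {
    shuffle_fn <- switch(scheme,
      labels = function(d) { d$labels <- sample(d$labels); d },
      rows = function(d) { d$y <- d$y[sample.int(nrow(d$y)), , drop = FALSE]; d })
  }
  obs <- statistic(data)
  if (!is.null(seed)) set.seed(seed)
  null <- vapply(seq_len(n_shuffles), function(i)
    statistic(shuffle_fn(data)), numeric(1))
  pct <- 100 * mean(null < obs)
  list(observed = obs, null = null, percentile = pct,
       significant = obs > stats::quantile(null, 0.95))
}
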