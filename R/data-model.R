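#' Default task epoch windows
#'
#' Named half-open intervals `[start, end)` in milliseconds relative to target
#' onset, matching the delayed-saccade-with-distractor task: 500 ms fixation,
#' 300 ms target, 1000 ms Delay 1, 300 ms distractor, 1000 ms Delay 2.
#' Two Delay-2 conventions coexist deliberately: `delay2` (2000--2500 ms) is
#' used for the unmixing analysis while `selectivity_delay2` (2100--2600 ms)
#' is used for the ANOVA selectivity classification; both are kept as named
#' windows so each analysis uses its own. `pre_saccade` is relative to
#' saccade onset rather than target onset.
#'
#' @return A named list of numeric `c(start, end)` pairs (ms). Windows whose
#'   name appears in the `"saccade_relative"` attribute are interpreted
#'   relative to each trial's saccade onset.
#' @export
default_epochs <- function() {
  ep <- list(
    fixation           = c(-300, 0),
    target             = c(0, 300),
    delay1             = c(800, 1300),
    distractor         = c(1300, 1600),
    delay2             = c(2000, 2500),
    selectivity_delay1 = c(800, 1300),
    selectivity_delay2 = c(2100, 2600),
    pre_saccade        = c(-150, 0)
  )
  attr(ep, "saccade_relative") <- "pre_saccade"
  ep
}

#' Construct a binned population recording
#'
#' The universal input container: a trials x neurons x time-bins tensor of
#' spike counts (or firing rates, for rate-mode simulator output) plus a
#' per-trial metadata table.
#'
#' @param counts numeric array `[trials, neurons, bins]`, spikes per bin
#'   (non-negative integers) or rates in model units when `unit = "rate"`.
#' @param bin_width bin width in ms (> 0).
#' @param t_start time (ms, relative to target onset) of the left edge of the
#'   first bin.
#' @param trials data.frame with columns `trial_id`, `session_id`,
#'   `target_location`, `distractor_location`, `outcome` ("correct"/"error"),
#'   `saccade_onset_ms` (NA allowed).
#' @param t0_event label of the event at time 0; default `"target_onset"`.
#' @param unit `"count"` (default) or `"rate"`; rate-mode data skip the
#'   integer/non-negativity check (linear-model rates may dip below zero
#'   under noise).
#' @param distractor_offset_ms end of the distractor epoch, used to validate
#'   saccade onsets; default 1600.
#' @return An object of class `population_dataset`.
#' @export
population_dataset <- function(counts, bin_width, t_start, trials,
                               t0_event = "target_onset",
                               unit = c("count", "rate"),
                               distractor_offset_ms = 1600) {
  unit <- match.arg(unit)
  stopifnot(is.array(counts), length(dim(counts)) == 3)
  x <- structure(
    list(counts = counts, bin_width = bin_width, t_start = t_start,
         trials = as.data.frame(trials), t0_event = t0_event, unit = unit,
         distractor_offset_ms = distractor_offset_ms),
    class = "population_dataset")
  validate_dataset(x)
}

#' Validate a population dataset against its invariants
#'
#' Checks shape agreement between the count tensor and the trial table,
#' non-negativity of counts (count mode), distractor != target on every
#' trial, positive bin width, and saccade onsets later than distractor
#' offset. Errors name the offending trial.
#'
#' @param x a `population_dataset`.
#' @return `x`, invisibly usable, after passing all checks.
#' @export
validate_dataset <- function(x) {
  stopifnot(inherits(x, "population_dataset"))
  d <- dim(x$counts)
  need <- c("trial_id", "session_id", "target_location",
            "distractor_location", "outcome", "saccade_onset_ms")
  miss <- setdiff(need, names(x$trials))
  if (length(miss) > 0)
    stop("trial table is missing column(s): ", paste(miss, collapse = ", "))
  if (nrow(x$trials) != d[1])
    stop("shape mismatch: counts has ", d[1], " trials but trial table has ",
         nrow(x$trials), " rows")
  if (!is.numeric(x$bin_width) || x$bin_width <= 0)
    stop("bin_width must be > 0")
  if (x$unit == "count" && any(x$counts < 0))
    stop("counts must be non-negative")
  bad <- which(x$trials$distractor_location == x$trials$target_location)
  if (length(bad) > 0)
    stop("distractor_location equals target_location on trial ", bad[1])
  so <- x$trials$saccade_onset_ms
  bad <- which(!is.na(so) & so <= x$distractor_offset_ms)
  if (length(bad) > 0)
    stop("saccade_onset_ms precedes distractor offset on trial ", bad[1])
  x
}

#' @export
print.population_dataset <- function(x, ...) {
  d <- dim(x$counts)
  cat(sprintf(
    "population_dataset: %d trials x %d neurons x %d bins (%g ms bins, t0 = %s, %s mode)\n",
    d[1], d[2], d[3], x$bin_width, x$t0_event, x$unit))
  cat(sprintf("  correct: %d, error: %d; target locations: %s\n",
              sum(x$trials$outcome == "correct"),
              sum(x$trials$outcome == "error"),
              paste(sort(unique(x$trials$target_location)), collapse = " ")))
  invisible(x)
}

#' Write a population dataset to a plain-text dataset directory
#'
#' The on-disk format is a directory holding `counts.csv` (one row per
#' trial/neuron, one column per bin), `trials.csv`, and `meta.yaml`.
#' Integer counts round-trip bit-exactly.
#'
#' @param x a `population_dataset`.
#' @param path directory to create/overwrite.
#' @return `path`, invisibly.
#' @seealso [read_dataset()]
#' @export
write_dataset <- function(x, path) {
  stopifnot(inherits(x, "population_dataset"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  d <- dim(x$counts)
  flat <- matrix(aperm(x$counts, c(3, 2, 1)), nrow = d[1] * d[2], byrow = TRUE)
  dt <- data.table::data.table(
    trial = rep(seq_len(d[1]), each = d[2]),
    neuron = rep(seq_len(d[2]), times = d[1]))
  dt <- cbind(dt, data.table::as.data.table(flat))
  data.table::setnames(dt, c("trial", "neuron", paste0("b", seq_len(d[3]))))
  data.table::fwrite(dt, file.path(path, "counts.csv"))
  data.table::fwrite(x$trials, file.path(path, "trials.csv"))
  yaml::write_yaml(
    list(bin_width_ms = x$bin_width, t_start_ms = x$t_start,
         t0_event = x$t0_event, unit = x$unit,
         distractor_offset_ms = x$distractor_offset_ms,
         n_trials = d[1], n_neurons = d[2], n_bins = d[3]),
    file.path(path, "meta.yaml"))
  invisible(path)
}

#' Read a population dataset from a dataset directory
#'
#' Reads the layout written by [write_dataset()] and validates every
#' container invariant; malformed files (missing members, shape mismatches,
#' distractor == target) raise errors naming the offending member or trial.
#'
#' @param path dataset directory.
#' @return a validated `population_dataset`.
#' @export
read_dataset <- function(path) {
  need <- c("counts.csv", "trials.csv", "meta.yaml")
  have <- file.exists(file.path(path, need))
  if (!all(have))
    stop("dataset directory is missing: ",
         paste(need[!have], collapse = ", "))
  meta <- yaml::read_yaml(file.path(path, "meta.yaml"))
  dt <- data.table::fread(file.path(path, "counts.csv"))
  trials <- as.data.frame(data.table::fread(file.path(path, "trials.csv"),
                                            na.strings = c("NA", "")))
  nb <- meta$n_bins
  if (ncol(dt) != nb + 2L)
    stop("counts.csv has ", ncol(dt) - 2L, " bins; meta.yaml declares ", nb)
  if (nrow(dt) != meta$n_trials * meta$n_neurons)
    stop("counts.csv has ", nrow(dt), " rows; expected ",
         meta$n_trials * meta$n_neurons)
  data.table::setorderv(dt, c("trial", "neuron"))
  flat <- as.matrix(dt[, -(1:2)])
  counts <- aperm(array(t(flat), dim = c(nb, meta$n_neurons, meta$n_trials)),
                  c(3, 2, 1))
  if (meta$unit == "count") storage.mode(counts) <- "integer"
  population_dataset(counts, meta$bin_width_ms, meta$t_start_ms, trials,
                     t0_event = meta$t0_event, unit = meta$unit,
                     distractor_offset_ms = meta$distractor_offset_ms)
}

# bin indices fully inside [start, end) given the dataset's bin grid;
# edges: bin i covers [t_start + (i-1)*bw, t_start + i*bw)
bins_in_window <- function(x, window) {
  bw <- x$bin_width
  nb <- dim(x$counts)[3]
  left <- x$t_start + (seq_len(nb) - 1L) * bw
  idx <- which(left >= window[1] - 1e-9 & left + bw <= window[2] + 1e-9)
  if (length(idx) == 0)
    stop("window [", window[1], ", ", window[2],
         ") contains no complete time bin")
  idx
}

#' Time-bin indices covered by an epoch window
#'
#' Returns the indices of the dataset's time bins lying fully inside the
#' (target-onset-relative) window; useful for restricting decoding grids to
#' the delay epochs.
#'
#' @param x a `population_dataset`.
#' @param window epoch name or numeric `c(start, end)` in ms.
#' @param epochs epoch list; default [default_epochs()].
#' @return integer vector of bin indices.
#' @export
window_bins <- function(x, window, epochs = default_epochs()) {
  bins_in_window(x, resolve_window(epochs, window))
}

resolve_window <- function(epochs, name) {
  if (is.numeric(name) && length(name) == 2) return(name)
  if (!name %in% names(epochs)) stop("unknown epoch window: ", name)
  epochs[[name]]
}

is_saccade_relative <- function(epochs, name) {
  is.character(name) && name %in% attr(epochs, "saccade_relative")
}

# rate tensor slice averaged over the bins of `window` -> trials x neurons.
# For saccade-relative windows the bin set differs per trial.
window_mean_rate <- function(x, window, epochs, trial_idx = NULL) {
  if (is.null(trial_idx)) trial_idx <- seq_len(dim(x$counts)[1])
  scale <- if (x$unit == "count") 1000 / x$bin_width else 1
  if (is_saccade_relative(epochs, window)) {
    w <- resolve_window(epochs, window)
    so <- x$trials$saccade_onset_ms[trial_idx]
    if (anyNA(so))
      stop("saccade_onset_ms missing for a trial in a saccade-relative window")
    out <- matrix(NA_real_, length(trial_idx), dim(x$counts)[2])
    for (k in seq_along(trial_idx)) {
      idx <- bins_in_window(x, w + so[k])
      out[k, ] <- rowMeans(matrix(x$counts[trial_idx[k], , idx],
                                  nrow = dim(x$counts)[2])) * scale
    }
    return(out)
  }
  idx <- bins_in_window(x, resolve_window(epochs, window))
  sl <- x$counts[trial_idx, , idx, drop = FALSE]
  apply(sl, c(1, 2), mean) * scale
}

select_trials <- function(x, outcome) {
  switch(outcome,
         correct = which(x$trials$outcome == "correct"),
         error   = which(x$trials$outcome == "error"),
         all     = seq_len(nrow(x$trials)),
         stop("outcome must be 'correct', 'error' or 'all'"))
}

#' Baseline-subtracted condition-mean activity matrix
#'
#' Builds a neurons x conditions matrix: entry `(i, c)` is neuron `i`'s mean
#' firing rate over the trials of condition `c` and the bins of `window`,
#' minus the neuron's mean rate over the `baseline` bins across all selected
#' trials (baseline normalization to the pre-target fixation level).
#' Rates are spikes/s for count data.
#'
#' @param x a `population_dataset`.
#' @param window epoch name (see [default_epochs()]) or numeric `c(start,end)`.
#' @param baseline epoch name for the baseline, or `NULL` to skip subtraction.
#' @param group_by `"target"` or `"distractor"`: which location label defines
#'   the conditions.
#' @param outcome `"correct"` (default), `"error"`, or `"all"`.
#' @param epochs epoch window list; default [default_epochs()].
#' @return a `condition_matrix`: a numeric matrix with attributes
#'   `condition_labels` and `epoch`.
#' @export
condition_matrix <- function(x, window, baseline = "fixation",
                             group_by = c("target", "distractor"),
                             outcome = "correct", epochs = default_epochs()) {
  group_by <- match.arg(group_by)
  tr <- select_trials(x, outcome)
  lab <- if (group_by == "target") x$trials$target_location[tr] else
    x$trials$distractor_location[tr]
  conds <- sort(unique(if (group_by == "target") x$trials$target_location else
    x$trials$distractor_location))
  zero <- conds[!conds %in% lab]
  if (length(zero) > 0)
    stop("condition(s) with zero ", outcome, " trials: ",
         paste(zero, collapse = ", "))
  rate <- window_mean_rate(x, window, epochs, tr)
  base <- if (is.null(baseline)) 0 else
    colMeans(window_mean_rate(x, baseline, epochs, tr))
  vals <- vapply(conds, function(cc) {
    colMeans(rate[lab == cc, , drop = FALSE]) - base
  }, numeric(dim(x$counts)[2]))
  structure(vals, condition_labels = conds,
            epoch = if (is.character(window)) window else "custom",
            class = c("condition_matrix", class(vals)))
}

#' @export
print.condition_matrix <- function(x, ...) {
  cat(sprintf("condition_matrix (%s): %d neurons x %d conditions\n",
              attr(x, "epoch"), nrow(x), ncol(x)))
  invisible(x)
}

# Sample per-neuron, per-condition trial indices for a pseudo-population:
# each neuron's trial pool for a condition is split at random into two
# disjoint halves (train / test sources); n draws per condition come from
# each half, with replacement whenever the half is smaller than n.
pseudopop_indices <- function(x, n_per_condition,
                              group_by = "target", outcome = "correct") {
  tr <- select_trials(x, outcome)
  all_lab <- if (group_by == "target") x$trials$target_location else
    x$trials$distractor_location
  lab <- all_lab[tr]
  conds <- sort(unique(all_lab))
  n_neurons <- dim(x$counts)[2]
  npt <- n_per_condition * length(conds)
  train <- matrix(NA_integer_, n_neurons, npt)
  test <- matrix(NA_integer_, n_neurons, npt)
  labels <- rep(conds, each = n_per_condition)
  for (ci in seq_along(conds)) {
    pool <- tr[lab == conds[ci]]
    if (length(pool) < 2)
      stop("need at least 2 ", outcome, " trials per condition; condition ",
           conds[ci], " has ", length(pool))
    cols <- (ci - 1L) * n_per_condition + seq_len(n_per_condition)
    for (ni in seq_len(n_neurons)) {
      sh <- sample(pool)
      half <- length(sh) %/% 2
      a <- sh[seq_len(half)]
      b <- sh[(half + 1L):length(sh)]
      train[ni, cols] <- sample(a, n_per_condition,
                                replace = length(a) < n_per_condition)
      test[ni, cols] <- sample(b, n_per_condition,
                               replace = length(b) < n_per_condition)
    }
  }
  list(train = train, test = test, labels = labels, conds = conds)
}

# Materialise a neurons x pseudo-trials matrix from sampled indices for a
# fixed set of time bins (rate - per-neuron baseline).
pseudopop_matrix <- function(x, idx_mat, bins, baseline_vec) {
  scale <- if (x$unit == "count") 1000 / x$bin_width else 1
  n_neurons <- dim(x$counts)[2]
  sl <- x$counts[, , bins, drop = FALSE]
  m <- if (length(bins) > 1) apply(sl, c(1, 2), mean) else sl[, , 1]
  m <- m * scale
  out <- matrix(NA_real_, n_neurons, ncol(idx_mat))
  for (ni in seq_len(n_neurons))
    out[ni, ] <- m[idx_mat[ni, ], ni] - baseline_vec[ni]
  out
}

neuron_baseline <- function(x, epochs, baseline = "fixation",
                            outcome = "correct") {
  if (is.null(baseline)) return(rep(0, dim(x$counts)[2]))
  colMeans(window_mean_rate(x, baseline, epochs, select_trials(x, outcome)))
}

#' Build a pseudo-population for one epoch window
#'
#' Neurons are treated as independently sampled: for every neuron and
#' condition, one source trial is drawn per pseudo-trial, with the train and
#' test splits drawn from disjoint halves of that neuron's trial pool.
#' Source-trial indices are retained so the disjointness is testable.
#'
#' @inheritParams condition_matrix
#' @param n_per_condition pseudo-trials per condition in each split.
#' @param seed optional integer seed for reproducible sampling.
#' @return a `pseudo_population`: list with `train`, `test`
#'   (neurons x pseudo-trials, baseline-subtracted rates), `labels`,
#'   `n_per_condition`, and provenance index matrices `train_idx`, `test_idx`.
#' @export
build_pseudopopulation <- function(x, window, n_per_condition,
                                   seed = NULL, baseline = "fixation",
                                   group_by = c("target", "distractor"),
                                   outcome = "correct",
                                   epochs = default_epochs()) {
  group_by <- match.arg(group_by)
  if (!is.null(seed)) set.seed(seed)
  idx <- pseudopop_indices(x, n_per_condition, group_by, outcome)
  bins <- bins_in_window(x, resolve_window(epochs, window))
  base <- neuron_baseline(x, epochs, baseline,
                          if (outcome == "error") "correct" else outcome)
  structure(
    list(train = pseudopop_matrix(x, idx$train, bins, base),
         test = pseudopop_matrix(x, idx$test, bins, base),
         labels = idx$labels, n_per_condition = n_per_condition,
         conditions = idx$conds,
         train_idx = idx$train, test_idx = idx$test),
    class = "pseudo_population")
}

#' @export
print.pseudo_population <- function(x, ...) {
  cat(sprintf(
    "pseudo_population: %d neurons x %d pseudo-trials (%d conditions x %d)\n",
    nrow(x$train), ncol(x$train), length(x$conditions), x$n_per_condition))
  invisible(x)
}
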