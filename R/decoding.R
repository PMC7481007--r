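#' PCA denoising of a train/test pair
#'
#' Principal components are computed on the training matrix alone; both
#' matrices are reconstructed in the original neuron space from the minimal
#' number of leading components whose cumulative variance reaches
#' `var_threshold`. The test matrix is centred and reconstructed with the
#' training means and components (no test leakage).
#'
#' @param train,test neurons x samples matrices (pseudo-trials in columns).
#' @param var_threshold cumulative variance threshold in (0, 1].
#' @return list with `train`, `test` (reconstructed, original space),
#'   `n_components`, `rotation` (neurons x k), `center`.
#' @export
pca_denoise <- function(train, test, var_threshold = 0.95) {
  if (ncol(train) < 2) stop("need at least 2 training samples")
  ctr <- rowMeans(train)
  xc <- t(train - ctr)
  s <- svd(xc, nu = 0)
  var_frac <- cumsum(s$d^2) / sum(s$d^2)
  k <- which(var_frac >= var_threshold - 1e-12)[1]
  V <- s$v[, seq_len(k), drop = FALSE]
  proj <- function(m) {
    sc <- crossprod(m - ctr, V)            # samples x k
    V %*% t(sc) + ctr
  }
  list(train = proj(train), test = proj(test), n_components = k,
       rotation = V, center = ctr)
}

#' Train a pooled-covariance linear discriminant classifier
#'
#' Standard LDA: class means, a pooled within-class covariance shared by all
#' classes, priors from class frequencies, and linear discriminant scores
#' `x' S^-1 mu_c - mu_c' S^-1 mu_c / 2 + log pi_c`. A ridge term
#' `ridge * trace(S)/p` is added to the pooled covariance; the
#' high-dimensional pseudo-population regime is near-singular without it.
#'
#' @param x samples x features matrix.
#' @param labels class label per row (>= 2 classes, >= 2 samples each).
#' @param ridge relative ridge strength (0 disables regularization).
#' @return an `lda_classifier`.
#' @export
lda_train <- function(x, labels, ridge = 1e-6) {
  x <- as.matrix(x)
  labels <- as.vector(labels)
  cls <- sort(unique(labels))
  if (length(cls) < 2) stop("need at least 2 classes")
  counts <- table(factor(labels, levels = cls))
  if (any(counts < 2)) stop("every class needs at least 2 samples")
  p <- ncol(x)
  means <- t(vapply(cls, function(cc)
    colMeans(x[labels == cc, , drop = FALSE]), numeric(p)))
  S <- matrix(0, p, p)
  for (i in seq_along(cls)) {
    xc <- sweep(x[labels == cls[i], , drop = FALSE], 2, means[i, ])
    S <- S + crossprod(xc)
  }
  S <- S / (nrow(x) - length(cls))
  if (ridge > 0) S <- S + diag(ridge * sum(diag(S)) / p, p)
  Sinv <- tryCatch(solve(S), error = function(e)
    stop("pooled covariance is singular; use a positive ridge"))
  W <- Sinv %*% t(means)                       # p x k
  const <- -0.5 * colSums(t(means) * W) + log(as.numeric(counts) / nrow(x))
  structure(list(classes = cls, W = W, const = const),
            class = "lda_classifier")
}

#' Predict classes with a fitted linear discriminant
#'
#' @param classifier an `lda_classifier` from [lda_train()].
#' @param x samples x features matrix.
#' @return predicted class label per row.
#' @export
lda_predict <- function(classifier, x) {
  scores <- as.matrix(x) %*% classifier$W +
    rep(classifier$const, each = nrow(as.matrix(x)))
  classifier$classes[max.col(scores, ties.method = "first")]
}

project_samples <- function(mat, projection, train_ref = NULL) {
  # mat: neurons x samples -> samples x dims for the classifier
  if (is.null(projection)) t(mat) else crossprod(mat, as_basis(projection))
}

#' Cross-temporal population decoding
#'
#' Trains a linear discriminant at each training time bin and tests it at
#' every test bin. Per repeat, a fresh pseudo-population is sampled (train
#' and test splits from disjoint source trials per neuron). In the full
#' space (`projection = NULL`) the training bin is PCA-denoised at
#' `var_threshold` and the classifier operates on the training-bin component
#' scores; with a `subspace` projection both splits are projected onto the
#' subspace basis instead.
#'
#' @param data a `population_dataset`.
#' @param projection `NULL` (full space) or a `subspace`.
#' @param bins integer bin indices forming the time grid (default: all bins).
#' @param n_per_condition pseudo-trials per condition per split.
#' @param n_repeats pseudo-population resamples averaged into the grid.
#' @param seed integer seed.
#' @param labels decode `"target"` or `"distractor"` location.
#' @param var_threshold PCA variance threshold for full-space decoding.
#' @param ridge LDA ridge strength.
#' @param baseline,epochs baseline window and epoch list (see
#'   [condition_matrix()]).
#' @param outcome trial set to decode (default correct trials).
#' @return a `decoding_grid`: `accuracy` (train-bin x test-bin, %),
#'   `times` (bin left edges, ms), `n_classes`, `per_repeat` array.
#' @export
cross_temporal_decode <- function(data, projection = NULL, bins = NULL,
                                  n_per_condition = 100, n_repeats = 10,
                                  seed = NULL,
                                  labels = c("target", "distractor"),
                                  var_threshold = 0.95, ridge = 1e-6,
                                  baseline = "fixation",
                                  epochs = default_epochs(),
                                  outcome = "correct") {
  labels <- match.arg(labels)
  if (!is.null(seed)) set.seed(seed)
  nb <- dim(data$counts)[3]
  if (is.null(bins)) bins <- seq_len(nb)
  if (length(bins) == 0) stop("empty bin grid")
  times <- data$t_start + (bins - 1) * data$bin_width
  n_bins <- length(bins)
  base <- neuron_baseline(data, epochs, baseline)
  acc <- array(NA_real_, dim = c(n_repeats, n_bins, n_bins))
  for (rep_i in seq_len(n_repeats)) {
    idx <- pseudopop_indices(data, n_per_condition, labels, outcome)
    Xtr <- lapply(bins, function(b) pseudopop_matrix(data, idx$train, b, base))
    Xte <- lapply(bins, function(b) pseudopop_matrix(data, idx$test, b, base))
    y <- idx$labels
    for (t1 in seq_len(n_bins)) {
      if (is.null(projection)) {
        pc <- pca_denoise(Xtr[[t1]], Xtr[[t1]], var_threshold)
        tr <- crossprod(Xtr[[t1]] - pc$center, pc$rotation)
        clf <- lda_train(tr, y, ridge)
        for (t2 in seq_len(n_bins)) {
          te <- crossprod(Xte[[t2]] - pc$center, pc$rotation)
          acc[rep_i, t1, t2] <- 100 * mean(lda_predict(clf, te) == y)
        }
      } else {
        B <- as_basis(projection)
        clf <- lda_train(crossprod(Xtr[[t1]], B), y, ridge)
        for (t2 in seq_len(n_bins)) {
          acc[rep_i, t1, t2] <-
            100 * mean(lda_predict(clf, crossprod(Xte[[t2]], B)) == y)
        }
      }
    }
  }
  grid <- apply(acc, c(2, 3), mean)
  dimnames(grid) <- list(train = times, test = times)
  structure(list(accuracy = grid, times = times,
                 n_classes = length(unique(
                   if (labels == "target") data$trials$target_location
                   else data$trials$distractor_location)),
                 n_repeats = n_repeats, per_repeat = acc,
                 labels = labels),
            class = "decoding_grid")
}

#' @export
print.decoding_grid <- function(x, ...) {
  cat(sprintf(
    "decoding_grid (%s): %d x %d bins, %d classes (chance %.1f%%), %d repeats\n",
    x$labels, nrow(x$accuracy), ncol(x$accuracy), x$n_classes,
    100 / x$n_classes, x$n_repeats))
  cat(sprintf("  diagonal accuracy %.1f%% (mean), grid mean %.1f%%\n",
              mean(diag(x$accuracy)), mean(x$accuracy)))
  invisible(x)
}

#' Mean accuracy of a decoding grid within a train/test window pair
#'
#' Averages grid cells whose train bin lies in `train_window` and test bin
#' in `test_window` (the scalar "Delay 1 accuracy"-style summaries).
#'
#' @param grid a `decoding_grid`.
#' @param train_window,test_window epoch names or `c(start, end)` ms;
#'   `test_window` defaults to `train_window`.
#' @param epochs epoch list.
#' @return mean accuracy in percent.
#' @export
grid_window_mean <- function(grid, train_window, test_window = train_window,
                             epochs = default_epochs()) {
  tw <- resolve_window(epochs, train_window)
  sw <- resolve_window(epochs, test_window)
  bw <- diff(grid$times[1:2])
  tr <- grid$times >= tw[1] - 1e-9 & grid$times + bw <= tw[2] + 1e-9
  te <- grid$times >= sw[1] - 1e-9 & grid$times + bw <= sw[2] + 1e-9
  if (!any(tr) || !any(te)) stop("window contains no grid bins")
  mean(grid$accuracy[tr, te])
}

#' Cross-temporal decoding of distractor location
#'
#' [cross_temporal_decode()] with trials grouped by distractor rather than
#' target labels.
#'
#' @inheritParams cross_temporal_decode
#' @param ... passed to [cross_temporal_decode()].
#' @export
decode_distractor <- function(data, projection = NULL, ...) {
  cross_temporal_decode(data, projection = projection,
                        labels = "distractor", ...)
}

#' Decode error-trial activity with a correct-trial classifier
#'
#' Fits the discriminant on projected correct-trial training activity and
#' reports accuracy on projected error-trial activity (plus the held-out
#' correct-trial accuracy for reference). Conditions with no error trials
#' are dropped from the error average with a warning.
#'
#' @param correct a `pseudo_population` (or list with `train`, `test`,
#'   `labels`) of correct-trial activity.
#' @param error a `pseudo_population`, or a list with `test` (neurons x
#'   trials) and `labels`, of error-trial activity.
#' @param projection a `subspace` (or `NULL` for the full space).
#' @param ridge LDA ridge strength.
#' @return list with `accuracy_error`, `accuracy_correct` (held-out), and
#'   `n_error_trials`.
#' @export
decode_error_trials <- function(correct, error, projection, ridge = 1e-6) {
  err_mat <- if (!is.null(error$test)) error$test else error$train
  err_lab <- error$labels
  keep <- err_lab %in% unique(correct$labels)
  dropped <- setdiff(unique(correct$labels), unique(err_lab))
  if (length(dropped) > 0)
    warning("condition(s) with no error trials dropped: ",
            paste(dropped, collapse = ", "))
  clf <- lda_train(project_samples(correct$train, projection),
                   correct$labels, ridge)
  pr_err <- lda_predict(clf, project_samples(
    err_mat[, keep, drop = FALSE], projection))
  pr_cor <- lda_predict(clf, project_samples(correct$test, projection))
  list(accuracy_error = 100 * mean(pr_err == err_lab[keep]),
       accuracy_correct = 100 * mean(pr_cor == correct$labels),
       n_error_trials = sum(keep))
}
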