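#' Principal angles between two subspaces
#'
#' SVD of the product of the two orthonormal bases: the angles are the
#' inverse cosines of the singular values (clamped to [0, 1] against
#' floating-point overshoot), reported in degrees in ascending order, so the
#' leading angles indicate overall alignment.
#'
#' @param x,y `subspace` objects or matrices with orthonormal columns
#'   (checked; non-orthonormal input errors).
#' @return numeric vector of `min(dx, dy)` angles in degrees, ascending.
#' @export
principal_angles <- function(x, y) {
  bx <- as_basis(x); by <- as_basis(y)
  s <- svd(crossprod(bx, by), nu = 0, nv = 0)$d
  s <- pmin(pmax(s, 0), 1)
  sort(acos(s) * 180 / pi)
}

#' Null distribution of principal angles against random subspaces
#'
#' Samples principal angles between a fixed subspace and random subspaces
#' (orthonormalised standard-Gaussian matrices) of a given dimension,
#' yielding one chance distribution per angle rank. An observed angle below
#' the 5th percentile of its per-rank null is "significantly closer than
#' chance".
#'
#' @param ambient_dim dimension of the full space.
#' @param fixed a `subspace` (the one compared against).
#' @param d_random dimension of the random subspaces (<= `ambient_dim`).
#' @param n number of random subspaces (1000 by default).
#' @param seed integer seed.
#' @return an `n x min(d_fixed, d_random)` matrix of angles (degrees).
#' @export
random_subspace_null <- function(ambient_dim, fixed, d_random, n = 1000,
                                 seed = NULL) {
  if (d_random > ambient_dim) stop("d_random exceeds ambient_dim")
  if (!is.null(seed)) set.seed(seed)
  bf <- as_basis(fixed)
  if (nrow(bf) != ambient_dim) stop("fixed subspace has wrong ambient dim")
  k <- min(ncol(bf), d_random)
  out <- vapply(seq_len(n), function(i) {
    z <- matrix(stats::rnorm(ambient_dim * d_random), ambient_dim)
    principal_angles(qr.Q(qr(z)), bf)
  }, numeric(k))
  if (k == 1) matrix(out, ncol = 1) else t(out)
}

#' Significance of observed principal angles against the random-subspace null
#'
#' @param observed angles (degrees, ascending) from [principal_angles()].
#' @param null matrix from [random_subspace_null()] with matching rank count.
#' @param prob percentile defining "closer than chance" (default 0.05).
#' @return logical vector: is each observed angle below its per-rank null
#'   percentile.
#' @export
angles_below_chance <- function(observed, null, prob = 0.05) {
  stopifnot(length(observed) == ncol(null))
  observed < apply(null, 2, stats::quantile, probs = prob)
}

pairwise_dist_mean <- function(m) {
  # m: points x dims
  if (nrow(m) < 2) return(NA_real_)
  mean(stats::dist(m))
}

#' Inter-to-intra cluster distance ratio
#'
#' A state-space signal-to-noise measure: the grand mean of pairwise
#' Euclidean distances between cluster (condition) means, divided by the
#' grand mean over clusters of the mean pairwise within-cluster distance.
#' A bootstrap (resampling `n_per_cluster` points per cluster with
#' replacement) yields the ratio distribution summarised by its 5th-95th
#' percentiles.
#'
#' @param points points x dims matrix (e.g. projected single trials).
#' @param labels cluster (condition) label per row; >= 2 clusters with
#'   >= 2 points each.
#' @param n_boot bootstrap resamples (1000 by default).
#' @param n_per_cluster points drawn per cluster per resample (250).
#' @param seed integer seed.
#' @return a `cluster_metrics` list: point estimates `inter`, `intra`,
#'   `ratio`; bootstrap vector `boot_ratio`; `ci` (5th/95th percentiles).
#' @export
inter_intra_ratio <- function(points, labels, n_boot = 1000,
                              n_per_cluster = 250, seed = NULL) {
  points <- as.matrix(points)
  labels <- as.vector(labels)
  cls <- sort(unique(labels))
  if (length(cls) < 2) stop("need at least 2 clusters")
  idx <- lapply(cls, function(cc) which(labels == cc))
  if (any(lengths(idx) < 2))
    stop("intra-cluster distance undefined: a cluster has fewer than 2 points")
  compute <- function(ii) {
    means <- t(vapply(ii, function(i)
      colMeans(points[i, , drop = FALSE]), numeric(ncol(points))))
    inter <- pairwise_dist_mean(means)
    intra <- mean(vapply(ii, function(i)
      pairwise_dist_mean(points[i, , drop = FALSE]), numeric(1)))
    c(inter = inter, intra = intra)
  }
  pt <- compute(idx)
  if (pt["intra"] == 0)
    stop("intra-cluster distance is zero; ratio undefined")
  if (!is.null(seed)) set.seed(seed)
  boot <- vapply(seq_len(n_boot), function(i) {
    ii <- lapply(idx, function(p) sample(p, n_per_cluster, replace = TRUE))
    v <- compute(ii)
    v["inter"] / v["intra"]
  }, numeric(1))
  structure(list(inter = unname(pt["inter"]), intra = unname(pt["intra"]),
                 ratio = unname(pt["inter"] / pt["intra"]),
                 boot_ratio = boot,
                 ci = stats::quantile(boot, c(0.05, 0.95))),
            class = "cluster_metrics")
}

#' @export
print.cluster_metrics <- function(x, ...) {
  cat(sprintf(
    "cluster_metrics: inter %.3f / intra %.3f = ratio %.3f [boot 5-95%%: %.3f, %.3f]\n",
    x$inter, x$intra, x$ratio, x$ci[1], x$ci[2]))
  invisible(x)
}

#' Per-neuron loading weights in two subspaces
#'
#' The loading weight of neuron `i` in a subspace is the norm of the
#' projection of its standard basis vector, i.e. the Euclidean norm of row
#' `i` of the orthonormal basis (always in [0, 1]; the squared weights sum
#' to the subspace dimension). Also computes the across-neuron weight
#' correlation with a permutation null, and flags "exclusive" neurons whose
#' log weight ratio lies more than `sd_mult` standard deviations from the
#' mean.
#'
#' @param memory,preparation `subspace` objects with equal ambient dimension.
#' @param n_perm shuffles for the correlation null (1000).
#' @param seed integer seed.
#' @param sd_mult exclusivity cut in SDs of the log weight ratio (2).
#' @return a `loading_weights` list: `w_memory`, `w_preparation`,
#'   `log_ratio`, `exclusive_memory`/`exclusive_preparation` (logical),
#'   `correlation`, `perm_null`, `null_q95`, `significant`.
#' @export
loading_weights <- function(memory, preparation, n_perm = 1000,
                            seed = NULL, sd_mult = 2) {
  bm <- as_basis(memory); bp <- as_basis(preparation)
  if (nrow(bm) != nrow(bp)) stop("subspaces have different ambient dims")
  wm <- sqrt(rowSums(bm^2))
  wp <- sqrt(rowSums(bp^2))
  lr <- log((wm + 1e-12) / (wp + 1e-12))
  excl_m <- lr > mean(lr) + sd_mult * stats::sd(lr)
  excl_p <- lr < mean(lr) - sd_mult * stats::sd(lr)
  r <- stats::cor(wm, wp)
  if (!is.null(seed)) set.seed(seed)
  null <- vapply(seq_len(n_perm), function(i)
    stats::cor(wm, sample(wp)), numeric(1))
  q95 <- stats::quantile(null, 0.95)
  structure(list(w_memory = wm, w_preparation = wp, log_ratio = lr,
                 exclusive_memory = excl_m, exclusive_preparation = excl_p,
                 correlation = r, perm_null = null, null_q95 = unname(q95),
                 significant = r > q95),
            class = "loading_weights")
}

#' @export
print.loading_weights <- function(x, ...) {
  cat(sprintf(
    "loading_weights: %d neurons; correlation %.3f (perm 95th %.3f%s); %d exclusive\n",
    length(x$w_memory), x$correlation, x$null_q95,
    if (x$significant) ", significant" else "",
    sum(x$exclusive_memory) + sum(x$exclusive_preparation)))
  invisible(x)
}

#' Bootstrap test for axis clustering of loading weights
#'
#' Each neuron's weight pair defines an angle `atan2(w_memory,
#' w_preparation)` in [0, 90] degrees. Per bootstrap, a random
#' `exclusion` fraction of neurons is dropped and the fraction of remaining
#' neurons near an axis (angle above 67.5 or below 22.5 degrees) is
#' computed; the 5th-95th percentile intervals of both the near-axis and
#' off-axis fractions are returned.
#'
#' @param weights a `loading_weights` object (or list with `w_memory`,
#'   `w_preparation`).
#' @param n_boot bootstraps (1000). @param exclusion dropped fraction (0.10).
#' @param seed integer seed.
#' @param cut axis cut in degrees from each axis (22.5).
#' @return list with `near_axis_ci`, `off_axis_ci` (5th/95th percentiles),
#'   and the bootstrap vectors.
#' @export
axis_clustering_test <- function(weights, n_boot = 1000, exclusion = 0.10,
                                 seed = NULL, cut = 22.5) {
  wm <- weights$w_memory; wp <- weights$w_preparation
  n <- length(wm)
  if (n < 10) stop("need at least 10 neurons")
  ang <- atan2(wm, wp) * 180 / pi
  if (!is.null(seed)) set.seed(seed)
  keep_n <- n - floor(exclusion * n)
  near <- vapply(seq_len(n_boot), function(i) {
    a <- ang[sample.int(n, keep_n)]
    mean(a > 90 - cut | a < cut)
  }, numeric(1))
  list(near_axis_ci = stats::quantile(near, c(0.05, 0.95)),
       off_axis_ci = stats::quantile(1 - near, c(0.05, 0.95)),
       near_axis_boot = near)
}

#' Projection-magnitude time course of condition-mean activity
#'
#' For every time bin, the baseline-subtracted, trial-averaged neurons x
#' conditions activity matrix is projected onto the subspace and its
#' Frobenius norm recorded; the trace is also returned normalised to a
#' maximum of 1.
#'
#' @param data a `population_dataset`.
#' @param subspace a `subspace`.
#' @param bins bin indices (default all).
#' @param baseline,group_by,outcome,epochs see [condition_matrix()].
#' @return data.frame with `time` (bin left edge, ms), `magnitude`,
#'   `magnitude_norm`.
#' @export
projection_magnitude_timecourse <- function(data, subspace, bins = NULL,
                                            baseline = "fixation",
                                            group_by = "target",
                                            outcome = "correct",
                                            epochs = default_epochs()) {
  B <- as_basis(subspace)
  nb <- dim(data$counts)[3]
  if (is.null(bins)) bins <- seq_len(nb)
  bw <- data$bin_width
  mag <- vapply(bins, function(b) {
    w <- data$t_start + c((b - 1) * bw, b * bw)
    cm <- condition_matrix(data, w, baseline = baseline,
                           group_by = group_by, outcome = outcome,
                           epochs = epochs)
    sqrt(sum(crossprod(B, unclass(cm))^2))
  }, numeric(1))
  data.frame(time = data$t_start + (bins - 1) * bw, magnitude = mag,
             magnitude_norm = mag / max(mag))
}

#' Effective dimensionality of projected single trials
#'
#' PCA on the projected single-trial activity; the effective dimensionality
#' is the smallest number of components whose cumulative variance reaches
#' the threshold.
#'
#' @param x samples x dims matrix (e.g. single trials projected into a
#'   subspace).
#' @param threshold cumulative variance threshold (0.95).
#' @return integer component count.
#' @export
effective_dimensionality <- function(x, threshold = 0.95) {
  x <- as.matrix(x)
  if (nrow(x) < 2) stop("need at least 2 samples")
  xc <- sweep(x, 2, colMeans(x))
  d <- svd(xc, nu = 0, nv = 0)$d
  v <- cumsum(d^2) / sum(d^2)
  as.integer(which(v >= threshold - 1e-12)[1])
}

#' Fraction of variance captured by a subspace
#'
#' Mean-centres the samples and returns the ratio of the variance of the
#' projection onto the subspace to the total variance.
#'
#' @param x samples x neurons matrix of single-trial activity.
#' @param subspace a `subspace`.
#' @return fraction in [0, 1].
#' @export
variance_explained <- function(x, subspace) {
  B <- as_basis(subspace)
  x <- as.matrix(x)
  xc <- sweep(x, 2, colMeans(x))
  tot <- sum(xc^2)
  if (tot == 0) stop("zero total variance")
  sum((xc %*% B)^2) / tot
}

#' Orthogonal complement of a set of subspaces
#'
#' Orthonormal basis of the null space of the union span. The condition
#' means of the two delay matrices collapse to (near-)zero there: all
#' linearly decodable condition information in the time-averaged data lives
#' inside the union of the memory and preparation subspaces.
#'
#' @param subspaces a `subspace` or list of them (equal ambient dims).
#' @return a `subspace` labelled `"null"`.
#' @export
null_space_projection <- function(subspaces) {
  if (inherits(subspaces, "subspace")) subspaces <- list(subspaces)
  B <- do.call(cbind, lapply(subspaces, as_basis))
  n <- nrow(B)
  s <- svd(B, nu = n)
  r <- sum(s$d > 1e-10 * s$d[1])
  if (r >= n) stop("the union span fills the ambient space; complement empty")
  structure(list(basis = s$u[, (r + 1):n, drop = FALSE], d = n - r,
                 label = "null"),
            class = "subspace")
}

#' Correlation between two flattened elements
#'
#' Pearson correlation of the two matrices flattened to 1-D, with its
#' standard p-value.
#'
#' @param e1,e2 matrices of equal shape.
#' @return list with `r`, `p`.
#' @export
element_correlation <- function(e1, e2) {
  v1 <- as.vector(unclass(e1)); v2 <- as.vector(unclass(e2))
  if (length(v1) != length(v2)) stop("elements must have equal shapes")
  if (stats::sd(v1) == 0 || stats::sd(v2) == 0)
    stop("zero-variance element")
  ct <- stats::cor.test(v1, v2)
  list(r = unname(ct$estimate), p = ct$p.value)
}

#' Per-cell tuning correlation between two elements with a shuffle null
#'
#' For each (selective) cell, the Pearson correlation between its condition
#' tuning in the two elements; reports the fraction of cells significant at
#' `alpha` and a chance band obtained by shuffling the second element's
#' tuning across cells.
#'
#' @param e_a,e_b neurons x conditions matrices (equal shapes, >= 3
#'   conditions).
#' @param cells indices of cells to analyse (default all).
#' @param n_shuffles cross-cell tuning shuffles for the chance band (1000).
#' @param seed integer seed.
#' @param alpha per-cell significance level (0.05).
#' @return list with `fraction_significant`, `n_significant`, `n_cells`,
#'   `chance_band` (5th/95th percentiles), `null_fractions`.
#' @export
per_cell_tuning_correlation <- function(e_a, e_b, cells = NULL,
                                        n_shuffles = 1000, seed = NULL,
                                        alpha = 0.05) {
  a <- as.matrix(unclass(e_a)); b <- as.matrix(unclass(e_b))
  if (!all(dim(a) == dim(b))) stop("elements must have equal shapes")
  if (ncol(a) < 3) stop("need at least 3 conditions")
  if (is.null(cells)) cells <- seq_len(nrow(a))
  sig_frac <- function(bm) {
    mean(vapply(cells, function(i) {
      if (stats::sd(a[i, ]) == 0 || stats::sd(bm[i, ]) == 0) return(FALSE)
      stats::cor.test(a[i, ], bm[i, ])$p.value < alpha
    }, logical(1)))
  }
  obs <- sig_frac(b)
  if (!is.null(seed)) set.seed(seed)
  null <- vapply(seq_len(n_shuffles), function(s)
    sig_frac(b[sample.int(nrow(b)), , drop = FALSE]), numeric(1))
  list(fraction_significant = obs,
       n_significant = round(obs * length(cells)),
       n_cells = length(cells),
       chance_band = stats::quantile(null, c(0.05, 0.95)),
       null_fractions = null)
}
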