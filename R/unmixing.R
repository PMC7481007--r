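#' Sturges' rule bin count
#'
#' `ceil(1 + log2(n))`: a conservative bin count that keeps every histogram
#' bin populated for the sample sizes used here (a flattened neurons x
#' conditions element has `n = 1582` points in the reference geometry,
#' giving 12 bins).
#'
#' @param n sample count (>= 1).
#' @return integer number of bins.
#' @export
sturges_bins <- function(n) {
  if (any(n < 1)) stop("sturges_bins requires n >= 1")
  as.integer(ceiling(1 + log2(n)))
}

bin_index <- function(x, n_bins, breaks = NULL) {
  if (is.null(breaks)) {
    lo <- min(x)
    w <- (max(x) - lo) / n_bins
    pmin.int(pmax.int(floor((x - lo) / w) + 1L, 1L), n_bins)
  } else {
    findInterval(x, breaks, all.inside = TRUE)
  }
}

#' Histogram mutual information in bits
#'
#' Discretizes each array into [sturges_bins()] equal-width bins over its own
#' min-max range (so the estimate is invariant to affine rescaling of either
#' argument), forms the joint 2-D histogram, and returns
#' `sum p(x,y) log2( p(x,y) / (p(x) p(y)) )` over the non-empty cells.
#' A constant input has zero range; its MI is defined as 0 with a warning.
#'
#' @param x,y numeric vectors of equal length (>= 2).
#' @param binning `"width"` (equal-width, default) or `"frequency"`
#'   (equal-frequency quantile bins).
#' @param n_bins optional override of the Sturges bin count.
#' @return mutual information in bits (>= 0 up to floating point).
#' @export
mutual_information <- function(x, y, binning = c("width", "frequency"),
                               n_bins = NULL) {
  binning <- match.arg(binning)
  x <- as.vector(x); y <- as.vector(y)
  n <- length(x)
  if (length(y) != n || n < 2)
    stop("x and y must have equal length >= 2")
  if (!all(is.finite(x)) || !all(is.finite(y)))
    stop("inputs must be finite")
  if (diff(range(x)) == 0 || diff(range(y)) == 0) {
    warning("constant input: mutual information defined as 0")
    return(0)
  }
  if (is.null(n_bins)) n_bins <- sturges_bins(n)
  if (binning == "width") {
    ix <- bin_index(x, n_bins)
    iy <- bin_index(y, n_bins)
  } else {
    qx <- unique(stats::quantile(x, probs = seq(0, 1, length.out = n_bins + 1)))
    qy <- unique(stats::quantile(y, probs = seq(0, 1, length.out = n_bins + 1)))
    ix <- findInterval(x, qx, all.inside = TRUE)
    iy <- findInterval(y, qy, all.inside = TRUE)
    n_bins <- max(length(qx), length(qy))
  }
  joint <- tabulate((iy - 1L) * n_bins + ix, nbins = n_bins * n_bins) / n
  dim(joint) <- c(n_bins, n_bins)
  px <- rowSums(joint)
  py <- colSums(joint)
  nz <- joint > 0
  sum(joint[nz] * log2(joint[nz] / outer(px, py)[nz]))
}

#' Solve the 2x2 mixing model for the unmixed elements
#'
#' Inverts `D1 = M + a P`, `D2 = b M + P` element-wise:
#' `M = (D1 - a D2) / (1 - a b)`, `P = (D2 - b D1) / (1 - a b)`. The
#' diagonal of the mixing matrix is stipulated to be identity, so `a` is the
#' fraction of preparation activity present in Delay 1 and `b` the fraction
#' of memory activity persisting into Delay 2.
#'
#' @param d1bar,d2bar matrices of identical shape (neurons x conditions).
#' @param a,b mixing coefficients with `a * b != 1`.
#' @return list with elements `m` and `p` (same shape as the inputs).
#' @export
unmix_pair <- function(d1bar, d2bar, a, b) {
  if (!all(dim(as.matrix(d1bar)) == dim(as.matrix(d2bar))))
    stop("d1bar and d2bar must have identical shapes")
  det <- 1 - a * b
  if (abs(det) < 1e-12)
    stop("singular mixing: a * b = 1")
  m <- (unclass(d1bar) - a * unclass(d2bar)) / det
  p <- (unclass(d2bar) - b * unclass(d1bar)) / det
  list(m = m, p = p)
}

mi_objective <- function(d1vec, d2vec, bounds, binning) {
  force(d1vec); force(d2vec)
  function(ab) {
    a <- ab[1]; b <- ab[2]
    if (a < bounds[1] || a > bounds[2] || b < bounds[1] || b > bounds[2])
      return(1e6)
    det <- 1 - a * b
    if (abs(det) < 1e-3) return(1e6)
    m <- (d1vec - a * d2vec) / det
    p <- (d2vec - b * d1vec) / det
    if (diff(range(m)) == 0 || diff(range(p)) == 0) return(1e6)
    mutual_information(m, p, binning = binning)
  }
}

#' Fit the mixing coefficients by mutual-information minimization
#'
#' Flattens the two condition matrices and searches for the `(a, b)` whose
#' unmixed elements have the least histogram mutual information. Because the
#' histogram objective is piecewise constant, each of the `n_restarts`
#' randomly initialised Nelder-Mead refinements is seeded from within the
#' bounds, and one additional start comes from a coarse grid scan; the
#' singular curve `a b = 1` and the box bounds are enforced by penalty.
#' Restart spreads are reported both over all restarts and over the restarts
#' that reached within `restart_tol` bits of the optimum.
#'
#' @param d1bar,d2bar condition matrices (identical shape).
#' @param n_restarts random restarts (1000 by default).
#' @param bounds search box for both coefficients.
#' @param seed integer seed for the restart initialisations.
#' @param grid_step spacing of the seeding grid scan.
#' @param binning passed to [mutual_information()].
#' @param restart_tol tolerance (bits) defining "converged" restarts for the
#'   filtered spread.
#' @return a `mixing_solution`: `a`, `b`, rounded 2-dp values `a_round`,
#'   `b_round`, `mi_min`, `mi_at_rounded`, `mi_original`, restart table,
#'   spreads `a_sd`/`b_sd` (all restarts) and `a_sd_conv`/`b_sd_conv`
#'   (near-optimal restarts), and an `improved` flag (FALSE when no restart
#'   beat the un-mixed `(0, 0)` baseline).
#' @export
fit_mixing <- function(d1bar, d2bar, n_restarts = 1000,
                       bounds = c(-0.5, 1.5), seed = NULL,
                       grid_step = 0.02, binning = "width",
                       restart_tol = 0.01) {
  if (!is.null(seed)) set.seed(seed)
  d1vec <- as.vector(unclass(d1bar))
  d2vec <- as.vector(unclass(d2bar))
  obj <- mi_objective(d1vec, d2vec, bounds, binning)
  mi_original <- mutual_information(d1vec, d2vec, binning = binning)

  grid <- seq(bounds[1], bounds[2], by = grid_step)
  gvals <- outer(grid, grid, Vectorize(function(a, b) obj(c(a, b))))
  gbest <- arrayInd(which.min(gvals), dim(gvals))
  starts <- rbind(
    c(grid[gbest[1]], grid[gbest[2]]),
    matrix(stats::runif(2 * n_restarts, bounds[1], bounds[2]),
           ncol = 2, byrow = TRUE))

  restarts <- as.data.frame(t(apply(starts, 1, function(s) {
    fit <- stats::optim(s, obj, method = "Nelder-Mead",
                        control = list(reltol = 1e-10, maxit = 500))
    c(a = fit$par[1], b = fit$par[2], mi = fit$value)
  })))
  best <- which.min(restarts$mi)
  a <- restarts$a[best]; b <- restarts$b[best]
  mi_min <- restarts$mi[best]
  improved <- mi_min < mi_original - 1e-12
  if (!improved) { a <- 0; b <- 0; mi_min <- mi_original }
  conv <- restarts$mi <= mi_min + restart_tol
  structure(list(
    a = a, b = b, a_round = round(a, 2), b_round = round(b, 2),
    mi_min = mi_min, mi_at_rounded = obj(c(round(a, 2), round(b, 2))),
    mi_original = mi_original, improved = improved,
    a_sd = stats::sd(restarts$a), b_sd = stats::sd(restarts$b),
    a_sd_conv = stats::sd(restarts$a[conv]),
    b_sd_conv = stats::sd(restarts$b[conv]),
    restarts = restarts, bounds = bounds, binning = binning),
    class = "mixing_solution")
}

#' @export
print.mixing_solution <- function(x, ...) {
  cat(sprintf(
    "mixing_solution: a = %.3f (sd %.3f), b = %.3f (sd %.3f)\n",
    x$a, x$a_sd_conv, x$b, x$b_sd_conv))
  cat(sprintf("  MI: %.4f bits (original %.4f); %d restarts%s\n",
              x$mi_min, x$mi_original, nrow(x$restarts),
              if (x$improved) "" else " [no improvement over (0,0)]"))
  invisible(x)
}

#' Orthonormal basis of an element's column space
#'
#' Thin SVD with a relative singular-value tolerance determines the
#' numerical rank `d`; the subspace is the span of the element's columns.
#'
#' @param element neurons x conditions matrix with at least one nonzero
#'   column.
#' @param label optional label (`"memory"`, `"preparation"`, ...).
#' @param tol relative singular value tolerance for rank detection.
#' @return a `subspace`: list with `basis` (neurons x d, orthonormal
#'   columns), `d`, `label`.
#' @export
build_subspace <- function(element, label = NULL, tol = 1e-8) {
  m <- as.matrix(unclass(element))
  s <- svd(m)
  if (s$d[1] <= 0 || !any(s$d > 0))
    stop("cannot build a subspace from an all-zero element")
  d <- sum(s$d > tol * s$d[1])
  structure(list(basis = s$u[, seq_len(d), drop = FALSE], d = d,
                 label = label),
            class = "subspace")
}

#' @export
print.subspace <- function(x, ...) {
  cat(sprintf("subspace%s: %d-dimensional in %d-dimensional ambient space\n",
              if (is.null(x$label)) "" else paste0(" (", x$label, ")"),
              x$d, nrow(x$basis)))
  invisible(x)
}

as_basis <- function(x) {
  b <- if (inherits(x, "subspace")) x$basis else as.matrix(x)
  g <- crossprod(b)
  if (max(abs(g - diag(ncol(b)))) > 1e-8)
    stop("basis columns are not orthonormal")
  b
}

#' Unmix single-trial activity
#'
#' Applies the fitted mixing model trial-by-trial using the label-matched
#' column of the condition-mean elements:
#' `M1 = D1 - a P[, c]`, `M2 = D2 - P[, c]`, `P1 = D1 - M[, c]`,
#' `P2 = D2 - b M[, c]` for a trial of condition `c`.
#'
#' @param d1,d2 neurons x trials matrices (or `pseudo_population` objects,
#'   in which case the train and test splits are both unmixed).
#' @param labels condition label per trial column (ignored for
#'   `pseudo_population` input).
#' @param mbar,pbar unmixed condition-mean elements whose columns align with
#'   the condition labels.
#' @param a,b fitted mixing coefficients.
#' @return list of matrices `m1`, `m2`, `p1`, `p2` (for matrix input), or a
#'   list of such lists (`train`, `test`) for `pseudo_population` input,
#'   with the labels attached.
#' @export
unmix_single_trials <- function(d1, d2, mbar, pbar, a, b, labels = NULL) {
  if (inherits(d1, "pseudo_population")) {
    stopifnot(inherits(d2, "pseudo_population"))
    tr <- unmix_single_trials(d1$train, d2$train, mbar, pbar, a, b, d1$labels)
    te <- unmix_single_trials(d1$test, d2$test, mbar, pbar, a, b, d1$labels)
    return(list(train = tr, test = te, labels = d1$labels))
  }
  if (is.null(labels)) stop("labels are required for matrix input")
  conds <- attr(mbar, "condition_labels") %||% seq_len(ncol(mbar))
  ci <- match(labels, conds)
  if (anyNA(ci))
    stop("label(s) without a matching element column: ",
         paste(unique(labels[is.na(ci)]), collapse = ", "))
  mbar <- unclass(mbar); pbar <- unclass(pbar)
  list(m1 = d1 - a * pbar[, ci, drop = FALSE],
       m2 = d2 - pbar[, ci, drop = FALSE],
       p1 = d1 - mbar[, ci, drop = FALSE],
       p2 = d2 - b * mbar[, ci, drop = FALSE],
       labels = labels)
}

#' Unmix error-trial activity with correct-trial elements
#'
#' Identical algebra to [unmix_single_trials()] but applied to error-trial
#' activity, keeping the condition-mean elements and coefficients estimated
#' from correct trials (the error-trial estimates `M1E`, `M2E`, `P1E`,
#' `P2E`).
#'
#' @inheritParams unmix_single_trials
#' @export
unmix_error_trials <- function(d1, d2, mbar, pbar, a, b, labels = NULL) {
  unmix_single_trials(d1, d2, mbar, pbar, a, b, labels)
}

#' Unmix Delay 1 against pre-saccadic activity
#'
#' The same machinery as [fit_mixing()] / [unmix_pair()] applied to the pair
#' (Delay 1 condition matrix, pre-saccade condition matrix), yielding the
#' primed coefficients `(a', b')` and the elements `M'` and `S` used to test
#' whether the second subspace reflects saccade preparation.
#'
#' @param d1bar Delay 1 condition matrix.
#' @param ds_bar pre-saccade-window condition matrix.
#' @param ... passed to [fit_mixing()].
#' @return list with `solution` (a `mixing_solution`), `m_prime`, `s`.
#' @export
unmix_presaccade <- function(d1bar, ds_bar, ...) {
  sol <- fit_mixing(d1bar, ds_bar, ...)
  el <- unmix_pair(d1bar, ds_bar, sol$a, sol$b)
  list(solution = sol, m_prime = el$m, s = el$p)
}

#' Unmix two condition matrices grouped by different, possibly uncorrelated
#' labels
#'
#' Generalises the paired unmixing to two task variables without a
#' one-to-one mapping: `G1 = L + a E[C | L]`, `G2 = C + b E[L | C]`, where
#' the conditional expectations use the empirical joint label frequencies.
#' At each candidate `(a, b)` the coupled system is solved by fixed-point
#' iteration; the coefficients minimise the mutual information between the
#' recovered elements, paired over every (neuron, label-1, label-2) cell
#' with positive joint probability. With a one-to-one label mapping this
#' reduces exactly to [unmix_pair()]/[fit_mixing()]; when the conditional
#' expectations vanish (fully crossed labels, zero net translation) the
#' elements are already unmixed and the optimization is skipped.
#'
#' @param g1bar condition matrix grouped by the first label (epoch 1).
#' @param g2bar condition matrix grouped by the second label (epoch 2).
#' @param joint_counts L x C table of trial counts (or probabilities) for
#'   the two labels; rows align with `g1bar` columns, columns with `g2bar`
#'   columns.
#' @param n_restarts,bounds,seed,grid_step as in [fit_mixing()].
#' @param fp_tol,fp_maxit fixed-point stopping rule (Frobenius change /
#'   iteration cap).
#' @return list with `l`, `c` (the unmixed elements), `a`, `b`, `mi_min`,
#'   `skipped` (TRUE when the expectations vanish), and the restart table.
#' @export
unmix_uncorrelated <- function(g1bar, g2bar, joint_counts,
                               n_restarts = 100, bounds = c(-0.5, 1.5),
                               seed = NULL, grid_step = 0.05,
                               fp_tol = 1e-8, fp_maxit = 100) {
  if (!is.null(seed)) set.seed(seed)
  g1 <- as.matrix(unclass(g1bar)); g2 <- as.matrix(unclass(g2bar))
  J <- as.matrix(joint_counts)
  if (nrow(J) != ncol(g1) || ncol(J) != ncol(g2))
    stop("joint_counts must be (ncol(g1bar) x ncol(g2bar))")
  if (any(rowSums(J) == 0) || any(colSums(J) == 0))
    stop("non-overlapping label support in joint_counts")
  p_c_given_l <- J / rowSums(J)              # L x C
  p_l_given_c <- t(t(J) / colSums(J))        # L x C, columns sum to 1
  e_c <- function(C) C %*% t(p_c_given_l)    # neurons x L
  e_l <- function(L) L %*% p_l_given_c       # neurons x C

  # degenerate case: expectations vanish at the starting point
  if (max(abs(e_c(g2))) < 1e-10 * max(1, max(abs(g2))) &&
      max(abs(e_l(g1))) < 1e-10 * max(1, max(abs(g1)))) {
    return(list(l = g1, c = g2, a = 0, b = 0,
                mi_min = NA_real_, skipped = TRUE, restarts = NULL))
  }

  pos <- which(J > 0, arr.ind = TRUE)
  solve_fp <- function(a, b) {
    L <- g1; C <- g2
    for (it in seq_len(fp_maxit)) {
      L_new <- g1 - a * e_c(C)
      C_new <- g2 - b * e_l(L_new)
      dl <- sqrt(sum((L_new - L)^2)) + sqrt(sum((C_new - C)^2))
      L <- L_new; C <- C_new
      if (dl < fp_tol) break
    }
    list(l = L, c = C)
  }
  obj <- function(ab) {
    a <- ab[1]; b <- ab[2]
    if (a < bounds[1] || a > bounds[2] || b < bounds[1] || b > bounds[2])
      return(1e6)
    if (abs(1 - a * b) < 1e-3) return(1e6)
    el <- solve_fp(a, b)
    x <- el$l[, pos[, 1]]; y <- el$c[, pos[, 2]]
    if (diff(range(x)) == 0 || diff(range(y)) == 0) return(1e6)
    mutual_information(as.vector(x), as.vector(y))
  }
  grid <- seq(bounds[1], bounds[2], by = grid_step)
  gvals <- outer(grid, grid, Vectorize(function(a, b) obj(c(a, b))))
  gbest <- arrayInd(which.min(gvals), dim(gvals))
  starts <- rbind(c(grid[gbest[1]], grid[gbest[2]]),
                  matrix(stats::runif(2 * n_restarts, bounds[1], bounds[2]),
                         ncol = 2, byrow = TRUE))
  restarts <- as.data.frame(t(apply(starts, 1, function(s) {
    fit <- stats::optim(s, obj, method = "Nelder-Mead",
                        control = list(reltol = 1e-10, maxit = 300))
    c(a = fit$par[1], b = fit$par[2], mi = fit$value)
  })))
  best <- which.min(restarts$mi)
  el <- solve_fp(restarts$a[best], restarts$b[best])
  list(l = el$l, c = el$c, a = restarts$a[best], b = restarts$b[best],
       mi_min = restarts$mi[best], skipped = FALSE, restarts = restarts)
}

#' Orthogonal subspaces by Gram-Schmidt on the Delay 2 columns
#'
#' The constrained alternative to MI unmixing: the first subspace is the
#' span of the Delay 1 columns; the second is the span of the Delay 2
#' columns after removing their projections onto the first, so the two
#' subspaces are exactly orthogonal by construction.
#'
#' @param d1bar,d2bar condition matrices.
#' @param tol relative tolerance for declaring the residual zero.
#' @return list of two `subspace` objects (`first`, `second`).
#' @export
gram_schmidt_subspaces <- function(d1bar, d2bar, tol = 1e-10) {
  s1 <- build_subspace(d1bar, label = "delay1")
  d2 <- as.matrix(unclass(d2bar))
  resid <- d2 - s1$basis %*% crossprod(s1$basis, d2)
  if (max(svd(resid)$d) <= tol * max(svd(d2)$d))
    stop("Delay 2 activity lies entirely inside the Delay 1 span")
  list(first = s1, second = build_subspace(resid, label = "delay2_orth"))
}
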