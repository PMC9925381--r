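# Trajectory and velocity analysis: FACS marker imputation, ternary
# differentiation coordinates, pseudotime from selected principal
# components, spline fits of signal along pseudotime and their derivative
# (chromatin velocity), projected back into PC space.

#' Impute a missing FACS marker from latent-space neighbours
#'
#' Cells with exactly one of the (Sca1, cKit, Lin) markers missing get the
#' mean value of their k nearest neighbours (Euclidean distance in the
#' provided latent embedding) among cells where that marker was measured.
#'
#' @param facs data.frame with columns cell, Sca1, cKit, Lin; at most one
#'   NA of the three per cell.
#' @param latent Cell x dimension embedding, rows named or ordered as
#'   `facs$cell`.
#' @param k Number of neighbours averaged; default 10.
#' @return List with `facs` (completed table) and `imputed` (logical cell
#'   x marker matrix of which entries were filled).
#' @export
impute_missing_marker <- function(facs, latent, k = 10) {
  if (k < 1) stop_config("k must be >= 1")
  markers <- c("Sca1", "cKit", "Lin")
  stopifnot(all(c("cell", markers) %in% names(facs)))
  miss_per_cell <- rowSums(is.na(facs[, markers]))
  if (any(miss_per_cell > 1)) {
    stop_config("cells with more than one missing marker cannot be imputed")
  }
  latent <- as_dense(latent)
  if (!is.null(rownames(latent))) latent <- latent[facs$cell, , drop = FALSE]
  if (nrow(latent) != nrow(facs)) stop_config("latent rows must match facs cells")
  imputed <- matrix(FALSE, nrow(facs), 3L,
                    dimnames = list(facs$cell, markers))
  out <- facs
  for (m in markers) {
    need <- which(is.na(facs[[m]]))
    have <- which(!is.na(facs[[m]]))
    if (!length(need)) next
    if (!length(have)) stop_config("marker %s missing in every cell", m)
    kk <- min(k, length(have))
    if (kk < k) warning(sprintf("only %d complete cells for %s; using all", kk, m))
    for (i in need) {
      d2 <- colSums((t(latent[have, , drop = FALSE]) - latent[i, ])^2)
      nn <- have[order(d2)[seq_len(kk)]]
      out[[m]][i] <- mean(facs[[m]][nn])
      imputed[i, m] <- TRUE
    }
  }
  list(facs = out, imputed = imputed)
}

#' Ternary differentiation coordinates from marker levels
#'
#' Normalises the nonnegative (Sca1, cKit, Lin) triple to the unit
#' simplex, placing each cell on the stem-progenitor-mature ternary plot.
#'
#' @param sca1,ckit,lin Nonnegative marker levels (vectors of equal
#'   length).
#' @return n x 3 matrix of simplex coordinates (rows sum to 1).
#' @export
ternary_coords <- function(sca1, ckit, lin) {
  m <- cbind(Sca1 = sca1, cKit = ckit, Lin = lin)
  if (any(m < 0)) stop_config("marker levels must be nonnegative")
  s <- rowSums(m)
  if (any(s == 0)) stop_config("all-zero marker triple")
  m / s
}

#' Pseudotime from two selected principal components
#'
#' Projects the trajectory cells onto the first principal axis of the
#' selected two-PC subspace, rank-transforms the projection to \[0, 1\],
#' and orients it so that the starting population has mean pseudotime
#' below 0.5.
#'
#' @param scores Cell x PC score matrix (from [project_pca()]).
#' @param pcs Indices of the two selected PCs.
#' @param trajectory_cells Cells (names or indices) forming the
#'   trajectory.
#' @param start_label Per-cell labels (named) and
#' @param start_type the label of the starting population used to orient
#'   the axis.
#' @return Named pseudotime in \[0, 1\] for the trajectory cells.
#' @export
pseudotime_from_pcs <- function(scores, pcs, trajectory_cells,
                                start_label, start_type) {
  if (length(pcs) != 2L || any(pcs > ncol(scores))) {
    stop_config("pcs must index two columns of the score matrix")
  }
  sub <- scores[trajectory_cells, pcs, drop = FALSE]
  if (nrow(sub) < 2L) stop_config("trajectory needs >= 2 cells")
  axis1 <- prcomp(sub, center = TRUE, scale. = FALSE)$x[, 1L]
  r <- rank(axis1, ties.method = "average")
  t <- (r - 1) / (length(r) - 1)
  labs <- start_label[rownames(sub)]
  if (!any(labs == start_type, na.rm = TRUE)) {
    stop_config("start type '%s' absent from the trajectory", start_type)
  }
  if (mean(t[labs == start_type], na.rm = TRUE) > 0.5) t <- 1 - t
  setNames(t, rownames(sub))
}

#' Cubic spline fit of signal along pseudotime
#'
#' Least-squares cubic B-spline regression of one region's per-cell
#' signal on pseudotime, with `df` basis functions and internal knots at
#' pseudotime quantiles. The cubic family contains linear trends exactly.
#'
#' @param signal Per-cell signal values for one region.
#' @param t Per-cell pseudotime in \[0, 1\].
#' @param df Spline degrees of freedom (>= 4 for a cubic); default 6.
#' @return A `trajectory_spline` with the `lm` fit and a `predict_at`
#'   function.
#' @export
fit_trajectory_spline <- function(signal, t, df = 6) {
  if (df < 4) stop_config("cubic splines need df >= 4")
  if (length(signal) != length(t)) stop_config("signal and t differ in length")
  if (length(signal) < df + 2) stop_config("need at least df + 2 cells")
  if (diff(range(t)) < .Machine$double.eps) stop_config("degenerate pseudotime")
  basis <- splines::bs(t, df = df, degree = 3L, Boundary.knots = c(0, 1))
  fit <- lm(signal ~ basis)
  knots <- attr(basis, "knots")
  structure(list(fit = fit, knots = knots, df = df), class = "trajectory_spline")
}

#' @export
predict.trajectory_spline <- function(object, t, ...) {
  basis <- splines::bs(t, knots = object$knots, degree = 3L,
                       Boundary.knots = c(0, 1))
  as.numeric(cbind(1, basis) %*% coef(object$fit))
}

#' Chromatin velocity: spline derivative along pseudotime
#'
#' The per-cell velocity is the forward difference of the spline
#' prediction between t and the near future t + delta, divided by delta.
#' Near the trajectory end, t + delta is clipped to 1 and the difference
#' taken one-sided (backward) over the same width.
#'
#' @param fit A [fit_trajectory_spline()] result.
#' @param t Per-cell pseudotime in \[0, 1\].
#' @param delta Look-ahead in pseudotime units; default 0.01.
#' @return Per-cell velocity (signal units per unit pseudotime).
#' @export
chromatin_velocity <- function(fit, t, delta = 0.01) {
  if (delta <= 0) stop_config("delta must be > 0")
  t2 <- pmin(t + delta, 1)
  t1 <- t2 - delta
  (predict(fit, t2) - predict(fit, t1)) / delta
}

#' Project per-region velocities onto principal components
#'
#' Linearly maps the region x cell velocity field through the PCA
#' loadings, giving a 2-D (or higher) arrow per cell in the embedding.
#' Velocities are differences of signal, so the PCA centring constant
#' cancels and no re-centring is needed.
#'
#' @param velocities Region x cell velocity matrix.
#' @param loadings Region x PC loading matrix from [project_pca()] on the
#'   same regions.
#' @param pcs PC columns to keep; default the first two.
#' @return Cell x PC matrix of velocity arrows.
#' @export
project_velocity <- function(velocities, loadings, pcs = 1:2) {
  velocities <- as_dense(velocities)
  if (nrow(velocities) != nrow(loadings)) {
    stop_config("velocity and loading region registries differ")
  }
  if (!is.null(rownames(velocities)) && !is.null(rownames(loadings)) &&
      !identical(rownames(velocities), rownames(loadings))) {
    stop_config("velocity and loading region registries differ in order")
  }
  t(velocities) %*% loadings[, pcs, drop = FALSE]
}
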