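# Single-cell TF motif activity inference: the imputed log signal of each
# cell is modelled as a linear combination of motif site counts,
# Y[g, c] = sum_m N[g, m] A[m, c] + eps, fitted by ridge regression with a
# cross-validated penalty shared across cells, followed by z-score
# significance filtering.

#' Fit single-cell motif activities by ridge regression
#'
#' Regresses each cell's (batch-corrected) imputed signal over regions on
#' the region x motif site-count design with an L2 penalty. One penalty is
#' shared across cells so activities remain comparable between cells; it
#' is selected by an 80/20 region-holdout: for each grid value the model
#' is fitted on the training regions and the penalty minimising the mean
#' held-out squared error is kept. By default the signal is centred per
#' region across cells (activities then express deviation from the mean
#' cell, rather than absorbing the mean profile into every motif) and the
#' site-count columns are scaled to unit variance; coefficients are
#' reported back on the original site-count scale.
#'
#' @param signal Region x cell matrix of imputed log signal.
#' @param N Region x motif nonnegative site-count matrix on the same
#'   region registry; all-zero motif columns are dropped with a warning.
#' @param lambda_grid Penalty grid; default 13 points log-spaced over
#'   `1e-3..1e3` times the mean diagonal of the (scaled) `N' N`.
#'   A 0 entry is skipped with a warning when the design is singular.
#' @param cv_fraction Fraction of regions in the training split;
#'   default 0.8.
#' @param center Centre the signal per region across cells; default TRUE.
#' @param standardize Scale site-count columns to unit variance;
#'   default TRUE.
#' @param seed Integer seed for the region split.
#' @return An `activity_fit` with `A` (motif x cell activities), `lambda`,
#'   `cv_error` (per-grid-value held-out MSE), `sigma2` (per-cell residual
#'   variance), and the sandwich standard errors used by
#'   [motif_zscores()].
#' @export
fit_activities <- function(signal, N, lambda_grid = NULL, cv_fraction = 0.8,
                           center = TRUE, standardize = TRUE, seed = 1L) {
  signal <- as_dense(signal); N <- as_dense(N)
  if (nrow(signal) != nrow(N)) stop_config("region registries differ")
  if (!is.null(rownames(signal)) && !is.null(rownames(N)) &&
      !identical(rownames(signal), rownames(N))) {
    stop_config("region registries differ in order")
  }
  if (any(N < 0)) stop_config("site counts must be nonnegative")
  zero_col <- colSums(N) == 0
  if (any(zero_col)) {
    warning(sprintf("dropping %d all-zero motif columns", sum(zero_col)))
    N <- N[, !zero_col, drop = FALSE]
  }
  motifs <- colnames(N) %||% paste0("motif", seq_len(ncol(N)))
  G <- nrow(N); M <- ncol(N)
  Y <- if (center) signal - rowMeans(signal) else signal
  col_scale <- rep(1, M)
  if (standardize) {
    col_scale <- apply(N, 2L, sd)
    col_scale[col_scale == 0] <- 1
  }
  Ns <- sweep(N, 2L, col_scale, "/")
  if (is.null(lambda_grid)) {
    base <- mean(diag(crossprod(Ns)))
    lambda_grid <- base * 10^seq(-3, 3, length.out = 13)
  }
  if (length(lambda_grid) == 0L) stop_config("empty lambda grid")
  lambda_grid <- sort(lambda_grid)
  if (any(lambda_grid == 0) && qr(Ns)$rank < M) {
    warning("singular design: skipping lambda = 0")
    lambda_grid <- lambda_grid[lambda_grid > 0]
  }

  ridge_solve <- function(X, Yt, lambda) {
    solve(crossprod(X) + diag(lambda, ncol(X)), crossprod(X, Yt))
  }

  n_train <- max(1L, round(cv_fraction * G))
  train <- with_seed(seed, sample.int(G, n_train))
  test <- setdiff(seq_len(G), train)
  cv_mse <- vapply(lambda_grid, function(lambda) {
    A_tr <- ridge_solve(Ns[train, , drop = FALSE], Y[train, , drop = FALSE],
                        lambda)
    resid <- Y[test, , drop = FALSE] - Ns[test, , drop = FALSE] %*% A_tr
    mean(resid^2)
  }, 0)
  lambda <- lambda_grid[which.min(cv_mse)]

  XtX <- crossprod(Ns)
  Minv <- solve(XtX + diag(lambda, M))
  A_std <- Minv %*% crossprod(Ns, Y)
  fitted <- Ns %*% A_std
  rss <- colSums((Y - fitted)^2)
  df_eff <- sum(diag(Minv %*% XtX))
  sigma2 <- rss / max(1, G - df_eff)
  # ridge sandwich: Var(A_.c) = sigma2_c * Minv XtX Minv
  sand_diag <- diag(Minv %*% XtX %*% Minv)
  se_std <- sqrt(outer(pmax(sand_diag, 0), sigma2))
  A <- sweep(A_std, 1L, col_scale, "/")
  dimnames(A) <- list(motifs, colnames(signal))
  dimnames(A_std) <- dimnames(A)
  dimnames(se_std) <- dimnames(A)
  structure(list(A = A, A_std = A_std, se_std = se_std, lambda = lambda,
                 cv_error = data.frame(lambda = lambda_grid, mse = cv_mse),
                 sigma2 = sigma2, df_eff = df_eff,
                 center = center, standardize = standardize, seed = seed),
            class = "activity_fit")
}

#' @export
print.activity_fit <- function(x, ...) {
  cat(sprintf("Motif activity fit: %d motifs x %d cells, lambda = %.4g (80/20 CV)\n",
              nrow(x$A), ncol(x$A), x$lambda))
  invisible(x)
}

#' Motif z-scores and the significant motif set
#'
#' For each motif, the z-score is the root mean square over cells of the
#' activity-to-standard-error ratio (standard errors from the ridge
#' sandwich variance with per-cell residual variance): motifs with
#' consistently nonzero activity across cells score high. Motifs with
#' `z > threshold` (default 0.7) form the significant set.
#'
#' @param fit An [fit_activities()] result.
#' @param threshold Significance cutoff on z; default 0.7.
#' @return List with `z` (named, >= 0) and `significant` (motif names).
#' @export
motif_zscores <- function(fit, threshold = 0.7) {
  stopifnot(inherits(fit, "activity_fit"))
  se <- pmax(fit$se_std, 1e-12)
  if (any(fit$se_std < 1e-12)) {
    warning("zero residual variance: standard errors floored at 1e-12")
  }
  z <- sqrt(rowMeans((fit$A_std / se)^2))
  list(z = z, significant = names(z)[z > threshold], threshold = threshold)
}
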