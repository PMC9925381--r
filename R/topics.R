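# Topic-model dimensionality reduction of cut-count matrices: collapsed
# Gibbs LDA, imputed (smoothed) log signal, latent-space batch correction,
# seeded clustering and PCA over dynamic bins.

#' Fit the multinomial topic model to a count matrix
#'
#' Models the region x cell counts as a hierarchical multinomial (LDA):
#' topics are probability distributions over regions, each cell is a
#' mixture over topics, and a cell's cuts are drawn from its mixture.
#' This is the discrete analogue of probabilistic PCA and yields a
#' denoised per-cell profile from sparse counts. Inference is collapsed
#' Gibbs sampling with symmetric Dirichlet priors; the point estimate
#' averages the posterior-mean parameters over the final sweeps.
#'
#' @param mat Region x cell count matrix (dense or sparse). Cells with
#'   zero totals are an error: filter them first with [filter_cells()].
#' @param K Number of topics (>= 1); default 30.
#' @param alpha Cell-topic Dirichlet prior; default `50 / K`.
#' @param beta Topic-region Dirichlet prior; default 0.1.
#' @param n_iter Gibbs sweeps; default 500.
#' @param n_avg Final sweeps averaged for the point estimate; default 50.
#' @param seed Integer seed; identical seeds give identical fits.
#' @return A `topic_fit` with `theta` (cell x K, rows sum to 1), `phi`
#'   (K x region, rows sum to 1), `loglik` trace, and the call parameters.
#' @export
fit_topics <- function(mat, K = 30, alpha = 50 / K, beta = 0.1,
                       n_iter = 500, n_avg = 50, seed = 1L) {
  if (K < 1) stop_config("K must be >= 1")
  m <- as(Matrix::Matrix(mat, sparse = TRUE), "TsparseMatrix")
  totals <- Matrix::colSums(m)
  if (any(totals == 0)) {
    stop_config("%d cells have zero counts; remove them with filter_cells()",
                sum(totals == 0))
  }
  x <- as.integer(m@x)
  doc <- rep(m@j, x)    # 0-based cell index per token
  word <- rep(m@i, x)   # 0-based region index per token
  fit <- with_seed(seed,
    lda_gibbs(doc, word, ncol(m), nrow(m), as.integer(K), alpha, beta,
              as.integer(n_iter), as.integer(n_avg)))
  theta <- fit$theta
  phi <- fit$phi
  dimnames(theta) <- list(colnames(mat), paste0("topic", seq_len(K)))
  dimnames(phi) <- list(paste0("topic", seq_len(K)), rownames(mat))
  structure(list(K = as.integer(K), theta = theta, phi = phi,
                 loglik = fit$loglik, alpha = alpha, beta = beta,
                 n_iter = n_iter, n_avg = n_avg, seed = seed),
            class = "topic_fit")
}

#' @export
print.topic_fit <- function(x, ...) {
  cat(sprintf("Multinomial topic model: %d cells, %d regions, K = %d\n",
              nrow(x$theta), ncol(x$phi), x$K))
  cat(sprintf("  %d Gibbs sweeps (last %d averaged), alpha = %.3g, beta = %.3g\n",
              x$n_iter, x$n_avg, x$alpha, x$beta))
  invisible(x)
}

#' Imputed log signal from a topic fit
#'
#' Reconstructs each cell's multinomial probability vector over regions,
#' `phi' theta'`, and returns its natural logarithm: the smoothed
#' ("imputed") signal used by motif-activity inference and velocity.
#'
#' @param fit A [fit_topics()] result.
#' @return Region x cell matrix of log probabilities; `exp()` of each
#'   column sums to 1.
#' @export
impute_signal <- function(fit) {
  stopifnot(inherits(fit, "topic_fit"))
  p <- t(fit$phi) %*% t(fit$theta)  # region x cell
  log(p)
}

#' Remove plate (batch) effects in latent space
#'
#' Fits, per latent dimension, the least-squares model
#' `value ~ cluster + cluster:batch` and subtracts the cell-type-specific
#' batch terms. Batch deviations are measured against the (cell-weighted)
#' cluster mean, so cluster means are preserved exactly. A cluster
#' residing entirely in one plate has no estimable batch term; it is
#' skipped with a warning.
#'
#' @param latent Cell x dimension matrix (e.g. topic weights, their
#'   log-odds, or imputed signal transposed).
#' @param batch Per-cell plate labels.
#' @param cluster Per-cell cluster labels.
#' @return Corrected matrix of the same shape.
#' @export
correct_batch <- function(latent, batch, cluster) {
  latent <- as_dense(latent)
  if (length(batch) != nrow(latent) || length(cluster) != nrow(latent)) {
    stop_config("every cell needs a batch and a cluster label")
  }
  if (anyNA(batch) || anyNA(cluster)) stop_config("NA batch or cluster label")
  out <- latent
  for (cl in unique(cluster)) {
    rows <- which(cluster == cl)
    b <- factor(batch[rows])
    if (nlevels(b) < 2L) {
      warning(sprintf("cluster '%s' lies in a single batch; no correction applied",
                      cl))
      next
    }
    sub <- latent[rows, , drop = FALSE]
    cl_mean <- colMeans(sub)
    for (lv in levels(b)) {
      br <- b == lv
      shift <- colMeans(sub[br, , drop = FALSE]) - cl_mean
      out[rows[br], ] <- sweep(sub[br, , drop = FALSE], 2L, shift)
    }
  }
  out
}

#' Cluster cells in the latent space
#'
#' Seeded k-means on the latent coordinates (topic weights); deterministic
#' for a fixed seed.
#'
#' @param latent Cell x dimension matrix.
#' @param k Number of clusters.
#' @param seed Integer seed.
#' @param nstart Random restarts; default 10.
#' @return Named integer cluster labels per cell.
#' @export
cluster_cells <- function(latent, k, seed = 1L, nstart = 10) {
  latent <- as_dense(latent)
  if (!all(is.finite(latent))) stop_config("latent coordinates must be finite")
  if (k > nrow(latent)) stop_config("more clusters than cells")
  if (nrow(unique(latent)) < k) {
    # fewer distinct points than clusters: collapse to the distinct points
    labels <- match(apply(latent, 1L, paste, collapse = "\r"),
                    unique(apply(latent, 1L, paste, collapse = "\r")))
    return(setNames(labels, rownames(latent)))
  }
  km <- with_seed(seed, kmeans(latent, centers = k, nstart = nstart))
  setNames(km$cluster, rownames(latent))
}

#' PCA of imputed signal over selected regions
#'
#' Region-centred principal component analysis of the (typically dynamic-
#' bin-restricted) imputed signal; cells are observations.
#'
#' @param signal Region x cell matrix (e.g. from [impute_signal()],
#'   subset to dynamic bins).
#' @return List with `scores` (cell x PC), `loadings` (region x PC),
#'   `center` (per-region means) and `var_frac` (non-increasing variance
#'   fractions).
#' @export
project_pca <- function(signal) {
  signal <- as_dense(signal)
  if (nrow(signal) < 2L || ncol(signal) < 2L) {
    stop_config("need >= 2 regions and >= 2 cells")
  }
  if (all(apply(signal, 1L, var) < .Machine$double.eps)) {
    stop_config("constant signal matrix: PCA undefined")
  }
  pc <- prcomp(t(signal), center = TRUE, scale. = FALSE)
  var_frac <- pc$sdev^2 / sum(pc$sdev^2)
  list(scores = pc$x, loadings = pc$rotation, center = pc$center,
       var_frac = var_frac)
}
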