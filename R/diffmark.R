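# Differential histone-mark analysis: per-region Poisson regression
# comparing a cell-type-free null model to a cell-type full model by
# deviance, BH q-values, mark-specific dynamic-bin calling, fold changes
# vs a reference population, and fate-independence classification.

#' Poisson deviance test for one region
#'
#' Fits, with `stats::glm`, the null model
#' `log E[Y] = mu + offset` and the full model
#' `log E[Y] = mu + gamma_celltype + offset` (reference type constrained
#' to 0) to the per-cell counts of one region, and compares their
#' deviances: the difference is chi-squared with `#types - 1` degrees of
#' freedom under the null of no cell-type effect. The offset is the log
#' total cut count per cell, so depth differences are not mistaken for
#' cell-type effects.
#'
#' @param y Per-cell counts for one region.
#' @param celltype Per-cell type labels (>= 2 types for a test).
#' @param offset Per-cell log total cuts; must be finite.
#' @param reference Reference type (fold changes are relative to it);
#'   default the first level.
#' @return List with `null_dev`, `full_dev`, `dev_diff`, `df`, `p` and
#'   `log2fc` (named per non-reference type; reference is 0).
#' @export
fit_region_glm <- function(y, celltype, offset, reference = NULL) {
  if (!all(is.finite(offset))) stop_config("offsets must be finite")
  celltype <- as.character(celltype)
  keep_types <- unique(celltype)
  reference <- reference %||% keep_types[1L]
  if (!reference %in% keep_types) stop_config("reference type '%s' absent", reference)
  ct <- factor(celltype, levels = c(reference, setdiff(sort(keep_types), reference)))
  types <- levels(ct)
  log2fc <- setNames(rep(0, length(types)), types)
  if (sum(y) == 0) {
    return(list(null_dev = 0, full_dev = 0, dev_diff = 0,
                df = length(types) - 1L, p = 1, log2fc = log2fc))
  }
  null_fit <- glm(y ~ 1 + offset(offset), family = poisson())
  if (length(types) < 2L) {
    return(list(null_dev = null_fit$deviance, full_dev = null_fit$deviance,
                dev_diff = 0, df = 0L, p = 1, log2fc = log2fc))
  }
  full_fit <- glm(y ~ ct + offset(offset), family = poisson())
  dev_diff <- max(0, null_fit$deviance - full_fit$deviance)
  df <- length(types) - 1L
  gamma <- coef(full_fit)[paste0("ct", types[-1L])]
  log2fc[types[-1L]] <- unname(gamma) / log(2)
  list(null_dev = null_fit$deviance, full_dev = full_fit$deviance,
       dev_diff = dev_diff, df = df,
       p = pchisq(dev_diff, df, lower.tail = FALSE), log2fc = log2fc)
}

#' Region-wise differential test over a count matrix
#'
#' Applies [fit_region_glm()] to every region of a count matrix and
#' collects deviances, p-values, BH q-values and per-type log2 fold
#' changes versus the reference population.
#'
#' @param mat Region x cell count matrix.
#' @param celltype Per-cell labels (named or in column order).
#' @param reference Reference cell type; default first sorted label.
#' @param offset Per-cell log total cuts; default `log(colSums(mat))`.
#' @return A `diff_result` data.frame with one row per region: deviances,
#'   `dev_diff`, `df`, `p`, `q` and `log2fc_<type>` columns (reference
#'   column all zero).
#' @export
diff_mark_test <- function(mat, celltype, reference = NULL, offset = NULL) {
  if (!is.null(names(celltype))) celltype <- celltype[colnames(mat)]
  if (length(celltype) != ncol(mat) || anyNA(celltype)) {
    stop_config("every cell must carry a type label")
  }
  celltype <- as.character(celltype)
  counts_per_type <- table(celltype)
  if (any(counts_per_type == 0)) {
    warning("dropping empty cell types")
  }
  offset <- offset %||% log(Matrix::colSums(mat))
  if (!all(is.finite(offset))) {
    stop_config("zero-depth cells give infinite offsets; filter them first")
  }
  reference <- reference %||% sort(unique(celltype))[1L]
  dense <- as_dense(mat)
  fits <- lapply(seq_len(nrow(dense)), function(r) {
    fit_region_glm(dense[r, ], celltype, offset, reference)
  })
  types <- names(fits[[1L]]$log2fc)
  out <- data.frame(
    region = rownames(mat) %||% paste0("region", seq_len(nrow(mat))),
    null_dev = vapply(fits, `[[`, 0, "null_dev"),
    full_dev = vapply(fits, `[[`, 0, "full_dev"),
    dev_diff = vapply(fits, `[[`, 0, "dev_diff"),
    df = vapply(fits, `[[`, 0L, "df"),
    p = vapply(fits, `[[`, 0, "p"),
    stringsAsFactors = FALSE)
  out$q <- adjust_q(out$p)
  for (t in types) {
    out[[paste0("log2fc_", t)]] <- vapply(fits, function(f) f$log2fc[[t]], 0)
  }
  attr(out, "reference") <- reference
  attr(out, "types") <- types
  class(out) <- c("diff_result", "data.frame")
  out
}

#' Benjamini-Hochberg adjusted q-values
#'
#' @param p Vector of p-values in \[0, 1\].
#' @return Step-up adjusted values, monotone in `p` and `>= p`.
#' @export
adjust_q <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop_config("p-values must lie in [0,1]")
  p.adjust(p, method = "BH")
}

#' Default per-mark q-value thresholds for dynamic bins
#'
#' `1e-50` for the active marks and H3K27me3, `1e-9` for H3K9me3 (whose
#' broad heterochromatic signal yields weaker per-bin statistics).
#'
#' @return Named numeric vector of thresholds.
#' @export
default_q_thresholds <- function() {
  c(H3K4me1 = 1e-50, H3K4me3 = 1e-50, H3K27me3 = 1e-50, H3K9me3 = 1e-9)
}

#' Flag dynamic regions at a mark-specific q threshold
#'
#' @param res A `diff_result` (or any data.frame with a `q` column).
#' @param mark Histone mark name used to look up the threshold.
#' @param q_thresholds Named map mark -> threshold in (0, 1\];
#'   default [default_q_thresholds()].
#' @return The input with a logical `dynamic` column added.
#' @export
call_dynamic <- function(res, mark, q_thresholds = default_q_thresholds()) {
  if (!mark %in% names(q_thresholds)) {
    stop_config("unknown mark '%s'; thresholds defined for: %s", mark,
                paste(names(q_thresholds), collapse = ", "))
  }
  thr <- q_thresholds[[mark]]
  if (thr <= 0 || thr > 1) stop_config("q threshold must lie in (0,1]")
  res$dynamic <- res$q < thr
  res
}

#' Log2 fold changes versus a reference population
#'
#' Either extracts the Poisson GLM coefficients (divided by `ln 2`) from a
#' `diff_result`, or computes depth-normalised pseudobulk log2 ratios from
#' a group x region count matrix. The two agree at high counts.
#'
#' @param x A `diff_result` or a pseudobulk matrix (group x region).
#' @param reference Reference type label.
#' @param pseudocount Added to pseudobulk counts before the ratio
#'   (pseudobulk branch only); default 0.5.
#' @return Type x region matrix of log2 fold changes; the reference row is
#'   all zeros.
#' @export
fold_change_vs_reference <- function(x, reference, pseudocount = 0.5) {
  if (inherits(x, "diff_result")) {
    types <- attr(x, "types")
    if (!reference %in% types) stop_config("reference '%s' missing", reference)
    out <- t(as.matrix(x[, paste0("log2fc_", types), drop = FALSE]))
    rownames(out) <- types
    colnames(out) <- x$region
    return(out)
  }
  x <- as_dense(x)
  if (!reference %in% rownames(x)) stop_config("reference '%s' missing", reference)
  depth <- rowSums(x)
  rate <- (x + pseudocount) / depth
  out <- log2(sweep(rate, 2L, rate[reference, ], "/"))
  out
}

#' Classify fate-independent chromatin changes
#'
#' A region "changes" in cell type t with direction d (gain or loss) iff
#' it is dynamic and `sign(log2FC_t) == d` with `|log2FC_t| > min_effect`.
#' It changes fate-independently in direction d iff it changes with that
#' direction in every non-reference cell type. For each (type, direction)
#' the summary fraction divides the count of fate-independent bins by the
#' count of bins changing in that type and direction.
#'
#' @param res A `diff_result` with a `dynamic` column (see
#'   [call_dynamic()]).
#' @param min_effect Minimum |log2FC| for a change to count; default 0.
#' @return List with `fraction` (type x direction matrix, `NA` where no
#'   bins change), `changes` (region x type signed direction matrix:
#'   +1 gain, -1 loss, 0 no change) and `fate_independent` (per-region
#'   "gain"/"loss"/NA).
#' @export
classify_fate_independent <- function(res, min_effect = 0) {
  if (is.null(res$dynamic)) stop_config("run call_dynamic() first")
  types <- setdiff(attr(res, "types"), attr(res, "reference"))
  if (length(types) == 0L) stop_config("no non-reference cell types")
  fc <- as.matrix(res[, paste0("log2fc_", types), drop = FALSE])
  colnames(fc) <- types
  changes <- sign(fc) * (abs(fc) > min_effect) * res$dynamic
  rownames(changes) <- res$region
  fate_dir <- apply(changes, 1L, function(z) {
    if (all(z == 1)) "gain" else if (all(z == -1)) "loss" else NA_character_
  })
  if (all(changes == 0)) {
    warning("no dynamic regions pass min_effect; fractions undefined")
  }
  fraction <- matrix(NA_real_, length(types), 2L,
                     dimnames = list(types, c("gain", "loss")))
  for (t in types) {
    for (d in c(gain = 1, loss = -1)) {
      dname <- if (d == 1) "gain" else "loss"
      changing <- changes[, t] == d
      if (!any(changing)) next
      fraction[t, dname] <- sum(changing & !is.na(fate_dir) &
                                  fate_dir == dname) / sum(changing)
    }
  }
  list(fraction = fraction, changes = changes, fate_independent = fate_dir)
}

#' Select the regions with the strongest depletion
#'
#' Returns the `k` most-negative log2 fold changes for one cell type, with
#' ties broken lexicographically by region id. The default k = 150 is the
#' set size used to define cluster-specific heterochromatin regions.
#'
#' @param folds Named per-region log2 fold change vector for one type.
#' @param k Number of regions; default 150.
#' @return Character vector of region ids, most depleted first.
#' @export
select_top_depleted <- function(folds, k = 150) {
  if (k < 1) stop_config("k must be >= 1")
  if (is.null(names(folds))) names(folds) <- paste0("region", seq_along(folds))
  if (k > length(folds)) {
    warning(sprintf("k = %d exceeds %d regions; returning all", k, length(folds)))
    k <- length(folds)
  }
  ord <- order(folds, names(folds))
  names(folds)[ord][seq_len(k)]
}
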