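# Reference-based probabilistic cell typing: each cell type is a
# multinomial over genomic features, built from labelled reference cells;
# query cells are assigned by multinomial likelihood.

#' Build a multinomial typing reference from labelled cells
#'
#' Pools counts per FACS-defined type, adds a pseudocount and normalises,
#' giving one strictly positive probability vector over the feature
#' registry per type.
#'
#' @param mat Region x cell count matrix of labelled reference cells.
#' @param labels Per-cell type labels (named or in column order).
#' @param pseudocount Added per feature; default 1.
#' @return A `typing_reference` with `profiles` (type x feature, rows sum
#'   to 1), `n_cells` per type, `pseudocount`.
#' @export
build_typing_reference <- function(mat, labels, pseudocount = 1) {
  if (!is.null(names(labels))) labels <- labels[colnames(mat)]
  if (length(labels) != ncol(mat) || anyNA(labels)) {
    stop_config("every reference cell must be labelled")
  }
  pooled <- pseudobulk(mat, labels)
  if (any(rowSums(pooled) + pseudocount * ncol(pooled) == 0)) {
    stop_config("a type has zero counts and zero pseudocount")
  }
  prof <- pooled + pseudocount
  prof <- sweep(prof, 1L, rowSums(prof), "/")
  structure(list(profiles = prof,
                 n_cells = table(as.character(labels)),
                 pseudocount = pseudocount),
            class = "typing_reference")
}

#' Classify cells against a typing reference
#'
#' Under the multinomial model, `log P(type | y)` is proportional to
#' `log prior + sum_i y_i log p_type,i`; posteriors are softmax-normalised
#' in log space with max-subtraction, so depths up to 1e7 cuts pose no
#' overflow risk. A zero-count cell carries no information and gets the
#' prior back, flagged.
#'
#' @param mat Region x cell count matrix on the reference feature
#'   registry.
#' @param ref A [build_typing_reference()] result.
#' @param prior `"uniform"` (default) or a per-type probability vector.
#' @return List with `posterior` (cell x type, rows sum to 1), `label`
#'   (argmax type per cell) and `zero_count` flags.
#' @export
classify_cells <- function(mat, ref, prior = "uniform") {
  stopifnot(inherits(ref, "typing_reference"))
  if (nrow(mat) != ncol(ref$profiles)) {
    stop_config("feature registries differ between cells and reference")
  }
  types <- rownames(ref$profiles)
  if (identical(prior, "uniform")) {
    log_prior <- rep(0, length(types))
  } else {
    if (length(prior) != length(types)) stop_config("prior length mismatch")
    assert_prob(prior, "prior", tol = 1e-8)
    log_prior <- log(prior)
  }
  # cell x type log-likelihood; log profiles are finite (pseudocounted)
  ll <- as.matrix(Matrix::t(mat) %*% t(log(ref$profiles)))
  ll <- sweep(ll, 2L, log_prior, "+")
  zero_count <- Matrix::colSums(mat) == 0
  mx <- apply(ll, 1L, max)
  post <- exp(ll - mx)
  post <- post / rowSums(post)
  dimnames(post) <- list(colnames(mat), types)
  label <- types[max.col(post, ties.method = "first")]
  if (any(zero_count)) {
    warning(sprintf("%d zero-count cells: posterior equals the prior",
                    sum(zero_count)))
  }
  list(posterior = post, label = setNames(label, colnames(mat)),
       zero_count = zero_count)
}
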