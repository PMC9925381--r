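# Deconvolution of double-incubated cells: counts are modelled as N draws
# from a w-weighted mixture of one active-mark cell-type multinomial
# (profile p_c) and one repressive-mark lineage multinomial (profile q_l);
# model selection over (c, l) pairs with profile-likelihood w.

#' Build a mixture reference from single-incubated pseudobulks
#'
#' Converts per-cluster pseudobulk counts of the active mark and the
#' repressive mark, on one shared feature registry, into pseudocounted
#' probability vectors p_c and q_l.
#'
#' @param active_pseudobulk Cluster x feature count matrix (active mark).
#' @param repressive_pseudobulk Cluster x feature count matrix
#'   (repressive mark), same features.
#' @param pseudocount Added to every count before normalisation; default 1
#'   (guarantees strictly positive profiles, hence finite likelihoods).
#' @return A `mixture_reference` with `p` (cluster x feature, rows sum to
#'   1), `q`, `features`, `pseudocount`.
#' @export
build_reference <- function(active_pseudobulk, repressive_pseudobulk,
                            pseudocount = 1) {
  p <- as_dense(active_pseudobulk); q <- as_dense(repressive_pseudobulk)
  if (ncol(p) != ncol(q)) stop_config("pseudobulks must share the feature registry")
  if (nrow(p) == 0L || nrow(q) == 0L) stop_config("empty cluster set")
  if (any(rowSums(p) + pseudocount * ncol(p) == 0) ||
      any(rowSums(q) + pseudocount * ncol(q) == 0)) {
    stop_config("empty cluster: all-zero counts with zero pseudocount")
  }
  norm <- function(m) {
    m <- m + pseudocount
    sweep(m, 1L, rowSums(m), "/")
  }
  structure(list(p = norm(p), q = norm(q),
                 features = colnames(p) %||% paste0("f", seq_len(ncol(p))),
                 pseudocount = pseudocount),
            class = "mixture_reference")
}

#' Mixture log-likelihood of a count vector for one (p, q, w)
#'
#' `sum_i y_i * log(w p_i + (1 - w) q_i)`, the multinomial log-likelihood
#' up to the multinomial coefficient (constant across candidate models,
#' so dropped). Features where both profiles are zero but the count is
#' positive give `-Inf`; pseudocounted references prevent this.
#'
#' @param y Count vector.
#' @param p,q Probability vectors on the same registry.
#' @param w Mixing fraction in \[0, 1\].
#' @return Log-likelihood (natural log), constant dropped.
#' @export
pair_loglik <- function(y, p, q, w) {
  if (w < 0 || w > 1) stop_config("w must lie in [0,1]")
  if (length(y) != length(p) || length(p) != length(q)) {
    stop_config("registries not aligned")
  }
  nz <- which(y > 0)
  mix <- w * p[nz] + (1 - w) * q[nz]
  sum(y[nz] * log(mix))
}

#' Maximum-likelihood mixing fraction for one (p, q) pair
#'
#' The mixture log-likelihood is concave in w, so a golden-section search
#' (via `stats::optimize`) on \[0, 1\] finds the global maximum. When the
#' two profiles coincide the likelihood is flat in w; 0.5 is returned with
#' a flag.
#'
#' @param y Count vector.
#' @param p,q Probability vectors.
#' @param tol Search tolerance on w; default 1e-4.
#' @return List with `w_hat`, `loglik` at the optimum, and `flat`
#'   (TRUE when p = q and w is unidentifiable).
#' @export
fit_w <- function(y, p, q, tol = 1e-4) {
  if (isTRUE(all.equal(p, q, tolerance = 1e-12))) {
    return(list(w_hat = 0.5, loglik = pair_loglik(y, p, q, 0.5), flat = TRUE))
  }
  opt <- optimize(function(w) pair_loglik(y, p, q, w),
                  interval = c(0, 1), maximum = TRUE, tol = tol)
  # the optimizer never evaluates the exact endpoints; take them if better
  cand <- c(opt$maximum, 0, 1)
  ll <- c(opt$objective, pair_loglik(y, p, q, 0), pair_loglik(y, p, q, 1))
  best <- which.max(ll)
  list(w_hat = cand[best], loglik = ll[best], flat = FALSE)
}

#' Assign a double-incubated cell to a (cell type, lineage) pair
#'
#' Evaluates the profile log-likelihood of every (c, l) pair — maximising
#' over w per pair, or at a fixed w — and selects the maximum. The
#' posterior over pairs is the softmax of the log-likelihoods under a
#' uniform pair prior. Exact ties are broken lexicographically (active
#' cluster first) and flagged.
#'
#' @param y Count vector for one cell on the reference registry.
#' @param ref A [build_reference()] result.
#' @param w_mode `"free"` (per-pair maximum-likelihood w, default) or a
#'   fixed numeric w in \[0, 1\].
#' @param tol Tolerance for the w search.
#' @return A `pair_assignment`: `best` (c, l labels), `w_hat`, `loglik`
#'   (c x l table), `w` (c x l table of fitted w), `posterior` (sums to
#'   1), `N` (total reads), `tie` flag.
#' @export
assign_pair <- function(y, ref, w_mode = "free", tol = 1e-4) {
  stopifnot(inherits(ref, "mixture_reference"))
  if (length(y) != ncol(ref$p)) stop_config("cell vector not on reference registry")
  fixed_w <- NULL
  if (is.numeric(w_mode)) {
    if (w_mode < 0 || w_mode > 1) stop_config("fixed w must lie in [0,1]")
    fixed_w <- w_mode
  } else if (!identical(w_mode, "free")) {
    stop_config("w_mode must be 'free' or a numeric w")
  }
  cs <- rownames(ref$p) %||% paste0("c", seq_len(nrow(ref$p)))
  ls <- rownames(ref$q) %||% paste0("l", seq_len(nrow(ref$q)))
  ll <- matrix(NA_real_, length(cs), length(ls), dimnames = list(cs, ls))
  wmat <- ll
  for (i in seq_along(cs)) {
    for (j in seq_along(ls)) {
      if (is.null(fixed_w)) {
        f <- fit_w(y, ref$p[i, ], ref$q[j, ], tol = tol)
        ll[i, j] <- f$loglik; wmat[i, j] <- f$w_hat
      } else {
        ll[i, j] <- pair_loglik(y, ref$p[i, ], ref$q[j, ], fixed_w)
        wmat[i, j] <- fixed_w
      }
    }
  }
  mx <- max(ll)
  post <- exp(ll - mx)
  post <- post / sum(post)
  hits <- which(ll == mx, arr.ind = TRUE)
  tie <- nrow(hits) > 1L
  hits <- hits[order(hits[, 1L], hits[, 2L]), , drop = FALSE]
  best <- c(c = cs[hits[1L, 1L]], l = ls[hits[1L, 2L]])
  structure(list(best = best, w_hat = wmat[hits[1L, 1L], hits[1L, 2L]],
                 loglik = ll, w = wmat, posterior = post,
                 N = sum(y), tie = tie),
            class = "pair_assignment")
}

#' @export
print.pair_assignment <- function(x, ...) {
  cat(sprintf("Double-incubation assignment: (%s, %s), w = %.3f, N = %d%s\n",
              x$best[["c"]], x$best[["l"]], x$w_hat, x$N,
              if (x$tie) " [tie]" else ""))
  invisible(x)
}

#' Assign every column of a count matrix to a pair
#'
#' @param counts Feature x cell count matrix on the reference registry.
#' @param ref A [build_reference()] result.
#' @param ... Passed to [assign_pair()].
#' @return data.frame with one row per cell: best c, best l, `w_hat`,
#'   max log-likelihood, posterior of the best pair, `N`, tie flag.
#' @export
assign_pairs <- function(counts, ref, ...) {
  counts <- as_dense(counts)
  rows <- lapply(seq_len(ncol(counts)), function(i) {
    a <- assign_pair(counts[, i], ref, ...)
    data.frame(cell = colnames(counts)[i] %||% paste0("cell", i),
               c = a$best[["c"]], l = a$best[["l"]], w_hat = a$w_hat,
               loglik = max(a$loglik), posterior = max(a$posterior),
               N = a$N, tie = a$tie, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
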