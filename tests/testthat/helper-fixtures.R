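# Shared fixtures built in code: cluster profile sets, small cut tables,
# and a constructor for differential-result tables with known folds.

# Well-separated probability profiles, one per cluster, over n_feature
# regions (sparse-gamma draws, normalised).
make_profiles <- function(n_cluster, n_feature, seed, conc = 0.3,
                          prefix = "c") {
  withr::with_seed(seed, {
    m <- matrix(rgamma(n_cluster * n_feature, shape = conc) + 1e-9,
                n_cluster, n_feature)
    m <- m / rowSums(m)
    dimnames(m) <- list(paste0(prefix, seq_len(n_cluster)),
                        paste0("f", seq_len(n_feature)))
    m
  })
}

# Minimal diff_result-like table for fate-independence tests: log2fc is a
# region x type matrix for the non-reference types.
make_diff_result <- function(log2fc, dynamic, reference = "ref") {
  types <- colnames(log2fc)
  out <- data.frame(region = rownames(log2fc),
                    q = ifelse(dynamic, 0, 1), dynamic = dynamic,
                    stringsAsFactors = FALSE)
  out[[paste0("log2fc_", reference)]] <- 0
  for (t in types) out[[paste0("log2fc_", t)]] <- log2fc[, t]
  attr(out, "reference") <- reference
  attr(out, "types") <- c(reference, types)
  class(out) <- c("diff_result", "data.frame")
  out
}

# A tiny deterministic cut table spread over two chromosomes.
make_cut_table <- function(n = 100, seed = 42) {
  withr::with_seed(seed, {
    data.frame(
      chrom = sample(c("chr1", "chr2"), n, replace = TRUE),
      pos = sample.int(120000, n) - 1L,
      cell = sample(paste0("cell", 1:5), n, replace = TRUE),
      count = sample(1:3, n, replace = TRUE),
      stringsAsFactors = FALSE)
  })
}

ari <- function(a, b) mclust::adjustedRandIndex(a, b)
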