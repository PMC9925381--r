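test_that("genome tiling produces half-open truncated bins", {
  b <- make_bins(c(chr1 = 120000), width = 50000)
  expect_equal(b$start, c(0, 50000, 100000))
  expect_equal(b$end, c(50000, 100000, 120000))
  # width equal to the chromosome gives a single bin
  expect_equal(nrow(make_bins(c(chr1 = 50000), width = 50000)), 1)
  # default width is 50 kb
  expect_equal(formals(make_bins)$width, 50000)
  expect_error(make_bins(numeric(0)), "empty genome")
})

test_that("TSS windows clip at zero and disambiguate duplicate genes", {
  tss <- data.frame(chrom = "chr1", tss = c(100000, 2000, 50000),
                    strand = c("+", "-", "+"),
                    gene = c("GeneA", "GeneB", "GeneA"))
  w <- make_tss_windows(tss, halfwidth = 5000)
  expect_equal(w$start[1], 95000)
  expect_equal(w$end[1], 105000)
  expect_equal(w$start[2], 0)   # clipped at chromosome start
  expect_equal(w$end[2], 7000)
  expect_false(anyDuplicated(w$id) > 0)
  expect_equal(formals(make_tss_windows)$halfwidth, 5000)
  tss$strand[1] <- "x"
  expect_error(make_tss_windows(tss), "strand")
})

test_that("cut counting respects half-open boundaries and conserves totals", {
  bins <- make_bins(c(chr1 = 120000), width = 50000)
  cuts <- data.frame(chrom = "chr1", pos = c(0, 49999, 50000, 119999),
                     cell = "cellA", count = 1)
  m <- count_cuts(cuts, bins)
  expect_equal(as.numeric(m[, 1]), c(2, 1, 1))

  # brute-force double-loop oracle on a random 100-cut fixture
  cuts100 <- make_cut_table(100)
  regions <- rbind(make_bins(c(chr1 = 120000), 30000),
                   make_bins(c(chr2 = 90000), 30000))
  m100 <- count_cuts(cuts100, regions)
  brute <- matrix(0, nrow(regions), 5,
                  dimnames = list(regions$id, paste0("cell", 1:5)))
  for (i in seq_len(nrow(cuts100))) {
    for (r in seq_len(nrow(regions))) {
      if (cuts100$chrom[i] == regions$chrom[r] &&
          cuts100$pos[i] >= regions$start[r] &&
          cuts100$pos[i] < regions$end[r]) {
        brute[r, cuts100$cell[i]] <- brute[r, cuts100$cell[i]] + cuts100$count[i]
      }
    }
  }
  expect_equal(as.matrix(m100)[, colnames(brute)], brute)
  expect_equal(sum(m100), sum(brute))

  # unknown chromosomes are dropped with a warning, full registries kept
  cuts_bad <- rbind(cuts, data.frame(chrom = "chrX", pos = 5, cell = "cellA",
                                     count = 2))
  expect_warning(m2 <- count_cuts(cuts_bad, bins), "dropped 2")
  expect_equal(sum(m2), 4)
  empty <- count_cuts(cuts[0, ], bins, cells = "cellA")
  expect_equal(dim(empty), c(3L, 1L))
  expect_equal(sum(empty), 0)
})

test_that("overlapping regions are rejected unless count-in-all is chosen", {
  ov <- data.frame(chrom = "chr1", start = c(0, 500), end = c(1000, 1500),
                   id = c("a", "b"))
  cuts <- data.frame(chrom = "chr1", pos = 700, cell = "c1", count = 1)
  expect_error(count_cuts(cuts, ov), "overlap")
  m <- count_cuts(cuts, ov, overlap_ok = TRUE)
  expect_equal(as.numeric(m), c(1, 1))
})

test_that("fraction in peaks matches hand counts", {
  peaks <- data.frame(chrom = "chr1", start = 0, end = 100, id = "pk1")
  cuts <- data.frame(chrom = "chr1", pos = c(10, 50, 99, 100, 150, 200),
                     cell = "c1", count = 1)
  expect_equal(fraction_in_peaks(cuts, peaks), 0.5)  # 3 of 6
  expect_equal(fraction_in_peaks(cuts[1:3, ], peaks), 1)
  expect_equal(fraction_in_peaks(cuts[4:6, ], peaks), 0)
  expect_warning(v <- fraction_in_peaks(cuts[0, ], peaks), "undefined")
  expect_true(is.na(v))
  pc <- fraction_in_peaks(rbind(cuts, data.frame(chrom = "chr1", pos = 5,
                                                 cell = "c2", count = 2)),
                          peaks, per_cell = TRUE)
  expect_equal(unname(pc), c(0.5, 1))
})

test_that("gini matches the explicit pairwise-difference oracle", {
  expect_equal(gini(rep(7, 10)), 0)
  # oracle: mean absolute pairwise difference / (2 * mean), all pairs
  pair_gini <- function(x) {
    n <- length(x)
    sum(abs(outer(x, x, "-"))) / (2 * n^2 * mean(x))
  }
  expect_equal(gini(c(0, 0, 0, 10)), 0.75)
  expect_equal(pair_gini(c(0, 0, 0, 10)), 0.75)
  withr::with_seed(1, {
    for (i in 1:5) {
      x <- rpois(20, 3)
      expect_equal(gini(x), pair_gini(x))
      expect_equal(gini(x * 13.7), gini(x))  # scale invariance
      expect_true(gini(x) >= 0 && gini(x) < 1)
    }
  })
  expect_equal(gini(rep(0, 5)), 0)
  expect_error(gini(c(-1, 2)), "nonnegative")
})

test_that("signal enrichment is the coverage-normalised in-peak fraction", {
  marked <- data.frame(chrom = "chr1", start = 0, end = 100, id = "m")
  cuts_in <- data.frame(chrom = "chr1", pos = c(10, 20), cell = "c", count = 1)
  expect_equal(signal_enrichment(cuts_in, marked, genome_size = 1000), 10)
  # whole genome marked: exactly 1
  whole <- data.frame(chrom = "chr1", start = 0, end = 1000, id = "w")
  expect_equal(signal_enrichment(cuts_in, whole, 1000), 1)
  # uniform cuts: enrichment near 1 (uniform-sampling oracle)
  unif <- withr::with_seed(3, data.frame(chrom = "chr1",
                                         pos = sample.int(1000, 5000, TRUE) - 1L,
                                         cell = "c", count = 1))
  expect_equal(signal_enrichment(unif, marked, 1000), 1, tolerance = 0.15)
  expect_error(signal_enrichment(cuts_in, marked, genome_size = 50), "cover")
})

test_that("cell filtering removes exactly the planted low-depth cells", {
  m <- Matrix::Matrix(cbind(lowA = c(1, 0), ok1 = c(50, 60), lowB = c(2, 1),
                            ok2 = c(30, 30)), sparse = TRUE)
  rownames(m) <- c("r1", "r2")
  res <- filter_cells(m, min_cuts = 10)
  expect_equal(colnames(res$counts), c("ok1", "ok2"))
  expect_equal(res$qc$reason[!res$qc$pass], c("low_cuts", "low_cuts"))
  expect_equal(sum(res$qc$pass) + sum(!res$qc$pass), 4)
  # zero thresholds keep everything
  expect_equal(ncol(filter_cells(m, min_cuts = 0)$counts), 4)
  expect_error(filter_cells(m, min_cuts = 1000), "all 4 cells")
})

test_that("background calling finds the valley of a bimodal log bin-sum", {
  withr::with_seed(9, {
    lo <- rlnorm(400, meanlog = log(10), sdlog = 0.3)
    hi <- rlnorm(400, meanlog = log(1000), sdlog = 0.3)
    sums <- c(lo, hi)
    m <- Matrix::Matrix(matrix(round(sums), ncol = 1), sparse = TRUE)
    rownames(m) <- paste0("bin", seq_along(sums))
    mask <- bins_above_background(m)
    truth <- c(rep(FALSE, 400), rep(TRUE, 400))
    expect_lt(mean(mask != truth), 0.01)
    # manual cutoff overrides the automatic valley
    mask2 <- bins_above_background(m, manual_cutoff = log10(100))
    expect_equal(as.vector(mask2), unname(round(sums) > 100))
    expect_equal(attr(mask2, "cutoff"), 2)
  })
  flat <- Matrix::Matrix(matrix(5, 10, 2), sparse = TRUE)
  rownames(flat) <- paste0("b", 1:10)
  expect_warning(mk <- bins_above_background(flat), "keeping all")
  expect_true(all(mk))
})

test_that("pseudobulk conserves totals and handles degenerate groupings", {
  withr::with_seed(4, {
    m <- Matrix::Matrix(matrix(rpois(60, 2), 10, 6), sparse = TRUE,
                        dimnames = list(paste0("r", 1:10), paste0("c", 1:6)))
  })
  lab <- rep(c("g1", "g2"), each = 3)
  pb <- pseudobulk(m, lab)
  expect_equal(sum(pb), sum(m))
  expect_equal(pb["g1", ], Matrix::rowSums(m[, 1:3]))
  # one group: row equals matrix row sums
  one <- pseudobulk(m, rep("all", 6))
  expect_equal(unname(one[1, ]), unname(Matrix::rowSums(m)))
  # singleton groups: identity up to transpose
  single <- pseudobulk(m, paste0("c", 1:6))
  expect_equal(unname(single), unname(t(as.matrix(m))))
  expect_error(pseudobulk(m, lab[1:3]), "label")
})
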