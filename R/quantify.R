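# Quantification and QC: cut tables -> region x cell matrices, FRiP, Gini,
# signal enrichment, cell filtering, above-background bin calling and
# pseudobulks. All genomic coordinates are 0-based half-open, matching BED.

region_set <- function(chrom, start, end, id) {
  if (any(start < 0) || any(end <= start)) {
    stop_config("regions must satisfy 0 <= start < end")
  }
  id <- as.character(id)
  if (anyDuplicated(id)) stop_config("region ids must be unique")
  data.frame(chrom = as.character(chrom), start = as.numeric(start),
             end = as.numeric(end), id = id, stringsAsFactors = FALSE)
}

#' Tile a genome into fixed-width bins
#'
#' Produces non-overlapping half-open bins per chromosome; the final bin is
#' truncated at the chromosome end. The 50 kb default is the genome-wide
#' feature width used for histone-mark count matrices.
#'
#' @param chrom_sizes Named numeric vector of chromosome lengths (bp).
#' @param width Bin width in bp, default 50000.
#' @return A region data.frame (chrom, start, end, id) in 0-based
#'   half-open coordinates.
#' @export
make_bins <- function(chrom_sizes, width = 50000) {
  if (length(chrom_sizes) == 0L) stop_config("empty genome")
  if (width < 1) stop_config("width must be >= 1")
  if (any(chrom_sizes < 1)) stop_config("chromosome sizes must be >= 1")
  pieces <- lapply(names(chrom_sizes), function(ch) {
    len <- chrom_sizes[[ch]]
    starts <- seq(0, len - 1, by = width)
    ends <- pmin(starts + width, len)
    data.frame(chrom = ch, start = starts, end = ends,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, pieces)
  region_set(out$chrom, out$start, out$end,
             sprintf("%s:%d-%d", out$chrom, as.integer(out$start),
                     as.integer(out$end)))
}

#' Build windows around transcription start sites
#'
#' One half-open window `[tss - halfwidth, tss + halfwidth)` per TSS,
#' clipped at 0 and (when `chrom_sizes` is given) at the chromosome end.
#' The default half-width of 5 kb matches the promoter windows used to
#' define cell-type marker genes. Duplicate gene names are disambiguated
#' with a numeric suffix.
#'
#' @param tss_table data.frame with columns chrom, tss, strand, gene.
#' @param halfwidth Window half-width in bp, default 5000.
#' @param chrom_sizes Optional named vector for right clipping.
#' @return Region data.frame with gene-derived ids.
#' @export
make_tss_windows <- function(tss_table, halfwidth = 5000, chrom_sizes = NULL) {
  if (halfwidth < 1) stop_config("halfwidth must be >= 1")
  if (!all(tss_table$strand %in% c("+", "-"))) {
    stop_config("strand must be '+' or '-'")
  }
  start <- pmax(0, tss_table$tss - halfwidth)
  end <- tss_table$tss + halfwidth
  if (!is.null(chrom_sizes)) {
    end <- pmin(end, chrom_sizes[tss_table$chrom])
  }
  gene <- as.character(tss_table$gene)
  dup <- duplicated(gene) | duplicated(gene, fromLast = TRUE)
  if (any(dup)) {
    gene <- make.unique(gene, sep = "_")
  }
  region_set(tss_table$chrom, start, end, gene)
}

#' Count cut events in regions, per cell
#'
#' Assigns each deduplicated cut at position p to the region with
#' `start <= p < end`. Cuts on chromosomes absent from the region registry
#' are dropped with a warning that reports the dropped event count.
#'
#' @param cuts data.frame with columns chrom, pos, cell, count (count is
#'   the deduplicated cut multiplicity, >= 1).
#' @param regions Region data.frame; must be non-overlapping unless
#'   `overlap_ok = TRUE`, in which case a cut is counted in every region
#'   containing it.
#' @param overlap_ok Allow overlapping regions (count-in-all policy).
#' @param cells Optional character vector fixing the cell registry (zero
#'   columns are kept for cells with no in-region cuts).
#' @return Sparse region x cell integer matrix with full registries.
#' @export
count_cuts <- function(cuts, regions, overlap_ok = FALSE, cells = NULL) {
  stopifnot(all(c("chrom", "pos", "cell", "count") %in% names(cuts)))
  if (is.null(cells)) cells <- sort(unique(as.character(cuts$cell)))
  n_reg <- nrow(regions)
  mat <- Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                              dims = c(n_reg, length(cells)),
                              dimnames = list(regions$id, cells))
  dropped <- sum(cuts$count[!(cuts$chrom %in% regions$chrom)])
  if (dropped > 0) {
    warning(sprintf("dropped %d cut events on chromosomes absent from the region set",
                    dropped))
  }
  if (!overlap_ok) {
    ord <- order(regions$chrom, regions$start)
    for (ch in unique(regions$chrom)) {
      ri <- ord[regions$chrom[ord] == ch]
      st <- regions$start[ri]; en <- regions$end[ri]
      if (length(ri) > 1L && any(st[-1L] < en[-length(en)])) {
        stop_config("overlapping regions on %s; set overlap_ok = TRUE for count-in-all",
                    ch)
      }
      sel <- cuts$chrom == ch
      if (!any(sel)) next
      pos <- cuts$pos[sel]
      idx <- findInterval(pos, st)
      hit <- idx >= 1L & pos < en[pmax(idx, 1L)]
      if (!any(hit)) next
      tri <- ri[idx[hit]]
      cj <- match(as.character(cuts$cell[sel][hit]), cells)
      mat <- mat + Matrix::sparseMatrix(
        i = tri, j = cj, x = cuts$count[sel][hit],
        dims = dim(mat), dimnames = dimnames(mat))
    }
  } else {
    for (r in seq_len(n_reg)) {
      sel <- cuts$chrom == regions$chrom[r] &
        cuts$pos >= regions$start[r] & cuts$pos < regions$end[r]
      if (!any(sel)) next
      cj <- match(as.character(cuts$cell[sel]), cells)
      mat <- mat + Matrix::sparseMatrix(
        i = rep(r, sum(sel)), j = cj, x = cuts$count[sel],
        dims = dim(mat), dimnames = dimnames(mat))
    }
  }
  as(mat, "CsparseMatrix")
}

#' Fraction of cut events falling inside peaks
#'
#' The specificity metric FRiP: in-peak events divided by total events,
#' overall or per cell.
#'
#' @param cuts Cut table (chrom, pos, cell, count).
#' @param peaks Region data.frame of peak intervals.
#' @param per_cell Return one fraction per cell instead of the pooled one.
#' @return Fraction(s) in \[0, 1\]; `NA` with a warning when a cell (or the
#'   pool) has zero events.
#' @export
fraction_in_peaks <- function(cuts, peaks, per_cell = FALSE) {
  in_peak <- rep(FALSE, nrow(cuts))
  for (ch in unique(peaks$chrom)) {
    pk <- peaks[peaks$chrom == ch, , drop = FALSE]
    pk <- pk[order(pk$start), , drop = FALSE]
    sel <- which(cuts$chrom == ch)
    if (!length(sel)) next
    idx <- findInterval(cuts$pos[sel], pk$start)
    in_peak[sel] <- idx >= 1L & cuts$pos[sel] < pk$end[pmax(idx, 1L)]
  }
  if (!per_cell) {
    tot <- sum(cuts$count)
    if (tot == 0) {
      warning("no cut events; fraction in peaks undefined")
      return(NA_real_)
    }
    return(sum(cuts$count[in_peak]) / tot)
  }
  cells <- sort(unique(as.character(cuts$cell)))
  tot <- tapply(cuts$count, factor(cuts$cell, levels = cells), sum,
                default = 0)
  hit <- tapply(cuts$count * in_peak, factor(cuts$cell, levels = cells), sum,
                default = 0)
  out <- as.numeric(hit) / as.numeric(tot)
  if (anyNA(out) || any(tot == 0)) warning("cells with zero events: FRiP undefined")
  setNames(out, cells)
}

#' Gini coefficient of a nonnegative count vector
#'
#' Mean absolute pairwise difference divided by twice the mean, computed
#' with the sorted-cumulative formula. 0 for perfectly even coverage, near
#' 1 when signal concentrates in few regions; scale-invariant.
#'
#' @param counts Nonnegative numeric vector.
#' @return Gini coefficient in \[0, 1\); 0 for an all-zero vector.
#' @export
gini <- function(counts) {
  if (length(counts) == 0L) stop_config("empty vector")
  if (any(counts < 0)) stop_config("counts must be nonnegative")
  n <- length(counts)
  s <- sum(counts)
  if (s == 0) return(0)
  x <- sort(counts)
  2 * sum(seq_len(n) * x) / (n * s) - (n + 1) / n
}

#' Signal enrichment of cuts in marked regions
#'
#' Fraction of cuts inside the marked regions divided by the fraction of
#' the genome they cover; 1 for uniform coverage, larger when cuts
#' concentrate in the marked territory.
#'
#' @param cuts Cut table.
#' @param marked Region data.frame of marked intervals.
#' @param genome_size Total genome size in bp.
#' @return Enrichment ratio >= 0; `NA` with a warning when there are no
#'   cuts.
#' @export
signal_enrichment <- function(cuts, marked, genome_size) {
  covered <- sum(marked$end - marked$start)
  if (covered <= 0 || covered > genome_size) {
    stop_config("marked regions must cover between 1 bp and the genome")
  }
  tot <- sum(cuts$count)
  if (tot == 0) {
    warning("no cut events; signal enrichment undefined")
    return(NA_real_)
  }
  frip <- fraction_in_peaks(cuts, marked)
  frip / (covered / genome_size)
}

#' Filter cells on depth and fraction-in-peaks
#'
#' Removes cells whose total cut count falls below `min_cuts` or whose
#' FRiP falls below `min_frip`, and reports per-cell QC with the reason
#' for each failure.
#'
#' @param mat Region x cell count matrix.
#' @param min_cuts Minimum total cuts per cell (default 0: keep all).
#' @param min_frip Optional minimum fraction-in-peaks; requires `frip`.
#' @param frip Optional named per-cell FRiP vector (from
#'   [fraction_in_peaks()] with `per_cell = TRUE`).
#' @return List with `counts` (filtered matrix) and `qc` (data.frame cell,
#'   total_cuts, frip, pass, reason).
#' @export
filter_cells <- function(mat, min_cuts = 0, min_frip = NULL, frip = NULL) {
  if (min_cuts < 0) stop_config("min_cuts must be >= 0")
  total <- Matrix::colSums(mat)
  pass <- total >= min_cuts
  reason <- ifelse(pass, "", "low_cuts")
  fr <- rep(NA_real_, ncol(mat))
  if (!is.null(min_frip)) {
    if (is.null(frip)) stop_config("min_frip given but no per-cell frip values")
    fr <- frip[colnames(mat)]
    fail_frip <- !is.na(fr) & fr < min_frip
    reason[fail_frip] <- trimws(paste(reason[fail_frip], "low_frip"))
    pass <- pass & !fail_frip
  }
  if (!any(pass)) {
    stop_config("all %d cells removed (min_cuts = %g); check thresholds",
                ncol(mat), min_cuts)
  }
  qc <- data.frame(cell = colnames(mat), total_cuts = as.numeric(total),
                   frip = as.numeric(fr), pass = pass, reason = reason,
                   stringsAsFactors = FALSE)
  list(counts = mat[, pass, drop = FALSE], qc = qc)
}

#' Call bins above background from the bimodal log bin-sum distribution
#'
#' Sums counts per bin over all cells; in log10 space the summed counts of
#' real single-cell histone-mark data are bimodal (background vs marked
#' bins). The threshold is placed at the minimum-density valley between the
#' two largest modes of a kernel density estimate, or at `manual_cutoff`
#' (log10 scale) when supplied. Bins strictly above the threshold are kept.
#' When no valley exists (unimodal or degenerate input) all bins are kept
#' with a warning.
#'
#' @param mat Region x cell count matrix (>= 2 bins).
#' @param manual_cutoff Optional manual log10 bin-sum cutoff overriding the
#'   automatic rule.
#' @return Logical mask over bins (`TRUE` = above background), with the
#'   chosen log10 cutoff in attribute `cutoff`.
#' @export
bins_above_background <- function(mat, manual_cutoff = NULL) {
  if (nrow(mat) < 2L) stop_config("need >= 2 bins")
  sums <- Matrix::rowSums(mat)
  lg <- log10(sums[sums > 0])
  if (!is.null(manual_cutoff)) {
    mask <- sums > 0 & log10(pmax(sums, 1e-300)) > manual_cutoff
    attr(mask, "cutoff") <- manual_cutoff
    names(mask) <- rownames(mat)
    return(mask)
  }
  if (length(unique(lg)) < 2L) {
    warning("bin sums carry no spread; no background valley, keeping all bins")
    mask <- rep(TRUE, nrow(mat))
    names(mask) <- rownames(mat)
    attr(mask, "cutoff") <- -Inf
    return(mask)
  }
  d <- density(lg)
  y <- d$y
  is_max <- which(diff(sign(diff(y))) == -2) + 1L
  if (length(is_max) < 2L) {
    warning("log bin-sum density is unimodal; keeping all bins")
    mask <- rep(TRUE, nrow(mat))
    names(mask) <- rownames(mat)
    attr(mask, "cutoff") <- -Inf
    return(mask)
  }
  top2 <- is_max[order(y[is_max], decreasing = TRUE)][1:2]
  lo <- min(top2); hi <- max(top2)
  valley <- lo + which.min(y[lo:hi]) - 1L
  cutoff <- d$x[valley]
  mask <- log10(pmax(sums, 1e-300)) > cutoff & sums > 0
  names(mask) <- rownames(mat)
  attr(mask, "cutoff") <- cutoff
  mask
}

#' Sum single-cell counts into pseudobulk profiles
#'
#' @param mat Region x cell count matrix.
#' @param labels Per-cell group labels (named or in column order); every
#'   cell must be labelled.
#' @return Group x region matrix of summed counts; the grand total equals
#'   the input total.
#' @export
pseudobulk <- function(mat, labels) {
  if (!is.null(names(labels))) labels <- labels[colnames(mat)]
  if (length(labels) != ncol(mat) || anyNA(labels)) {
    stop_config("every cell must carry a group label")
  }
  groups <- sort(unique(as.character(labels)))
  ind <- Matrix::sparseMatrix(
    i = match(as.character(labels), groups), j = seq_along(labels), x = 1,
    dims = c(length(groups), length(labels)))
  out <- as.matrix(ind %*% Matrix::t(mat))
  dimnames(out) <- list(groups, rownames(mat))
  out
}
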