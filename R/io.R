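# Standard-format I/O: sparse counts as Matrix Market with row/column
# registries, regions as BED (0-based half-open, the native BED
# convention), cell metadata and results as TSV, configs as YAML.

#' Write a sparse count matrix as Matrix Market plus registries
#'
#' Writes `<prefix>.mtx`, `<prefix>.rows.tsv` (region ids) and
#' `<prefix>.cols.tsv` (cell ids).
#'
#' @param mat Region x cell matrix (coerced to sparse).
#' @param prefix Output path prefix.
#' @return Invisibly, the three file paths.
#' @export
write_counts <- function(mat, prefix) {
  m <- as(Matrix::Matrix(mat, sparse = TRUE), "CsparseMatrix")
  paths <- paste0(prefix, c(".mtx", ".rows.tsv", ".cols.tsv"))
  Matrix::writeMM(m, paths[1L])
  writeLines(rownames(m) %||% paste0("region", seq_len(nrow(m))), paths[2L])
  writeLines(colnames(m) %||% paste0("cell", seq_len(ncol(m))), paths[3L])
  invisible(paths)
}

#' Read a count matrix written by [write_counts()]
#'
#' @param prefix Path prefix used at write time.
#' @return Sparse region x cell matrix with registries as dimnames.
#' @export
read_counts <- function(prefix) {
  m <- as(Matrix::readMM(paste0(prefix, ".mtx")), "CsparseMatrix")
  dimnames(m) <- list(readLines(paste0(prefix, ".rows.tsv")),
                      readLines(paste0(prefix, ".cols.tsv")))
  m
}

#' Write regions as BED
#'
#' BED is natively 0-based half-open, matching the package's coordinate
#' convention, so values are written verbatim. Input row order is
#' preserved.
#'
#' @param regions Region data.frame (chrom, start, end, id).
#' @param path Output file.
#' @export
write_bed <- function(regions, path) {
  write.table(regions[, c("chrom", "start", "end", "id")], path,
              sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED file of regions
#'
#' Accepts 3+ columns; a missing name column is filled with
#' `chrom:start-end` ids. Input order (sorted or not) is preserved.
#'
#' @param path BED file.
#' @return Region data.frame in 0-based half-open coordinates.
#' @export
read_bed <- function(path) {
  raw <- tryCatch(
    read.table(path, sep = "\t", header = FALSE, stringsAsFactors = FALSE),
    error = function(e) stop_config("malformed BED '%s': %s", path,
                                    conditionMessage(e)))
  if (ncol(raw) < 3L) stop_config("BED '%s' needs >= 3 columns", path)
  id <- if (ncol(raw) >= 4L) as.character(raw[[4L]]) else
    sprintf("%s:%d-%d", raw[[1L]], as.integer(raw[[2L]]), as.integer(raw[[3L]]))
  region_set(raw[[1L]], raw[[2L]], raw[[3L]], id)
}

#' Write a cut table or cell metadata as TSV
#'
#' Missing values are written as empty fields and survive a round trip.
#'
#' @param df data.frame.
#' @param path Output file.
#' @export
write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "")
  invisible(path)
}

#' Read a TSV written by [write_tsv()]
#'
#' @param path Input file.
#' @return data.frame with empty fields restored as NA.
#' @export
read_tsv <- function(path) {
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
             na.strings = "", quote = "")
}
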