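#' Fragment-count matrices over a peak set
#'
#' A `counts_matrix` couples a non-negative peaks-by-samples matrix with its
#' `peak_set` (supplying coordinates and hence peak lengths) and optional
#' per-sample metadata (`cell_type`, `study`). Rows are named by peak id and
#' columns by sample id.
#'
#' @param values numeric matrix, peaks x samples, non-negative.
#' @param peaks `peak_set` with `nrow(peaks) == nrow(values)`.
#' @param sample_meta optional data.frame with `sample_id` and, typically,
#'   `cell_type` and `study` columns.
#' @return A `counts_matrix` object.
#' @export
counts_matrix <- function(values, peaks, sample_meta = NULL) {
  values <- as.matrix(values)
  if (!is_peak_set(peaks)) stopf("peaks must be a peak_set")
  if (nrow(values) != nrow(peaks))
    stopf("values has %d rows but peaks has %d regions", nrow(values),
          nrow(peaks))
  if (any(values < 0)) stopf("counts must be non-negative")
  if (is.null(colnames(values)))
    colnames(values) <- sprintf("S%d", seq_len(ncol(values)))
  if (anyDuplicated(colnames(values))) stopf("duplicate sample ids")
  rownames(values) <- peaks$id
  if (!is.null(sample_meta)) {
    if (!"sample_id" %in% names(sample_meta))
      stopf("sample_meta needs a sample_id column")
    sample_meta <- sample_meta[match(colnames(values),
                                     sample_meta$sample_id), , drop = FALSE]
    if (any(is.na(sample_meta$sample_id)))
      stopf("sample_meta is missing some samples")
    rownames(sample_meta) <- NULL
  }
  structure(list(values = values, peaks = peaks, sample_meta = sample_meta),
            class = "counts_matrix")
}

#' @export
print.counts_matrix <- function(x, ...) {
  cat(sprintf("counts_matrix: %d peaks x %d samples [%s]%s\n",
              nrow(x$values), ncol(x$values), genome_build(x$peaks),
              if (isTRUE(attr(x, "normalized"))) " (TPM-like)" else ""))
  invisible(x)
}

#' @rdname counts_matrix
#' @param x object to test.
#' @export
is_counts_matrix <- function(x) inherits(x, "counts_matrix")

peak_lengths <- function(peaks) peaks$end - peaks$start

#' Read and write counts matrices as TSV
#'
#' The TSV layout is row ids `"chrom:start-end"` in the first column and one
#' column per sample. `read_counts_tsv()` reconstructs the `peak_set` from
#' the row ids.
#'
#' @param path file path (plain or gzipped for reading).
#' @param genome_build build tag for the reconstructed peaks.
#' @param sample_meta optional per-sample metadata (see [counts_matrix()]).
#' @return A `counts_matrix`.
#' @export
read_counts_tsv <- function(path, genome_build = "hg38",
                            sample_meta = NULL) {
  df <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE)
  ids <- df[[1]]
  values <- as.matrix(df[, -1, drop = FALSE])
  peaks <- parse_peak_ids(ids, genome_build = genome_build)
  values <- values[match(peaks$id, ids), , drop = FALSE]
  counts_matrix(values, peaks, sample_meta)
}

#' @rdname read_counts_tsv
#' @param counts a `counts_matrix`.
#' @export
write_counts_tsv <- function(counts, path) {
  df <- data.frame(peak_id = rownames(counts$values),
                   counts$values, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sparse MatrixMarket counts file
#'
#' Companion reader for sparse pseudobulk exports: an MTX triplet file plus
#' one-per-line row-id (`"chrom:start-end"`) and column-id text files.
#'
#' @param mtx,row_ids,col_ids paths to the triplet file and id files.
#' @inheritParams read_counts_tsv
#' @return A dense `counts_matrix`.
#' @export
read_counts_mtx <- function(mtx, row_ids, col_ids, genome_build = "hg38",
                            sample_meta = NULL) {
  if (!requireNamespace("Matrix", quietly = TRUE))
    stopf("the Matrix package is required to read MTX input")
  m <- as.matrix(Matrix::readMM(mtx))
  ids <- readLines(row_ids)
  colnames(m) <- readLines(col_ids)
  peaks <- parse_peak_ids(ids, genome_build = genome_build)
  counts_matrix(m[match(peaks$id, ids), , drop = FALSE], peaks, sample_meta)
}

#' TPM-like normalization of ATAC-Seq counts
#'
#' Divides each count by its peak length (in bp), then rescales every sample
#' so its column sums to 10^6 — the chromatin-accessibility analogue of the
#' transcripts-per-million transform, appropriate for estimating cell
#' fractions because it removes both depth and peak-length effects.
#'
#' @param counts a `counts_matrix` with positive peak lengths.
#' @return A `counts_matrix` whose values are TPM-like (attribute
#'   `normalized` set); every column sums to 10^6.
#' @export
tpm_like <- function(counts) {
  L <- peak_lengths(counts$peaks)
  if (any(L <= 0)) stopf("all peak lengths must be positive")
  rate <- counts$values / L
  tot <- colSums(rate)
  if (any(tot <= 0))
    stopf("sample '%s' has all-zero counts",
          colnames(counts$values)[which(tot <= 0)[1]])
  out <- counts_matrix(sweep(rate, 2, tot, "/") * 1e6, counts$peaks,
                       counts$sample_meta)
  attr(out, "normalized") <- TRUE
  out
}

#' Aggregate bulk counts onto matched reference peaks
#'
#' Given the bulk-to-reference assignment from [match_features()], sums the
#' counts of all bulk peaks mapped to each reference peak (several bulk peaks
#' may share one reference peak); unmatched bulk peaks are discarded. The
#' output rows are the reference peaks that received at least one bulk peak,
#' with lengths taken from the reference coordinates.
#'
#' @param bulk a `counts_matrix` of bulk samples.
#' @param mapping integer vector from [match_features()] (`NA` = unmatched).
#' @param ref_peaks the reference `peak_set` the mapping was built against.
#' @return A `counts_matrix` over the matched reference peaks.
#' @export
aggregate_matched_counts <- function(bulk, mapping, ref_peaks) {
  if (length(mapping) != nrow(bulk$values))
    stopf("mapping length does not match bulk rows")
  keep <- !is.na(mapping)
  if (!any(keep)) stopf("no shared features between bulk and reference")
  idx <- mapping[keep]
  agg <- rowsum(bulk$values[keep, , drop = FALSE], group = idx)
  ref_rows <- as.integer(rownames(agg))
  counts_matrix(agg, ref_peaks[ref_rows, , drop = FALSE], bulk$sample_meta)
}
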