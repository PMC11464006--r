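#' Genomic peak sets
#'
#' A `peak_set` is the coordinate backbone of the package: an ordered table of
#' genomic intervals ("peaks") in 0-based half-open (BED) convention, each with
#' a stable identifier of the form `"chrom:start-end"`, an optional
#' peak-calling score, and a genome-build tag. All downstream objects (count
#' matrices, reference profiles, marker sets) refer to peaks by these ids.
#'
#' @param chrom character vector of chromosome names (non-empty strings).
#' @param start,end integer vectors; 0-based half-open, `start < end`.
#' @param score optional numeric vector of non-negative peak-calling scores.
#' @param genome_build genome build tag, e.g. `"hg38"`.
#' @param sort sort regions by (chrom, start, end)? Sorting is idempotent and
#'   all package functions assume sorted input; disable only for round-trip
#'   tests.
#' @return A `peak_set`: a data.frame with columns `chrom`, `start`, `end`,
#'   `score`, `id` and a `genome_build` attribute.
#' @examples
#' ps <- peak_set(c("chr1", "chr1"), c(100, 300), c(200, 400))
#' ps$id
#' @export
peak_set <- function(chrom, start, end, score = NULL, genome_build = "hg38",
                     sort = TRUE) {
  n <- length(chrom)
  if (length(start) != n || length(end) != n)
    stopf("chrom, start, end must have equal length")
  start <- as.numeric(start); end <- as.numeric(end)
  if (n > 0) {
    if (any(is.na(start)) || any(is.na(end)) || any(start != floor(start)) ||
        any(end != floor(end)))
      stopf("coordinates must be integers")
    if (any(!nzchar(chrom))) stopf("chromosome names must be non-empty")
    if (any(start < 0)) stopf("start must be >= 0")
    bad <- which(start >= end)
    if (length(bad))
      stopf("start >= end for region %s:%d-%d", chrom[bad[1]],
            start[bad[1]], end[bad[1]])
  }
  if (is.null(score)) score <- rep(NA_real_, n)
  if (length(score) != n) stopf("score length mismatch")
  df <- data.frame(chrom = as.character(chrom), start = start, end = end,
                   score = as.numeric(score),
                   id = sprintf("%s:%d-%d", chrom, start, end),
                   stringsAsFactors = FALSE)
  if (sort) df <- df[order(df$chrom, df$start, df$end), , drop = FALSE]
  rownames(df) <- NULL
  if (anyDuplicated(df$id))
    stopf("duplicate peak ids (first: %s)", df$id[duplicated(df$id)][1])
  structure(df, genome_build = genome_build,
            class = c("peak_set", "data.frame"))
}

#' @rdname peak_set
#' @param x object to test or convert.
#' @export
is_peak_set <- function(x) inherits(x, "peak_set")

#' @export
`[.peak_set` <- function(x, ...) {
  gb <- attr(x, "genome_build")
  out <- NextMethod()
  if (is.data.frame(out)) {
    attr(out, "genome_build") <- gb
    class(out) <- c("peak_set", "data.frame")
    rownames(out) <- NULL
  }
  out
}

#' @export
print.peak_set <- function(x, ...) {
  cat(sprintf("peak_set: %d regions [%s]\n", nrow(x), genome_build(x)))
  print.data.frame(head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat(sprintf("... and %d more\n", nrow(x) - 6))
  invisible(x)
}

#' @rdname peak_set
#' @export
genome_build <- function(x) attr(x, "genome_build") %||% NA_character_

#' Parse "chrom:start-end" peak identifiers
#'
#' @param ids character vector of canonical peak ids.
#' @inheritParams peak_set
#' @return A `peak_set` in the order implied by sorting (or input order with
#'   `sort = FALSE`).
#' @export
parse_peak_ids <- function(ids, genome_build = "hg38", sort = TRUE) {
  m <- regmatches(ids, regexec("^(.+):([0-9]+)-([0-9]+)$", ids))
  bad <- which(lengths(m) != 4)
  if (length(bad)) stopf("malformed peak id: '%s'", ids[bad[1]])
  peak_set(vapply(m, `[`, "", 2), as.numeric(vapply(m, `[`, "", 3)),
           as.numeric(vapply(m, `[`, "", 4)), genome_build = genome_build,
           sort = sort)
}

as_granges <- function(ps) {
  GenomicRanges::GRanges(ps$chrom,
                         IRanges::IRanges(start = ps$start + 1, end = ps$end))
}

#' Read and write BED intervals
#'
#' `parse_bed()` reads BED3/BED5 (tab-separated; column 5, when present, is
#' the peak-calling score). Comment (`#`), `track` and `browser` lines are
#' skipped. Malformed lines are reported with their line number.
#'
#' @param path file path or text connection.
#' @inheritParams peak_set
#' @return `parse_bed()` returns a sorted `peak_set`; `write_bed()` invisibly
#'   returns `path`.
#' @export
parse_bed <- function(path, genome_build = "hg38") {
  lines <- readLines(path)
  keep <- !grepl("^(#|track\\b|browser\\b)", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (!length(lines)) return(peak_set(character(), numeric(), numeric(),
                                      genome_build = genome_build))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3)) stopf("line %d: fewer than 3 BED columns",
                         lineno[which(nf < 3)[1]])
  chrom <- vapply(fields, `[`, "", 1)
  start <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 2)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 3)))
  bad <- which(is.na(start) | is.na(end) | start != floor(start) |
                 end != floor(end))
  if (length(bad)) stopf("line %d: non-integer coordinates", lineno[bad[1]])
  bad <- which(start >= end)
  if (length(bad)) stopf("line %d: start >= end", lineno[bad[1]])
  score <- rep(NA_real_, length(lines))
  has5 <- nf >= 5
  score[has5] <- suppressWarnings(
    as.numeric(vapply(fields[has5], `[`, "", 5)))
  peak_set(chrom, start, end, score, genome_build = genome_build)
}

#' @rdname parse_bed
#' @param ps a `peak_set`.
#' @export
write_bed <- function(ps, path) {
  df <- data.frame(ps$chrom, ps$start, ps$end, ps$id,
                   ifelse(is.na(ps$score), 0, ps$score))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Interval arithmetic on half-open regions
#'
#' `overlap_bp()` returns the number of overlapping base pairs between two
#' regions (0 when the chromosomes differ or the regions merely abut, since
#' coordinates are half-open). `nearest_region()` returns the index of the
#' nearest target region and the gap in bp (0 iff overlapping); ties are
#' broken toward the lowest target index.
#'
#' @param a,b single regions: either a one-row `peak_set` subset or a
#'   `"chrom:start-end"` id string.
#' @return `overlap_bp()`: integer bp. `nearest_region()`: list with `index`
#'   and `distance` (`Inf` when no target shares the chromosome).
#' @export
overlap_bp <- function(a, b) {
  a <- as_region(a); b <- as_region(b)
  if (a$chrom != b$chrom) return(0L)
  as.integer(max(0, min(a$end, b$end) - max(a$start, b$start)))
}

as_region <- function(x) {
  if (is.character(x)) x <- parse_peak_ids(x, sort = FALSE)
  if (is.data.frame(x) && nrow(x) == 1)
    return(list(chrom = x$chrom, start = x$start, end = x$end))
  stopf("expected a single region (one-row peak_set or id string)")
}

#' @rdname overlap_bp
#' @param query a single region.
#' @param targets a `peak_set` with at least one region.
#' @export
nearest_region <- function(query, targets) {
  if (!is_peak_set(targets) || nrow(targets) == 0)
    stopf("targets must be a non-empty peak_set")
  q <- as_region(query)
  d <- rep(Inf, nrow(targets))
  same <- targets$chrom == q$chrom
  gap <- pmax(targets$start - q$end, q$start - targets$end, 0)
  d[same] <- gap[same]
  i <- which.min(d)  # which.min takes the first (lowest-index) minimum
  list(index = i, distance = d[i])
}

#' Match bulk peaks to reference peaks by overlap
#'
#' Each bulk peak is assigned to its nearest reference peak provided they
#' overlap by at least 1 bp; non-overlapping bulk peaks are unassigned.
#' Several bulk peaks may map to the same reference peak (their counts are
#' later summed by [aggregate_matched_counts()]). Among multiple overlapping
#' reference peaks the lowest-index (leftmost) one is chosen.
#'
#' @param bulk_peaks,ref_peaks sorted `peak_set`s on the same genome build.
#' @return Integer vector of length `nrow(bulk_peaks)`: the matched reference
#'   row index, or `NA` for unmatched peaks.
#' @export
match_features <- function(bulk_peaks, ref_peaks) {
  if (!identical(genome_build(bulk_peaks), genome_build(ref_peaks)))
    stopf(paste("genome builds differ (%s vs %s):",
                "lift the bulk peaks over first (see liftover_regions)"),
          genome_build(bulk_peaks), genome_build(ref_peaks))
  hits <- suppressWarnings(
    GenomicRanges::findOverlaps(as_granges(bulk_peaks),
                                as_granges(ref_peaks), minoverlap = 1))
  map <- rep(NA_integer_, nrow(bulk_peaks))
  qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
  if (length(qh)) {
    # all overlapping refs are at distance 0; tie-break = lowest ref index
    best <- tapply(sh, qh, min)
    map[as.integer(names(best))] <- as.integer(best)
  }
  map
}
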