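#' Iterative overlap collapse of scored peaks
#'
#' Repeatedly keeps the highest-scoring remaining peak and removes every peak
#' overlapping it by at least 1 bp, until no peaks remain. Coordinates are
#' never merged or averaged: every emitted peak is a member of the input, and
#' the output is overlap-free. Score ties are broken by (chrom, start) order,
#' so the result is deterministic.
#'
#' @param peaks a `peak_set` in which every region has a score.
#' @return A sorted, overlap-free `peak_set`.
#' @export
collapse_iterative <- function(peaks) {
  if (nrow(peaks) == 0) return(peaks)
  if (any(is.na(peaks$score))) stopf("collapse_iterative requires scores")
  ord <- order(-peaks$score, peaks$chrom, peaks$start, peaks$end)
  # The iterative remove-overlaps rule is equivalent to a greedy scan in
  # score order: a peak survives iff it overlaps no higher-priority survivor.
  hits <- GenomicRanges::findOverlaps(as_granges(peaks), minoverlap = 1,
                                      drop.self = TRUE)
  nb <- split(S4Vectors::subjectHits(hits), S4Vectors::queryHits(hits))
  kept <- logical(nrow(peaks))
  removed <- logical(nrow(peaks))
  for (i in ord) {
    if (removed[i]) next
    kept[i] <- TRUE
    js <- nb[[as.character(i)]]
    if (!is.null(js)) removed[js] <- TRUE
  }
  res <- peaks[kept, , drop = FALSE]
  peak_set(res$chrom, res$start, res$end, res$score,
           genome_build = genome_build(peaks))
}

# TRUE for each collapsed peak that overlaps (>= 1 bp) at least one region
# in `other`.
detected_in <- function(collapsed, other) {
  if (nrow(other) == 0) return(logical(nrow(collapsed)))
  GenomicRanges::countOverlaps(as_granges(collapsed), as_granges(other),
                               minoverlap = 1) > 0
}

pool_peaks <- function(peak_sets) {
  stopifnot(length(peak_sets) >= 1)
  build <- genome_build(peak_sets[[1]])
  df <- do.call(rbind, lapply(peak_sets, as.data.frame))
  # pooled calls may contain identical coordinates from different samples;
  # keep the highest score per coordinate so ids stay unique
  df <- df[order(df$chrom, df$start, df$end, -df$score), , drop = FALSE]
  df <- df[!duplicated(df[c("chrom", "start", "end")]), , drop = FALSE]
  peak_set(df$chrom, df$start, df$end, df$score, genome_build = build)
}

#' Study-level reproducible peaks
#'
#' Collapses the pooled peak calls of one study's samples
#' ([collapse_iterative()]) and keeps a collapsed peak only when it is
#' detected (>= 1 bp overlap with an original call) in at least half of the
#' samples — `ceiling(n/2)`, i.e. 3 of 5. With exactly two samples a peak
#' must be detected in both.
#'
#' @param per_sample_peaks list of scored `peak_set`s, one per sample.
#' @return A `peak_set` of study-reproducible peaks.
#' @export
study_reproducible <- function(per_sample_peaks) {
  n <- length(per_sample_peaks)
  if (n < 1) stopf("need at least one sample")
  collapsed <- collapse_iterative(pool_peaks(per_sample_peaks))
  need <- if (n == 2) 2L else as.integer(ceiling(n / 2))
  det <- Reduce(`+`, lapply(per_sample_peaks, function(s)
    as.integer(detected_in(collapsed, s))))
  collapsed[det >= need, , drop = FALSE]
}

#' Cell-type consensus across studies
#'
#' Collapses the pooled study-level peak sets of one cell type and keeps only
#' collapsed peaks detected (>= 1 bp overlap) in every study of origin,
#' limiting study batch effects downstream.
#'
#' @param per_study_peaks list of scored `peak_set`s, one per study.
#' @return A `peak_set` of cell-type consensus peaks.
#' @export
celltype_consensus <- function(per_study_peaks) {
  if (length(per_study_peaks) < 1) stopf("need at least one study")
  collapsed <- collapse_iterative(pool_peaks(per_study_peaks))
  in_all <- Reduce(`&`, lapply(per_study_peaks, function(s)
    detected_in(collapsed, s)))
  collapsed[in_all, , drop = FALSE]
}

#' Global consensus peak set
#'
#' Collapses the union of all cell-type consensus sets into the final list of
#' peaks and removes chromosome Y regions.
#'
#' @param per_celltype_peaks list of scored `peak_set`s, one per cell type.
#' @return The final sorted consensus `peak_set` (no chrY).
#' @export
build_global_consensus <- function(per_celltype_peaks) {
  collapsed <- collapse_iterative(pool_peaks(per_celltype_peaks))
  collapsed[collapsed$chrom != "chrY", , drop = FALSE]
}

#' Consensus pipeline over a sample manifest
#'
#' Reads a manifest TSV with columns `path`, `sample_id`, `cell_type`,
#' `study`, loads each sample's BED5 peak calls, and runs the two-level
#' scheme: per-study collapse + half-the-samples reproducibility, then
#' per-cell-type collapse requiring detection in all studies, then the global
#' collapse with chrY removal.
#'
#' @param manifest path to the manifest TSV (or an already-read data.frame).
#' @param genome_build build tag applied to all loaded peaks.
#' @return List with `consensus` (final `peak_set`) and `report` (data.frame
#'   of per-stage peak counts).
#' @export
consensus_from_manifest <- function(manifest, genome_build = "hg38") {
  mf <- if (is.data.frame(manifest)) manifest
        else read.table(manifest, sep = "\t", header = TRUE,
                        stringsAsFactors = FALSE)
  need <- c("path", "sample_id", "cell_type", "study")
  if (!all(need %in% names(mf)))
    stopf("manifest must have columns: %s", paste(need, collapse = ", "))
  report <- list()
  per_ct <- list()
  for (ct in unique(mf$cell_type)) {
    mf_ct <- mf[mf$cell_type == ct, , drop = FALSE]
    per_study <- list()
    for (st in unique(mf_ct$study)) {
      paths <- mf_ct$path[mf_ct$study == st]
      samples <- lapply(paths, parse_bed, genome_build = genome_build)
      rep_peaks <- study_reproducible(samples)
      per_study[[st]] <- rep_peaks
      report[[length(report) + 1]] <- data.frame(
        stage = "study", cell_type = ct, study = st,
        n_in = sum(vapply(samples, nrow, 0L)), n_out = nrow(rep_peaks))
    }
    per_ct[[ct]] <- celltype_consensus(per_study)
    report[[length(report) + 1]] <- data.frame(
      stage = "cell_type", cell_type = ct, study = NA,
      n_in = sum(vapply(per_study, nrow, 0L)), n_out = nrow(per_ct[[ct]]))
  }
  consensus <- build_global_consensus(per_ct)
  report[[length(report) + 1]] <- data.frame(
    stage = "global", cell_type = NA, study = NA,
    n_in = sum(vapply(per_ct, nrow, 0L)), n_out = nrow(consensus))
  list(consensus = consensus, report = do.call(rbind, report))
}
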