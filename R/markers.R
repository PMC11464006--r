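#' Marker-selection parameters
#'
#' Tuning knobs of the marker-discovery pipeline, with the defaults used
#' throughout: a candidate must show log2 fold change above `lfc_min` (0.2)
#' in favor of its cell type in every contrast, the `top_n` (200) candidates
#' with the lowest maximum BH-adjusted p are kept per fold, markers must
#' recur in at least `min_folds` (3) of `n_folds` (10) leave-one-fold-out
#' runs, and correlation pruning cuts at the `corr_percentile`-th (90)
#' percentile of pairwise Pearson correlations.
#'
#' @param lfc_min minimum log2 fold change toward the target cell type.
#' @param top_n markers retained per fold and cell type.
#' @param n_folds number of stratified folds.
#' @param min_folds minimum folds a marker must recur in.
#' @param corr_percentile percentile (0-100) defining the correlation cutoff.
#' @param all_contrasts require `lfc > lfc_min` in all contrasts (`TRUE`,
#'   the recurrent-accessibility reading) or in at least one (`FALSE`).
#' @param prune_mode `"keep_correlated"` retains the most inter-correlated
#'   markers flagged by the correlation scan (co-varying markers are the
#'   informative ones in tumor bulk); `"drop_correlated"` is the
#'   conventional redundancy-removal reading.
#' @return A validated list of class `marker_params`.
#' @export
marker_params <- function(lfc_min = 0.2, top_n = 200, n_folds = 10,
                          min_folds = 3, corr_percentile = 90,
                          all_contrasts = TRUE,
                          prune_mode = c("keep_correlated",
                                         "drop_correlated")) {
  prune_mode <- match.arg(prune_mode)
  if (min_folds > n_folds) stopf("min_folds must be <= n_folds")
  if (top_n < 1) stopf("top_n must be >= 1")
  if (lfc_min < 0) stopf("lfc_min must be >= 0")
  if (corr_percentile <= 0 || corr_percentile >= 100)
    stopf("corr_percentile must be in (0, 100)")
  structure(list(lfc_min = lfc_min, top_n = top_n, n_folds = n_folds,
                 min_folds = min_folds, corr_percentile = corr_percentile,
                 all_contrasts = all_contrasts, prune_mode = prune_mode),
            class = "marker_params")
}

#' Stratified sample folds
#'
#' Partitions samples into `n_folds` folds, stratified by cell type (each
#' type spread round-robin over folds after a seeded shuffle). Fold `f`'s
#' *analysis set* is every sample except partition `f` (leave-one-fold-out);
#' an error is raised if any analysis set would lose a cell type entirely.
#'
#' @param sample_ids character vector of sample ids.
#' @param labels cell-type label per sample.
#' @param n_folds number of folds.
#' @param seed RNG seed; folds are deterministic given the seed.
#' @return List of `n_folds` character vectors (the held-out partitions),
#'   with the full id vector in attribute `all_ids`.
#' @export
make_folds <- function(sample_ids, labels, n_folds = 10, seed = 1) {
  stopifnot(length(sample_ids) == length(labels))
  folds <- rep(list(character()), n_folds)
  with_seed(seed, {
    for (ct in sort(unique(labels))) {
      ids <- sample_ids[labels == ct]
      ids <- ids[sample.int(length(ids))]
      f <- rep_len(seq_len(n_folds), length(ids))
      for (k in seq_len(n_folds))
        folds[[k]] <- c(folds[[k]], ids[f == k])
    }
  })
  for (k in seq_len(n_folds)) {
    keep <- !(sample_ids %in% folds[[k]])
    missing <- setdiff(unique(labels), unique(labels[keep]))
    if (length(missing))
      stopf("cell type '%s' has too few samples: fold %d's analysis set %s",
            missing[1], k, "would contain none of it")
  }
  attr(folds, "all_ids") <- sample_ids
  folds
}

#' @rdname make_folds
#' @param folds result of `make_folds()`.
#' @param k fold index.
#' @return `analysis_set()`: the sample ids used for fold `k` (all samples
#'   except partition `k`).
#' @export
analysis_set <- function(folds, k) {
  setdiff(attr(folds, "all_ids"), folds[[k]])
}

#' Select candidate markers for one cell type from pairwise contrasts
#'
#' Candidates are peaks with log2 fold change above `lfc_min` in favor of the
#' target cell type in all of its contrasts (including contrasts against
#' external-tissue groups). They are ranked ascending by the maximum
#' BH-adjusted p-value across those contrasts — the peaks most consistently
#' differential — and truncated to `top_n`. Ties on the maximum adjusted p
#' are broken by larger minimum log2 fold change, then by peak id.
#'
#' @param da a `da_pairs` list from [pairwise_da()] covering every contrast
#'   that involves `target`.
#' @param target the cell type to select markers for.
#' @param params a [marker_params()] object.
#' @return Ordered character vector of marker peak ids (length <= `top_n`).
#' @export
select_fold_markers <- function(da, target, params = marker_params()) {
  contrasts <- Filter(function(df) target %in% attr(df, "contrast"), da)
  if (!length(contrasts)) stopf("no contrasts involve '%s'", target)
  others <- unique(unlist(lapply(da, attr, "contrast")))
  missing <- setdiff(setdiff(others, target),
                     unlist(lapply(contrasts, attr, "contrast")))
  if (length(missing))
    stopf("missing contrast %s vs %s", target, missing[1])
  lfc <- vapply(contrasts, function(df) {
    s <- if (attr(df, "contrast")[1] == target) 1 else -1
    s * df$lfc
  }, numeric(nrow(contrasts[[1]])))
  padj <- vapply(contrasts, `[[`, numeric(nrow(contrasts[[1]])), "padj")
  if (is.null(dim(lfc))) { lfc <- rbind(lfc); padj <- rbind(padj) }
  ids <- contrasts[[1]]$peak_id
  pass <- if (params$all_contrasts)
    rowSums(lfc > params$lfc_min) == ncol(lfc)
  else rowSums(lfc > params$lfc_min) >= 1
  if (!any(pass)) return(character())
  max_padj <- apply(padj[pass, , drop = FALSE], 1, max)
  min_lfc <- apply(lfc[pass, , drop = FALSE], 1, min)
  ids <- ids[pass]
  ord <- order(max_padj, -min_lfc, ids)
  head(ids[ord], params$top_n)
}

#' Keep markers recurring across folds
#'
#' @param per_fold_markers list of per-fold marker id vectors (length
#'   `n_folds`).
#' @param params a [marker_params()] object.
#' @return data.frame with `peak_id` and `fold_count`, restricted to ids
#'   seen in at least `min_folds` folds, ordered by decreasing count then id.
#' @export
stability_filter <- function(per_fold_markers, params = marker_params()) {
  if (length(per_fold_markers) != params$n_folds)
    stopf("expected %d per-fold lists, got %d", params$n_folds,
          length(per_fold_markers))
  counts <- table(unlist(lapply(per_fold_markers, unique)))
  keep <- counts[counts >= params$min_folds]
  df <- data.frame(peak_id = names(keep), fold_count = as.integer(keep),
                   row.names = NULL)
  df[order(-df$fold_count, df$peak_id), , drop = FALSE]
}

#' Chromatin-module annotations
#'
#' Open-chromatin modules from tissue atlases: genomic intervals grouped
#' into modules, each labeled with a class — `"universal"` (accessible
#' across essentially all human tissues) or a tissue class such as
#' `"immune"`, `"endothelial"`, `"stromal"`. Markers overlapping universal
#' modules, or tissue modules whose class is not exempted for the marker's
#' cell type, are vetoed.
#'
#' @param module_id module identifier per interval.
#' @param chrom,start,end interval coordinates (0-based half-open).
#' @param class module class per interval.
#' @return A `chromatin_modules` data.frame.
#' @export
chromatin_modules <- function(module_id, chrom, start, end, class) {
  df <- data.frame(module_id = as.character(module_id),
                   chrom = as.character(chrom),
                   start = as.numeric(start), end = as.numeric(end),
                   class = as.character(class), stringsAsFactors = FALSE)
  if (any(df$start >= df$end)) stopf("module start must be < end")
  structure(df, class = c("chromatin_modules", "data.frame"))
}

#' @rdname chromatin_modules
#' @param path TSV with columns module_id, chrom, start, end, class.
#' @export
read_modules_tsv <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  chromatin_modules(df$module_id, df$chrom, df$start, df$end, df$class)
}

#' Default module-class exemptions
#'
#' Immune cell types keep markers overlapping immune-class modules,
#' endothelial cells keep endothelial-class modules, and fibroblasts keep
#' stromal-class modules; everything else has no exemption. Cell types are
#' recognized by common naming (B/T/NK/dendritic/monocyte/macrophage/
#' neutrophil for immune; "endo" for endothelial; "fibro" for stromal).
#'
#' @param cell_types character vector of cell-type names.
#' @return Named list mapping each cell type to exempted module classes.
#' @export
default_module_exemptions <- function(cell_types) {
  immune_re <- paste0("(?i)b[ _-]?cell|cd4|cd8|t[ _-]?cell|nk|natural",
                      "|dendritic|dc|mono|macro|neutro|immune")
  ex <- lapply(cell_types, function(ct) {
    if (grepl("endo", ct, ignore.case = TRUE)) "endothelial"
    else if (grepl("fibro|stromal", ct, ignore.case = TRUE)) "stromal"
    else if (grepl(immune_re, ct, perl = TRUE)) "immune"
    else character()
  })
  setNames(ex, cell_types)
}

#' Veto markers overlapping chromatin modules
#'
#' A marker is removed iff it overlaps (>= 1 bp) any universal module, or
#' any tissue module whose class is not exempted for the marker's cell type.
#' The filter never adds markers; removing exemptions removes at least as
#' many.
#'
#' @param markers marker table: data.frame with `cell_type`, `peak_id` (and
#'   any provenance columns, preserved).
#' @param modules a [chromatin_modules()] table.
#' @param exemptions named list cell type -> exempted module classes;
#'   `NULL` (default) uses [default_module_exemptions()] restricted to the
#'   classes the module table actually contains. Explicitly passed classes
#'   must exist in `modules`.
#' @return The surviving marker rows, with a `module_pass` column set to
#'   `TRUE`; removed rows are available in attribute `removed`.
#' @export
module_filter <- function(markers, modules, exemptions = NULL) {
  if (is.null(exemptions)) {
    # defaults may name classes absent from this module table; keep the
    # ones that exist
    exemptions <- lapply(default_module_exemptions(
      unique(markers$cell_type)), intersect, unique(modules$class))
  } else {
    bad_class <- setdiff(unlist(exemptions), unique(modules$class))
    if (length(bad_class))
      stopf("exempted class '%s' not present in modules", bad_class[1])
  }
  mk_peaks <- parse_peak_ids(markers$peak_id, sort = FALSE)
  mod_gr <- GenomicRanges::GRanges(
    modules$chrom, IRanges::IRanges(modules$start + 1, modules$end))
  hits <- GenomicRanges::findOverlaps(as_granges(mk_peaks), mod_gr,
                                      minoverlap = 1)
  removed <- logical(nrow(markers))
  qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
  for (k in seq_along(qh)) {
    cls <- modules$class[sh[k]]
    ct <- markers$cell_type[qh[k]]
    if (cls == "universal" || !(cls %in% (exemptions[[ct]] %||% character())))
      removed[qh[k]] <- TRUE
  }
  out <- markers[!removed, , drop = FALSE]
  out$module_pass <- rep(TRUE, nrow(out))
  attr(out, "removed") <- markers[removed, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# The pairwise correlation scan: pairs (i, j), i < j, visited in
# column-major order; a pair with |r| > cutoff and neither member flagged
# flags the member with the larger mean absolute off-diagonal correlation
# (ties flag the lower index).
correlation_scan <- function(r, cutoff) {
  n <- ncol(r)
  mean_abs <- (rowSums(abs(r)) - 1) / (n - 1)
  flagged <- logical(n)
  for (j in 2:n) for (i in seq_len(j - 1)) {
    if (flagged[i] || flagged[j]) next
    if (abs(r[i, j]) > cutoff)
      flagged[if (mean_abs[i] >= mean_abs[j]) i else j] <- TRUE
  }
  flagged
}

#' Correlation-based marker refinement on tumor bulk data
#'
#' Cell-type-specific markers of the tumor microenvironment co-vary across
#' tumor bulk samples (they all track that cell type's abundance), so the
#' markers exhibiting the strongest correlation patterns are the reliable
#' ones. Per cell type, the Pearson correlation matrix of the markers across
#' bulk samples is computed; the cutoff is the `corr_percentile`-th
#' percentile of the upper-triangle values (linear interpolation); the
#' pairwise scan then flags, for each pair exceeding the cutoff, the member
#' with the larger mean absolute correlation (column-major pair order,
#' skipping flagged members, ties to the lower index). Under the default
#' `prune_mode = "keep_correlated"` the flagged (most inter-correlated)
#' markers are retained; if no pair exceeds the cutoff the set is kept
#' unpruned with a warning. `"drop_correlated"` instead removes the flagged
#' members. Markers absent from the bulk matrix pass through unchanged with
#' `corr_pass = NA`; cell types with fewer than two present markers pass
#' through unchanged.
#'
#' @param markers marker table (`cell_type`, `peak_id`, provenance columns).
#' @param bulk a TPM-like `counts_matrix` of tumor bulk samples (>= 3
#'   samples).
#' @param params a [marker_params()] object (`corr_percentile`,
#'   `prune_mode`).
#' @return The retained marker rows with a `corr_pass` column; removed rows
#'   in attribute `removed`.
#' @export
correlation_prune <- function(markers, bulk, params = marker_params()) {
  vals <- if (is_counts_matrix(bulk)) bulk$values else as.matrix(bulk)
  if (ncol(vals) < 3) stopf("correlation pruning needs >= 3 bulk samples")
  keep <- logical(nrow(markers))
  pass_flag <- rep(NA, nrow(markers))
  for (ct in unique(markers$cell_type)) {
    rows <- which(markers$cell_type == ct)
    present <- rows[markers$peak_id[rows] %in% rownames(vals)]
    absent <- setdiff(rows, present)
    keep[absent] <- TRUE          # not measurable in this bulk: untouched
    if (length(present) < 2) { keep[present] <- TRUE; next }
    x <- t(vals[markers$peak_id[present], , drop = FALSE])
    r <- suppressWarnings(cor(x))
    r[!is.finite(r)] <- 0
    ut <- r[upper.tri(r)]
    cutoff <- quantile(ut, params$corr_percentile / 100, type = 7,
                       names = FALSE)
    flagged <- correlation_scan(r, cutoff)
    retained <- if (params$prune_mode == "keep_correlated") flagged
                else !flagged
    if (!any(retained)) {
      warnf("no marker pair of '%s' exceeds the correlation cutoff; %s", ct,
            "keeping the set unpruned")
      retained <- rep(TRUE, length(present))
    }
    keep[present[retained]] <- TRUE
    pass_flag[present] <- retained
  }
  out <- markers[keep, , drop = FALSE]
  out$corr_pass <- pass_flag[keep]
  attr(out, "removed") <- markers[!keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Full marker-discovery pipeline
#'
#' Runs, per fold: pairwise differential accessibility on the fold's
#' analysis set and top-`top_n` candidate selection per cell type; then the
#' cross-fold stability filter, the chromatin-module veto (when `modules`
#' are given), and correlation pruning on tumor bulk data (when `bulk` is
#' given — the refinement applied to tumor-microenvironment marker sets; the
#' PBMC-style marker set omits it).
#'
#' @param counts sorted-sample `counts_matrix` whose `sample_meta` carries
#'   `cell_type` (marker targets) and optionally external-tissue labels.
#' @param cell_types cell types to derive markers for; defaults to all
#'   labels, but external-tissue groups should be excluded here (they still
#'   participate in every contrast).
#' @param modules optional [chromatin_modules()] table.
#' @param bulk optional TPM-like tumor bulk `counts_matrix` for correlation
#'   pruning.
#' @param params a [marker_params()] object.
#' @param exemptions module-class exemptions (see [module_filter()]).
#' @param seed fold-assignment seed.
#' @return Marker table: `cell_type`, `peak_id`, `fold_count`, plus
#'   `module_pass` / `corr_pass` provenance columns when those filters ran.
#' @export
select_markers <- function(counts, cell_types = NULL, modules = NULL,
                           bulk = NULL, params = marker_params(),
                           exemptions = NULL, seed = 1) {
  labels <- counts$sample_meta$cell_type
  if (is.null(labels)) stopf("counts$sample_meta must carry cell_type")
  cell_types <- cell_types %||% sort(unique(labels))
  folds <- make_folds(colnames(counts$values), labels, params$n_folds, seed)
  per_fold <- vector("list", params$n_folds)
  for (k in seq_len(params$n_folds)) {
    use <- analysis_set(folds, k)
    sel <- match(use, colnames(counts$values))
    da <- pairwise_da(counts$values[, sel, drop = FALSE], labels[sel])
    per_fold[[k]] <- lapply(setNames(cell_types, cell_types), function(ct)
      select_fold_markers(da, ct, params))
  }
  tabs <- lapply(cell_types, function(ct) {
    st <- stability_filter(lapply(per_fold, `[[`, ct), params)
    if (nrow(st)) data.frame(cell_type = ct, st) else NULL
  })
  markers <- do.call(rbind, tabs)
  if (is.null(markers) || nrow(markers) == 0)
    stopf("no stable markers found for any cell type")
  dup <- duplicated(markers$peak_id) | duplicated(markers$peak_id,
                                                  fromLast = TRUE)
  if (any(dup))  # cannot happen under all_contrasts = TRUE; guard otherwise
    markers <- markers[!dup, , drop = FALSE]
  if (!is.null(modules)) {
    ex <- exemptions %||% default_module_exemptions(cell_types)
    markers <- module_filter(markers, modules, ex)
  }
  if (!is.null(bulk)) markers <- correlation_prune(markers, bulk, params)
  rownames(markers) <- NULL
  markers
}

#' Write a marker table to TSV
#'
#' @param markers marker table from [select_markers()].
#' @param path output path.
#' @export
write_markers_tsv <- function(markers, path) {
  write.table(markers, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
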