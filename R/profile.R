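#' Reference chromatin-accessibility profiles
#'
#' A `reference_profile` holds, over a fixed `peak_set`, the per-cell-type
#' median TPM-like accessibility `R`, its interquartile range `v` (the
#' feature-variability input to the deconvolution weights), and per-cell-type
#' logical marker flags filled in by the marker-selection pipeline.
#'
#' `build_profile()` computes `R` and `v` from a TPM-like-normalized sorted
#' sample matrix: for every peak and cell type, the median and `Q3 - Q1`
#' across that cell type's samples (quantile type 7, i.e. linear
#' interpolation between order statistics). Marker flags start out unset.
#'
#' @param norm a TPM-like `counts_matrix` (see [tpm_like()]) whose
#'   `sample_meta` carries `cell_type`, or an explicit `cell_type_labels`.
#' @param cell_type_labels optional character vector, one label per sample,
#'   overriding `sample_meta$cell_type`.
#' @return A `reference_profile` with fields `peaks`, `cell_types`, `R`, `v`,
#'   `markers`, `genome_build`.
#' @export
build_profile <- function(norm, cell_type_labels = NULL) {
  labels <- cell_type_labels %||% norm$sample_meta$cell_type
  if (is.null(labels)) stopf("cell-type labels required")
  if (length(labels) != ncol(norm$values))
    stopf("one label per sample required")
  cts <- sort(unique(labels))
  R <- v <- matrix(0, nrow(norm$values), length(cts),
                   dimnames = list(rownames(norm$values), cts))
  for (ct in cts) {
    sub <- norm$values[, labels == ct, drop = FALSE]
    R[, ct] <- apply(sub, 1, median)
    v[, ct] <- if (ncol(sub) == 1) 0 else
      apply(sub, 1, function(x) diff(quantile(x, c(0.25, 0.75), type = 7,
                                              names = FALSE)))
  }
  markers <- matrix(FALSE, nrow(norm$values), length(cts),
                    dimnames = dimnames(R))
  structure(list(peaks = norm$peaks, cell_types = cts, R = R, v = v,
                 markers = markers,
                 genome_build = genome_build(norm$peaks)),
            class = "reference_profile")
}

#' @export
print.reference_profile <- function(x, ...) {
  cat(sprintf("reference_profile: %d peaks x %d cell types [%s]; %d markers\n",
              nrow(x$R), length(x$cell_types), x$genome_build,
              sum(x$markers)))
  invisible(x)
}

#' Set marker flags on a reference profile
#'
#' @param profile a `reference_profile`.
#' @param markers a marker table (see [stability_filter()] /
#'   [select_markers()]): data.frame with `cell_type` and `peak_id` columns.
#' @return The profile with `markers` flags set.
#' @export
set_profile_markers <- function(profile, markers) {
  profile$markers[] <- FALSE
  missing <- setdiff(markers$peak_id, profile$peaks$id)
  if (length(missing))
    stopf("marker peak %s is not in the profile peak set", missing[1])
  bad_ct <- setdiff(markers$cell_type, profile$cell_types)
  if (length(bad_ct)) stopf("unknown cell type '%s'", bad_ct[1])
  idx <- cbind(match(markers$peak_id, profile$peaks$id),
               match(markers$cell_type, profile$cell_types))
  profile$markers[idx] <- TRUE
  profile
}

PROFILE_FORMAT_VERSION <- "1"

#' Serialize reference profiles
#'
#' The on-disk format is a gzipped TSV with a three-line header (format
#' version, genome build, cell-type list) followed by one row per peak:
#' `peak_id`, `length`, then `R.<ct>`, `v.<ct>` and `marker.<ct>` columns for
#' every cell type. The round-trip is lossless.
#'
#' @param profile a `reference_profile`.
#' @param path output path (written gzip-compressed).
#' @return `write_profile()` invisibly returns `path`; `read_profile()`
#'   returns the `reference_profile`.
#' @export
write_profile <- function(profile, path) {
  con <- gzfile(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# profile_format_version: %s",
                       PROFILE_FORMAT_VERSION),
               sprintf("# genome_build: %s", profile$genome_build),
               sprintf("# cell_types: %s",
                       paste(profile$cell_types, collapse = ","))), con)
  df <- data.frame(peak_id = profile$peaks$id,
                   length = peak_lengths(profile$peaks),
                   check.names = FALSE)
  for (ct in profile$cell_types) df[[paste0("R.", ct)]] <- profile$R[, ct]
  for (ct in profile$cell_types) df[[paste0("v.", ct)]] <- profile$v[, ct]
  for (ct in profile$cell_types)
    df[[paste0("marker.", ct)]] <- as.integer(profile$markers[, ct])
  write.table(format(df, digits = 15, trim = TRUE, scientific = FALSE),
              con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_profile
#' @export
read_profile <- function(path) {
  con <- gzfile(path, "r")
  on.exit(close(con))
  hdr <- readLines(con, n = 3)
  get_field <- function(key) {
    line <- grep(sprintf("^# %s:", key), hdr, value = TRUE)
    if (!length(line)) stopf("profile file missing header field '%s'", key)
    trimws(sub(sprintf("^# %s:", key), "", line))
  }
  ver <- get_field("profile_format_version")
  if (!identical(ver, PROFILE_FORMAT_VERSION))
    stopf("unsupported profile format version '%s'", ver)
  build <- get_field("genome_build")
  cts <- strsplit(get_field("cell_types"), ",")[[1]]
  df <- read.table(con, sep = "\t", header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE)
  need <- c(paste0("R.", cts), paste0("v.", cts), paste0("marker.", cts))
  absent <- setdiff(need, names(df))
  if (length(absent)) stopf("profile file missing column '%s'", absent[1])
  peaks <- parse_peak_ids(df$peak_id, genome_build = build, sort = FALSE)
  if (!identical(peaks$id, df$peak_id))
    stopf("profile rows must be sorted by coordinate")
  take <- function(prefix) {
    m <- as.matrix(df[paste0(prefix, cts)])
    dimnames(m) <- list(df$peak_id, cts)
    m
  }
  prof <- structure(list(peaks = peaks, cell_types = cts,
                         R = take("R."), v = take("v."),
                         markers = take("marker.") > 0,
                         genome_build = build),
                    class = "reference_profile")
  if (any(prof$R < 0) || any(prof$v < 0))
    stopf("profile R and v must be non-negative")
  none <- colSums(prof$markers) == 0
  if (any(none))
    warnf("cell type(s) with no marker flags: %s",
          paste(cts[none], collapse = ", "))
  prof
}
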