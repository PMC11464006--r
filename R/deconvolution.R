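#' Feature-variability weights for the deconvolution fit
#'
#' Variable reference features should influence the fit less. For every
#' marker peak the cell-type-averaged IQR `vbar` is taken from the profile
#' and the weight is `w = 1 / (vbar + eps)`, with
#' `eps = 1e-2 * median(positive vbar)` (or 1 when every `vbar` is zero) to
#' keep weights finite and bounded.
#'
#' @param profile a `reference_profile`.
#' @param marker_ids peak ids (subset of the profile peaks) used in the fit.
#' @return List with `w` (named weights) and `epsilon`.
#' @export
feature_weights <- function(profile, marker_ids) {
  rows <- match(marker_ids, profile$peaks$id)
  if (any(is.na(rows)))
    stopf("marker '%s' not in profile", marker_ids[which(is.na(rows))[1]])
  vbar <- rowMeans(profile$v[rows, , drop = FALSE])
  eps <- if (any(vbar > 0)) 1e-2 * median(vbar[vbar > 0]) else 1
  list(w = setNames(1 / (vbar + eps), marker_ids), epsilon = eps)
}

#' Constrained weighted least-squares mixture fit for one sample
#'
#' Solves the convex quadratic program at the heart of the framework:
#' minimize `sum_j w_j (b_j - sum_i R_ji p_i)^2` over cell-type proportions
#' `p_i >= 0` with `sum_i p_i <= 1`. The slack `1 - sum p` is the
#' uncharacterized fraction, identifiable because the fit runs on marker
#' peaks where uncharacterized cells contribute no signal. Solved exactly
#' with the dual active-set method (`quadprog::solve.QP`); a rank-deficient
#' system is regularized with a tiny ridge (`1e-10 * trace`) and flagged as
#' potentially non-unique.
#'
#' @param b TPM-like bulk accessibility on the marker peaks.
#' @param R marker-by-cell-type reference matrix.
#' @param w feature weights from [feature_weights()] (list or bare vector).
#' @return Named proportions `p` with attributes `objective` (weighted
#'   residual sum of squares) and `non_unique` (logical).
#' @export
epic_fit_sample <- function(b, R, w) {
  R <- as.matrix(R)
  if (is.list(w)) w <- w$w
  if (length(b) != nrow(R) || length(w) != nrow(R))
    stopf("b, w and rows of R must align")
  if (nrow(R) < ncol(R))
    stopf("need at least as many marker peaks as cell types")
  n <- ncol(R)
  Dmat <- 2 * crossprod(R, w * R)
  dvec <- 2 * as.numeric(crossprod(R, w * b))
  Amat <- cbind(diag(n), -1)           # p_i >= 0 ; -sum(p) >= -1
  bvec <- c(rep(0, n), -1)
  non_unique <- FALSE
  sol <- tryCatch(quadprog::solve.QP(Dmat, dvec, Amat, bvec),
                  error = function(e) NULL)
  if (is.null(sol)) {
    non_unique <- TRUE
    Dmat <- Dmat + diag(1e-10 * sum(diag(Dmat)), n)
    sol <- quadprog::solve.QP(Dmat, dvec, Amat, bvec)
  }
  p <- pmax(sol$solution, 0)
  names(p) <- colnames(R)
  attr(p, "objective") <- sum(w * (b - as.numeric(R %*% p))^2)
  attr(p, "non_unique") <- non_unique
  p
}

#' Uncharacterized-cell fraction
#'
#' The deficit left by the constrained fit: `p_u = max(0, 1 - sum(p))`,
#' clamped so solver slack never leaks a negative fraction.
#'
#' @param p fitted proportions from [epic_fit_sample()].
#' @return The uncharacterized fraction.
#' @export
estimate_uncharacterized <- function(p) max(0, 1 - sum(p))

#' Signal-content renormalization of fitted proportions
#'
#' RNA-based deconvolution corrects fitted weights for per-cell-type mRNA
#' content. ATAC-Seq measures signal at the DNA level, where per-cell
#' content is comparable across cell types, so all factors default to 1 and
#' the step reduces to normalizing the proportions (including the
#' uncharacterized component, whose factor is fixed at 1) to sum to 1.
#'
#' @param p named cell-type proportions.
#' @param p_u uncharacterized fraction.
#' @param factors named positive per-cell-type factors (default all 1).
#' @return Named fractions over `c(names(p), "uncharacterized")`, summing
#'   to 1.
#' @export
mrna_renormalize <- function(p, p_u = 0,
                             factors = setNames(rep(1, length(p)),
                                                names(p))) {
  if (any(factors <= 0)) stopf("factors must be positive")
  f <- factors[names(p)]
  if (any(is.na(f))) stopf("factors must cover every cell type")
  adj <- c(p / f, uncharacterized = p_u)
  adj / sum(adj)
}

#' Deconvolve bulk ATAC-Seq samples against a reference profile
#'
#' End-to-end pipeline: optional liftover of the bulk peaks onto the
#' reference build, feature matching by overlap, count aggregation onto the
#' matched reference peaks, TPM-like normalization, restriction to the
#' matched marker peaks, IQR-based feature weighting, per-sample constrained
#' least-squares fitting, and renormalization including the uncharacterized
#' fraction. Samples are fitted independently.
#'
#' @param bulk a `counts_matrix` of bulk samples.
#' @param profile a `reference_profile` with marker flags set.
#' @param chains optional chains from [read_chain()] when the bulk genome
#'   build differs from the profile's.
#' @param mrna_factors optional per-cell-type factors (default all 1; see
#'   [mrna_renormalize()]).
#' @param normalize `"post"` (default) applies the TPM-like transform after
#'   aggregation onto matched reference peaks, using reference peak lengths;
#'   `"pre"` normalizes the full bulk feature set first.
#' @param min_matched_markers hard minimum of matched marker peaks.
#' @return A `deconvolution_result`: data.frame of per-sample fractions
#'   (cell types + `uncharacterized`, rows summing to 1) plus `residual`
#'   (weighted residual norm), `non_unique` flag and `n_matched_features`;
#'   attribute `marker_report` gives per-cell-type marker matching counts.
#' @export
deconvolve <- function(bulk, profile, chains = NULL, mrna_factors = NULL,
                       normalize = c("post", "pre"),
                       min_matched_markers = 10) {
  normalize <- match.arg(normalize)
  if (!identical(genome_build(bulk$peaks), profile$genome_build)) {
    if (is.null(chains))
      stopf("bulk is on %s but the profile is on %s: supply a chain file",
            genome_build(bulk$peaks), profile$genome_build)
    lift <- liftover_regions(bulk$peaks, chains,
                             target_build = profile$genome_build)
    rows <- match(attr(lift$lifted, "source_id"), bulk$peaks$id)
    bulk <- counts_matrix(bulk$values[rows, , drop = FALSE], lift$lifted,
                          bulk$sample_meta)
  }
  if (normalize == "pre") bulk <- tpm_like(bulk)
  mapping <- match_features(bulk$peaks, profile$peaks)
  if (all(is.na(mapping))) stopf("no shared features between bulk and %s",
                                 "the reference profile")
  matched <- aggregate_matched_counts(bulk, mapping, profile$peaks)
  norm <- if (normalize == "post") tpm_like(matched) else matched
  marker_union <- profile$peaks$id[rowSums(profile$markers) > 0]
  marker_report <- do.call(rbind, lapply(profile$cell_types, function(ct) {
    ids <- profile$peaks$id[profile$markers[, ct]]
    data.frame(cell_type = ct, n_markers = length(ids),
               n_matched = sum(ids %in% norm$peaks$id))
  }))
  low <- marker_report$n_matched < 0.5 * marker_report$n_markers
  if (any(low))
    warnf("fewer than half of the markers matched for: %s",
          paste(marker_report$cell_type[low], collapse = ", "))
  fit_ids <- intersect(marker_union, norm$peaks$id)
  if (length(fit_ids) < min_matched_markers)
    stopf("only %d marker peaks matched (minimum %d)", length(fit_ids),
          min_matched_markers)
  w <- feature_weights(profile, fit_ids)
  Rm <- profile$R[match(fit_ids, profile$peaks$id), , drop = FALSE]
  B <- norm$values[match(fit_ids, norm$peaks$id), , drop = FALSE]
  res <- lapply(seq_len(ncol(B)), function(k) {
    p <- epic_fit_sample(B[, k], Rm, w)
    p_u <- estimate_uncharacterized(p)
    frac <- mrna_renormalize(p, p_u,
                             mrna_factors %||%
                               setNames(rep(1, length(p)), names(p)))
    list(frac = frac, residual = sqrt(attr(p, "objective")),
         non_unique = attr(p, "non_unique"))
  })
  fractions <- do.call(rbind, lapply(res, `[[`, "frac"))
  out <- data.frame(sample_id = colnames(B), fractions,
                    residual = vapply(res, `[[`, 0, "residual"),
                    non_unique = vapply(res, `[[`, TRUE, "non_unique"),
                    n_matched_features = length(fit_ids),
                    check.names = FALSE, row.names = NULL)
  attr(out, "marker_report") <- marker_report
  class(out) <- c("deconvolution_result", "data.frame")
  out
}

#' Extract the fraction matrix from a deconvolution result
#'
#' @param result a `deconvolution_result`.
#' @return Numeric matrix, samples x (cell types + uncharacterized), rows
#'   named by sample id.
#' @export
fractions_matrix <- function(result) {
  drop_cols <- c("sample_id", "residual", "non_unique",
                 "n_matched_features")
  m <- as.matrix(as.data.frame(result)[, setdiff(names(result), drop_cols),
                                       drop = FALSE])
  rownames(m) <- result$sample_id
  m
}
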