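#' Prediction-accuracy metrics
#'
#' `pearson_r()` is the product-moment correlation, returning `NA` (with no
#' error) when either vector is constant; `rmse()` is
#' `sqrt(mean((x - y)^2))`.
#'
#' @param x,y numeric vectors of equal length.
#' @return A single numeric value.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stopf("x and y must have equal length")
  if (length(x) < 2) stopf("need at least two observations")
  if (sd(x) == 0 || sd(y) == 0) return(NA_real_)
  cor(x, y)
}

#' @rdname pearson_r
#' @export
rmse <- function(x, y) {
  if (length(x) != length(y)) stopf("x and y must have equal length")
  sqrt(mean((x - y)^2))
}

as_fraction_matrix <- function(x) {
  if (inherits(x, "deconvolution_result")) return(fractions_matrix(x))
  if (is.data.frame(x)) {
    ids <- x$sample_id %||% rownames(x)
    m <- as.matrix(x[, setdiff(names(x), "sample_id"), drop = FALSE])
    rownames(m) <- ids
    return(m)
  }
  as.matrix(x)
}

#' Per-cell-type and pooled accuracy of predicted proportions
#'
#' Aligns prediction and truth tables on sample ids and cell-type columns,
#' then reports Pearson r and RMSE per cell type (across samples) and pooled
#' over all (sample, cell type) pairs. Correlations undefined because a
#' column is constant are reported as `NA` and excluded from nothing else —
#' RMSE is still computed.
#'
#' @param pred,truth samples x cell-type fraction tables (matrix,
#'   data.frame with `sample_id`, or `deconvolution_result`); an
#'   `uncharacterized` column is allowed and treated as a cell type.
#' @return data.frame with rows per cell type plus `"pooled"`, columns
#'   `cell_type`, `r`, `rmse`, `n`.
#' @export
metrics_table <- function(pred, truth) {
  P <- as_fraction_matrix(pred); T_ <- as_fraction_matrix(truth)
  if (!setequal(colnames(P), colnames(T_)))
    stopf("cell-type columns differ: %s",
          paste(union(setdiff(colnames(P), colnames(T_)),
                      setdiff(colnames(T_), colnames(P))), collapse = ", "))
  T_ <- T_[, colnames(P), drop = FALSE]
  if (!setequal(rownames(P), rownames(T_)))
    stopf("sample ids differ between pred and truth")
  T_ <- T_[rownames(P), , drop = FALSE]
  per_ct <- do.call(rbind, lapply(colnames(P), function(ct) data.frame(
    cell_type = ct,
    r = if (nrow(P) >= 2) pearson_r(P[, ct], T_[, ct]) else NA_real_,
    rmse = rmse(P[, ct], T_[, ct]), n = nrow(P))))
  pooled <- data.frame(cell_type = "pooled",
                       r = pearson_r(as.numeric(P), as.numeric(T_)),
                       rmse = rmse(as.numeric(P), as.numeric(T_)),
                       n = length(P))
  rbind(per_ct, pooled)
}

#' Rescale fractions excluding uncharacterized cells
#'
#' Tools that cannot predict uncharacterized cells are compared on the
#' characterized cell types only: the `uncharacterized` column is dropped
#' from both tables and every row renormalized to sum 1. Rows whose
#' remaining sum is 0 (entirely uncharacterized) are excluded and reported.
#'
#' @inheritParams metrics_table
#' @return List with rescaled `pred` and `truth` matrices and `excluded`
#'   (character vector of dropped sample ids).
#' @export
rescale_excluding_uncharacterized <- function(pred, truth) {
  P <- as_fraction_matrix(pred); T_ <- as_fraction_matrix(truth)
  if (!"uncharacterized" %in% colnames(P) ||
      !"uncharacterized" %in% colnames(T_))
    stopf("both tables need an 'uncharacterized' column")
  P <- P[, colnames(P) != "uncharacterized", drop = FALSE]
  T_ <- T_[, colnames(T_) != "uncharacterized", drop = FALSE]
  bad <- rowSums(P) == 0 | rowSums(T_[rownames(P), , drop = FALSE]) == 0
  excluded <- rownames(P)[bad]
  P <- P[!bad, , drop = FALSE]; T_ <- T_[rownames(P), , drop = FALSE]
  list(pred = P / rowSums(P), truth = T_ / rowSums(T_),
       excluded = excluded)
}
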