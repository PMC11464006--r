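#' TMM scaling factors
#'
#' Effective-library-size factors by the trimmed mean of M-values: the
#' reference sample is the one whose upper-quartile count (relative to
#' library size) is closest to the mean upper quartile; each sample's factor
#' is `2^` the precision-weighted trimmed mean of per-peak log-ratios (M)
#' against the reference, trimming the extreme `trimM` fraction of M values
#' and `trimA` fraction of A values; factors are rescaled to geometric mean
#' 1. Delegates to `edgeR::calcNormFactors(method = "TMM")`, the canonical
#' implementation of this estimator.
#'
#' @param counts a `counts_matrix` or numeric matrix (peaks x samples).
#' @param trimM,trimA trim fractions for log-ratios and average log
#'   intensities (canonical published constants 0.3 and 0.05).
#' @return Named numeric vector of per-sample factors (geometric mean 1).
#' @export
tmm_factors <- function(counts, trimM = 0.3, trimA = 0.05) {
  m <- if (is_counts_matrix(counts)) counts$values else as.matrix(counts)
  if (ncol(m) < 2) stopf("TMM needs at least two samples")
  if (any(colSums(m) <= 0)) stopf("all library sizes must be positive")
  f <- edgeR::calcNormFactors(m, method = "TMM", logratioTrim = trimM,
                              sumTrim = trimA)
  if (any(!is.finite(f)) || any(f <= 0))
    stopf("TMM failed: a sample shares no positive peaks with the reference")
  setNames(f, colnames(m))
}

#' Log counts-per-million
#'
#' `log2((c + prior) / (libsize * factor + 2 * prior) * 1e6)`, the
#' effective-library-size log-CPM transform used before linear modeling.
#'
#' @inheritParams tmm_factors
#' @param factors positive per-sample scaling factors (see [tmm_factors()]).
#' @param prior_count offset avoiding log of zero.
#' @return Numeric matrix of log2 CPM values.
#' @export
log_cpm <- function(counts, factors, prior_count = 0.5) {
  m <- if (is_counts_matrix(counts)) counts$values else as.matrix(counts)
  if (length(factors) != ncol(m)) stopf("one factor per sample required")
  if (any(factors <= 0)) stopf("factors must be positive")
  eff <- colSums(m) * factors
  log2(sweep(m, 2, eff + 2 * prior_count, function(x, s)
    (x + prior_count) / s) * 1e6)
}

#' Per-peak group means and pooled variance
#'
#' Fits the one-way group-means linear model to each peak: per-group means,
#' the pooled within-group residual variance `s2`, and its residual degrees
#' of freedom `d = n_total - n_groups`.
#'
#' @param logcpm numeric matrix (peaks x samples) of log2 CPM values.
#' @param labels character vector of group labels, one per sample.
#' @return List with `means` (peaks x groups), `s2`, `d`, and `n` (named
#'   group sizes).
#' @export
fit_group_stats <- function(logcpm, labels) {
  logcpm <- as.matrix(logcpm)
  if (length(labels) != ncol(logcpm)) stopf("one label per sample required")
  groups <- sort(unique(labels))
  n <- vapply(groups, function(g) sum(labels == g), 0L)
  d <- ncol(logcpm) - length(groups)
  if (d < 1) stopf("no residual degrees of freedom (all groups singletons)")
  means <- vapply(groups, function(g)
    rowMeans(logcpm[, labels == g, drop = FALSE]), numeric(nrow(logcpm)))
  if (is.null(dim(means))) means <- matrix(means, nrow = 1,
                                           dimnames = list(NULL, groups))
  rss <- rowSums((logcpm - means[, match(labels, groups), drop = FALSE])^2)
  list(means = means, s2 = rss / d, d = d, n = n)
}

#' Empirical-Bayes variance moderation
#'
#' Estimates the prior degrees of freedom `d0` and prior variance `s02` of
#' the scaled-F model for per-peak sample variances by moment matching on
#' `log s2` (mean and variance matched to digamma/trigamma expressions, the
#' trigamma equation solved by monotone root finding — via
#' `limma::fitFDist`), then shrinks each variance to its posterior
#' `s2_post = (d0 * s02 + d * s2) / (d0 + d)`. When the moments imply
#' non-positive excess variance, `d0 = Inf` and every posterior equals
#' `s02`. Zero variances are excluded from the moment estimation but still
#' shrunk.
#'
#' @param s2 per-peak residual variances.
#' @param d residual degrees of freedom of `s2`.
#' @return List with `d0`, `s02`, and `s2_post`.
#' @export
ebayes_moderate <- function(s2, d) {
  use <- is.finite(s2) & s2 > 0
  if (sum(use) < 2) stopf("need at least two positive finite variances")
  fit <- limma::fitFDist(s2[use], df1 = d)
  d0 <- fit$df2
  s02 <- fit$scale
  s2_post <- if (is.infinite(d0)) rep(s02, length(s2))
             else (d0 * s02 + d * s2) / (d0 + d)
  list(d0 = d0, s02 = s02, s2_post = s2_post)
}

#' Moderated t-statistics for a two-group contrast
#'
#' `t = (mean_a - mean_b) / sqrt(s2_post * (1/n_a + 1/n_b))`, with two-sided
#' p-values from the t distribution on `d + d0` degrees of freedom (standard
#' normal when `d0 = Inf`). With `d0 = 0` this is the ordinary pooled
#' two-sample t-test.
#'
#' @param mean_a,mean_b per-peak group means.
#' @param s2_post moderated variances from [ebayes_moderate()].
#' @param n_a,n_b group sizes.
#' @param d,d0 residual and prior degrees of freedom.
#' @return List with `t` and `p`.
#' @export
moderated_t <- function(mean_a, mean_b, s2_post, n_a, n_b, d, d0) {
  if (any(s2_post <= 0)) stopf("moderated variances must be positive")
  t <- (mean_a - mean_b) / sqrt(s2_post * (1 / n_a + 1 / n_b))
  p <- 2 * pt(-abs(t), df = d + d0)
  list(t = t, p = p)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment (`stats::p.adjust(method = "BH")`) with input
#' validation: p-values must lie in \[0, 1\].
#'
#' @param p numeric vector of raw p-values.
#' @return Adjusted p-values in the original order.
#' @export
bh_adjust <- function(p) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stopf("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Pairwise differential accessibility across all groups
#'
#' The marker-discovery engine: TMM factors and log-CPM are computed once on
#' the full matrix, the group-means model is fitted across all groups
#' (pooling residual variance, which empirical Bayes then moderates), and
#' every unordered pair of groups yields one contrast with log2 fold change
#' (first minus second group), moderated t, raw p and BH-adjusted p (within
#' the contrast). External-tissue groups (e.g. ENCODE organs) participate as
#' ordinary groups, so candidate markers are also tested against non-TME
#' tissue.
#'
#' @inheritParams tmm_factors
#' @param labels group label per sample (cell types and any external-tissue
#'   groups).
#' @param prior_count log-CPM offset.
#' @return A named list (`"A|B"`) of data.frames with columns `peak_id`,
#'   `lfc`, `t`, `p`, `padj`; each carries attributes `contrast`, `d`, `d0`,
#'   `s02`. The list itself has class `"da_pairs"`.
#' @export
pairwise_da <- function(counts, labels, trimM = 0.3, trimA = 0.05,
                        prior_count = 0.5) {
  m <- if (is_counts_matrix(counts)) counts$values else as.matrix(counts)
  groups <- sort(unique(labels))
  if (length(groups) < 2) stopf("need at least two groups")
  f <- tmm_factors(m, trimM, trimA)
  lcpm <- log_cpm(m, f, prior_count)
  st <- fit_group_stats(lcpm, labels)
  eb <- ebayes_moderate(st$s2, st$d)
  ids <- rownames(m) %||% as.character(seq_len(nrow(m)))
  out <- list()
  for (i in seq_len(length(groups) - 1)) for (j in (i + 1):length(groups)) {
    a <- groups[i]; b <- groups[j]
    tt <- moderated_t(st$means[, a], st$means[, b], eb$s2_post,
                      st$n[[a]], st$n[[b]], st$d, eb$d0)
    df <- data.frame(peak_id = ids, lfc = st$means[, a] - st$means[, b],
                     t = tt$t, p = tt$p, padj = bh_adjust(tt$p),
                     row.names = NULL)
    attr(df, "contrast") <- c(a, b)
    attr(df, "d") <- st$d; attr(df, "d0") <- eb$d0
    attr(df, "s02") <- eb$s02
    out[[paste(a, b, sep = "|")]] <- df
  }
  class(out) <- "da_pairs"
  out
}

#' Write differential results to TSV
#'
#' @param da a `da_pairs` list from [pairwise_da()].
#' @param path output path.
#' @export
write_da_tsv <- function(da, path) {
  rows <- lapply(names(da), function(nm)
    data.frame(contrast = nm, da[[nm]], row.names = NULL))
  write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
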