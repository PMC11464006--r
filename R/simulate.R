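#' Synthetic-data configuration
#'
#' Defines the generative model used for validation: a ground-truth
#' accessibility profile per cell type (planted marker peaks highly
#' accessible in exactly one type, log-normal background peaks shared by all
#' types, and module decoys — peaks that look like markers within the sorted
#' collection but sit inside universal chromatin modules), sorted samples
#' with negative-binomial count noise and multiplicative log-normal study
#' batch effects, and bulk mixtures with Dirichlet proportions plus an
#' uncharacterized component whose profile is zero at every marker peak.
#'
#' @param n_cell_types number of reference cell types (named from a standard
#'   immune/stromal/vascular panel).
#' @param markers_per_type planted marker peaks per cell type.
#' @param n_background_peaks shared background peaks.
#' @param decoys_per_type module-decoy peaks per cell type.
#' @param n_studies,samples_per_study sorted-sample design (per cell type).
#' @param depth expected sequencing depth per sample (fragments).
#' @param phi negative-binomial dispersion (variance `mu + phi mu^2`); 0
#'   gives Poisson noise.
#' @param marker_high,marker_low TPM-like accessibility of a marker peak in
#'   its own / in other cell types.
#' @param background_meanlog,background_sdlog log-normal background means.
#' @param batch_sdlog sd (log scale) of the multiplicative per-(study,
#'   peak-block) batch effect.
#' @param n_batch_blocks number of contiguous peak blocks sharing a batch
#'   multiplier.
#' @param alpha Dirichlet concentration for bulk cell fractions.
#' @param include_uncharacterized include an uncharacterized component in
#'   bulk mixtures?
#' @param uncharacterized_range range its fraction is drawn from (uniform).
#' @param leaky_markers accessibility of the uncharacterized profile at
#'   marker peaks (0 = the idealization the deconvolution model assumes;
#'   small positive values support robustness studies).
#' @param seed master RNG seed.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_cell_types = 5, markers_per_type = 100,
                       n_background_peaks = 2000, decoys_per_type = 10,
                       n_studies = 3, samples_per_study = 4, depth = 1e6,
                       phi = 0.2, marker_high = 200, marker_low = 0.5,
                       background_meanlog = log(50), background_sdlog = 0.5,
                       batch_sdlog = 0.2, n_batch_blocks = 20, alpha = 1,
                       include_uncharacterized = TRUE,
                       uncharacterized_range = c(0, 0.6),
                       leaky_markers = 0, seed = 1) {
  cfg <- as.list(environment())
  if (cfg$n_cell_types < 2 || cfg$markers_per_type < 1 ||
      cfg$n_background_peaks < 1 || cfg$depth <= 0)
    stopf("counts, means and depths must be positive")
  if (cfg$phi < 0 || cfg$alpha <= 0 || cfg$marker_high <= 0)
    stopf("phi must be >= 0 and alpha, marker_high > 0")
  structure(cfg, class = "sim_config")
}

SIM_CELL_TYPES <- c("Bcells", "CD4_Tcells", "CD8_Tcells", "NK", "Monocytes",
                    "Dendritic", "Neutrophils", "Macrophages", "Fibroblasts",
                    "Endothelial")

# NB draw parameterized by mean and dispersion phi; phi = 0 is Poisson.
rnb <- function(n, mu, phi) {
  if (phi == 0) stats::rpois(n, mu) else rnbinom(n, mu = mu, size = 1 / phi)
}

#' Ground-truth profiles, markers and decoy modules
#'
#' Deterministic under the config seed. Marker rows are pairwise disjoint
#' across cell types; the uncharacterized profile equals the background at
#' background peaks and is exactly `leaky_markers` (default 0) at every
#' planted marker. Decoy peaks mimic a marker of one cell type within the
#' sorted collection while lying inside a universal chromatin module, so the
#' module filter — not the differential analysis — must remove them. A few
#' immune-class modules overlapping true markers exercise the exemption
#' rules.
#'
#' @param config a [sim_config()].
#' @return A `sim_truth` list: `peaks`, `cell_types`, `profiles` (TPM-like,
#'   columns cell types + `"uncharacterized"`, each summing to 10^6),
#'   `marker_truth` (data.frame `cell_type`, `peak_id`), `decoy_ids`,
#'   `modules` ([chromatin_modules()]), `config`.
#' @export
simulate_reference_truth <- function(config = sim_config()) {
  cts <- if (config$n_cell_types <= length(SIM_CELL_TYPES))
    SIM_CELL_TYPES[seq_len(config$n_cell_types)]
  else paste0("CellType", seq_len(config$n_cell_types))
  n_mk <- config$n_cell_types * config$markers_per_type
  n_dc <- config$n_cell_types * config$decoys_per_type
  n <- n_mk + config$n_background_peaks + n_dc
  width <- 300 + (seq_len(n) %% 5) * 100
  start <- cumsum(c(0, width[-n] + 1000))
  peaks <- peak_set(rep("chr1", n), start, start + width, sort = FALSE)
  role <- c(rep(cts, each = config$markers_per_type),
            rep("background", config$n_background_peaks),
            if (n_dc) rep(cts, each = config$decoys_per_type))
  kind <- c(rep("marker", n_mk), rep("background", config$n_background_peaks),
            rep("decoy", n_dc))
  profiles <- matrix(0, n, config$n_cell_types + 1,
                     dimnames = list(peaks$id, c(cts, "uncharacterized")))
  with_seed(config$seed, {
    bg <- rlnorm(config$n_background_peaks, config$background_meanlog,
                 config$background_sdlog)
    profiles[kind == "background", ] <- bg
    for (ct in cts) {
      own <- kind != "background" & role == ct
      profiles[own, ] <- config$marker_low
      profiles[own, ct] <- config$marker_high
    }
    profiles[kind == "marker", "uncharacterized"] <- config$leaky_markers
    profiles[kind == "decoy", "uncharacterized"] <- config$marker_high
  })
  profiles <- sweep(profiles, 2, colSums(profiles), "/") * 1e6
  marker_truth <- data.frame(cell_type = role[kind == "marker"],
                             peak_id = peaks$id[kind == "marker"])
  decoy_idx <- which(kind == "decoy")
  mods <- list()
  if (length(decoy_idx))
    mods[[1]] <- chromatin_modules(
      sprintf("U%d", seq_along(decoy_idx)), "chr1",
      peaks$start[decoy_idx] - 50, peaks$end[decoy_idx] + 50, "universal")
  # immune-class modules over the first two markers of each cell type:
  # exempted for immune cell types, vetoed otherwise
  first_mk <- which(kind == "marker")[
    (match(role[kind == "marker"], cts) - 1) * config$markers_per_type + 1]
  imm <- c(first_mk, first_mk + 1)
  mods[[length(mods) + 1]] <- chromatin_modules(
    sprintf("I%d", seq_along(imm)), "chr1",
    peaks$start[imm], peaks$end[imm], "immune")
  modules <- do.call(rbind, mods)
  class(modules) <- c("chromatin_modules", "data.frame")
  structure(list(peaks = peaks, cell_types = cts, profiles = profiles,
                 marker_truth = marker_truth,
                 decoy_ids = peaks$id[decoy_idx], modules = modules,
                 config = config),
            class = "sim_truth")
}

#' Simulate sorted-cell count matrices
#'
#' Per cell type, `n_studies x samples_per_study` samples with counts
#' `NB(mean = profile * batch * depth / 1e6, dispersion phi)`. Batch effects
#' are multiplicative log-normal multipliers shared within each (study,
#' peak-block) pair.
#'
#' @param truth a `sim_truth` from [simulate_reference_truth()].
#' @param config a [sim_config()] (defaults to the truth's).
#' @param seed RNG seed (defaults to `config$seed + 1`).
#' @return A `counts_matrix` whose `sample_meta` carries `cell_type` and
#'   `study`.
#' @export
simulate_sorted_samples <- function(truth, config = truth$config,
                                    seed = config$seed + 1) {
  n <- nrow(truth$peaks)
  block <- rep_len(rep(seq_len(config$n_batch_blocks),
                       each = ceiling(n / config$n_batch_blocks)), n)
  cols <- list(); meta <- list()
  with_seed(seed, {
    mult <- matrix(rlnorm(config$n_studies * config$n_batch_blocks, 0,
                          config$batch_sdlog),
                   config$n_studies, config$n_batch_blocks)
    L <- peak_lengths(truth$peaks)
    for (ct in truth$cell_types) for (s in seq_len(config$n_studies))
      for (r in seq_len(config$samples_per_study)) {
        # fragment rate is accessibility x peak length, scaled to depth, so
        # the TPM-like transform recovers the (batch-distorted) profile
        rate <- truth$profiles[, ct] * mult[s, block] * L
        mu <- rate / sum(rate) * config$depth
        id <- sprintf("%s.study%d.rep%d", ct, s, r)
        cols[[id]] <- rnb(n, mu, config$phi)
        meta[[id]] <- data.frame(sample_id = id, cell_type = ct,
                                 study = sprintf("study%d", s))
      }
  })
  counts_matrix(do.call(cbind, cols), truth$peaks, do.call(rbind, meta))
}

#' Simulate bulk mixtures with known proportions
#'
#' Cell fractions are Dirichlet(`alpha`) draws; when uncharacterized cells
#' are included their fraction is drawn uniformly from
#' `uncharacterized_range` (or fixed via `unchar_fractions`) and the
#' cell-type fractions are scaled to fill the remainder. The expected bulk
#' profile is the proportion-weighted mix of the truth profiles; counts are
#' negative-binomial around it at the configured depth (`noise = FALSE`
#' returns the expectation itself, for noiseless identifiability checks).
#'
#' @param truth a `sim_truth`.
#' @param n_samples number of bulk mixtures.
#' @param config a [sim_config()].
#' @param seed RNG seed (defaults to `config$seed + 2`).
#' @param noise add negative-binomial count noise?
#' @param unchar_fractions optional fixed uncharacterized fraction(s),
#'   recycled over samples.
#' @return List with `counts` (a `counts_matrix`) and `proportions`
#'   (data.frame: `sample_id`, one column per cell type, `uncharacterized`).
#' @export
simulate_bulk <- function(truth, n_samples, config = truth$config,
                          seed = config$seed + 2, noise = TRUE,
                          unchar_fractions = NULL) {
  k <- length(truth$cell_types)
  cols <- list(); props <- list()
  with_seed(seed, {
    for (i in seq_len(n_samples)) {
      g <- rgamma(k, shape = config$alpha)
      p <- g / sum(g)
      p_u <- 0
      if (config$include_uncharacterized)
        p_u <- if (!is.null(unchar_fractions))
          unchar_fractions[(i - 1) %% length(unchar_fractions) + 1]
        else runif(1, config$uncharacterized_range[1],
                   config$uncharacterized_range[2])
      p <- p * (1 - p_u)
      mix <- as.numeric(truth$profiles %*% c(p, p_u))
      rate <- mix * peak_lengths(truth$peaks)
      mu <- rate / sum(rate) * config$depth
      id <- sprintf("bulk%d", i)
      cols[[id]] <- if (noise) rnb(length(mu), mu, config$phi) else mu
      props[[id]] <- data.frame(sample_id = id, rbind(setNames(p,
        truth$cell_types)), uncharacterized = p_u, check.names = FALSE)
    }
  })
  list(counts = counts_matrix(do.call(cbind, cols), truth$peaks),
       proportions = do.call(rbind, c(props, list(make.row.names = FALSE))))
}

#' Pseudobulk aggregation of per-cell profiles
#'
#' Pseudobulk accessibility is the per-peak mean over member cells; the true
#' proportion of a cell type is its share of member cells.
#'
#' @param cells numeric matrix, peaks x cells (normalized counts).
#' @param labels cell-type label per cell.
#' @param peaks `peak_set` for the rows.
#' @param groups optional pseudobulk id per cell (default: one pseudobulk).
#' @return List with `counts` (a `counts_matrix`, one column per pseudobulk)
#'   and `proportions`.
#' @export
simulate_pseudobulk_from_cells <- function(cells, labels, peaks,
                                           groups = NULL) {
  cells <- as.matrix(cells)
  groups <- groups %||% rep("pseudobulk1", ncol(cells))
  stopifnot(length(labels) == ncol(cells), length(groups) == ncol(cells))
  cts <- sort(unique(labels))
  ids <- unique(groups)
  vals <- vapply(ids, function(g)
    rowMeans(cells[, groups == g, drop = FALSE]), numeric(nrow(cells)))
  if (is.null(dim(vals))) vals <- matrix(vals, ncol = length(ids))
  colnames(vals) <- ids
  props <- do.call(rbind, lapply(ids, function(g) {
    tab <- table(factor(labels[groups == g], levels = cts))
    data.frame(sample_id = g, rbind(as.numeric(tab) / sum(tab)),
               check.names = FALSE)
  }))
  names(props)[-1] <- cts
  list(counts = counts_matrix(vals, peaks), proportions = props)
}
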