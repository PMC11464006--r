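test_that("feature weights decrease with cell-type-averaged IQR", {
  cfg <- sim_config(n_cell_types = 3, markers_per_type = 4,
                    n_background_peaks = 10, decoys_per_type = 0, seed = 31)
  truth <- simulate_reference_truth(cfg)
  prof <- truth_profile(truth)
  ids <- prof$peaks$id[1:4]
  # all-zero IQR: equal weights with epsilon = 1
  fw <- feature_weights(prof, ids)
  expect_equal(unname(fw$w), rep(1, 4))
  expect_equal(fw$epsilon, 1)
  # monotone decreasing in vbar, epsilon from the positive median
  prof$v[1:4, ] <- c(0, 1, 5, 50)
  fw2 <- feature_weights(prof, ids)
  vbar <- c(0, 1, 5, 50)
  eps <- 1e-2 * median(vbar[vbar > 0])
  expect_equal(unname(fw2$w), 1 / (vbar + eps))
  expect_true(all(diff(fw2$w) < 0))
  expect_error(feature_weights(prof, "chrX:1-2"), "not in profile")
})

test_that("the constrained fit recovers exact and mixed columns", {
  set.seed(32)
  R <- matrix(rexp(60 * 3, rate = 1 / 100), ncol = 3,
              dimnames = list(NULL, c("Bcells", "Tcells", "NK")))
  w <- rep(1, 60)
  p1 <- epic_fit_sample(R[, "Bcells"], R, w)
  expect_equal(as.numeric(p1), c(1, 0, 0), tolerance = 1e-6)
  b <- 0.3 * R[, "Tcells"] + 0.7 * R[, "NK"]
  p2 <- epic_fit_sample(b, R, w)
  expect_equal(as.numeric(p2), c(0, 0.3, 0.7), tolerance = 1e-6)
  # sum <= 1 binds when signal is diluted
  p3 <- epic_fit_sample(0.5 * b, R, w)
  expect_equal(sum(p3), 0.5, tolerance = 1e-6)
  expect_error(epic_fit_sample(b[1:2], R[1:2, ], w[1:2]), "at least")
})

test_that("the fit matches an exhaustive simplex grid search", {
  set.seed(33)
  for (rep in 1:5) {
    R <- matrix(rexp(6 * 3, rate = 1 / 50), ncol = 3)
    truep <- c(0.5, 0.2, 0.1)
    b <- as.numeric(R %*% truep) + rnorm(6, sd = 1)
    w <- runif(6, 0.5, 2)
    p <- epic_fit_sample(b, R, w)
    grid <- grid_search_qp(b, R, w)
    expect_lte(attr(p, "objective"), grid$objective + 1e-8)
    # within one grid cell: rounding the QP optimum onto the grid bounds
    # the possible grid advantage
    p_round <- round(p / 0.005) * 0.005
    if (sum(p_round) > 1) p_round <- p_round / sum(p_round)
    bound <- qp_objective(p_round, b, R, w) - attr(p, "objective")
    expect_lte(grid$objective - attr(p, "objective"), bound + 1e-8)
  }
})

test_that("rank-deficient references are ridged and flagged, not fatal", {
  set.seed(34)
  base <- rexp(20, 1 / 50)
  R <- cbind(a = base, b = base, c = rexp(20, 1 / 50))  # duplicated column
  p <- epic_fit_sample(R[, "c"], R, rep(1, 20))
  expect_true(attr(p, "non_unique"))
  expect_equal(sum(p), 1, tolerance = 1e-4)
  expect_equal(unname(p["c"]), 1, tolerance = 1e-3)
})

test_that("the uncharacterized fraction is the clamped simplex deficit", {
  expect_equal(estimate_uncharacterized(c(0.5, 0.2, 0.0)), 0.3)
  expect_equal(estimate_uncharacterized(c(0.6, 0.4)), 0)
  expect_equal(estimate_uncharacterized(c(0.6, 0.4 + 1e-12)), 0)
})

test_that("signal-content renormalization defaults to the identity", {
  p <- c(A = 0.5, B = 0.3)
  out <- mrna_renormalize(p, p_u = 0.2)
  expect_equal(unname(out), c(0.5, 0.3, 0.2))
  out2 <- mrna_renormalize(c(A = 0.5, B = 0.5), p_u = 0,
                           factors = c(A = 2, B = 1))
  expect_equal(unname(out2), c(1 / 3, 2 / 3, 0))
  expect_equal(sum(mrna_renormalize(c(A = .1, B = .2), 0.05)), 1)
  expect_error(mrna_renormalize(p, 0, c(A = -1, B = 1)), "positive")
})

test_that("noiseless bulk deconvolution recovers the planted proportions", {
  cfg <- sim_config(n_cell_types = 5, seed = 35)
  truth <- simulate_reference_truth(cfg)
  prof <- truth_profile(truth)
  b <- simulate_bulk(truth, 6, cfg, noise = FALSE)
  res <- deconvolve(b$counts, prof)
  got <- fractions_matrix(res)
  want <- as.matrix(b$proportions[, colnames(got)])
  expect_lt(max(abs(got - want)), 1e-4)
  expect_equal(unname(rowSums(got)), rep(1, 6), tolerance = 1e-9)
})

test_that("deconvolution is invariant to overlap-preserving coordinate
           jitter and to per-sample count scaling", {
  cfg <- sim_config(n_cell_types = 4, markers_per_type = 30,
                    n_background_peaks = 300, decoys_per_type = 0,
                    seed = 36)
  truth <- simulate_reference_truth(cfg)
  prof <- truth_profile(truth)
  b <- simulate_bulk(truth, 3, cfg, noise = FALSE)
  base <- fractions_matrix(deconvolve(b$counts, prof))
  # shift every bulk peak by +/- 37 bp: overlaps (peaks are >= 300 bp wide)
  # and hence the matching are unchanged
  shift <- ifelse(seq_len(nrow(truth$peaks)) %% 2 == 0, 37, -37)
  shift[truth$peaks$start + shift < 0] <- 37
  jit <- peak_set(truth$peaks$chrom, truth$peaks$start + shift,
                  truth$peaks$end + shift, sort = FALSE)
  bulk_jit <- counts_matrix(b$counts$values, jit)
  expect_equal(fractions_matrix(deconvolve(bulk_jit, prof)), base,
               tolerance = 1e-12)
  # scaling one sample's counts leaves its fractions unchanged
  scaled <- b$counts
  scaled$values[, 2] <- scaled$values[, 2] * 7.3
  expect_equal(fractions_matrix(deconvolve(scaled, prof)), base,
               tolerance = 1e-9)
})

test_that("uncharacterized dilution of the cell-type signal is read back
           as 1 - alpha", {
  cfg <- sim_config(n_cell_types = 4, markers_per_type = 30,
                    n_background_peaks = 300, decoys_per_type = 0,
                    seed = 37)
  truth <- simulate_reference_truth(cfg)
  prof <- truth_profile(truth)
  for (alpha in c(1, 0.7, 0.4, 0.1)) {
    b <- simulate_bulk(truth, 1, cfg, noise = FALSE,
                       unchar_fractions = 1 - alpha)
    res <- deconvolve(b$counts, prof)
    expect_equal(res$uncharacterized, 1 - alpha, tolerance = 0.01)
  }
})

test_that("disjoint genomes and build mismatches fail with guidance", {
  cfg <- sim_config(n_cell_types = 3, markers_per_type = 10,
                    n_background_peaks = 50, decoys_per_type = 0, seed = 38)
  truth <- simulate_reference_truth(cfg)
  prof <- truth_profile(truth)
  other <- counts_matrix(matrix(1:4, ncol = 1),
                         peak_set(rep("chr9", 4), (1:4) * 1000,
                                  (1:4) * 1000 + 100))
  expect_error(deconvolve(other, prof), "no shared features")
  hg19 <- counts_matrix(matrix(1:4, ncol = 1),
                        peak_set(rep("chr1", 4), (1:4) * 1000,
                                 (1:4) * 1000 + 100,
                                 genome_build = "hg19"))
  expect_error(deconvolve(hg19, prof), "chain")
})

test_that("deconvolution through a liftover matches the direct result", {
  cfg <- sim_config(n_cell_types = 3, markers_per_type = 10,
                    n_background_peaks = 50, decoys_per_type = 0, seed = 39)
  truth <- simulate_reference_truth(cfg)
  prof <- truth_profile(truth)
  b <- simulate_bulk(truth, 2, cfg, noise = FALSE)
  direct <- fractions_matrix(deconvolve(b$counts, prof))
  # shift the whole bulk genome by 10 kb and lift it back with one chain
  span <- max(truth$peaks$end) + 20000
  shifted <- counts_matrix(
    b$counts$values,
    peak_set(truth$peaks$chrom, truth$peaks$start + 10000,
             truth$peaks$end + 10000, genome_build = "hg19", sort = FALSE))
  f <- withr::local_tempfile(fileext = ".chain")
  writeLines(c(sprintf("chain 100 chr1 %d + 10000 %d chr1 %d + 0 %d 1",
                       span + 10000, span + 10000, span, span),
               sprintf("%d", span)), f)
  res <- deconvolve(shifted, prof, chains = read_chain(f))
  expect_equal(fractions_matrix(res), direct, tolerance = 1e-12)
})
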