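# build a da_pairs-like structure by hand for selection tests
fake_da <- function(ids, contrasts) {
  out <- lapply(names(contrasts), function(nm) {
    pair <- strsplit(nm, "|", fixed = TRUE)[[1]]
    df <- data.frame(peak_id = ids, lfc = contrasts[[nm]]$lfc,
                     t = 0, p = contrasts[[nm]]$padj,
                     padj = contrasts[[nm]]$padj)
    attr(df, "contrast") <- pair
    df
  })
  names(out) <- names(contrasts)
  class(out) <- "da_pairs"
  out
}

test_that("fold markers require the fold change in every contrast and rank
           by worst adjusted p", {
  ids <- c("chr1:0-100", "chr1:200-300", "chr1:400-500")
  da <- fake_da(ids, list(
    "A|B" = list(lfc = c(0.5, 0.1, 0.6), padj = c(0.001, 0.001, 0.01)),
    "A|C" = list(lfc = c(0.5, 0.9, 0.6), padj = c(0.002, 0.001, 0.2))))
  got <- select_fold_markers(da, "A")
  # peak 2 fails the 0.2 threshold in one contrast; peak 1 has the lowest
  # maximum adjusted p
  expect_equal(got, c("chr1:0-100", "chr1:400-500"))
  expect_equal(select_fold_markers(da, "A",
                                   marker_params(top_n = 1)), "chr1:0-100")
  # orientation flips when the target is the second group of a contrast
  da2 <- fake_da(ids, list(
    "A|B" = list(lfc = c(-0.5, -0.5, -0.5), padj = rep(0.01, 3))))
  expect_equal(select_fold_markers(da2, "B"), ids)
  # a missing contrast is an error
  da3 <- fake_da(ids, list(
    "A|B" = list(lfc = rep(1, 3), padj = rep(0.01, 3)),
    "B|C" = list(lfc = rep(1, 3), padj = rep(0.01, 3))))
  expect_error(select_fold_markers(da3, "A"), "missing contrast")
})

test_that("truncation caps the list at top_n with deterministic tie-breaks", {
  n <- 300
  ids <- sprintf("chr1:%d-%d", (1:n) * 1000, (1:n) * 1000 + 100)
  da <- fake_da(ids, list("A|B" = list(lfc = rep(0.5, n),
                                       padj = rep(0.5, n))))
  got <- select_fold_markers(da, "A")
  expect_length(got, 200)
  expect_equal(got, sort(ids)[1:200])   # all tied: peak-id order decides
})

test_that("the stability filter keeps markers recurring in >= min_folds", {
  folds <- c(rep(list(c("a", "b")), 3), rep(list(c("b")), 7))
  st <- stability_filter(folds)
  expect_equal(st$peak_id, c("b", "a"))
  expect_equal(st$fold_count, c(10L, 3L))
  st2 <- stability_filter(c(rep(list("a"), 2), rep(list(character()), 8)))
  expect_equal(nrow(st2), 0)
  # monotone in min_folds
  st3 <- stability_filter(folds, marker_params(min_folds = 4))
  expect_true(all(st3$peak_id %in% st$peak_id))
  expect_error(stability_filter(folds[1:5]), "expected 10")
})

test_that("folds are stratified, deterministic and leave-one-fold-out", {
  ids <- sprintf("s%02d", 1:20)
  lab <- rep(c("A", "B"), each = 10)
  f1 <- make_folds(ids, lab, n_folds = 10, seed = 5)
  f2 <- make_folds(ids, lab, n_folds = 10, seed = 5)
  expect_identical(f1, f2)
  expect_setequal(unlist(f1), ids)
  for (k in 1:10) {
    an <- analysis_set(f1, k)
    expect_length(an, 18)
    expect_setequal(unique(lab[match(an, ids)]), c("A", "B"))
  }
  expect_false(identical(make_folds(ids, lab, seed = 6), f1))
  # a singleton cell type cannot survive leave-one-fold-out
  expect_error(make_folds(c(ids, "s21"), c(lab, "C"), n_folds = 10),
               "too few samples")
})

test_that("module vetoes respect universal modules and class exemptions", {
  markers <- data.frame(
    cell_type = c("Bcells", "Bcells", "Endothelial", "Endothelial"),
    peak_id = c("chr1:100-200", "chr1:1000-1100",
                "chr1:100-200", "chr1:5000-5100"),
    fold_count = 10)
  markers$peak_id[3] <- "chr1:120-220"   # also overlaps the immune module
  mods <- chromatin_modules(c("U1", "I1"), c("chr1", "chr1"),
                            c(3000, 90), c(3100, 250),
                            c("universal", "immune"))
  out <- module_filter(markers, mods)
  # B-cell marker in an immune module is exempt and kept
  expect_true("chr1:100-200" %in% out$peak_id[out$cell_type == "Bcells"])
  # endothelial marker in an immune module is removed
  expect_false(any(out$cell_type == "Endothelial" &
                     out$peak_id == "chr1:120-220"))
  # non-overlapping markers kept
  expect_true("chr1:1000-1100" %in% out$peak_id)
  expect_true("chr1:5000-5100" %in% out$peak_id)
  # anything overlapping a universal module is removed even when exempted
  markers2 <- data.frame(cell_type = "Bcells", peak_id = "chr1:3050-3150",
                         fold_count = 5)
  expect_equal(nrow(module_filter(markers2, mods)), 0)
  # dropping exemptions removes at least as many markers
  out_noex <- module_filter(markers, mods,
                            exemptions = setNames(
                              rep(list(character()), 2),
                              c("Bcells", "Endothelial")))
  expect_lte(nrow(out_noex), nrow(out))
  expect_error(module_filter(markers, mods,
                             exemptions = list(Bcells = "plasma")),
               "not present")
})

test_that("the correlation scan follows the worked three-marker example", {
  r <- diag(3)
  r[1, 2] <- r[2, 1] <- 0.95
  r[1, 3] <- r[3, 1] <- 0.1
  r[2, 3] <- r[3, 2] <- 0.1
  # mean |r|: A = B = 0.525, C = 0.1; pair (A,B) exceeds 0.9; tie flags A
  expect_equal(atacdeconv:::correlation_scan(r, 0.9), c(TRUE, FALSE, FALSE))
})

test_that("the correlation scan matches an independent step-through", {
  set.seed(12)
  for (rep in 1:300) {
    x <- matrix(rnorm(8 * 12), ncol = 8)
    r <- cor(x)
    cutoff <- runif(1, 0.1, 0.9)
    expect_equal(atacdeconv:::correlation_scan(r, cutoff), brute_corr_scan(r, cutoff))
  }
})

test_that("correlation pruning keeps block-correlated markers and falls back
           when nothing exceeds the cutoff", {
  set.seed(13)
  n_samp <- 30
  drive1 <- rnorm(n_samp); drive2 <- rnorm(n_samp)
  block1 <- sapply(1:4, function(i) drive1 + rnorm(n_samp, sd = 0.1))
  block2 <- sapply(1:4, function(i) drive2 + rnorm(n_samp, sd = 0.1))
  singletons <- sapply(1:4, function(i) rnorm(n_samp))
  ids <- sprintf("chr1:%d-%d", (1:12) * 1000, (1:12) * 1000 + 100)
  bulk <- t(cbind(block1, block2, singletons))
  rownames(bulk) <- ids
  colnames(bulk) <- sprintf("b%d", 1:n_samp)
  markers <- data.frame(cell_type = "A", peak_id = ids, fold_count = 10)
  out <- correlation_prune(markers, bulk)
  expect_true(all(out$peak_id %in% ids[1:8]))   # only block members retained
  expect_gt(nrow(out), 0)
  # drop mode removes the flagged members instead
  out2 <- correlation_prune(markers, bulk,
                            marker_params(prune_mode = "drop_correlated"))
  expect_true(all(ids[9:12] %in% out2$peak_id))
  # exactly orthogonal markers: every pairwise correlation is 0, no pair
  # exceeds the cutoff, so the set falls back unpruned with a warning
  H <- contr.helmert(n_samp)[, 1:4]   # centered, mutually orthogonal
  bulk_orth <- t(H)
  rownames(bulk_orth) <- ids[9:12]
  colnames(bulk_orth) <- colnames(bulk)
  markers3 <- data.frame(cell_type = "A", peak_id = ids[9:12],
                         fold_count = 10)
  expect_warning(out3 <- correlation_prune(markers3, bulk_orth), "unpruned")
  expect_equal(nrow(out3), 4)
  # markers absent from the bulk pass through unchanged
  markers4 <- data.frame(cell_type = "A",
                         peak_id = c(ids[1:3], "chr9:1-100"),
                         fold_count = 10)
  out4 <- correlation_prune(markers4, bulk)
  expect_true("chr9:1-100" %in% out4$peak_id)
  expect_error(correlation_prune(markers, bulk[, 1:2]), "3 bulk samples")
})

test_that("planted markers are recovered with full recall and decoys are
           removed by the module veto", {
  cfg <- sim_config(seed = 21)
  truth <- simulate_reference_truth(cfg)
  sorted <- simulate_sorted_samples(truth, cfg)
  mk <- select_markers(sorted, cell_types = truth$cell_types,
                       modules = truth$modules, seed = 22)
  for (ct in truth$cell_types) {
    sel <- mk$peak_id[mk$cell_type == ct]
    tru <- truth$marker_truth$peak_id[truth$marker_truth$cell_type == ct]
    expect_gte(mean(tru %in% sel), 0.9)          # recall
  }
  # marker lists are disjoint across cell types
  expect_false(any(duplicated(mk$peak_id)))
  # every decoy was selected by the DA step and then vetoed
  expect_false(any(mk$peak_id %in% truth$decoy_ids))
  removed <- attr(mk, "removed")
  expect_true(all(truth$decoy_ids %in% removed$peak_id))
})
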