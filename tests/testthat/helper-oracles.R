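# Independent reference implementations used as oracles. These deliberately
# use the most direct (often quadratic) formulation of each rule and share no
# code with the package internals.

# nearest target by exhaustive scan; ties to the lowest index
brute_nearest <- function(q, targets) {
  d <- rep(Inf, nrow(targets))
  for (i in seq_len(nrow(targets))) {
    if (targets$chrom[i] != q$chrom) next
    d[i] <- max(targets$start[i] - q$end, q$start - targets$end[i], 0)
  }
  list(index = which.min(d), distance = min(d))
}

# literal iterative overlap collapse: emit the max-score peak, delete
# everything overlapping it, repeat
brute_collapse <- function(df) {
  kept <- df[0, ]
  pool <- df
  while (nrow(pool) > 0) {
    ord <- order(-pool$score, pool$chrom, pool$start, pool$end)
    top <- pool[ord[1], ]
    kept <- rbind(kept, top)
    ov <- pool$chrom == top$chrom & pool$start < top$end &
      pool$end > top$start
    pool <- pool[!ov, , drop = FALSE]
  }
  kept[order(kept$chrom, kept$start, kept$end), , drop = FALSE]
}

# BH step-up as min over tails, O(m^2)
brute_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    tail_vals <- vapply(i:m, function(k) p[ord[k]] * m / k, 0)
    q[ord[i]] <- min(1, min(tail_vals))
  }
  q
}

# step-through of the correlation scan rule: column-major pair order, flag
# the larger-mean-|r| member, skip flagged, ties flag the lower index
brute_corr_scan <- function(r, cutoff) {
  n <- ncol(r)
  ma <- sapply(seq_len(n), function(i) mean(abs(r[i, -i])))
  flagged <- rep(FALSE, n)
  for (j in seq(2, n)) for (i in seq(1, j - 1)) {
    if (flagged[i] || flagged[j] || abs(r[i, j]) <= cutoff) next
    if (ma[i] > ma[j]) flagged[i] <- TRUE
    else if (ma[j] > ma[i]) flagged[j] <- TRUE
    else flagged[i] <- TRUE
  }
  flagged
}

# weighted trimmed-mean-of-M TMM factors, following the published estimator
# step by step: upper-quartile reference selection, double (M and A)
# rank-based trimming, precision weighting by the binomial variance
# approximation, geometric-mean-1 rescaling
brute_tmm_pair <- function(counts, k, r, trimM = 0.3, trimA = 0.05) {
  nk <- sum(counts[, k]); nr <- sum(counts[, r])
  keep <- counts[, k] > 0 & counts[, r] > 0
  yk <- counts[keep, k]; yr <- counts[keep, r]
  M <- log2((yk / nk) / (yr / nr))
  A <- (log2(yk / nk) + log2(yr / nr)) / 2
  w <- (nk - yk) / (nk * yk) + (nr - yr) / (nr * yr)
  if (max(abs(M)) < 1e-6) return(1)
  n <- length(M)
  loM <- floor(n * trimM) + 1; hiM <- n + 1 - loM
  loA <- floor(n * trimA) + 1; hiA <- n + 1 - loA
  use <- rank(M) >= loM & rank(M) <= hiM &
    rank(A) >= loA & rank(A) <= hiA
  2^(sum(M[use] / w[use]) / sum(1 / w[use]))
}

brute_tmm <- function(counts, trimM = 0.3, trimA = 0.05) {
  f75 <- apply(counts, 2, quantile, 0.75) / colSums(counts)
  ref <- which.min(abs(f75 - mean(f75)))
  f <- vapply(seq_len(ncol(counts)), function(k)
    if (k == ref) 1 else brute_tmm_pair(counts, k, ref, trimM, trimA), 0)
  f / exp(mean(log(f)))
}

# exhaustive simplex grid search for the 3-cell-type weighted LS problem
grid_search_qp <- function(b, R, w, step = 0.005) {
  if (!exists(".qp_grid", envir = globalenv())) {
    s <- seq(0, 1, by = step)
    g <- expand.grid(p1 = s, p2 = s)
    g <- g[g$p1 + g$p2 <= 1 + 1e-12, ]
    # third coordinate ranges over the remaining budget; build in chunks
    grid <- do.call(rbind, lapply(seq_len(nrow(g)), function(i) {
      p3 <- seq(0, 1 - g$p1[i] - g$p2[i] + 1e-12, by = step)
      cbind(g$p1[i], g$p2[i], pmin(p3, 1))
    }))
    assign(".qp_grid", grid, envir = globalenv())
  }
  P <- get(".qp_grid", envir = globalenv())
  Rw <- sqrt(w) * R
  bw <- sqrt(w) * b
  M <- crossprod(Rw)
  a <- as.numeric(crossprod(Rw, bw))
  obj <- sum(bw^2) - 2 * as.numeric(P %*% a) + rowSums((P %*% M) * P)
  i <- which.min(obj)
  list(p = P[i, ], objective = obj[i])
}

qp_objective <- function(p, b, R, w) sum(w * (b - as.numeric(R %*% p))^2)

# per-base chain mapping oracle: walk the blocks and enumerate every source
# base's destination coordinate
chain_base_map <- function(chain) {
  s <- chain$s_start; q <- chain$q_start
  map <- list()
  for (b in seq_len(nrow(chain$blocks))) {
    size <- chain$blocks$size[b]
    src <- s + seq_len(size) - 1
    dst <- q + seq_len(size) - 1
    if (chain$q_strand == "-") dst <- chain$q_size - 1 - dst
    map[[b]] <- data.frame(src = src, dst = dst)
    s <- s + size + chain$blocks$dt[b]
    q <- q + size + chain$blocks$dq[b]
  }
  do.call(rbind, map)
}

random_peak_set <- function(n, chroms = c("chr1", "chr2"), span = 5000) {
  start <- sample.int(span, n, replace = TRUE)
  width <- sample(20:300, n, replace = TRUE)
  df <- data.frame(chrom = sample(chroms, n, replace = TRUE),
                   start = start, end = start + width,
                   score = round(runif(n, 1, 100), 3))
  df <- df[!duplicated(df[c("chrom", "start", "end")]), ]
  peak_set(df$chrom, df$start, df$end, df$score)
}

# a reference_profile whose R equals the simulation truth exactly (zero IQR),
# with the planted markers flagged — the ideal reference for noiseless checks
truth_profile <- function(truth) {
  n <- nrow(truth$peaks)
  cts <- truth$cell_types
  prof <- structure(list(
    peaks = truth$peaks, cell_types = cts,
    R = truth$profiles[, cts, drop = FALSE],
    v = matrix(0, n, length(cts), dimnames = list(truth$peaks$id, cts)),
    markers = matrix(FALSE, n, length(cts),
                     dimnames = list(truth$peaks$id, cts)),
    genome_build = genome_build(truth$peaks)),
    class = "reference_profile")
  set_profile_markers(prof, truth$marker_truth)
}
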