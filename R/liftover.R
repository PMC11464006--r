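#' Read a UCSC chain file
#'
#' Parses the standard chain format: a header line
#' `chain score tName tSize tStrand tStart tEnd qName qSize qStrand qStart
#' qEnd id` followed by alignment-block triples `size dt dq` (the final line
#' of each chain carries only `size`). The `t` (target-of-alignment) side is
#' treated as the *source* genome of the liftover and the `q` side as the
#' *destination*, matching how UCSC hg19-to-hg38 chains are consumed.
#'
#' @param path path to an uncompressed chain file.
#' @return A list of chains; each chain is a list with `score`, source
#'   (`s_chrom`, `s_size`, `s_start`, `s_end`) and destination (`q_chrom`,
#'   `q_size`, `q_strand`, `q_start`, `q_end`) fields plus a `blocks`
#'   data.frame (`size`, `dt`, `dq`, all non-negative, `size > 0`).
#' @export
read_chain <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[!grepl("^#", lines)]
  heads <- grep("^chain\\b", lines)
  if (!length(heads)) stopf("no chain records in %s", path)
  ends <- c(heads[-1] - 1, length(lines))
  chains <- vector("list", length(heads))
  for (k in seq_along(heads)) {
    h <- strsplit(lines[heads[k]], "[ \t]+")[[1]]
    if (length(h) < 12) stopf("malformed chain header: %s", lines[heads[k]])
    body <- lines[(heads[k] + 1):ends[k]]
    body <- body[nzchar(body)]
    tri <- lapply(strsplit(body, "[ \t]+"), as.numeric)
    sizes <- vapply(tri, `[`, 0, 1)
    dt <- vapply(tri, function(x) if (length(x) >= 2) x[2] else 0, 0)
    dq <- vapply(tri, function(x) if (length(x) >= 3) x[3] else 0, 0)
    if (any(sizes <= 0) || any(dt < 0) || any(dq < 0))
      stopf("invalid block triple in chain %s", h[13] %||% "")
    ch <- list(score = as.numeric(h[2]),
               s_chrom = h[3], s_size = as.numeric(h[4]),
               s_strand = h[5],
               s_start = as.numeric(h[6]), s_end = as.numeric(h[7]),
               q_chrom = h[8], q_size = as.numeric(h[9]),
               q_strand = h[10],
               q_start = as.numeric(h[11]), q_end = as.numeric(h[12]),
               id = if (length(h) >= 13) h[13] else NA_character_,
               blocks = data.frame(size = sizes, dt = dt, dq = dq))
    if (sum(sizes) + sum(dt[-length(dt)]) > ch$s_end - ch$s_start)
      stopf("chain %s: blocks exceed source span", ch$id)
    chains[[k]] <- ch
  }
  chains
}

# Map a single source base position through a chain; NA when the position
# falls in a gap. Returns the 0-based destination position (forward strand).
map_position <- function(chain, pos) {
  s <- chain$s_start
  q <- chain$q_start
  for (b in seq_len(nrow(chain$blocks))) {
    size <- chain$blocks$size[b]
    if (pos >= s && pos < s + size) {
      qp <- q + (pos - s)
      if (chain$q_strand == "-") qp <- chain$q_size - 1 - qp
      return(list(pos = qp, block = b))
    }
    s <- s + size + chain$blocks$dt[b]
    q <- q + size + chain$blocks$dq[b]
  }
  NULL
}

#' Lift genomic regions between assemblies
#'
#' Implements conservative single-best-chain semantics: a region lifts iff
#' both its start and its last base (`end - 1`) fall inside aligned blocks of
#' the single highest-scoring chain overlapping it on the source genome, and
#' inside the *same* block (so length is always preserved). Regions spanning
#' an alignment gap, split across chains, or on chromosomes without any chain
#' are dropped with a reason (`"unmapped"` / `"no_chain"`). On reverse-strand
#' chains destination coordinates are flipped against the destination
#' chromosome size and re-normalized so that `start < end`.
#'
#' @param peaks a `peak_set` on the source build.
#' @param chains list of chains from [read_chain()].
#' @param target_build genome-build tag for the lifted `peak_set`.
#' @return List with `lifted` (a sorted `peak_set` on `target_build`) and
#'   `dropped` (data.frame with columns `id`, `reason`).
#' @export
liftover_regions <- function(peaks, chains, target_build = "hg38") {
  by_chrom <- split(chains, vapply(chains, `[[`, "", "s_chrom"))
  out <- vector("list", nrow(peaks))
  drop_id <- character(); drop_reason <- character()
  for (i in seq_len(nrow(peaks))) {
    cand <- by_chrom[[peaks$chrom[i]]]
    if (is.null(cand)) {
      drop_id <- c(drop_id, peaks$id[i])
      drop_reason <- c(drop_reason, "no_chain")
      next
    }
    ov <- vapply(cand, function(ch)
      peaks$start[i] < ch$s_end && peaks$end[i] > ch$s_start, TRUE)
    cand <- cand[ov]
    mapped <- NULL
    if (length(cand)) {
      best <- cand[[which.max(vapply(cand, `[[`, 0, "score"))]]
      a <- map_position(best, peaks$start[i])
      b <- map_position(best, peaks$end[i] - 1)
      if (!is.null(a) && !is.null(b) && a$block == b$block) {
        st <- min(a$pos, b$pos)
        en <- max(a$pos, b$pos) + 1
        mapped <- data.frame(chrom = best$q_chrom, start = st, end = en,
                             score = peaks$score[i])
      }
    }
    if (is.null(mapped)) {
      drop_id <- c(drop_id, peaks$id[i])
      drop_reason <- c(drop_reason, "unmapped")
    } else out[[i]] <- data.frame(mapped, source_id = peaks$id[i])
  }
  kept <- do.call(rbind, out[!vapply(out, is.null, TRUE)])
  if (!is.null(kept)) {
    # two source regions can land on identical destination coordinates;
    # ids must stay unique, so later duplicates are dropped
    kept <- kept[order(kept$chrom, kept$start, kept$end), , drop = FALSE]
    dup <- duplicated(kept[c("chrom", "start", "end")])
    if (any(dup)) {
      drop_id <- c(drop_id, kept$source_id[dup])
      drop_reason <- c(drop_reason, rep("duplicate_target", sum(dup)))
      kept <- kept[!dup, , drop = FALSE]
    }
  }
  lifted <- if (is.null(kept) || nrow(kept) == 0)
    peak_set(character(), numeric(), numeric(), genome_build = target_build)
  else
    peak_set(kept$chrom, kept$start, kept$end, kept$score,
             genome_build = target_build, sort = FALSE)
  attr(lifted, "source_id") <- if (is.null(kept)) character()
                               else kept$source_id
  list(lifted = lifted,
       dropped = data.frame(id = drop_id, reason = drop_reason))
}
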