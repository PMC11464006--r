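#' @importFrom stats median quantile var sd cor rnorm rgamma rnbinom rlnorm
#'   runif p.adjust pt setNames
#' @importFrom utils read.table write.table head
NULL

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG afterwards so library code never clobbers user seeds.
with_seed <- function(seed, code) {
  force(seed)  # the seed may itself be drawn from the caller's RNG stream
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
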