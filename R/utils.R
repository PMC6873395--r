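## Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so callers' random streams are not
#' disturbed; used to make preset expansion and other "pure given seed"
#' operations side-effect free.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
#' @noRd
with_local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  expr
}

## Deterministic per-sample substream seeds from one root seed.  Seeds are
## drawn once, in a fixed (group, sample) enumeration order, so results do
## not depend on the order samples are later iterated in.
derive_substream_seeds <- function(root_seed, n_streams) {
  with_local_seed(root_seed, sample.int(.Machine$integer.max - 1L, n_streams))
}

## Largest-remainder apportionment of `total` units proportional to `weights`.
## Features with zero weight never receive a unit (the number of leftover
## units is always strictly less than the number of positive fractional
## parts), which preserves structural zeros.
largest_remainder <- function(weights, total) {
  stopifnot(all(weights >= 0), sum(weights) > 0, total >= 0)
  shares <- weights / sum(weights) * total
  base <- floor(shares)
  rem <- as.integer(round(total - sum(base)))
  if (rem > 0L) {
    frac <- shares - base
    ## ties broken toward the earlier feature index
    take <- order(-frac, seq_along(frac))[seq_len(rem)]
    base[take] <- base[take] + 1
  }
  as.integer(base)
}

## log-space binomial coefficient ratio choose(a, k) / choose(b, k)
lchoose_ratio <- function(a, k, b) {
  lchoose(a, k) - lchoose(b, k)
}

is_wholenumber <- function(x, tol = 1e-8) {
  is.finite(x) & abs(x - round(x)) < tol
}

abort_data <- function(..., call. = FALSE) {
  stop(..., call. = call.)
}
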