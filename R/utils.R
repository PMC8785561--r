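#' @keywords internal
"_PACKAGE"

## Canonical amino-acid alphabet, alphabetical one-letter order. All
## probability vectors in the package are named with and ordered by this.
AMINO_ACIDS <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

GAP_CHAR <- "-"
UNKNOWN_CHAR <- "X"

## Run `expr` under a fixed RNG seed without leaking state into the
## caller's RNG stream (generators take one explicit seed per call).
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("`seed` must be a single integer", call. = FALSE)
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

#' Rank-based separation AUC
#'
#' Probability that a randomly chosen positive score exceeds a randomly
#' chosen negative score (ties count 1/2); equals the area under the ROC
#' curve of the score as a classifier of positive vs negative.
#'
#' @param positive,negative numeric score vectors.
#' @return AUC in \[0, 1\].
#' @export
separation_auc <- function(positive, negative) {
  stopifnot(length(positive) > 0, length(negative) > 0)
  r <- rank(c(positive, negative))
  n1 <- length(positive)
  (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * length(negative))
}

assert_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != floor(x))
    stop(sprintf("`%s` must be an integer >= %d", name, min), call. = FALSE)
  as.integer(x)
}

assert_fraction <- function(x, name, lo = 0, hi = 1, hi_open = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && !is.na(x) && x >= lo &&
    (if (hi_open) x < hi else x <= hi)
  if (!ok) stop(sprintf("`%s` must be in [%g, %g%s", name, lo, hi,
                        if (hi_open) ")" else "]"), call. = FALSE)
  as.numeric(x)
}
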