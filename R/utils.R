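# Internal helpers shared across modules.

#' Round half away from zero
#'
#' Rounding rule used for all trait-abundance allocation: values ending in
#' .5 are rounded away from zero (so 1.75 -> 2, 2.5 -> 3), unlike base R's
#' round-half-to-even. Centralized so the allocation rounding rule can be
#' audited (and swapped) in one place.
#'
#' @param x numeric vector.
#' @return integer-valued numeric vector.
#' @export
#' @examples
#' round_half_away(c(1.75, 5.25, 2.5, -2.5))
round_half_away <- function(x) {
  stopifnot(is.numeric(x))
  sign(x) * floor(abs(x) + 0.5)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`,
# restoring the caller's RNG state afterwards.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

# stop() with call. = FALSE, sprintf-style
abort <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

is_count_vector <- function(x) {
  is.numeric(x) && !anyNA(x) && all(x >= 0) && all(x == floor(x))
}
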