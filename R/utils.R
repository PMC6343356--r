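#' Round half away from zero
#'
#' Report tables in the field round 95.05 to 95.1, not to the even digit as
#' base [round()] does. Internal metric values are kept at full precision;
#' this is applied only when formatting reports.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector rounded half-up (half away from zero).
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Evaluate an expression with a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so generators are deterministic without
#' clobbering the caller's RNG state.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Dice overlap of two logical arrays of equal shape.
#' Dice coefficient between two masks
#' @param a,b logical arrays of identical shape.
#' @return Dice overlap in `[0, 1]`; 1 when both masks are empty.
#' @export
dice <- function(a, b) {
  stopifnot(identical(dim(a), dim(b)))
  sa <- sum(a); sb <- sum(b)
  if (sa + sb == 0) return(1)
  2 * sum(a & b) / (sa + sb)
}
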