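#' @keywords internal
"_PACKAGE"

## NULL coalescing for config handling
`%||%` <- function(a, b) if (is.null(a)) b else a

#' Round half away from zero
#'
#' Base `round()` rounds half to even; group-comparison percentages are
#' conventionally rounded half-up (16.74 -> 17, 5.5 -> 6).
#'
#' @param x numeric vector
#' @param digits integer, decimal places
#' @return rounded numeric vector
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

## Deterministic per-stage sub-seed: a single pipeline seed is expanded with
## one step of the MINSTD linear congruential generator plus the stage index,
## kept inside the 32-bit signed range so set.seed() accepts it.
split_seed <- function(seed, stage_index) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  as.integer((abs(seed) * 48271 + stage_index) %% 2147483647)
}

stopifnot_scalar_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
    stop(sprintf("'%s' must be a single positive finite number", name),
         call. = FALSE)
  invisible(x)
}
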