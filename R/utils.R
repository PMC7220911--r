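# Internal helpers shared across modules.

#' Round half away from zero
#'
#' Deterministic rounding used for all pixel-index arithmetic (notably the
#' OCT-to-a/LCI depth mapping). `round()` in R rounds half to even; boundary
#' mapping instead rounds 0.5 up (and -0.5 down) so mapped intervals are
#' stable under rescaling.
#'
#' @param x numeric vector.
#' @return integer-valued numeric vector.
#' @keywords internal
round_half_away <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

#' Derive a child seed from a master seed
#'
#' Counter scheme used by the pipeline so that every stage and record has its
#' own reproducible stream: `child = (master * 48271 + stage * 1299721 + index)
#' mod (2^31 - 1)`. Stages are identified by small integer codes; the result
#' always fits a 32-bit integer.
#'
#' @param master master seed (integer).
#' @param stage stage code (integer, 0-99).
#' @param index record counter within the stage (integer).
#' @return a single integer seed.
#' @export
derive_seed <- function(master, stage = 0L, index = 0L) {
  m <- 2147483647
  s <- (as.numeric(master) %% m) * 48271 + as.numeric(stage) * 1299721 +
    as.numeric(index) * 7919
  as.integer(s %% m)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_retscat <- function(msg, class) {
  stop(structure(
    class = c(class, "retscat_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

is_count <- function(x, min = 1) {
  is.numeric(x) && length(x) == 1 && is.finite(x) && x >= min && x == floor(x)
}

is_scalar <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x)
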