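`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a reproducible child seed from a master seed
#'
#' A small multiplicative-congruential scramble (Lehmer step modulo the
#' Mersenne prime 2^31 - 1) folds one or more stream identifiers into a
#' master seed. Every source of randomness in the package draws its own
#' child seed this way, so that a single master seed fixes fold assignment,
#' model fits, subsampling and simulation independently of evaluation order.
#'
#' @param seed master seed (integer-like scalar).
#' @param ... integer stream identifiers.
#' @return an integer seed in `[1, 2^31 - 2]`.
#' @export
child_seed <- function(seed, ...) {
  v <- abs(as.numeric(seed)) %% 2147483647
  for (id in c(...)) {
    v <- (v * 48271 + abs(as.numeric(id)) + 1) %% 2147483647
  }
  as.integer(v + 1)
}

stop_if <- function(cond, ...) if (isTRUE(cond)) stop(..., call. = FALSE)
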