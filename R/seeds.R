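#' Derive a reproducible sub-seed from a master seed
#'
#' Counter scheme for parallel-safe fixture generation: sub-seed
#' `(master * 48271 + counter * 16807) mod (2^31 - 1)`, kept strictly inside
#' the 32-bit integer range R requires of `set.seed()`. Distinct counters give
#' distinct sub-seeds for any fixed master seed (both multipliers are units
#' modulo the Mersenne prime 2^31 - 1).
#'
#' @param master integer master seed.
#' @param counter non-negative integer fixture counter.
#' @return an integer seed in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(master, counter = 0L) {
  stopifnot(is.numeric(master), length(master) == 1L, is.finite(master),
            is.numeric(counter), length(counter) == 1L, counter >= 0)
  m <- 2147483647
  s <- ((abs(master) %% m) * 48271 + (counter %% m) * 16807) %% m
  as.integer(if (s == 0) 1 else s)
}
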