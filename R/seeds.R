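#' Derive a child seed from a global seed
#'
#' Every randomized stage of the pipeline takes its own seed so that stages
#' are individually reproducible and mutually independent.  A single global
#' seed is expanded into per-component child seeds by a fixed affine rule on
#' the Mersenne-prime modulus 2^31 - 1:
#'
#' \deqn{child = (seed \cdot 48271 + k \cdot 104729) \bmod (2^{31}-1)}
#'
#' where `k` is the component index.  48271 is the classic minimal-standard
#' LCG multiplier and 104729 an odd prime offset; the arithmetic stays below
#' 2^53 so the computation is exact in doubles, and the result always fits a
#' 32-bit R integer.
#'
#' @param seed integer global seed.
#' @param k integer component index (0, 1, 2, ...).
#' @return an integer seed in `[0, 2^31 - 2]`.
#' @examples
#' split_seed(1L, 0:3)
#' @export
split_seed <- function(seed, k) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed),
            is.numeric(k), all(k >= 0))
  m <- 2147483647
  as.integer(((seed %% m) * 48271 + k * 104729) %% m)
}
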