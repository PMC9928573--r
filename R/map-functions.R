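# Map functions: conversions between recombination fraction and map
# distance.  Kosambi is used for reported map distances (it allows for
# crossover interference); Haldane (no interference) matches the
# simulator's crossover process and is used for conditional genotype
# probabilities in interval mapping.

#' Kosambi and Haldane map functions
#'
#' `kosambi_cm(r)` converts a recombination fraction to centimorgans,
#' `d = 25 * ln((1 + 2r) / (1 - 2r))`; `kosambi_r(d)` inverts it,
#' `r = tanh(d / 50) / 2`.  `haldane_cm()` / `haldane_r()` are the
#' no-interference equivalents `d = -50 * ln(1 - 2r)` and
#' `r = (1 - exp(-d / 50)) / 2`.  All are monotone; for every
#' `r` in (0, 0.5), `kosambi_cm(r) < haldane_cm(r)`.
#'
#' @param r recombination fraction(s) in `[0, 0.5)`.
#' @param d map distance(s) in cM, `>= 0`.
#' @return numeric vector of distances (cM) or fractions.
#' @examples
#' kosambi_cm(0.2)            # 21.18 cM
#' kosambi_r(kosambi_cm(0.3)) # 0.3
#' @export
kosambi_cm <- function(r) {
  if (any(!is.finite(r)) || any(r < 0) || any(r >= 0.5))
    stop("recombination fraction must lie in [0, 0.5)")
  25 * log((1 + 2 * r) / (1 - 2 * r))
}

#' @rdname kosambi_cm
#' @export
kosambi_r <- function(d) {
  if (any(!is.finite(d)) || any(d < 0)) stop("map distance must be >= 0")
  0.5 * tanh(d / 50)
}

#' @rdname kosambi_cm
#' @export
haldane_cm <- function(r) {
  if (any(!is.finite(r)) || any(r < 0) || any(r >= 0.5))
    stop("recombination fraction must lie in [0, 0.5)")
  -50 * log(1 - 2 * r)
}

#' @rdname kosambi_cm
#' @export
haldane_r <- function(d) {
  if (any(!is.finite(d)) || any(d < 0)) stop("map distance must be >= 0")
  0.5 * (1 - exp(-d / 50))
}
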