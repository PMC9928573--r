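# Recombination-fraction estimation for pairs of codominant F2 markers.
#
# For two codominant loci in an F2 the nine observed genotype classes have
# probabilities determined by the recombination fraction r (coupling phase,
# which is known by construction in a DH x DH cross).  Eight classes carry
# a fixed number of recombinant gametes (0, 1 or 2); the double
# heterozygote is a mixture of the parental-type (0 recombinants) and
# double-recombinant (2) configurations, with conditional recombinant
# expectation 2 r^2 / ((1-r)^2 + r^2).  The EM iteration counts expected
# recombinant gametes and divides by twice the number of individuals.
#
# MLOD is the maximized log10 likelihood ratio against free recombination
# (r = 0.5), the linkage support used for grouping.

# counts: list of 9 matrices (or scalars) n_jk, j = genotype at marker A,
# k = at marker B, each in {0,1,2}.  All entries vectorized.
rf_em_core <- function(n00, n01, n02, n10, n11, n12, n20, n21, n22,
                       tol = 1e-12, max_iter = 500) {
  N <- n00 + n01 + n02 + n10 + n11 + n12 + n20 + n21 + n22
  n_par <- n00 + n22              # 0 recombinant gametes
  n_one <- n01 + n10 + n12 + n21  # 1 recombinant gamete
  n_dbl <- n02 + n20              # 2 recombinant gametes
  r <- pmin(pmax((n_one + 2 * n_dbl) / pmax(2 * (N - n11), 1), 1e-6), 0.49)
  for (it in seq_len(max_iter)) {
    w <- 2 * r^2 / ((1 - r)^2 + r^2)   # E[recombinants | double het]
    r_new <- (n_one + 2 * n_dbl + n11 * w) / (2 * N)
    r_new[N == 0] <- 0.5
    if (max(abs(r_new - r)) < tol) { r <- r_new; break }
    r <- r_new
  }
  r <- pmin(pmax(r, 0), 0.5)
  list(r = r, mlod = rf_lod(r, n_par, n_one, n_dbl, n11), n = N)
}

# log10 L(r) / L(0.5) from the collapsed class counts
rf_lod <- function(r, n_par, n_one, n_dbl, n11) {
  term <- function(n, p, p0) ifelse(n > 0, n * (log(p) - log(p0)), 0)
  ll <- term(n_par, (1 - r)^2 / 4, 1 / 16) +
        term(n_one, r * (1 - r) / 2, 1 / 8) +
        term(n_dbl, r^2 / 4, 1 / 16) +
        term(n11, ((1 - r)^2 + r^2) / 2, 1 / 4)
  pmax(ll / log(10), 0)
}

# profile log10-likelihood of r given a single pair's 9 counts (used by the
# tests' grid-search oracle as well as internally)
rf_loglik10 <- function(r, counts9) {
  n_par <- counts9[1] + counts9[9]
  n_one <- counts9[2] + counts9[4] + counts9[6] + counts9[8]
  n_dbl <- counts9[3] + counts9[7]
  n11 <- counts9[5]
  term <- function(n, p) ifelse(n > 0, n * log(p), 0)
  (term(n_par, (1 - r)^2 / 4) + term(n_one, r * (1 - r) / 2) +
     term(n_dbl, r^2 / 4) + term(n11, ((1 - r)^2 + r^2) / 2)) / log(10)
}

#' Estimate the recombination fraction between two F2 markers
#'
#' Maximum-likelihood estimate of the recombination fraction for a pair of
#' codominant markers in an F2, with the double-heterozygote phase mixture
#' handled by expectation-maximization, plus the MLOD linkage support
#' `log10 L(r-hat) / L(0.5)`.  Individuals missing at either marker are
#' ignored.
#'
#' @param g1,g2 integer genotype vectors (0 = aa, 1 = ab, 2 = bb, `NA`)
#'   over the same individuals.
#' @param min_informative pairs with fewer jointly non-missing individuals
#'   than this are flagged unlinked (`r = 0.5`, `MLOD = 0`); default 2 for
#'   the single-pair estimator.
#' @return list with `r`, `mlod`, `n` (informative individuals).
#' @examples
#' g <- rep(c(0L, 1L, 2L), c(25, 50, 25))
#' estimate_rf_em(g, g)   # r = 0, MLOD = 45.15
#' @export
estimate_rf_em <- function(g1, g2, min_informative = 2) {
  stopifnot(length(g1) == length(g2))
  ok <- !is.na(g1) & !is.na(g2)
  if (sum(ok) < min_informative)
    return(list(r = 0.5, mlod = 0, n = sum(ok)))
  counts <- tabulate(g1[ok] * 3L + g2[ok] + 1L, nbins = 9L)
  fit <- rf_em_core(counts[1], counts[2], counts[3], counts[4], counts[5],
                    counts[6], counts[7], counts[8], counts[9])
  list(r = fit$r, mlod = fit$mlod, n = fit$n)
}

#' All pairwise recombination fractions and MLOD supports
#'
#' Vectorized EM over every marker pair of a genotype matrix.  Class
#' counts for all pairs are accumulated with indicator cross-products, and
#' the EM update runs element-wise on whole matrices, so the cost is a few
#' dense matrix multiplications.
#'
#' @param x a [geno_matrix()] or an integer genotype matrix
#'   (markers x individuals).
#' @param min_informative pairs with fewer jointly non-missing individuals
#'   are set unlinked (`r = 0.5`, `MLOD = 0`); default 20, guarding
#'   against spurious linkage from sparse overlap.
#' @return list of symmetric matrices `r`, `mlod`, `n` (marker ids as
#'   dimnames); diagonals are `r = 0`, `mlod = 0`.
#' @export
pairwise_linkage <- function(x, min_informative = 20) {
  g <- if (inherits(x, "geno_matrix")) x$geno else x
  m <- nrow(g)
  ind <- lapply(0:2, function(c) {
    z <- (g == c)
    z[is.na(z)] <- FALSE
    storage.mode(z) <- "double"
    z
  })
  cnt <- vector("list", 9)
  for (j in 0:2) for (k in 0:2)
    cnt[[j * 3 + k + 1]] <- tcrossprod(ind[[j + 1]], ind[[k + 1]])
  fit <- rf_em_core(cnt[[1]], cnt[[2]], cnt[[3]], cnt[[4]], cnt[[5]],
                    cnt[[6]], cnt[[7]], cnt[[8]], cnt[[9]])
  r <- fit$r; mlod <- fit$mlod; n <- fit$n
  sparse <- n < min_informative
  r[sparse] <- 0.5
  mlod[sparse] <- 0
  diag(r) <- 0
  diag(mlod) <- 0
  # enforce exact symmetry (floating accumulation order can differ)
  r <- (r + t(r)) / 2
  mlod <- (mlod + t(mlod)) / 2
  dimnames(r) <- dimnames(mlod) <- dimnames(n) <- list(rownames(g), rownames(g))
  list(r = r, mlod = mlod, n = n)
}
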