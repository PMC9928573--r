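# Marker-level quality control: segregation-pattern classification,
# 1:2:1 distortion testing, and the four-rule filter (SNP count,
# completeness, distortion, parental depth) that turns raw polymorphic
# SLAF genotypes into map-ready aa x bb markers.

#' Classify the segregation pattern of a marker from its parental calls
#'
#' Two-parent diploid loci fall into eight informative segregation
#' patterns (the outcross nomenclature): `ab x cd`, `ef x eg`, `ab x cc`,
#' `cc x ab`, `hk x hk`, `lm x ll`, `nn x np`, and `aa x bb`.  A cross of
#' two homozygous parents carrying different alleles is `aa x bb` — the
#' only pattern usable in a DH x DH F2.  Loci with more than four distinct
#' alleles are flagged `"repetitive"` (multi-copy, discarded upstream);
#' two identical homozygous parents give `"uninformative"`.
#'
#' @param p1,p2 parental genotype calls: either a single allele
#'   (homozygote, e.g. `"A"`), an `"X/Y"` string, or a character vector of
#'   alleles.
#' @return the pattern label as a string.
#' @examples
#' classify_segregation_pattern("A", "G")    # "aaxbb"
#' classify_segregation_pattern("A/G", "A")  # "lmxll"
#' @export
classify_segregation_pattern <- function(p1, p2) {
  parse_call <- function(p) {
    if (length(p) == 1 && grepl("/", p)) p <- strsplit(p, "/")[[1]]
    unique(p)
  }
  a1 <- parse_call(p1)
  a2 <- parse_call(p2)
  if (length(unique(c(a1, a2))) > 4) return("repetitive")
  if (length(a1) > 2 || length(a2) > 2)
    stop("a diploid parental call carries at most two distinct alleles")
  het1 <- length(a1) == 2
  het2 <- length(a2) == 2
  if (!het1 && !het2)
    return(if (a1 == a2) "uninformative" else "aaxbb")
  if (het1 && het2) {
    shared <- length(intersect(a1, a2))
    return(c("abxcd", "efxeg", "hkxhk")[shared + 1L])
  }
  if (het1) return(if (a2 %in% a1) "lmxll" else "abxcc")
  if (a1 %in% a2) "nnxnp" else "ccxab"
}

#' Chi-square test of 1:2:1 F2 segregation
#'
#' Pearson chi-square of the genotype counts (aa, ab, bb) against the
#' Mendelian 1:2:1 expectation, df = 2, upper-tail p-value.
#'
#' @param counts numeric vector `c(n_aa, n_ab, n_bb)`.
#' @return list with `statistic` and `p_value`.
#' @examples
#' segregation_chi2(c(75, 166, 80))  # statistic 0.533, p 0.766
#' @export
segregation_chi2 <- function(counts) {
  if (length(counts) != 3 || any(counts < 0) || any(!is.finite(counts)))
    stop("counts must be three non-negative numbers")
  n <- sum(counts)
  if (n == 0) stop("total count must be > 0")
  expected <- n * c(0.25, 0.5, 0.25)
  stat <- sum((counts - expected)^2 / expected)
  list(statistic = stat, p_value = pchisq(stat, df = 2, lower.tail = FALSE))
}

#' Default marker-filter thresholds
#'
#' The four rules of the QC filter with their study defaults: markers fail
#' if they carry more than 5 SNPs, are complete in fewer than 70% of
#' progeny, show significant segregation distortion at alpha = 0.05, or
#' have either parent sequenced below 10x.
#'
#' @param max_snps maximum SNPs per SLAF tag (default 5).
#' @param min_complete minimum non-missing fraction across progeny
#'   (default 0.70).
#' @param alpha distortion significance level (default 0.05; no
#'   multiple-testing correction, per-marker threshold).
#' @param min_depth minimum parental fold-coverage (default 10).
#' @return a named list of thresholds.
#' @export
qc_thresholds <- function(max_snps = 5, min_complete = 0.7, alpha = 0.05,
                          min_depth = 10) {
  stopifnot(max_snps >= 1, min_complete >= 0, min_complete <= 1,
            alpha > 0, alpha < 1, min_depth >= 0)
  list(max_snps = max_snps, min_complete = min_complete, alpha = alpha,
       min_depth = min_depth)
}

#' Apply the four-rule filter to one marker
#'
#' Rules are evaluated in the fixed order snp_count, completeness,
#' distortion, depth, and the first failing rule is recorded as the
#' reason, so reports are reproducible.  An all-missing marker fails
#' completeness.
#'
#' @param genotypes integer genotype vector (0/1/2/NA) across progeny.
#' @param snp_count,depth_p1,depth_p2 marker metadata; `NA` metadata
#'   passes the corresponding rule.
#' @param thresholds a [qc_thresholds()] list.
#' @return list with `pass` (logical) and `reason` (`NA` or one of
#'   `"snp_count"`, `"completeness"`, `"distortion"`, `"depth"`).
#' @export
filter_marker <- function(genotypes, snp_count = NA, depth_p1 = NA,
                          depth_p2 = NA, thresholds = qc_thresholds()) {
  if (!is.na(snp_count) && snp_count > thresholds$max_snps)
    return(list(pass = FALSE, reason = "snp_count"))
  if (mean(!is.na(genotypes)) < thresholds$min_complete)
    return(list(pass = FALSE, reason = "completeness"))
  counts <- tabulate(genotypes + 1L, nbins = 3L)
  if (sum(counts) > 0 &&
      segregation_chi2(counts)$p_value < thresholds$alpha)
    return(list(pass = FALSE, reason = "distortion"))
  if (!is.na(depth_p1) && !is.na(depth_p2) &&
      min(depth_p1, depth_p2) < thresholds$min_depth)
    return(list(pass = FALSE, reason = "depth"))
  list(pass = TRUE, reason = NA_character_)
}

#' Run marker QC over a genotype matrix
#'
#' Markers whose parental calls are not the `aa x bb` pattern are excluded
#' first (reason `"pattern"`); the rest pass through [filter_marker()].
#' The report accounts for every input marker exactly once.
#'
#' @param x a [geno_matrix()]; metadata columns `allele_p1` / `allele_p2`
#'   (pattern), `snp_count`, `depth_p1`, `depth_p2` are used when present.
#' @param thresholds a [qc_thresholds()] list.
#' @return list with `matrix` (retained [geno_matrix()]), `report` (data
#'   frame `marker_id`, `pass`, `reason`), and `counts` (named vector of
#'   per-reason failures plus `retained`).
#' @export
run_qc <- function(x, thresholds = qc_thresholds()) {
  stopifnot(inherits(x, "geno_matrix"))
  m <- nrow(x$geno)
  if (m == 0) {
    warning("empty genotype matrix; nothing to filter")
    return(list(matrix = x,
                report = data.frame(marker_id = character(0),
                                    pass = logical(0), reason = character(0)),
                counts = c(retained = 0)))
  }
  info <- x$info
  meta <- function(col) if (col %in% names(info)) info[[col]] else rep(NA, m)
  a1 <- meta("allele_p1"); a2 <- meta("allele_p2")
  snp <- meta("snp_count"); d1 <- meta("depth_p1"); d2 <- meta("depth_p2")
  pass <- logical(m)
  reason <- rep(NA_character_, m)
  for (i in seq_len(m)) {
    if (!is.na(a1[i]) && !is.na(a2[i]) &&
        classify_segregation_pattern(a1[i], a2[i]) != "aaxbb") {
      reason[i] <- "pattern"
      next
    }
    f <- filter_marker(x$geno[i, ], snp[i], d1[i], d2[i], thresholds)
    pass[i] <- f$pass
    reason[i] <- f$reason
  }
  report <- data.frame(marker_id = rownames(x$geno), pass = pass,
                       reason = reason, stringsAsFactors = FALSE)
  reasons <- c("pattern", "snp_count", "completeness", "distortion", "depth")
  counts <- c(vapply(reasons, function(rr) sum(reason == rr, na.rm = TRUE),
                     numeric(1)),
              retained = sum(pass))
  list(matrix = subset_markers(x, which(pass)), report = report,
       counts = counts)
}
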