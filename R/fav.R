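# Favorable-allelic-variant (FAV) analysis: since heterozygote advantage
# (heterosis) should enrich heterozygotes among the tallest individuals,
# candidate markers from QTL intervals are scored by the proportion of
# heterozygous carriers in each phenotype bin; markers whose proportion
# rises with the phenotype are flagged "effective" FAVs, and individuals
# are scored by how many effective FAVs they carry heterozygously.

#' Bin a continuous phenotype into fixed-width half-open intervals
#'
#' Bins are `(anchor + k*width, anchor + (k+1)*width]`; with the defaults
#' (width 10 cm anchored at 90 cm) a value of exactly 100 falls in
#' (90, 100].  Bins cover the full observed range, so every individual
#' lands in exactly one bin.
#'
#' @param phenotype data frame with `individual_id` and the trait column,
#'   or a named numeric vector.
#' @param trait trait column name (default `"fsh_cm"`).
#' @param width bin width (default 10).
#' @param anchor left edge of the reference bin (default 90).
#' @return object of class `pheno_bins`: list with `edges` (data frame
#'   `lower`, `upper`, `mid`), `bin` (per-individual bin index),
#'   `individuals` (list of id vectors per bin), `counts`.
#' @export
bin_phenotype <- function(phenotype, trait = "fsh_cm", width = 10,
                          anchor = 90) {
  if (width <= 0) stop("bin width must be > 0")
  if (is.data.frame(phenotype)) {
    v <- setNames(phenotype[[trait]], phenotype$individual_id)
  } else v <- phenotype
  stopifnot(is.numeric(v), all(is.finite(v)))
  k <- ceiling((v - anchor) / width - 1e-9)
  ks <- seq(min(k), max(k))
  edges <- data.frame(lower = anchor + (ks - 1) * width,
                      upper = anchor + ks * width)
  edges$mid <- (edges$lower + edges$upper) / 2
  bin <- match(k, ks)
  ids <- names(v)
  if (is.null(ids)) ids <- as.character(seq_along(v))
  individuals <- lapply(seq_along(ks), function(b) ids[bin == b])
  structure(list(edges = edges, bin = setNames(bin, ids),
                 individuals = individuals,
                 counts = lengths(individuals)),
            class = "pheno_bins")
}

#' @export
print.pheno_bins <- function(x, ...) {
  df <- cbind(x$edges, count = x$counts,
              pct = round(100 * x$counts / sum(x$counts)))
  print(df, row.names = FALSE)
  invisible(x)
}

#' Heterozygote proportion of a marker within each phenotype bin
#'
#' For each bin, the number of its individuals heterozygous at the marker
#' divided by the bin size.  By default individuals missing at the marker
#' stay in the denominator (fixed printed bin sizes); set
#' `informative_only = TRUE` to divide by the genotyped count instead.
#' Empty bins give `NA`.
#'
#' @param x a [geno_matrix()] (or integer genotype matrix with marker row
#'   names and individual column names).
#' @param marker marker id.
#' @param bins a [bin_phenotype()] result.
#' @param informative_only denominator choice (default `FALSE`).
#' @return numeric vector, one proportion per bin.
#' @export
het_proportion_per_bin <- function(x, marker, bins,
                                   informative_only = FALSE) {
  g <- if (inherits(x, "geno_matrix")) x$geno else x
  stopifnot(inherits(bins, "pheno_bins"), marker %in% rownames(g))
  row <- g[marker, ]
  vapply(bins$individuals, function(ids) {
    if (length(ids) == 0) return(NA_real_)
    calls <- row[ids]
    denom <- if (informative_only) sum(!is.na(calls)) else length(ids)
    if (denom == 0) return(NA_real_)
    sum(calls == 1L, na.rm = TRUE) / denom
  }, numeric(1))
}

#' Trend of heterozygote proportion across phenotype bins
#'
#' Pearson correlation of bin midpoints against per-bin proportions.
#' Needs at least 3 non-missing bins; constant proportions return 0 by
#' convention (flagged by attribute `"constant"`).
#'
#' @param proportions per-bin proportions (`NA` allowed).
#' @param midpoints bin midpoints (same length).
#' @return correlation in `[-1, 1]`.
#' @export
trend_statistic <- function(proportions, midpoints) {
  stopifnot(length(proportions) == length(midpoints))
  ok <- !is.na(proportions) & !is.na(midpoints)
  if (sum(ok) < 3) stop("need at least 3 non-missing bins for a trend")
  if (sd(proportions[ok]) == 0)
    return(structure(0, constant = TRUE))
  cor(midpoints[ok], proportions[ok])
}

#' Flag effective FAV markers
#'
#' A candidate is flagged effective when its trend correlation is at least
#' `trend_min` **and** (optionally) its proportion in the highest bin
#' exceeds that in the lowest.  Both ranking measures — the unweighted
#' mean of the per-bin proportions and the heterozygote fraction over the
#' whole population — are computed for every candidate regardless of flag.
#'
#' @param prop_matrix candidates x bins matrix of proportions.
#' @param midpoints bin midpoints.
#' @param total_prop per-candidate heterozygote fraction over the full
#'   population.
#' @param trend_min minimum trend correlation (default 0.5).
#' @param require_top_gt_bottom require top-bin > bottom-bin proportion
#'   (default `TRUE`).
#' @return data frame `marker_id`, `trend`, `avg_prop`, `total_prop`,
#'   `effective`.
#' @export
select_effective_favs <- function(prop_matrix, midpoints, total_prop,
                                  trend_min = 0.5,
                                  require_top_gt_bottom = TRUE) {
  stopifnot(nrow(prop_matrix) >= 1)
  trend <- apply(prop_matrix, 1, trend_statistic, midpoints = midpoints)
  first_last <- t(apply(prop_matrix, 1, function(p) {
    ok <- which(!is.na(p))
    c(p[ok[1]], p[ok[length(ok)]])
  }))
  eff <- trend >= trend_min
  if (require_top_gt_bottom) eff <- eff & first_last[, 2] > first_last[, 1]
  data.frame(marker_id = rownames(prop_matrix),
             trend = as.numeric(trend),
             avg_prop = rowMeans(prop_matrix, na.rm = TRUE),
             total_prop = total_prop,
             effective = eff,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Per-individual effective-FAV load in a designated bin
#'
#' For each individual of the designated bin (default the top bin), the
#' number of effective markers at which it is heterozygous, plus the
#' fraction of those individuals carrying more than half of the effective
#' markers.
#'
#' @param x a [geno_matrix()] or integer genotype matrix.
#' @param effective_markers character vector of flagged marker ids.
#' @param bins a [bin_phenotype()] result.
#' @param bin_index which bin (default: the top one).
#' @return list with `load` (named integer vector), `n_effective`, and
#'   `frac_above_half`.
#' @export
individual_fav_load <- function(x, effective_markers, bins,
                                bin_index = NULL) {
  g <- if (inherits(x, "geno_matrix")) x$geno else x
  stopifnot(length(effective_markers) > 0,
            all(effective_markers %in% rownames(g)))
  if (is.null(bin_index)) bin_index <- length(bins$individuals)
  ids <- bins$individuals[[bin_index]]
  sub <- g[effective_markers, ids, drop = FALSE] == 1L
  load <- colSums(sub, na.rm = TRUE)
  list(load = load, n_effective = length(effective_markers),
       frac_above_half = mean(load > length(effective_markers) / 2))
}

#' Full FAV report for a candidate marker set
#'
#' Bins the phenotype, computes every candidate's per-bin heterozygote
#' proportions, trend statistic, ranking measures and effectiveness flag,
#' and the per-individual load in the top bin.
#'
#' @param x a [geno_matrix()] covering the candidates.
#' @param phenotype data frame with `individual_id` and the trait column.
#' @param candidates character vector of candidate marker ids (typically
#'   the mapped markers inside declared QTL intervals).
#' @param trait,width,anchor see [bin_phenotype()].
#' @param min_bin_count bins holding fewer individuals than this are
#'   reported `NA` and excluded from trends and averages (default 10):
#'   a heterozygote proportion over a handful of plants is noise, and the
#'   reference procedure's smallest bin held 11 individuals.
#' @param trend_min,require_top_gt_bottom see [select_effective_favs()].
#' @param informative_only see [het_proportion_per_bin()].
#' @return object of class `fav_report`: list with `bins`, `proportions`
#'   (matrix), `table` (per-candidate data frame), `effective` (flagged
#'   ids), `load` (see [individual_fav_load()]; `NULL` when nothing is
#'   flagged).
#' @export
fav_report <- function(x, phenotype, candidates, trait = "fsh_cm",
                       width = 10, anchor = 90, min_bin_count = 10,
                       trend_min = 0.5, require_top_gt_bottom = TRUE,
                       informative_only = FALSE) {
  g <- if (inherits(x, "geno_matrix")) x$geno else x
  if (length(candidates) == 0) stop("candidate set is empty")
  stopifnot(all(candidates %in% rownames(g)))
  bins <- bin_phenotype(phenotype, trait = trait, width = width,
                        anchor = anchor)
  prop <- t(vapply(candidates, function(mk)
    het_proportion_per_bin(g, mk, bins, informative_only = informative_only),
    numeric(length(bins$counts))))
  if (!is.matrix(prop)) prop <- matrix(prop, nrow = length(candidates))
  prop[, bins$counts < min_bin_count] <- NA_real_
  rownames(prop) <- candidates
  pop_ids <- names(bins$bin)
  total_prop <- vapply(candidates, function(mk) {
    calls <- g[mk, pop_ids]
    denom <- if (informative_only) sum(!is.na(calls)) else length(calls)
    sum(calls == 1L, na.rm = TRUE) / denom
  }, numeric(1))
  tab <- select_effective_favs(prop, bins$edges$mid, total_prop,
                               trend_min = trend_min,
                               require_top_gt_bottom = require_top_gt_bottom)
  eff <- tab$marker_id[tab$effective]
  top_bin <- max(which(bins$counts >= min_bin_count))
  load <- if (length(eff))
    individual_fav_load(g, eff, bins, bin_index = top_bin) else NULL
  structure(list(bins = bins, proportions = prop, table = tab,
                 effective = eff, load = load),
            class = "fav_report")
}

#' @export
print.fav_report <- function(x, ...) {
  cat(sprintf("fav_report: %d candidates, %d effective FAVs\n",
              nrow(x$table), length(x$effective)))
  if (!is.null(x$load))
    cat(sprintf("  top bin: %d individuals, %.0f%% carry > half the effective markers\n",
                length(x$load$load), 100 * x$load$frac_above_half))
  invisible(x)
}
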