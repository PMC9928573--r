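# Published summary statistics of the onion DH-1 x DH-17 F2 SLAF mapping
# study that this package's defaults emulate.  These tables are inputs for
# consistency checks (column totals, bin accounting, trend recomputation),
# not outputs of the package.

#' Reference per-linkage-group map summary (onion DH F2 study)
#'
#' Marker/SNP counts, total distance, average adjacent distance, fraction
#' of gaps <= 5 cM and maximum gap for each of the 8 linkage groups of the
#' published high-resolution onion map.  Feed to [overall_map_stats()] to
#' recompute the study-wide figures (10,584 SLAFs, 21,250 SNPs, 928.32 cM,
#' mean group length 116.04 cM, mean adjacent interval 0.09 cM, mean max
#' gap 2.91 cM).
#'
#' @return data frame, one row per linkage group.
#' @export
onion_ref_map_summary <- function() {
  data.frame(
    lg = 1:8,
    n_markers = c(1185L, 1704L, 1689L, 1425L, 1209L, 198L, 1500L, 1674L),
    n_snp = c(2336L, 3396L, 3369L, 2922L, 2368L, 352L, 3059L, 3448L),
    total_dis_cM = c(115.29, 131.33, 140.43, 102.40, 100.99, 103.59,
                     96.24, 138.05),
    avg_dis_cM = c(0.10, 0.08, 0.08, 0.07, 0.08, 0.53, 0.06, 0.08),
    gaps_le_5 = c(1, 0.9994, 1, 1, 1, 1, 1, 1),
    max_gap_cM = c(3.60, 6.27, 2.18, 2.92, 1.35, 2.59, 2.12, 2.27))
}

#' Reference flower-stalk-height QTL table (onion DH F2 study)
#'
#' The four published FSH QTLs with interval, shared threshold LOD, peak
#' LOD, SLAF-marker count, additive and dominance effects and PVE.
#'
#' @return data frame, one row per QTL.
#' @export
onion_ref_qtl_table <- function() {
  data.frame(
    qtl = c("qtl-FSH2.1", "qtl-FSH2.2", "qtl-FSH5.1", "qtl-FSH8.1"),
    lg = c(2L, 2L, 5L, 8L),
    start_cM = c(59.82, 64.11, 42.16, 66.01),
    end_cM = c(59.83, 64.27, 42.90, 66.60),
    interval_cM = c(0, 0.15, 0.74, 0.59),
    lod_threshold = c(5.15, 5.15, 5.15, 5.15),
    max_lod = c(5.55, 5.55, 5.94, 6.48),
    n_slaf = c(5L, 10L, 17L, 17L),
    add = c(2.80, 2.86, -2.99, 3.00),
    dom = c(2.98, 2.48, 0.83, 1.60),
    pve = c(7.19, 6.65, 6.45, 6.28))
}

#' Reference effective-FAV heterozygote proportions (onion DH F2 study)
#'
#' The 20 markers flagged as effective favorable allelic variants, with
#' the published heterozygote proportions in the five 10-cm flower-stalk
#' height bins (90,100], (100,110], (110,120], (120,130], (130,140].
#'
#' @return data frame: `lg`, `marker_id`, then `p_90_100` .. `p_130_140`.
#' @export
onion_ref_fav_proportions <- function() {
  m <- rbind(
    c(0.27, 0.33, 0.42, 0.47, 0.47), c(0.27, 0.33, 0.38, 0.44, 0.35),
    c(0.27, 0.25, 0.39, 0.53, 0.53), c(0.36, 0.37, 0.43, 0.43, 0.65),
    c(0.27, 0.39, 0.46, 0.47, 0.53), c(0.27, 0.39, 0.42, 0.47, 0.65),
    c(0.27, 0.35, 0.46, 0.46, 0.59), c(0.18, 0.29, 0.43, 0.41, 0.47),
    c(0.27, 0.33, 0.41, 0.44, 0.65), c(0.27, 0.39, 0.47, 0.56, 0.59),
    c(0.27, 0.39, 0.45, 0.44, 0.47), c(0.27, 0.37, 0.42, 0.52, 0.65),
    c(0.18, 0.37, 0.43, 0.49, 0.65), c(0.18, 0.35, 0.46, 0.43, 0.53),
    c(0.27, 0.39, 0.43, 0.54, 0.65), c(0.27, 0.39, 0.42, 0.48, 0.59),
    c(0.27, 0.41, 0.44, 0.51, 0.65), c(0.27, 0.41, 0.47, 0.52, 0.65),
    c(0.36, 0.41, 0.49, 0.54, 0.65), c(0.18, 0.35, 0.38, 0.48, 0.53))
  colnames(m) <- c("p_90_100", "p_100_110", "p_110_120", "p_120_130",
                   "p_130_140")
  cbind(
    data.frame(
      lg = c(2L, 2L, 2L, rep(8L, 17L)),
      marker_id = c("Marker150989", "Marker285135", "Marker226058",
                    "Marker105154", "Marker99568", "Marker68370",
                    "Marker99657", "Marker194036", "Marker110725",
                    "Marker36724", "Marker60226", "Marker50587",
                    "Marker138614", "Marker76340", "Marker70349",
                    "Marker131660", "Marker76408", "Marker34305",
                    "Marker55369", "Marker150308"),
      stringsAsFactors = FALSE),
    as.data.frame(m))
}

#' Reference per-marker QTL statistics for the 20 effective FAVs
#'
#' Map position, SNP count, LOD, additive/dominance effect and PVE of each
#' effective FAV marker; marker rows share the statistics of their QTL
#' sub-region (three regions: LG2 at 59.822 cM, LG2 at 64.263 cM, LG8 at
#' 66.0-66.6 cM).
#'
#' @return data frame, one row per marker.
#' @export
onion_ref_fav_markers <- function() {
  data.frame(
    lg = c(2L, 2L, 2L, rep(8L, 17L)),
    pos_cM = c(59.822, 64.263, 64.263, rep(66.010, 5), 66.157,
               rep(66.304, 10), 66.598),
    marker_id = c("Marker150989", "Marker285135", "Marker226058",
                  "Marker105154", "Marker99568", "Marker68370",
                  "Marker99657", "Marker194036", "Marker110725",
                  "Marker36724", "Marker60226", "Marker50587",
                  "Marker138614", "Marker76340", "Marker70349",
                  "Marker131660", "Marker76408", "Marker34305",
                  "Marker55369", "Marker150308"),
    n_snp = c(1L, 2L, 4L, 2L, 3L, 1L, 2L, 3L, 1L, 2L, 1L, 2L, 2L, 2L,
              5L, 5L, 1L, 2L, 3L, 3L),
    lod = c(5.55, 5.17, 5.17, rep(6.42, 5), 6.38, rep(6.48, 10), 5.40),
    add = c(2.80, 2.83, 2.83, rep(2.91, 5), 2.90, rep(3.00, 10), 2.63),
    dom = c(2.98, 2.39, 2.39, rep(1.75, 5), 1.77, rep(1.60, 10), 1.85),
    pve = c(7.19, 6.43, 6.43, rep(6.07, 5), 6.08, rep(6.28, 10), 5.17),
    stringsAsFactors = FALSE)
}

#' Reference population-level counts (onion DH F2 study)
#'
#' Tag and segregation accounting of the reference study: total and
#' polymorphic SLAF tags, encoded tags, aa x bb tags, flower-stalk-height
#' bin counts (10-cm bins from 90 cm), fertility class counts, and the
#' restorer-locus genotype counts.
#'
#' @return named list.
#' @export
onion_ref_counts <- function() {
  list(total_slaf = 692676, polymorphic_slaf = 155067,
       encoded_slaf = 93539, aabb_slaf = 77766,
       fsh_bin_counts = c(`(90,100]` = 11, `(100,110]` = 51,
                          `(110,120]` = 125, `(120,130]` = 117,
                          `(130,140]` = 17),
       fertility = c(fertile = 241, sterile = 81),
       ms_genotypes = c(MsMs = 75, Msms = 166, msms = 80))
}
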