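# End-to-end driver: configuration with study defaults, staged execution
# (simulate -> qc -> map -> scan -> fav), TSV/JSON artifacts, a run
# manifest sufficient to replay the run, and plain-text report rendering.

#' Pipeline configuration with study defaults
#'
#' Every parameter defaults to the reference study's stated value where
#' one exists: QC max 5 SNPs / completeness 0.70 / distortion alpha 0.05 /
#' parental depth 10x; MLOD 5 with 8 expected groups; 1000 permutations
#' with the 0.99/0.95/0.90 confidence ladder and 3.0/2.5/2.0 manual
#' fallback; 10-cm phenotype bins anchored at 90 cm.
#'
#' @param ... overrides for any default field.
#' @return a validated `pipeline_config` list.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    seed = 1L,
    # simulation stage
    n_individuals = 321, n_groups = 8, markers_per_group = 100,
    group_lengths = c(115.29, 131.33, 140.43, 102.40, 100.99, 103.59,
                      96.24, 138.05),
    missing_rate = 0.04, error_rate = 0.005,
    ms_group = 8, ms_pos = 85.1,
    # qc stage
    max_snps = 5, min_complete = 0.7, alpha = 0.05, min_depth = 10,
    # map stage
    mlod = 5, knn = 5, smooth_window = 5, order_window = Inf,
    # scan stage
    step = 1, n_perm = 1000, max_cofactors = 5, exclusion_window = 10,
    # fav stage
    bin_width = 10, bin_anchor = 90, trend_min = 0.5)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown))
    stop("unknown config fields: ", paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  validate_config(cfg)
  structure(cfg, class = "pipeline_config")
}

validate_config <- function(cfg) {
  chk <- function(ok, msg) if (!ok) stop("invalid config: ", msg, call. = FALSE)
  chk(cfg$n_individuals >= 2, "n_individuals must be >= 2")
  chk(cfg$n_groups >= 1, "n_groups must be >= 1")
  chk(all(cfg$markers_per_group >= 1), "markers_per_group must be >= 1")
  chk(all(is.finite(cfg$group_lengths)) && all(cfg$group_lengths >= 0),
      "group_lengths must be finite and >= 0")
  chk(cfg$missing_rate >= 0 && cfg$missing_rate <= 1, "missing_rate in [0,1]")
  chk(cfg$error_rate >= 0 && cfg$error_rate <= 1, "error_rate in [0,1]")
  chk(cfg$max_snps >= 1, "max_snps must be >= 1")
  chk(cfg$min_complete >= 0 && cfg$min_complete <= 1, "min_complete in [0,1]")
  chk(cfg$alpha > 0 && cfg$alpha < 1, "alpha in (0,1)")
  chk(cfg$min_depth >= 0, "min_depth must be >= 0")
  chk(cfg$mlod > 0, "mlod must be > 0")
  chk(cfg$ms_group >= 1 && cfg$ms_group <= cfg$n_groups,
      "ms_group must index a simulated group")
  chk(cfg$step > 0, "step must be > 0")
  chk(cfg$n_perm >= 1, "n_perm must be >= 1")
  chk(cfg$bin_width > 0, "bin_width must be > 0")
  invisible(cfg)
}

#' Run the full pipeline
#'
#' Stages execute in order simulate -> qc -> map -> scan (flower stalk
#' height, then fertility as a 0/1 trait) -> fav; every artifact is
#' written under `out_dir` in the package's TSV schemas, together with a
#' JSON manifest (config, seeds, stage row counts, package version) that
#' fully determines the outputs.  Supplying `genotypes` and `phenotypes`
#' skips the simulation stage (real-data mode).
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if needed).
#' @param genotypes optional observed [geno_matrix()] (skips simulation).
#' @param phenotypes optional phenotype data frame (`individual_id`,
#'   `fsh_cm`, `fertility`).
#' @return invisibly, a list with all stage objects (`observed`, `qc`,
#'   `map`, `scan_fsh`, `qtls_fsh`, `scan_fert`, `qtls_fert`, `fav`,
#'   `manifest`).
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir,
                         genotypes = NULL, phenotypes = NULL) {
  validate_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  counts <- list()
  art <- function(name) file.path(out_dir, name)

  if (is.null(genotypes)) {
    # default trait architecture, restricted to the simulated groups
    tm0 <- trait_model()
    on_map <- tm0$qtls$lg <= config$n_groups
    sim <- simulate_study(
      design = cross_design(n_individuals = config$n_individuals,
                            n_linkage_groups = config$n_groups,
                            markers_per_group = config$markers_per_group,
                            group_lengths = config$group_lengths),
      trait = trait_model(qtls = tm0$qtls[on_map, , drop = FALSE],
                          target_pve = c(7.19, 6.65, 6.45, 6.28)[on_map]),
      obs = observation_model(missing_rate = config$missing_rate,
                              genotype_error_rate = config$error_rate),
      ms_group = config$ms_group, ms_pos = config$ms_pos,
      seed = config$seed)
    genotypes <- sim$observed
    phenotypes <- sim$pheno
    write_genotype_tsv(sim$truth, art("genotypes_truth.tsv"))
    write_genotype_tsv(genotypes, art("genotypes_observed.tsv"))
    write_phenotype_tsv(phenotypes, art("phenotypes.tsv"))
  }
  if (is.null(phenotypes)) stop("phenotypes required in real-data mode")
  counts$markers_in <- nrow(genotypes$geno)
  counts$individuals <- ncol(genotypes$geno)

  qc <- run_qc(genotypes, qc_thresholds(config$max_snps, config$min_complete,
                                        config$alpha, config$min_depth))
  write.table(qc$report, art("qc_report.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE, na = ".")
  jsonlite::write_json(as.list(qc$counts), art("qc_summary.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  write_genotype_tsv(qc$matrix, art("genotypes_qc.tsv"))
  counts$markers_qc <- nrow(qc$matrix$geno)

  map <- build_genetic_map(qc$matrix, mlod_threshold = config$mlod,
                           expected_groups = config$n_groups,
                           knn_k = config$knn,
                           smooth_window = config$smooth_window,
                           order_window = config$order_window)
  map_df <- do.call(rbind, lapply(seq_along(map$groups), function(gi)
    data.frame(marker_id = map$groups[[gi]]$marker_id, lg = gi,
               order_index = seq_len(nrow(map$groups[[gi]])),
               position_cM = map$groups[[gi]]$position_cM)))
  write.table(map_df, art("map.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  msum <- map_summary(map)
  write.table(msum, art("map_summary.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE, na = ".")
  counts$linkage_groups <- length(map$groups)

  pol <- threshold_policy(n_permutations = config$n_perm,
                          seed = split_seed(config$seed, 10L))
  y_fsh <- setNames(phenotypes$fsh_cm, phenotypes$individual_id)
  cof <- select_cofactors(map, y_fsh, max_cofactors = config$max_cofactors)
  scan_fsh <- scan_trait(map, y_fsh, cofactors = cof, step = config$step,
                         exclusion_window = config$exclusion_window)
  perm_fsh <- permutation_threshold(scan_fsh, pol)
  dec_fsh <- declare_with_ladder(scan_fsh, perm_fsh, pol, map = map,
                                 trait_name = "FSH")
  write.table(scan_fsh$grid, art("scan_fsh.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write_qtl_tsv(dec_fsh$qtls, art("qtl_fsh.tsv"))

  y_fert <- setNames(as.numeric(phenotypes$fertility == "fertile"),
                     phenotypes$individual_id)
  scan_fert <- scan_trait(map, y_fert, cofactors = NULL, step = config$step)
  perm_fert <- permutation_threshold(scan_fert, pol)
  dec_fert <- declare_with_ladder(scan_fert, perm_fert, pol, map = map,
                                  trait_name = "MS")
  write.table(scan_fert$grid, art("scan_fertility.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write_qtl_tsv(dec_fert$qtls, art("qtl_fertility.tsv"))
  counts$qtls_fsh <- nrow(dec_fsh$qtls)
  counts$qtls_fertility <- nrow(dec_fert$qtls)

  fav <- NULL
  candidates <- unique(unlist(dec_fsh$qtls$markers))
  if (length(candidates) > 0) {
    fav <- fav_report(map$geno, phenotypes, candidates,
                      width = config$bin_width, anchor = config$bin_anchor,
                      trend_min = config$trend_min)
    fav_tab <- cbind(fav$table,
                     as.data.frame(fav$proportions,
                                   row.names = NULL))
    write.table(fav_tab, art("fav_report.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    if (!is.null(fav$load))
      write.table(data.frame(individual_id = names(fav$load$load),
                             fav_load = as.integer(fav$load$load)),
                  art("fav_load.tsv"), sep = "\t", quote = FALSE,
                  row.names = FALSE)
    counts$fav_candidates <- length(candidates)
    counts$fav_effective <- length(fav$effective)
  }

  manifest <- list(
    package = "slafmap",
    version = as.character(utils::packageVersion("slafmap")),
    config = unclass(config),
    seeds = list(global = config$seed,
                 simulate = split_seed(config$seed, 0L),
                 observation = split_seed(config$seed, 1L),
                 phenotype = split_seed(config$seed, 2L),
                 permutation = split_seed(config$seed, 10L)),
    counts = counts,
    thresholds = list(fsh = list(rung = dec_fsh$rung,
                                 threshold = dec_fsh$threshold),
                      fertility = list(rung = dec_fert$rung,
                                       threshold = dec_fert$threshold)))
  jsonlite::write_json(manifest, art("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)

  report <- render_report(msum, dec_fsh$qtls,
                          if (!is.null(fav)) fav else NULL)
  writeLines(report, art("report.txt"))

  invisible(list(observed = genotypes, pheno = phenotypes, qc = qc,
                 map = map, scan_fsh = scan_fsh, qtls_fsh = dec_fsh$qtls,
                 scan_fert = scan_fert, qtls_fert = dec_fert$qtls,
                 fav = fav, manifest = manifest))
}

write_qtl_tsv <- function(qtls, path) {
  flat <- qtls
  flat$markers <- vapply(qtls$markers, paste, character(1), collapse = ",")
  write.table(flat, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

fmt_row <- function(...) paste(..., sep = "\t")

#' Render a plain-text summary report
#'
#' Map, QTL and FAV tables in the layout of the study's published
#' summaries; totals rows are recomputed from the body rows, never
#' copied.  Missing artifacts produce a notice instead of a section.
#'
#' @param map_summary per-group map summary data frame (or `NULL`).
#' @param qtls declared QTL data frame (or `NULL`).
#' @param fav a `fav_report` (or `NULL`).
#' @return character vector of report lines.
#' @export
render_report <- function(map_summary = NULL, qtls = NULL, fav = NULL) {
  out <- character(0)
  push <- function(...) out <<- c(out, ...)
  push("== Genetic map ==")
  if (is.null(map_summary)) {
    push("  (no map artifact)")
  } else {
    push(fmt_row("LG", "Markers", "SNPs", "Total_cM", "Avg_cM",
                 "GapsLE5", "MaxGap_cM"))
    for (i in seq_len(nrow(map_summary)))
      push(fmt_row(map_summary$lg[i], map_summary$n_markers[i],
                   map_summary$n_snp[i],
                   sprintf("%.2f", map_summary$total_dis_cM[i]),
                   sprintf("%.2f", map_summary$avg_dis_cM[i]),
                   sprintf("%.2f%%", 100 * map_summary$gaps_le_5[i]),
                   sprintf("%.2f", map_summary$max_gap_cM[i])))
    ov <- overall_map_stats(map_summary)
    push(fmt_row("Total", ov$total_markers, ov$total_snp,
                 sprintf("%.2f", ov$total_dis_cM),
                 sprintf("%.2f", ov$mean_interval_cM), "",
                 sprintf("%.2f", ov$mean_max_gap_cM)))
  }
  push("", "== QTLs ==")
  if (is.null(qtls)) {
    push("  (no scan artifact)")
  } else if (nrow(qtls) == 0) {
    push("  no QTL declared")
  } else {
    push(fmt_row("QTL", "LG", "Pos_cM", "Interval_cM", "MaxLOD", "SLAF",
                 "ADD", "DOM", "PVE%"))
    for (i in seq_len(nrow(qtls)))
      push(fmt_row(qtls$qtl[i], qtls$lg[i],
                   sprintf("%.2f-%.2f", qtls$start_cM[i], qtls$end_cM[i]),
                   sprintf("%.2f", qtls$end_cM[i] - qtls$start_cM[i]),
                   sprintf("%.2f", qtls$peak_lod[i]), qtls$n_markers[i],
                   sprintf("%.2f", qtls$add[i]), sprintf("%.2f", qtls$dom[i]),
                   sprintf("%.2f", qtls$pve[i])))
    push(fmt_row("Total", "", "", "", "", sum(qtls$n_markers), "",
                 sprintf("%.2f", sum(qtls$dom)),
                 sprintf("%.2f", sum(qtls$pve))))
  }
  push("", "== Effective FAVs ==")
  if (is.null(fav)) {
    push("  (no FAV artifact)")
  } else {
    push(sprintf("  %d of %d candidate markers flagged effective",
                 length(fav$effective), nrow(fav$table)))
    if (!is.null(fav$load))
      push(sprintf("  top bin: %d individuals, %.0f%% carrying > half of the effective markers",
                   length(fav$load$load), 100 * fav$load$frac_above_half))
  }
  out
}
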