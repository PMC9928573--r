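# Synthetic F2 populations from two homozygous doubled-haploid parents.
#
# The generator is the package's source of ground truth: genotypes are
# produced gamete-by-gamete with a no-interference (Poisson) crossover
# process along the centimorgan axis, so the expected recombination
# fraction between two markers separated by d cM is the Haldane transform
# r = (1 - exp(-2d/100)) / 2.  Defaults mirror the onion DH-1 x DH-17 F2
# study the package emulates: 321 individuals, 8 linkage groups with the
# published group lengths, parental/progeny depths around 319x / 29x.

#' Cross design for an F2 simulation
#'
#' @param n_individuals number of F2 individuals (default 321).
#' @param n_linkage_groups number of chromosomes / linkage groups (default 8).
#' @param markers_per_group integer vector (recycled) of marker counts per
#'   group.
#' @param group_lengths numeric vector of group lengths in cM.  Defaults to
#'   the published per-group lengths of the onion reference map.
#' @param marker_positions optional list of numeric vectors giving explicit
#'   marker positions (cM) per group; otherwise positions are drawn
#'   uniformly along each group and sorted.
#' @param seed integer seed; all randomness in [simulate_f2_genotypes()]
#'   derives from it.
#' @return an object of class `cross_design`.
#' @export
cross_design <- function(n_individuals = 321,
                         n_linkage_groups = 8,
                         markers_per_group = 100,
                         group_lengths = c(115.29, 131.33, 140.43, 102.40,
                                           100.99, 103.59, 96.24, 138.05),
                         marker_positions = NULL,
                         seed = 1L) {
  n_linkage_groups <- as.integer(n_linkage_groups)
  markers_per_group <- rep_len(as.integer(markers_per_group), n_linkage_groups)
  group_lengths <- rep_len(as.numeric(group_lengths), n_linkage_groups)
  if (n_individuals < 2) stop("n_individuals must be >= 2")
  if (any(!is.finite(group_lengths)) || any(group_lengths < 0))
    stop("group lengths must be finite and >= 0")
  if (any(markers_per_group < 1)) stop("markers_per_group entries must be >= 1")
  if (!is.null(marker_positions)) {
    stopifnot(is.list(marker_positions),
              length(marker_positions) == n_linkage_groups)
    for (g in seq_len(n_linkage_groups)) {
      p <- marker_positions[[g]]
      if (length(p) != markers_per_group[g])
        stop("marker_positions[[", g, "]] length disagrees with markers_per_group")
      if (any(p < 0 | p > group_lengths[g]))
        stop("marker positions must lie within [0, group length]")
    }
  }
  structure(list(n_individuals = as.integer(n_individuals),
                 n_linkage_groups = n_linkage_groups,
                 markers_per_group = markers_per_group,
                 group_lengths = group_lengths,
                 marker_positions = marker_positions,
                 seed = as.integer(seed)),
            class = "cross_design")
}

#' Trait architecture for the simulated quantitative phenotype
#'
#' Each QTL contributes `-a` to the aa homozygote, `+a` to the bb
#' homozygote and `+d` to the heterozygote.  Under F2 1:2:1 frequencies a
#' single locus contributes genetic variance `a^2/2 + d^2/4`.  When target
#' per-QTL PVE values (percent of phenotypic variance explained) are
#' supplied, the residual standard deviation is solved so that
#' `sum(Vg_q) / VP = sum(PVE_q)/100` with `VP = Vg_tot + residual_sd^2`
#' (QTL linkage covariance ignored; the default QTLs sit on distinct or
#' well-separated positions).
#'
#' Defaults reproduce the four flower-stalk-height QTLs of the onion
#' reference study (additive effects about 2.8-3.0 cm, dominance 0.8-3.0
#' cm, per-QTL PVE 6.3-7.2%) around a 117.4 cm population mean.
#'
#' @param trait_mean population mean of the trait (cm).
#' @param qtls data frame with columns `lg`, `pos_cM`, `add`, `dom`.
#' @param residual_sd residual (environmental) standard deviation in cm;
#'   ignored when `target_pve` is given.
#' @param target_pve optional numeric vector, one percent-variance value
#'   per QTL, from which `residual_sd` is solved.
#' @return an object of class `trait_model`.
#' @export
trait_model <- function(trait_mean = 117.4,
                        qtls = data.frame(
                          lg = c(2, 2, 5, 8),
                          pos_cM = c(59.8, 64.2, 42.5, 66.3),
                          add = c(2.80, 2.86, -2.99, 3.00),
                          dom = c(2.98, 2.48, 0.83, 1.60)),
                        residual_sd = NULL,
                        target_pve = c(7.19, 6.65, 6.45, 6.28)) {
  if (nrow(qtls) > 0)
    stopifnot(all(c("lg", "pos_cM", "add", "dom") %in% names(qtls)))
  vg <- if (nrow(qtls)) qtls$add^2 / 2 + qtls$dom^2 / 4 else numeric(0)
  if (!is.null(target_pve) && nrow(qtls) > 0) {
    stopifnot(length(target_pve) == nrow(qtls), all(target_pve > 0))
    vp <- sum(vg) / (sum(target_pve) / 100)
    rv <- vp - sum(vg)
    if (rv <= 0) stop("target PVEs imply non-positive residual variance")
    residual_sd <- sqrt(rv)
  }
  if (is.null(residual_sd)) residual_sd <- 1
  if (residual_sd <= 0) stop("residual_sd must be > 0")
  structure(list(trait_mean = trait_mean, qtls = qtls,
                 residual_sd = residual_sd, vg = vg),
            class = "trait_model")
}

#' Observation model: missingness, genotyping error, depths, SNP counts
#'
#' @param missing_rate probability that a call is unobserved (default 0.04,
#'   matching the ~96% marker integrity of the reference map).
#' @param genotype_error_rate probability that a surviving call is flipped
#'   to a uniformly chosen different genotype class (default 0.005).
#' @param parental_depth_mean,progeny_depth_mean Poisson means of the
#'   per-marker fold-coverage laws (defaults 319.07 and 29.12, the
#'   reference study's average depths).
#' @param snp_per_slaf_prob probability weights on 1..8 SNPs per SLAF tag;
#'   the default geometric-type weights give a mean near 2 SNPs/tag.
#' @return an object of class `observation_model`.
#' @export
observation_model <- function(missing_rate = 0.04,
                              genotype_error_rate = 0.005,
                              parental_depth_mean = 319.07,
                              progeny_depth_mean = 29.12,
                              snp_per_slaf_prob = 0.5^(1:8)) {
  if (missing_rate < 0 || missing_rate > 1 ||
      genotype_error_rate < 0 || genotype_error_rate > 1)
    stop("rates must lie in [0, 1]")
  stopifnot(parental_depth_mean >= 0, progeny_depth_mean >= 0,
            length(snp_per_slaf_prob) == 8, all(snp_per_slaf_prob >= 0))
  structure(list(missing_rate = missing_rate,
                 genotype_error_rate = genotype_error_rate,
                 parental_depth_mean = parental_depth_mean,
                 progeny_depth_mean = progeny_depth_mean,
                 snp_per_slaf_prob = snp_per_slaf_prob / sum(snp_per_slaf_prob)),
            class = "observation_model")
}

# Simulate n gametes over markers at `positions` (cM): matrix n x m of
# 0/1 parental-origin alleles.  Crossovers follow a no-interference
# process, i.e. the allele flips between adjacent markers with the
# Haldane probability of their cM separation.
sim_gametes <- function(n, positions) {
  m <- length(positions)
  a <- matrix(0L, n, m)
  a[, 1] <- rbinom(n, 1L, 0.5)
  if (m > 1) {
    r <- haldane_r(diff(positions))
    flips <- matrix(rbinom(n * (m - 1), 1L, rep(r, each = n)), n, m - 1)
    cum <- if (m == 2) flips else t(apply(flips, 1, cumsum))
    a <- (a[, 1] + cbind(0L, cum)) %% 2L
  }
  storage.mode(a) <- "integer"
  a
}

#' Simulate true F2 genotypes
#'
#' For each individual and linkage group, two gametes are generated
#' independently under a no-interference crossover process (Haldane
#' relation between cM separation and recombination probability); the
#' genotype at each marker is the sum of the two parental-origin alleles
#' (0 = aa, 1 = ab, 2 = bb).  Every marker therefore segregates 1:2:1 in
#' expectation, and linkage decays with map distance.
#'
#' @param design a [cross_design()].
#' @return a [geno_matrix()] with no missing entries; `info` carries
#'   `lg_truth`, `pos_truth_cM` and parental SNP alleles (`allele_p1`,
#'   `allele_p2`).
#' @export
simulate_f2_genotypes <- function(design) {
  stopifnot(inherits(design, "cross_design"))
  withr::with_seed(design$seed, {
    n <- design$n_individuals
    geno_blocks <- vector("list", design$n_linkage_groups)
    info_blocks <- vector("list", design$n_linkage_groups)
    for (g in seq_len(design$n_linkage_groups)) {
      m <- design$markers_per_group[g]
      pos <- if (!is.null(design$marker_positions))
        sort(design$marker_positions[[g]])
      else sort(runif(m, 0, design$group_lengths[g]))
      gam1 <- sim_gametes(n, pos)
      gam2 <- sim_gametes(n, pos)
      geno <- t(gam1 + gam2)          # markers x individuals
      ids <- sprintf("M%d_%03d", g, seq_len(m))
      rownames(geno) <- ids
      geno_blocks[[g]] <- geno
      bases <- c("A", "C", "G", "T")
      a1 <- sample(bases, m, replace = TRUE)
      a2 <- vapply(a1, function(b) sample(setdiff(bases, b), 1), character(1))
      info_blocks[[g]] <- data.frame(
        marker_id = ids, lg_truth = g, pos_truth_cM = pos,
        allele_p1 = a1, allele_p2 = unname(a2),
        stringsAsFactors = FALSE)
    }
    geno <- do.call(rbind, geno_blocks)
    colnames(geno) <- sprintf("F2-%03d", seq_len(n))
    geno_matrix(geno, do.call(rbind, info_blocks))
  })
}

#' Overlay observation noise on a true genotype matrix
#'
#' Each entry is independently set missing with `missing_rate`; surviving
#' entries are flipped to a uniformly chosen *different* genotype class
#' with `genotype_error_rate`.  Per-marker parental depths, progeny mean
#' depth and SNP-per-tag counts are drawn from the model's laws and
#' attached to the metadata.  The input is not modified.
#'
#' @param truth a complete (no missing) [geno_matrix()].
#' @param obs an [observation_model()].
#' @param seed integer seed.
#' @return a new [geno_matrix()] with noisy genotypes and metadata columns
#'   `snp_count`, `depth_p1`, `depth_p2`, `depth_progeny`.
#' @export
apply_observation_model <- function(truth, obs, seed = 1L) {
  stopifnot(inherits(truth, "geno_matrix"), inherits(obs, "observation_model"))
  if (anyNA(truth$geno)) stop("truth matrix must have no missing entries")
  withr::with_seed(seed, {
    g <- truth$geno
    nm <- length(g)
    flip <- runif(nm) < obs$genotype_error_rate
    if (any(flip)) {
      # uniformly one of the two other codes
      shift <- 1L + (runif(sum(flip)) < 0.5)
      g[flip] <- (g[flip] + shift) %% 3L
    }
    g[runif(nm) < obs$missing_rate] <- NA_integer_
    info <- truth$info
    m <- nrow(g)
    info$snp_count <- sample(1:8, m, replace = TRUE,
                             prob = obs$snp_per_slaf_prob)
    info$depth_p1 <- rpois(m, obs$parental_depth_mean)
    info$depth_p2 <- rpois(m, obs$parental_depth_mean)
    info$depth_progeny <- rpois(m, obs$progeny_depth_mean)
    geno_matrix(g, info)
  })
}

nearest_marker_index <- function(truth, lg, pos_cM) {
  idx <- which(truth$info$lg_truth == lg)
  if (length(idx) == 0) stop("no markers on linkage group ", lg)
  idx[which.min(abs(truth$info$pos_truth_cM[idx] - pos_cM))]
}

#' Simulate a quantitative phenotype from true genotypes
#'
#' Each QTL is anchored at the nearest simulated marker on its group; the
#' phenotype is `trait_mean + sum of QTL genetic values + N(0, residual_sd^2)`
#' with genetic value `-a` / `+d` / `+a` for the aa / ab / bb genotype.
#'
#' @param truth a [geno_matrix()] carrying `lg_truth` / `pos_truth_cM`.
#' @param model a [trait_model()].
#' @param seed integer seed for the residual draw.
#' @return data frame with columns `individual_id`, `fsh_cm`; the truth
#'   anchor markers are attached as attribute `"qtl_markers"`.
#' @export
simulate_phenotype <- function(truth, model, seed = 1L) {
  stopifnot(inherits(truth, "geno_matrix"), inherits(model, "trait_model"))
  n <- ncol(truth$geno)
  gv <- numeric(n)
  anchors <- character(0)
  if (nrow(model$qtls)) {
    if (any(!model$qtls$lg %in% truth$info$lg_truth))
      stop("QTL placed on a linkage group absent from the simulation")
    for (q in seq_len(nrow(model$qtls))) {
      i <- nearest_marker_index(truth, model$qtls$lg[q], model$qtls$pos_cM[q])
      anchors <- c(anchors, rownames(truth$geno)[i])
      g <- truth$geno[i, ]
      gv <- gv + ifelse(g == 0L, -model$qtls$add[q],
                 ifelse(g == 1L, model$qtls$dom[q], model$qtls$add[q]))
    }
  }
  y <- withr::with_seed(seed,
         model$trait_mean + gv + rnorm(n, 0, model$residual_sd))
  out <- data.frame(individual_id = colnames(truth$geno), fsh_cm = y,
                    stringsAsFactors = FALSE)
  attr(out, "qtl_markers") <- anchors
  out
}

#' Simulate a monogenic dominant fertility trait
#'
#' The restorer locus is anchored at the nearest simulated marker; the
#' parent-2 allele is dominant, so `ab` and `bb` individuals are fertile
#' and `aa` individuals sterile — the classic 3:1 F2 ratio.
#'
#' @param truth a [geno_matrix()].
#' @param ms_group linkage group carrying the locus (default 8).
#' @param ms_pos position in cM (default 85.1).
#' @return data frame with columns `individual_id`, `fertility`
#'   (`"fertile"`/`"sterile"`); the anchor marker is attached as attribute
#'   `"ms_marker"`.
#' @export
simulate_fertility <- function(truth, ms_group = 8, ms_pos = 85.1) {
  stopifnot(inherits(truth, "geno_matrix"))
  i <- nearest_marker_index(truth, ms_group, ms_pos)
  g <- truth$geno[i, ]
  if (anyNA(g)) stop("fertility locus genotypes must be complete")
  out <- data.frame(individual_id = colnames(truth$geno),
                    fertility = ifelse(g == 0L, "sterile", "fertile"),
                    stringsAsFactors = FALSE)
  attr(out, "ms_marker") <- rownames(truth$geno)[i]
  out
}

#' Simulate a complete study data set
#'
#' Convenience wrapper: true genotypes, observed (noisy) genotypes, a
#' quantitative flower-stalk-height phenotype and a monogenic fertility
#' phenotype, with per-stage child seeds derived from one global seed via
#' [split_seed()].
#'
#' @param design a [cross_design()]; its `seed` field is overridden by
#'   `split_seed(seed, 0)`.
#' @param trait a [trait_model()]; by default the reference four-QTL
#'   architecture, restricted to the groups the design simulates.
#' @param obs an [observation_model()].
#' @param ms_group,ms_pos fertility locus placement (see
#'   [simulate_fertility()]).
#' @param seed global integer seed.
#' @return list with elements `truth`, `observed` (both [geno_matrix()])
#'   and `pheno` (data frame `individual_id`, `fsh_cm`, `fertility`).
#' @export
simulate_study <- function(design = cross_design(), trait = NULL,
                           obs = observation_model(),
                           ms_group = 8, ms_pos = 85.1, seed = 1L) {
  if (is.null(trait)) {
    # default architecture, restricted to the groups this design simulates
    tm0 <- trait_model()
    on_map <- tm0$qtls$lg <= design$n_linkage_groups
    trait <- trait_model(qtls = tm0$qtls[on_map, , drop = FALSE],
                         target_pve = c(7.19, 6.65, 6.45, 6.28)[on_map])
  }
  if (ms_group > design$n_linkage_groups)
    stop("fertility locus placed on a linkage group absent from the design")
  design$seed <- split_seed(seed, 0L)
  truth <- simulate_f2_genotypes(design)
  observed <- apply_observation_model(truth, obs, seed = split_seed(seed, 1L))
  fsh <- simulate_phenotype(truth, trait, seed = split_seed(seed, 2L))
  fert <- simulate_fertility(truth, ms_group = ms_group, ms_pos = ms_pos)
  pheno <- merge(fsh, fert, by = "individual_id", sort = FALSE)
  pheno <- pheno[match(colnames(truth$geno), pheno$individual_id), ]
  rownames(pheno) <- NULL
  attr(pheno, "qtl_markers") <- attr(fsh, "qtl_markers")
  attr(pheno, "ms_marker") <- attr(fert, "ms_marker")
  list(truth = truth, observed = observed, pheno = pheno)
}
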