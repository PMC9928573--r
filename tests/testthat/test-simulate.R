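test_that("zero map length forbids recombination", {
  d <- cross_design(n_individuals = 50, n_linkage_groups = 1,
                    markers_per_group = 5, group_lengths = 0, seed = 3)
  g <- simulate_f2_genotypes(d)$geno
  expect_true(all(apply(g, 2, function(col) length(unique(col)) == 1)))
})

test_that("gamete recombinant fraction matches the Haldane transform", {
  # 10 cM apart: 0.5 * (1 - exp(-0.2)) = 0.09063
  gam <- withr::with_seed(11, slafmap:::sim_gametes(1e5, c(0, 10)))
  rf <- mean(gam[, 1] != gam[, 2])
  expect_lt(abs(rf - 0.09063), 0.003)
  # and through the F2 pair estimator at a second separation
  tr <- simulate_f2_genotypes(cross_design(
    n_individuals = 1e5, n_linkage_groups = 1, markers_per_group = 2,
    group_lengths = 20, marker_positions = list(c(0, 20)), seed = 5))
  est <- estimate_rf_em(tr$geno[1, ], tr$geno[2, ])
  r_true <- haldane_r(20)
  se <- sqrt(r_true * (1 - r_true) / (2 * 1e5))
  expect_lt(abs(est$r - r_true), 3 * se)
})

test_that("single markers segregate 1:2:1", {
  # large-n frequency convergence
  tr <- simulate_f2_genotypes(cross_design(
    n_individuals = 1e5, n_linkage_groups = 1, markers_per_group = 1,
    group_lengths = 10, seed = 2))
  freq <- tabulate(tr$geno[1, ] + 1L, 3) / 1e5
  expect_true(all(abs(freq - c(0.25, 0.5, 0.25)) < 0.01))
  # chi-square acceptance rate at study n over replicates
  pass <- vapply(1:300, function(s) {
    g <- simulate_f2_genotypes(cross_design(
      n_individuals = 321, n_linkage_groups = 1, markers_per_group = 1,
      group_lengths = 1, seed = 5000 + s))$geno
    segregation_chi2(tabulate(g + 1L, 3))$p_value >= 0.01
  }, logical(1))
  expect_gte(mean(pass), 0.98)
})

test_that("simulation is deterministic given seed and config", {
  d <- cross_design(n_individuals = 40, n_linkage_groups = 2,
                    markers_per_group = 10, group_lengths = c(50, 60),
                    seed = 7)
  expect_identical(simulate_f2_genotypes(d), simulate_f2_genotypes(d))
  s1 <- simulate_study(design = d, ms_group = 2, ms_pos = 30, seed = 9)
  s2 <- simulate_study(design = d, ms_group = 2, ms_pos = 30, seed = 9)
  expect_identical(s1$observed$geno, s2$observed$geno)
  expect_identical(s1$pheno, s2$pheno)
})

test_that("observation model: identity, missing rate, forced flips", {
  tr <- simulate_f2_genotypes(cross_design(
    n_individuals = 100, n_linkage_groups = 1, markers_per_group = 100,
    group_lengths = 100, seed = 4))
  clean <- apply_observation_model(
    tr, observation_model(missing_rate = 0, genotype_error_rate = 0),
    seed = 1)
  expect_identical(clean$geno, tr$geno)
  noisy <- apply_observation_model(
    tr, observation_model(missing_rate = 0.3, genotype_error_rate = 0),
    seed = 2)
  expect_lt(abs(mean(is.na(noisy$geno)) - 0.3), 0.02)
  flipped <- apply_observation_model(
    tr, observation_model(missing_rate = 0, genotype_error_rate = 1),
    seed = 3)
  expect_true(all(flipped$geno != tr$geno))
  # input untouched, rates validated, metadata attached
  expect_false(anyNA(tr$geno))
  expect_error(observation_model(missing_rate = 1.2), "rates")
  expect_true(all(c("snp_count", "depth_p1", "depth_p2") %in%
                    names(noisy$info)))
  expect_true(all(noisy$info$snp_count %in% 1:8))
})

test_that("phenotype model reproduces the F2 variance decomposition", {
  tr <- even_truth(n = 321, m = 21, len = 100, seed = 6)
  # degenerate: no QTLs, vanishing residual
  ph0 <- simulate_phenotype(tr, trait_model(qtls = data.frame(
    lg = integer(0), pos_cM = numeric(0), add = numeric(0),
    dom = numeric(0)), target_pve = NULL, residual_sd = 1e-9), seed = 1)
  expect_true(all(abs(ph0$fsh_cm - 117.4) < 1e-6))
  # single-locus genetic variance a^2/2 + d^2/4
  tm <- trait_model(qtls = data.frame(lg = 1, pos_cM = 50, add = 3.0,
                                      dom = 1.6), target_pve = 6)
  expect_equal(tm$vg, 3^2 / 2 + 1.6^2 / 4)  # 5.14
  expect_equal(tm$vg / (tm$vg + tm$residual_sd^2), 0.06, tolerance = 1e-10)
  # defaults: unimodal, approximately normal phenotype at study scale
  tr8 <- simulate_f2_genotypes(cross_design(markers_per_group = 20, seed = 8))
  ph <- simulate_phenotype(tr8, trait_model(), seed = 2)
  expect_gt(stats::shapiro.test(ph$fsh_cm)$p.value, 0.01)
  expect_error(simulate_phenotype(tr, trait_model(qtls = data.frame(
    lg = 99, pos_cM = 1, add = 1, dom = 0), target_pve = NULL)),
    "linkage group")
})

test_that("dominant fertility locus segregates 3:1", {
  # degenerate all-aa input
  g <- matrix(0L, 1, 10, dimnames = list("M1", paste0("I", 1:10)))
  gm <- geno_matrix(g, data.frame(marker_id = "M1", lg_truth = 1,
                                  pos_truth_cM = 0))
  expect_true(all(simulate_fertility(gm, 1, 0)$fertility == "sterile"))
  # printed-count check: (241, 81) against 3:1
  chi <- stats::chisq.test(c(241, 81), p = c(0.75, 0.25))
  expect_equal(unname(chi$statistic), 0.00414, tolerance = 1e-2)
  expect_equal(unname(chi$p.value), 0.949, tolerance = 1e-3)
  # operating characteristics over replicates
  pass <- vapply(1:400, function(s) {
    tr <- simulate_f2_genotypes(cross_design(
      n_individuals = 321, n_linkage_groups = 1, markers_per_group = 1,
      group_lengths = 1, seed = 7000 + s))
    fert <- simulate_fertility(tr, 1, 0)
    tab <- table(factor(fert$fertility, c("fertile", "sterile")))
    stats::chisq.test(as.vector(tab), p = c(0.75, 0.25))$p.value >= 0.05
  }, logical(1))
  expect_gte(mean(pass), 0.93)
})

test_that("design and model validation reject bad inputs", {
  expect_error(cross_design(n_individuals = 1), "n_individuals")
  expect_error(cross_design(group_lengths = c(NA, 1)), "finite")
  expect_error(cross_design(markers_per_group = 0), "markers_per_group")
  expect_error(trait_model(residual_sd = 0, target_pve = NULL),
               "residual_sd")
  # PVE targets too large for the fixed effects
  expect_error(trait_model(qtls = data.frame(lg = 1, pos_cM = 1, add = 1,
                                             dom = 0), target_pve = 120),
               "residual")
})
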