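test_that("phenotype binning is half-open, exhaustive and conserving", {
  b <- bin_phenotype(setNames(c(95, 105, 115), c("a", "b", "c")))
  expect_identical(unname(b$counts), c(1L, 1L, 1L))
  # boundary value: exactly 100 falls in (90, 100]
  b2 <- bin_phenotype(setNames(c(100, 100.01), c("a", "b")))
  expect_identical(b2$bin[["a"]], 1L)
  expect_identical(b2$bin[["b"]], 2L)
  expect_error(bin_phenotype(setNames(1, "a"), width = 0), "width")
  # conservation on an arbitrary sample
  v <- withr::with_seed(3, setNames(rnorm(321, 117.4, 9),
                                    paste0("I", 1:321)))
  b3 <- bin_phenotype(v)
  expect_identical(sum(b3$counts), 321L)
  expect_true(all(vapply(seq_along(v), function(i) {
    lo <- b3$edges$lower[b3$bin[i]]; up <- b3$edges$upper[b3$bin[i]]
    v[i] > lo - 1e-6 && v[i] <= up + 1e-6
  }, logical(1))))
  # published bin counts give the published percentages
  cnt <- onion_ref_counts()$fsh_bin_counts
  expect_identical(sum(cnt), 321)
  expect_identical(unname(round(100 * cnt / sum(cnt))),
                   c(3, 16, 39, 36, 5))
})

test_that("heterozygote proportions divide by fixed bin sizes", {
  # 17-individual bin with 11 heterozygotes -> 0.647 (prints 0.65)
  g <- matrix(c(rep(1L, 11), rep(0L, 6)), 1, 17,
              dimnames = list("mk", paste0("I", 1:17)))
  b <- bin_phenotype(setNames(rep(135, 17), paste0("I", 1:17)))
  p <- het_proportion_per_bin(g, "mk", b)
  expect_equal(p, 11 / 17, tolerance = 1e-12)
  expect_equal(round(p, 2), 0.65)
  # all-homozygous bin
  g0 <- matrix(rep(0L, 17), 1, 17, dimnames = dimnames(g))
  expect_equal(het_proportion_per_bin(g0, "mk", b), 0)
  # missing calls stay in the denominator by default, not when informative_only
  g[1, 1:2] <- NA
  expect_equal(het_proportion_per_bin(g, "mk", b), 9 / 17)
  expect_equal(het_proportion_per_bin(g, "mk", b, informative_only = TRUE),
               9 / 15)
  # relabeling the homozygote classes leaves proportions unchanged
  g2 <- matrix(sample(0:2, 300, replace = TRUE), 3, 100,
               dimnames = list(paste0("m", 1:3), paste0("I", 1:100)))
  bb <- bin_phenotype(setNames(runif(100, 91, 139), paste0("I", 1:100)))
  g2_swapped <- 2L - g2
  dimnames(g2_swapped) <- dimnames(g2)
  for (mk in rownames(g2))
    expect_identical(het_proportion_per_bin(g2, mk, bb),
                     het_proportion_per_bin(g2_swapped, mk, bb))
})

test_that("trend statistics reproduce the published rows", {
  fp <- onion_ref_fav_proportions()
  r1 <- trend_statistic(as.numeric(fp[fp$marker_id == "Marker150989",
                                      3:7]), ref_bin_mids)
  expect_equal(as.numeric(r1), 0.959, tolerance = 1e-3)
  r2 <- trend_statistic(as.numeric(fp[fp$marker_id == "Marker285135",
                                      3:7]), ref_bin_mids)
  expect_equal(as.numeric(r2), 0.681, tolerance = 1e-3)
  expect_lt(trend_statistic(c(0.5, 0.4, 0.3, 0.2, 0.1), ref_bin_mids), 0)
  cst <- trend_statistic(rep(0.3, 5), ref_bin_mids)
  expect_equal(as.numeric(cst), 0)
  expect_true(isTRUE(attr(cst, "constant")))
  expect_error(trend_statistic(c(0.1, NA, NA, NA, 0.3), ref_bin_mids),
               "3 non-missing")
})

test_that("effective-FAV selection applies the trend criteria", {
  fp <- onion_ref_fav_proportions()
  prop <- as.matrix(fp[, 3:7])
  rownames(prop) <- fp$marker_id
  sel <- select_effective_favs(prop, ref_bin_mids,
                               total_prop = rowMeans(prop))
  # every published effective FAV passes the default criteria
  expect_true(all(sel$effective))
  expect_true(all(sel$trend >= 0.5))
  # planted negatives are rejected
  prop2 <- rbind(prop,
                 down = c(0.5, 0.4, 0.3, 0.2, 0.1),
                 flat = rep(0.3, 5))
  sel2 <- select_effective_favs(prop2, ref_bin_mids,
                                total_prop = rowMeans(prop2))
  expect_identical(sum(sel2$effective), 20L)
  expect_false(sel2$effective[sel2$marker_id == "down"])
})

test_that("individual FAV loads count heterozygous carriers", {
  n_eff <- 20
  ids <- paste0("I", 1:17)
  g <- matrix(0L, n_eff, 17, dimnames = list(paste0("m", 1:n_eff), ids))
  g[, 1] <- 1L                 # I1 heterozygous at all 20
  g[1:11, 2:11] <- 1L          # I2..I11 at 11 of 20 (> 50%)
  b <- bin_phenotype(setNames(rep(135, 17), ids))
  load <- individual_fav_load(g, rownames(g), b)
  expect_identical(unname(load$load[1]), 20)
  expect_identical(unname(load$load[12]), 0)
  expect_equal(load$frac_above_half, 11 / 17)
  expect_identical(load$n_effective, 20L)
})

test_that("flagging is calibrated under independence, sensitive to overdominance", {
  # specificity: markers independent of the phenotype.  Pearson trend over
  # k populated bins is scale-free (null P(r >= 0.5) is ~0.20 for k = 5,
  # 0.25 for k = 4), so the default shortlist rule admits roughly a
  # quarter of null markers; at a stringent trend the rate drops below 10%
  nm <- 400
  g <- withr::with_seed(61, matrix(sample(0:2, nm * 321, replace = TRUE,
                                          prob = c(.25, .5, .25)),
                                   nm, 321,
                                   dimnames = list(paste0("m", 1:nm),
                                                   paste0("I", 1:321))))
  ph <- withr::with_seed(62,
                         data.frame(individual_id = paste0("I", 1:321),
                                    fsh_cm = rnorm(321, 117.4, 9)))
  rep0 <- fav_report(g, ph, rownames(g))
  expect_lt(length(rep0$effective) / nm, 0.35)
  rep_strict <- fav_report(g, ph, rownames(g), trend_min = 0.9)
  expect_lt(length(rep_strict$effective) / nm, 0.10)
  # sensitivity: a strongly overdominant locus is flagged
  hits <- 0
  for (s in 1:10) {
    tr <- even_truth(n = 321, m = 21, len = 100, seed = 900 + s)
    ph <- simulate_phenotype(tr, trait_model(
      trait_mean = 117.4,
      qtls = data.frame(lg = 1, pos_cM = 50, add = 0.5, dom = 6),
      target_pve = NULL, residual_sd = 8), seed = s)
    near <- tr$info$marker_id[abs(tr$info$pos_truth_cM - 50) <= 5]
    rep1 <- fav_report(tr$geno, ph, near)
    if (length(rep1$effective) > 0) hits <- hits + 1
  }
  expect_gte(hits, 8)
})
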