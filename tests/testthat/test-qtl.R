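# shared fixture: clean single-group map with markers on integer positions
qtl_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      tr <- even_truth(n = 321, m = 21, len = 100, seed = 81)
      cache <<- list(truth = tr, map = truth_map(tr))
    }
    cache
  }
})

test_that("conditional genotype probabilities follow the flanking algebra", {
  fx <- qtl_fixture()
  map <- fx$map
  grp <- map$groups[[1]]
  # degenerate at an observed marker
  pos1 <- grp$position_cM[3]
  pr <- genotype_probabilities(map, 1, pos1)
  g3 <- map$geno[grp$marker_id[3], ]
  expect_true(all(abs(pr[cbind(seq_along(g3), g3 + 1L)] - 1) < 1e-12))
  # midpoint of a 20 cM aa--aa bracket: closed-form conditional
  r <- haldane_r(10)
  num_aa <- (1 - r)^2 * (1 - r)^2
  num_ab <- (2 * r * (1 - r)) * (r * (1 - r))
  num_bb <- r^2 * r^2
  expected_aa <- num_aa / (num_aa + num_ab + num_bb)
  g <- matrix(c(0L, 0L), 2, 1, dimnames = list(c("m1", "m2"), "I1"))
  pr2 <- slafmap:::condprob_individual(c(0, 20), c(0L, 0L), 10)
  expect_equal(pr2[1, 1], expected_aa, tolerance = 1e-12)
  expect_gt(pr2[1, 1], 0.9)
  # no informative markers: Mendelian prior
  pr3 <- slafmap:::condprob_individual(numeric(0), integer(0), 5)
  expect_equal(as.numeric(pr3), c(0.25, 0.5, 0.25))
  expect_error(genotype_probabilities(map, 1, 1e6), "span")
})

test_that("scan LOD equals the single-marker regression at a marker", {
  fx <- qtl_fixture()
  map <- fx$map
  ph <- simulate_phenotype(fx$truth, trait_model(
    qtls = data.frame(lg = 1, pos_cM = 50, add = 3, dom = 1.6),
    target_pve = 6.3), seed = 3)
  y <- setNames(ph$fsh_cm, ph$individual_id)
  sc <- scan_trait(map, y, cofactors = NULL, step = 1)
  # marker positions sit on the integer grid of this fixture
  for (mi in c(5, 11, 17)) {
    mpos <- map$groups[[1]]$position_cM[mi]
    gi <- which.min(abs(sc$grid$pos - mpos))
    g <- map$geno[map$groups[[1]]$marker_id[mi], ]
    fit0 <- lm(y ~ 1)
    fit1 <- lm(y ~ I(g - 1) + I(as.numeric(g == 1)))
    lod_lm <- (length(y) / 2) *
      log10(sum(resid(fit0)^2) / sum(resid(fit1)^2))
    expect_lt(abs(sc$grid$lod[gi] - lod_lm), 1e-8)
  }
  # LOD invariant under affine phenotype rescaling
  sc2 <- scan_trait(map, 3.2 * y + 40, cofactors = NULL, step = 1)
  expect_equal(sc2$grid$lod, sc$grid$lod, tolerance = 1e-8)
  # constant phenotype: flat zero profile
  sc0 <- scan_trait(map, setNames(rep(5, length(y)), names(y)))
  expect_true(all(sc0$grid$lod == 0))
})

test_that("cofactor selection finds planted signal and respects limits", {
  fx <- qtl_fixture()
  map <- fx$map
  ph <- simulate_phenotype(fx$truth, trait_model(
    qtls = data.frame(lg = 1, pos_cM = 50, add = 3, dom = 1.6),
    target_pve = 12), seed = 4)
  y <- setNames(ph$fsh_cm, ph$individual_id)
  cof <- select_cofactors(map, y)
  anchor <- attr(ph, "qtl_markers")
  anchor_pos <- fx$truth$info$pos_truth_cM[
    match(anchor, fx$truth$info$marker_id)]
  first_pos <- fx$truth$info$pos_truth_cM[
    match(cof[1], fx$truth$info$marker_id)]
  expect_lte(abs(first_pos - anchor_pos), 5)
  expect_identical(select_cofactors(map, y, max_cofactors = 0), character(0))
  # pure-noise phenotype: the best chance marker improves RSS by a few
  # percent at n = 321, so emptiness needs a matching improvement floor
  ynull <- withr::with_seed(5, setNames(rnorm(ncol(map$geno)),
                                        colnames(map$geno)))
  expect_length(select_cofactors(map, ynull, min_improve = 0.05), 0)
  expect_lte(length(select_cofactors(map, ynull)), 5)
})

test_that("permutation thresholds are monotone and deterministic", {
  fx <- qtl_fixture()
  ynull <- withr::with_seed(6, setNames(rnorm(ncol(fx$map$geno), 100, 8),
                                        colnames(fx$map$geno)))
  sc <- scan_trait(fx$map, ynull)
  pol <- threshold_policy(n_permutations = 200, seed = 17)
  p1 <- permutation_threshold(sc, pol)
  p2 <- permutation_threshold(sc, pol)
  expect_identical(p1, p2)
  thr <- p1$thresholds
  expect_gte(thr[["0.99"]], thr[["0.95"]])
  expect_gte(thr[["0.95"]], thr[["0.9"]])
  expect_warning(threshold_policy(n_permutations = 50), "100")
  expect_error(threshold_policy(confidence_ladder = c(0.9, 0.95)))
})

test_that("PVE follows the likelihood-R2 identity", {
  expect_equal(pve(0, 321), 0)
  expect_equal(pve(5.55, 321), 7.65, tolerance = 1e-2)
  lods <- seq(0, 20, by = 0.5)
  expect_true(all(diff(pve(lods, 321)) > 0))
  expect_true(all(pve(c(100, 1000), 321) < 100))
})

test_that("QTL declaration recovers planted effects and intervals", {
  fx <- qtl_fixture()
  map <- fx$map
  # threshold above the global maximum declares nothing
  ph <- simulate_phenotype(fx$truth, trait_model(
    qtls = data.frame(lg = 1, pos_cM = 50, add = 3, dom = 1.6),
    target_pve = 6.3), seed = 7)
  y <- setNames(ph$fsh_cm, ph$individual_id)
  sc <- scan_trait(map, y)
  expect_identical(nrow(declare_qtls(sc, max(sc$grid$lod) + 1, map)), 0L)
  # two QTLs 60 cM apart on one group declare two disjoint intervals
  ph2 <- simulate_phenotype(fx$truth, trait_model(
    qtls = data.frame(lg = c(1, 1), pos_cM = c(20, 80),
                      add = c(3, 3), dom = c(1.6, 1.6)),
    target_pve = c(8, 8)), seed = 8)
  sc2 <- scan_trait(map, setNames(ph2$fsh_cm, ph2$individual_id))
  q2 <- declare_qtls(sc2, 3.5, map, trait_name = "FSH")
  expect_gte(nrow(q2), 2)
  expect_true(all(q2$start_cM <= q2$end_cM))
  expect_true(all(q2$pve >= 0 & q2$pve < 100))
  # member markers lie inside their intervals
  for (i in seq_len(nrow(q2))) {
    mpos <- map$info$position_cM[match(q2$markers[[i]],
                                       map$info$marker_id)]
    expect_true(all(mpos >= q2$start_cM[i] & mpos <= q2$end_cM[i]))
  }
  # effect recovery across seeds: ADD within 0.75, DOM within 1.2 (median)
  adds <- doms <- perr <- numeric(20)
  for (s in 1:20) {
    tr <- even_truth(n = 321, m = 21, len = 100, seed = 800 + s)
    mp <- truth_map(tr)
    ph <- simulate_phenotype(tr, trait_model(
      qtls = data.frame(lg = 1, pos_cM = 50, add = 3, dom = 1.6),
      target_pve = 6.3), seed = s)
    sc <- scan_trait(mp, setNames(ph$fsh_cm, ph$individual_id))
    q <- declare_qtls(sc, 3, mp)
    if (nrow(q) == 0) { adds[s] <- NA; next }
    top <- q[which.max(q$peak_lod), ]
    adds[s] <- top$add
    doms[s] <- top$dom
    anchor <- attr(ph, "qtl_markers")
    perr[s] <- abs(top$peak_cM - mp$info$position_cM[
      match(anchor, mp$info$marker_id)])
  }
  expect_lte(median(abs(adds - 3), na.rm = TRUE), 0.75)
  expect_lte(median(abs(doms - 1.6), na.rm = TRUE), 1.2)
  expect_lte(median(perr, na.rm = TRUE), 5)
})

test_that("a monogenic binary trait gives one dominating peak", {
  tr <- simulate_f2_genotypes(cross_design(
    n_individuals = 321, n_linkage_groups = 3, markers_per_group = 20,
    group_lengths = c(80, 70, 90), seed = 55))
  map <- build_genetic_map(tr)
  fert <- simulate_fertility(tr, ms_group = 2, ms_pos = 35)
  y <- setNames(as.numeric(fert$fertility == "fertile"),
                fert$individual_id)
  sc <- scan_trait(map, y)
  by_group <- vapply(split(sc$grid$lod, sc$grid$lg), max, numeric(1))
  top2 <- sort(by_group, decreasing = TRUE)[1:2]
  expect_gt(top2[1] - top2[2], 10)
  # the peak sits on the group carrying the locus
  lg_truth <- map_group_truth(map, tr)
  expect_identical(lg_truth[as.integer(names(which.max(by_group)))], 2L)
})

test_that("ladder stepping records provenance and falls back manually", {
  fx <- qtl_fixture()
  map <- fx$map
  ph <- simulate_phenotype(fx$truth, trait_model(
    qtls = data.frame(lg = 1, pos_cM = 50, add = 3, dom = 1.6),
    target_pve = 6.3), seed = 9)
  y <- setNames(ph$fsh_cm, ph$individual_id)
  sc <- scan_trait(map, y)
  pol <- threshold_policy(n_permutations = 200, seed = 2)
  perm <- permutation_threshold(sc, pol)
  dec <- declare_with_ladder(sc, perm, pol, map = map, trait_name = "FSH")
  expect_true(dec$rung %in% c("0.99", "0.95", "0.9", "manual:3",
                              "manual:2.5", "manual:2", "none"))
  if (dec$rung != "none") expect_gte(nrow(dec$qtls), 1)
  # a null phenotype walks the whole ladder
  ynull <- withr::with_seed(10, setNames(rnorm(ncol(map$geno)),
                                         colnames(map$geno)))
  scn <- scan_trait(map, ynull)
  permn <- permutation_threshold(scn, pol)
  decn <- declare_with_ladder(scn, permn, pol, map = map)
  if (decn$rung == "none") expect_identical(nrow(decn$qtls), 0L)
})
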