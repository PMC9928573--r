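# Shared fixtures, all generated in code.

# bin midpoints of the 10-cm flower-stalk-height bins from 90 cm
ref_bin_mids <- c(95, 105, 115, 125, 135)

# a small error-free single-group truth with evenly spaced markers, so the
# marker order is statistically identifiable at the given sample size
even_truth <- function(n = 321, m = 50, len = 100, seed = 1) {
  simulate_f2_genotypes(cross_design(
    n_individuals = n, n_linkage_groups = 1, markers_per_group = m,
    group_lengths = len,
    marker_positions = list(seq(0, len, length.out = m)), seed = seed))
}

# independent grid-search oracle for the two-locus F2 likelihood: class
# probabilities written out from the gamete model, no package internals
oracle_rf_grid <- function(g1, g2, step = 1e-4) {
  ok <- !is.na(g1) & !is.na(g2)
  cnt <- tabulate(g1[ok] * 3L + g2[ok] + 1L, nbins = 9L)
  loglik <- function(r) {
    s <- 1 - r
    p <- c(s^2 / 4, r * s / 2, r^2 / 4,
           r * s / 2, (s^2 + r^2) / 2, r * s / 2,
           r^2 / 4, r * s / 2, s^2 / 4)
    sum(ifelse(cnt > 0, cnt * log(p), 0))
  }
  grid <- seq(0, 0.5, by = step)
  ll <- vapply(grid, loglik, numeric(1))
  best <- which.max(ll)
  list(r = grid[best], mlod = (ll[best] - ll[length(grid)]) / log(10))
}

# a genetic_map assembled from the simulation's true order and positions
# (no estimation), for tests that need exact marker placement
truth_map <- function(truth) {
  info <- truth$info
  groups <- lapply(sort(unique(info$lg_truth)), function(lg) {
    sub <- info[info$lg_truth == lg, ]
    sub <- sub[order(sub$pos_truth_cM), ]
    data.frame(marker_id = sub$marker_id,
               position_cM = sub$pos_truth_cM - min(sub$pos_truth_cM))
  })
  ord <- unlist(lapply(groups, `[[`, "marker_id"))
  info <- info[match(ord, info$marker_id), ]
  info$lg <- rep(seq_along(groups), vapply(groups, nrow, integer(1)))
  info$position_cM <- unlist(lapply(groups, `[[`, "position_cM"))
  rownames(info) <- NULL
  structure(list(groups = groups, geno = truth$geno[ord, , drop = FALSE],
                 info = info, n_blanked = 0L, mlod_threshold = 5),
            class = "genetic_map")
}

# truth -> observed order mapping: majority truth linkage group per built
# group
map_group_truth <- function(map, truth) {
  vapply(map$groups, function(g) {
    tl <- truth$info$lg_truth[match(g$marker_id, truth$info$marker_id)]
    as.integer(names(sort(table(tl), decreasing = TRUE))[1])
  }, integer(1))
}
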