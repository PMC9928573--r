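# QTL scanning by Haley-Knott regression on a built genetic map, with
# forward-selected background cofactors (composite-interval-mapping style),
# empirical permutation thresholds, and QTL-interval declaration with
# additive / dominance effects and percent variance explained.

# F2 genotype transition probabilities between two loci with recombination
# fraction r: P(g_to | g_from), each gamete transiting independently.
trans_prob <- function(from, to, r) {
  s <- 1 - r
  idx <- from * 3L + to
  out <- numeric(length(idx))
  out[idx == 0L] <- (s^2)[idx == 0L]
  out[idx == 1L] <- (2 * r * s)[idx == 1L]
  out[idx == 2L] <- (r^2)[idx == 2L]
  out[idx == 3L] <- (r * s)[idx == 3L]
  out[idx == 4L] <- (s^2 + r^2)[idx == 4L]
  out[idx == 5L] <- (r * s)[idx == 5L]
  out[idx == 6L] <- (r^2)[idx == 6L]
  out[idx == 7L] <- (2 * r * s)[idx == 7L]
  out[idx == 8L] <- (s^2)[idx == 8L]
  out
}

# Conditional genotype probabilities for one individual at query positions.
# pos/g: the individual's non-missing marker positions and genotypes
# (sorted by position); q: query positions.  Returns length(q) x 3 matrix.
condprob_individual <- function(pos, g, q) {
  nq <- length(q)
  out <- matrix(rep(c(0.25, 0.5, 0.25), each = nq), nq, 3)
  if (length(pos) == 0) return(out)
  L <- findInterval(q, pos)
  R <- L + 1L
  hasL <- L >= 1L
  hasR <- R <= length(pos)
  for (gg in 0:2) {
    p <- rep(1, nq)
    p[hasL] <- p[hasL] * trans_prob(g[L[hasL]], rep(gg, sum(hasL)),
                                    haldane_r(q[hasL] - pos[L[hasL]]))
    p[hasR] <- p[hasR] * trans_prob(rep(gg, sum(hasR)), g[R[hasR]],
                                    haldane_r(pos[R[hasR]] - q[hasR]))
    out[hasL | hasR, gg + 1L] <- p[hasL | hasR]
  }
  out / rowSums(out)
}

#' Conditional F2 genotype probabilities at a map position
#'
#' For every individual, P(aa), P(ab), P(bb) at the query position given
#' the nearest non-missing flanking markers, using the Haldane transform
#' of the flanking cM distances (matching the no-interference crossover
#' model).  At a non-missing marker the distribution is degenerate on the
#' observed class; an individual with no informative marker on the group
#' gets the Mendelian prior (1/4, 1/2, 1/4).
#'
#' @param map a `genetic_map` from [build_genetic_map()].
#' @param lg linkage-group index.
#' @param pos position in cM within the group's span.
#' @return numeric matrix individuals x 3 (columns aa, ab, bb).
#' @export
genotype_probabilities <- function(map, lg, pos) {
  stopifnot(inherits(map, "genetic_map"))
  grp <- map$groups[[lg]]
  if (pos < 0 || pos > max(grp$position_cM))
    stop("position outside the span of linkage group ", lg)
  g <- map$geno[grp$marker_id, , drop = FALSE]
  out <- matrix(NA_real_, ncol(g), 3,
                dimnames = list(colnames(g), c("aa", "ab", "bb")))
  for (j in seq_len(ncol(g))) {
    nm <- which(!is.na(g[, j]))
    out[j, ] <- condprob_individual(grp$position_cM[nm], g[nm, j], pos)
  }
  out
}

# Precompute additive (P(bb) - P(aa)) and dominance (P(ab)) scores on a
# cM grid over all groups.  Returns list(grid = data.frame(lg, pos),
# xa, xd = n x P matrices).
scan_scores <- function(map, step = 1) {
  if (step <= 0) stop("step must be > 0")
  grids <- lapply(seq_along(map$groups), function(gi) {
    span <- max(map$groups[[gi]]$position_cM)
    pos <- unique(c(seq(0, span, by = step), span))
    data.frame(lg = gi, pos = pos)
  })
  grid <- do.call(rbind, grids)
  n <- ncol(map$geno)
  P <- nrow(grid)
  xa <- matrix(NA_real_, n, P)
  xd <- matrix(NA_real_, n, P)
  for (gi in seq_along(map$groups)) {
    grp <- map$groups[[gi]]
    g <- map$geno[grp$marker_id, , drop = FALSE]
    cols <- which(grid$lg == gi)
    q <- grid$pos[cols]
    for (j in seq_len(n)) {
      nm <- which(!is.na(g[, j]))
      pr <- condprob_individual(grp$position_cM[nm], g[nm, j], q)
      xa[j, cols] <- pr[, 3] - pr[, 1]
      xd[j, cols] <- pr[, 2]
    }
  }
  list(grid = grid, xa = xa, xd = xd)
}

# additive + dominance design columns for cofactor markers, mean-imputed
cofactor_design <- function(map, cofactors) {
  if (length(cofactors) == 0) return(NULL)
  g <- map$geno[cofactors, , drop = FALSE]
  X <- matrix(0, ncol(g), 2 * length(cofactors))
  for (i in seq_along(cofactors)) {
    a <- g[i, ] - 1
    d <- as.numeric(g[i, ] == 1L)
    a[is.na(a)] <- mean(a, na.rm = TRUE)
    d[is.na(d)] <- mean(d, na.rm = TRUE)
    X[, 2 * i - 1] <- a
    X[, 2 * i] <- d
  }
  colnames(X) <- paste0(rep(cofactors, each = 2), c("_a", "_d"))
  X
}

rss_fit <- function(X, y) {
  fit <- stats::lm.fit(X, y)
  sum(fit$residuals^2)
}

#' Genome scan by Haley-Knott regression
#'
#' At every grid position the phenotype is regressed on the expected
#' additive score `x_a = P(bb) - P(aa)` and dominance score `x_d = P(ab)`
#' from [genotype_probabilities()]; cofactor markers (additive + dominance
#' coding) are included in both the null and full models except those
#' mapped within `exclusion_window` cM of the tested position on the same
#' group.  `LOD = (n/2) log10(RSS_null / RSS_full)`.  Binary traits can be
#' scanned as 0/1 phenotypes with the same linear model.
#'
#' @param map a `genetic_map`.
#' @param phenotype numeric vector over the map's individuals (names are
#'   matched to individual ids when present); `NA`s dropped.
#' @param cofactors character vector of cofactor marker ids (possibly from
#'   [select_cofactors()]); `NULL` for simple interval mapping.
#' @param step grid step in cM (default 1).
#' @param exclusion_window cM window around the tested position within
#'   which cofactors are dropped (default 10).
#' @return object of class `qtl_scan`: list with `grid` (data frame `lg`,
#'   `pos`, `lod`, `add`, `dom`), `n`, `cofactors`, plus the cached score
#'   matrices used by [permutation_threshold()] and [declare_qtls()].
#' @export
scan_trait <- function(map, phenotype, cofactors = NULL, step = 1,
                       exclusion_window = 10) {
  stopifnot(inherits(map, "genetic_map"))
  y <- phenotype
  if (!is.null(names(y))) y <- y[colnames(map$geno)]
  keep <- which(!is.na(y))
  y <- as.numeric(y[keep])
  n <- length(y)
  if (n < 3) stop("need at least 3 phenotyped individuals")
  sc <- scan_scores(map, step = step)
  xa <- sc$xa[keep, , drop = FALSE]
  xd <- sc$xd[keep, , drop = FALSE]
  C <- cofactor_design(map, cofactors)
  if (!is.null(C)) C <- C[keep, , drop = FALSE]
  cof_lg <- cof_pos <- NULL
  if (length(cofactors)) {
    idx <- match(cofactors, map$info$marker_id)
    cof_lg <- map$info$lg[idx]
    cof_pos <- map$info$position_cM[idx]
  }
  P <- nrow(sc$grid)
  lod <- add <- dom <- numeric(P)
  const_y <- var(y) < .Machine$double.eps
  for (p in seq_len(P)) {
    if (const_y) next
    keep_cof <- if (length(cofactors))
      !(cof_lg == sc$grid$lg[p] &
          abs(cof_pos - sc$grid$pos[p]) <= exclusion_window)
    else logical(0)
    X0 <- cbind(rep(1, n), if (any(keep_cof)) C[, rep(keep_cof, each = 2),
                                                drop = FALSE])
    X1 <- cbind(X0, xa_ = xa[, p], xd_ = xd[, p])
    rss0 <- rss_fit(X0, y)
    fit1 <- stats::lm.fit(X1, y)
    rss1 <- sum(fit1$residuals^2)
    lod[p] <- max((n / 2) * log10(rss0 / max(rss1, 1e-300)), 0)
    cf <- coef(fit1)
    add[p] <- if (is.na(cf["xa_"])) 0 else cf[["xa_"]]
    dom[p] <- if (is.na(cf["xd_"])) 0 else cf[["xd_"]]
  }
  grid <- cbind(sc$grid, lod = lod, add = add, dom = dom)
  structure(list(grid = grid, n = n, cofactors = cofactors,
                 xa = xa, xd = xd, y = y, step = step,
                 exclusion_window = exclusion_window),
            class = "qtl_scan")
}

#' @export
print.qtl_scan <- function(x, ...) {
  cat(sprintf("qtl_scan: %d positions over %d groups, n = %d, max LOD = %.2f\n",
              nrow(x$grid), length(unique(x$grid$lg)), x$n, max(x$grid$lod)))
  invisible(x)
}

#' Forward selection of background cofactor markers
#'
#' Greedy forward selection of mapped markers (additive + dominance
#' coding) by residual-sum-of-squares reduction, stopping at
#' `max_cofactors` or when the next marker improves RSS by less than
#' `min_improve` of the total phenotypic variance.
#'
#' @param map a `genetic_map`.
#' @param phenotype numeric phenotype vector (as in [scan_trait()]).
#' @param max_cofactors maximum number selected (default 5).
#' @param min_improve minimum RSS improvement as a fraction of total sum
#'   of squares (default 0.01).
#' @return character vector of selected marker ids (possibly empty).
#' @export
select_cofactors <- function(map, phenotype, max_cofactors = 5,
                             min_improve = 0.01) {
  stopifnot(inherits(map, "genetic_map"))
  if (max_cofactors <= 0) return(character(0))
  y <- phenotype
  if (!is.null(names(y))) y <- y[colnames(map$geno)]
  keep <- which(!is.na(y))
  y <- as.numeric(y[keep])
  markers <- map$info$marker_id
  D <- cofactor_design(map, markers)[keep, , drop = FALSE]
  tss <- sum((y - mean(y))^2)
  if (tss == 0) return(character(0))
  selected <- integer(0)
  X <- matrix(1, length(y), 1)
  rss_cur <- tss
  while (length(selected) < max_cofactors) {
    best <- NA_integer_
    best_rss <- rss_cur
    for (i in setdiff(seq_along(markers), selected)) {
      rss <- rss_fit(cbind(X, D[, c(2 * i - 1, 2 * i)]), y)
      if (rss < best_rss) { best_rss <- rss; best <- i }
    }
    if (is.na(best) || (rss_cur - best_rss) / tss < min_improve) break
    selected <- c(selected, best)
    X <- cbind(X, D[, c(2 * best - 1, 2 * best)])
    rss_cur <- best_rss
  }
  markers[selected]
}

#' Threshold policy for QTL declaration
#'
#' @param n_permutations number of phenotype permutations (default 1000;
#'   below 100 a warning is issued, the empirical quantile is unstable).
#' @param confidence_ladder genome-wide confidence levels tried in order
#'   (default 0.99, 0.95, 0.90).
#' @param manual_ladder fixed LOD fallbacks tried next (default 3.0, 2.5,
#'   2.0).
#' @param seed integer seed for the permutations.
#' @return a `threshold_policy` list.
#' @export
threshold_policy <- function(n_permutations = 1000,
                             confidence_ladder = c(0.99, 0.95, 0.90),
                             manual_ladder = c(3.0, 2.5, 2.0),
                             seed = 1L) {
  stopifnot(all(diff(confidence_ladder) < 0), all(diff(manual_ladder) < 0))
  if (n_permutations < 100)
    warning("fewer than 100 permutations gives unstable quantiles")
  structure(list(n_permutations = n_permutations,
                 confidence_ladder = confidence_ladder,
                 manual_ladder = manual_ladder, seed = as.integer(seed)),
            class = "threshold_policy")
}

#' Permutation thresholds for a genome scan
#'
#' The phenotype vector is permuted against the whole-individual genotype
#' vectors (preserving marker correlation), the genome-wide maximum LOD of
#' a cofactor-free Haley-Knott scan is recorded for each permutation, and
#' thresholds are the empirical quantiles at the policy's confidence
#' ladder.  Deterministic given the policy seed.
#'
#' @param scan a `qtl_scan` from [scan_trait()] (its cached scores are
#'   reused, so no re-scan is needed).
#' @param policy a [threshold_policy()].
#' @return list with `thresholds` (named by confidence level), `max_lods`
#'   (the permutation null sample), `n_permutations` and `seed`.
#' @export
permutation_threshold <- function(scan, policy = threshold_policy()) {
  stopifnot(inherits(scan, "qtl_scan"), inherits(policy, "threshold_policy"))
  n <- scan$n
  Y <- withr::with_seed(policy$seed, {
    matrix(scan$y[vapply(seq_len(policy$n_permutations),
                         function(i) sample.int(n), integer(n))],
           n, policy$n_permutations)
  })
  rss0 <- colSums(sweep(Y, 2, colMeans(Y))^2)
  P <- nrow(scan$grid)
  maxlod <- rep(0, policy$n_permutations)
  for (p in seq_len(P)) {
    X <- cbind(1, scan$xa[, p], scan$xd[, p])
    qr_x <- qr(X)
    Q <- qr.Q(qr_x)[, seq_len(qr_x$rank), drop = FALSE]
    resid <- Y - Q %*% crossprod(Q, Y)
    lod <- (n / 2) * log10(rss0 / pmax(colSums(resid^2), 1e-300))
    maxlod <- pmax(maxlod, lod)
  }
  thr <- quantile(maxlod, probs = policy$confidence_ladder, names = FALSE,
                  type = 7)
  list(thresholds = setNames(thr, policy$confidence_ladder),
       max_lods = maxlod, n_permutations = policy$n_permutations,
       seed = policy$seed)
}

#' Percent phenotypic variance explained from a peak LOD
#'
#' The likelihood-R^2 identity `PVE = (1 - 10^(-2 LOD / n)) * 100`.
#'
#' @param lod peak LOD score (>= 0).
#' @param n number of phenotyped individuals (>= 2).
#' @return PVE in percent, strictly below 100.
#' @export
pve <- function(lod, n) {
  stopifnot(all(lod >= 0), n >= 2)
  (1 - 10^(-2 * lod / n)) * 100
}

#' Declare QTL intervals from a scan
#'
#' Maximal contiguous runs of grid positions with `LOD >= threshold`
#' become QTLs.  Each gets its interval extent, peak position and LOD,
#' the Haley-Knott additive (`ADD`, half the homozygote mean difference,
#' signed toward the parent-2 allele) and dominance (`DOM`, heterozygote
#' deviation from the homozygote midpoint) coefficients at the peak, the
#' PVE from the peak LOD, and the mapped markers inside the interval.
#'
#' @param scan a `qtl_scan`.
#' @param threshold LOD threshold.
#' @param map the `genetic_map` the scan ran on (for member markers).
#' @param trait_name short trait tag used in QTL names (default "trait").
#' @return data frame with one row per QTL (possibly zero rows).
#' @export
declare_qtls <- function(scan, threshold, map = NULL, trait_name = "trait") {
  stopifnot(inherits(scan, "qtl_scan"))
  g <- scan$grid
  out <- list()
  for (lg in unique(g$lg)) {
    sub <- g[g$lg == lg, ]
    above <- sub$lod >= threshold
    if (!any(above)) next
    runs <- rle(above)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1
    k <- 0
    for (ri in which(runs$values)) {
      k <- k + 1
      seg <- sub[starts[ri]:ends[ri], ]
      peak <- seg[which.max(seg$lod), ]
      # effects re-estimated at the peak without cofactors: ADD and DOM are
      # defined on the raw genotype contrast, and background cofactors in
      # linkage with the peak would otherwise absorb part of the effect
      pidx <- which(g$lg == peak$lg & g$pos == peak$pos)[1]
      cf <- coef(stats::lm.fit(cbind(1, xa_ = scan$xa[, pidx],
                                     xd_ = scan$xd[, pidx]), scan$y))
      peak$add <- if (is.na(cf["xa_"])) 0 else cf[["xa_"]]
      peak$dom <- if (is.na(cf["xd_"])) 0 else cf[["xd_"]]
      members <- character(0)
      if (!is.null(map)) {
        grp <- map$groups[[lg]]
        members <- grp$marker_id[grp$position_cM >= min(seg$pos) &
                                   grp$position_cM <= max(seg$pos)]
      }
      out[[length(out) + 1]] <- data.frame(
        qtl = sprintf("qtl-%s%d.%d", trait_name, lg, k),
        lg = lg, start_cM = min(seg$pos), end_cM = max(seg$pos),
        peak_cM = peak$pos, peak_lod = peak$lod,
        add = peak$add, dom = peak$dom,
        pve = pve(peak$lod, scan$n),
        n_markers = length(members),
        markers = I(list(members)),
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0)
    return(data.frame(qtl = character(0), lg = integer(0),
                      start_cM = numeric(0), end_cM = numeric(0),
                      peak_cM = numeric(0), peak_lod = numeric(0),
                      add = numeric(0), dom = numeric(0), pve = numeric(0),
                      n_markers = integer(0),
                      markers = I(list())))
  do.call(rbind, out)
}

#' Pick the first threshold rung that declares a QTL
#'
#' Walks the permutation confidence ladder, then the manual fallback
#' ladder, and returns the first threshold at which the scan declares at
#' least one QTL, together with provenance.
#'
#' @param scan a `qtl_scan`.
#' @param perm result of [permutation_threshold()].
#' @param policy the [threshold_policy()] (for the manual ladder).
#' @param map,trait_name passed to [declare_qtls()].
#' @return list with `qtls`, `threshold`, `rung` (e.g. `"0.95"` or
#'   `"manual:2.5"`; `"none"` when nothing is declared anywhere).
#' @export
declare_with_ladder <- function(scan, perm, policy = threshold_policy(),
                                map = NULL, trait_name = "trait") {
  rungs <- c(setNames(perm$thresholds,
                      paste0(names(perm$thresholds))),
             setNames(policy$manual_ladder,
                      paste0("manual:", policy$manual_ladder)))
  for (i in seq_along(rungs)) {
    q <- declare_qtls(scan, rungs[i], map = map, trait_name = trait_name)
    if (nrow(q) > 0)
      return(list(qtls = q, threshold = unname(rungs[i]),
                  rung = names(rungs)[i]))
  }
  list(qtls = declare_qtls(scan, Inf, map = map, trait_name = trait_name),
       threshold = NA_real_, rung = "none")
}
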