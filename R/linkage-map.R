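# Linkage-map construction: MLOD grouping, MST-seeded marker ordering with
# windowed 2-opt refinement, singleton (double-crossover) error blanking,
# k-nearest-neighbour imputation, and Kosambi cumulative positions.

#' Partition markers into linkage groups by MLOD support
#'
#' Single-linkage clustering: markers are the vertices of a graph with an
#' edge wherever the pairwise MLOD exceeds the threshold, and linkage
#' groups are the connected components (any supra-threshold edge joins two
#' clusters).  Groups are reported largest first; ties broken by the
#' lexicographically smallest member id, so the partition does not depend
#' on marker input order.
#'
#' @param mlod symmetric MLOD matrix from [pairwise_linkage()].
#' @param threshold minimum MLOD for an edge (default 5).
#' @return list of character vectors of marker ids, one per group.
#' @export
group_markers <- function(mlod, threshold = 5) {
  if (threshold <= 0) stop("MLOD threshold must be > 0")
  adj <- mlod > threshold
  diag(adj) <- FALSE
  gr <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(gr)
  ids <- rownames(mlod)
  groups <- split(ids, comp$membership)
  groups <- lapply(groups, sort)
  key <- vapply(groups, function(g) g[1], character(1))
  groups <- groups[order(-lengths(groups), key)]
  names(groups) <- NULL
  groups
}

sarf <- function(ord, r) sum(r[cbind(ord[-length(ord)], ord[-1])])

# Order refinement minimizing the sum of adjacent recombination fractions
# (SARF): windowed 2-opt segment reversals interleaved with single-marker
# reinsertion sweeps.  The insertion move relocates markers stranded far
# from their true place by the DFS linearization, which segment reversal
# inside a finite window cannot fix.

# one windowed 2-opt sweep; returns list(ord, improved)
two_opt_pass <- function(ord, r, window) {
  m <- length(ord)
  improved <- FALSE
  for (i in seq_len(m - 1)) {
    for (j in (i + 1):min(i + window - 1, m)) {
      left <- if (i > 1) r[ord[i - 1], ord[j]] - r[ord[i - 1], ord[i]] else 0
      right <- if (j < m) r[ord[i], ord[j + 1]] - r[ord[j], ord[j + 1]] else 0
      if (left + right < -1e-12) {
        ord[i:j] <- ord[j:i]
        improved <- TRUE
      }
    }
  }
  list(ord = ord, improved = improved)
}

# one reinsertion sweep: move each marker to its SARF-optimal slot
insertion_pass <- function(ord, r) {
  m <- length(ord)
  improved <- FALSE
  for (x in seq_len(m)) {
    i <- x
    mk <- ord[i]
    rem <- (if (i > 1) r[ord[i - 1], mk] else 0) +
      (if (i < m) r[mk, ord[i + 1]] else 0) -
      (if (i > 1 && i < m) r[ord[i - 1], ord[i + 1]] else 0)
    rest <- ord[-i]
    # cost of inserting mk before rest[j] (slot j in 1..m); slot m = end
    rleft <- c(0, r[rest, mk])
    rright <- c(r[mk, rest], 0)
    broken <- c(0, r[cbind(rest[-(m - 1)], rest[-1])], 0)
    ins <- rleft + rright - broken
    j <- which.min(ins)
    if (ins[j] < rem - 1e-12) {
      ord <- append(rest, mk, after = j - 1)
      improved <- TRUE
    }
  }
  list(ord = ord, improved = improved)
}

two_opt <- function(ord, r, window = Inf, max_pass = 50) {
  if (length(ord) < 3) return(ord)
  for (pass in seq_len(max_pass)) {
    a <- two_opt_pass(ord, r, window)
    b <- insertion_pass(a$ord, r)
    ord <- b$ord
    if (!a$improved && !b$improved) break
  }
  ord
}

#' Order the markers of one linkage group
#'
#' A minimum spanning tree is built on the complete graph weighted by the
#' pairwise recombination-fraction estimates; a depth-first traversal
#' rooted at one endpoint of the tree's weighted diameter seeds a linear
#' order, which is then refined by windowed 2-opt segment reversals
#' minimizing the sum of adjacent recombination fractions (SARF).  The
#' orientation is canonicalized so the first marker id sorts before the
#' last.
#'
#' @param markers character vector of marker ids (>= 2).
#' @param r pairwise recombination-fraction matrix covering the markers.
#' @param window 2-opt segment window (default `Inf`, i.e. full-length reversals; restrict for very large groups).
#' @return marker ids in map order.
#' @export
order_markers <- function(markers, r, window = Inf) {
  if (length(markers) < 2) return(markers)
  if (length(markers) == 2) return(sort(markers))
  rg <- r[markers, markers]
  if (any(!is.finite(rg))) stop("non-finite recombination fractions in group")
  # epsilon keeps r = 0 edges present in the weighted graph
  gr <- igraph::graph_from_adjacency_matrix(rg + 1e-9, mode = "undirected",
                                            weighted = TRUE, diag = FALSE)
  tree <- igraph::mst(gr, algorithm = "prim")
  dmat <- igraph::distances(tree)
  ends <- which(dmat == max(dmat), arr.ind = TRUE)[1, ]
  ord <- markers[as.integer(igraph::dfs(tree, root = ends[1])$order)]
  ord <- two_opt(ord, rg, window = window)
  if (ord[1] > ord[length(ord)]) ord <- rev(ord)
  ord
}

#' Blank singleton genotypes implying a double crossover
#'
#' A genotyping-error correction in the spirit of SMOOTH: within each
#' individual, a non-missing call whose nearest non-missing neighbours on
#' both sides (within `window` markers along the map order) agree with
#' each other but differ from the focal call would require a double
#' crossover in a short interval, which is far more likely to be a
#' genotyping error.  Such singletons are set to missing — never changed
#' to a different concrete call — and the sweep repeats until stable (at
#' most `max_iter` rounds).  Clean data pass through unchanged.
#'
#' @param geno integer genotype matrix with markers already in map order
#'   (markers x individuals).
#' @param window maximum marker distance to a flanking call (default 5).
#' @param max_iter maximum sweeps (default 10).
#' @return list with `geno` (corrected matrix) and `n_blanked`.
#' @export
smooth_correct <- function(geno, window = 5, max_iter = 10) {
  m <- nrow(geno)
  n_blanked <- 0L
  if (m < 3) return(list(geno = geno, n_blanked = 0L))
  for (it in seq_len(max_iter)) {
    changed <- FALSE
    for (j in seq_len(ncol(geno))) {
      g <- geno[, j]
      nm <- which(!is.na(g))
      if (length(nm) < 3) next
      v <- g[nm]
      k <- length(nm)
      gapL <- c(Inf, diff(nm))
      gapR <- c(diff(nm), Inf)
      lval <- c(NA, v[-k])
      rval <- c(v[-1], NA)
      bad <- gapL <= window & gapR <= window &
        !is.na(lval) & !is.na(rval) & lval == rval & v != lval
      if (any(bad)) {
        geno[nm[bad], j] <- NA_integer_
        n_blanked <- n_blanked + sum(bad)
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  list(geno = geno, n_blanked = n_blanked)
}

#' Impute missing genotypes from the k nearest flanking markers
#'
#' Each missing call is replaced by the majority genotype among the `k`
#' map-nearest non-missing markers of the same individual; ties are broken
#' toward the heterozygote (the F2 modal class).  Individuals missing at
#' every marker of the group are left missing.
#'
#' @param geno integer genotype matrix, markers in map order.
#' @param positions marker positions in cM (same length as `nrow(geno)`).
#' @param k neighbourhood size (default 5).
#' @return completed integer matrix.
#' @export
impute_knn <- function(geno, positions, k = 5) {
  stopifnot(nrow(geno) == length(positions))
  for (j in seq_len(ncol(geno))) {
    g <- geno[, j]
    miss <- which(is.na(g))
    if (length(miss) == 0) next
    nm <- which(!is.na(g))
    if (length(nm) == 0) next
    for (i in miss) {
      d <- abs(positions[nm] - positions[i])
      nb <- g[nm[order(d)[seq_len(min(k, length(nm)))]]]
      tab <- tabulate(nb + 1L, nbins = 3L)
      win <- which(tab == max(tab))
      geno[i, j] <- if (length(win) == 1L) win - 1L else 1L
    }
  }
  geno
}

# cumulative Kosambi positions from adjacent-pair recombination fractions
positions_from_adjacent <- function(geno_ordered) {
  m <- nrow(geno_ordered)
  if (m == 1) return(0)
  d <- numeric(m - 1)
  for (i in seq_len(m - 1)) {
    fit <- estimate_rf_em(geno_ordered[i, ], geno_ordered[i + 1, ])
    d[i] <- kosambi_cm(min(fit$r, 0.4999))
  }
  c(0, cumsum(d))
}

#' Build a genetic map from a QC-passed genotype matrix
#'
#' Runs the full map-construction chain: pairwise recombination fractions
#' and MLOD supports ([pairwise_linkage()]), single-linkage grouping at
#' the MLOD threshold ([group_markers()]), per-group MST ordering
#' ([order_markers()]), singleton blanking ([smooth_correct()]),
#' k-nearest-neighbour imputation ([impute_knn()]), and cumulative Kosambi
#' positions from adjacent-pair recombination fractions.  Groups of a
#' single marker are retained with position 0.
#'
#' If `expected_groups` is supplied and the partition disagrees, the map
#' is still returned as found, with a warning — the threshold, not the
#' requested count, defines the groups.
#'
#' @param x a [geno_matrix()].
#' @param mlod_threshold MLOD grouping threshold (default 5).
#' @param expected_groups optional expected number of linkage groups.
#' @param knn_k imputation neighbourhood (default 5).
#' @param smooth_window singleton-blanking window (default 5).
#' @param order_window 2-opt window (default `Inf`).
#' @param min_informative see [pairwise_linkage()].
#' @return object of class `genetic_map`: list with `groups` (list of data
#'   frames `marker_id`, `position_cM`), `geno` (corrected + imputed
#'   genotypes, markers reordered), `info` (metadata reordered, with `lg`
#'   and `position_cM` added), and `n_blanked`.
#' @export
build_genetic_map <- function(x, mlod_threshold = 5, expected_groups = NULL,
                              knn_k = 5, smooth_window = 5, order_window = Inf,
                              min_informative = 20) {
  stopifnot(inherits(x, "geno_matrix"))
  pl <- pairwise_linkage(x, min_informative = min_informative)
  groups <- group_markers(pl$mlod, threshold = mlod_threshold)
  if (!is.null(expected_groups) && length(groups) != expected_groups)
    warning("single-linkage grouping at MLOD > ", mlod_threshold, " gives ",
            length(groups), " groups, not the expected ", expected_groups)
  out_groups <- vector("list", length(groups))
  geno_blocks <- vector("list", length(groups))
  n_blanked <- 0L
  for (gi in seq_along(groups)) {
    ids <- groups[[gi]]
    ord <- order_markers(ids, pl$r, window = order_window)
    g <- x$geno[ord, , drop = FALSE]
    if (length(ord) >= 3) {
      sm <- smooth_correct(g, window = smooth_window)
      g <- sm$geno
      n_blanked <- n_blanked + sm$n_blanked
    }
    pos <- positions_from_adjacent(g)
    g <- impute_knn(g, pos, k = knn_k)
    # re-estimate distances on the completed data
    pos <- positions_from_adjacent(g)
    out_groups[[gi]] <- data.frame(marker_id = ord, position_cM = pos,
                                   stringsAsFactors = FALSE)
    geno_blocks[[gi]] <- g
  }
  geno <- do.call(rbind, geno_blocks)
  info <- x$info[match(rownames(geno), x$info$marker_id), , drop = FALSE]
  info$lg <- rep(seq_along(out_groups),
                 vapply(out_groups, nrow, integer(1)))
  info$position_cM <- unlist(lapply(out_groups, `[[`, "position_cM"))
  rownames(info) <- NULL
  structure(list(groups = out_groups, geno = geno, info = info,
                 n_blanked = n_blanked,
                 mlod_threshold = mlod_threshold),
            class = "genetic_map")
}

#' @export
print.genetic_map <- function(x, ...) {
  cat(sprintf("genetic_map: %d linkage groups, %d markers\n",
              length(x$groups), nrow(x$geno)))
  s <- map_summary(x)
  print(s, row.names = FALSE)
  invisible(x)
}

#' Per-group and overall map summary
#'
#' For each linkage group: marker count, SNP count (sum of per-marker
#' `snp_count` when available), total map distance, average adjacent
#' distance under the reference convention total / marker count (the
#' per-gap version total / (count - 1) is reported as
#' `avg_dis_per_gap_cM`), the fraction of adjacent gaps <= 5 cM, and the
#' largest gap.
#'
#' @param map a `genetic_map`.
#' @return data frame, one row per group.
#' @seealso [overall_map_stats()] for the totals-and-means row.
#' @export
map_summary <- function(map) {
  stopifnot(inherits(map, "genetic_map"))
  has_snp <- "snp_count" %in% names(map$info)
  rows <- lapply(seq_along(map$groups), function(gi) {
    grp <- map$groups[[gi]]
    pos <- grp$position_cM
    nmk <- nrow(grp)
    gaps <- diff(pos)
    data.frame(
      lg = gi,
      n_markers = nmk,
      n_snp = if (has_snp)
        sum(map$info$snp_count[match(grp$marker_id, map$info$marker_id)])
      else NA_integer_,
      total_dis_cM = max(pos),
      avg_dis_cM = max(pos) / nmk,
      avg_dis_per_gap_cM = if (nmk > 1) max(pos) / (nmk - 1) else 0,
      gaps_le_5 = if (nmk > 1) mean(gaps <= 5) else NA_real_,
      max_gap_cM = if (nmk > 1) max(gaps) else 0)
  })
  do.call(rbind, rows)
}

#' Overall statistics across linkage-group summary rows
#'
#' Works on any per-group summary table with columns `n_markers`, `n_snp`,
#' `total_dis_cM`, `max_gap_cM` (e.g. the output of [map_summary()] or a
#' published per-group table): totals of marker/SNP counts and map length,
#' their per-group means, the map-wide mean adjacent interval under the
#' total-length / marker-count convention, and the mean of the per-group
#' maximum gaps.
#'
#' @param per_group data frame of per-group rows.
#' @return one-row data frame.
#' @export
overall_map_stats <- function(per_group) {
  stopifnot(all(c("n_markers", "total_dis_cM", "max_gap_cM") %in%
                  names(per_group)))
  data.frame(
    n_groups = nrow(per_group),
    total_markers = sum(per_group$n_markers),
    mean_markers = mean(per_group$n_markers),
    total_snp = if ("n_snp" %in% names(per_group)) sum(per_group$n_snp)
                else NA_real_,
    mean_snp = if ("n_snp" %in% names(per_group)) mean(per_group$n_snp)
               else NA_real_,
    total_dis_cM = sum(per_group$total_dis_cM),
    mean_group_length_cM = mean(per_group$total_dis_cM),
    mean_interval_cM = sum(per_group$total_dis_cM) / sum(per_group$n_markers),
    mean_max_gap_cM = mean(per_group$max_gap_cM))
}
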