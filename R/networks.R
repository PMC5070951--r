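# Ratio-pooled summary graphs, cross-talk-aware hyperedge bundling,
# functional-system interaction matrices and hub-degree correlations.

#' Pool significant edges across frequency ratios
#'
#' Union of the significant edges of per-ratio statistical graphs with
#' per-edge ratio provenance; the pooled weight of an edge is the number
#' of ratios in which it is significant ("summing the shared edges
#' across ratios").
#'
#' @param stat_graphs Named list of `stat_graph` objects, one per ratio;
#'   names (or indices) are used as ratio labels.  Each graph's `edges`
#'   data frame must carry `p_low` and `q_high`.
#' @return Object of class `pooled_edges`: list with `edges` (data
#'   frame `p_low`, `q_high`, `weight`), `provenance` (long data frame
#'   `p_low`, `q_high`, `ratio`) and `ratios`.
#' @export
pool_ratios <- function(stat_graphs) {
  labels <- names(stat_graphs)
  if (is.null(labels)) labels <- as.character(seq_along(stat_graphs))
  rows <- list()
  for (i in seq_along(stat_graphs)) {
    g <- stat_graphs[[i]]
    if (is.null(g)) next
    sig <- which(g$significant %in% TRUE)
    if (length(sig) == 0) next
    rows[[length(rows) + 1]] <- data.frame(
      p_low = g$edges$p_low[sig], q_high = g$edges$q_high[sig],
      ratio = labels[i], stringsAsFactors = FALSE)
  }
  if (length(rows) == 0) {
    prov <- data.frame(p_low = integer(), q_high = integer(),
                       ratio = character())
  } else prov <- do.call(rbind, rows)
  key <- paste(prov$p_low, prov$q_high, sep = "-")
  if (nrow(prov) > 0) {
    tab <- table(key)
    uniq <- !duplicated(key)
    edges <- data.frame(p_low = prov$p_low[uniq],
                        q_high = prov$q_high[uniq],
                        weight = as.vector(tab[key[uniq]]))
    edges <- edges[order(edges$p_low, edges$q_high), ]
    rownames(edges) <- NULL
  } else {
    edges <- data.frame(p_low = integer(), q_high = integer(),
                        weight = integer())
  }
  structure(list(edges = edges, provenance = prov, ratios = labels),
            class = "pooled_edges")
}

#' Single-ratio attribution test for a hyperedge
#'
#' Permutation p-value for the dominance of the most frequent ratio
#' among a hyperedge's member edges, against ratio labels drawn without
#' replacement from the pooled edge set.  Hyperedges attributable to a
#' single ratio (small p) are excluded from cross-ratio summary graphs.
#' A single-member hyperedge returns p = 1 (no dominance evidence).
#'
#' @param member_ratios Ratio labels of the hyperedge's member edges.
#' @param pool_ratios_all Ratio labels of all pooled edges (the
#'   permutation urn).
#' @param n_permutations Number of label permutations.
#' @param seed Integer seed.
#' @return Permutation p-value in (0, 1].
#' @export
single_ratio_attribution <- function(member_ratios, pool_ratios_all,
                                     n_permutations = 1000, seed = 1) {
  k <- length(member_ratios)
  if (k <= 1) return(1)
  observed <- max(table(member_ratios))
  perm <- with_seed(seed, vapply(seq_len(n_permutations), function(i) {
    max(table(sample(pool_ratios_all, k)))
  }, numeric(1)))
  (1 + sum(perm >= observed)) / (1 + n_permutations)
}

#' Edge-edge affinity from parcel cross-talk
#'
#' The affinity of two edges is the product of the maximum pairwise
#' cross-talk among their low-frequency endpoints and among their
#' high-frequency endpoints (orientation-respecting); identical
#' endpoints count as cross-talk 1, and self-affinity is 1.  High
#' affinity flags edge pairs likely to reflect the same underlying
#' interaction smeared by signal mixing.
#'
#' @param edges Data frame with `p_low`, `q_high`.
#' @param cross_talk Symmetric parcel x parcel cross-talk matrix
#'   (e.g. `parcel_meta()$cross_talk_matrix`).
#' @return Symmetric affinity matrix in [0, 1], unit diagonal.
#' @export
edge_adjacency <- function(edges, cross_talk) {
  ne <- nrow(edges)
  stop_if_not(!anyNA(cross_talk), "cross-talk matrix has missing values")
  ct_pair <- function(a, b) {
    v <- ifelse(a == b, 1, pmax(cross_talk[cbind(a, b)],
                                cross_talk[cbind(b, a)]))
    v
  }
  aff <- matrix(1, ne, ne)
  if (ne > 1) {
    idx <- which(upper.tri(aff), arr.ind = TRUE)
    lo <- ct_pair(edges$p_low[idx[, 1]], edges$p_low[idx[, 2]])
    hi <- ct_pair(edges$q_high[idx[, 1]], edges$q_high[idx[, 2]])
    aff[idx] <- lo * hi
    aff[idx[, c(2, 1), drop = FALSE]] <- lo * hi
  }
  aff
}

#' Bundle edges into hyperedges by cross-talk affinity
#'
#' Average-linkage agglomerative clustering of edges at distance
#' `1 - affinity`, cut at `cut_height`; bundles smaller than `min_size`
#' are dropped (small bundles are unlikely to reflect a true
#' interaction), and within a surviving bundle, member edges whose
#' end-vertex degree centrality lies below the bundle's
#' `centrality_floor` quantile are discarded.
#'
#' @param affinity Symmetric affinity matrix from [edge_adjacency()].
#' @param edges Data frame with `p_low`, `q_high` (and optionally
#'   `ratio` labels used by attribution tests).
#' @param min_size Minimum bundle size (default 4).
#' @param centrality_floor Quantile below which bundle members are
#'   dropped (default 0.5 = below-median).
#' @param cut_height Dendrogram cut distance (default 0.5).
#' @return List of hyperedges; each is a list with `members` (row
#'   indices into `edges`), `size`, and `dropped` (members removed by
#'   the centrality rule).
#' @export
cluster_hyperedges <- function(affinity, edges, min_size = 4,
                               centrality_floor = 0.5, cut_height = 0.5) {
  ne <- nrow(edges)
  stop_if_not(nrow(affinity) == ne && ncol(affinity) == ne,
              "affinity must be edge x edge")
  if (ne == 0) return(list())
  cl <- if (ne == 1) 1L else {
    hc <- stats::hclust(stats::as.dist(1 - affinity), method = "average")
    stats::cutree(hc, h = cut_height)
  }
  deg <- vertex_degrees(edges)
  centrality <- deg$lf[edges$p_low] + deg$hf[edges$q_high]
  out <- list()
  for (g in sort(unique(cl))) {
    members <- which(cl == g)
    if (length(members) < min_size) next
    floor_val <- stats::quantile(centrality[members], centrality_floor,
                                 type = 1)
    keep <- members[centrality[members] >= floor_val]
    out[[length(out) + 1]] <- list(members = keep,
                                   size = length(keep),
                                   dropped = setdiff(members, keep))
  }
  out
}

# Uniform random directed graph with exactly ne edges (self-loops
# excluded, repeats allowed): the edge-count-preserving randomization
# behind the system-density null.
random_directed_edges <- function(np, ne) {
  pl <- sample.int(np, ne, replace = TRUE)
  qh <- sample.int(np, ne, replace = TRUE)
  redo <- which(pl == qh)
  while (length(redo) > 0) {
    qh[redo] <- sample.int(np, length(redo), replace = TRUE)
    redo <- redo[pl[redo] == qh[redo]]
  }
  list(p_low = pl, q_high = qh)
}

# Degree of each parcel as low-frequency endpoint (lf) and as
# high-frequency endpoint (hf).
vertex_degrees <- function(edges, n_parcels = NULL) {
  if (is.null(n_parcels))
    n_parcels <- max(c(edges$p_low, edges$q_high, 1))
  lf <- tabulate(edges$p_low, nbins = n_parcels)
  hf <- tabulate(edges$q_high, nbins = n_parcels)
  list(lf = lf, hf = hf)
}

#' Select the most central edges of a summary graph
#'
#' Ranks edges by the degree of their low-frequency (or high-frequency)
#' end vertex and keeps the top `n`; ties are broken deterministically
#' by pooled weight (descending) and then lexicographic parcel indices.
#'
#' @param edges Data frame with `p_low`, `q_high` and optionally
#'   `weight`.
#' @param n_edges Number of edges to keep (500 for Mean-condition and
#'   250 for Load-condition visualizations at full scale).
#' @param end `"LF"` or `"HF"`: which end's vertex degree ranks the
#'   edges.
#' @param n_parcels Optional parcel count for degree tabulation.
#' @return Subset of `edges` (with a `rank_degree` column), at most
#'   `n_edges` rows; if `n_edges` exceeds the edge count, all edges are
#'   returned with a message.
#' @export
select_central_edges <- function(edges, n_edges, end = c("LF", "HF"),
                                 n_parcels = NULL) {
  end <- match.arg(end)
  if (n_edges == 0) return(edges[integer(0), , drop = FALSE])
  deg <- vertex_degrees(edges, n_parcels)
  key <- if (end == "LF") deg$lf[edges$p_low] else deg$hf[edges$q_high]
  w <- if ("weight" %in% names(edges)) edges$weight else rep(0, nrow(edges))
  ord <- order(-key, -w, edges$p_low, edges$q_high)
  if (n_edges >= nrow(edges)) {
    message(sprintf("requested %d edges but only %d available",
                    n_edges, nrow(edges)))
    n_edges <- nrow(edges)
  }
  out <- edges[ord[seq_len(n_edges)], , drop = FALSE]
  out$rank_degree <- key[ord[seq_len(n_edges)]]
  rownames(out) <- NULL
  out
}

#' Functional-system interaction densities with randomized-graph nulls
#'
#' Collapses a parcel-level edge set into a directed system-by-system
#' connection-density matrix (rows = system of the low-frequency end)
#' and compares each cell against `n_rand` randomized graphs with the
#' same total edge count (edges re-drawn uniformly among all admissible
#' directed parcel pairs); cells exceeding the stated percentile of
#' their null are flagged significant.
#'
#' @param edges Data frame with `p_low`, `q_high` (parcel indices).
#' @param systems Integer vector: system membership (1..n_systems) per
#'   parcel.
#' @param n_systems Number of systems (default `max(systems)`).
#' @param n_rand Number of randomized graphs.
#' @param percentile Null threshold percentile (0-100).
#' @param seed Integer seed.
#' @return Object of class `system_matrix`: list with `K`, `threshold`,
#'   `significant` (all n_systems x n_systems), `edge_counts`,
#'   `n_rand`.
#' @export
system_density <- function(edges, systems, n_systems = max(systems),
                           n_rand = 5000, percentile = 95, seed = 1) {
  np <- length(systems)
  counts_sys <- tabulate(systems, nbins = n_systems)
  stop_if_not(all(counts_sys > 0), "every system needs at least one parcel")
  possible <- outer(counts_sys, counts_sys)
  diag(possible) <- counts_sys * (counts_sys - 1)
  cell_counts <- function(pl, qh) {
    m <- matrix(0, n_systems, n_systems)
    t <- table(factor(systems[pl], levels = seq_len(n_systems)),
               factor(systems[qh], levels = seq_len(n_systems)))
    m + as.matrix(t)
  }
  obs_counts <- cell_counts(edges$p_low, edges$q_high)
  K <- obs_counts / possible
  ne <- nrow(edges)
  null_q <- with_seed(seed, {
    arr <- array(NA_real_, dim = c(n_systems, n_systems, n_rand))
    for (i in seq_len(n_rand)) {
      rnd <- random_directed_edges(np, ne)
      arr[, , i] <- cell_counts(rnd$p_low, rnd$q_high) / possible
    }
    arr
  })
  thr <- apply(null_q, c(1, 2), stats::quantile, probs = percentile / 100)
  structure(list(K = K, threshold = thr, significant = K > thr,
                 edge_counts = obs_counts, possible = possible,
                 n_rand = n_rand, percentile = percentile),
            class = "system_matrix")
}

#' @export
print.system_matrix <- function(x, ...) {
  cat(sprintf(
    "system_matrix: %d x %d, %d significant cells (%d randomizations)\n",
    nrow(x$K), ncol(x$K), sum(x$significant), x$n_rand))
  invisible(x)
}

#' Hub-degree correlation between cross-frequency and 1:1 networks
#'
#' Pearson correlation across parcels between the low-frequency-end
#' degrees of a cross-frequency graph and the degrees of the 1:1
#' network at `f_low`, and between high-frequency-end degrees and the
#' 1:1 network at `f_high`; p-values Benjamini-Hochberg corrected over
#' the two tests (or the supplied family).
#'
#' @param cfs_edges Data frame with `p_low`, `q_high`.
#' @param ps_edges_low,ps_edges_high Data frames of 1:1 network edges
#'   (any two columns of parcel indices; undirected).
#' @param n_parcels Number of parcels.
#' @return Data frame with rows `LF` and `HF`: `r`, `p`, `p_adj`
#'   (`NA` when a degree vector is constant).
#' @export
degree_correlation <- function(cfs_edges, ps_edges_low, ps_edges_high,
                               n_parcels) {
  deg <- vertex_degrees(cfs_edges, n_parcels)
  und_deg <- function(e) {
    tabulate(e[[1]], nbins = n_parcels) + tabulate(e[[2]], nbins = n_parcels)
  }
  pairs <- list(LF = list(deg$lf, und_deg(ps_edges_low)),
                HF = list(deg$hf, und_deg(ps_edges_high)))
  res <- lapply(pairs, function(pr) {
    if (stats::sd(pr[[1]]) == 0 || stats::sd(pr[[2]]) == 0)
      return(c(r = NA_real_, p = NA_real_))
    ct <- stats::cor.test(pr[[1]], pr[[2]])
    c(r = unname(ct$estimate), p = ct$p.value)
  })
  out <- data.frame(end = names(res),
                    r = vapply(res, `[`, numeric(1), "r"),
                    p = vapply(res, `[`, numeric(1), "p"))
  out$p_adj <- stats::p.adjust(out$p, method = "BH")
  rownames(out) <- NULL
  out
}

#' Degree-similarity matrix of 1:1 networks across frequencies
#'
#' Pearson correlation of parcel degree vectors between every pair of
#' within-frequency (1:1) networks; symmetric with unit diagonal.
#'
#' @param ps_graphs List of edge data frames (undirected 1:1 networks),
#'   one per frequency.
#' @param n_parcels Number of parcels.
#' @return Symmetric correlation matrix (frequency x frequency); `NA`
#'   where a degree vector is constant.
#' @export
cross_frequency_degree_similarity <- function(ps_graphs, n_parcels) {
  degs <- vapply(ps_graphs, function(e) {
    tabulate(e[[1]], nbins = n_parcels) + tabulate(e[[2]], nbins = n_parcels)
  }, numeric(n_parcels))
  nf <- length(ps_graphs)
  r <- suppressWarnings(stats::cor(degs))
  diag(r) <- 1
  r
}
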