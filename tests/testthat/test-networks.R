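mk_graph <- function(sig_edges, np = 6) {
  edges <- expand.grid(p_low = seq_len(np), q_high = seq_len(np))
  edges <- edges[edges$p_low != edges$q_high, ]
  rownames(edges) <- NULL
  sig <- rep(FALSE, nrow(edges))
  for (e in sig_edges) {
    sig[edges$p_low == e[1] & edges$q_high == e[2]] <- TRUE
  }
  g <- list(edges = edges, significant = sig,
            effect = as.numeric(sig), p = ifelse(sig, 0.001, 0.5),
            sign = rep(1, nrow(edges)), n_parcels = np, directed = TRUE)
  class(g) <- "stat_graph"
  g
}

test_that("ratio pooling counts shared edges across ratios", {
  g1 <- mk_graph(list(c(1, 2), c(3, 4)))
  g2 <- mk_graph(list(c(1, 2), c(5, 6)))
  pooled <- pool_ratios(list("2" = g1, "3" = g2))
  e12 <- pooled$edges[pooled$edges$p_low == 1 & pooled$edges$q_high == 2, ]
  expect_equal(e12$weight, 2)
  expect_equal(sum(pooled$edges$weight), 4)
  # disjoint sets: all weights 1
  pooled2 <- pool_ratios(list(mk_graph(list(c(1, 2))),
                              mk_graph(list(c(3, 4)))))
  expect_true(all(pooled2$edges$weight == 1))
  # empty graphs: empty pool
  expect_identical(nrow(pool_ratios(list(mk_graph(list())))$edges), 0L)
})

test_that("single-ratio attribution flags ratio-dominated hyperedges", {
  pool <- rep(c("2", "3", "4", "5"), each = 25)
  p_dom <- single_ratio_attribution(rep("2", 12), pool,
                                    n_permutations = 500, seed = 1)
  expect_lt(p_dom, 0.05)
  p_mix <- single_ratio_attribution(c("2", "3", "4", "5", "2", "3", "4", "5"),
                                    pool, n_permutations = 500, seed = 1)
  expect_gt(p_mix, 0.2)
  expect_identical(single_ratio_attribution("2", pool), 1)
})

test_that("edge affinity multiplies endpoint cross-talk", {
  ct <- matrix(0, 4, 4)
  ct[1, 2] <- ct[2, 1] <- 0.5
  ct[3, 4] <- ct[4, 3] <- 0.4
  diag(ct) <- 1
  edges <- data.frame(p_low = c(1, 2), q_high = c(3, 4))
  aff <- edge_adjacency(edges, ct)
  expect_equal(diag(aff), c(1, 1))
  expect_equal(aff[1, 2], 0.5 * 0.4)
  # identical edges: affinity 1
  same <- data.frame(p_low = c(1, 1), q_high = c(3, 3))
  expect_equal(edge_adjacency(same, ct)[1, 2], 1)
  # zero mutual cross-talk: affinity 0
  far <- data.frame(p_low = c(1, 3), q_high = c(2, 4))
  expect_equal(edge_adjacency(far, ct)[1, 2], 0)
  expect_error(edge_adjacency(edges, matrix(NA_real_, 4, 4)), "missing")
})

test_that("hyperedge clustering respects size and centrality rules", {
  # 5 mutually close edges + 3 isolates
  ne <- 8
  aff <- diag(ne)
  aff[1:5, 1:5] <- 0.9; diag(aff) <- 1
  edges <- data.frame(p_low = c(1, 1, 1, 2, 2, 5, 6, 7),
                      q_high = c(3, 4, 5, 3, 4, 8, 9, 10))
  bundles <- cluster_hyperedges(aff, edges, min_size = 4)
  expect_length(bundles, 1)
  expect_true(all(bundles[[1]]$members %in% 1:5))
  expect_gte(bundles[[1]]$size, 3)
  # all-zero affinity: nothing survives the size rule
  expect_length(cluster_hyperedges(diag(ne), edges, min_size = 4), 0)
  # a 3-edge cluster is dropped at min_size = 4
  aff3 <- diag(3); aff3[] <- 0.9; diag(aff3) <- 1
  expect_length(cluster_hyperedges(aff3, edges[1:3, ], min_size = 4), 0)
  # bundling is invariant to edge input order
  perm <- c(3, 1, 5, 2, 4, 8, 6, 7)
  b2 <- cluster_hyperedges(aff[perm, perm], edges[perm, ], min_size = 4)
  expect_equal(sort(perm[b2[[1]]$members]),
               sort(bundles[[1]]$members))
})

test_that("central-edge selection ranks by end-vertex degree with stable ties", {
  # star on hub 1 (LF end) plus stragglers
  edges <- data.frame(p_low = c(1, 1, 1, 1, 2, 3),
                      q_high = c(2, 3, 4, 5, 6, 6),
                      weight = c(1, 1, 1, 1, 5, 5))
  top4 <- select_central_edges(edges, 4, end = "LF")
  expect_true(all(top4$p_low == 1))
  expect_identical(nrow(select_central_edges(edges, 0)), 0L)
  # two hubs, degree 10 vs 5: only the larger hub's edges selected
  e2 <- data.frame(p_low = rep(c(1, 2), c(10, 5)),
                   q_high = c(2:11, 7:11))
  sel <- select_central_edges(e2, 10, end = "LF")
  expect_true(all(sel$p_low == 1))
  expect_message(select_central_edges(edges, 100), "available")
})

test_that("system densities and their randomized nulls are consistent", {
  systems <- rep(1:3, each = 4)          # 12 parcels, 3 systems
  edges <- data.frame(p_low = c(1, 2, 3, 4), q_high = c(5, 6, 7, 8))
  sm <- system_density(edges, systems, n_rand = 200, seed = 4)
  expect_equal(sm$K[1, 2], 4 / 16)
  expect_equal(sum(sm$edge_counts), nrow(edges))
  expect_true(all(sm$K[-4] == 0))        # only cell (1, 2) is occupied
  expect_equal(sum(sm$K * sm$possible), nrow(edges))
  # the concentrated cell is flagged, empty cells are not
  expect_true(sm$significant[1, 2])
  expect_false(any(sm$significant[-4]))
  expect_error(system_density(edges, c(1, 1, 2), n_systems = 3), "system")

  # edge-count preservation of the randomizer
  set.seed(8)
  for (i in 1:25) {
    rnd <- crossfreq:::random_directed_edges(12, 7)
    expect_length(rnd$p_low, 7)
    expect_true(all(rnd$p_low != rnd$q_high))
  }
})

test_that("degree correlations recover shared hub structure", {
  cfs <- data.frame(p_low = c(1, 1, 1, 2), q_high = c(3, 4, 5, 5))
  ps_low <- data.frame(a = c(1, 1, 1, 2), b = c(2, 3, 4, 4))
  ps_high <- data.frame(a = c(5, 5, 3, 4), b = c(3, 4, 2, 2))
  res <- degree_correlation(cfs, ps_low, ps_high, n_parcels = 5)
  expect_identical(res$end, c("LF", "HF"))
  # oracle Pearson on the degree vectors
  lf_deg <- tabulate(cfs$p_low, 5)
  ps_deg <- tabulate(ps_low$a, 5) + tabulate(ps_low$b, 5)
  expect_equal(res$r[1], oracle_pearson(lf_deg, ps_deg), tolerance = 1e-12)
  expect_true(all(res$p_adj >= res$p))
  # a 1:1 network with the same degree profile as the CFS LF ends
  # gives r = 1
  cfs2 <- data.frame(p_low = c(1, 1, 2, 2), q_high = c(3, 4, 4, 5))
  ps_same <- data.frame(a = c(1, 2), b = c(2, 1))   # degrees (2, 2, 0, 0, 0)
  r1 <- degree_correlation(cfs2, ps_same, ps_same, 5)$r[1]
  expect_equal(r1, 1, tolerance = 1e-12)

  g <- list(data.frame(a = c(1, 1), b = c(2, 3)),
            data.frame(a = c(1, 1), b = c(2, 3)),
            data.frame(a = c(2, 3), b = c(4, 4)))
  sim <- cross_frequency_degree_similarity(g, 4)
  expect_equal(diag(sim), rep(1, 3))
  expect_equal(sim, t(sim))
  expect_equal(sim[1, 2], 1)
})
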