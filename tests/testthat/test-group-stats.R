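test_that("trial equalization subsamples every condition to the minimum", {
  sel <- equalize_trials(c(300, 280, 310), seed = 3)
  expect_true(all(lengths(sel) == 280))
  expect_true(all(vapply(seq_along(sel), function(i) {
    all(sel[[i]] %in% seq_len(c(300, 280, 310)[i]))
  }, logical(1))))
  expect_identical(sel, equalize_trials(c(300, 280, 310), seed = 3))
  expect_identical(lengths(equalize_trials(c(5, 5), seed = 1)), c(5L, 5L))
  expect_error(equalize_trials(c(10, 0)), "zero")
})

test_that("adjacency collapse averages fine entries into coarse cells", {
  meta <- list(fine_to_coarse = c(1, 1, 2, 2), excluded = rep(FALSE, 4))
  m <- matrix(0.5, 4, 4)
  expect_equal(collapse_adjacency(m, meta), matrix(0.5, 2, 2))
  # one fine parcel per coarse parcel: identity
  meta1 <- list(fine_to_coarse = 1:3, excluded = rep(FALSE, 3))
  m3 <- matrix(rnorm(9), 3, 3)
  expect_equal(collapse_adjacency(m3, meta1), m3)
  # a 2 x 2 block with values 0.1 and 0.3 averages to 0.2
  m2 <- matrix(0, 4, 4)
  m2[1:2, 3:4] <- c(0.1, 0.3, 0.3, 0.1)
  expect_equal(collapse_adjacency(m2, meta)[1, 2], 0.2)
  # excluded parcels are dropped from the means
  meta_ex <- list(fine_to_coarse = c(1, 1, 2, 2),
                  excluded = c(FALSE, TRUE, FALSE, FALSE))
  m4 <- matrix(1, 4, 4); m4[2, ] <- 100
  expect_equal(collapse_adjacency(m4, meta_ex), matrix(1, 2, 2))
  expect_error(collapse_adjacency(m, list(fine_to_coarse = c(1, NA, 2, 2),
                                          excluded = rep(FALSE, 4))),
               "coarse")
})

test_that("Mean-condition test equals a paired t-test and is antisymmetric", {
  set.seed(19)
  ns <- 12; ne <- 6
  ret <- matrix(rnorm(ns * ne, 0.2), ns, ne)
  bl <- matrix(rnorm(ns * ne, 0.18), ns, ne)
  g <- mean_condition_test(ret, bl, fdr = "bh")
  for (e in seq_len(ne)) {
    tt <- t.test(ret[, e], bl[, e], paired = TRUE)
    expect_equal(g$p[e], tt$p.value, tolerance = 1e-12)
    d <- ret[, e] - bl[, e]
    expect_equal(g$effect[e], mean(d) / sd(d), tolerance = 1e-12)
  }
  swapped <- mean_condition_test(bl, ret, fdr = "bh")
  expect_equal(swapped$effect, -g$effect, tolerance = 1e-12)

  # identical inputs: indeterminate edges, nothing significant
  same <- mean_condition_test(ret, ret)
  expect_true(all(is.na(same$effect)))
  expect_false(any(same$significant))

  # a planted strong effect is detected
  ret2 <- bl + matrix(rnorm(ns * ne, 0, 0.05), ns, ne)
  ret2[, 3] <- bl[, 3] + 0.1 + rnorm(ns, 0, 0.05)
  g2 <- mean_condition_test(ret2, bl)
  expect_true(g2$significant[3])
  expect_gt(g2$effect[3], 0)
})

test_that("Load-condition test equals a rank-based oracle", {
  set.seed(23)
  ns <- 12; nl <- 6
  x <- array(rnorm(ns * nl * 3), dim = c(ns, nl, 3))
  # edge 2: strictly increasing with load for every subject
  x[, , 2] <- matrix(rep(1:nl, each = ns), ns, nl) + 0.01 * x[, , 2]
  g <- load_condition_test(x, fdr = "bh")
  loads <- rep(1:nl, each = ns)
  for (e in 1:3) {
    expect_equal(g$effect[e], oracle_spearman(as.vector(x[, , e]), loads),
                 tolerance = 1e-10)
  }
  expect_gt(g$effect[2], 0.95)
  expect_true(g$significant[2])
  # deterministic monotone case without noise: rho exactly 1
  x[, , 2] <- matrix(rep(1:nl, each = ns), ns, nl)
  g1 <- load_condition_test(x)
  expect_equal(g1$effect[2], 1, tolerance = 1e-12)
  # constant edges are skipped
  x[, , 3] <- 1
  expect_true(is.na(load_condition_test(x)$effect[3]))
})

test_that("both FDR variants behave as specified", {
  p <- c(0.001, 0.003, 0.04, 0.2, 0.8, 0.01, 0.03, 0.045, 0.5, 0.9)
  bh <- crossfreq:::fdr_significant(p, 0.05, "bh")
  expect_identical(bh, stats::p.adjust(p, "BH") < 0.05)
  # expected_fp: of the 6 edges with p < alpha, ceiling(0.05 * 10) = 1
  # (the largest p among them, 0.045) is removed
  efp <- crossfreq:::fdr_significant(p, 0.05, "expected_fp")
  expect_identical(which(efp), which(p < 0.05 & p != 0.045))
})

test_that("connection density counts significant edges over possible edges", {
  g <- list(significant = rep(FALSE, 148 * 147), n_parcels = 148,
            directed = TRUE)
  class(g) <- "stat_graph"
  expect_equal(connection_density(g), 0)
  g$significant <- rep(TRUE, 148 * 147)
  expect_equal(connection_density(g), 1)
  # 147 significant of 148 * 147 / 2 possible 1:1 edges
  g2 <- list(significant = c(rep(TRUE, 147), rep(FALSE, 148 * 147 / 2 - 147)),
             n_parcels = 148, directed = FALSE)
  class(g2) <- "stat_graph"
  expect_equal(connection_density(g2), 147 / (148 * 147 / 2))
  expect_equal(round(connection_density(g2), 4), 0.0135)
})

test_that("leave-one-out pruning removes single-subject-driven edges", {
  set.seed(31)
  ns <- 8; ne <- 4
  bl <- matrix(rnorm(ns * ne, 0.1, 0.02), ns, ne)
  ret <- bl + matrix(rnorm(ns * ne, 0, 0.01), ns, ne)
  # edge 1: homogeneous strong effect; edge 2: one-subject outlier
  ret[, 1] <- bl[, 1] + 0.1 + rnorm(ns, 0, 0.02)
  ret[, 2] <- bl[, 2] + rnorm(ns, 0, 0.005)
  ret[1, 2] <- bl[1, 2] + 1.5
  base <- mean_condition_test(ret, bl, fdr = "bh")
  pruned <- leave_one_out_mask(list(retention = ret, baseline = bl),
                               base, condition = "mean")
  expect_true(pruned$significant[1])
  expect_false(pruned$significant[2])
  # empty base graph stays empty
  empty <- mean_condition_test(ret, ret + matrix(rnorm(ns * ne), ns, ne))
  empty$significant[] <- FALSE
  out <- leave_one_out_mask(list(retention = ret, baseline = bl), empty,
                            condition = "mean")
  expect_false(any(out$significant))
})

test_that("effect-size mask keeps only strong significant edges", {
  g <- mean_condition_test(matrix(rnorm(40, 1), 10, 4),
                           matrix(rnorm(40), 10, 4), fdr = "bh")
  expect_identical(effect_size_mask(g, 0)$significant, g$significant)
  expect_false(any(effect_size_mask(g, max(abs(g$effect)) + 1)$significant))
  g$effect <- c(0.8, 1.0, 0.95, 0.5)
  g$significant <- rep(TRUE, 4)
  expect_identical(which(effect_size_mask(g, 0.9)$significant), c(2L, 3L))
})

test_that("minimal detectable effect matches noncentral power calculations", {
  d <- minimal_detectable_effect(12, 0.05, 0.8, "one_sample_t")
  expect_equal(round(d, 1), 0.9)
  # agreement with power.t.test as an independent implementation
  ref <- stats::power.t.test(n = 12, sig.level = 0.05, power = 0.8,
                             type = "one.sample")$delta
  expect_equal(d, ref, tolerance = 1e-4)
  expect_equal(minimal_detectable_effect(12, 0.05, 0.05), 0)
  # correlation design shrinks with sample size
  r36 <- minimal_detectable_effect(36, 0.05, 0.8, "correlation")
  r72 <- minimal_detectable_effect(72, 0.05, 0.8, "correlation")
  expect_gt(r36, r72)
  # empirical check: the returned d reaches the target power
  set.seed(5)
  hits <- mean(replicate(2000, {
    t.test(rnorm(12, mean = d))$p.value < 0.05
  }))
  expect_equal(hits, 0.8, tolerance = 0.05)
})

test_that("PLV-amplitude effect correlation and its surrogate band work", {
  set.seed(3)
  eff <- rnorm(40)
  res <- plv_amplitude_effect_correlation(eff, eff, n_surrogates = 200)
  expect_equal(res$r, 1)
  expect_true(res$significant)
  expect_equal(res$r2_signed, 1)
  # oracle equality on 10 fixed pairs
  a <- c(0.12, -0.31, 0.25, 0.07, -0.18, 0.44, -0.02, 0.3, -0.11, 0.21)
  b <- c(0.05, -0.22, 0.19, 0.01, -0.09, 0.38, 0.04, 0.2, -0.15, 0.13)
  res2 <- plv_amplitude_effect_correlation(a, b, n_surrogates = 200)
  expect_equal(res2$r, oracle_pearson(a, b), tolerance = 1e-12)
  # endpoint averaging
  edges <- data.frame(p_low = c(1, 2), q_high = c(3, 4))
  expect_equal(edge_amplitude_effects(c(1, 2, 3, 4), edges), c(2, 3))
  expect_error(plv_amplitude_effect_correlation(a[1:2], b[1:2]), "3 edges")
})
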