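# Group-level edge statistics: retention-vs-baseline (Mean condition),
# memory-load correlation (Load condition), FDR control, connection
# density, robustness masks and power analysis.

#' Equalize trial counts across conditions
#'
#' PLV estimates are biased by the number of observations, so conditions
#' (memory loads) are subsampled without replacement to the smallest
#' per-condition trial count before estimation.
#'
#' @param trial_counts Integer vector of trial counts per condition.
#' @param seed Integer seed for the subsampling.
#' @return List of sorted index vectors, one per condition, all of equal
#'   length `min(trial_counts)`.
#' @export
equalize_trials <- function(trial_counts, seed = 1) {
  stop_if_not(all(trial_counts > 0), "zero trials in some condition")
  nmin <- min(trial_counts)
  with_seed(seed, lapply(trial_counts, function(n) {
    sort(sample.int(n, nmin))
  }))
}

#' Collapse a fine-parcellation adjacency matrix to a coarse one
#'
#' Each coarse entry is the mean of its constituent fine entries
#' (orientation preserved for directed low->high matrices); excluded
#' fine parcels are dropped from the means.
#'
#' @param fine_matrix Square matrix on the fine parcellation.
#' @param meta A [parcel_meta()] (or any list with `fine_to_coarse` and
#'   `excluded`).
#' @return Square matrix on the coarse parcellation; coarse diagonal
#'   retains within-coarse means and is ignored by edge statistics.
#' @export
collapse_adjacency <- function(fine_matrix, meta) {
  f2c <- meta$fine_to_coarse
  stop_if_not(!anyNA(f2c) && length(f2c) == nrow(fine_matrix),
              "every fine parcel must map to a coarse parcel")
  keep <- !meta$excluded
  f2c <- f2c[keep]
  m <- fine_matrix[keep, keep, drop = FALSE]
  g <- factor(f2c, levels = sort(unique(f2c)))
  # row then column group means
  rowagg <- rowsum(m, g) / as.vector(table(g))
  colagg <- t(rowsum(t(rowagg), g) / as.vector(table(g)))
  unname(as.matrix(colagg))
}

# -- FDR ---------------------------------------------------------------

# Two multiple-comparison variants over edge p-values:
#  * "expected_fp": among edges with p < alpha, remove the
#    ceiling(alpha * n_tests) with the largest p -- the expected number
#    of false positives at level alpha ("remove as many of the least
#    significant edges as predicted by the p-value").
#  * "bh": Benjamini-Hochberg adjusted p < alpha.
fdr_significant <- function(p, alpha, method = c("bh", "expected_fp")) {
  method <- match.arg(method)
  ok <- is.finite(p)
  sig <- rep(FALSE, length(p))
  if (method == "bh") {
    sig[ok] <- stats::p.adjust(p[ok], method = "BH") < alpha
  } else {
    cand <- which(ok & p < alpha)
    n_remove <- min(length(cand), ceiling(alpha * sum(ok)))
    if (n_remove > 0 && length(cand) > 0) {
      drop <- cand[order(p[cand], decreasing = TRUE)][seq_len(n_remove)]
      cand <- setdiff(cand, drop)
    }
    sig[cand] <- TRUE
  }
  sig
}

stat_graph <- function(edges, effect, p, significant, alpha, method,
                       condition, n_parcels, directed = TRUE,
                       level = "fine") {
  structure(list(edges = edges, effect = effect, p = p,
                 significant = significant, sign = sign(effect),
                 alpha = alpha, fdr = method, condition = condition,
                 n_parcels = n_parcels, directed = directed,
                 level = level),
            class = "stat_graph")
}

#' @export
print.stat_graph <- function(x, ...) {
  cat(sprintf(
    "stat_graph (%s condition, %s): %d/%d edges significant (alpha = %g, %s FDR)\n",
    x$condition, if (x$directed) "directed" else "undirected",
    sum(x$significant, na.rm = TRUE), length(x$p), x$alpha, x$fdr))
  invisible(x)
}

#' Retention-versus-baseline (Mean condition) edge test
#'
#' Per edge, a paired two-sided t-test of the retention-period coupling
#' (averaged over the two retention windows and all memory loads)
#' against the first pre-stimulus baseline window, across subjects.  The
#' effect size is the mean difference divided by the standard deviation
#' of the difference (paired Cohen's d).  Positive and negative tails
#' are retained with their signs.  Edges with zero difference variance
#' are flagged indeterminate (`NA`).
#'
#' @param retention,baseline Numeric matrices, subject x edge.
#' @param alpha Significance level after FDR control.
#' @param fdr `"bh"` (Benjamini-Hochberg, the default) or
#'   `"expected_fp"` (remove the `ceiling(alpha * n_tests)` least
#'   significant discoveries -- the expected false-positive count).
#'   The latter is only meaningful when the edge count is large
#'   relative to `1 / alpha`; at small edge counts it removes every
#'   discovery.
#' @param edges Optional edge data frame carried through.
#' @param n_parcels,directed Graph bookkeeping for density computations.
#' @return A `stat_graph`.
#' @export
mean_condition_test <- function(retention, baseline, alpha = 0.05,
                                fdr = c("bh", "expected_fp"),
                                edges = NULL, n_parcels = NULL,
                                directed = TRUE) {
  fdr <- match.arg(fdr)
  stop_if_not(all(dim(retention) == dim(baseline)),
              "retention and baseline dimensions differ")
  stop_if_not(nrow(retention) >= 2, "need at least 2 subjects")
  d <- retention - baseline
  mu <- colMeans(d)
  sdd <- apply(d, 2, stats::sd)
  nsub <- nrow(d)
  effect <- ifelse(sdd > 0, mu / sdd, NA_real_)
  tstat <- effect * sqrt(nsub)
  p <- 2 * stats::pt(abs(tstat), df = nsub - 1, lower.tail = FALSE)
  sig <- fdr_significant(p, alpha, fdr)
  if (is.null(n_parcels)) n_parcels <- infer_n_parcels(ncol(d), directed)
  stat_graph(edges, effect, p, sig, alpha, fdr, "mean", n_parcels,
             directed)
}

#' Memory-load (Load condition) edge test
#'
#' Per edge, the Spearman rank correlation between retention-period
#' coupling and memory load over the pooled subject-by-load
#' observations; the effect size is the correlation coefficient.
#' Constant edges are skipped (`NA`).
#'
#' @param x Array subject x load x edge of retention-period coupling.
#' @param loads Numeric vector of memory loads (default `1:n_loads`).
#' @inheritParams mean_condition_test
#' @return A `stat_graph`.
#' @export
load_condition_test <- function(x, loads = NULL, alpha = 0.05,
                                fdr = c("bh", "expected_fp"),
                                edges = NULL, n_parcels = NULL,
                                directed = TRUE) {
  fdr <- match.arg(fdr)
  d <- dim(x)
  stop_if_not(length(d) == 3, "x must be subject x load x edge")
  if (is.null(loads)) loads <- seq_len(d[2])
  lvec <- rep(loads, each = d[1])
  ne <- d[3]
  effect <- p <- rep(NA_real_, ne)
  for (e in seq_len(ne)) {
    v <- as.vector(x[, , e])
    if (stats::sd(v) == 0) next
    ct <- suppressWarnings(
      stats::cor.test(v, lvec, method = "spearman", exact = FALSE))
    effect[e] <- unname(ct$estimate)
    p[e] <- ct$p.value
  }
  sig <- fdr_significant(p, alpha, fdr)
  if (is.null(n_parcels)) n_parcels <- infer_n_parcels(ne, directed)
  stat_graph(edges, effect, p, sig, alpha, fdr, "load", n_parcels,
             directed)
}

infer_n_parcels <- function(n_edges, directed) {
  np <- if (directed) (1 + sqrt(1 + 4 * n_edges)) / 2
        else (1 + sqrt(1 + 8 * n_edges)) / 2
  if (abs(np - round(np)) > 1e-8) return(NA_integer_)
  round(np)
}

#' Connection density
#'
#' The fraction of statistically significant edges among all possible
#' edges of the graph: directed low->high pairs `n (n - 1)` for
#' cross-frequency graphs, unordered pairs `n (n - 1) / 2` for 1:1
#' graphs.  Invariant to parcel relabeling.
#'
#' @param graph A `stat_graph`.
#' @return Density `K` in [0, 1].
#' @export
connection_density <- function(graph) {
  np <- graph$n_parcels
  stop_if_not(!is.na(np), "graph lacks a parcel count")
  possible <- if (graph$directed) np * (np - 1) else np * (np - 1) / 2
  sum(graph$significant, na.rm = TRUE) / possible
}

#' Leave-one-out robustness mask
#'
#' Repeats the edge test on every cohort of `n - 1` subjects and retains
#' only edges that are significant in the base analysis and reach
#' uncorrected `p < alpha` in every leave-one-out cohort, guarding
#' against effects driven by single subjects.
#'
#' @param per_subject For the Mean condition, `list(retention =,
#'   baseline =)` subject x edge matrices; for the Load condition,
#'   `list(x =)` subject x load x edge array (and optionally `loads`).
#' @param base_graph The full-cohort `stat_graph`.
#' @param alpha Per-cohort significance level (uncorrected).
#' @param condition `"mean"` or `"load"`.
#' @return A `stat_graph` with the pruned significance mask.
#' @export
leave_one_out_mask <- function(per_subject, base_graph, alpha = 0.05,
                               condition = c("mean", "load")) {
  condition <- match.arg(condition)
  ns <- if (condition == "mean") nrow(per_subject$retention)
        else dim(per_subject$x)[1]
  stop_if_not(ns >= 3, "need at least 3 subjects for leave-one-out")
  keep <- base_graph$significant
  if (!any(keep, na.rm = TRUE))
    return(stat_graph(base_graph$edges, base_graph$effect, base_graph$p,
                      keep, base_graph$alpha, base_graph$fdr,
                      base_graph$condition, base_graph$n_parcels,
                      base_graph$directed, base_graph$level))
  for (s in seq_len(ns)) {
    g <- if (condition == "mean") {
      mean_condition_test(per_subject$retention[-s, , drop = FALSE],
                          per_subject$baseline[-s, , drop = FALSE],
                          alpha = 1, fdr = "bh",
                          n_parcels = base_graph$n_parcels,
                          directed = base_graph$directed)
    } else {
      load_condition_test(per_subject$x[-s, , , drop = FALSE],
                          loads = per_subject$loads, alpha = 1,
                          fdr = "bh", n_parcels = base_graph$n_parcels,
                          directed = base_graph$directed)
    }
    keep <- keep & !is.na(g$p) & g$p < alpha
  }
  stat_graph(base_graph$edges, base_graph$effect, base_graph$p, keep,
             base_graph$alpha, base_graph$fdr, base_graph$condition,
             base_graph$n_parcels, base_graph$directed, base_graph$level)
}

#' Effect-size mask
#'
#' Retains significant edges whose absolute effect size exceeds a
#' threshold (0.9 for the Mean condition's paired d, 0.35 for the Load
#' condition's correlation coefficient, per the power analysis of a
#' 12-subject design).
#'
#' @param graph A `stat_graph`.
#' @param threshold Minimum absolute effect size.
#' @return A `stat_graph` with the pruned mask.
#' @export
effect_size_mask <- function(graph, threshold) {
  keep <- graph$significant & !is.na(graph$effect) &
    abs(graph$effect) > threshold
  stat_graph(graph$edges, graph$effect, graph$p, keep, graph$alpha,
             graph$fdr, graph$condition, graph$n_parcels, graph$directed,
             graph$level)
}

#' Minimal detectable effect size
#'
#' The smallest effect size reaching a target power in a two-sided test
#' at level `alpha` with `n` subjects, via the noncentral distribution
#' of the test statistic: for `"one_sample_t"` (paired retention-vs-
#' baseline design) the noncentral t with `ncp = d sqrt(n)`; for
#' `"correlation"` the Fisher z approximation with `SE = 1 /
#' sqrt(n - 3)`.
#'
#' @param n Number of subjects (observations for the correlation
#'   design).
#' @param alpha Two-sided significance level.
#' @param power Target power.
#' @param design `"one_sample_t"` or `"correlation"`.
#' @return The minimal effect size (Cohen's d, or correlation r).
#' @export
#' @examples
#' round(minimal_detectable_effect(12, 0.05, 0.8, "one_sample_t"), 1)  # 0.9
minimal_detectable_effect <- function(n, alpha = 0.05, power = 0.8,
                                      design = c("one_sample_t",
                                                 "correlation")) {
  design <- match.arg(design)
  stop_if_not(alpha > 0 && alpha < 1 && power > 0 && power < 1,
              "alpha and power must lie in (0, 1)")
  stop_if_not(n >= 3, "need n >= 3")
  if (power <= alpha) return(0)
  pw <- if (design == "one_sample_t") {
    function(d) {
      df <- n - 1
      crit <- stats::qt(1 - alpha / 2, df)
      ncp <- d * sqrt(n)
      stats::pt(crit, df, ncp, lower.tail = FALSE) +
        stats::pt(-crit, df, ncp)
    }
  } else {
    function(r) {
      se <- 1 / sqrt(n - 3)
      zc <- stats::qnorm(1 - alpha / 2)
      mu <- atanh(r) / se
      stats::pnorm(zc - mu, lower.tail = FALSE) + stats::pnorm(-zc - mu)
    }
  }
  upper <- if (design == "correlation") 1 - 1e-9 else 100
  if (pw(upper) < power)
    stop("target power unreachable for this design", call. = FALSE)
  stats::uniroot(function(e) pw(e) - power, c(1e-9, upper),
                 tol = 1e-10)$root
}

#' Correlation between coupling effects and amplitude effects
#'
#' Pearson correlation across edges between the observed coupling
#' (PLV) effect and the band-amplitude effect, tested against a null of
#' `n_surrogates` random re-assignments of the amplitude effects across
#' edges; significant when the observed r falls in the highest or
#' lowest 2.5 percent of the surrogate values.  Reports `r2_signed =
#' sign(r) * r^2`, the signed fraction of variance explained.
#'
#' @param plv_effects Numeric vector, per edge.
#' @param amp_effects Numeric vector, per edge (endpoint-averaged; see
#'   [edge_amplitude_effects()]).
#' @param n_surrogates Number of shuffles.
#' @param seed Integer seed.
#' @param central Central coverage of the surrogate band (default 0.95).
#' @return List with `r`, `r2_signed`, `significant`, `surrogate_lo`,
#'   `surrogate_hi`.
#' @export
plv_amplitude_effect_correlation <- function(plv_effects, amp_effects,
                                             n_surrogates = 1000,
                                             seed = 1, central = 0.95) {
  stop_if_not(length(plv_effects) == length(amp_effects),
              "effect vectors differ in length")
  ok <- is.finite(plv_effects) & is.finite(amp_effects)
  stop_if_not(sum(ok) >= 3, "need at least 3 edges")
  x <- plv_effects[ok]; y <- amp_effects[ok]
  r <- stats::cor(x, y)
  surr <- with_seed(seed, vapply(seq_len(n_surrogates), function(i) {
    stats::cor(x, sample(y))
  }, numeric(1)))
  tail_p <- (1 - central) / 2
  lo <- unname(stats::quantile(surr, tail_p))
  hi <- unname(stats::quantile(surr, 1 - tail_p))
  list(r = r, r2_signed = sign(r) * r^2, significant = r < lo || r > hi,
       surrogate_lo = lo, surrogate_hi = hi)
}

#' Per-edge amplitude effects from per-parcel effects
#'
#' The amplitude effect of an edge is the mean of its two endpoint
#' parcels' amplitude effects.
#'
#' @param parcel_effects Numeric vector per parcel.
#' @param edges Data frame with `p_low`, `q_high`.
#' @return Numeric vector per edge.
#' @export
edge_amplitude_effects <- function(parcel_effects, edges) {
  (parcel_effects[edges$p_low] + parcel_effects[edges$q_high]) / 2
}
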