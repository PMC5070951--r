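# End-to-end orchestration: simulate -> filter/couple -> group stats ->
# consistency -> networks -> behavior, with TSV/JSON/YAML input-output.

#' Collapse a coupling tensor to the coarse parcellation
#'
#' Rebuilds each (window, load, subject) adjacency matrix on the fine
#' parcellation, collapses it with [collapse_adjacency()] (directional
#' orientation preserved) and re-extracts the directed coarse edge set.
#'
#' @param tensor A [compute_coupling()] result on fine parcels.
#' @param meta A [parcel_meta()].
#' @return A `coupling_tensor` on the coarse parcellation (amplitude
#'   arrays are collapsed by parcel means).
#' @export
collapse_tensor <- function(tensor, meta) {
  d <- dim(tensor$value)
  npc <- length(unique(meta$fine_to_coarse[!meta$excluded]))
  edges_c <- expand.grid(p_low = seq_len(npc), q_high = seq_len(npc))
  edges_c <- edges_c[edges_c$p_low != edges_c$q_high, ]
  rownames(edges_c) <- NULL
  value <- array(NA_real_, dim = c(nrow(edges_c), d[2], d[3], d[4]))
  fine_idx <- cbind(tensor$edges$p_low, tensor$edges$q_high)
  np <- tensor$n_parcels
  keep <- !meta$excluded
  coarse_of <- function(v) {
    g <- factor(meta$fine_to_coarse[keep],
                levels = sort(unique(meta$fine_to_coarse[keep])))
    rowsum(v[keep], g) / as.vector(table(g))
  }
  for (w in seq_len(d[2])) for (l in seq_len(d[3])) for (s in seq_len(d[4])) {
    m <- matrix(NA_real_, np, np)
    m[fine_idx] <- tensor$value[, w, l, s]
    diag(m) <- 0
    mc <- collapse_adjacency(m, meta)
    value[, w, l, s] <- mc[cbind(edges_c$p_low, edges_c$q_high)]
  }
  amp_collapse <- function(a) {
    out <- array(NA_real_, dim = c(npc, d[2], d[3], d[4]))
    for (w in seq_len(d[2])) for (l in seq_len(d[3]))
      for (s in seq_len(d[4])) out[, w, l, s] <- coarse_of(a[, w, l, s])
    out
  }
  structure(list(value = value, edges = edges_c,
                 amp_low = amp_collapse(tensor$amp_low),
                 amp_high = amp_collapse(tensor$amp_high),
                 f_low = tensor$f_low, f_high = tensor$f_high,
                 ratio_m = tensor$ratio_m, metric = tensor$metric,
                 n_obs = tensor$n_obs, n_parcels = npc),
            class = "coupling_tensor")
}

#' Run the full analysis pipeline on a synthetic study
#'
#' Executes simulate -> filter/couple -> group statistics ->
#' consistency -> summary networks -> behavior on one study, for a set
#' of low frequencies and frequency ratios, and optionally writes all
#' stage outputs (TSV edge lists and profiles, JSON manifest with seeds
#' and checksums) to a directory.
#'
#' @param config A [study_config()], or an existing `synthetic_study`.
#' @param truth List of [coupling_spec()]s (ignored when `config` is a
#'   study).
#' @param f_lows Low frequencies to analyze (Hz).
#' @param ratios Integer CFS ratios (default 2:9); ratio 1 (1:1 phase
#'   synchrony) is always added.
#' @param metric Coupling metric for the cross-frequency graphs.
#' @param alpha Edge significance level.
#' @param fdr FDR variant (see [mean_condition_test()]).
#' @param collapse Collapse to the coarse parcellation before
#'   statistics (skipped when the study is generated with
#'   `n_coarse == n_parcels`).
#' @param run_behavior Compute strength-capacity correlations.
#' @param out_dir Optional output directory.
#' @return Object of class `cfs_pipeline`: list with `tensors`,
#'   `mean_graphs`, `load_graphs`, `K` (f_low x ratio densities for the
#'   Mean condition), `consistency`, `pooled`, `systems`, `hyperedges`
#'   (cross-talk bundles of the pooled edges, single-ratio-attributable
#'   bundles removed), `behavior`, `manifest`.  The SNR audit runs
#'   separately via [build_plv_surface()] and [observed_delta_plv()].
#' @export
run_pipeline <- function(config, truth = list(), f_lows, ratios = 2:9,
                         metric = "cfs", alpha = 0.05,
                         fdr = c("bh", "expected_fp"), collapse = TRUE,
                         run_behavior = TRUE, out_dir = NULL) {
  fdr <- match.arg(fdr)
  study <- if (inherits(config, "synthetic_study")) config
           else generate_study(config, truth)
  cfg <- study$config
  do_collapse <- collapse && cfg$n_coarse < cfg$n_parcels
  all_ratios <- sort(unique(c(1L, as.integer(ratios))))
  nyq <- cfg$sampling_rate / 2

  tensors <- list()
  mean_graphs <- list()
  load_graphs <- list()
  K <- matrix(NA_real_, length(f_lows), length(all_ratios),
              dimnames = list(as.character(f_lows),
                              as.character(all_ratios)))
  for (fi in seq_along(f_lows)) {
    for (m in all_ratios) {
      if (m * f_lows[fi] >= nyq || m * f_lows[fi] > 90) next
      key <- sprintf("f%g_m%d", f_lows[fi], m)
      tn <- compute_coupling(study, f_lows[fi], m, metric = metric)
      if (do_collapse) tn <- collapse_tensor(tn, study$meta)
      cs <- condition_summaries(tn)
      mg <- mean_condition_test(cs$retention, cs$baseline, alpha = alpha,
                                fdr = fdr, edges = tn$edges,
                                n_parcels = tn$n_parcels)
      csl <- condition_summaries(tn, average_loads = FALSE)
      lg <- if (cfg$n_loads >= 2) {
        load_condition_test(csl$retention, alpha = alpha, fdr = fdr,
                            edges = tn$edges, n_parcels = tn$n_parcels)
      } else NULL
      tensors[[key]] <- tn
      mean_graphs[[key]] <- mg
      load_graphs[[key]] <- lg
      K[fi, as.character(m)] <- connection_density(mg)
    }
  }

  # consistency over CFS ratios (1:1 excluded)
  cfs_cols <- setdiff(colnames(K), "1")
  consistency <- if (length(f_lows) >= 2 && length(cfs_cols) >= 2) {
    km <- K[, cfs_cols, drop = FALSE]
    km[is.na(km)] <- 0
    consistency_null(km, n_shuffles = 2000, seed = cfg$seed)
  } else NULL

  # ratio-pooled summary graph and system matrix, per f_low pooled
  ct_coarse <- if (do_collapse)
    collapse_adjacency(study$meta$cross_talk_matrix, study$meta)
  else study$meta$cross_talk_matrix
  systems <- if (do_collapse)
    study$meta$coarse_to_system
  else rep_len(seq_len(cfg$n_systems), cfg$n_parcels)
  pooled <- list()
  sysmats <- list()
  hyperedges <- list()
  for (fi in seq_along(f_lows)) {
    keys <- sprintf("f%g_m%d", f_lows[fi], as.integer(cfs_cols))
    keys <- keys[keys %in% names(mean_graphs)]
    if (length(keys) == 0) next
    gset <- mean_graphs[keys]
    names(gset) <- sub(".*_m", "", keys)
    pl <- pool_ratios(gset)
    pooled[[as.character(f_lows[fi])]] <- pl
    if (nrow(pl$edges) > 0) {
      sysmats[[as.character(f_lows[fi])]] <-
        system_density(pl$edges, systems, n_systems = cfg$n_systems,
                       n_rand = 1000, seed = cfg$seed)
    }
    if (nrow(pl$provenance) > 1) {
      aff <- edge_adjacency(pl$provenance, ct_coarse)
      bundles <- cluster_hyperedges(aff, pl$provenance)
      # drop bundles attributable to a single ratio
      bundles <- Filter(function(b) {
        single_ratio_attribution(pl$provenance$ratio[b$members],
                                 pl$provenance$ratio,
                                 seed = cfg$seed) >= 0.05
      }, bundles)
      hyperedges[[as.character(f_lows[fi])]] <- bundles
    }
  }

  behavior_res <- NULL
  if (run_behavior && cfg$n_loads >= 2 && cfg$n_subjects >= 2) {
    cap <- matrix(study$behavior$capacity,
                  nrow = cfg$n_subjects)          # subject x load
    c_prime <- detrend_normalize(cap)
    behavior_res <- list()
    for (fi in seq_along(f_lows)) {
      strengths <- list()
      for (m in setdiff(all_ratios, 1L)) {
        key <- sprintf("f%g_m%d", f_lows[fi], m)
        if (is.null(tensors[[key]])) next
        strengths[[as.character(m)]] <-
          network_strength(tensors[[key]], mean_graphs[[key]])
      }
      if (length(strengths) == 0) next
      grp <- list()
      low_set <- intersect(names(strengths), as.character(2:5))
      high_set <- intersect(names(strengths), as.character(6:9))
      if (length(low_set) > 0) grp$low <- ratio_group_strength(strengths, low_set)
      if (length(high_set) > 0) grp$high <- ratio_group_strength(strengths, high_set)
      grp <- Filter(function(g) stats::sd(g - rowMeans(g)) > 0, grp)
      if (length(grp) == 0) next
      sp <- lapply(grp, detrend_normalize)
      behavior_res[[as.character(f_lows[fi])]] <-
        strength_capacity_correlation(sp, c_prime)
    }
  }

  res <- structure(list(study = study, tensors = tensors,
                        mean_graphs = mean_graphs,
                        load_graphs = load_graphs, K = K,
                        consistency = consistency, pooled = pooled,
                        systems = sysmats, hyperedges = hyperedges,
                        behavior = behavior_res,
                        alpha = alpha, fdr = fdr, f_lows = f_lows,
                        ratios = all_ratios),
                   class = "cfs_pipeline")
  if (!is.null(out_dir)) res$manifest <- write_pipeline(res, out_dir)
  res
}

#' @export
print.cfs_pipeline <- function(x, ...) {
  cat(sprintf(
    "cfs_pipeline: %d frequency/ratio tensors, alpha = %g (%s FDR)\n",
    length(x$tensors), x$alpha, x$fdr))
  cat("Mean-condition connection density K:\n")
  print(round(x$K, 4))
  invisible(x)
}

#' Write a statistical edge graph as a TSV edge list
#'
#' Columns: `p_low`, `q_high`, `effect`, `p`, `significant`, `sign`.
#'
#' @param graph A `stat_graph`.
#' @param path Output file.
#' @return The path, invisibly.
#' @export
write_stat_graph_tsv <- function(graph, path) {
  edges <- graph$edges
  if (is.null(edges)) {
    ne <- length(graph$p)
    edges <- data.frame(p_low = rep(NA_integer_, ne),
                        q_high = rep(NA_integer_, ne))
  }
  df <- data.frame(p_low = edges$p_low, q_high = edges$q_high,
                   effect = graph$effect, p = graph$p,
                   significant = graph$significant, sign = graph$sign)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# Write all pipeline stage outputs + manifest; returns the manifest.
write_pipeline <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character()
  for (key in names(res$mean_graphs)) {
    f <- file.path(out_dir, sprintf("mean_%s.tsv", key))
    write_stat_graph_tsv(res$mean_graphs[[key]], f)
    files <- c(files, f)
    if (!is.null(res$load_graphs[[key]])) {
      f <- file.path(out_dir, sprintf("load_%s.tsv", key))
      write_stat_graph_tsv(res$load_graphs[[key]], f)
      files <- c(files, f)
    }
  }
  kf <- file.path(out_dir, "connection_density.tsv")
  utils::write.table(data.frame(f_low = rownames(res$K), res$K,
                                check.names = FALSE),
                     kf, sep = "\t", quote = FALSE, row.names = FALSE)
  files <- c(files, kf)
  if (!is.null(res$consistency)) {
    cf <- file.path(out_dir, "consistency.tsv")
    utils::write.table(
      data.frame(f_low = res$f_lows, C = res$consistency$C,
                 null_threshold = res$consistency$threshold,
                 significant = res$consistency$significant),
      cf, sep = "\t", quote = FALSE, row.names = FALSE)
    files <- c(files, cf)
  }
  if (!is.null(res$behavior) && length(res$behavior) > 0) {
    bf <- file.path(out_dir, "strength_capacity.tsv")
    bdf <- do.call(rbind, lapply(names(res$behavior), function(fl) {
      cbind(f_low = fl, res$behavior[[fl]])
    }))
    utils::write.table(bdf, bf, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    files <- c(files, bf)
  }
  manifest <- list(
    package = "crossfreq",
    version = as.character(utils::packageVersion("crossfreq")),
    seed = res$study$config$seed,
    alpha = res$alpha, fdr = res$fdr,
    files = lapply(files, function(f) {
      list(path = basename(f), md5 = unname(tools::md5sum(f)))
    }))
  mf <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, mf, auto_unbox = TRUE, pretty = TRUE)
  manifest
}

#' Read a pipeline configuration from YAML
#'
#' Maps a flat YAML document onto [study_config()] arguments; unknown
#' keys raise an error.
#'
#' @param path YAML file.
#' @return A `study_config`.
#' @export
read_study_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(study_config))
  bad <- setdiff(names(vals), known)
  stop_if_not(length(bad) == 0, "unknown config keys: %s",
              paste(bad, collapse = ", "))
  if (!is.null(vals$trial_layout))
    vals$trial_layout <- matrix(unlist(vals$trial_layout), ncol = 2,
                                byrow = TRUE)
  do.call(study_config, vals)
}

#' Write a study configuration to YAML
#'
#' @param config A `study_config`.
#' @param path Output file.
#' @return The path, invisibly.
#' @export
write_study_config <- function(config, path) {
  vals <- unclass(config)
  vals$trial_layout <- lapply(seq_len(nrow(config$trial_layout)),
                              function(i) as.numeric(config$trial_layout[i, ]))
  yaml::write_yaml(vals, path)
  invisible(path)
}
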