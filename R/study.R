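# Multi-subject synthetic studies of coupled narrow-band oscillations.
#
# The generator emulates the statistical structure the downstream
# analysis assumes: trials with pre-stimulus baseline and retention
# windows, narrow-band stochastic oscillations, planted 1:1 / n:m phase
# coupling, phase-amplitude coupling without phase-phase locking,
# amplitude co-modulation, broadband pink noise at a controlled SNR, and
# distance-decaying linear mixing between parcels.

#' Study configuration
#'
#' Defaults describe the emulated experiment: 12 subjects performing a
#' visual working-memory task at 6 memory loads with ~300 trials per
#' load, sampled at 600 Hz, with two pre-stimulus baseline windows and
#' two retention windows at 0.4--0.7 s and 0.7--1.0 s after stimulus
#' onset.  All sizes scale down for simulation studies.
#'
#' @param n_subjects,n_loads,n_trials_per_load,n_parcels Study sizes.
#' @param sampling_rate Sampling rate in Hz.
#' @param trial_layout 4 x 2 matrix of window boundaries in seconds
#'   relative to stimulus onset, rows = (baseline 1, baseline 2,
#'   retention 1, retention 2), non-overlapping and ordered.
#' @param snr Amplitude signal-to-noise ratio of each planted oscillation
#'   against the broadband pink noise (`Inf` = noise-free).
#' @param mixing_width Decay length of inter-parcel mixing in
#'   parcel-index units; 0 disables mixing.
#' @param pad Seconds of extra signal generated before the first and
#'   after the last window so that wavelet filtering has valid support
#'   inside the windows.
#' @param n_coarse Number of coarse parcels the fine parcellation
#'   collapses onto (consecutive grouping).
#' @param n_systems Number of functional systems coarse parcels are
#'   assigned to (cyclic assignment).
#' @param subject_sd SD of the subject-level multiplier on planted
#'   coupling factors (mean 1).
#' @param behavior_link Shift of the hit-rate logit per unit of the
#'   subject coupling ability; 0 unties behavior from coupling.
#' @param hr_l0,hr_k Logistic hit-rate decline parameters: the expected
#'   hit rate at load l is `0.5 + 0.5 * plogis((hr_l0 - l) / hr_k)`,
#'   which stays above chance (0.5) at the highest load.
#' @param morlet_m Morlet parameter used for oscillator generation.
#' @param seed Master seed; every random stream in the study derives
#'   from it deterministically.
#' @return Object of class `study_config`.
#' @export
study_config <- function(n_subjects = 12, n_loads = 6,
                         n_trials_per_load = 300, n_parcels = 400,
                         sampling_rate = 600,
                         trial_layout = rbind(c(-0.6, -0.3), c(-0.3, 0),
                                              c(0.4, 0.7), c(0.7, 1.0)),
                         snr = 1, mixing_width = 1, pad = 0.6,
                         n_coarse = NULL, n_systems = 7,
                         subject_sd = 0.15, behavior_link = 0,
                         hr_l0 = 4.5, hr_k = 1,
                         morlet_m = 5, seed = 1) {
  trial_layout <- as.matrix(trial_layout)
  stop_if_not(nrow(trial_layout) == 4 && ncol(trial_layout) == 2,
              "trial_layout must be a 4 x 2 matrix of window boundaries")
  stop_if_not(all(trial_layout[, 2] > trial_layout[, 1]),
              "window ends must follow their starts")
  stop_if_not(all(diff(as.vector(t(trial_layout))) >= 0),
              "windows must be ordered and non-overlapping")
  stop_if_not(n_loads >= 1 && n_subjects >= 1 && n_trials_per_load >= 1 &&
                n_parcels >= 2, "invalid study sizes")
  stop_if_not(snr > 0, "snr must be positive")
  if (is.null(n_coarse)) n_coarse <- max(1L, round(n_parcels * 148 / 400))
  structure(list(n_subjects = n_subjects, n_loads = n_loads,
                 n_trials_per_load = n_trials_per_load,
                 n_parcels = n_parcels, sampling_rate = sampling_rate,
                 trial_layout = trial_layout, snr = snr,
                 mixing_width = mixing_width, pad = pad,
                 n_coarse = n_coarse, n_systems = n_systems,
                 subject_sd = subject_sd, behavior_link = behavior_link,
                 hr_l0 = hr_l0, hr_k = hr_k,
                 morlet_m = morlet_m, seed = seed),
            class = "study_config")
}

#' Planted coupling specification
#'
#' One ground-truth interaction between two parcels.  Kinds:
#' `"cfs"` plants n:m phase coupling (slow end at `source_parcel`),
#' `"pac"` modulates the fast oscillation's amplitude by the slow phase
#' with no phase-phase injection, `"amp_corr"` co-modulates amplitude
#' envelopes, `"one_to_one"` plants within-frequency phase coupling
#' (`ratio_m` must then be 1).
#'
#' @param source_parcel,target_parcel Parcel indices (slow / fast end).
#' @param f_low Slow frequency in Hz (within 3--90 Hz).
#' @param ratio_m Integer ratio m >= 1; the fast frequency is
#'   `m * f_low` and must not exceed 90 Hz.
#' @param coupling_factor Baseline coupling factor in [0, 1].
#' @param kind Coupling kind (see above).
#' @param load_slope Per-load increment of the coupling factor; the
#'   effective factor at load l is
#'   `coupling_factor + load_slope * (l - 1)`, clipped to [0, 1] with a
#'   warning if clipping occurs.
#' @param windows `"retention"` (coupling active only during retention
#'   windows, the default) or `"all"`.
#' @return Object of class `coupling_spec`.
#' @export
coupling_spec <- function(source_parcel, target_parcel, f_low,
                          ratio_m = 1, coupling_factor = 0.5,
                          kind = c("cfs", "pac", "amp_corr", "one_to_one"),
                          load_slope = 0, windows = c("retention", "all")) {
  kind <- match.arg(kind)
  windows <- match.arg(windows)
  stop_if_not(source_parcel != target_parcel,
              "source and target parcels must differ")
  stop_if_not(f_low >= 3 && f_low <= 90, "f_low must lie within 3-90 Hz")
  stop_if_not(ratio_m >= 1 && ratio_m == round(ratio_m),
              "ratio_m must be a positive integer")
  stop_if_not(ratio_m * f_low <= 90,
              "fast frequency %g Hz exceeds the 90 Hz analysis ceiling",
              ratio_m * f_low)
  stop_if_not(coupling_factor >= 0 && coupling_factor <= 1,
              "coupling_factor must lie in [0, 1]")
  if (kind == "one_to_one")
    stop_if_not(ratio_m == 1, "one_to_one coupling requires ratio_m = 1")
  structure(list(source_parcel = source_parcel,
                 target_parcel = target_parcel, f_low = f_low,
                 ratio_m = ratio_m, coupling_factor = coupling_factor,
                 kind = kind, load_slope = load_slope, windows = windows),
            class = "coupling_spec")
}

# Smooth 0/1 activation profile over the trial time axis for the given
# windows (k x 2 matrix, seconds), with raised-cosine ramps.
window_profile <- function(time, windows, ramp = 0.05) {
  prof <- numeric(length(time))
  for (i in seq_len(nrow(windows))) {
    a <- windows[i, 1]; b <- windows[i, 2]
    up <- (time - (a - ramp)) / ramp
    dn <- ((b + ramp) - time) / ramp
    w <- pmin(pmax(up, 0), 1) * pmin(pmax(dn, 0), 1)
    w <- 0.5 * (1 - cos(pi * pmin(w, 1)))
    prof <- pmax(prof, w)
  }
  prof
}

#' Synthetic parcel metadata from a mixing matrix
#'
#' Derives the reconstruction-quality metrics the real pipeline obtains
#' from forward/inverse simulations, here analytically from the known
#' mixing weights `W` (rows = observed parcels, columns = true sources):
#' the pairwise cross-talk between observed parcels p and q is the cosine
#' similarity of their mixing rows; fidelity is the share of a parcel's
#' own source in its observed signal, `W[p,p] / ||W[p,]||`; scalar
#' cross-talk is the mean phase correlation of an observed parcel with
#' all other true sources; spread is the mean contamination a source
#' emits into other observed parcels.
#'
#' @param config A [study_config()].
#' @param mixing Mixing matrix (defaults to the config's
#'   [mixing_matrix()]).
#' @param exclude_cutoff Parcels with `fidelity / (cross_talk * spread)`
#'   below this value are flagged excluded (default `0`: none).
#' @return Object of class `parcel_meta`: list with `fine_to_coarse`,
#'   `coarse_to_system`, `fidelity`, `cross_talk`, `spread`,
#'   `cross_talk_matrix`, `excluded`.
#' @export
parcel_meta <- function(config, mixing = NULL, exclude_cutoff = 0) {
  np <- config$n_parcels
  if (is.null(mixing)) mixing <- mixing_matrix(np, config$mixing_width)
  rn <- sqrt(rowSums(mixing^2))
  ctm <- (mixing %*% t(mixing)) / outer(rn, rn)
  fidelity <- diag(mixing) / rn
  cross_talk <- vapply(seq_len(np), function(p) {
    mean((mixing[p, -p]) / rn[p])
  }, numeric(1))
  spread <- vapply(seq_len(np), function(p) {
    mean(mixing[-p, p] / rn[-p])
  }, numeric(1))
  fine_to_coarse <- as.integer(ceiling(seq_len(np) * config$n_coarse / np))
  coarse_to_system <- rep_len(seq_len(config$n_systems), config$n_coarse)
  score <- fidelity / pmax(cross_talk * spread, .Machine$double.eps)
  structure(list(fine_to_coarse = fine_to_coarse,
                 coarse_to_system = coarse_to_system,
                 fidelity = fidelity, cross_talk = cross_talk,
                 spread = spread, cross_talk_matrix = ctm,
                 excluded = score < exclude_cutoff),
            class = "parcel_meta")
}

#' Generate a synthetic multi-subject study
#'
#' Assembles broadband real-valued parcel series as sums of band-limited
#' oscillator components plus pink noise, with the interactions listed in
#' `truth` planted per [coupling_spec()], linear mixing between parcels,
#' and per-subject behavioral hit rates that decline logistically with
#' memory load.  Subject-level coupling ability (a multiplier on all
#' planted coupling factors) can optionally shift hit rates via
#' `behavior_link`, planting a strength--capacity association.
#'
#' Every random stream derives deterministically from the master seed, so
#' equal configs give bit-identical studies.
#'
#' @param config A [study_config()].
#' @param truth List of [coupling_spec()] objects.
#' @return Object of class `synthetic_study`: list with `config`,
#'   `truth`, `series` (list `[[subject]][[load]]` of arrays
#'   sample x trial x parcel), `time` (sample times in seconds relative
#'   to stimulus onset), `behavior` (data frame subject, load, hit_rate,
#'   capacity), `meta` (a [parcel_meta()]), `mixing`, and
#'   `subject_ability`.
#' @export
generate_study <- function(config, truth = list()) {
  stop_if_not(inherits(config, "study_config"), "config must be a study_config")
  for (sp in truth) {
    stop_if_not(inherits(sp, "coupling_spec"), "truth must hold coupling_spec objects")
    stop_if_not(sp$source_parcel <= config$n_parcels &&
                  sp$target_parcel <= config$n_parcels,
                "coupling_spec references parcel outside the study")
    f_high <- sp$ratio_m * sp$f_low
    stop_if_not(f_high < config$sampling_rate / 2,
                "planted fast frequency %g Hz at/above Nyquist", f_high)
  }
  fs <- config$sampling_rate
  lay <- config$trial_layout
  t0 <- lay[1, 1] - config$pad
  t1 <- lay[4, 2] + config$pad
  nsamp <- round((t1 - t0) * fs)
  time <- t0 + (seq_len(nsamp) - 1) / fs
  master <- config$seed
  np <- config$n_parcels

  mixing <- mixing_matrix(np, config$mixing_width)
  meta <- parcel_meta(config, mixing)

  ability <- with_seed(stream_seed(master, 999),
                       stats::rnorm(config$n_subjects))
  gmult <- pmax(0, 1 + config$subject_sd * ability)

  # per-edge activation profiles over the trial time axis
  ret_windows <- lay[3:4, , drop = FALSE]
  profiles <- lapply(truth, function(sp) {
    if (sp$windows == "all") rep(1, nsamp)
    else window_profile(time, ret_windows)
  })

  clip_warned <- FALSE
  noise_rms <- if (is.infinite(config$snr)) 0 else
    (1 / sqrt(2)) / config$snr

  series <- vector("list", config$n_subjects)
  for (s in seq_len(config$n_subjects)) {
    series[[s]] <- vector("list", config$n_loads)
    for (l in seq_len(config$n_loads)) {
      arr <- array(0, dim = c(nsamp, config$n_trials_per_load, np))
      for (r in seq_len(config$n_trials_per_load)) {
        sig <- matrix(0, nsamp, np)
        for (e in seq_along(truth)) {
          sp <- truth[[e]]
          c_eff <- sp$coupling_factor + sp$load_slope * (l - 1)
          if ((c_eff < 0 || c_eff > 1) && !clip_warned) {
            warning(sprintf(
              "effective coupling factor %.3f at load %d clipped to [0, 1]",
              c_eff, l), call. = FALSE)
            clip_warned <- TRUE
          }
          c_eff <- min(1, max(0, c_eff)) * gmult[s]
          c_t <- c_eff * profiles[[e]]
          f_hi <- sp$ratio_m * sp$f_low
          x <- generate_oscillation(nsamp, sp$f_low, fs,
                                    seed = stream_seed(master, s, l, r, e, 1),
                                    morlet_m = config$morlet_m)
          y <- generate_oscillation(nsamp, f_hi, fs,
                                    seed = stream_seed(master, s, l, r, e, 2),
                                    morlet_m = config$morlet_m)
          comp <- plant_edge(sp, x, y, c_t)
          sig[, sp$source_parcel] <- sig[, sp$source_parcel] + comp$x_real
          sig[, sp$target_parcel] <- sig[, sp$target_parcel] + comp$y_real
        }
        if (noise_rms > 0) {
          for (p in seq_len(np)) {
            sig[, p] <- sig[, p] + noise_rms *
              pink_noise(nsamp, seed = stream_seed(master, s, l, r, 0, p))
          }
        }
        if (config$mixing_width > 0) sig <- apply_mixing(sig, mixing)
        arr[, r, ] <- sig
      }
      series[[s]][[l]] <- arr
    }
  }

  behavior <- generate_behavior(config, ability)
  structure(list(config = config, truth = truth, series = series,
                 time = time, behavior = behavior, meta = meta,
                 mixing = mixing, subject_ability = ability),
            class = "synthetic_study")
}

# Realize one planted interaction for one trial; returns real-valued
# component series for the source (slow) and target (fast) parcel.
plant_edge <- function(sp, x, y, c_t) {
  if (sp$kind %in% c("cfs", "one_to_one")) {
    z <- inject_cfs(x, y, c_t, sp$ratio_m)
    list(x_real = Re(z$x), y_real = Re(z$y))
  } else if (sp$kind == "pac") {
    # amplitude of the fast oscillation modulated by the slow phase;
    # fast phase untouched -> PAC without phase-phase coupling
    amod <- 1 + c_t * cos(Arg(x))
    list(x_real = Re(unit_amplitude(x)),
         y_real = Re(unit_amplitude(y)) * amod / sqrt(1 + c_t^2 / 2))
  } else {  # amp_corr: share amplitude envelopes, keep phases independent
    ax <- Mod(x); ay <- Mod(y)
    ax <- ax / mean(ax) * mean(ay)
    a_shared <- (1 - c_t) * ay + c_t * ax
    list(x_real = Re(x), y_real = Re(unit_amplitude(y)) * a_shared)
  }
}

# Hit rates: logistic decline with load, above chance at the highest
# load; realized as binomial proportions over the accepted trials.
generate_behavior <- function(config, ability) {
  rows <- expand.grid(subject = seq_len(config$n_subjects),
                      load = seq_len(config$n_loads))
  p <- 0.5 + 0.5 * stats::plogis((config$hr_l0 - rows$load) / config$hr_k +
                                   config$behavior_link * ability[rows$subject])
  hits <- with_seed(stream_seed(config$seed, 998), stats::rbinom(
    nrow(rows), config$n_trials_per_load, p)) / config$n_trials_per_load
  data.frame(subject = rows$subject, load = rows$load, hit_rate = hits,
             capacity = hits * rows$load)
}

#' @export
print.synthetic_study <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "synthetic_study: %d subjects x %d loads x %d trials x %d parcels (%d planted edges)\n",
    cfg$n_subjects, cfg$n_loads, cfg$n_trials_per_load, cfg$n_parcels,
    length(x$truth)))
  invisible(x)
}

#' Sample windows of a study's trial time axis
#'
#' @param study A `synthetic_study`.
#' @return List of 4 integer vectors of sample indices (baseline 1,
#'   baseline 2, retention 1, retention 2).
#' @export
study_windows <- function(study) {
  lay <- study$config$trial_layout
  lapply(seq_len(nrow(lay)), function(i) {
    which(study$time >= lay[i, 1] & study$time < lay[i, 2])
  })
}
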