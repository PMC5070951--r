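# Across-trial coupling estimation over a whole study: the bridge from
# raw parcel series to the group-level edge statistics.

#' Pair low frequencies with ratio-matched high frequencies on a grid
#'
#' For each `f_low` in `frequencies` and ratio `m`, the high frequency is
#' the grid frequency closest to `m * f_low` (on the log scale, matching
#' the grid's spacing); pairs whose target `m * f_low` exceeds `f_max`
#' are excluded.
#'
#' @param frequencies Frequency grid (Hz).
#' @param m Integer ratio.
#' @param f_max Highest admissible frequency (default: top of the grid).
#' @return Data frame with `f_low`, `f_high`, `valid`.
#' @export
ratio_pairs <- function(frequencies, m, f_max = max(frequencies)) {
  target <- m * frequencies
  idx <- vapply(target, function(ft) {
    which.min(abs(log(frequencies) - log(ft)))
  }, integer(1))
  data.frame(f_low = frequencies, f_high = frequencies[idx],
             valid = target <= f_max)
}

#' Across-trial coupling tensor for one frequency pair
#'
#' Filters every trial of a study at `f_low` and `f_high = ratio_m *
#' f_low`, then estimates the requested coupling metric for every
#' ordered parcel pair (slow end first) in each of the four trial
#' windows, separately per memory load and subject.  Trial counts are
#' equalized across loads within each subject before estimation (PLV is
#' biased by the number of observations).  Mean band amplitudes per
#' parcel are recorded alongside for amplitude-confound audits.
#'
#' Metrics: `"cfs"` n:m phase locking (1:1 when `ratio_m = 1`),
#' `"pac"` slow-phase/envelope-phase locking, `"cc"` amplitude
#' correlation.
#'
#' @param study A [generate_study()] result.
#' @param f_low Slow frequency (Hz).
#' @param ratio_m Integer ratio (1 for within-frequency synchrony).
#' @param metric Coupling metric.
#' @param equalize Equalize trial counts across loads (default TRUE).
#' @param mixed Use the mixed (observed) series; no alternative is
#'   stored, argument reserved for future use.
#' @return Object of class `coupling_tensor`: list with `value` (array
#'   edge x window x load x subject), `edges` (data frame `p_low`,
#'   `q_high`), `amp_low`, `amp_high` (arrays parcel x window x load x
#'   subject), `f_low`, `f_high`, `ratio_m`, `metric`, `n_obs`.
#' @export
compute_coupling <- function(study, f_low, ratio_m = 1,
                             metric = c("cfs", "pac", "cc"),
                             equalize = TRUE, mixed = TRUE) {
  metric <- match.arg(metric)
  cfg <- study$config
  fs <- cfg$sampling_rate
  f_high <- ratio_m * f_low
  stop_if_not(f_high < fs / 2, "f_high %g at/above Nyquist", f_high)
  bank <- wavelet_bank(frequencies = sort(unique(c(f_low, f_high))),
                       morlet_m = cfg$morlet_m, sampling_rate = fs)
  np <- cfg$n_parcels
  nl <- cfg$n_loads
  ns <- cfg$n_subjects
  windows <- study_windows(study)
  nw <- length(windows)

  edges <- expand.grid(p_low = seq_len(np), q_high = seq_len(np))
  edges <- edges[edges$p_low != edges$q_high, ]
  rownames(edges) <- NULL
  ne <- nrow(edges)

  n_keep <- if (equalize) {
    min(vapply(seq_len(nl), function(l) dim(study$series[[1]][[l]])[2],
               numeric(1)))
  } else NA
  value <- array(NA_real_, dim = c(ne, nw, nl, ns))
  amp_low <- array(NA_real_, dim = c(np, nw, nl, ns))
  amp_high <- array(NA_real_, dim = c(np, nw, nl, ns))
  n_obs <- array(NA_integer_, dim = c(nw, nl, ns))

  for (s in seq_len(ns)) {
    counts <- vapply(seq_len(nl), function(l) dim(study$series[[s]][[l]])[2],
                     numeric(1))
    sel <- if (equalize) {
      equalize_trials(counts, seed = stream_seed(cfg$seed, 997, s))
    } else lapply(counts, seq_len)
    for (l in seq_len(nl)) {
      arr <- study$series[[s]][[l]][, sel[[l]], , drop = FALSE]
      d <- dim(arr)
      flat <- matrix(arr, nrow = d[1])        # samples x (trial*parcel)
      fser <- filter_series(flat, bank)
      i_lo <- match(f_low, bank$frequencies)
      i_hi <- match(f_high, bank$frequencies)
      zlo <- fser$values[[i_lo]]
      zhi <- fser$values[[i_hi]]
      vmask <- fser$valid[[i_lo]] & fser$valid[[i_hi]]
      env <- NULL
      if (metric == "pac") {
        ep <- envelope_phase(zhi, f_low, f_high, bank)
        env <- ep$values
        vmask <- vmask & ep$valid
      }
      for (w in seq_len(nw)) {
        idx <- windows[[w]][vmask[windows[[w]]]]
        stop_if_not(length(idx) > 0,
                    "window %d has no valid samples after filtering; increase pad",
                    w)
        pick <- function(z) {
          zz <- z[idx, , drop = FALSE]
          dim(zz) <- c(length(idx) * d[2], d[3])   # obs x parcel
          zz
        }
        lo <- pick(zlo); hi <- pick(zhi)
        nobs <- nrow(lo)
        n_obs[w, l, s] <- nobs
        amp_low[, w, l, s] <- colMeans(Mod(lo))
        amp_high[, w, l, s] <- colMeans(Mod(hi))
        cross <- switch(metric,
          cfs = {
            u <- exp(1i * ratio_m * Arg(lo))
            v <- exp(1i * Arg(hi))
            Mod(t(u) %*% Conj(v)) / nobs     # [p_low, q_high]
          },
          pac = {
            u <- exp(1i * Arg(lo))
            v <- exp(1i * Arg(pick(env)))
            Mod(t(u) %*% Conj(v)) / nobs
          },
          cc = {
            zl <- scale(Mod(lo)) * sqrt((nobs - 1) / nobs)
            zh <- scale(Mod(hi)) * sqrt((nobs - 1) / nobs)
            (t(zl) %*% zh) / nobs
          })
        value[, w, l, s] <- cross[cbind(edges$p_low, edges$q_high)]
      }
    }
  }
  structure(list(value = value, edges = edges, amp_low = amp_low,
                 amp_high = amp_high, f_low = f_low, f_high = f_high,
                 ratio_m = ratio_m, metric = metric, n_obs = n_obs,
                 n_parcels = np),
            class = "coupling_tensor")
}

#' @export
print.coupling_tensor <- function(x, ...) {
  d <- dim(x$value)
  cat(sprintf(
    "coupling_tensor (%s, %g -> %g Hz, 1:%d): %d edges x %d windows x %d loads x %d subjects\n",
    x$metric, x$f_low, x$f_high, x$ratio_m, d[1], d[2], d[3], d[4]))
  invisible(x)
}

#' Retention / baseline summaries of a coupling tensor
#'
#' Averages the two retention windows (3, 4) and takes the first
#' baseline window, optionally averaging across loads, yielding the
#' subject-by-edge matrices the Mean-condition test consumes.
#'
#' @param tensor A [compute_coupling()] result.
#' @param average_loads Average across memory loads (Mean condition).
#' @return List with matrices `retention` and `baseline`
#'   (subject x edge), or arrays subject x load x edge when
#'   `average_loads = FALSE`.
#' @export
condition_summaries <- function(tensor, average_loads = TRUE) {
  v <- tensor$value                      # edge x window x load x subject
  ret <- (v[, 3, , , drop = FALSE] + v[, 4, , , drop = FALSE]) / 2
  bl <- v[, 1, , , drop = FALSE]
  ret <- array(ret, dim = dim(v)[c(1, 3, 4)])
  bl <- array(bl, dim = dim(v)[c(1, 3, 4)])
  if (average_loads) {
    list(retention = t(apply(ret, c(1, 3), mean)),   # subject x edge
         baseline = t(apply(bl, c(1, 3), mean)))
  } else {
    list(retention = aperm(ret, c(3, 2, 1)),         # subject x load x edge
         baseline = aperm(bl, c(3, 2, 1)))
  }
}
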