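# Phase-synchrony, phase-amplitude and amplitude-correlation estimators.

coupling_estimate <- function(value, kind, n, m, n_obs,
                              f_low = NA_real_, f_high = NA_real_,
                              window = NA_integer_) {
  structure(list(value = value, kind = kind, n = n, m = m,
                 n_obs = n_obs, f_low = f_low, f_high = f_high,
                 window = window),
            class = "coupling_estimate")
}

#' @export
print.coupling_estimate <- function(x, ...) {
  cat(sprintf("%s estimate (%d:%d): %.4f  [N = %d]\n",
              toupper(x$kind), x$n, x$m, x$value, x$n_obs))
  invisible(x)
}

#' n:m phase-locking value
#'
#' The modulus of the mean unit phasor of the generalized phase
#' difference,
#' \deqn{\mathrm{PLV}_{n:m} = \frac{1}{N}\left| \sum_{r,t}
#'   \exp i\,(m\,\theta_{low}(r,t) - n\,\theta_{high}(r,t)) \right|,}
#' pooled over all valid (trial, sample) observations.  `n = m = 1` gives
#' within-frequency (1:1) phase synchrony.  Amplitudes are discarded:
#' only unit phasors enter the sum.
#'
#' @param theta_low,theta_high Phase series (vectors or matrices with
#'   aligned trial/sample layout), in radians; `NA` marks invalid
#'   samples and is dropped pairwise.
#' @param n,m Positive integer ratio coefficients with
#'   \eqn{n f_{high} = m f_{low}}.
#' @param f_low,f_high Optional frequencies (Hz), recorded in the result.
#' @return A `coupling_estimate` with `value` in [0, 1].
#' @export
#' @examples
#' th <- runif(500, -pi, pi)
#' plv_nm(th, 3 * th, n = 1, m = 3)$value   # exactly 1
plv_nm <- function(theta_low, theta_high, n = 1, m = 1,
                   f_low = NA_real_, f_high = NA_real_) {
  stop_if_not(length(theta_low) == length(theta_high),
              "phase series lengths differ")
  stop_if_not(n >= 1 && m >= 1 && n == round(n) && m == round(m),
              "n and m must be positive integers")
  ok <- is.finite(theta_low) & is.finite(theta_high)
  nobs <- sum(ok)
  if (nobs == 0) stop("no valid phase observations", call. = FALSE)
  v <- Mod(mean(exp(1i * (m * theta_low[ok] - n * theta_high[ok]))))
  coupling_estimate(v, "plv", n, m, nobs, f_low, f_high)
}

#' Phase-amplitude coupling as envelope-phase locking
#'
#' PAC is the 1:1 phase-locking value between the phase of the slow
#' oscillation and the phase of the fast oscillation's amplitude envelope
#' filtered at the slow frequency (see [envelope_phase()]).
#'
#' @param theta_low Slow-band phase series.
#' @param theta_env Envelope-phase series from [envelope_phase()].
#' @inheritParams plv_nm
#' @return A `coupling_estimate` with kind `"pac"`.
#' @export
pac <- function(theta_low, theta_env, f_low = NA_real_, f_high = NA_real_) {
  est <- plv_nm(theta_low, theta_env, n = 1, m = 1,
                f_low = f_low, f_high = f_high)
  est$kind <- "pac"
  est
}

#' Cross-frequency amplitude correlation
#'
#' Pearson correlation CC of two amplitude-envelope series, computed as
#' the mean product of amplitudes z-scored over all valid
#' (trial, sample) observations.
#'
#' @param a_low,a_high Nonnegative amplitude series with aligned layout;
#'   `NA` dropped pairwise.
#' @inheritParams plv_nm
#' @return A `coupling_estimate` with `value` in [-1, 1].
#' @export
amp_correlation <- function(a_low, a_high,
                            f_low = NA_real_, f_high = NA_real_) {
  stop_if_not(length(a_low) == length(a_high),
              "amplitude series lengths differ")
  ok <- is.finite(a_low) & is.finite(a_high)
  nobs <- sum(ok)
  if (nobs < 2) stop("too few valid amplitude observations", call. = FALSE)
  x <- a_low[ok]; y <- a_high[ok]
  sx <- sqrt(mean((x - mean(x))^2)); sy <- sqrt(mean((y - mean(y))^2))
  if (sx == 0 || sy == 0)
    stop("zero-variance amplitude series: correlation undefined",
         call. = FALSE)
  v <- mean((x - mean(x)) / sx * (y - mean(y)) / sy)
  coupling_estimate(v, "cc", 1, 1, nobs, f_low, f_high)
}

#' Sliding-window single-trial phase-locking value
#'
#' Computes the n:m PLV within sliding windows (default 300 ms wide at
#' 50 ms spacing) over the valid span of a single trial.
#'
#' @param theta_low,theta_high Phase vectors for one trial.
#' @param n,m Ratio coefficients.
#' @param fs Sampling rate (Hz).
#' @param window_len Window length in seconds.
#' @param step Window spacing in seconds.
#' @param valid Logical vector of usable samples (default: all finite).
#' @return Data frame with one row per window: `t_start`, `t_center`
#'   (seconds from series start), `plv`, `n_obs`.
#' @export
sliding_plv <- function(theta_low, theta_high, n = 1, m = 1, fs,
                        window_len = 0.3, step = 0.05, valid = NULL) {
  stop_if_not(length(theta_low) == length(theta_high),
              "phase series lengths differ")
  if (is.null(valid)) valid <- is.finite(theta_low) & is.finite(theta_high)
  idx <- which(valid)
  stop_if_not(length(idx) > 0, "no valid samples")
  wlen <- round(window_len * fs)
  stp <- max(1L, round(step * fs))
  first <- min(idx); last <- max(idx)
  starts <- seq.int(first, last - wlen + 1L, by = stp)
  rows <- lapply(starts, function(s) {
    sel <- s:(s + wlen - 1L)
    sel <- sel[valid[sel]]
    if (length(sel) == 0) return(NULL)      # window w/o valid samples
    v <- Mod(mean(exp(1i * (m * theta_low[sel] - n * theta_high[sel]))))
    data.frame(t_start = (s - 1) / fs,
               t_center = (s - 1 + wlen / 2) / fs,
               plv = v, n_obs = length(sel))
  })
  do.call(rbind, rows)
}

#' Time-shift surrogate null distribution
#'
#' Builds the null distribution of a coupling estimator by circularly
#' shifting one series relative to the other by a random lag of 0 to
#' `max_shift` seconds and re-estimating, `n_surrogates` times.  Circular
#' shifting preserves all local features of each series (spectra,
#' autocorrelations, amplitude dynamics) and destroys only their temporal
#' alignment, so the threshold reflects chance-level locking for signals
#' with exactly these single-series properties.
#'
#' For the default PLV estimator the surrogate values at all integer lags
#' are obtained in one pass via the circular cross-correlation of the
#' unit phasor series (FFT), which is exactly equivalent to shifting and
#' re-estimating.
#'
#' @param theta_low,theta_high Phase vectors (one trial or concatenated
#'   valid samples).
#' @param n,m Ratio coefficients for the PLV fast path.
#' @param fs Sampling rate (Hz).
#' @param n_surrogates Number of surrogate realizations.
#' @param max_shift Maximum shift in seconds.
#' @param percentile Null threshold percentile (0-100).
#' @param seed Integer seed for lag sampling.
#' @param estimator Optional function `(theta_low, theta_high) -> value`
#'   evaluated on shifted copies instead of the PLV fast path.
#' @return Object of class `surrogate_null`: list with `observed`,
#'   `threshold`, `percentile`, `surrogates`, `n_surrogates`,
#'   `max_shift`.
#' @export
timeshift_null <- function(theta_low, theta_high, n = 1, m = 1, fs,
                           n_surrogates = 1000, max_shift = 0.3,
                           percentile = 99, seed = 1, estimator = NULL) {
  stop_if_not(length(theta_low) == length(theta_high),
              "phase series lengths differ")
  nt <- length(theta_low)
  max_lag <- round(max_shift * fs)
  stop_if_not(nt > max_lag, "series shorter than the maximum shift")
  # lags drawn uniformly from (0, max_shift]: the zero lag would
  # reproduce the observed alignment and bias the threshold upward
  lags <- with_seed(seed, sample.int(max_lag, n_surrogates,
                                     replace = TRUE))
  if (is.null(estimator)) {
    a <- exp(1i * m * theta_low)
    b <- exp(1i * n * theta_high)
    observed <- Mod(mean(a * Conj(b)))
    # Circular cross-correlation via FFT:
    #   y_s = sum_t a_t conj(b_{t-s});  shifting b forward by lag s
    #   corresponds to y at index (nt - s) mod nt, so
    #   PLV(lag s) = |y_{(nt - s) mod nt}| / nt  -- identical to shifting
    #   b by s samples and re-estimating.
    y <- stats::fft(stats::fft(a) * Conj(stats::fft(b)),
                    inverse = TRUE) / nt
    all_lags <- Mod(y) / nt
    surr <- all_lags[((nt - lags) %% nt) + 1L]
  } else {
    observed <- estimator(theta_low, theta_high)
    surr <- vapply(lags, function(s) {
      estimator(theta_low, theta_high[wrap_index(seq_len(nt) + s, nt)])
    }, numeric(1))
  }
  structure(list(observed = observed,
                 threshold = unname(stats::quantile(surr, percentile / 100,
                                                    type = 7)),
                 percentile = percentile, surrogates = surr,
                 n_surrogates = n_surrogates, max_shift = max_shift),
            class = "surrogate_null")
}

#' @export
print.surrogate_null <- function(x, ...) {
  cat(sprintf(
    "time-shift surrogate null: observed %.4f vs %g%%-ile threshold %.4f (%d surrogates)\n",
    x$observed, x$percentile, x$threshold, x$n_surrogates))
  invisible(x)
}
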