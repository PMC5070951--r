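# Synthetic narrow-band oscillators and coupling injection.
#
# All simulated oscillations are Morlet-filtered uniform white noise:
# stochastic narrow-band processes whose instantaneous frequency drifts
# around the center frequency, like cortical oscillations and unlike
# deterministic sinusoids.

#' Generate a narrow-band stochastic oscillation
#'
#' White noise (uniform in -1..1) filtered with a complex Morlet wavelet
#' at `f`, returned as a complex analytic series of exactly `n_samples`
#' valid samples (the filter roll-in is generated and discarded
#' internally).
#'
#' @param n_samples Number of samples to return.
#' @param f Center frequency (Hz), strictly below Nyquist.
#' @param fs Sampling rate (Hz).
#' @param seed Integer seed; equal seeds give identical series.
#' @param morlet_m Morlet width parameter.
#' @return Complex vector of length `n_samples`.
#' @export
generate_oscillation <- function(n_samples, f, fs, seed = 1, morlet_m = 5) {
  stop_if_not(f > 0 && f < fs / 2,
              "oscillation frequency %g Hz must lie in (0, Nyquist = %g)",
              f, fs / 2)
  bank <- wavelet_bank(frequencies = f, morlet_m = morlet_m,
                       sampling_rate = fs)
  w <- morlet_kernel(f, bank)
  h <- attr(w, "half")
  ntot <- n_samples + 2L * h
  x <- with_seed(seed, stats::runif(ntot, -1, 1))
  y <- convolve_columns(matrix(x, ncol = 1), w)[, 1]
  y[(h + 1L):(h + n_samples)]
}

#' Inject n:m cross-frequency phase coupling into an oscillator pair
#'
#' Couples a slow series `x` (at \eqn{f_1}) and a fast series `y` (at
#' \eqn{f_2 = n f_1}) by injecting a phase-transformed copy of the slow
#' series into the fast one,
#' \deqn{Y' = Y + c \, A_x \exp(i n \varphi_x),}
#' where \eqn{c} is the coupling factor, and then renormalizing both
#' outputs to unit instantaneous amplitude (\eqn{X'_n = X'/|X'|}).  The
#' injected term oscillates at \eqn{n f_1 = f_2}, inside the fast band,
#' and phase-locks the pair at ratio 1:n with locking strength monotone
#' in `c` -- the property the coupling-factor inversion of the SNR audit
#' rests on.
#'
#' With `reciprocal = TRUE` the slow series additionally receives the
#' symmetric term \eqn{X' = X + c \, A_y \exp(i n \varphi_y)}.  That
#' term lies at \eqn{n f_2}, outside both analysis bands; it contributes
#' no phase locking but leaks into the slow phase through the amplitude
#' normalization, which degrades and eventually destroys the
#' monotonicity of PLV in `c`.  It is therefore off by default and
#' provided for completeness only.
#'
#' `c` may be a scalar or a per-sample vector (e.g. nonzero only during a
#' retention window).
#'
#' @param x_low,y_high Complex analytic series of equal length.
#' @param c_factor Coupling factor(s), >= 0.
#' @param n Integer frequency ratio (>= 1).
#' @param reciprocal Also inject into the slow series (see above).
#' @return List with components `x` and `y`, unit-amplitude complex
#'   series.
#' @export
inject_cfs <- function(x_low, y_high, c_factor, n, reciprocal = FALSE) {
  stop_if_not(length(x_low) == length(y_high),
              "series lengths differ (%d vs %d)",
              length(x_low), length(y_high))
  stop_if_not(all(c_factor >= 0), "coupling factor must be >= 0")
  stop_if_not(n >= 1 && n == round(n), "ratio n must be a positive integer")
  if (length(c_factor) != 1L)
    stop_if_not(length(c_factor) == length(x_low),
                "c_factor must be scalar or per-sample")
  phx <- Arg(x_low)
  yp <- y_high + c_factor * Mod(x_low) * exp(1i * n * phx)
  xp <- if (reciprocal) {
    x_low + c_factor * Mod(y_high) * exp(1i * n * Arg(y_high))
  } else x_low
  list(x = unit_amplitude(xp), y = unit_amplitude(yp))
}

# x / |x| with zero-amplitude samples left at zero.
unit_amplitude <- function(x) {
  a <- Mod(x)
  a[a == 0] <- 1
  x / a
}

#' Add band-matched noise at a given signal-to-noise ratio
#'
#' Adds an independent Morlet-filtered, unit-amplitude-normalized noise
#' series scaled by \eqn{s = 1/\mathrm{SNR}}:
#' \eqn{X'' = X + s N_n}.  With `snr = Inf` the input is returned
#' unchanged.
#'
#' @param x Complex series (typically unit amplitude).
#' @param snr Signal-to-noise ratio (> 0; amplitude ratio).
#' @param f Noise band center frequency (Hz).
#' @param fs Sampling rate (Hz).
#' @param seed Integer seed for the noise stream.
#' @param morlet_m Morlet width parameter.
#' @return Complex series of the same length.
#' @export
add_noise <- function(x, snr, f, fs, seed = 1, morlet_m = 5) {
  stop_if_not(is.finite(snr) || is.infinite(snr), "snr must be numeric")
  stop_if_not(snr > 0, "snr must be positive")
  if (is.infinite(snr)) return(x)
  nn <- generate_oscillation(length(x), f, fs, seed = seed,
                             morlet_m = morlet_m)
  x + (1 / snr) * unit_amplitude(nn)
}

#' Distance-decay linear mixing matrix
#'
#' Row-normalized, diagonally dominant mixing weights
#' \eqn{W_{ij} \propto \exp(-|i - j| / \mathrm{width})}, a qualitative
#' stand-in for the distance-dependent cross-talk that source
#' reconstruction leaves between nearby parcels.  `width = 0` gives the
#' identity (no mixing).
#'
#' @param n_parcels Number of parcels.
#' @param width Decay length in parcel-index units (>= 0).
#' @return `n_parcels x n_parcels` matrix with rows summing to 1.
#' @export
mixing_matrix <- function(n_parcels, width = 1) {
  stop_if_not(width >= 0, "mixing width must be >= 0")
  if (width == 0) return(diag(n_parcels))
  d <- abs(outer(seq_len(n_parcels), seq_len(n_parcels), "-"))
  w <- exp(-d / width)
  w / rowSums(w)
}

#' Apply linear mixing across parcels
#'
#' Each output parcel series is the weighted sum of the input parcel
#' series: for a samples-by-parcels matrix `x`, returns `x %*% t(W)`.
#'
#' @param x Numeric or complex matrix, samples in rows, parcels in
#'   columns.
#' @param mixing Square mixing matrix (parcels x parcels), rows = output
#'   parcels.
#' @return Matrix of the same shape.
#' @export
apply_mixing <- function(x, mixing) {
  stop_if_not(is.matrix(mixing) && nrow(mixing) == ncol(mixing),
              "mixing matrix must be square")
  stop_if_not(ncol(x) == nrow(mixing),
              "parcel count mismatch: %d series vs %d x %d matrix",
              ncol(x), nrow(mixing), ncol(mixing))
  x %*% t(mixing)
}

# Pink (1/f) broadband noise via spectral shaping of white noise;
# scaled to unit RMS.
pink_noise <- function(n, seed = 1) {
  x <- with_seed(seed, stats::rnorm(n))
  nfft <- fft_length(n)
  xf <- stats::fft(c(x, rep(0, nfft - n)))
  freq <- c(1, seq_len(nfft - 1))           # avoid DC blow-up
  shape <- 1 / sqrt(pmin(freq, nfft - freq + 1))
  shape[1] <- 0
  y <- Re(stats::fft(xf * shape, inverse = TRUE))[seq_len(n)] / nfft
  y / stats::sd(y)
}
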