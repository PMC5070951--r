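#' Default narrow-band analysis frequencies
#'
#' Returns `n` log-spaced center frequencies between `f_min` and `f_max`,
#' by default 25 frequencies from 3 to 90 Hz, the standard grid for
#' broadband M/EEG connectivity analyses: \eqn{f_i = f_{min} \cdot
#' (f_{max}/f_{min})^{(i-1)/(n-1)}}.
#'
#' @param n Number of frequencies.
#' @param f_min,f_max Band edges in Hz.
#' @return Numeric vector of frequencies in Hz, strictly increasing.
#' @export
#' @examples
#' default_frequencies()[c(1, 25)]  # 3 and 90 Hz
default_frequencies <- function(n = 25, f_min = 3, f_max = 90) {
  stop_if_not(n >= 2 && f_min > 0 && f_max > f_min,
              "need n >= 2 and 0 < f_min < f_max")
  f_min * (f_max / f_min)^((seq_len(n) - 1) / (n - 1))
}

#' Morlet wavelet filter bank
#'
#' Bundles the frequency grid, the Morlet width parameter and the sampling
#' rate.  The Morlet parameter `m` fixes the spectral width of each band,
#' \eqn{\sigma_f = f/m}, and the temporal envelope width
#' \eqn{\sigma_t = 1/(2\pi\sigma_f)}; `m = 5` trades time against
#' frequency resolution as is conventional for cortical oscillations.
#'
#' @param frequencies Center frequencies in Hz (strictly increasing).
#' @param morlet_m Morlet width parameter \eqn{m = f/\sigma_f} (> 0).
#' @param sampling_rate Sampling rate in Hz; all frequencies must lie
#'   below the Nyquist frequency.
#' @return An object of class `wavelet_bank`.
#' @export
wavelet_bank <- function(frequencies = default_frequencies(),
                         morlet_m = 5, sampling_rate = 600) {
  stop_if_not(all(diff(frequencies) > 0), "frequencies must be increasing")
  stop_if_not(morlet_m > 0, "morlet_m must be positive")
  stop_if_not(all(frequencies > 0) &&
                all(frequencies < sampling_rate / 2),
              "frequencies must lie in (0, sampling_rate/2)")
  structure(list(frequencies = frequencies, morlet_m = morlet_m,
                 sampling_rate = sampling_rate),
            class = "wavelet_bank")
}

#' @export
print.wavelet_bank <- function(x, ...) {
  cat(sprintf(
    "Morlet wavelet bank: %d frequencies %.3g-%.3g Hz, m = %g, fs = %g Hz\n",
    length(x$frequencies), min(x$frequencies), max(x$frequencies),
    x$morlet_m, x$sampling_rate))
  invisible(x)
}

#' Complex Morlet kernel
#'
#' Kernel \eqn{w(t,f) = A \exp(-t^2 / 2\sigma_t^2) \exp(2 i \pi f t)} with
#' \eqn{A = (\sigma_t \sqrt{\pi})^{-1/2}}, sampled symmetrically around
#' t = 0 and truncated at \eqn{\pm 5 \sigma_t} (Gaussian tail loss below
#' 1e-5).  The sampled kernel is rescaled to unit energy so that band
#' amplitudes are comparable across frequencies.
#'
#' @param f Center frequency in Hz.
#' @param bank A [wavelet_bank()].
#' @param truncate_sd Half-support in units of \eqn{\sigma_t}.
#' @return Complex vector of odd length `2*half + 1` with attribute
#'   `half` (half-width in samples) and `sigma_t` (seconds).
#' @export
morlet_kernel <- function(f, bank = wavelet_bank(), truncate_sd = 5) {
  fs <- bank$sampling_rate
  stop_if_not(f > 0 && f < fs / 2,
              "frequency %g Hz outside (0, Nyquist = %g Hz)", f, fs / 2)
  sigma_f <- f / bank$morlet_m
  sigma_t <- 1 / (2 * pi * sigma_f)
  half <- max(1L, ceiling(truncate_sd * sigma_t * fs))
  t <- (-half:half) / fs
  w <- exp(-t^2 / (2 * sigma_t^2)) * exp(2i * pi * f * t)
  w <- w / sqrt(sum(Mod(w)^2))       # unit energy
  attr(w, "half") <- half
  attr(w, "sigma_t") <- sigma_t
  w
}

# FFT-based complex convolution of every column of x (real matrix
# n_samples x n_series) with kernel w, aligned so that output sample i is
# centered on input sample i.  Returns complex matrix of the same shape.
convolve_columns <- function(x, w) {
  n <- nrow(x)
  half <- attr(w, "half")
  nk <- length(w)
  stop_if_not(n >= nk, "series length %d shorter than kernel %d", n, nk)
  nfft <- fft_length(n + nk - 1L)
  wf <- stats::fft(c(w, rep(0, nfft - nk)))
  xf <- stats::mvfft(rbind(x, matrix(0, nfft - n, ncol(x))) + 0i)
  y <- stats::mvfft(xf * wf, inverse = TRUE) / nfft
  y[(half + 1L):(half + n), , drop = FALSE]
}

#' Filter series into narrow-band complex analytic form
#'
#' Convolves real-valued series with the complex Morlet kernels of `bank`,
#' yielding per frequency a complex series whose modulus is the
#' instantaneous amplitude and whose argument the instantaneous phase.
#' Samples closer to either series edge than the kernel half-width carry
#' filter roll-in and are flagged invalid; downstream estimators must
#' exclude them rather than use reflected or fabricated data.
#'
#' @param x Real vector or matrix (samples in rows, series in columns).
#' @param bank A [wavelet_bank()].
#' @param frequencies Frequencies to filter at (default: the bank's grid).
#' @return Object of class `filtered_series`: list with `frequencies`,
#'   `values` (list of complex matrices, one per frequency), `valid`
#'   (list of logical vectors flagging usable samples) and
#'   `sampling_rate`.
#' @export
filter_series <- function(x, bank = wavelet_bank(),
                          frequencies = bank$frequencies) {
  if (is.vector(x)) x <- matrix(x, ncol = 1)
  stop_if_not(all(is.finite(x)), "input contains non-finite samples")
  values <- vector("list", length(frequencies))
  valid <- vector("list", length(frequencies))
  n <- nrow(x)
  for (i in seq_along(frequencies)) {
    w <- morlet_kernel(frequencies[i], bank)
    values[[i]] <- convolve_columns(x, w)
    h <- attr(w, "half")
    v <- rep(TRUE, n)
    if (h >= 1) v[c(seq_len(min(h, n)), seq.int(max(1L, n - h + 1L), n))] <- FALSE
    valid[[i]] <- v
  }
  structure(list(frequencies = frequencies, values = values, valid = valid,
                 sampling_rate = bank$sampling_rate),
            class = "filtered_series")
}

#' @export
print.filtered_series <- function(x, ...) {
  cat(sprintf(
    "filtered_series: %d frequencies, %d samples x %d series, fs = %g Hz\n",
    length(x$frequencies), nrow(x$values[[1]]), ncol(x$values[[1]]),
    x$sampling_rate))
  invisible(x)
}

#' Phase of the amplitude envelope (for phase-amplitude coupling)
#'
#' Re-filters the amplitude envelope \eqn{A(t, f_{high})} of a fast band
#' at a slow frequency, \eqn{E(t, f_{low}, f_{high}) = A(t, f_{high})
#' \otimes w(t, f_{low})}; the argument of `E` is the envelope phase used
#' by the PAC estimator.  A constant (unmodulated) envelope has virtually
#' no power at `f_low` after filtering; such samples are returned with a
#' near-zero modulus and the caller may treat PAC as undefined.
#'
#' @param x_high Complex matrix (samples x series) of the fast band, or a
#'   `filtered_series` with a single frequency.
#' @param f_low Envelope-modulation frequency in Hz; must be smaller than
#'   `f_high`.
#' @param f_high Center frequency of the fast band (Hz).
#' @param bank A [wavelet_bank()].
#' @return List with `values` (complex matrix of the filtered envelope),
#'   `valid` (logical vector) -- the envelope phase is `Arg(values)`.
#' @export
envelope_phase <- function(x_high, f_low, f_high, bank = wavelet_bank()) {
  stop_if_not(f_low < f_high, "f_low (%g) must be below f_high (%g)",
              f_low, f_high)
  if (inherits(x_high, "filtered_series")) {
    stop_if_not(length(x_high$frequencies) == 1L,
                "pass a single-frequency filtered_series")
    x_high <- x_high$values[[1]]
  }
  if (is.vector(x_high)) x_high <- matrix(x_high, ncol = 1)
  w <- morlet_kernel(f_low, bank)
  env <- convolve_columns(Mod(x_high), w)
  h <- attr(w, "half")
  n <- nrow(env)
  v <- rep(TRUE, n)
  if (h >= 1) v[c(seq_len(min(h, n)), seq.int(max(1L, n - h + 1L), n))] <- FALSE
  list(values = env, valid = v)
}
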