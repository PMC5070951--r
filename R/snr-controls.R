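# SNR-confound audit: can observed changes in phase locking be explained
# by changes in oscillation amplitude (signal-to-noise) alone?
#
# The machinery: a coupled-oscillator simulator maps (coupling factor c,
# SNR_x, SNR_y) to an expected PLV; apparent SNR (aSNR) estimated from
# amplitude ratios is mapped to simulator SNR through a numerically
# estimated link function; the coupling factor behind an observed PLV is
# inferred by monotone inversion; and the PLV change predicted from the
# SNR change alone is compared with the observed change.

#' Geometric SNR grid
#'
#' Strictly increasing SNR values spaced by a constant factor
#' (`SNR_{i+1} = factor * SNR_i`, default 1.3).
#'
#' @param snr_min Smallest value.
#' @param n Number of values.
#' @param factor Geometric spacing factor.
#' @return Numeric vector.
#' @export
snr_grid <- function(snr_min = 0.25, n = 12, factor = 1.3) {
  stop_if_not(snr_min > 0 && factor > 1, "need snr_min > 0, factor > 1")
  snr_min * factor^(seq_len(n) - 1)
}

# Simulate the canonical coupled pair once: four Morlet-filtered white
# noise series (X, Nx at f1; Y, Ny at f2 = n f1), cross-injected
# coupling at factor c, unit-amplitude normalization, additive noise at
# s = 1/SNR.  Returns the *filtered* components so that noisy
# combinations for many SNR values are formed cheaply by linearity:
# filt(Xn' + s Nn) = filt(Xn') + s filt(Nn).
coupled_components <- function(f1, n, c_factor, n_samples = 1e5,
                               fs = 600, seed = 1, morlet_m = 5) {
  f2 <- n * f1
  x <- generate_oscillation(n_samples, f1, fs, seed = stream_seed(seed, 1),
                            morlet_m = morlet_m)
  y <- generate_oscillation(n_samples, f2, fs, seed = stream_seed(seed, 2),
                            morlet_m = morlet_m)
  nx <- generate_oscillation(n_samples, f1, fs, seed = stream_seed(seed, 3),
                             morlet_m = morlet_m)
  ny <- generate_oscillation(n_samples, f2, fs, seed = stream_seed(seed, 4),
                             morlet_m = morlet_m)
  z <- inject_cfs(x, y, c_factor, n)
  bank1 <- wavelet_bank(frequencies = f1, morlet_m = morlet_m,
                        sampling_rate = fs)
  bank2 <- wavelet_bank(frequencies = f2, morlet_m = morlet_m,
                        sampling_rate = fs)
  refilt <- function(v, bank) {
    fs_ <- filter_series(Re(v), bank)
    list(z = fs_$values[[1]][, 1], valid = fs_$valid[[1]])
  }
  fx <- refilt(z$x, bank1); fy <- refilt(z$y, bank2)
  fnx <- refilt(unit_amplitude(nx), bank1)
  fny <- refilt(unit_amplitude(ny), bank2)
  list(x = fx$z, y = fy$z, nx = fnx$z, ny = fny$z,
       valid = fx$valid & fy$valid & fnx$valid & fny$valid, n = n)
}

# PLV between the noisy coupled components at one (snr_x, snr_y).
components_plv <- function(comp, snr_x, snr_y) {
  sx <- 1 / snr_x; sy <- 1 / snr_y
  xs <- comp$x + sx * comp$nx
  ys <- comp$y + sy * comp$ny
  v <- comp$valid
  Mod(mean(exp(1i * (comp$n * Arg(xs[v]) - Arg(ys[v])))))
}

#' Simulated PLV surface over SNR and coupling factor
#'
#' Simulates the coupled pair for every coupling factor in `c_values`
#' and evaluates the 1:n PLV at every combination of `snr_x` and
#' `snr_y` (grid per [snr_grid()]).  PLV is estimated on the
#' Morlet-refiltered noisy series, mirroring how experimental PLVs are
#' obtained.
#'
#' @param f1 Slow frequency (Hz).
#' @param n Integer frequency ratio (`f2 = n * f1`).
#' @param snr_values SNR grid (used for both axes).
#' @param c_values Coupling-factor grid in [0, 1] (must include enough
#'   points for interpolation; default 0 to 1 in steps of 0.2).
#' @param n_samples Simulation length (1e6 at full scale; 1e5 gives
#'   usable surfaces with wider Monte-Carlo error).
#' @param fs Sampling rate (Hz).
#' @param seed Integer seed.
#' @param morlet_m Morlet parameter.
#' @return Object of class `plv_surface`: list with `plv` (array
#'   c x snr_x x snr_y), `c_values`, `snr_values`, `f1`, `n`.
#' @export
build_plv_surface <- function(f1, n, snr_values = snr_grid(),
                              c_values = seq(0, 1, by = 0.2),
                              n_samples = 1e5, fs = 600, seed = 1,
                              morlet_m = 5) {
  ns <- length(snr_values)
  plv <- array(NA_real_, dim = c(length(c_values), ns, ns))
  for (ci in seq_along(c_values)) {
    comp <- coupled_components(f1, n, c_values[ci], n_samples, fs,
                               seed = stream_seed(seed, ci),
                               morlet_m = morlet_m)
    for (i in seq_len(ns)) for (j in seq_len(ns)) {
      plv[ci, i, j] <- components_plv(comp, snr_values[i], snr_values[j])
    }
  }
  structure(list(plv = plv, c_values = c_values,
                 snr_values = snr_values, f1 = f1, n = n,
                 n_samples = n_samples),
            class = "plv_surface")
}

# Linear interpolation weights of x0 on grid g (clamped to range).
interp_weights <- function(g, x0) {
  x0 <- min(max(x0, g[1]), g[length(g)])
  i <- findInterval(x0, g, all.inside = TRUE)
  w <- (x0 - g[i]) / (g[i + 1] - g[i])
  list(i = i, w = w)
}

#' Interpolate a PLV surface
#'
#' Trilinear interpolation: linear in the coupling factor, bilinear in
#' log-SNR; arguments are clamped to the simulated grid.
#'
#' @param surface A [build_plv_surface()] result.
#' @param c_factor Coupling factor.
#' @param snr_x,snr_y SNR of the slow and fast series.
#' @return Interpolated PLV.
#' @export
plv_surface_lookup <- function(surface, c_factor, snr_x, snr_y) {
  wc <- interp_weights(surface$c_values, c_factor)
  wx <- interp_weights(log(surface$snr_values), log(snr_x))
  wy <- interp_weights(log(surface$snr_values), log(snr_y))
  acc <- 0
  for (dc in 0:1) for (dx in 0:1) for (dy in 0:1) {
    wt <- (if (dc == 1) wc$w else 1 - wc$w) *
          (if (dx == 1) wx$w else 1 - wx$w) *
          (if (dy == 1) wy$w else 1 - wy$w)
    acc <- acc + wt * surface$plv[wc$i + dc, wx$i + dx, wy$i + dy]
  }
  acc
}

#' Apparent signal-to-noise ratio
#'
#' \deqn{\mathrm{aSNR} = \frac{1}{N_s N_p} \sum_s \sum_p
#'   \frac{A_{exp,s,p} - A_{noise,s,p}}{A_{noise,s,p}}}
#' comparing mean band amplitudes of task data against noise-only
#' (empty-room) data per subject and parcel.
#'
#' @param a_exp Matrix (or vector) of experimental mean amplitudes.
#' @param a_noise Matching noise-only mean amplitudes (> 0).
#' @return List with `per_cell` (same shape as the input) and `asnr`
#'   (the average).
#' @export
asnr <- function(a_exp, a_noise) {
  stop_if_not(length(a_exp) == length(a_noise),
              "amplitude arrays differ in shape")
  stop_if_not(all(a_noise > 0), "noise amplitudes must be positive")
  per_cell <- (a_exp - a_noise) / a_noise
  list(per_cell = per_cell, asnr = mean(per_cell))
}

#' Numerical aSNR-to-SNR link table
#'
#' Simulates a unit-amplitude oscillation plus scaled unit-amplitude
#' noise for every SNR on the grid and records the apparent SNR
#' `(A_{S+N} - A_N) / A_N`; the link is monotone increasing and is
#' inverted by [asnr_to_snr()].
#'
#' @param snr_values SNR grid.
#' @param f Oscillation frequency (Hz).
#' @param n_samples Simulation length.
#' @param fs Sampling rate (Hz).
#' @param seed Integer seed.
#' @return Data frame with `snr`, `asnr`, strictly increasing in both
#'   columns.
#' @export
build_asnr_table <- function(snr_values = snr_grid(), f = 10,
                             n_samples = 1e5, fs = 600, seed = 1) {
  x <- unit_amplitude(generate_oscillation(n_samples, f, fs,
                                           seed = stream_seed(seed, 1)))
  nn <- unit_amplitude(generate_oscillation(n_samples, f, fs,
                                            seed = stream_seed(seed, 2)))
  vals <- vapply(snr_values, function(snr) {
    s <- 1 / snr
    a_sn <- mean(Mod(x + s * nn))
    a_n <- mean(Mod(s * nn))
    (a_sn - a_n) / a_n
  }, numeric(1))
  data.frame(snr = snr_values, asnr = vals)
}

#' Map apparent SNR to simulator SNR
#'
#' Monotone linear interpolation of the simulated link table in
#' (aSNR, log SNR).  Values below the simulated range raise an error;
#' values above it are clamped to the top of the table with a warning
#' (extrapolation flag).
#'
#' @param asnr_value Apparent SNR estimate.
#' @param table A [build_asnr_table()] result.
#' @return SNR value.
#' @export
asnr_to_snr <- function(asnr_value, table) {
  stop_if_not(all(diff(table$asnr) > 0), "link table must be increasing")
  stop_if_not(asnr_value >= min(table$asnr),
              "aSNR %.3g below the simulated range (min %.3g)",
              asnr_value, min(table$asnr))
  if (asnr_value > max(table$asnr)) {
    warning("aSNR above the simulated range; clamped", call. = FALSE)
    return(max(table$snr))
  }
  exp(stats::approx(table$asnr, log(table$snr), xout = asnr_value)$y)
}

#' Infer the coupling factor behind an observed PLV
#'
#' Inverts the simulated PLV surface at fixed SNRs by monotone
#' interpolation over the coupling-factor axis.  Observations above the
#' surface maximum are clipped to the largest simulated factor with a
#' warning; observations at or below the chance level map to c = 0.
#'
#' @param plv_obs Observed PLV.
#' @param snr_x,snr_y SNR of the two series.
#' @param surface A [build_plv_surface()] result.
#' @return Coupling factor in `[min(c_values), max(c_values)]`.
#' @export
infer_coupling_factor <- function(plv_obs, snr_x, snr_y, surface) {
  g <- vapply(surface$c_values, function(cv) {
    plv_surface_lookup(surface, cv, snr_x, snr_y)
  }, numeric(1))
  g <- cummax(g)                          # enforce monotone inversion
  if (plv_obs <= g[1]) return(surface$c_values[1])
  if (plv_obs >= g[length(g)]) {
    warning("observed PLV above the simulated surface; coupling clipped",
            call. = FALSE)
    return(surface$c_values[length(g)])
  }
  stats::approx(g, surface$c_values, xout = plv_obs, ties = "ordered")$y
}

#' PLV change predicted from an SNR change alone
#'
#' Surface lookup at the modulated SNRs minus the lookup at the initial
#' SNRs, at a fixed inferred coupling factor:
#' \eqn{\Delta PLV_{pred} = PLV_{sim}(c, SNR_{mod}) -
#' PLV_{sim}(c, SNR_{init})}.
#'
#' @param c_factor Inferred coupling factor.
#' @param snr_init,snr_mod Length-2 vectors `(snr_x, snr_y)` for the
#'   initial and modulated condition.
#' @param surface A [build_plv_surface()] result.
#' @return Predicted PLV change.
#' @export
predicted_delta_plv <- function(c_factor, snr_init, snr_mod, surface) {
  rng <- range(surface$snr_values)
  stop_if_not(all(c(snr_init, snr_mod) >= rng[1] - 1e-12) &&
                all(c(snr_init, snr_mod) <= rng[2] + 1e-12),
              "SNR outside the simulated grid")
  plv_surface_lookup(surface, c_factor, snr_mod[1], snr_mod[2]) -
    plv_surface_lookup(surface, c_factor, snr_init[1], snr_init[2])
}

#' Observed PLV change per edge
#'
#' Mean condition: mean over subjects and loads of the retention-period
#' PLV (average of the two retention windows) minus the first-baseline
#' PLV.  Load condition: mean over subjects of the highest-load
#' retention PLV minus the lowest-load retention PLV.
#'
#' @param tensor A [compute_coupling()] result.
#' @param condition `"mean"` or `"load"`.
#' @return Numeric vector per edge (aligned with `tensor$edges`).
#' @export
observed_delta_plv <- function(tensor, condition = c("mean", "load")) {
  condition <- match.arg(condition)
  v <- tensor$value                        # edge x window x load x subject
  ret <- (v[, 3, , , drop = FALSE] + v[, 4, , , drop = FALSE]) / 2
  ret <- array(ret, dim(v)[c(1, 3, 4)])    # edge x load x subject
  if (condition == "mean") {
    bl <- array(v[, 1, , , drop = FALSE], dim(v)[c(1, 3, 4)])
    apply(ret - bl, 1, mean)
  } else {
    nl <- dim(ret)[2]
    stop_if_not(nl >= 2, "load condition needs at least 2 loads")
    apply(ret[, nl, , drop = FALSE] - ret[, 1, , drop = FALSE], 1, mean)
  }
}

#' Indices of the largest observed PLV changes
#'
#' The audit focuses on the edges with the largest observed change
#' (200 at full scale).
#'
#' @param delta Numeric vector of observed changes.
#' @param top_n Number of edges to keep.
#' @return Integer indices, sorted by decreasing change.
#' @export
top_delta_edges <- function(delta, top_n = 200) {
  ord <- order(delta, decreasing = TRUE)
  ord[seq_len(min(top_n, length(delta)))]
}
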