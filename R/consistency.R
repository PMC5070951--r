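# Harmonic consistency of connection density across frequency ratios.

#' Harmonic consistency of per-ratio connection densities
#'
#' \deqn{C = \bar K \cdot \exp\!\left(- \frac{\sum_m |K_m - \bar K|}
#'   {N \bar K}\right)}
#' where the `K_m` are the connection densities of one low frequency at
#' each of the `N` ratios and \eqn{\bar K} their mean.  `C` equals
#' \eqn{\bar K} when density is identical across ratios and shrinks as
#' the densities concentrate on few ratios; `C = 0` when all densities
#' are zero (degenerate case).
#'
#' @param k_values Numeric vector of per-ratio densities in [0, 1]
#'   (length >= 2).
#' @return Consistency `C` (scalar, `0 <= C <= mean(k_values)`).
#' @export
#' @examples
#' harmonic_consistency(rep(0.1, 8))                   # 0.1
#' harmonic_consistency(c(0.2, rep(0, 7)))             # 0.025 * exp(-1.75)
harmonic_consistency <- function(k_values) {
  stop_if_not(length(k_values) >= 2, "need at least 2 ratios")
  stop_if_not(all(k_values >= 0 & k_values <= 1),
              "densities must lie in [0, 1]")
  kbar <- mean(k_values)
  if (kbar == 0) return(0)
  n <- length(k_values)
  kbar * exp(-sum(abs(k_values - kbar)) / (n * kbar))
}

#' Shuffle-surrogate thresholds for harmonic consistency
#'
#' Null distribution of `C` obtained by permuting the density values
#' across low frequencies independently within each ratio column (so
#' each shuffled frequency draws its per-ratio densities from the
#' observed marginal distributions), recomputing `C` per frequency, and
#' taking the stated percentile.
#'
#' @param k_matrix Numeric matrix, rows = low frequencies, columns =
#'   ratios.
#' @param n_shuffles Number of shuffle realizations.
#' @param percentile Threshold percentile (0-100).
#' @param seed Integer seed.
#' @return Object of class `consistency_profile`: list with `C`
#'   (observed per frequency), `threshold` (per frequency),
#'   `significant`, `n_shuffles`, `percentile`.
#' @export
consistency_null <- function(k_matrix, n_shuffles = 2000,
                             percentile = 95, seed = 1) {
  k_matrix <- as.matrix(k_matrix)
  nf <- nrow(k_matrix)
  stop_if_not(nf >= 2, "need at least 2 low frequencies to shuffle over")
  observed <- apply(k_matrix, 1, harmonic_consistency)
  surr <- with_seed(seed, {
    out <- matrix(NA_real_, n_shuffles, nf)
    for (i in seq_len(n_shuffles)) {
      shuf <- apply(k_matrix, 2, sample)
      out[i, ] <- apply(shuf, 1, harmonic_consistency)
    }
    out
  })
  thr <- apply(surr, 2, stats::quantile, probs = percentile / 100)
  structure(list(C = observed, threshold = unname(thr),
                 significant = observed > thr, n_shuffles = n_shuffles,
                 percentile = percentile),
            class = "consistency_profile")
}

#' @export
print.consistency_profile <- function(x, ...) {
  cat(sprintf(
    "consistency_profile: %d frequencies, %d significant at the %g%%-ile (%d shuffles)\n",
    length(x$C), sum(x$significant), x$percentile, x$n_shuffles))
  invisible(x)
}
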