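# Behavioral capacity and network-strength correlation.

#' Visual working-memory capacity
#'
#' Capacity at load l is the hit rate scaled by the load:
#' `C(l) = HR(l) * l`.
#'
#' @param behavior Data frame with `subject`, `load`, `hit_rate`.
#' @return The data frame with a `capacity` column (added or
#'   recomputed).
#' @export
vwm_capacity <- function(behavior) {
  stop_if_not(all(c("subject", "load", "hit_rate") %in% names(behavior)),
              "behavior needs subject, load, hit_rate columns")
  stop_if_not(all(behavior$hit_rate >= 0 & behavior$hit_rate <= 1),
              "hit rates must lie in [0, 1]")
  behavior$capacity <- behavior$hit_rate * behavior$load
  behavior
}

#' Individual network strength over significant edges
#'
#' \deqn{S(l, s) = \sum_p \sum_{q \ne p} \sum_{t = 3, 4}
#'   M(p, q, t) \, \mathrm{PLV}(p, q, l, t, s)}
#' the sum of coupling values over the edges of a binary mask (edges
#' significant in the positive tail of the Mean-condition statistics)
#' and the two retention windows.
#'
#' @param tensor A [compute_coupling()] result.
#' @param mask Logical/0-1 vector per edge (aligned with
#'   `tensor$edges`), or a `stat_graph` whose positive significant
#'   edges define the mask.
#' @return Matrix subject x load of strengths `S`; all zero (with a
#'   message) when the mask is empty.
#' @export
network_strength <- function(tensor, mask) {
  if (inherits(mask, "stat_graph"))
    mask <- mask$significant %in% TRUE & mask$sign > 0
  mask <- as.logical(mask)
  stop_if_not(length(mask) == nrow(tensor$edges),
              "mask length must equal the edge count")
  d <- dim(tensor$value)                  # edge x window x load x subject
  if (!any(mask)) {
    message("empty mask: network strength is zero everywhere")
    return(matrix(0, d[4], d[3]))
  }
  v <- tensor$value[mask, c(3, 4), , , drop = FALSE]
  s <- apply(v, c(3, 4), sum)             # load x subject
  t(s)                                    # subject x load
}

#' Detrend and normalize a subject-by-load table
#'
#' Removes the subject mean across loads (individual offset) and the
#' load-wise population mean of the subject-centered values (group
#' trend), then scales by the per-subject mean of the summed absolute
#' centered values, \eqn{\bar S_{abs} = \frac{1}{N_s} \sum_s \sum_l
#' |S(l, s) - \bar S_L(s)|}:
#' \deqn{S'(l, s) = \frac{S(l, s) - \bar S_L(s) - \bar S_{pop}(l)}
#'   {\bar S_{abs}}.}
#' The output has exactly zero mean over subjects at every load and a
#' zero grand sum; it is exactly invariant to adding a per-subject
#' constant, while a per-load constant only rescales it (which leaves
#' all downstream correlations unchanged).  Applied identically to
#' strength and capacity before correlation.
#'
#' @param x Numeric matrix, subjects in rows, loads in columns.
#' @return Matrix of the same shape.
#' @export
detrend_normalize <- function(x) {
  x <- as.matrix(x)
  stop_if_not(nrow(x) >= 2 && ncol(x) >= 2,
              "need at least 2 subjects and 2 loads")
  centered <- x - rowMeans(x)
  s_abs <- sum(abs(centered)) / nrow(x)
  if (s_abs == 0) return(centered)        # constant table: all zeros
  sweep(centered, 2, colMeans(centered)) / s_abs
}

#' Correlation of network strength with behavioral capacity
#'
#' Pearson correlation between detrend-normalized strength `S'`
#' (averaged within a ratio group, e.g. low 1:2-1:5 or high 1:6-1:9)
#' and detrend-normalized capacity `C'`, pooled over all
#' (subject, load) points, computed per low frequency and
#' Benjamini-Hochberg corrected across the tested frequencies.
#'
#' @param s_prime Named list (per f_low) of subject x load matrices of
#'   detrend-normalized strength, or a single matrix.
#' @param c_prime Subject x load matrix of detrend-normalized capacity.
#' @return Data frame with `f_low` (label), `r`, `p`, `p_adj`.
#' @export
strength_capacity_correlation <- function(s_prime, c_prime) {
  if (is.matrix(s_prime)) s_prime <- list(s_prime)
  labels <- names(s_prime)
  if (is.null(labels)) labels <- as.character(seq_along(s_prime))
  res <- lapply(s_prime, function(sp) {
    stop_if_not(all(dim(sp) == dim(c_prime)),
                "strength and capacity tables differ in shape")
    x <- as.vector(sp); y <- as.vector(c_prime)
    if (stats::sd(x) == 0 || stats::sd(y) == 0)
      return(c(r = NA_real_, p = NA_real_))
    ct <- stats::cor.test(x, y)
    c(r = unname(ct$estimate), p = ct$p.value)
  })
  out <- data.frame(f_low = labels,
                    r = vapply(res, `[`, numeric(1), "r"),
                    p = vapply(res, `[`, numeric(1), "p"))
  out$p_adj <- stats::p.adjust(out$p, method = "BH")
  rownames(out) <- NULL
  out
}

#' Average strength tables across a ratio group
#'
#' @param strengths Named list (per ratio) of subject x load strength
#'   matrices.
#' @param ratios Character or integer labels of the ratios to average
#'   (e.g. 2:5 for the low group, 6:9 for the high group).
#' @return Subject x load matrix.
#' @export
ratio_group_strength <- function(strengths, ratios) {
  labels <- names(strengths)
  if (is.null(labels)) labels <- as.character(seq_along(strengths))
  pick <- labels %in% as.character(ratios)
  stop_if_not(any(pick), "no strength tables match the requested ratios")
  Reduce(`+`, strengths[pick]) / sum(pick)
}
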