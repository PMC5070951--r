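# Independent brute-force oracles: literal loop-based evaluations of the
# estimator definitions, kept free of the package's vectorized paths.

oracle_plv <- function(th_low, th_high, n, m) {
  acc <- 0 + 0i
  N <- length(th_low)
  for (k in seq_len(N)) {
    acc <- acc + exp(1i * (m * th_low[k] - n * th_high[k]))
  }
  Mod(acc) / N
}

oracle_pearson <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n; my <- sum(y) / n
  num <- 0; dx <- 0; dy <- 0
  for (k in seq_len(n)) {
    num <- num + (x[k] - mx) * (y[k] - my)
    dx <- dx + (x[k] - mx)^2
    dy <- dy + (y[k] - my)^2
  }
  num / sqrt(dx * dy)
}

oracle_spearman <- function(x, y) {
  oracle_pearson(rank(x), rank(y))
}

oracle_consistency <- function(k) {
  kbar <- sum(k) / length(k)
  if (kbar == 0) return(0)
  acc <- 0
  for (v in k) acc <- acc + abs(v - kbar)
  kbar * exp(-acc / (length(k) * kbar))
}

# Triple-loop network strength on an edge-indexed tensor.
oracle_strength <- function(value, edges, mask, load, subject) {
  s <- 0
  for (e in seq_len(nrow(edges))) {
    if (!mask[e]) next
    for (w in c(3, 4)) s <- s + value[e, w, load, subject]
  }
  s
}

# Spreadsheet-style detrending of a subject x load table.
oracle_detrend <- function(x) {
  ns <- nrow(x); nl <- ncol(x)
  subj_mean <- sapply(seq_len(ns), function(s) mean(x[s, ]))
  centered <- x
  for (s in seq_len(ns)) centered[s, ] <- x[s, ] - subj_mean[s]
  pop <- sapply(seq_len(nl), function(l) mean(centered[, l]))
  s_abs <- sum(sapply(seq_len(ns), function(s) sum(abs(centered[s, ])))) / ns
  out <- centered
  for (l in seq_len(nl)) out[, l] <- centered[, l] - pop[l]
  out / s_abs
}
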