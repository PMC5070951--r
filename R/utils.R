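#' @keywords internal
"_PACKAGE"

# Deterministic sub-stream seeds: one master seed, one stream per
# (subject, load, trial, parcel, ...) index tuple.  Plain multiplicative
# mixing mod (2^31 - 1) keeps seeds in the 32-bit integer range that
# set.seed() accepts and makes studies bit-identical under a fixed master
# seed regardless of generation order.
stream_seed <- function(master, ...) {
  idx <- c(...)
  s <- as.double(master) %% 2147483647
  for (i in idx) {
    s <- (s * 69069 + as.double(i) + 1) %% 2147483647
  }
  as.integer(s)
}

# Evaluate expr with a local RNG state seeded by `seed`, restoring the
# caller's state afterwards.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

# Next fast FFT length (products of 2, 3, 5 via nextn).
fft_length <- function(n) stats::nextn(n, factors = c(2, 3, 5))

# Circular index helper: 1-based wrap-around.
wrap_index <- function(i, n) ((i - 1L) %% n) + 1L

stop_if_not <- function(cond, msg, ...) {
  if (!cond) stop(sprintf(msg, ...), call. = FALSE)
}
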