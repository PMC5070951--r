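test_that("n:m PLV matches its definition, bounds and invariances", {
  set.seed(42)
  th <- runif(300, -pi, pi)
  # perfect m:1 locking
  expect_equal(plv_nm(th, 3 * th, n = 1, m = 3)$value, 1, tolerance = 1e-12)
  # self-locking at any ratio 1:1
  expect_equal(plv_nm(th, th)$value, 1, tolerance = 1e-12)

  # literal loop-based oracle on random phases
  for (k in 1:5) {
    a <- runif(100, -pi, pi); b <- runif(100, -pi, pi)
    est <- plv_nm(a, b, n = 2, m = 5)
    expect_equal(est$value, oracle_plv(a, b, 2, 5), tolerance = 1e-12)
    expect_gte(est$value, 0); expect_lte(est$value, 1)
  }

  # invariance to constant phase offsets on either series
  a <- runif(500, -pi, pi); b <- runif(500, -pi, pi)
  v0 <- plv_nm(a, b, 1, 4)$value
  expect_equal(plv_nm(a + 0.7, b, 1, 4)$value, v0, tolerance = 1e-12)
  expect_equal(plv_nm(a, b - 1.3, 1, 4)$value, v0, tolerance = 1e-12)

  # independent phases: mean PLV ~ (sqrt(pi)/2) / sqrt(N)
  N <- 200
  sims <- replicate(400, plv_nm(runif(N, -pi, pi),
                                runif(N, -pi, pi))$value)
  expect_equal(mean(sims), sqrt(pi) / 2 / sqrt(N), tolerance = 0.05)

  # NA handling and the empty-observation error
  a[1:10] <- NA
  expect_equal(plv_nm(a, b)$n_obs, 490)
  expect_error(plv_nm(rep(NA_real_, 5), runif(5)), "no valid")
})

test_that("PAC is envelope-phase locking with a proper chance level", {
  set.seed(7)
  th <- runif(400, -pi, pi)
  expect_equal(pac(th, th)$value, 1, tolerance = 1e-12)
  expect_identical(pac(th, th)$kind, "pac")

  # planted modulation of depth 0.5 exceeds the 99% matched-N null;
  # an unmodulated envelope stays within it
  fs <- 600; n <- 6000; t <- (0:(n - 1)) / fs
  f_low <- 8; f_high <- 40
  bank <- wavelet_bank(frequencies = c(f_low, f_high), sampling_rate = fs)
  slow <- filter_series(cos(2 * pi * f_low * t) + 0.1 * rnorm(n), bank,
                        frequencies = f_low)
  carrier <- generate_oscillation(n, f_high, fs, seed = 3)
  th_slow <- Arg(slow$values[[1]][, 1])
  make_pac <- function(depth) {
    env <- 1 + depth * cos(th_slow)
    ep <- envelope_phase(matrix(unit_amplitude(carrier) * env, ncol = 1),
                         f_low, f_high, bank)
    ok <- ep$valid & slow$valid[[1]]
    list(th = th_slow[ok], env = Arg(ep$values[ok, 1]))
  }
  mod <- make_pac(0.5)
  null_thr <- timeshift_null(mod$th, mod$env, fs = fs,
                             n_surrogates = 500, seed = 2)$threshold
  expect_gt(pac(mod$th, mod$env)$value, null_thr)
  unmod <- make_pac(0)
  thr0 <- timeshift_null(unmod$th, unmod$env, fs = fs,
                         n_surrogates = 500, seed = 2)$threshold
  expect_lt(pac(unmod$th, unmod$env)$value, max(thr0, 0.5))
})

test_that("amplitude correlation equals textbook Pearson r", {
  set.seed(11)
  a <- abs(rnorm(300)) + 0.1
  expect_equal(amp_correlation(a, 2 * a + 1)$value, 1, tolerance = 1e-12)
  b <- abs(rnorm(300)) + 0.1
  expect_equal(amp_correlation(a, b)$value, oracle_pearson(a, b),
               tolerance = 1e-12)
  expect_equal(amp_correlation(a, b)$value, stats::cor(a, b),
               tolerance = 1e-12)
  expect_error(amp_correlation(a, rep(1, 300)), "variance")

  # independent amplitudes: |CC| <= 3 / sqrt(N) in ~99% of draws
  N <- 400
  cc <- replicate(300, amp_correlation(abs(rnorm(N)) + 0.1,
                                       abs(rnorm(N)) + 0.1)$value)
  expect_gt(mean(abs(cc) <= 3 / sqrt(N)), 0.95)
})

test_that("sliding-window PLV tracks nonstationary coupling", {
  fs <- 600
  th <- runif(1200, -pi, pi)
  # stationary perfect 1:4 locking: every window at 1
  out <- sliding_plv(th, 4 * th, n = 1, m = 4, fs = fs)
  expect_true(all(abs(out$plv - 1) < 1e-12))
  # window arithmetic: 0.3 s window, 0.05 s step, 1.0 s span -> 15 windows
  out1 <- sliding_plv(th[1:600], 4 * th[1:600], n = 1, m = 4, fs = fs)
  expect_identical(nrow(out1), 15L)

  # coupling switched on mid-trial: late windows beat the early maximum
  x <- generate_oscillation(1200, 10, fs, seed = 4)
  y <- generate_oscillation(1200, 40, fs, seed = 5)
  c_t <- c(rep(0, 600), rep(1, 600))
  z <- inject_cfs(x, y, c_t, 4)
  tr <- sliding_plv(Arg(z$x), Arg(z$y), n = 1, m = 4, fs = fs)
  early <- tr$plv[tr$t_start + 0.3 <= 1.0]
  late <- tr$plv[tr$t_start >= 1.2]
  expect_gt(max(late), max(early))
})

test_that("time-shift surrogates reproduce direct re-estimation", {
  fs <- 300
  x <- generate_oscillation(2000, 10, fs, seed = 8)
  y <- generate_oscillation(2000, 30, fs, seed = 9)
  thx <- Arg(x); thy <- Arg(y)
  sn <- timeshift_null(thx, thy, n = 1, m = 3, fs = fs,
                       n_surrogates = 64, seed = 13)
  # oracle: explicit circular shifts with the same lag draws
  lags <- with(list(), {
    set.seed(13); sample.int(round(0.3 * fs), 64, replace = TRUE)
  })
  nt <- length(thx)
  direct <- vapply(lags, function(s) {
    shifted <- thy[((seq_len(nt) + s - 1L) %% nt) + 1L]
    oracle_plv(thx, shifted, 1, 3)
  }, numeric(1))
  expect_equal(sn$surrogates, direct, tolerance = 1e-10)

  # the generic estimator path agrees with the fast path
  sn2 <- timeshift_null(thx, thy, fs = fs, n_surrogates = 32, seed = 4,
                        estimator = function(a, b) oracle_plv(a, b, 1, 3))
  sn2_fast <- timeshift_null(thx, thy, n = 1, m = 3, fs = fs,
                             n_surrogates = 32, seed = 4)
  expect_equal(sn2$surrogates, sn2_fast$surrogates, tolerance = 1e-10)

  # percentile = 50 gives the surrogate median
  sn3 <- timeshift_null(thx, thy, n = 1, m = 3, fs = fs,
                        n_surrogates = 101, percentile = 50, seed = 3)
  expect_equal(sn3$threshold, stats::median(sn3$surrogates))

  # perfectly coupled series exceed their threshold
  z <- inject_cfs(x, y, 1, 3)
  snc <- timeshift_null(Arg(z$x), Arg(z$y), n = 1, m = 3, fs = fs,
                        n_surrogates = 200, seed = 6)
  expect_gt(snc$observed, snc$threshold)

  expect_error(timeshift_null(thx[1:50], thy[1:50], fs = fs), "shorter")
})
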