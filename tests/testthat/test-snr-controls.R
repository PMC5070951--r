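# Reduced-size simulations: surfaces at 2e4-3e4 samples and fs = 300
# are noisier than the 1e6-sample production setting but preserve the
# monotonicity and round-trip properties under the wider tolerances
# asserted here.

surf_fixture <- function() {
  fixture("surf", function() {
    build_plv_surface(10, 3, snr_values = snr_grid(1, 6, 1.3),
                      c_values = seq(0, 1, 0.25), n_samples = 3e4,
                      fs = 300, seed = 17)
  })
}

test_that("apparent SNR follows its defining ratio", {
  expect_equal(asnr(2, 1)$asnr, 1)
  expect_equal(asnr(5, 5)$asnr, 0)
  a_exp <- matrix(c(2, 3, 4, 6), 2, 2)
  a_n <- matrix(c(1, 2, 2, 3), 2, 2)
  res <- asnr(a_exp, a_n)
  expect_equal(res$per_cell, (a_exp - a_n) / a_n)
  expect_equal(res$asnr, mean(res$per_cell))
  expect_error(asnr(1, 0), "positive")
})

test_that("the aSNR-SNR link is monotone and invertible", {
  tab <- build_asnr_table(snr_grid(0.4, 8, 1.5), f = 10,
                          n_samples = 2e4, fs = 300, seed = 2)
  expect_true(all(diff(tab$asnr) > 0))
  # aSNR vanishes as SNR goes to zero
  expect_lt(tab$asnr[1], 0.1)
  # round trip within 5% over the grid interior
  for (i in 2:(nrow(tab) - 1)) {
    expect_equal(asnr_to_snr(tab$asnr[i], tab), tab$snr[i],
                 tolerance = 0.05)
  }
  expect_error(asnr_to_snr(min(tab$asnr) - 1, tab), "below")
  expect_warning(out <- asnr_to_snr(max(tab$asnr) + 1, tab), "clamped")
  expect_equal(out, max(tab$snr))
})

test_that("the simulated PLV surface is monotone where it matters", {
  surf <- surf_fixture()
  # nondecreasing in SNR at fixed c (within sampling error)
  for (ci in 2:5) {
    diag_vals <- vapply(seq_along(surf$snr_values), function(i) {
      surf$plv[ci, i, i]
    }, numeric(1))
    expect_true(all(diff(diag_vals) > -0.05))
  }
  # increasing in c at comfortable SNR
  g <- surf$plv[, 5, 5]
  expect_gt(g[5], g[1] + 0.05)
  # chance level at c = 0 regardless of SNR
  expect_lt(max(surf$plv[1, , ]), 0.12)
})

test_that("coupling-factor inversion round-trips through the surface", {
  surf <- surf_fixture()
  snr <- surf$snr_values[4]
  plv_mid <- plv_surface_lookup(surf, 0.5, snr, snr)
  c_hat <- infer_coupling_factor(plv_mid, snr, snr, surf)
  expect_equal(c_hat, 0.5, tolerance = 0.1)
  # inversion is nondecreasing in the observed PLV
  plvs <- seq(0.02, 0.3, by = 0.04)
  cs <- suppressWarnings(vapply(plvs, infer_coupling_factor,
                                numeric(1), snr, snr, surf))
  expect_true(all(diff(cs) >= 0))
  # chance-level observations map to c ~ 0
  expect_equal(infer_coupling_factor(0, snr, snr, surf),
               min(surf$c_values))
  expect_warning(infer_coupling_factor(0.99, snr, snr, surf), "clipped")
})

test_that("predicted PLV changes follow the surface", {
  surf <- surf_fixture()
  s_mid <- c(surf$snr_values[3], surf$snr_values[3])
  s_hi <- c(surf$snr_values[5], surf$snr_values[5])
  expect_equal(predicted_delta_plv(0.5, s_mid, s_mid, surf), 0)
  expect_gt(predicted_delta_plv(0.5, s_mid, s_hi, surf), -0.02)
  # no coupling: no SNR-driven PLV change beyond noise
  expect_lt(abs(predicted_delta_plv(0, s_mid, s_hi, surf)), 0.05)
  expect_error(predicted_delta_plv(0.5, c(0.01, 1), s_hi, surf), "grid")
})

test_that("observed PLV changes reduce to the stated contrasts", {
  ne <- 3
  v <- array(0.1, dim = c(ne, 4, 2, 2))   # edge x window x load x subject
  tensor <- structure(list(value = v), class = "coupling_tensor")
  expect_equal(observed_delta_plv(tensor, "mean"), rep(0, ne))
  expect_equal(observed_delta_plv(tensor, "load"), rep(0, ne))
  # hand-computed two-subject toy
  v[1, 3, , 1] <- 0.3; v[1, 4, , 1] <- 0.5   # subject 1 retention 0.4
  v[1, 3:4, , 2] <- 0.2                      # subject 2 retention 0.2
  tensor2 <- structure(list(value = v), class = "coupling_tensor")
  # mean over subjects/loads of retention minus baseline (0.1)
  expect_equal(observed_delta_plv(tensor2, "mean")[1],
               mean(c(0.4, 0.4, 0.2, 0.2)) - 0.1)
  # load contrast: load 2 minus load 1, mean over subjects
  v[1, 3:4, 2, ] <- 0.6
  tensor3 <- structure(list(value = v), class = "coupling_tensor")
  d_load <- observed_delta_plv(tensor3, "load")[1]
  ret_l1 <- c(mean(c(0.3, 0.5)), 0.2)
  expect_equal(d_load, mean(0.6 - ret_l1))

  expect_identical(top_delta_edges(c(0.1, 0.5, 0.3), 2), c(2L, 3L))
})
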