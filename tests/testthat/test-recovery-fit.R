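test_that("noiseless voxel fits recover (M0, T1) to high precision", {
  tr <- protocol_trs(); w <- protocol_averages()
  f <- fit_voxel(100 * (1 - exp(-tr / 1.6)), tr, w)
  expect_true(f$converged)
  expect_equal(f$m0, 100, tolerance = 1e-6)
  expect_equal(f$t1_s, 1.6, tolerance = 1e-6)
  # fast recovery: near-saturated at every TR
  f2 <- fit_voxel(1 * (1 - exp(-tr / 0.125)), tr, w)
  expect_equal(f2$m0, 1, tolerance = 1e-3)
  expect_equal(f2$t1_s, 0.125, tolerance = 1e-3)
})

test_that("degenerate voxel inputs are handled", {
  expect_error(fit_voxel(c(1, 2), c(0.5, 1)), "3 TR")
  f <- fit_voxel(rep(0, 6), protocol_trs(), protocol_averages())
  expect_false(f$converged)
  expect_identical(f$m0, 0)
})

test_that("mean fitted M0 is within 1% under noise (Monte-Carlo, seed 0)", {
  tr <- protocol_trs(); w <- protocol_averages()
  clean <- 100 * (1 - exp(-tr / 1.6))
  set.seed(0)
  m0s <- replicate(1000, fit_voxel(clean + rnorm(6, 0, 1), tr, w)$m0)
  expect_equal(mean(m0s), 100, tolerance = 0.01)
})

test_that("fit is scale-equivariant and TR-subset consistent", {
  tr <- protocol_trs(); w <- protocol_averages()
  s <- 80 * (1 - exp(-tr / 1.35))
  f1 <- fit_voxel(s, tr, w)
  f2 <- fit_voxel(7.5 * s, tr, w)
  expect_equal(f2$m0, 7.5 * f1$m0, tolerance = 1e-9)
  expect_equal(f2$t1_s, f1$t1_s, tolerance = 1e-9)
  for (idx in list(c(1, 4, 6), c(2, 3, 5, 6), 1:5)) {
    fs <- fit_voxel(s[idx], tr[idx], w[idx])
    expect_equal(fs$m0, 80, tolerance = 1e-6)
    expect_equal(fs$t1_s, 1.35, tolerance = 1e-6)
  }
})

test_that("fit matches a brute-force grid-search oracle", {
  tr <- protocol_trs(); w <- protocol_averages()
  set.seed(7)
  for (i in 1:20) {
    m0 <- runif(1, 20, 150); t1 <- runif(1, 0.3, 3.5)
    sig <- m0 * (1 - exp(-tr / t1)) + rnorm(6, 0, 0.5)
    f <- fit_voxel(sig, tr, w)
    g <- grid_fit_voxel(sig, tr, w)
    # quantization on the correlated (M0, T1) ridge: within a few grid cells,
    # and the continuous fit attains at least the grid minimum
    expect_lt(abs(f$m0 - g$par[["m0"]]), 3 * g$res[["m0"]])
    expect_lt(abs(f$t1_s - g$par[["t1"]]), 3 * g$res[["t1"]])
    rss_grid <- sum(w * (sig - g$par[["m0"]] *
                           (1 - exp(-tr / g$par[["t1"]])))^2)
    expect_lte(f$rss, rss_grid + 1e-6)
  }
})

test_that("noiseless map fit reproduces the truth and converges everywhere", {
  ph <- default_phantom_cached()
  pd <- noiseless_pd_map_cached()
  mask <- ph$label_map > 0
  expect_equal(max(abs(pd$m0[mask] / ph$pd_truth[mask] - 1)), 0,
               tolerance = 1e-6)
  expect_equal(sum(pd$converged[mask]), sum(mask))
  expect_true(all(is.na(pd$m0[!mask])))
  expect_error(fit_recovery_map(noiseless_series_cached(),
                                array(FALSE, dim(mask))), "empty")
})

test_that("ROI-mean error grows monotonically with noise", {
  ph <- default_phantom_cached()
  code <- castrr_labels()[["phantom_100"]]
  sel <- ph$label_map == code
  rmse <- vapply(c(0, 1, 2, 5), function(pct) {
    errs <- vapply(1:5, function(rep) {
      spec <- acquisition_spec(noise_sigma = pct, seed = 100 * pct + rep)
      ser <- simulate_recovery_series(ph, spec)
      pd <- fit_recovery_map(ser, sel)
      mean(pd$m0[sel & pd$converged]) - 100
    }, numeric(1))
    sqrt(mean(errs^2))
  }, numeric(1))
  expect_true(all(diff(rmse) >= -1e-9))
})

test_that("auto mask covers the foreground and rejects degenerate input", {
  ph <- default_phantom_cached()
  ser <- noiseless_series_cached()
  m <- auto_mask(ser)
  fg <- ph$label_map > 0
  # in-plane-eroded truth foreground is fully inside the mask
  er <- castrr:::erode_inplane(fg)
  expect_true(all(m[er]))
  # eroded background is fully outside
  bg_er <- castrr:::erode_inplane(!fg)
  expect_equal(sum(m[bg_er]), 0)
  zed <- ser; zed$volumes <- lapply(zed$volumes, function(v) array(0, dim(v)))
  expect_error(auto_mask(zed), "uniform")
})

test_that("auto mask false-positive rate is below 1% at SNR 50", {
  ph <- default_phantom_cached()
  sigma <- noise_sigma_for_snr(ph, 50)
  ser <- simulate_recovery_series(ph, acquisition_spec(noise_sigma = sigma,
                                                       seed = 21))
  m <- auto_mask(ser)
  bg <- ph$label_map == 0
  expect_lt(sum(m[bg]) / sum(bg), 0.01)
})
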