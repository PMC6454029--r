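test_that("noiseless forward model matches the closed form", {
  ph <- make_default_phantom()
  ph$pd_truth[] <- 100; ph$t1_truth[] <- 1.6
  ser <- simulate_recovery_series(ph, acquisition_spec(tr_list_s = c(0.5, 1, 2),
                                                       averages = c(1L, 1L, 1L)))
  expect_equal(ser$volumes[[3]][1, 1, 1], 71.349520313981, tolerance = 1e-12)
  # saturation limit: TR much longer than T1 recovers M0 itself
  sat <- simulate_recovery_series(ph, acquisition_spec(tr_list_s = c(1, 1000),
                                                       averages = c(1L, 1L)))
  expect_equal(max(abs(sat$volumes[[2]] / 100 - 1)), 0, tolerance = 1e-9)
})

test_that("per-volume noise scales as sigma/sqrt(averages)", {
  ph <- default_phantom_cached()
  spec <- acquisition_spec(noise_sigma = 2, seed = 11)
  ser <- simulate_recovery_series(ph, spec)
  ser0 <- noiseless_series_cached()
  sds <- vapply(seq_along(ser$volumes), function(i)
    sd(ser$volumes[[i]] - ser0$volumes[[i]]), numeric(1))
  # 16384 voxels per volume: empirical SD within 5% of sigma/sqrt(averages)
  expect_equal(sds, 2 / sqrt(protocol_averages()), tolerance = 0.05)
  ratios <- sds / sds[4]
  expect_equal(ratios, c(1 / 2, 1 / 2, 1 / sqrt(2), 1, 1, 1), tolerance = 0.05)
})

test_that("simulation is reproducible and noise-free runs are seed-independent", {
  ph <- default_phantom_cached()
  s1 <- simulate_recovery_series(ph, acquisition_spec(noise_sigma = 1, seed = 3))
  s2 <- simulate_recovery_series(ph, acquisition_spec(noise_sigma = 1, seed = 3))
  expect_identical(s1$volumes, s2$volumes)
  n1 <- simulate_recovery_series(ph, acquisition_spec(seed = 1))
  n2 <- simulate_recovery_series(ph, acquisition_spec(seed = 99))
  expect_identical(n1$volumes, n2$volumes)
})

test_that("rician option is unbiased-noiseless and <1% biased at SNR > 10", {
  ph <- make_default_phantom()
  ph$pd_truth[] <- 100; ph$t1_truth[] <- 1.6
  spec0 <- acquisition_spec(tr_list_s = c(1, 2), averages = c(1L, 1L),
                            noise_model = "rician")
  g0 <- acquisition_spec(tr_list_s = c(1, 2), averages = c(1L, 1L))
  expect_equal(simulate_recovery_series(ph, spec0)$volumes,
               simulate_recovery_series(ph, g0)$volumes)
  # SNR ~ 14 at TR = 1 s (signal 46.5, sigma 3.3): Rician mean bias < 1%
  spec <- acquisition_spec(tr_list_s = c(1, 2), averages = c(1L, 1L),
                           noise_sigma = 3.3, noise_model = "rician", seed = 5)
  ser <- simulate_recovery_series(ph, spec)
  truth <- 100 * (1 - exp(-1 / 1.6))
  bias <- mean(ser$volumes[[1]]) / truth - 1
  expect_gt(bias, 0)          # Rician mean exceeds the true magnitude
  expect_lt(bias, 0.01)
})

test_that("pCASL simulator inverts the quantification equation exactly", {
  ph <- default_phantom_cached()
  p <- quant_params()
  asl <- simulate_pcasl(ph, p, n_pairs = 2, noise_sigma = 0)
  brain <- phantom_brain_mask(ph)
  md <- mean_difference(asl)
  cbf <- quantify_cbf(md$dm, md$m0, p, mask = brain)
  expect_equal(max(abs(cbf$cbf[brain] / ph$cbf_truth[brain] - 1)), 0,
               tolerance = 1e-9)
  # zero flow: control and label identical
  ph0 <- make_default_phantom(region_cbf = c(neocortex = 0, corpus_callosum = 0,
                                             hippocampus = 0, other_brain = 0))
  asl0 <- simulate_pcasl(ph0, p, n_pairs = 1, noise_sigma = 0)
  expect_identical(asl0$control, asl0$label)
})

test_that("pCASL simulator validates its inputs", {
  ph <- default_phantom_cached()
  expect_error(quant_params(alpha = 1.2), "alpha")
  expect_error(quant_params(t1_blood_s = -1), "t1_blood_s")
  expect_error(simulate_pcasl(ph, quant_params(), n_pairs = 0), "n_pairs")
})
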