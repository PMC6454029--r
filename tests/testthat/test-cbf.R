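test_that("mean difference is zero for identical control/label", {
  ph <- default_phantom_cached()
  asl <- simulate_pcasl(make_default_phantom(
    region_cbf = c(neocortex = 0, corpus_callosum = 0, hippocampus = 0,
                   other_brain = 0)), quant_params(), n_pairs = 3)
  md <- mean_difference(asl)
  expect_true(all(md$dm == 0))
})

test_that("noiseless mean difference equals the simulated label difference", {
  ph <- default_phantom_cached()
  asl <- simulate_pcasl(ph, quant_params(), n_pairs = 4, noise_sigma = 0)
  md <- mean_difference(asl)
  expect_equal(max(abs(md$dm - asl$dm_truth)), 0, tolerance = 1e-12)
})

test_that("difference-map noise follows sigma*sqrt(2/n) propagation", {
  ph <- default_phantom_cached()
  asl <- simulate_pcasl(ph, quant_params(), n_pairs = 120, noise_sigma = 1,
                        seed = 17)
  md <- mean_difference(asl)
  emp_sd <- sd(md$dm - asl$dm_truth)  # over 16384 voxels
  expect_equal(emp_sd, sqrt(2 / 120), tolerance = 0.05)
})

test_that("quantification matches the hand-evaluated closed form", {
  p <- quant_params()
  dm <- array(0.05, c(2, 2, 1)); m0 <- array(1, c(2, 2, 1))
  cbf <- quantify_cbf(dm, m0, p)
  expect_equal(unique(cbf$cbf[cbf$mask]), 1.39698175629731, tolerance = 1e-12)
  # zero perfusion maps to zero flow; PLD = 0 means decay factor exactly 1
  expect_equal(unique(as.vector(quantify_cbf(dm * 0, m0, p)$cbf)), 0)
  p2 <- quant_params(pld_s = 0)
  expect_identical(exp(p2$pld_s / p2$t1_blood_s), 1)
})

test_that("cbf is degree-1 in dm and degree -1 in m0", {
  p <- quant_params()
  set.seed(8)
  dm <- array(runif(8, 0.01, 0.1), c(2, 2, 2))
  m0 <- array(runif(8, 0.5, 2), c(2, 2, 2))
  base <- quantify_cbf(dm, m0, p)$cbf
  expect_equal(quantify_cbf(3 * dm, m0, p)$cbf, 3 * base, tolerance = 1e-12)
  expect_equal(quantify_cbf(dm, 2 * m0, p)$cbf, base / 2, tolerance = 1e-12)
})

test_that("a smooth coil gain common to all volumes cancels", {
  ph <- default_phantom_cached()
  p <- quant_params()
  brain <- phantom_brain_mask(ph)
  a1 <- simulate_pcasl(ph, p, n_pairs = 2, noise_sigma = 0)
  a2 <- simulate_pcasl(ph, p, n_pairs = 2, noise_sigma = 0, bias_field = TRUE)
  m1 <- mean_difference(a1); m2 <- mean_difference(a2)
  c1 <- quantify_cbf(m1$dm, m1$m0, p, mask = brain)
  c2 <- quantify_cbf(m2$dm, m2$m0, p, mask = brain)
  expect_equal(c2$cbf[brain], c1$cbf[brain], tolerance = 1e-9)
})

test_that("BBPC correction is the algebraic lambda substitution", {
  ph <- default_phantom_cached()
  p <- quant_params()
  brain <- phantom_brain_mask(ph)
  asl <- simulate_pcasl(ph, p, n_pairs = 2, noise_sigma = 0)
  md <- mean_difference(asl)
  unc <- quantify_cbf(md$dm, md$m0, p, mask = brain)
  # neutral correction: a uniform 0.9 mL/g map changes nothing
  bb9 <- structure(list(bbpc = array(0.9, dim(md$dm)), mask = brain,
                        blood_wc_mean = 1, density_brain = 1.04,
                        voxel_size = ph$voxel_size), class = "castrr_bbpc_map")
  expect_identical(correct_with_bbpc(unc, bb9)$cbf[brain], unc$cbf[brain])
  # general map: equals re-quantifying with lambda = bbpc, ratio = bbpc/0.9
  set.seed(4)
  bbv <- array(runif(length(md$dm), 0.8, 1.1), dim(md$dm))
  bb <- bb9; bb$bbpc <- bbv
  corr <- correct_with_bbpc(unc, bb)
  req <- quantify_cbf(md$dm, md$m0, p, lambda = bbv, mask = brain)
  expect_equal(corr$cbf[brain], req$cbf[brain], tolerance = 1e-12)
  expect_equal(corr$cbf[brain] / unc$cbf[brain], bbv[brain] / 0.9,
               tolerance = 1e-12)
  # grid mismatch is refused with advice
  bb_small <- bb
  bb_small$bbpc <- bbv[1:32, 1:32, , drop = FALSE]
  bb_small$mask <- brain[1:32, 1:32, , drop = FALSE]
  expect_error(correct_with_bbpc(unc, bb_small), "resample")
})

test_that("non-positive m0 voxels are flagged, not propagated", {
  p <- quant_params()
  dm <- array(0.05, c(2, 2, 1)); m0 <- array(1, c(2, 2, 1))
  m0[1, 1, 1] <- 0
  expect_warning(cbf <- quantify_cbf(dm, m0, p, mask = array(TRUE, dim(dm))),
                 "non-positive")
  expect_true(is.na(cbf$cbf[1, 1, 1]))
  expect_equal(sum(is.na(cbf$cbf)), 1)
})
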