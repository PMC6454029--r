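# Test image with through-slice structure so all six degrees of freedom
# are identifiable (the phantom itself is a stack of identical slices).
z_structured_image <- function() {
  ph <- default_phantom_cached()
  img <- ph$pd_truth
  for (z in seq_len(dim(img)[3])) img[, , z] <- img[, , z] * (1 + 0.15 * z)
  img
}

test_that("the printed acquisition grids imply a 22% resolution reduction", {
  castrr_grid <- grid_spec(c(256L, 256L, 10L), c(28 / 256, 28 / 256, 1))
  pcasl_grid <- grid_spec(c(128L, 96L, 6L), c(18 / 128, 18 / 128, 1))
  expect_equal(castrr_grid$voxel_size[1], 0.109375)
  expect_equal(pcasl_grid$voxel_size[1], 0.140625)
  pct <- resolution_reduction_pct(castrr_grid, pcasl_grid)
  expect_equal(round(pct), 22)
})

test_that("identity resample on the same grid is exact", {
  ph <- default_phantom_cached()
  g <- grid_spec(dim(ph$pd_truth), ph$voxel_size)
  id <- rigid_transform(center_mm = g$origin + (g$shape - 1) * g$voxel_size / 2)
  out <- resample_to_grid(ph$pd_truth, id, g, g)
  expect_identical(out, ph$pd_truth)
})

test_that("down-sampling preserves interior means of constant regions", {
  ph <- default_phantom_cached()
  g_hi <- grid_spec(dim(ph$pd_truth), ph$voxel_size)
  # coarser grid covering the same field of view (22%-style reduction)
  g_lo <- grid_spec(c(50L, 50L, 4L), c(dim(ph$pd_truth)[1:2], 1) *
                      g_hi$voxel_size / c(50, 50, 1))
  id <- rigid_transform()
  lo <- resample_to_grid(ph$pd_truth, id, g_hi, g_lo)
  # interior of the hippocampus core region, mapped to the coarse grid
  sel_hi <- castrr:::erode_inplane(
    ph$label_map == castrr_labels()[["hippocampus"]])
  sel_lo_arr <- resample_to_grid(array(as.numeric(sel_hi), dim(sel_hi)),
                                 id, g_hi, g_lo)
  sel_lo <- !is.na(sel_lo_arr) & sel_lo_arr > 0.999
  truth <- mean(ph$pd_truth[sel_hi])
  expect_equal(mean(lo[sel_lo]), truth, tolerance = 0.01)
})

test_that("self-registration returns the identity", {
  img <- z_structured_image()
  g <- grid_spec(dim(img), default_phantom_cached()$voxel_size)
  tr <- rigid_register(img, img, g, g)
  expect_lt(max(abs(tr$translation_mm / g$voxel_size)), 0.01)
  expect_lt(max(abs(tr$rotation_deg)), 0.01)
})

test_that("a known two-voxel shift is recovered", {
  # the stacked-cylinder phantom has no through-slice structure, so the
  # in-plane components are asserted; z is unidentifiable by construction
  img <- default_phantom_cached()$pd_truth
  g <- grid_spec(dim(img), default_phantom_cached()$voxel_size)
  shifted <- array(0, dim(img))
  shifted[3:dim(img)[1], , ] <- img[1:(dim(img)[1] - 2), , ]
  tr <- rigid_register(shifted, img, g, g)
  expect_equal(tr$translation_mm[1] / g$voxel_size[1], 2, tolerance = 0.05)
  expect_lt(abs(tr$translation_mm[2] / g$voxel_size[2]), 0.1)
})

test_that("shift plus small rotation is recovered under noise", {
  img <- default_phantom_cached()$pd_truth
  g <- grid_spec(dim(img), default_phantom_cached()$voxel_size)
  center <- g$origin + (g$shape - 1) * g$voxel_size / 2
  truth <- rigid_transform(c(g$voxel_size[1], 0, 0), c(0, 0, 2), center)
  warped <- resample_to_grid(img, truth, g, g)
  warped[is.na(warped)] <- 0
  set.seed(3)
  fixed <- warped + array(rnorm(length(warped), 0, max(img) / 50), dim(img))
  tr <- rigid_register(img, fixed, g, g)
  # residual misalignment measured at the brain-region voxel centers
  brain <- which(phantom_brain_mask(default_phantom_cached()), arr.ind = TRUE)
  pts <- sweep(sweep(brain - 1, 2, g$voxel_size, "*"), 2, g$origin, "+")
  p_true <- castrr:::apply_transform(truth, pts)
  p_est <- castrr:::apply_transform(tr, pts)
  resid_vox <- sweep(abs(p_true - p_est), 2, g$voxel_size, "/")[, 1:2]
  expect_lt(max(rowSums(resid_vox^2)^0.5), 0.5)
})

test_that("non-overlapping fields of view raise an error", {
  img <- z_structured_image()
  g1 <- grid_spec(dim(img), c(0.1, 0.1, 1), origin = c(0, 0, 0))
  g2 <- grid_spec(dim(img), c(0.1, 0.1, 1), origin = c(1000, 1000, 0))
  expect_error(rigid_register(img, img, g1, g2), "overlap")
})
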