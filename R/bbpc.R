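
#' Mean water content of the blood reference ROI
#'
#' Mean relative water content over the blood-capillary label eroded
#' in-plane by one voxel, using converged voxels only. This is the
#' denominator of the partition-coefficient computation.
#'
#' @param wc_map An [apply_calibration()] result.
#' @param atlas Integer label map containing the `blood_capillary` label.
#' @return Single numeric, dimensionless water content.
#' @export
blood_reference <- function(wc_map, atlas) {
  stopifnot(inherits(wc_map, "castrr_wc_map"))
  assert_that(all(dim(atlas) == dim(wc_map$wc)),
              "atlas shape must match the map")
  res <- eroded_label_mean(wc_map$wc, wc_map$mask, atlas,
                           castrr_labels()[["blood_capillary"]],
                           "blood_capillary")
  res$mean
}

#' Voxel-wise brain-blood partition coefficient map
#'
#' `bbpc = wc / (blood_wc * 1.04)` inside the brain mask: mL of water per
#' gram of tissue, taking blood density as 1.04 g/mL. A voxel holding the
#' same water content as blood therefore maps to 1/1.04 = 0.9615 mL/g.
#' Non-converged voxels stay flagged (`NA`) so ROI means never mix
#' failures with estimates.
#'
#' @param wc_map An [apply_calibration()] result.
#' @param blood_wc Mean blood water content from [blood_reference()]; must
#'   be positive.
#' @param brain_mask 3-D logical array restricting the map to brain tissue.
#' @param density_brain Tissue density, g/mL (fixed constant 1.04; change
#'   only by explicit override).
#' @return Object of class `castrr_bbpc_map`: `bbpc` (3-D, mL/g), `mask`,
#'   `blood_wc_mean`, `density_brain`.
#' @export
compute_bbpc <- function(wc_map, blood_wc, brain_mask,
                         density_brain = 1.04) {
  stopifnot(inherits(wc_map, "castrr_wc_map"))
  assert_that(is.numeric(blood_wc) && length(blood_wc) == 1 && blood_wc > 0,
              "blood_wc must be a single positive value")
  assert_that(all(dim(brain_mask) == dim(wc_map$wc)),
              "brain_mask shape must match the map")
  mask <- brain_mask & wc_map$mask
  bbpc <- array(NA_real_, dim(wc_map$wc))
  bbpc[mask] <- wc_map$wc[mask] / (blood_wc * density_brain)
  structure(list(bbpc = bbpc, mask = mask, blood_wc_mean = blood_wc,
                 density_brain = density_brain,
                 voxel_size = wc_map$voxel_size),
            class = "castrr_bbpc_map")
}

#' @export
print.castrr_bbpc_map <- function(x, ...) {
  v <- x$bbpc[x$mask]
  cat(sprintf(paste0("BBPC map: %d brain voxels, mean %.3f mL/g ",
                     "(blood wc %.3f, density %.2f g/mL)\n"),
              sum(x$mask), mean(v, na.rm = TRUE), x$blood_wc_mean,
              x$density_brain))
  invisible(x)
}
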