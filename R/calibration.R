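
# Mean of converged m0 over a label eroded in-plane by 1 voxel (guards
# against edge/partial-volume voxels).
eroded_label_mean <- function(values, converged, atlas, code, what) {
  sel <- erode_inplane(atlas == code)
  use <- sel & converged
  n <- sum(use)
  if (n < 5) stopf("%s absent or too small: %d usable voxels (need >= 5)",
                   what, n)
  list(mean = mean(values[use]), n = n)
}

#' Extract per-phantom mean M0 from a fitted map
#'
#' For each of the five calibration phantoms (60-100% water) computes the
#' mean fitted M0 over the phantom label eroded in-plane by one voxel,
#' using converged voxels only.
#'
#' @param pd_map A [fit_recovery_map()] result.
#' @param atlas Integer label map (see [castrr_labels()]), same shape.
#' @return Object of class `castrr_phantom_readout`: data frame with
#'   `water_fraction`, `mean_m0`, `voxel_count`.
#' @export
extract_phantom_readout <- function(pd_map, atlas) {
  stopifnot(inherits(pd_map, "castrr_pd_map"))
  assert_that(all(dim(atlas) == dim(pd_map$m0)),
              "atlas shape must match the map")
  labels <- castrr_labels()
  wf <- c(0.60, 0.70, 0.80, 0.90, 1.00)
  nms <- phantom_label_names()
  res <- lapply(seq_along(nms), function(i)
    eroded_label_mean(pd_map$m0, pd_map$converged, atlas,
                      labels[[nms[i]]], nms[i]))
  out <- data.frame(water_fraction = wf,
                    mean_m0 = vapply(res, `[[`, numeric(1), "mean"),
                    voxel_count = vapply(res, `[[`, integer(1), "n"),
                    row.names = nms)
  class(out) <- c("castrr_phantom_readout", "data.frame")
  out
}

#' Linear calibration of M0 against known water fraction
#'
#' Ordinary least-squares line `mean_m0 ~ water_fraction` through the five
#' phantom readouts. The fit is rejected (an error, signalling a corrupted
#' acquisition) if the slope is not positive or R-squared falls below
#' `r2_min`.
#'
#' @param readout An [extract_phantom_readout()] result (or data frame with
#'   `water_fraction`, `mean_m0`).
#' @param r2_min Quality-control threshold on R-squared (default 0.98).
#' @return Object of class `castrr_calibration` with `slope`, `intercept`,
#'   `r_squared` and the readout used.
#' @examples
#' ro <- data.frame(water_fraction = c(.6, .7, .8, .9, 1),
#'                  mean_m0 = 100 * c(.6, .7, .8, .9, 1))
#' fit_calibration(ro)
#' @export
fit_calibration <- function(readout, r2_min = 0.98) {
  assert_that(nrow(readout) == 5 && all(is.finite(readout$mean_m0)),
              "readout must hold 5 finite phantom means")
  assert_that(all(diff(readout$water_fraction) > 0),
              "water fractions must be strictly increasing")
  fit <- lm(mean_m0 ~ water_fraction, data = readout)
  slope <- unname(coef(fit)[2]); intercept <- unname(coef(fit)[1])
  tss <- sum((readout$mean_m0 - mean(readout$mean_m0))^2)
  r2 <- if (tss > 0) 1 - sum(fit$residuals^2) / tss else 1
  if (slope <= 0) stopf("calibration rejected: non-positive slope (%.4g)", slope)
  if (r2 < r2_min)
    stopf("calibration rejected: R-squared %.4f below %.2f", r2, r2_min)
  structure(list(slope = slope, intercept = intercept, r_squared = r2,
                 readout = readout),
            class = "castrr_calibration")
}

#' @export
print.castrr_calibration <- function(x, ...) {
  cat(sprintf("Phantom calibration: M0 = %.4g + %.4g * water_fraction (R^2 = %.4f)\n",
              x$intercept, x$slope, x$r_squared))
  invisible(x)
}

#' @export
coef.castrr_calibration <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' @export
#' @param object A `castrr_calibration`.
#' @param m0 Numeric M0 values to convert to relative water content.
#' @param ... Unused.
#' @rdname fit_calibration
predict.castrr_calibration <- function(object, m0, ...) {
  (m0 - object$intercept) / object$slope
}

#' Convert a fitted M0 map to relative water content
#'
#' Applies the affine phantom calibration voxel-wise:
#' `wc = (m0 - intercept) / slope`, a dimensionless relative water content
#' with 1.0 corresponding to the pure-water phantom signal. With
#' `ratio_only = TRUE` the intercept is ignored and M0 is simply divided by
#' the slope, reproducing the uncalibrated phantom-ratio normalization.
#'
#' @param pd_map A [fit_recovery_map()] result.
#' @param fit A [fit_calibration()] result.
#' @param ratio_only Logical; drop the intercept term.
#' @return Object of class `castrr_wc_map`: `wc` (3-D, `NA` where the fit
#'   did not converge) and `mask` (converged in-mask voxels).
#' @export
apply_calibration <- function(pd_map, fit, ratio_only = FALSE) {
  stopifnot(inherits(pd_map, "castrr_pd_map"),
            inherits(fit, "castrr_calibration"))
  intercept <- if (ratio_only) 0 else fit$intercept
  wc <- (pd_map$m0 - intercept) / fit$slope
  wc[!pd_map$converged] <- NA_real_
  structure(list(wc = wc, mask = pd_map$mask & pd_map$converged,
                 calibration = fit, voxel_size = pd_map$voxel_size),
            class = "castrr_wc_map")
}
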