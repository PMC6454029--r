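#' @keywords internal
"_PACKAGE"

#' @importFrom stats coef lm optim qt rnorm sd setNames cor predict
#' @importFrom utils write.table modifyList packageVersion
NULL

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

assert_that <- function(ok, fmt, ...) if (!isTRUE(ok)) stopf(fmt, ...)

is_count <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) &&
  x >= 1 && x == round(x)

#' Canonical label dictionary of the digital phantom
#'
#' Integer codes used in the atlas/label map: background, the three reported
#' brain regions, remaining brain tissue, the blood capillary, and the five
#' water-content calibration phantoms.
#'
#' @return Named integer vector mapping label names to atlas codes.
#' @export
castrr_labels <- function() {
  c(background = 0L, neocortex = 1L, corpus_callosum = 2L, hippocampus = 3L,
    other_brain = 4L, blood_capillary = 5L,
    phantom_60 = 6L, phantom_70 = 7L, phantom_80 = 8L,
    phantom_90 = 9L, phantom_100 = 10L)
}

brain_label_names <- function() {
  c("neocortex", "corpus_callosum", "hippocampus", "other_brain")
}

phantom_label_names <- function() {
  paste0("phantom_", c(60L, 70L, 80L, 90L, 100L))
}

# In-plane (per-slice) binary erosion with a 3x3 box; slices are thick
# relative to in-plane voxels, so morphology never crosses slices.
erode_inplane <- function(mask) {
  stopifnot(length(dim(mask)) == 3L)
  out <- array(FALSE, dim(mask))
  brush <- EBImage::makeBrush(3L, shape = "box")
  for (z in seq_len(dim(mask)[3])) {
    sl <- matrix(as.numeric(mask[, , z]), nrow = dim(mask)[1])
    out[, , z] <- EBImage::erode(sl, brush) > 0.5
  }
  out
}

dilate_inplane <- function(mask) {
  stopifnot(length(dim(mask)) == 3L)
  out <- array(FALSE, dim(mask))
  brush <- EBImage::makeBrush(3L, shape = "box")
  for (z in seq_len(dim(mask)[3])) {
    sl <- matrix(as.numeric(mask[, , z]), nrow = dim(mask)[1])
    out[, , z] <- EBImage::dilate(sl, brush) > 0.5
  }
  out
}

# Drop in-plane connected components smaller than min_voxels.
filter_small_components <- function(mask, min_voxels = 9L) {
  out <- array(FALSE, dim(mask))
  for (z in seq_len(dim(mask)[3])) {
    sl <- matrix(as.numeric(mask[, , z]), nrow = dim(mask)[1])
    lab <- EBImage::bwlabel(sl)
    if (max(lab) == 0) next
    sizes <- tabulate(lab[lab > 0], nbins = max(lab))
    keep <- which(sizes >= min_voxels)
    out[, , z] <- matrix(lab %in% keep, nrow = dim(mask)[1])
  }
  out
}

# Trilinear interpolation of a 3-D volume at fractional voxel coordinates
# (1-based). Coordinates outside the volume return NA.
interp_trilinear <- function(vol, x, y, z) {
  d <- dim(vol)
  ok <- x >= 1 & x <= d[1] & y >= 1 & y <= d[2] & z >= 1 & z <= d[3] &
    is.finite(x) & is.finite(y) & is.finite(z)
  out <- rep(NA_real_, length(x))
  if (!any(ok)) return(out)
  x <- x[ok]; y <- y[ok]; z <- z[ok]
  x0 <- pmin(floor(x), d[1] - 1L); x0[d[1] == 1L] <- 1L
  y0 <- pmin(floor(y), d[2] - 1L); y0[d[2] == 1L] <- 1L
  z0 <- pmin(floor(z), d[3] - 1L); z0[d[3] == 1L] <- 1L
  xd <- x - x0; yd <- y - y0; zd <- z - z0
  x1 <- pmin(x0 + 1L, d[1]); y1 <- pmin(y0 + 1L, d[2]); z1 <- pmin(z0 + 1L, d[3])
  idx <- function(i, j, k) i + (j - 1) * d[1] + (k - 1) * d[1] * d[2]
  v <- vol[idx(x0, y0, z0)] * (1 - xd) * (1 - yd) * (1 - zd) +
    vol[idx(x1, y0, z0)] * xd * (1 - yd) * (1 - zd) +
    vol[idx(x0, y1, z0)] * (1 - xd) * yd * (1 - zd) +
    vol[idx(x0, y0, z1)] * (1 - xd) * (1 - yd) * zd +
    vol[idx(x1, y1, z0)] * xd * yd * (1 - zd) +
    vol[idx(x1, y0, z1)] * xd * (1 - yd) * zd +
    vol[idx(x0, y1, z1)] * (1 - xd) * yd * zd +
    vol[idx(x1, y1, z1)] * xd * yd * zd
  out[ok] <- v
  out
}

# Nearest-neighbour lookup at fractional voxel coordinates (1-based).
interp_nearest <- function(vol, x, y, z) {
  d <- dim(vol)
  xi <- round(x); yi <- round(y); zi <- round(z)
  ok <- xi >= 1 & xi <= d[1] & yi >= 1 & yi <= d[2] & zi >= 1 & zi <= d[3] &
    is.finite(xi) & is.finite(yi) & is.finite(zi)
  out <- rep(NA_real_, length(x))
  out[ok] <- vol[cbind(xi[ok], yi[ok], zi[ok])]
  out
}
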