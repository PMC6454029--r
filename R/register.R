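
#' Axis-aligned image grid specification
#'
#' @param shape Integer triple of voxel counts.
#' @param voxel_size Positive mm triple.
#' @param origin World coordinate (mm) of the first voxel's center.
#' @return Object of class `castrr_grid`: `shape`, `voxel_size`, `origin`,
#'   and the 4x4 voxel-to-world `affine` (1-based voxel indices).
#' @examples
#' grid_spec(c(256L, 256L, 10L), c(28 / 256, 28 / 256, 1))
#' @export
grid_spec <- function(shape, voxel_size, origin = c(0, 0, 0)) {
  assert_that(length(shape) == 3 && all(shape >= 1), "shape must be a positive triple")
  assert_that(length(voxel_size) == 3 && all(voxel_size > 0),
              "voxel_size must be positive")
  affine <- diag(4)
  diag(affine)[1:3] <- voxel_size
  affine[1:3, 4] <- origin - voxel_size  # world = affine %*% (i, j, k, 1)
  structure(list(shape = as.integer(shape), voxel_size = as.numeric(voxel_size),
                 origin = as.numeric(origin), affine = affine),
            class = "castrr_grid")
}

grid_world_coords <- function(grid) {
  idx <- arrayInd(seq_len(prod(grid$shape)), grid$shape)
  sweep(sweep(idx - 1, 2, grid$voxel_size, "*"), 2, grid$origin, "+")
}

world_to_voxel <- function(grid, pts) {
  sweep(sweep(pts, 2, grid$origin, "-"), 2, grid$voxel_size, "/") + 1
}

rot_matrix <- function(deg) {
  r <- deg * pi / 180
  cx <- cos(r[1]); sx <- sin(r[1]); cy <- cos(r[2]); sy <- sin(r[2])
  cz <- cos(r[3]); sz <- sin(r[3])
  Rx <- rbind(c(1, 0, 0), c(0, cx, -sx), c(0, sx, cx))
  Ry <- rbind(c(cy, 0, sy), c(0, 1, 0), c(-sy, 0, cy))
  Rz <- rbind(c(cz, -sz, 0), c(sz, cz, 0), c(0, 0, 1))
  Rz %*% Ry %*% Rx
}

#' Construct a rigid (6-DOF) transform
#'
#' Maps fixed-image world coordinates into moving-image world coordinates:
#' `p' = R (p - center) + center + t`, rotation about `center`.
#'
#' @param translation_mm Length-3 translation, mm.
#' @param rotation_deg Length-3 rotation angles (x, y, z), degrees.
#' @param center_mm Rotation center, world mm.
#' @return Object of class `castrr_transform` (holds the 4x4 homogeneous
#'   matrix in `matrix`).
#' @export
rigid_transform <- function(translation_mm = c(0, 0, 0),
                            rotation_deg = c(0, 0, 0),
                            center_mm = c(0, 0, 0)) {
  R <- rot_matrix(rotation_deg)
  m <- diag(4)
  m[1:3, 1:3] <- R
  m[1:3, 4] <- center_mm + translation_mm - R %*% center_mm
  structure(list(matrix = m, translation_mm = translation_mm,
                 rotation_deg = rotation_deg, center_mm = center_mm),
            class = "castrr_transform")
}

apply_transform <- function(transform, pts) {
  t(transform$matrix[1:3, 1:3] %*% t(pts)) +
    matrix(transform$matrix[1:3, 4], nrow(pts), 3, byrow = TRUE)
}

#' @export
print.castrr_transform <- function(x, ...) {
  cat(sprintf("Rigid transform: t = (%s) mm, rot = (%s) deg\n",
              paste(signif(x$translation_mm, 4), collapse = ", "),
              paste(signif(x$rotation_deg, 4), collapse = ", ")))
  invisible(x)
}

ncc_cost <- function(par, fixed_vals, fixed_pts, moving, moving_grid, center) {
  tr <- rigid_transform(par[1:3], par[4:6], center)
  vox <- world_to_voxel(moving_grid, apply_transform(tr, fixed_pts))
  mv <- interp_trilinear(moving, vox[, 1], vox[, 2], vox[, 3])
  ok <- !is.na(mv)
  if (sum(ok) < 20) return(2)
  f <- fixed_vals[ok]; m <- mv[ok]
  if (sd(f) == 0 || sd(m) == 0) return(2)
  1 - suppressWarnings(cor(f, m))
}

downsample2_inplane <- function(vol, grid) {
  d <- dim(vol)
  nx <- d[1] %/% 2L; ny <- d[2] %/% 2L
  v <- vol[seq_len(2L * nx), seq_len(2L * ny), , drop = FALSE]
  out <- (v[seq(1, 2 * nx, 2), seq(1, 2 * ny, 2), , drop = FALSE] +
          v[seq(2, 2 * nx, 2), seq(1, 2 * ny, 2), , drop = FALSE] +
          v[seq(1, 2 * nx, 2), seq(2, 2 * ny, 2), , drop = FALSE] +
          v[seq(2, 2 * nx, 2), seq(2, 2 * ny, 2), , drop = FALSE]) / 4
  g <- grid_spec(c(nx, ny, d[3]),
                 grid$voxel_size * c(2, 2, 1),
                 grid$origin + grid$voxel_size * c(0.5, 0.5, 0))
  list(vol = out, grid = g)
}

#' Rigid intensity-based registration
#'
#' Estimates the 6-DOF rigid transform mapping the fixed image's world
#' space into the moving image's, by maximizing normalized cross-correlation
#' with a 2-level multi-resolution (in-plane) pyramid and Nelder-Mead
#' refinement. Rotation is about the fixed-image center. Both images should
#' already be masked to the brain; zero-valued fixed voxels are excluded
#' from the metric.
#'
#' @param moving,fixed 3-D arrays.
#' @param moving_grid,fixed_grid Matching [grid_spec()] objects.
#' @param assume_aligned If `TRUE`, skip optimization and return identity
#'   (appropriate when the synthetic grids are constructed aligned).
#' @param levels Pyramid levels (1 or 2).
#' @return A `castrr_transform`.
#' @export
rigid_register <- function(moving, fixed, moving_grid, fixed_grid,
                           assume_aligned = FALSE, levels = 2L) {
  center <- fixed_grid$origin +
    (fixed_grid$shape - 1) * fixed_grid$voxel_size / 2
  if (assume_aligned) return(rigid_transform(center_mm = center))
  # field-of-view overlap check in world space
  lo_f <- fixed_grid$origin; hi_f <- lo_f + (fixed_grid$shape - 1) * fixed_grid$voxel_size
  lo_m <- moving_grid$origin; hi_m <- lo_m + (moving_grid$shape - 1) * moving_grid$voxel_size
  if (any(hi_f < lo_m) || any(hi_m < lo_f))
    stopf("non-overlapping fields of view")

  par <- rep(0, 6)
  level_seq <- if (levels >= 2 && all(dim(fixed)[1:2] >= 32)) c(2L, 1L) else 1L
  for (lev in level_seq) {
    if (lev == 2L) {
      fx <- downsample2_inplane(fixed, fixed_grid)
      mv <- downsample2_inplane(moving, moving_grid)
    } else {
      fx <- list(vol = fixed, grid = fixed_grid)
      mv <- list(vol = moving, grid = moving_grid)
    }
    sel <- which(fx$vol != 0 & is.finite(fx$vol))
    if (length(sel) < 50) sel <- which(is.finite(fx$vol))
    pts <- grid_world_coords(fx$grid)[sel, , drop = FALSE]
    vals <- fx$vol[sel]
    scale <- c(rep(max(fx$grid$voxel_size[1:2]), 3), rep(0.5, 3))
    restarts <- if (lev == 1L) 2L else 1L  # NM restart sharpens the optimum
    for (k in seq_len(restarts)) {
      opt <- optim(par, ncc_cost, fixed_vals = vals, fixed_pts = pts,
                   moving = mv$vol, moving_grid = mv$grid, center = center,
                   method = "Nelder-Mead",
                   control = list(parscale = scale, maxit = 400,
                                  reltol = 1e-12))
      par <- opt$par
    }
  }
  rigid_transform(par[1:3], par[4:6], center)
}

#' Resample a map onto a target grid
#'
#' Values are interpolated trilinearly at the target voxel centers (the
#' partition coefficient is a smooth quantity); the validity mask is
#' resampled by nearest neighbour. Voxels falling outside the source field
#' of view, or whose nearest source voxel is masked out, are flagged `NA`.
#'
#' @param map A `castrr_bbpc_map` or plain 3-D array.
#' @param transform A `castrr_transform` mapping target (fixed) world
#'   coordinates into source (moving) world coordinates.
#' @param source_grid,target_grid [grid_spec()] objects for the map and the
#'   output.
#' @return Same class as `map`, on the target grid.
#' @export
resample_to_grid <- function(map, transform, source_grid, target_grid) {
  stopifnot(inherits(transform, "castrr_transform"))
  vol <- if (inherits(map, "castrr_bbpc_map")) map$bbpc else map
  assert_that(all(dim(vol) == source_grid$shape),
              "map shape must match source_grid")
  pts <- apply_transform(transform, grid_world_coords(target_grid))
  vox <- world_to_voxel(source_grid, pts)
  src <- vol
  src[is.na(src)] <- 0
  vals <- interp_trilinear(src, vox[, 1], vox[, 2], vox[, 3])
  if (inherits(map, "castrr_bbpc_map")) {
    mk <- interp_nearest(array(as.numeric(map$mask), dim(vol)),
                         vox[, 1], vox[, 2], vox[, 3])
    mask <- array(!is.na(mk) & mk > 0.5, target_grid$shape)
    bb <- array(vals, target_grid$shape)
    bb[!mask] <- NA_real_
    structure(list(bbpc = bb, mask = mask,
                   blood_wc_mean = map$blood_wc_mean,
                   density_brain = map$density_brain,
                   voxel_size = target_grid$voxel_size),
              class = "castrr_bbpc_map")
  } else {
    array(vals, target_grid$shape)
  }
}

#' Percent in-plane resolution change between two grids
#'
#' Convenience for reporting how much finer/coarser a target grid is:
#' `100 * (target_voxel - source_voxel) / target_voxel` using the first
#' in-plane voxel dimension.
#'
#' @param source_grid,target_grid [grid_spec()] objects.
#' @return Percent reduction in resolution (positive when the target grid
#'   is coarser).
#' @export
resolution_reduction_pct <- function(source_grid, target_grid) {
  vs <- source_grid$voxel_size[1]; vt <- target_grid$voxel_size[1]
  100 * (vt - vs) / vt
}
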