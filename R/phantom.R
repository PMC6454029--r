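#' Build the default digital mouse-head phantom
#'
#' Constructs a piecewise-constant 3-D phantom emulating an axial mouse-head
#' acquisition: an elliptical brain with neocortex (outer shell), corpus
#' callosum (thin inner shell), hippocampus (core) and remaining brain
#' tissue, a blood capillary lying beside the head, and five calibration
#' cylinders containing 60-100% water (deuterium-diluted, gadolinium-doped
#' so T1 matches tissue at roughly 1.6 s).
#'
#' Ground-truth maps are generated so that each brain region's BBPC
#' (brain-blood partition coefficient, mL/g) equals the requested value
#' exactly: voxel proton density is set to
#' `bbpc * 1.04 * pd_blood`, with `pd_blood = wc_blood * pd_water`, so
#' the downstream identity `bbpc = pd_brain / (pd_blood * 1.04)` holds by
#' construction.
#'
#' @param region_bbpc Named list/vector of BBPC ground truths (mL/g) for
#'   `neocortex`, `corpus_callosum`, `hippocampus` (and optionally
#'   `other_brain`, default 0.96).
#' @param region_cbf Named list/vector of cerebral-blood-flow ground truths
#'   (mL/g/min) for the same regions.
#' @param shape Integer triple, volume dimensions; at least 32 x 32 x 4.
#' @param seed Integer, accepted for interface symmetry with the simulators;
#'   the geometry is deterministic.
#' @param pd_water Proton density assigned to pure water (arbitrary signal
#'   units); all other densities are relative to it.
#' @param wc_blood Relative water content of the blood sample (dimensionless,
#'   1 = pure water).
#' @param voxel_size Numeric triple, mm.
#' @param region_t1 Named vector of T1 values (seconds) per label; defaults
#'   bracket tissue (1.6-1.8 s), blood (2.2 s) and doped phantoms (1.6 s).
#'
#' @return An object of class `castrr_phantom` with fields `label_map`
#'   (integer array, see [castrr_labels()]), `pd_truth`, `t1_truth`,
#'   `cbf_truth`, `bbpc_truth`, `voxel_size`, `pd_water`, `pd_blood`.
#' @examples
#' ph <- make_default_phantom()
#' table(ph$label_map)
#' @export
make_default_phantom <- function(region_bbpc = c(neocortex = 0.99,
                                                 corpus_callosum = 0.93,
                                                 hippocampus = 0.95),
                                 region_cbf = c(neocortex = 2.81,
                                                corpus_callosum = 1.44,
                                                hippocampus = 2.90),
                                 shape = c(64L, 64L, 4L),
                                 seed = 0L,
                                 pd_water = 100,
                                 wc_blood = 0.85,
                                 voxel_size = c(0.109375, 0.109375, 1),
                                 region_t1 = NULL) {
  region_bbpc <- unlist(region_bbpc); region_cbf <- unlist(region_cbf)
  need <- c("neocortex", "corpus_callosum", "hippocampus")
  assert_that(all(need %in% names(region_bbpc)),
              "region_bbpc must name all of: %s", paste(need, collapse = ", "))
  assert_that(all(need %in% names(region_cbf)),
              "region_cbf must name all of: %s", paste(need, collapse = ", "))
  assert_that(all(region_bbpc > 0), "BBPC truths must be positive")
  assert_that(all(region_cbf >= 0), "CBF truths must be non-negative")
  assert_that(length(shape) == 3L && all(shape >= c(32L, 32L, 4L)),
              "shape must be at least 32 x 32 x 4 to place all labels")
  assert_that(pd_water > 0 && wc_blood > 0 && wc_blood <= 1,
              "pd_water must be > 0 and wc_blood in (0, 1]")
  if (!("other_brain" %in% names(region_bbpc)))
    region_bbpc["other_brain"] <- 0.96
  if (!("other_brain" %in% names(region_cbf)))
    region_cbf["other_brain"] <- 2.5
  t1_default <- c(neocortex = 1.8, corpus_callosum = 1.6, hippocampus = 1.75,
                  other_brain = 1.7, blood_capillary = 2.2,
                  phantom_60 = 1.6, phantom_70 = 1.6, phantom_80 = 1.6,
                  phantom_90 = 1.6, phantom_100 = 1.6)
  if (!is.null(region_t1)) t1_default[names(region_t1)] <- region_t1

  nx <- shape[1]; ny <- shape[2]; nz <- shape[3]
  lab <- array(0L, shape)
  labels <- castrr_labels()

  # In-plane coordinates (same geometry on every slice: cylinders).
  xg <- matrix(seq_len(nx), nx, ny)
  yg <- matrix(seq_len(ny), nx, ny, byrow = TRUE)

  place <- function(lab, region2d, code) {
    sel <- which(region2d)
    for (z in seq_len(nz)) {
      sl <- lab[, , z]
      if (any(sl[sel] != 0L))
        stopf("overlapping label placement for '%s'",
              names(labels)[labels == code])
      sl[sel] <- code
      lab[, , z] <- sl
    }
    lab
  }

  # Brain: concentric elliptical shells.
  cx <- 0.38 * nx; cy <- 0.50 * ny
  a <- 0.28 * nx; b <- 0.33 * ny
  r <- sqrt(((xg - cx) / a)^2 + ((yg - cy) / b)^2)
  lab <- place(lab, r <= 0.33, labels[["hippocampus"]])
  lab <- place(lab, r > 0.33 & r <= 0.60, labels[["other_brain"]])
  lab <- place(lab, r > 0.60 & r <= 0.72, labels[["corpus_callosum"]])
  lab <- place(lab, r > 0.72 & r <= 1.00, labels[["neocortex"]])

  # The blood tube is the single reference every BBPC voxel is divided by,
  # so it gets the largest reference ROI; sized so its eroded ROI-mean
  # sampling error stays well below the mapped regional differences.
  disk <- function(x0, y0, rad) (xg - x0)^2 + (yg - y0)^2 <= rad^2
  lab <- place(lab, disk(0.70 * nx, 0.10 * ny, 0.090 * ny),
               labels[["blood_capillary"]])
  ph_y <- ny * c(0.15, 0.32, 0.50, 0.68, 0.85)
  for (i in seq_along(ph_y))
    lab <- place(lab, disk(0.84 * nx, ph_y[i], 0.050 * ny),
                 labels[[phantom_label_names()[i]]])

  pd_blood <- wc_blood * pd_water
  pd <- array(0, shape); t1 <- array(1.6, shape)
  cbf <- array(0, shape); bbpc <- array(0, shape)
  for (nm in brain_label_names()) {
    sel <- lab == labels[[nm]]
    pd[sel] <- region_bbpc[[nm]] * 1.04 * pd_blood
    cbf[sel] <- region_cbf[[nm]]
    bbpc[sel] <- region_bbpc[[nm]]
    t1[sel] <- t1_default[[nm]]
  }
  sel <- lab == labels[["blood_capillary"]]
  pd[sel] <- pd_blood; t1[sel] <- t1_default[["blood_capillary"]]
  for (i in seq_along(ph_y)) {
    nm <- phantom_label_names()[i]
    sel <- lab == labels[[nm]]
    pd[sel] <- c(0.60, 0.70, 0.80, 0.90, 1.00)[i] * pd_water
    t1[sel] <- t1_default[[nm]]
  }

  structure(list(label_map = lab, pd_truth = pd, t1_truth = t1,
                 cbf_truth = cbf, bbpc_truth = bbpc,
                 voxel_size = voxel_size, pd_water = pd_water,
                 pd_blood = pd_blood, region_bbpc = region_bbpc,
                 region_cbf = region_cbf, seed = as.integer(seed)),
            class = "castrr_phantom")
}

#' @export
print.castrr_phantom <- function(x, ...) {
  d <- dim(x$label_map)
  cat(sprintf("Digital mouse-head phantom: %d x %d x %d voxels (%s mm)\n",
              d[1], d[2], d[3], paste(signif(x$voxel_size, 4), collapse = " x ")))
  counts <- table(factor(x$label_map, levels = castrr_labels(),
                         labels = names(castrr_labels())))
  cat("Label volumes (voxels):\n")
  print(counts)
  cat(sprintf("BBPC truths: %s\n",
              paste(sprintf("%s=%.2f", names(x$region_bbpc), x$region_bbpc),
                    collapse = ", ")))
  invisible(x)
}

#' Logical brain mask of a phantom (union of the brain tissue labels)
#' @param phantom A `castrr_phantom`.
#' @return 3-D logical array.
#' @export
phantom_brain_mask <- function(phantom) {
  labels <- castrr_labels()
  array(phantom$label_map %in% labels[brain_label_names()],
        dim(phantom$label_map))
}
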