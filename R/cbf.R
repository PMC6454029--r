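
#' Mean control-label difference and normalization volume
#'
#' Averages the perfusion-weighted difference over repetitions:
#' `dm = mean_r(control - label)`; the M0 normalization is the separate
#' unlabeled long-TR scan, which carries the receiver coil profile so that
#' the ratio `dm / m0` is coil-independent.
#'
#' @param series A [simulate_pcasl()] object (or list with 4-D `control`,
#'   `label` and 3-D `m0_norm`).
#' @return List with 3-D arrays `dm` and `m0`.
#' @export
mean_difference <- function(series) {
  assert_that(all(dim(series$control) == dim(series$label)),
              "control/label shape mismatch")
  d <- dim(series$control)
  assert_that(length(d) == 4 && d[4] >= 1, "need a 4-D series with >= 1 pair")
  dm <- array(rowMeans(matrix(series$control - series$label, ncol = d[4])),
              d[1:3])
  list(dm = dm, m0 = series$m0_norm)
}

#' Quantify cerebral blood flow from a pCASL difference map
#'
#' Single-compartment quantification:
#' `CBF = 60 * lambda * dm * exp(PLD/T1b) / (2 * alpha * T1b * m0 * (1 - exp(-LD/T1b)))`
#' in mL/g/min, with T1b in seconds and the factor 60 converting per-second
#' flow to per-minute. With zero post-label delay the decay factor is
#' exactly 1. Negative values are retained (noise can produce them);
#' non-positive `m0` voxels inside the mask are flagged `NA` with a
#' warning.
#'
#' @param dm 3-D mean difference map.
#' @param m0 3-D normalization map, positive within the mask.
#' @param params A [quant_params()].
#' @param lambda Partition coefficient: a single constant (mL/g) or a 3-D
#'   map such as `bbpc` from [compute_bbpc()].
#' @param mask 3-D logical; defaults to `m0 > 0`.
#' @return Object of class `castrr_cbf_map`: `cbf` (mL/g/min),
#'   `lambda_used`, `mask`.
#' @export
quantify_cbf <- function(dm, m0, params = quant_params(),
                         lambda = params$lambda_const, mask = NULL) {
  stopifnot(inherits(params, "castrr_quant_params"))
  assert_that(all(dim(dm) == dim(m0)), "dm/m0 shape mismatch")
  if (is.null(mask)) mask <- m0 > 0
  assert_that(all(dim(mask) == dim(dm)), "mask shape mismatch")
  lam <- if (length(lambda) == 1) array(lambda, dim(dm)) else lambda
  assert_that(all(dim(lam) == dim(dm)), "lambda map shape mismatch")
  assert_that(all(lam[mask & !is.na(lam)] > 0), "lambda must be positive")
  bad <- mask & (!is.finite(m0) | m0 <= 0)
  if (any(bad))
    warning(sprintf("%d in-mask voxels with non-positive m0 flagged absent",
                    sum(bad)))
  cbf <- array(NA_real_, dim(dm))
  use <- mask & !bad & !is.na(lam)
  cbf[use] <- 60 * lam[use] * dm[use] * exp(params$pld_s / params$t1_blood_s) /
    (2 * params$alpha * params$t1_blood_s * m0[use] *
       (1 - exp(-params$ld_s / params$t1_blood_s)))
  lambda_used <- if (length(lambda) == 1) unname(lambda) else lam
  structure(list(cbf = cbf, lambda_used = lambda_used, mask = use,
                 params = params),
            class = "castrr_cbf_map")
}

#' @export
print.castrr_cbf_map <- function(x, ...) {
  v <- x$cbf[x$mask]
  lam <- if (length(x$lambda_used) == 1)
    sprintf("constant %.2f mL/g", x$lambda_used) else "voxel-wise BBPC map"
  cat(sprintf("CBF map: %d voxels, mean %.2f mL/g/min (lambda: %s)\n",
              sum(x$mask), mean(v, na.rm = TRUE), lam))
  invisible(x)
}

#' Replace the constant partition coefficient by a voxel-wise BBPC map
#'
#' Rescales an uncorrected CBF map voxel-wise:
#' `cbf_corr = cbf_unc * bbpc / lambda_const`, algebraically identical to
#' re-quantifying with `lambda = bbpc`. Both maps must already live on the
#' same grid (resample the BBPC map first).
#'
#' @param cbf_unc A [quantify_cbf()] result computed with a constant lambda.
#' @param bbpc_on_grid A `castrr_bbpc_map` on the same grid.
#' @return A `castrr_cbf_map` with `lambda_used` set to the BBPC map.
#' @export
correct_with_bbpc <- function(cbf_unc, bbpc_on_grid) {
  stopifnot(inherits(cbf_unc, "castrr_cbf_map"),
            inherits(bbpc_on_grid, "castrr_bbpc_map"))
  assert_that(length(cbf_unc$lambda_used) == 1,
              "cbf_unc must be quantified with a constant lambda")
  if (!all(dim(cbf_unc$cbf) == dim(bbpc_on_grid$bbpc)))
    stopf("grid mismatch: resample the BBPC map to the CBF grid first")
  mask <- cbf_unc$mask & bbpc_on_grid$mask
  cbf <- array(NA_real_, dim(cbf_unc$cbf))
  cbf[mask] <- cbf_unc$cbf[mask] * bbpc_on_grid$bbpc[mask] /
    cbf_unc$lambda_used
  structure(list(cbf = cbf, lambda_used = bbpc_on_grid$bbpc, mask = mask,
                 params = cbf_unc$params),
            class = "castrr_cbf_map")
}
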