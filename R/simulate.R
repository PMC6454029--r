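
#' Noise level for a target SNR at the longest repetition time
#'
#' The series' signal-to-noise ratio is quoted at the most proton-density-
#' weighted volume: `SNR = (mean brain signal at the longest TR) / sigma`,
#' with sigma the single-average noise SD. This returns the sigma that
#' achieves a requested SNR for a given phantom.
#'
#' @param phantom A [make_default_phantom()] object.
#' @param snr Target signal-to-noise ratio (> 0).
#' @param tr_s Repetition time at which SNR is quoted (default 2 s, the
#'   longest TR of the reference protocol).
#' @return Single-average noise SD in signal units.
#' @export
noise_sigma_for_snr <- function(phantom, snr, tr_s = 2) {
  assert_that(snr > 0, "snr must be positive")
  br <- phantom_brain_mask(phantom)
  sig <- mean((phantom$pd_truth * (1 - exp(-tr_s / phantom$t1_truth)))[br])
  sig / snr
}

# Per-volume substream: each simulated volume draws from its own seed so
# adding volumes never perturbs earlier ones.
substream_seed <- function(seed, i) as.integer(seed) + 7919L * as.integer(i)

add_noise <- function(signal, sigma, n_avg, model, seed) {
  if (sigma == 0) return(signal)
  set.seed(seed)
  n <- length(signal)
  acc <- numeric(n)
  for (k in seq_len(n_avg)) {
    if (model == "gaussian") {
      acc <- acc + signal + rnorm(n, 0, sigma)
    } else {
      acc <- acc + sqrt((signal + rnorm(n, 0, sigma))^2 + rnorm(n, 0, sigma)^2)
    }
  }
  acc / n_avg
}

#' Simulate a multi-TR saturation-recovery image series
#'
#' Forward model per voxel: `S(TR) = M0 * (1 - exp(-TR / T1))`, evaluated at
#' every repetition time in `spec`; each returned volume is the mean of
#' `averages[i]` independent noisy realizations, so its effective noise SD
#' is `noise_sigma / sqrt(averages[i])`.
#'
#' @param phantom A [make_default_phantom()] object supplying `pd_truth`
#'   (the M0 map) and `t1_truth`.
#' @param spec An [acquisition_spec()].
#' @return Object of class `castrr_recovery_series`: `volumes` (list of 3-D
#'   arrays, one per TR), `tr_list_s`, `averages`, `te_s`, `voxel_size`.
#' @examples
#' ph <- make_default_phantom()
#' ser <- simulate_recovery_series(ph, acquisition_spec())
#' length(ser$volumes)
#' @export
simulate_recovery_series <- function(phantom, spec = acquisition_spec()) {
  stopifnot(inherits(phantom, "castrr_phantom"),
            inherits(spec, "castrr_acq_spec"))
  assert_that(all(is.finite(phantom$pd_truth)) && all(is.finite(phantom$t1_truth)),
              "phantom truth maps must be finite")
  vols <- vector("list", length(spec$tr_list_s))
  for (i in seq_along(spec$tr_list_s)) {
    s <- phantom$pd_truth * (1 - exp(-spec$tr_list_s[i] / phantom$t1_truth))
    s <- add_noise(as.vector(s), spec$noise_sigma, spec$averages[i],
                   spec$noise_model, substream_seed(spec$seed, i))
    vols[[i]] <- array(s, dim(phantom$pd_truth))
  }
  structure(list(volumes = vols, tr_list_s = spec$tr_list_s,
                 averages = spec$averages, te_s = spec$te_s,
                 voxel_size = phantom$voxel_size),
            class = "castrr_recovery_series")
}

#' @export
print.castrr_recovery_series <- function(x, ...) {
  d <- dim(x$volumes[[1]])
  cat(sprintf("Recovery series: %d TRs (%s s), averages (%s), %d x %d x %d\n",
              length(x$tr_list_s), paste(x$tr_list_s, collapse = ", "),
              paste(x$averages, collapse = ", "), d[1], d[2], d[3]))
  invisible(x)
}

# Smooth multiplicative coil-sensitivity surrogate (surface-coil-like
# in-plane falloff), applied identically to control, label and
# normalization volumes so the normalization scan cancels it.
default_bias_field <- function(shape, strength = 0.3) {
  xg <- matrix(seq_len(shape[1]), shape[1], shape[2])
  yg <- matrix(seq_len(shape[2]), shape[1], shape[2], byrow = TRUE)
  f2d <- 1 + strength * exp(-(((xg - 0.35 * shape[1]) / (0.6 * shape[1]))^2 +
                              ((yg - 0.25 * shape[2]) / (0.6 * shape[2]))^2))
  array(rep(f2d, shape[3]), shape)
}

#' Simulate a pCASL control/label series plus normalization scan
#'
#' The per-voxel label-control difference is set by inverting the CBF
#' quantification equation, so quantifying the noiseless output with the
#' same parameters and partition coefficient recovers `cbf_truth` exactly:
#' `dM = cbf * 2 * alpha * T1b * M0 * (1 - exp(-LD/T1b)) / (60 * lambda * exp(PLD/T1b))`.
#' Control and label are split symmetrically about the proton-density
#' signal M0; the unlabeled normalization volume is M0 plus averaged noise.
#'
#' @param phantom A [make_default_phantom()] object; `pd_truth` provides the
#'   M0 signal and `cbf_truth` the flow ground truth.
#' @param params A [quant_params()].
#' @param n_pairs Number of control/label repetitions (>= 1).
#' @param noise_sigma Additive Gaussian noise SD per repetition, signal units.
#' @param lambda_truth `"const"` to generate with the constant
#'   `params$lambda_const`, `"bbpc"` to use the phantom's voxel-wise
#'   `bbpc_truth`, or a single positive number.
#' @param seed Integer seed (per-volume substreams).
#' @param norm_averages Averages for the normalization volume (default 6,
#'   as in the long-TR unlabeled scan of the reference protocol).
#' @param bias_field Optional 3-D multiplicative coil-profile field (or
#'   `TRUE` for a built-in smooth field) applied identically to all volumes.
#' @return Object of class `castrr_asl_series`: `control` and `label`
#'   (4-D arrays x,y,z,repetition), `m0_norm` (3-D), `n_pairs`, `voxel_size`.
#' @export
simulate_pcasl <- function(phantom, params = quant_params(), n_pairs = 120L,
                           noise_sigma = 0, lambda_truth = "const",
                           seed = 0L, norm_averages = 6L, bias_field = NULL) {
  stopifnot(inherits(phantom, "castrr_phantom"),
            inherits(params, "castrr_quant_params"))
  assert_that(is_count(n_pairs), "n_pairs must be an integer >= 1")
  assert_that(noise_sigma >= 0, "noise_sigma must be >= 0")
  lam <- if (identical(lambda_truth, "bbpc")) {
    phantom$bbpc_truth
  } else if (identical(lambda_truth, "const")) {
    array(params$lambda_const, dim(phantom$pd_truth))
  } else {
    assert_that(is.numeric(lambda_truth) && all(lambda_truth > 0),
                "lambda_truth must be 'const', 'bbpc', or positive numeric")
    array(lambda_truth, dim(phantom$pd_truth))
  }
  m0 <- phantom$pd_truth
  dm <- array(0, dim(m0))
  act <- phantom$cbf_truth > 0 & lam > 0
  dm[act] <- phantom$cbf_truth[act] * 2 * params$alpha * params$t1_blood_s *
    m0[act] * (1 - exp(-params$ld_s / params$t1_blood_s)) /
    (60 * lam[act] * exp(params$pld_s / params$t1_blood_s))
  if (isTRUE(bias_field)) bias_field <- default_bias_field(dim(m0))
  if (is.null(bias_field)) bias_field <- array(1, dim(m0))
  stopifnot(all(dim(bias_field) == dim(m0)))

  shape <- dim(m0)
  ctl <- array(0, c(shape, n_pairs)); lbl <- array(0, c(shape, n_pairs))
  for (r in seq_len(n_pairs)) {
    ctl[, , , r] <- bias_field *
      array(add_noise(as.vector(m0 + dm / 2), noise_sigma, 1L, "gaussian",
                      substream_seed(seed, 2L * r - 1L)), shape)
    lbl[, , , r] <- bias_field *
      array(add_noise(as.vector(m0 - dm / 2), noise_sigma, 1L, "gaussian",
                      substream_seed(seed, 2L * r)), shape)
  }
  m0_norm <- bias_field *
    array(add_noise(as.vector(m0), noise_sigma, as.integer(norm_averages),
                    "gaussian", substream_seed(seed, 2L * n_pairs + 1L)), shape)
  structure(list(control = ctl, label = lbl, m0_norm = m0_norm,
                 n_pairs = as.integer(n_pairs),
                 voxel_size = phantom$voxel_size, dm_truth = dm),
            class = "castrr_asl_series")
}

#' @export
print.castrr_asl_series <- function(x, ...) {
  d <- dim(x$m0_norm)
  cat(sprintf("pCASL series: %d control/label pairs, %d x %d x %d voxels\n",
              x$n_pairs, d[1], d[2], d[3]))
  invisible(x)
}
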