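#' Acquisition specification for a multi-TR recovery series
#'
#' Defaults reproduce the reference protocol: six repetition times
#' (125, 187, 250, 500, 1000, 2000 ms) with 4, 4, 2, 1, 1, 1 averages and
#' TE = 3.2 ms. Times are stored in seconds.
#'
#' @param tr_list_s Strictly increasing positive repetition times, seconds.
#' @param averages One positive integer per TR; an n-average image has
#'   effective noise SD `noise_sigma / sqrt(n)`.
#' @param te_s Echo time, seconds (recorded only; no T2* decay is applied).
#' @param noise_sigma SD of additive noise on a single average, signal units.
#' @param noise_model `"gaussian"` (default) or `"rician"` (magnitude of a
#'   complex signal with i.i.d. Gaussian noise on both channels).
#' @param seed Integer seed expanded into per-volume substreams.
#' @return Object of class `castrr_acq_spec`.
#' @export
acquisition_spec <- function(tr_list_s = c(0.125, 0.187, 0.250, 0.500, 1.000, 2.000),
                             averages = c(4L, 4L, 2L, 1L, 1L, 1L),
                             te_s = 0.0032,
                             noise_sigma = 0,
                             noise_model = c("gaussian", "rician"),
                             seed = 0L) {
  noise_model <- match.arg(noise_model)
  assert_that(length(tr_list_s) >= 1 && all(tr_list_s > 0),
              "tr_list_s must be strictly positive")
  assert_that(all(diff(tr_list_s) > 0), "tr_list_s must be strictly increasing")
  assert_that(length(averages) == length(tr_list_s),
              "averages must have one entry per TR")
  assert_that(all(vapply(averages, is_count, logical(1))),
              "averages must be integers >= 1")
  assert_that(is.numeric(noise_sigma) && length(noise_sigma) == 1 &&
                noise_sigma >= 0, "noise_sigma must be a single value >= 0")
  structure(list(tr_list_s = as.numeric(tr_list_s),
                 averages = as.integer(averages), te_s = te_s,
                 noise_sigma = noise_sigma, noise_model = noise_model,
                 seed = as.integer(seed)),
            class = "castrr_acq_spec")
}

#' pCASL quantification parameters
#'
#' Defaults follow the reference protocol at 7T: label efficiency 0.85,
#' blood T1 = 2.2 s, label duration 1.6 s, zero post-label delay, the
#' conventional constant partition coefficient 0.9 mL/g, and brain tissue
#' density 1.04 g/mL.
#'
#' @param alpha Label efficiency, in (0, 1].
#' @param t1_blood_s Longitudinal relaxation time of blood, seconds.
#' @param ld_s Label duration, seconds.
#' @param pld_s Post-label delay, seconds (>= 0).
#' @param lambda_const Constant partition coefficient, mL/g.
#' @param density_brain Brain tissue density, g/mL.
#' @return Object of class `castrr_quant_params`.
#' @export
quant_params <- function(alpha = 0.85, t1_blood_s = 2.2, ld_s = 1.6,
                         pld_s = 0, lambda_const = 0.9,
                         density_brain = 1.04) {
  assert_that(alpha > 0 && alpha <= 1, "alpha must be in (0, 1]")
  assert_that(t1_blood_s > 0, "t1_blood_s must be positive")
  assert_that(ld_s > 0, "ld_s must be positive")
  assert_that(pld_s >= 0, "pld_s must be >= 0")
  assert_that(lambda_const > 0, "lambda_const must be positive")
  assert_that(density_brain > 0, "density_brain must be positive")
  structure(list(alpha = alpha, t1_blood_s = t1_blood_s, ld_s = ld_s,
                 pld_s = pld_s, lambda_const = lambda_const,
                 density_brain = density_brain, minutes_factor = 60),
            class = "castrr_quant_params")
}

#' @export
print.castrr_quant_params <- function(x, ...) {
  cat(sprintf(paste0("pCASL quantification parameters: alpha=%.2f, ",
                     "T1,blood=%.2f s, LD=%.2f s, PLD=%.2f s, ",
                     "lambda=%.2f mL/g, rho_brain=%.2f g/mL\n"),
              x$alpha, x$t1_blood_s, x$ld_s, x$pld_s, x$lambda_const,
              x$density_brain))
  invisible(x)
}
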