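
T1_BOUNDS <- c(0.1, 5.0)  # seconds; brackets tissue, blood, doped phantoms at 7T

# Two-point T1 initializer from the shortest and longest TR, assuming the
# longest-TR signal is near the M0 asymptote; falls back to 1.6 s.
t1_init_two_point <- function(signal, tr) {
  s1 <- signal[1]; sn <- signal[length(signal)]
  if (sn <= 0 || s1 <= 0 || s1 >= sn) return(1.6)
  ratio <- s1 / sn
  t1 <- -tr[1] / log(1 - ratio)
  if (!is.finite(t1)) return(1.6)
  min(max(t1, T1_BOUNDS[1]), T1_BOUNDS[2])
}

#' Fit the saturation-recovery model to one voxel's signal
#'
#' Weighted nonlinear least squares for `S(TR) = M0 * (1 - exp(-TR/T1))`
#' using bounded Levenberg-Marquardt (minpack.lm), minimizing
#' `sum(w_i * (S_i - M0*(1 - exp(-TR_i/T1)))^2)` over `M0 > 0`,
#' `T1` in \[0.1, 5\] s. Initialization: `M0 = 1.05 * max(S)`, `T1` from a
#' two-point estimate at the shortest and longest TR. A fit that stops at
#' the iteration cap or at a T1 bound is reported as not converged rather
#' than silently clipped.
#'
#' @param signal Numeric vector of voxel intensities, one per TR (>= 3).
#' @param tr_list_s Repetition times, seconds.
#' @param weights Positive weights, typically the number of averages per TR
#'   (an n-average mean has variance proportional to 1/n).
#' @return List with `m0`, `t1_s`, `rss` (weighted residual sum of squares)
#'   and logical `converged`.
#' @examples
#' tr <- c(0.125, 0.25, 0.5, 1, 2)
#' fit_voxel(100 * (1 - exp(-tr / 1.6)), tr)
#' @export
fit_voxel <- function(signal, tr_list_s, weights = rep(1, length(signal))) {
  assert_that(length(signal) >= 3, "at least 3 TR points are required")
  assert_that(length(tr_list_s) == length(signal) &&
                length(weights) == length(signal),
              "signal, tr_list_s and weights must have equal length")
  assert_that(all(weights > 0), "weights must be positive")
  if (all(signal == 0) || !all(is.finite(signal)))
    return(list(m0 = 0, t1_s = NA_real_, rss = 0, converged = FALSE))
  sw <- sqrt(weights)
  start <- c(m0 = 1.05 * max(signal), t1 = t1_init_two_point(signal, tr_list_s))
  fit <- minpack.lm::nls.lm(
    par = start,
    fn = function(p, s, tr, sw) sw * (s - p[1] * (1 - exp(-tr / p[2]))),
    s = signal, tr = tr_list_s, sw = sw,
    lower = c(1e-12, T1_BOUNDS[1]), upper = c(Inf, T1_BOUNDS[2]),
    control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-10,
                                         ptol = 1e-10))
  m0 <- fit$par[[1]]; t1 <- fit$par[[2]]
  eps <- 1e-8
  at_bound <- t1 <= T1_BOUNDS[1] + eps || t1 >= T1_BOUNDS[2] - eps || m0 <= eps
  converged <- fit$info %in% 1:3 && fit$niter < 200 && !at_bound
  list(m0 = m0, t1_s = t1, rss = fit$deviance, converged = converged)
}

#' Voxel-wise M0/T1 map from a recovery series
#'
#' Applies [fit_voxel()] to every in-mask voxel with weights equal to the
#' per-TR number of averages (inverse-variance weighting of averaged
#' noise). Deterministic given its inputs.
#'
#' @param series A [simulate_recovery_series()] object (or any list with
#'   `volumes`, `tr_list_s`, `averages`).
#' @param mask 3-D logical array selecting voxels to fit; see [auto_mask()].
#' @return Object of class `castrr_pd_map` with 3-D fields `m0`, `t1_s`,
#'   `rss`, `converged`, `mask`; `m0`/`t1_s` are `NA` outside the mask and
#'   where the fit failed.
#' @export
fit_recovery_map <- function(series, mask) {
  stopifnot(inherits(series, "castrr_recovery_series") || is.list(series))
  d <- dim(series$volumes[[1]])
  assert_that(all(dim(mask) == d), "mask shape must match the series")
  assert_that(any(mask), "mask is empty")
  nvol <- length(series$volumes)
  sig <- vapply(series$volumes, as.vector, numeric(prod(d)))  # voxels x TRs
  idx <- which(mask)
  m0 <- array(NA_real_, d); t1 <- array(NA_real_, d)
  rss <- array(NA_real_, d); conv <- array(FALSE, d)
  w <- as.numeric(series$averages)
  for (v in idx) {
    f <- fit_voxel(sig[v, ], series$tr_list_s, w)
    conv[v] <- f$converged
    rss[v] <- f$rss
    if (f$converged) { m0[v] <- f$m0; t1[v] <- f$t1_s }
  }
  structure(list(m0 = m0, t1_s = t1, rss = rss, converged = conv,
                 mask = mask, voxel_size = series$voxel_size),
            class = "castrr_pd_map")
}

#' @export
print.castrr_pd_map <- function(x, ...) {
  n <- sum(x$mask)
  cat(sprintf("Relative proton-density map: %d fitted voxels, %.1f%% converged\n",
              n, 100 * sum(x$converged) / max(n, 1)))
  invisible(x)
}

#' @export
summary.castrr_pd_map <- function(object, ...) {
  ok <- object$converged
  out <- list(
    n_mask = sum(object$mask), n_converged = sum(ok),
    m0 = summary(object$m0[ok]), t1_s = summary(object$t1_s[ok]))
  cat(sprintf("Fitted %d / %d in-mask voxels\n", out$n_converged, out$n_mask))
  cat("M0 (signal units):\n"); print(out$m0)
  cat("T1 (s):\n"); print(out$t1_s)
  invisible(out)
}

#' Automatic foreground mask (skull-strip surrogate)
#'
#' Thresholds the longest-TR (most proton-density-weighted) volume at the
#' Otsu optimum, applies an in-plane morphological opening of radius 1,
#' and removes small connected components, keeping the brain, blood sample
#' and calibration phantoms as separate foreground objects. An externally
#' supplied mask should always be preferred when one exists.
#'
#' @param series A recovery series.
#' @param min_component Minimum in-plane component size kept, voxels.
#' @return 3-D logical array.
#' @export
auto_mask <- function(series, min_component = 9L) {
  vol <- series$volumes[[length(series$volumes)]]
  rng <- range(vol)
  assert_that(rng[2] > rng[1], "uniform image: no foreground to segment")
  vn <- (vol - rng[1]) / (rng[2] - rng[1])
  th <- EBImage::otsu(EBImage::Image(matrix(as.vector(vn), ncol = 1L)),
                      range = c(0, 1))
  raw <- array(vn > th, dim(vol))
  opened <- dilate_inplane(erode_inplane(raw))
  out <- filter_small_components(opened, min_component)
  assert_that(any(out), "no foreground component survived masking")
  out
}
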