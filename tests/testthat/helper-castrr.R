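# Shared fixtures: built in code, cached per test run.

protocol_trs <- function() c(0.125, 0.187, 0.250, 0.500, 1.000, 2.000)
protocol_averages <- function() c(4L, 4L, 2L, 1L, 1L, 1L)

default_phantom_cached <- local({
  ph <- NULL
  function() {
    if (is.null(ph)) ph <<- make_default_phantom()
    ph
  }
})

noiseless_series_cached <- local({
  ser <- NULL
  function() {
    if (is.null(ser))
      ser <<- simulate_recovery_series(default_phantom_cached(),
                                       acquisition_spec())
    ser
  }
})

noiseless_pd_map_cached <- local({
  pd <- NULL
  function() {
    if (is.null(pd)) {
      ph <- default_phantom_cached()
      pd <<- fit_recovery_map(noiseless_series_cached(), ph$label_map > 0)
    }
    pd
  }
})

# Full recovery -> BBPC chain at a given noise level/seed.
bbpc_chain <- function(snr = Inf, seed = 0L, phantom = default_phantom_cached(),
                       gain = 1) {
  sigma <- if (is.finite(snr)) noise_sigma_for_snr(phantom, snr) else 0
  ser <- simulate_recovery_series(phantom,
                                  acquisition_spec(noise_sigma = sigma,
                                                   seed = seed))
  if (gain != 1) ser$volumes <- lapply(ser$volumes, function(v) gain * v)
  pd <- fit_recovery_map(ser, auto_mask(ser))
  cal <- fit_calibration(extract_phantom_readout(pd, phantom$label_map))
  wc <- apply_calibration(pd, cal)
  bw <- blood_reference(wc, phantom$label_map)
  compute_bbpc(wc, bw, phantom_brain_mask(phantom))
}

# Brute-force weighted-LSQ grid search over (M0, T1), refined 3 times.
# Independent of the Levenberg-Marquardt path used by fit_voxel.
grid_fit_voxel <- function(signal, tr, weights, n = 61L) {
  m0_rng <- c(0.2, 2.5) * max(signal)
  t1_rng <- c(0.1, 5.0)
  best <- NULL
  for (ref in 1:3) {
    m0s <- seq(m0_rng[1], m0_rng[2], length.out = n)
    t1s <- seq(t1_rng[1], t1_rng[2], length.out = n)
    rss <- outer(m0s, t1s, function(m, t) {
      sapply(seq_along(m), function(i)
        sum(weights * (signal - m[i] * (1 - exp(-tr / t[i])))^2))
    })
    k <- arrayInd(which.min(rss), dim(rss))
    best <- c(m0 = m0s[k[1]], t1 = t1s[k[2]])
    dm <- diff(m0s)[1]; dt <- diff(t1s)[1]
    m0_rng <- best[1] + c(-3, 3) * dm
    t1_rng <- pmax(best[2] + c(-3, 3) * dt, 1e-3)
  }
  list(par = best, res = c(m0 = dm, t1 = dt))
}

# Tiny atlas containing only a hippocampus label on given slices.
hippo_atlas <- function(slices, nz = 6L) {
  a <- array(0L, c(8L, 8L, nz))
  for (z in slices) a[3:5, 3:5, z] <- castrr_labels()[["hippocampus"]]
  a
}
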