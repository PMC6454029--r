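
#' Default synthetic run configuration
#'
#' Nested list consumed by [run_pipeline()]. Times are accepted in ms at
#' this boundary and converted to seconds internally. The defaults
#' reproduce the reference study conditions: six-TR recovery protocol,
#' SNR 50 (single-average noise SD = pure-water signal / 50), 120 pCASL
#' pairs with noise at 1% of the normalization signal, and region ground
#' truths from the reported group means.
#'
#' @param seed Integer master seed.
#' @return Nested configuration list.
#' @export
default_config <- function(seed = 0L) {
  list(
    seed = as.integer(seed),
    phantom = list(shape = c(64L, 64L, 4L),
                   region_bbpc = list(neocortex = 0.99, corpus_callosum = 0.93,
                                      hippocampus = 0.95),
                   region_cbf = list(neocortex = 2.81, corpus_callosum = 1.44,
                                     hippocampus = 2.90),
                   pd_water = 100, wc_blood = 0.85,
                   voxel_size_mm = c(0.109375, 0.109375, 1)),
    acquisition = list(tr_ms = c(125, 187, 250, 500, 1000, 2000),
                       averages = c(4L, 4L, 2L, 1L, 1L, 1L),
                       te_ms = 3.2, snr = 50,
                       noise_model = "gaussian"),
    quant = list(alpha = 0.85, t1_blood_s = 2.2, ld_ms = 1600, pld_ms = 0,
                 lambda_const = 0.9, density_brain = 1.04),
    pcasl = list(n_pairs = 120L, noise_pct_of_m0 = 1, norm_averages = 6L,
                 lambda_truth = "const"),
    flags = list(ratio_only = FALSE, assume_aligned = TRUE,
                 use_atlas_mask = FALSE))
}

config_from_yaml <- function(path) {
  assert_that(file.exists(path), "config file not found: %s", path)
  cfg <- yaml::read_yaml(path)
  base <- default_config(seed = if (is.null(cfg$seed)) 0L else cfg$seed)
  modifyList(base, cfg)
}

validate_config <- function(config) {
  for (p in c("phantom", "acquisition", "quant", "pcasl", "flags"))
    assert_that(!is.null(config[[p]]), "config is missing section '%s'", p)
  # boundary conversion and constructor-level validation happen here so a
  # broken config fails before any computation
  acq <- config$acquisition
  assert_that(acq$snr > 0, "acquisition snr must be positive")
  spec <- acquisition_spec(tr_list_s = acq$tr_ms / 1000,
                           averages = acq$averages, te_s = acq$te_ms / 1000,
                           noise_sigma = 0,  # set per phantom at simulate time
                           noise_model = acq$noise_model,
                           seed = config$seed)
  q <- config$quant
  params <- quant_params(alpha = q$alpha, t1_blood_s = q$t1_blood_s,
                         ld_s = q$ld_ms / 1000, pld_s = q$pld_ms / 1000,
                         lambda_const = q$lambda_const,
                         density_brain = q$density_brain)
  assert_that(is_count(config$pcasl$n_pairs), "pcasl n_pairs must be >= 1")
  list(spec = spec, params = params)
}

stage_simulate <- function(config, run_dir) {
  v <- validate_config(config)
  ph <- make_default_phantom(region_bbpc = config$phantom$region_bbpc,
                             region_cbf = config$phantom$region_cbf,
                             shape = config$phantom$shape,
                             seed = config$seed,
                             pd_water = config$phantom$pd_water,
                             wc_blood = config$phantom$wc_blood,
                             voxel_size = config$phantom$voxel_size_mm)
  write_vol(ph$label_map, file.path(run_dir, "atlas.nii"), ph$voxel_size,
            datatype = "int16")
  for (nm in c("pd_truth", "t1_truth", "cbf_truth", "bbpc_truth"))
    write_vol(ph[[nm]], file.path(run_dir, paste0(nm, ".nii")), ph$voxel_size)
  spec <- v$spec
  spec$noise_sigma <- noise_sigma_for_snr(ph, config$acquisition$snr,
                                          max(spec$tr_list_s))
  write_recovery_series(simulate_recovery_series(ph, spec), run_dir)
  noise <- config$pcasl$noise_pct_of_m0 / 100 * config$phantom$pd_water
  asl <- simulate_pcasl(ph, v$params, n_pairs = config$pcasl$n_pairs,
                        noise_sigma = noise,
                        lambda_truth = config$pcasl$lambda_truth,
                        seed = config$seed + 1L,
                        norm_averages = config$pcasl$norm_averages)
  write_asl_series(asl, run_dir)
  invisible(ph)
}

stage_fit_bbpc <- function(config, run_dir) {
  v <- validate_config(config)
  series <- read_recovery_series(run_dir)
  atlas <- read_vol(file.path(run_dir, "atlas.nii"))
  mask <- if (isTRUE(config$flags$use_atlas_mask)) atlas > 0
          else auto_mask(series)
  pd_map <- fit_recovery_map(series, mask)
  for (nm in c("m0", "t1_s", "rss"))
    write_vol(pd_map[[nm]], file.path(run_dir, paste0(nm, ".nii")),
              series$voxel_size)
  write_vol(array(as.integer(pd_map$converged), dim(mask)),
            file.path(run_dir, "converged.nii"), series$voxel_size, "int16")
  write_vol(array(as.integer(mask), dim(mask)),
            file.path(run_dir, "mask.nii"), series$voxel_size, "int16")
  readout <- extract_phantom_readout(pd_map, atlas)
  calib <- fit_calibration(readout)
  write.table(cbind(phantom = rownames(readout), readout),
              file.path(run_dir, "phantom_readout.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(slope = calib$slope, intercept = calib$intercept,
                            r_squared = calib$r_squared),
                       file.path(run_dir, "calibration.json"),
                       auto_unbox = TRUE, digits = NA)
  wc <- apply_calibration(pd_map, calib,
                          ratio_only = isTRUE(config$flags$ratio_only))
  blood_wc <- blood_reference(wc, atlas)
  labels <- castrr_labels()
  brain_mask <- array(atlas %in% labels[brain_label_names()], dim(atlas))
  bbpc <- compute_bbpc(wc, blood_wc, brain_mask,
                       density_brain = v$params$density_brain)
  write_vol(wc$wc, file.path(run_dir, "wc.nii"), series$voxel_size)
  write_vol(bbpc$bbpc, file.path(run_dir, "bbpc.nii"), series$voxel_size)
  jsonlite::write_json(list(blood_wc_mean = blood_wc,
                            density_brain = bbpc$density_brain),
                       file.path(run_dir, "bbpc_qc.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(bbpc)
}

load_bbpc <- function(run_dir) {
  qc <- jsonlite::read_json(file.path(run_dir, "bbpc_qc.json"),
                            simplifyVector = TRUE)
  bb <- read_vol(file.path(run_dir, "bbpc.nii"))
  structure(list(bbpc = array(bb, dim(bb)), mask = is.finite(bb),
                 blood_wc_mean = qc$blood_wc_mean,
                 density_brain = qc$density_brain,
                 voxel_size = attr(bb, "voxel_size")),
            class = "castrr_bbpc_map")
}

stage_quantify <- function(config, run_dir) {
  v <- validate_config(config)
  asl <- read_asl_series(run_dir)
  md <- mean_difference(asl)
  atlas <- read_vol(file.path(run_dir, "atlas.nii"))
  labels <- castrr_labels()
  brain <- array(atlas %in% labels[brain_label_names()], dim(atlas))
  cbf_unc <- quantify_cbf(md$dm, md$m0, v$params, mask = brain & md$m0 > 0)
  bbpc <- load_bbpc(run_dir)
  vs_c <- bbpc$voxel_size; vs_a <- asl$voxel_size
  grid_c <- grid_spec(dim(bbpc$bbpc), vs_c)
  grid_a <- grid_spec(dim(md$dm), vs_a)
  tr <- rigid_register(bbpc$bbpc, md$m0, grid_c, grid_a,
                       assume_aligned = isTRUE(config$flags$assume_aligned))
  jsonlite::write_json(list(matrix = tr$matrix),
                       file.path(run_dir, "bbpc_to_asl_transform.json"),
                       digits = NA)
  bbpc_on_asl <- resample_to_grid(bbpc, tr, grid_c, grid_a)
  cbf_corr <- correct_with_bbpc(cbf_unc, bbpc_on_asl)
  write_vol(cbf_unc$cbf, file.path(run_dir, "cbf_uncorrected.nii"), vs_a)
  write_vol(cbf_corr$cbf, file.path(run_dir, "cbf_corrected.nii"), vs_a)
  invisible(list(uncorrected = cbf_unc, corrected = cbf_corr))
}

stage_roi_report <- function(config, run_dir) {
  atlas <- read_vol(file.path(run_dir, "atlas.nii"))
  slices <- select_slices(atlas)
  maps <- list(bbpc = read_vol(file.path(run_dir, "bbpc.nii")),
               cbf_uncorrected = read_vol(file.path(run_dir, "cbf_uncorrected.nii")),
               cbf_corrected = read_vol(file.path(run_dir, "cbf_corrected.nii")))
  regions <- c("neocortex", "hippocampus", "corpus_callosum")
  tab <- data.frame(region = regions)
  for (nm in names(maps))
    tab[[nm]] <- unname(region_means(array(maps[[nm]], dim(atlas)), atlas,
                                     slices, regions))
  tab$slices <- paste(slices, collapse = ",")
  write.table(tab, file.path(run_dir, "roi_report.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  tab
}

#' Run the full synthetic quantification pipeline
#'
#' Executes, in order: phantom simulation (recovery series + pCASL),
#' voxel-wise M0/T1 fitting and phantom calibration to a BBPC map,
#' registration/resampling onto the pCASL grid, CBF quantification with
#' and without BBPC correction, and an ROI report on the two centermost
#' hippocampal slices. All volumetric outputs are uncompressed NIfTI; a
#' manifest records the configuration and output checksums, and a rerun
#' with the same seed is bit-identical.
#'
#' @param config Configuration list from [default_config()] (or a path to
#'   a YAML file with the same structure).
#' @param out_dir Run directory to create/populate.
#' @param stages Subset of `c("simulate", "fit-bbpc", "quantify-cbf",
#'   "roi-report")`; earlier stages must already have populated `out_dir`.
#' @return Invisibly, a list with the run directory, the ROI table (when
#'   computed) and the manifest path.
#' @examples
#' \donttest{
#' res <- run_pipeline(default_config(seed = 1), tempfile("castrr-run-"))
#' }
#' @export
run_pipeline <- function(config = default_config(), out_dir,
                         stages = c("simulate", "fit-bbpc", "quantify-cbf",
                                    "roi-report")) {
  if (is.character(config) && length(config) == 1) config <- config_from_yaml(config)
  validate_config(config)  # fail fast before touching the filesystem
  stages <- match.arg(stages, several.ok = TRUE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  report <- NULL
  run_stage <- function(name, fun) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(fun(config, out_dir), error = function(e)
      stopf("stage '%s' failed: %s", name, conditionMessage(e)))
    message(sprintf("[castrr] stage %-12s done in %.1f s", name,
                    proc.time()[["elapsed"]] - t0))
    res
  }
  if ("simulate" %in% stages) run_stage("simulate", stage_simulate)
  if ("fit-bbpc" %in% stages) run_stage("fit-bbpc", stage_fit_bbpc)
  if ("quantify-cbf" %in% stages) run_stage("quantify-cbf", stage_quantify)
  if ("roi-report" %in% stages)
    report <- run_stage("roi-report", stage_roi_report)
  outputs <- list.files(out_dir, full.names = FALSE)
  outputs <- setdiff(outputs, "manifest.json")
  manifest <- list(
    package_version = as.character(utils::packageVersion("castrr")),
    seed = config$seed, config = config, stages = stages,
    labels = as.list(castrr_labels()),
    outputs = as.list(tools::md5sum(file.path(out_dir, sort(outputs)))))
  names(manifest$outputs) <- sort(outputs)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(run_dir = out_dir, report = report,
                 manifest = file.path(out_dir, "manifest.json")))
}
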