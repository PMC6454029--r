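
write_vol <- function(x, file, voxel_size = c(1, 1, 1), datatype = "auto") {
  img <- RNifti::asNifti(x, internal = FALSE)
  RNifti::pixdim(img) <- voxel_size[seq_len(min(length(dim(x)), 3))]
  RNifti::writeNifti(img, file, datatype = datatype)
  invisible(file)
}

read_vol <- function(file) {
  img <- RNifti::readNifti(file)
  structure(array(as.vector(img), dim(img)),
            voxel_size = RNifti::pixdim(img)[1:3])
}

#' Write a recovery series as a 4-D NIfTI plus JSON sidecar
#'
#' @param series A `castrr_recovery_series`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_recovery_series <- function(series, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  d <- dim(series$volumes[[1]])
  stack <- array(unlist(series$volumes), c(d, length(series$volumes)))
  nii <- file.path(dir, "recovery.nii")
  write_vol(stack, nii, series$voxel_size)
  side <- file.path(dir, "recovery.json")
  jsonlite::write_json(list(tr_list_s = series$tr_list_s,
                            averages = series$averages, te_s = series$te_s,
                            voxel_size = series$voxel_size),
                       side, auto_unbox = FALSE, digits = NA)
  invisible(c(nii, side))
}

#' Read a recovery series written by [write_recovery_series()]
#' @param dir Directory holding `recovery.nii` and `recovery.json`.
#' @return A `castrr_recovery_series`.
#' @export
read_recovery_series <- function(dir) {
  side <- jsonlite::read_json(file.path(dir, "recovery.json"),
                              simplifyVector = TRUE)
  stack <- read_vol(file.path(dir, "recovery.nii"))
  d <- dim(stack)
  vols <- lapply(seq_len(d[4]), function(i) array(stack[, , , i], d[1:3]))
  structure(list(volumes = vols, tr_list_s = side$tr_list_s,
                 averages = as.integer(side$averages), te_s = side$te_s,
                 voxel_size = side$voxel_size),
            class = "castrr_recovery_series")
}

write_asl_series <- function(series, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_vol(series$control, file.path(dir, "asl_control.nii"), series$voxel_size)
  write_vol(series$label, file.path(dir, "asl_label.nii"), series$voxel_size)
  write_vol(series$m0_norm, file.path(dir, "asl_m0norm.nii"), series$voxel_size)
  jsonlite::write_json(list(n_pairs = series$n_pairs,
                            voxel_size = series$voxel_size),
                       file.path(dir, "asl.json"), auto_unbox = FALSE,
                       digits = NA)
  invisible(dir)
}

read_asl_series <- function(dir) {
  side <- jsonlite::read_json(file.path(dir, "asl.json"), simplifyVector = TRUE)
  structure(list(control = read_vol(file.path(dir, "asl_control.nii")),
                 label = read_vol(file.path(dir, "asl_label.nii")),
                 m0_norm = read_vol(file.path(dir, "asl_m0norm.nii")),
                 n_pairs = as.integer(side$n_pairs),
                 voxel_size = side$voxel_size),
            class = "castrr_asl_series")
}
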