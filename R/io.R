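## Raw-data container and NIfTI helpers.
##
## The raw container is a versioned single-file serialization with a fixed
## schema mirroring the acquisition layout: "kdata" (coils, excitations,
## samples), "traj" (excitations, samples, 3) in cycles/mm, "bellows"
## (excitations), plus the attributes tr_s, fov_mm, res_mm and seed.
## Reads validate the schema and cross-check array shapes.

RAW_SCHEMA_VERSION <- 1L

#' Write a raw-data container
#'
#' @param kdata a \linkS4class{KSpaceData}
#' @param path output file path
#' @param seed acquisition seed recorded as an attribute
#' @param truth optional list of phantom ground-truth NIfTI paths
#' @return the path, invisibly
#' @export
writeRawContainer <- function(kdata, path, seed = NA_integer_,
                              truth = list()) {
  obj <- list(
    version = RAW_SCHEMA_VERSION,
    kdata = kdata@samples,
    traj = kdata@traj@coords,
    bellows = kdata@bellows@values,
    cycle_fraction = kdata@bellows@cycle_fraction,
    true_state = kdata@bellows@true_state,
    attrs = list(tr_s = kdata@bellows@dt_s, fov_mm = kdata@traj@fov_mm,
                 res_mm = kdata@traj@res_mm, seed = seed,
                 noise_sd = kdata@noise_sd, truth = truth))
  saveRDS(obj, path)
  invisible(path)
}

#' Read a raw-data container
#'
#' @param path container path
#' @return a \linkS4class{KSpaceData}
#' @export
readRawContainer <- function(path) {
  obj <- readRDS(path)
  for (f in c("kdata", "traj", "bellows", "attrs"))
    if (is.null(obj[[f]]))
      stop(sprintf("raw container schema error: missing dataset '%s'", f))
  for (a in c("tr_s", "fov_mm", "res_mm"))
    if (is.null(obj$attrs[[a]]))
      stop(sprintf("raw container schema error: missing attribute '%s'", a))
  dk <- dim(obj$kdata)
  dt <- dim(obj$traj)
  if (length(dk) != 3 || length(dt) != 3 || dt[3] != 3)
    stop("raw container schema error: bad array ranks")
  if (dk[2] != dt[1] || dk[3] != dt[2] || length(obj$bellows) != dk[2])
    stop("raw container consistency error: kdata/traj/bellows shapes disagree")
  res_mm <- obj$attrs$res_mm
  traj <- new("TrajectorySet", coords = obj$traj,
              excitation_order = seq_len(dt[1]), kmax = 1 / (2 * res_mm),
              fov_mm = obj$attrs$fov_mm, res_mm = res_mm,
              hub_axes = diag(3)[, c(3, 1, 2)], hub_assign =
                rep(1L, dt[1]))
  bell <- new("BellowsTrace", values = obj$bellows, dt_s = obj$attrs$tr_s,
              cycle_fraction = if (is.null(obj$cycle_fraction)) numeric(0)
                else obj$cycle_fraction,
              true_state = if (is.null(obj$true_state)) numeric(0)
                else obj$true_state,
              outlier_log = integer(0))
  new("KSpaceData", samples = obj$kdata, traj = traj, bellows = bell,
      noise_sd = if (is.null(obj$attrs$noise_sd)) NA_real_
        else obj$attrs$noise_sd)
}

#' Write a volume or image series as NIfTI
#'
#' 3D arrays are written as 3D NIfTI; \linkS4class{ImageSeries} and
#' \linkS4class{DeformationField} objects as 4D NIfTI (phases or
#' displacement components along the 4th dimension). Complex series are
#' written as magnitudes.
#'
#' @param x array, \linkS4class{ImageSeries} or \linkS4class{DeformationField}
#' @param path output path (.nii or .nii.gz)
#' @param voxel_mm voxel spacing (taken from the object when available)
#' @return the path, invisibly
#' @export
writeImageNifti <- function(x, path, voxel_mm = 1) {
  if (is(x, "ImageSeries")) {
    arr <- Mod(x@volumes)
    voxel_mm <- x@voxel_mm
  } else if (is(x, "DeformationField")) {
    arr <- x@displacement
    voxel_mm <- x@voxel_mm
  } else {
    arr <- if (is.complex(x)) Mod(x) else x
  }
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- rep(voxel_mm, min(3, length(dim(arr))))
  RNifti::writeNifti(img, path, datatype = "float")
  invisible(path)
}

#' Read a NIfTI volume or series
#'
#' @param path NIfTI path
#' @return for 3D files an array with attribute \code{voxel_mm}; for 4D
#'   files an \linkS4class{ImageSeries}
#' @export
readImageNifti <- function(path) {
  img <- RNifti::readNifti(path)
  vox <- RNifti::pixdim(img)[1]
  arr <- array(as.numeric(img), dim = dim(img))
  if (length(dim(arr)) == 4) {
    new("ImageSeries", volumes = arr,
        bin_phases = rep(NA_real_, dim(arr)[4]), voxel_mm = vox)
  } else {
    attr(arr, "voxel_mm") <- vox
    arr
  }
}
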