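#' @include AllClasses.R
NULL

#' Extract k-space trajectory coordinates
#' @param object a \linkS4class{TrajectorySet}
#' @return array (excitations, samples, 3) in cycles/mm
#' @export
setGeneric("trajCoords", function(object) standardGeneric("trajCoords"))

#' @rdname trajCoords
#' @export
setMethod("trajCoords", "TrajectorySet", function(object) object@coords)

#' Extract per-bin excitation index lists
#' @param object a \linkS4class{RespiratoryBinSet}
#' @return list of integer vectors
#' @export
setGeneric("binIndices", function(object) standardGeneric("binIndices"))

#' @rdname binIndices
#' @export
setMethod("binIndices", "RespiratoryBinSet", function(object) object@bin_indices)

#' Extract the image data of a series
#' @param object an \linkS4class{ImageSeries}
#' @return 4D array (x, y, z, phase)
#' @export
setGeneric("volumes", function(object) standardGeneric("volumes"))

#' @rdname volumes
#' @export
setMethod("volumes", "ImageSeries", function(object) object@volumes)

#' Number of respiratory phases in a series
#' @param object an \linkS4class{ImageSeries}
#' @return integer
#' @export
setGeneric("nPhases", function(object) standardGeneric("nPhases"))

#' @rdname nPhases
#' @export
setMethod("nPhases", "ImageSeries", function(object) dim(object@volumes)[4])

#' Ventilation defect percentages
#' @param object a \linkS4class{VentilationMaps}
#' @return named numeric vector with vdp_rvent, vdp_fvlcm, mean_vttp
#' @export
setGeneric("vdpSummary", function(object) standardGeneric("vdpSummary"))

#' @rdname vdpSummary
#' @export
setMethod("vdpSummary", "VentilationMaps", function(object)
  c(vdp_rvent = object@vdp_rvent, vdp_fvlcm = object@vdp_fvlcm,
    mean_vttp = object@mean_vttp))

#' @describeIn TrajectorySet-class compact display
#' @param object a \linkS4class{TrajectorySet}
#' @export
setMethod("show", "TrajectorySet", function(object) {
  d <- dim(object@coords)
  cat(sprintf(
    "TrajectorySet: %d readouts x %d samples, kmax = %.4g cycles/mm\n",
    d[1], d[2], object@kmax))
  cat(sprintf("  FOV %.0f mm, res %.2g mm, %d hub(s)\n", object@fov_mm,
              object@res_mm, nrow(object@hub_axes)))
})

#' @describeIn BellowsTrace-class compact display
#' @param object a \linkS4class{BellowsTrace}
#' @export
setMethod("show", "BellowsTrace", function(object) {
  cat(sprintf("BellowsTrace: %d excitations, TR = %.4g ms\n",
              length(object@values), 1000 * object@dt_s))
})

#' @describeIn KSpaceData-class compact display
#' @param object a \linkS4class{KSpaceData}
#' @export
setMethod("show", "KSpaceData", function(object) {
  d <- dim(object@samples)
  cat(sprintf("KSpaceData: %d coil(s), %d excitations x %d samples\n",
              d[1], d[2], d[3]))
})

#' @describeIn RespiratoryBinSet-class compact display
#' @param object a \linkS4class{RespiratoryBinSet}
#' @export
setMethod("show", "RespiratoryBinSet", function(object) {
  n <- lengths(object@bin_indices)
  sh <- vapply(seq_along(n), function(b)
    sum(object@share_matrix[b, -b]), numeric(1))
  cat(sprintf(
    "RespiratoryBinSet: %d bins x %d excitations (%d excluded)\n",
    length(n), n[1], length(object@excluded)))
  cat(sprintf("  shared per bin: %s\n", paste(sh, collapse = " ")))
})

#' @describeIn ImageSeries-class compact display
#' @param object an \linkS4class{ImageSeries}
#' @export
setMethod("show", "ImageSeries", function(object) {
  d <- dim(object@volumes)
  cat(sprintf("ImageSeries: %d x %d x %d, %d phase(s), voxel %.3g mm\n",
              d[1], d[2], d[3], d[4], object@voxel_mm))
})

#' @describeIn VentilationMaps-class compact display
#' @param object a \linkS4class{VentilationMaps}
#' @export
setMethod("show", "VentilationMaps", function(object) {
  cat("VentilationMaps:\n")
  cat(sprintf("  VDP_RVent  = %.2f %%\n", object@vdp_rvent))
  cat(sprintf("  VDP_FVL-CM = %.2f %%\n", object@vdp_fvlcm))
  cat(sprintf("  mean VTTP  = %.2f %% of cycle\n", object@mean_vttp))
})

#' @describeIn MetricReport-class compact display
#' @param object a \linkS4class{MetricReport}
#' @export
setMethod("show", "MetricReport", function(object) {
  cat(sprintf("MetricReport: SNR = %.3g, sharpness = %.3g, VDP = %.3g %%\n",
              object@snr, object@sharpness, object@vdp_static))
})
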