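## Image-quality and comparison metrics: ROI SNR, Sobel sharpness, the
## static 60-percent-of-mean VDP used for gas-density ventilation images,
## and Bland-Altman/Pearson comparison of VDP lists.

#' Region-of-interest SNR
#'
#' Mean signal in the lung ROI divided by the standard deviation of the
#' background ROI. The same ROIs should be reused across compared
#' reconstruction settings.
#'
#' @param volume magnitude volume
#' @param lung_roi,background_roi disjoint non-empty logical arrays
#' @return SNR ratio
#' @export
roiSnr <- function(volume, lung_roi, background_roi) {
  stopifnot(any(lung_roi), any(background_roi))
  if (any(lung_roi & background_roi)) stop("ROIs must be disjoint")
  v <- if (is.complex(volume)) Mod(volume) else volume
  s <- stats::sd(v[background_roi])
  if (s == 0) stop("zero background SD")
  mean(v[lung_roi]) / s
}

# 3D Sobel kernels: derivative [-1,0,1] along one axis, smoothing [1,2,1]
# along the two others
sobelComponent <- function(v, axis) {
  dv <- switch(axis,
    (shift3(v, c(-1, 0, 0)) - shift3(v, c(1, 0, 0))),
    (shift3(v, c(0, -1, 0)) - shift3(v, c(0, 1, 0))),
    (shift3(v, c(0, 0, -1)) - shift3(v, c(0, 0, 1))))
  smooth_axes <- setdiff(1:3, axis)
  for (ax in smooth_axes) {
    s <- c(0, 0, 0)
    s[ax] <- 1
    dv <- shift3(dv, s) + 2 * dv + shift3(dv, -s)
  }
  dv
}

#' Sobel image sharpness
#'
#' Mean over the mask of the gradient magnitude
#' \eqn{\sqrt{G_x^2 + G_y^2 + G_z^2}} computed with 3D Sobel operators in
#' all three spatial directions.
#'
#' @param volume 3D magnitude volume
#' @param mask non-empty logical array
#' @return mean gradient magnitude inside the mask
#' @export
sobelSharpness <- function(volume, mask) {
  stopifnot(any(mask))
  v <- if (is.complex(volume)) Mod(volume) else volume
  g <- sqrt(sobelComponent(v, 1)^2 + sobelComponent(v, 2)^2 +
              sobelComponent(v, 3)^2)
  mean(g[mask])
}

#' Static threshold-based ventilation defect percentage
#'
#' Bias-field-corrects the image, then counts lung voxels with signal
#' below \code{threshold_frac} of the mean whole-lung signal.
#'
#' @param ventilation_volume gas-density-style ventilation image
#' @param lung_mask non-empty logical mask
#' @param threshold_frac defect threshold as a fraction of the mean
#' @param bias_correct apply bias-field correction first
#' @return list with \code{vdp} (percent) and \code{defect_mask}
#' @export
staticVdp <- function(ventilation_volume, lung_mask, threshold_frac = 0.6,
                      bias_correct = TRUE) {
  stopifnot(any(lung_mask))
  v <- if (is.complex(ventilation_volume)) Mod(ventilation_volume) else
    ventilation_volume
  if (bias_correct) v <- biasFieldCorrect(v, lung_mask)
  thr <- threshold_frac * mean(v[lung_mask])
  defect <- lung_mask & (v < thr)
  list(vdp = 100 * sum(defect) / sum(lung_mask), defect_mask = defect)
}

#' Bland-Altman and correlation comparison of two VDP lists
#'
#' @param vdp_a,vdp_b equal-length numeric vectors (percent), n >= 3
#' @return a \linkS4class{MetricReport} with bias = mean(a - b), 95 percent
#'   limits of agreement, and Pearson r
#' @export
compareVdp <- function(vdp_a, vdp_b) {
  if (length(vdp_a) != length(vdp_b)) stop("lists must have equal length")
  if (length(vdp_a) < 3) stop("need at least 3 paired values")
  d <- vdp_a - vdp_b
  bias <- mean(d)
  s <- stats::sd(d)
  new("MetricReport", bias = bias, loa_low = bias - 1.96 * s,
      loa_high = bias + 1.96 * s,
      pearson_r = stats::cor(vdp_a, vdp_b))
}

#' Default phantom ROIs for SNR measurement
#'
#' A small ROI inside the lung parenchyma on the central coronal slice at
#' the carina level and a background ROI in a corner outside the body.
#'
#' @param lung_mask logical lung mask
#' @return list with \code{lung_roi} and \code{background_roi}
#' @export
phantomSnrRois <- function(lung_mask) {
  d <- dim(lung_mask)
  w <- which(lung_mask, arr.ind = TRUE)
  ctr <- round(colMeans(w))
  lung_roi <- array(FALSE, d)
  half <- max(1, round(d[1] / 24))
  sel <- w[abs(w[, 2] - ctr[2]) <= 1 &
             abs(w[, 1] - ctr[1] + round(d[1] / 6)) <= half &
             abs(w[, 3] - ctr[3]) <= half, , drop = FALSE]
  lung_roi[sel] <- TRUE
  bg <- array(FALSE, d)
  m <- max(2, round(d[1] / 12))
  bg[1:m, 1:m, 1:m] <- TRUE
  list(lung_roi = lung_roi, background_roi = bg)
}
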