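## Nonrigid 3D registration: multiresolution diffeomorphic-demons-style
## algorithm. SSD (or locally normalized, "cross_correlation"-like) forces,
## Gaussian fluid smoothing of the update and elastic smoothing of the total
## field, with an optional phase-correlation translation initialization.
## Deterministic: no unseeded randomness anywhere.

# integer-voxel translation aligning moving to fixed via phase correlation
phaseCorrShift <- function(moving, fixed) {
  Fm <- fft(moving)
  Ff <- fft(fixed)
  cp <- Ff * Conj(Fm)
  r <- Re(fft(cp / pmax(Mod(cp), 1e-12), inverse = TRUE))
  w <- which.max(r)
  d <- dim(moving)
  idx <- arrayInd(w, d) - 1
  sh <- ifelse(idx > d / 2, idx - d, idx)
  as.numeric(sh)
}

warpReal <- function(vol, disp_vox) {
  d <- dim(vol)
  base <- as.matrix(expand.grid(seq_len(d[1]) - 1, seq_len(d[2]) - 1,
                                seq_len(d[3]) - 1))
  pts <- base + cbind(as.vector(disp_vox[, , , 1]),
                      as.vector(disp_vox[, , , 2]),
                      as.vector(disp_vox[, , , 3]))
  array(cpp_trilinear(as.double(vol), as.integer(d), pts), dim = d)
}

#' Warp a volume by a deformation field
#'
#' Trilinear interpolation; a voxel at position p samples the input at
#' p + displacement(p). Out-of-grid samples take nearest-edge values.
#' Complex volumes are warped component-wise.
#'
#' @param volume 3D array (real or complex)
#' @param field a \linkS4class{DeformationField} on the same grid
#' @return warped volume
#' @export
applyField <- function(volume, field) {
  if (!all(dim(volume) == field@fixed_shape))
    stop("volume shape does not match the deformation field grid")
  disp_vox <- field@displacement / field@voxel_mm
  if (is.complex(volume)) {
    warpReal(Re(volume), disp_vox) + 1i * warpReal(Im(volume), disp_vox)
  } else {
    warpReal(volume, disp_vox)
  }
}

#' Compose two deformation fields
#'
#' Returns the field equivalent to applying \code{f_outer} after
#' \code{f_inner}: warp by the composition samples the image at
#' p + f_outer(p) + f_inner(p + f_outer(p)).
#'
#' @param f_inner,f_outer \linkS4class{DeformationField}s on one grid
#' @return a \linkS4class{DeformationField}
#' @export
composeFields <- function(f_inner, f_outer) {
  stopifnot(all(f_inner@fixed_shape == f_outer@fixed_shape))
  d <- f_inner@fixed_shape
  disp_out_vox <- f_outer@displacement / f_outer@voxel_mm
  comp <- array(0, dim = c(d, 3))
  for (ax in 1:3) {
    inner_ax <- warpReal(f_inner@displacement[, , , ax], disp_out_vox)
    comp[, , , ax] <- f_outer@displacement[, , , ax] + inner_ax
  }
  initialize(f_inner, displacement = comp)
}

#' Invert a deformation field
#'
#' Fixed-point iteration for the inverse displacement:
#' \eqn{u^{-1}(p) = -u(p + u^{-1}(p))}, so that warping by the field and
#' then by its inverse approximates the identity to interpolation error.
#'
#' @param field a \linkS4class{DeformationField}
#' @param iters fixed-point iterations
#' @return the inverse \linkS4class{DeformationField}
#' @export
invertField <- function(field, iters = 6L) {
  d <- field@fixed_shape
  vox <- field@voxel_mm
  u <- field@displacement / vox  # voxel units
  inv <- -u
  for (it in seq_len(iters)) {
    comp <- array(0, dim = c(d, 3))
    for (ax in 1:3) comp[, , , ax] <- -warpReal(u[, , , ax], inv)
    inv <- comp
  }
  initialize(field, displacement = inv * vox)
}

zeroField <- function(dims, voxel_mm = 1) {
  new("DeformationField", displacement = array(0, dim = c(dims, 3)),
      fixed_shape = as.integer(dims), voxel_mm = voxel_mm,
      interpolation = "linear", converged = TRUE)
}

demonsLevel <- function(moving, fixed, disp, iters, fluid_sigma, field_sigma,
                        mask = NULL) {
  d <- dim(fixed)
  kappa <- mean((fixed - mean(fixed))^2)
  best <- disp
  metric <- function(dd) {
    r <- fixed - warpReal(moving, dd)
    if (!is.null(mask)) r <- r * mask
    mean(r^2)
  }
  best_m <- metric(disp)
  for (it in seq_len(iters)) {
    w <- warpReal(moving, disp)
    diffv <- fixed - w
    g <- gradient3(w)
    den <- g$gx^2 + g$gy^2 + g$gz^2 + diffv^2 / kappa
    den[den < 1e-12] <- 1e-12
    scl <- diffv / den
    if (!is.null(mask)) scl <- scl * mask
    ux <- gaussSmooth3(scl * g$gx, fluid_sigma)
    uy <- gaussSmooth3(scl * g$gy, fluid_sigma)
    uz <- gaussSmooth3(scl * g$gz, fluid_sigma)
    # cap the update magnitude at one voxel for stability
    mag <- sqrt(ux^2 + uy^2 + uz^2)
    cap <- pmin(1, 1 / pmax(mag, 1e-12))
    disp[, , , 1] <- gaussSmooth3(disp[, , , 1] + ux * cap, field_sigma)
    disp[, , , 2] <- gaussSmooth3(disp[, , , 2] + uy * cap, field_sigma)
    disp[, , , 3] <- gaussSmooth3(disp[, , , 3] + uz * cap, field_sigma)
    m <- metric(disp)
    if (m < best_m) {
      best_m <- m
      best <- disp
    }
  }
  best
}

#' Nonrigid registration of a moving to a fixed volume
#'
#' Multiresolution demons-style registration. The returned field never
#' worsens the similarity metric: the best iterate is kept, and the zero
#' field is the fallback.
#'
#' @param moving,fixed 3D arrays on the same grid (magnitude images)
#' @param params a \linkS4class{RegistrationParams}
#' @param voxel_mm voxel spacing in mm
#' @return a \linkS4class{DeformationField} such that
#'   \code{applyField(moving, field)} approximates \code{fixed}
#' @export
registerPair <- function(moving, fixed, params = registrationParams(),
                         voxel_mm = 1) {
  stopifnot(all(dim(moving) == dim(fixed)))
  if (stats::sd(moving) == 0 || stats::sd(fixed) == 0)
    stop("cannot register constant images")
  d <- dim(fixed)
  mask <- params@mask
  if (params@similarity == "cross_correlation") {
    # local-contrast normalization: dividing by a smooth local mean makes
    # the forces insensitive to regional intensity (density) differences,
    # so registration tracks structure without absorbing the parenchymal
    # signal change that the ventilation analysis measures
    ln <- function(x) {
      sm <- gaussSmooth3(x, 4)
      eps <- 0.05 * mean(abs(x))
      out <- x / (abs(sm) + eps)
      (out - mean(out)) / stats::sd(out)
    }
    moving_n <- ln(moving)
    fixed_n <- ln(fixed)
  } else {
    moving_n <- moving
    fixed_n <- fixed
  }
  disp <- array(0, dim = c(d, 3))
  if (params@mode == "affine_then_nonrigid") {
    sh <- phaseCorrShift(moving_n, fixed_n)
    for (ax in 1:3) disp[, , , ax] <- -sh[ax]
  }
  nl <- length(params@levels)
  for (l in seq_len(nl)) {
    f <- params@levels[l]
    if (f > 1) {
      mv <- downsample3(moving_n, f)
      fx <- downsample3(fixed_n, f)
      mk <- if (!is.null(mask)) {
        mm <- downsample3(array(as.numeric(mask), dim = d), f)
        (mm > 0.5) * 1
      } else NULL
      dl <- dim(fx)
      dsp <- array(0, dim = c(dl, 3))
      for (ax in 1:3) {
        sc <- dl[ax] / d[ax]
        dsp[, , , ax] <- resample3(disp[, , , ax], dl) * sc
      }
      dsp <- demonsLevel(mv, fx, dsp, params@iterations[l],
                         params@smoothing[l], params@field_sigma, mk)
      for (ax in 1:3) {
        sc <- d[ax] / dim(fx)[ax]
        disp[, , , ax] <- resample3(dsp[, , , ax], d) * sc
      }
    } else {
      mk <- if (!is.null(mask)) array(as.numeric(mask), dim = d) else NULL
      disp <- demonsLevel(moving_n, fixed_n, disp, params@iterations[l],
                          params@smoothing[l], params@field_sigma, mk)
    }
  }
  # metric non-worsening guard against the zero field
  ssd <- function(dd) {
    r <- fixed_n - warpReal(moving_n, dd)
    if (!is.null(mask)) r <- r * mask
    mean(r^2)
  }
  converged <- TRUE
  if (ssd(disp) > ssd(array(0, dim = c(d, 3)))) {
    disp <- array(0, dim = c(d, 3))
    converged <- FALSE
  }
  new("DeformationField", displacement = disp * voxel_mm,
      fixed_shape = as.integer(d), voxel_mm = voxel_mm,
      interpolation = "linear", converged = converged)
}

#' Stepwise registration of a respiratory series to a reference phase
#'
#' Each phase is registered to the reference by composing
#' neighbor-to-neighbor deformation fields toward the reference (stepwise,
#' not direct), restricting the metric to a rectangular mask covering the
#' lung volume when provided.
#'
#' @param series an \linkS4class{ImageSeries} (magnitudes are used)
#' @param ref reference phase index (typically end-inspiration)
#' @param params a \linkS4class{RegistrationParams}
#' @param mask optional rectangular lung-covering logical array
#' @return list with \code{series} (registered \linkS4class{ImageSeries})
#'   and \code{fields} (per-phase \linkS4class{DeformationField} to the
#'   reference)
#' @export
stepwiseRegisterSeries <- function(series, ref,
                                   params = registrationParams(),
                                   mask = NULL) {
  B <- nPhases(series)
  stopifnot(B >= 2)
  if (ref < 1 || ref > B) stop("reference phase out of range")
  if (!is.null(mask)) params@mask <- mask
  vols <- if (is.complex(series@volumes)) Mod(series@volumes) else
    series@volumes
  d <- dim(vols)[1:3]
  vox <- series@voxel_mm
  fields <- vector("list", B)
  fields[[ref]] <- zeroField(d, vox)
  # neighbor chains on either side of the reference
  for (dir in c(-1, 1)) {
    b <- ref + dir
    prev <- ref
    while (b >= 1 && b <= B) {
      step <- registerPair(vols[, , , b], vols[, , , prev], params, vox)
      fields[[b]] <- if (prev == ref) step else
        composeFields(step, fields[[prev]])
      prev <- b
      b <- b + dir
    }
  }
  out <- series@volumes
  for (b in seq_len(B)) if (b != ref)
    out[, , , b] <- applyField(series@volumes[, , , b], fields[[b]])
  list(series = initialize(series, volumes = out), fields = fields)
}
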