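## 3D PREFUL postprocessing: resorting the respiratory series into one
## canonical ventilation cycle, bias-field correction, stepwise
## registration to end-inspiration, Gaussian interpolation to equidistant
## phases, temporal low-pass + edge-preserving filtering, segmentation, and
## the ventilation parameters RVent, FVL-CM and VTTP with their defect
## maps and VDP summaries.

#' Resort a respiratory series into one canonical ventilation cycle
#'
#' Phases are reordered so the cycle starts at end-expiration (maximum
#' mask-mean parenchymal signal, i.e. densest lung), runs to
#' end-inspiration and ends back at end-expiration, using the per-bin
#' respiratory phase labels; the applied mapping is recorded in the
#' \code{"ordering"} attribute.
#'
#' @param series an \linkS4class{ImageSeries} with bin phase labels
#' @param lung_mask optional mask for the mean-signal EE/EI cross-check
#' @return reordered \linkS4class{ImageSeries}
#' @export
sortVentilationCycle <- function(series, lung_mask = NULL) {
  B <- nPhases(series)
  stopifnot(B >= 2)
  ph <- series@bin_phases
  if (!length(ph) || any(is.na(ph))) stop("missing respiratory phase labels")
  ord <- order(ph)
  mags <- Mod(series@volumes)
  msig <- vapply(seq_len(B), function(b) {
    v <- mags[, , , b]
    if (!is.null(lung_mask)) mean(v[lung_mask]) else
      mean(v[v < stats::quantile(v, 0.5) & v > stats::quantile(v, 0.02)])
  }, numeric(1))
  # rotate so the cycle starts at end-expiration (max parenchymal signal)
  ee_pos <- which.max(msig[ord])
  ord <- ord[((seq_len(B) + ee_pos - 2) %% B) + 1]
  # orient the cycle so end-inspiration (min signal) sits mid-cycle
  ei_pos <- which.min(msig[ord])
  if (ei_pos - 1 > B / 2) ord <- ord[c(1, rev(seq_len(B)[-1]))]
  out <- initialize(series, volumes = series@volumes[, , , ord, drop = FALSE],
                    bin_phases = series@bin_phases[ord])
  attr(out, "ordering") <- ord
  out
}

#' Multiplicative bias-field correction
#'
#' A low-order (degree-2) 3D polynomial is fitted to the log-intensity
#' inside the mask and divided out; the output is rescaled to preserve the
#' mask mean. Approximately idempotent.
#'
#' @param volume positive-valued 3D array
#' @param mask logical array delimiting the fit region (default: voxels
#'   above 5 percent of the maximum)
#' @return corrected volume
#' @export
biasFieldCorrect <- function(volume, mask = NULL, return_field = FALSE) {
  v <- volume
  if (all(v <= 0)) stop("bias-field correction requires positive voxels")
  if (any(v <= 0)) {
    warning("non-positive voxels clamped for bias-field correction")
    v[v <= 0] <- min(v[v > 0])
  }
  if (is.null(mask)) mask <- v > 0.05 * max(v)
  d <- dim(v)
  co <- lapply(1:3, function(ax) (seq_len(d[ax]) - (d[ax] + 1) / 2) / d[ax])
  X <- array(rep(co[[1]], times = d[2] * d[3]), d)
  Y <- array(rep(rep(co[[2]], each = d[1]), times = d[3]), d)
  Z <- array(rep(co[[3]], each = d[1] * d[2]), d)
  design <- cbind(1, X[mask], Y[mask], Z[mask], X[mask]^2, Y[mask]^2,
                  Z[mask]^2, X[mask] * Y[mask], X[mask] * Z[mask],
                  Y[mask] * Z[mask])
  beta <- stats::lm.fit(design, log(v[mask]))$coefficients
  beta[is.na(beta)] <- 0
  logfield <- beta[1] + beta[2] * X + beta[3] * Y + beta[4] * Z +
    beta[5] * X^2 + beta[6] * Y^2 + beta[7] * Z^2 + beta[8] * X * Y +
    beta[9] * X * Z + beta[10] * Y * Z
  # remove only the spatial variation of the field, not the overall level
  field <- exp(logfield - mean(logfield[mask]))
  out <- v / field
  out <- out * mean(v[mask]) / mean(out[mask])
  if (return_field) list(corrected = out, field = field) else out
}

#' Gaussian interpolation of a sorted cycle to equidistant phases
#'
#' Each output phase is a normalized Gaussian-weighted average of the input
#' phases under circular distance on the cycle, with sigma in units of the
#' input phase spacing.
#'
#' @param series sorted-cycle \linkS4class{ImageSeries} (B phases)
#' @param config a \linkS4class{PrefulConfig} (n_phases, gauss_sigma)
#' @return an \linkS4class{ImageSeries} with \code{n_phases} volumes
#' @export
interpolateToPhases <- function(series, config) {
  B <- nPhases(series)
  stopifnot(B >= 2)
  if (config@gauss_sigma <= 0) stop("gauss_sigma must be > 0")
  n_out <- config@n_phases
  pos_in <- (seq_len(B) - 1)          # in units of input phase spacing
  pos_out <- (seq_len(n_out) - 1) * B / n_out
  d <- dim(series@volumes)
  out <- array(if (is.complex(series@volumes)) 0 + 0i else 0,
               dim = c(d[1:3], n_out))
  Xm <- stackMatrix(series@volumes)
  for (t in seq_len(n_out)) {
    dd <- abs(((pos_in - pos_out[t] + B / 2) %% B) - B / 2)
    w <- exp(-0.5 * (dd / config@gauss_sigma)^2)
    w <- w / sum(w)
    out[, , , t] <- array(Xm %*% w, dim = d[1:3])
  }
  new("ImageSeries", volumes = out,
      bin_phases = 2 * pi * (seq_len(n_out) - 1) / n_out - pi,
      voxel_mm = series@voxel_mm)
}

#' Temporal low-pass and spatial edge-preserving filtering
#'
#' Voxelwise temporal Fourier filtering keeps cycle harmonics up to
#' \code{lowpass_hz * breathing_period_s} (the Hz cutoff expressed in
#' cycle harmonics); each phase is then filtered with an edge-preserving
#' 3D bilateral filter.
#'
#' @param series an \linkS4class{ImageSeries} over one ventilation cycle
#' @param config a \linkS4class{PrefulConfig}
#' @param spatial logical; apply the spatial bilateral stage
#' @return filtered \linkS4class{ImageSeries}
#' @export
temporalFilter <- function(series, config, spatial = TRUE) {
  B <- nPhases(series)
  stopifnot(B >= 4)
  cutoff <- config@lowpass_hz * config@breathing_period_s
  if (cutoff < 1) {
    warning("low-pass cutoff below the fundamental; keeping the fundamental")
    cutoff <- 1
  }
  keep <- floor(cutoff)
  X <- stackMatrix(series@volumes)
  Xf <- t(stats::mvfft(t(X)))
  h <- abs(fftfreq(B)) * B  # harmonic index per temporal frequency bin
  Xf[, h > keep] <- 0
  Xr <- t(stats::mvfft(t(Xf), inverse = TRUE)) / B
  vols <- array(if (is.complex(series@volumes)) Xr else Re(Xr),
                dim = dim(series@volumes))
  if (spatial) {
    mags <- if (is.complex(vols)) Mod(vols) else vols
    # background noise scale from the darkest corner octant
    bg <- stats::sd(mags[1:4, 1:4, 1:4, 1])
    sr <- max(config@bilateral_range_sd * bg, 1e-6 * max(abs(mags)))
    d <- dim(vols)[1:3]
    for (t in seq_len(dim(vols)[4])) {
      v <- if (is.complex(vols)) Mod(vols[, , , t]) else vols[, , , t]
      vols[, , , t] <- array(
        cpp_bilateral3(as.double(v), as.integer(d), 2L, 1.0, sr), dim = d)
    }
  }
  initialize(series, volumes = vols)
}

#' Simple threshold-based lung segmentation
#'
#' Two-class k-means on body voxels separates low-intensity lung candidates
#' from soft tissue; the two largest low-intensity connected components
#' inside the body are kept and holes are filled.
#'
#' @param volume reconstructed magnitude volume
#' @return logical lung mask
#' @export
segmentLungSimple <- function(volume) {
  v <- Mod(volume)
  d <- dim(v)
  if (stats::sd(v) == 0) stop("cannot segment a uniform volume")
  # body support: largest bright connected component, holes filled
  bright <- mean(v[v > stats::quantile(v, 0.75)])
  body <- v > 0.3 * bright
  lab <- array(cpp_label3d(body, as.integer(d)), dim = d)
  if (max(lab) == 0) stop("no lung candidate component found")
  body <- lab == which.max(tabulate(lab[lab > 0]))
  body <- fillHoles3(body)
  # erode the body so the partial-volume rim does not join the air spaces
  core <- body
  for (i in 1:3) core <- erode3(core)
  vals <- v[core]
  km <- stats::kmeans(vals, centers = range(vals), iter.max = 30)
  low <- array(FALSE, d)
  low[core] <- km$cluster == which.min(km$centers)
  # morphological opening detaches thin tubes (trachea) from the lungs
  low_open <- erode3(low)
  lab <- array(cpp_label3d(low_open, as.integer(d)), dim = d)
  if (max(lab) == 0) stop("no lung candidate component found")
  sizes <- tabulate(lab[lab > 0])
  keep <- order(sizes, decreasing = TRUE)[seq_len(min(2, length(sizes)))]
  keep <- keep[sizes[keep] > 0.001 * sum(core)]
  # discard slender components (e.g. the trachea): compare the z-extent to
  # the transverse extent
  keep <- Filter(function(k) {
    w <- which(lab == k, arr.ind = TRUE)
    ext <- apply(w, 2, function(x) diff(range(x))) + 1
    ext[3] < 4 * max(ext[1:2])
  }, keep)
  if (!length(keep)) stop("no lung candidate component found")
  mask <- array(array(lab, d) %in% keep, dim = d)
  # conditional dilation back into the un-opened candidate set
  for (i in 1:2) mask <- dilate3(mask) & low
  fillHoles3(mask)
}

# morphological dilation by one voxel (6-neighborhood)
dilate3 <- function(mask) {
  m <- mask
  for (s in list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                 c(0, 0, 1), c(0, 0, -1)))
    m <- m | shift3(mask, s)
  m
}

# morphological erosion by one voxel (6-neighborhood)
erode3 <- function(mask) {
  m <- mask
  for (s in list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                 c(0, 0, 1), c(0, 0, -1)))
    m <- m & shift3(mask, s)
  m
}

# fill interior holes: background components not touching the border
fillHoles3 <- function(mask) {
  d <- dim(mask)
  lab <- array(cpp_label3d(!mask, as.integer(d)), dim = d)
  border <- unique(c(lab[1, , ], lab[d[1], , ], lab[, 1, ], lab[, d[2], ],
                     lab[, , 1], lab[, , d[3]]))
  border <- border[border > 0]
  mask | !(lab %in% c(0, border))
}

#' Lung-vessel recognition inside a lung mask
#'
#' Bright tubular structures in the lung are flagged by an intensity
#' criterion (well above the parenchymal level) combined with an
#' elongation criterion per connected component; the parenchyma mask is
#' the lung minus the vessels.
#'
#' @param volume magnitude volume
#' @param lung_mask logical lung mask
#' @return list with \code{vessel_mask} and \code{parenchyma_mask}
#' @export
vesselMask <- function(volume, lung_mask) {
  v <- if (is.complex(volume)) Mod(volume) else volume
  stopifnot(any(lung_mask))
  # close the cavity so bright vessels excluded by intensity-based lung
  # segmentation are inside the search region
  cavity <- fillHoles3(dilate3(dilate3(lung_mask)))
  cavity <- erode3(erode3(cavity)) | lung_mask
  med <- stats::median(v[lung_mask])
  madv <- stats::mad(v[lung_mask])
  cand <- cavity & (v > med + 4 * madv) & (v > 2 * med)
  d <- dim(v)
  vessel <- array(FALSE, d)
  if (any(cand)) {
    lab <- array(cpp_label3d(cand, as.integer(d)), dim = d)
    for (k in seq_len(max(lab))) {
      w <- which(lab == k, arr.ind = TRUE)
      if (nrow(w) < 3) next
      ext <- apply(w, 2, function(x) diff(range(x))) + 1
      if (max(ext) >= 2 * stats::median(ext)) vessel[lab == k] <- TRUE
    }
  }
  list(vessel_mask = vessel, parenchyma_mask = cavity & !vessel)
}

# end-expiration/-inspiration phase indices of a sorted, registered cycle:
# parenchymal density (mask-mean signal) is maximal at EE, minimal at EI
eeEiPhases <- function(series, mask) {
  mags <- Mod(series@volumes)
  msig <- vapply(seq_len(nPhases(series)), function(b)
    mean(mags[, , , b][mask]), numeric(1))
  list(ee = which.max(msig), ei = which.min(msig), mean_signal = msig)
}

#' Regional ventilation over the cycle
#'
#' Per phase t, \eqn{RVent(t) = (S_{EE} - S(t)) / S(t)} per voxel: the
#' fractional density change relative to end-expiration, in mL/mL. Voxels
#' with non-positive signal are flagged invalid (NA).
#'
#' @param series registered, filtered series over one sorted cycle
#' @param parenchyma_mask logical analysis mask
#' @param ee_phase end-expiration phase index (default: detected as the
#'   phase of maximal mask-mean signal)
#' @return list with \code{rvent_cycle} (4D array), \code{rvent_ei},
#'   \code{ee_phase}, \code{ei_phase}
#' @export
computeRvent <- function(series, parenchyma_mask, ee_phase = NULL) {
  mags <- Mod(series@volumes)
  B <- dim(mags)[4]
  ph <- eeEiPhases(series, parenchyma_mask)
  if (is.null(ee_phase)) ee_phase <- ph$ee
  s_ee <- mags[, , , ee_phase]
  rv <- array(NA_real_, dim = dim(mags))
  for (t in seq_len(B)) {
    st <- mags[, , , t]
    r <- (s_ee - st) / st
    r[st <= 0] <- NA_real_
    rv[, , , t] <- r
  }
  list(rvent_cycle = rv, rvent_ei = rv[, , , ph$ei], ee_phase = ee_phase,
       ei_phase = ph$ei)
}

#' Flow-volume-loop cross-correlation metric (FVL-CM)
#'
#' Per voxel, flow is the circular central difference of RVent over the
#' cycle; the high-ventilation reference loop is the mean
#' (volume, flow) trajectory over voxels whose end-inspiration RVent lies
#' in the configured quantile band. CM is the Pearson correlation between
#' the voxel's and the reference's concatenated standardized volume-and-
#' flow series (optionally maximized over circular lags).
#'
#' @param rvent_cycle 4D RVent array over the cycle
#' @param rvent_ei end-inspiration RVent map
#' @param parenchyma_mask logical analysis mask
#' @param config a \linkS4class{PrefulConfig}
#' @return CM map in [-1, 1] (NA outside the mask)
#' @export
flowVolumeCm <- function(rvent_cycle, rvent_ei, parenchyma_mask, config) {
  d <- dim(rvent_cycle)
  B <- d[4]
  V <- matrix(rvent_cycle, ncol = B)[as.vector(parenchyma_mask), , drop = FALSE]
  Fm <- (V[, c(2:B, 1), drop = FALSE] - V[, c(B, 1:(B - 1)), drop = FALSE]) / 2
  ei <- rvent_ei[parenchyma_mask]
  qs <- stats::quantile(ei, config@ref_quantiles, na.rm = TRUE)
  ref_sel <- which(ei >= qs[1] & ei <= qs[2])
  if (!length(ref_sel)) stop("empty high-ventilation reference band")
  ref_v <- colMeans(V[ref_sel, , drop = FALSE], na.rm = TRUE)
  ref_f <- colMeans(Fm[ref_sel, , drop = FALSE], na.rm = TRUE)
  zs <- function(x) {
    s <- stats::sd(x)
    if (is.na(s) || s == 0) return(rep(0, length(x)))
    (x - mean(x)) / s
  }
  ref <- c(zs(ref_v), zs(ref_f))
  cmv <- rep(NA_real_, nrow(V))
  zrow <- function(M) {
    mu <- rowMeans(M)
    sd <- sqrt(pmax(rowMeans(M^2) - mu^2, 0))
    sweep(sweep(M, 1, mu), 1, pmax(sd, 1e-15), "/")
  }
  # zero-lag CM: correlation of concatenated standardized series
  corWithRef <- function(Vl, Fl) {
    X <- cbind(zrow(Vl), zrow(Fl))
    Xc <- X - rowMeans(X)
    refc <- ref - mean(ref)
    num <- as.vector(Xc %*% refc)
    den <- sqrt(rowSums(Xc^2) * sum(refc^2))
    num / pmax(den, 1e-15)
  }
  if (!config@cm_lag_search) {
    cmv <- corWithRef(V, Fm)
  } else {
    best <- rep(-Inf, nrow(V))
    for (l in 0:(B - 1)) {
      sh <- c(seq_len(B - l) + l, seq_len(l))
      best <- pmax(best, corWithRef(V[, sh, drop = FALSE],
                                    Fm[, sh, drop = FALSE]))
    }
    cmv <- best
  }
  out <- array(NA_real_, dim = d[1:3])
  out[parenchyma_mask] <- pmin(pmax(cmv, -1), 1)
  out
}

#' Ventilation time-to-peak (VTTP)
#'
#' Per voxel, the cycle fraction (in percent) at which RVent attains its
#' maximum over a cycle starting at end-expiration; ties take the earliest
#' phase. Voxels with a constant (all-equal) cycle are flagged undefined.
#'
#' @param rvent_cycle 4D RVent array over the cycle (starting at EE)
#' @param parenchyma_mask logical analysis mask
#' @return list with \code{vttp} map (percent of cycle, NA where undefined)
#'   and \code{mean_vttp}
#' @export
computeVttp <- function(rvent_cycle, parenchyma_mask) {
  d <- dim(rvent_cycle)
  B <- d[4]
  V <- matrix(rvent_cycle, ncol = B)[as.vector(parenchyma_mask), , drop = FALSE]
  peak <- max.col(V, ties.method = "first")
  rng <- apply(V, 1, function(x) diff(range(x)))
  vttp_v <- 100 * (peak - 1) / B
  vttp_v[rng == 0 | !is.finite(rng)] <- NA_real_
  out <- array(NA_real_, dim = d[1:3])
  out[parenchyma_mask] <- vttp_v
  list(vttp = out, mean_vttp = mean(vttp_v, na.rm = TRUE))
}

#' Ventilation defect maps and VDP values
#'
#' RVent defects fall below \code{rvent_frac} times the
#' \code{rvent_pct} percentile of the in-mask end-inspiration RVent
#' distribution; FVL-CM defects fall below the fixed CM threshold.
#'
#' @param rvent_ei end-inspiration RVent map
#' @param fvl_cm CM map
#' @param vttp_res result of \code{\link{computeVttp}} (optional)
#' @param rvent_cycle optional 4D RVent array stored alongside
#' @param parenchyma_mask logical analysis mask
#' @param config a \linkS4class{PrefulConfig}
#' @return a \linkS4class{VentilationMaps}
#' @export
defectMaps <- function(rvent_ei, fvl_cm, parenchyma_mask, config,
                       vttp_res = NULL, rvent_cycle = NULL) {
  if (!any(parenchyma_mask)) stop("empty parenchyma mask")
  ei <- rvent_ei[parenchyma_mask]
  thr <- config@rvent_frac *
    stats::quantile(ei, config@rvent_pct, na.rm = TRUE, names = FALSE)
  defect_rvent <- parenchyma_mask & !is.na(rvent_ei) & (rvent_ei < thr)
  defect_fvlcm <- parenchyma_mask & !is.na(fvl_cm) &
    (fvl_cm < config@fvl_cm_threshold)
  n_mask <- sum(parenchyma_mask)
  if (is.null(vttp_res)) vttp_res <- list(
    vttp = array(NA_real_, dim = dim(rvent_ei)), mean_vttp = NA_real_)
  if (is.null(rvent_cycle))
    rvent_cycle <- array(NA_real_, dim = c(dim(rvent_ei), 1))
  new("VentilationMaps", rvent_ei = rvent_ei, rvent_cycle = rvent_cycle,
      fvl_cm = fvl_cm, vttp = vttp_res$vttp,
      defect_rvent = array(defect_rvent, dim = dim(rvent_ei)),
      defect_fvlcm = array(defect_fvlcm, dim = dim(rvent_ei)),
      parenchyma_mask = array(parenchyma_mask, dim = dim(rvent_ei)),
      vdp_rvent = 100 * sum(defect_rvent) / n_mask,
      vdp_fvlcm = 100 * sum(defect_fvlcm) / n_mask,
      mean_vttp = vttp_res$mean_vttp)
}

#' Full PREFUL analysis of a reconstructed respiratory series
#'
#' Runs the postprocessing chain: cycle sorting, per-phase bias-field
#' correction, stepwise registration to end-inspiration, Gaussian
#' interpolation to \code{n_phases} phases, temporal low-pass +
#' edge-preserving filtering, lung/vessel segmentation (unless a mask is
#' supplied) and the ventilation parameters.
#'
#' @param series an \linkS4class{ImageSeries} from reconstruction
#' @param config a \linkS4class{PrefulConfig}
#' @param reg_params registration parameters for the stepwise registration
#' @param lung_mask optional lung mask on the reference (EI) frame; when
#'   omitted, \code{\link{segmentLungSimple}} is used
#' @param verbose print stage progress
#' @return a \linkS4class{VentilationMaps}
#' @export
prefulAnalysis <- function(series, config = prefulConfig(),
                           reg_params = registrationParams(),
                           lung_mask = NULL, verbose = FALSE) {
  say <- function(...) if (verbose) message(...)
  # a provisional lung mask drives EE/EI identification during sorting
  tmp_mask <- if (!is.null(lung_mask)) lung_mask else {
    m <- try(segmentLungSimple(Mod(series@volumes[, , , 1])), silent = TRUE)
    if (inherits(m, "try-error")) NULL else m
  }
  say("sorting ventilation cycle")
  sorted <- sortVentilationCycle(series, tmp_mask)
  mags <- Mod(sorted@volumes)
  B <- dim(mags)[4]
  say("bias-field correction")
  # the field is estimated once, on the first (end-expiration) phase, and
  # divided out of every phase: a per-phase fit would absorb part of the
  # parenchymal density change that the ventilation parameters measure
  bf <- biasFieldCorrect(mags[, , , 1], return_field = TRUE)
  mags[, , , 1] <- bf$corrected
  for (b in seq_len(B)[-1]) mags[, , , b] <- mags[, , , b] / bf$field
  sorted <- initialize(sorted, volumes = mags)

  ph <- eeEiPhases(sorted, if (!is.null(tmp_mask)) tmp_mask else
    mags[, , , 1] < stats::quantile(mags[, , , 1], 0.5))
  rect <- NULL
  if (!is.null(tmp_mask) && any(tmp_mask)) {
    w <- which(tmp_mask, arr.ind = TRUE)
    lo <- pmax(apply(w, 2, min) - 2, 1)
    hi <- pmin(apply(w, 2, max) + 2, dim(mags)[1:3])
    rect <- array(FALSE, dim(mags)[1:3])
    rect[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- TRUE
  }
  say(sprintf("stepwise registration to end-inspiration (phase %d)", ph$ei))
  reg <- stepwiseRegisterSeries(sorted, ph$ei, reg_params, mask = rect)

  say("phase interpolation and filtering")
  interp <- interpolateToPhases(reg$series, config)
  filt <- temporalFilter(interp, config)

  if (is.null(lung_mask)) {
    say("lung segmentation")
    lung_mask <- segmentLungSimple(Mod(filt@volumes[, , , 1]))
  }
  vs <- vesselMask(Mod(filt@volumes[, , , 1]), lung_mask)
  parenchyma <- vs$parenchyma_mask

  say("ventilation parameters")
  rv <- computeRvent(filt, parenchyma)
  # re-anchor the cycle at the detected EE phase
  if (rv$ee_phase != 1) {
    shift_ord <- ((seq_len(config@n_phases) + rv$ee_phase - 2) %%
                    config@n_phases) + 1
    rvc <- rv$rvent_cycle[, , , shift_ord, drop = FALSE]
  } else rvc <- rv$rvent_cycle
  cm <- flowVolumeCm(rvc, rv$rvent_ei, parenchyma, config)
  vt <- computeVttp(rvc, parenchyma)
  defectMaps(rv$rvent_ei, cm, parenchyma, config, vttp_res = vt,
             rvent_cycle = rvc)
}
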