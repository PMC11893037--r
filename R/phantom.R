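## Dynamic digital breathing-thorax phantom.
##
## The phantom is a soft-tissue ellipsoid body containing two lung
## ellipsoids. Breathing is modeled as a 1D cranio-caudal stretch of the
## lung compartment (diaphragm descends by a * tidal_amplitude * lung
## height at inflation state a, tapering to zero at the apex) together with
## the reciprocal parenchymal density law
## density(a) = lung_density_ee / (1 + a_eff * FV), so that lung-compartment
## mass is conserved when FV matches the geometric stretch. Defects locally
## scale FV down (amplitude defects) and/or delay filling by a fraction of
## the cycle (phase-lag defects).

#' Respiratory state of a sinusoidal breathing cycle
#'
#' Maps a cycle fraction (0 = end-expiration, 0.5 = end-inspiration) to the
#' inflation state a in [0, 1].
#'
#' @param cyc cycle fraction(s) in [0, 1)
#' @return inflation state(s) in [0, 1]
#' @export
stateFromCycle <- function(cyc) (1 - cos(2 * pi * cyc)) / 2

#' Build the dynamic breathing-thorax phantom
#'
#' @param spec a \linkS4class{PhantomSpec}
#' @return a \linkS4class{PhantomModel}
#' @export
buildPhantom <- function(spec) {
  validObject(spec)
  n <- spec@grid_size
  cx <- (n + 1) / 2
  ix <- seq_len(n)
  X <- array(rep(ix, times = n * n), dim = c(n, n, n))
  Y <- array(rep(rep(ix, each = n), times = n), dim = c(n, n, n))
  Z <- array(rep(ix, each = n * n), dim = c(n, n, n))

  body_ax <- c(0.42, 0.36, 0.48) * n
  qb <- ((X - cx) / body_ax[1])^2 + ((Y - cx) / body_ax[2])^2 +
    ((Z - cx) / body_ax[3])^2
  body_w <- 1 / (1 + exp((qb - 1) / 0.05))

  lung_ax <- c(0.14, 0.20, 0.24) * n
  zc <- 0.45 * n
  qL <- ((X - cx + 0.19 * n) / lung_ax[1])^2 + ((Y - cx) / lung_ax[2])^2 +
    ((Z - zc) / lung_ax[3])^2
  qR <- ((X - cx - 0.19 * n) / lung_ax[1])^2 + ((Y - cx) / lung_ax[2])^2 +
    ((Z - zc) / lung_ax[3])^2
  lung_level <- pmin(qL, qR)

  body <- body_w * 1.0
  if (spec@include_trachea) {
    rt <- 0.035 * n
    trachea <- ((X - cx)^2 + (Y - cx)^2 < rt^2) & (Z > 0.08 * n) & (Z < zc)
    body[trachea] <- 0.02
  }

  vessel <- array(FALSE, dim = c(n, n, n))
  if (spec@include_vessels) {
    for (sx in c(-1, 1)) {
      ccx <- cx + sx * 0.19 * n
      rv <- 0.03 * n
      vessel <- vessel |
        (((X - ccx)^2 + (Y - cx)^2 < rv^2) & lung_level < 0.85)
    }
  }

  vox_mm <- spec@fov_mm / n
  fv <- array(spec@tidal_amplitude, dim = c(n, n, n))
  lag <- array(0, dim = c(n, n, n))
  dmask <- array(FALSE, dim = c(n, n, n))
  lung_hard <- lung_level < 1
  for (df in spec@defects) {
    r_vox <- df@radius_mm / vox_mm
    sph <- (X - df@center_voxel[1])^2 + (Y - df@center_voxel[2])^2 +
      (Z - df@center_voxel[3])^2 <= r_vox^2
    if (any(sph & !lung_hard))
      stop("defect sphere extends outside the lung mask")
    fv[sph] <- spec@tidal_amplitude * df@amplitude_scale
    lag[sph] <- df@phase_lag
    dmask <- dmask | sph
  }

  geometry <- list(
    z_apex = zc - lung_ax[3], z_base = zc + lung_ax[3],
    lung_height_vox = 2 * lung_ax[3], vox_mm = vox_mm,
    lung_axes = lung_ax, body_axes = body_ax, center = cx, lung_zc = zc)
  new("PhantomModel", spec = spec, fv_map = fv, lag_map = lag,
      defect_mask = dmask, lung_level = lung_level, body_density = body,
      geometry = geometry)
}

# continuous lung level at stretched coordinates for inflation state a
lungLevelAt <- function(model, a) {
  n <- model@spec@grid_size
  g <- model@geometry
  stretch <- 1 + a * model@spec@tidal_amplitude
  z <- seq_len(n)
  z0 <- g$z_apex + (z - g$z_apex) / stretch
  # sample the EE level set at (x, y, z0): pure z-remap
  lev <- array(2, dim = c(n, n, n))
  pts_z <- pmin(pmax(z0, 1), n)
  for (k in seq_len(n)) {
    zl <- pts_z[k]
    k0 <- floor(zl)
    k1 <- min(k0 + 1, n)
    f <- zl - k0
    lev[, , k] <- (1 - f) * model@lung_level[, , k0] + f * model@lung_level[, , k1]
  }
  list(level = lev, z0 = z0, stretch = stretch)
}

# z-remap lookup of an EE-grid attribute map at inflation state a
remapZ <- function(map, z0, n) {
  out <- array(0, dim = dim(map))
  pts_z <- pmin(pmax(z0, 1), n)
  for (k in seq_len(n)) {
    zl <- pts_z[k]
    k0 <- floor(zl)
    k1 <- min(k0 + 1, n)
    f <- zl - k0
    out[, , k] <- (1 - f) * map[, , k0] + f * map[, , k1]
  }
  out
}

#' Render the phantom at a respiratory state
#'
#' @param model a \linkS4class{PhantomModel}
#' @param a inflation state in [0, 1] (0 = end-expiration)
#' @param cycle_fraction optional cycle fraction in [0, 1); required when the
#'   phantom contains phase-lag defects, whose effective inflation follows
#'   the cycle delayed by their lag
#' @return real 3D density volume
#' @export
evaluatePhantom <- function(model, a, cycle_fraction = NULL) {
  stopifnot(a >= 0, a <= 1)
  spec <- model@spec
  n <- spec@grid_size
  st <- lungLevelAt(model, a)
  w <- 1 / (1 + exp((st$level - 1) / 0.05))
  fv <- remapZ(model@fv_map, st$z0, n)
  a_eff <- array(a, dim = c(n, n, n))
  if (any(model@lag_map > 0)) {
    if (is.null(cycle_fraction))
      stop("cycle_fraction is required for phantoms with phase-lag defects")
    lagm <- remapZ(model@lag_map, st$z0, n)
    lagged <- lagm > 0
    a_eff[lagged] <- stateFromCycle((cycle_fraction - lagm[lagged]) %% 1)
  }
  parench <- spec@lung_density_ee / (1 + a_eff * fv)
  vol <- model@body_density * (1 - w) + w * parench
  if (spec@include_vessels) {
    vw <- remapZ(array(as.numeric(phantomVesselMask(model)), dim = c(n, n, n)),
                 st$z0, n)
    vol <- vol * (1 - vw) + vw * 1.0
  }
  vol
}

# EE-grid vessel mask (bright cylinders inside the lungs)
phantomVesselMask <- function(model) {
  n <- model@spec@grid_size
  if (!model@spec@include_vessels) return(array(FALSE, dim = c(n, n, n)))
  cx <- model@geometry$center
  ix <- seq_len(n)
  X <- array(rep(ix, times = n * n), dim = c(n, n, n))
  Y <- array(rep(rep(ix, each = n), times = n), dim = c(n, n, n))
  rv <- 0.03 * n
  m <- array(FALSE, dim = c(n, n, n))
  for (sx in c(-1, 1)) {
    ccx <- cx + sx * 0.19 * n
    m <- m | (((X - ccx)^2 + (Y - cx)^2 < rv^2) & model@lung_level < 0.85)
  }
  m
}

#' Lung-compartment mass of the phantom at a respiratory state
#'
#' Integral of parenchymal density over the (soft-edged, deforming) lung
#' compartment; conserved across inflation states when the
#' fractional-ventilation amplitude matches the geometric stretch.
#'
#' @param model a \linkS4class{PhantomModel}
#' @param a inflation state in [0, 1]
#' @param cycle_fraction optional cycle fraction (for lagged defects)
#' @return total mass in signal units x voxels
#' @export
phantomLungMass <- function(model, a, cycle_fraction = NULL) {
  spec <- model@spec
  n <- spec@grid_size
  st <- lungLevelAt(model, a)
  w <- 1 / (1 + exp((st$level - 1) / 0.05))
  fv <- remapZ(model@fv_map, st$z0, n)
  a_eff <- array(a, dim = c(n, n, n))
  if (any(model@lag_map > 0) && !is.null(cycle_fraction)) {
    lagm <- remapZ(model@lag_map, st$z0, n)
    lagged <- lagm > 0
    a_eff[lagged] <- stateFromCycle((cycle_fraction - lagm[lagged]) %% 1)
  }
  sum(w * spec@lung_density_ee / (1 + a_eff * fv))
}

#' Phantom ground truth maps
#'
#' @param model a \linkS4class{PhantomModel}
#' @return list with \code{fv} (fractional-ventilation amplitude),
#'   \code{lag} (cycle-fraction filling delay), \code{peak_phase}
#'   (true peak-filling cycle fraction), \code{defect_mask},
#'   \code{lung_mask_ee}, \code{vessel_mask} and \code{geometry}
#' @export
phantomTruth <- function(model) {
  lung <- model@lung_level < 1
  list(fv = model@fv_map, lag = model@lag_map,
       peak_phase = 0.5 + model@lag_map, defect_mask = model@defect_mask,
       lung_mask_ee = lung, vessel_mask = phantomVesselMask(model),
       geometry = model@geometry)
}

#' Phantom ground truth maps in the frame of a given inflation state
#'
#' Remaps the end-expiration ground-truth attribute maps (FV amplitude,
#' phase lag, defect mask, lung mask) onto the stretched geometry at
#' inflation state \code{a}, for comparison against analysis maps produced
#' in a registered frame (e.g. end-inspiration).
#'
#' @param model a \linkS4class{PhantomModel}
#' @param a inflation state of the target frame
#' @return list with \code{fv}, \code{lag}, \code{defect_mask},
#'   \code{lung_mask} in the state-a frame
#' @export
phantomTruthAtState <- function(model, a) {
  n <- model@spec@grid_size
  st <- lungLevelAt(model, a)
  list(fv = remapZ(model@fv_map, st$z0, n),
       lag = remapZ(model@lag_map, st$z0, n),
       defect_mask = remapZ(array(as.numeric(model@defect_mask),
                                  dim = c(n, n, n)), st$z0, n) > 0.5,
       lung_mask = st$level < 1)
}

#' Simulate a respiratory bellows trace
#'
#' Quasi-sinusoidal chest-expansion trace with cycle-to-cycle amplitude and
#' period jitter, linear drift, additive noise and sparse high-amplitude
#' outliers. The generator logs the true cycle fraction per excitation and
#' the injected outlier indices (phantom ground truth).
#'
#' @param spec a \linkS4class{PhantomSpec} (breathing period and seed)
#' @param n_excitations number of excitations
#' @param tr_s time per excitation (TR), seconds
#' @param drift linear drift in amplitude units per minute
#' @param outlier_rate fraction of samples replaced by high-amplitude spikes
#' @param amp_jitter SD of cycle-to-cycle amplitude jitter (fraction)
#' @param period_jitter SD of cycle-to-cycle period jitter (fraction)
#' @param noise_sd additive white-noise SD in amplitude units
#' @return a \linkS4class{BellowsTrace}
#' @export
simulateBellows <- function(spec, n_excitations, tr_s = 0.00376, drift = 0,
                            outlier_rate = 0, amp_jitter = 0.08,
                            period_jitter = 0.04, noise_sd = 0.01) {
  stopifnot(n_excitations >= 1)
  set.seed(spec@seed)
  t <- (seq_len(n_excitations) - 1) * tr_s
  n_cycles <- ceiling(t[n_excitations] / spec@breathing_period_s) + 2
  periods <- spec@breathing_period_s *
    pmax(0.5, 1 + period_jitter * stats::rnorm(n_cycles))
  amps <- pmax(0.2, 1 + amp_jitter * stats::rnorm(n_cycles))
  edges <- c(0, cumsum(periods))
  cyc_idx <- findInterval(t, edges)
  frac <- (t - edges[cyc_idx]) / periods[cyc_idx]
  values <- amps[cyc_idx] * stateFromCycle(frac) + drift * t / 60 +
    noise_sd * stats::rnorm(n_excitations)
  out_idx <- integer(0)
  if (outlier_rate > 0) {
    n_out <- round(outlier_rate * n_excitations)
    if (n_out > 0) {
      out_idx <- sort(sample.int(n_excitations, n_out))
      s <- stats::sd(values)
      values[out_idx] <- values[out_idx] +
        sample(c(-1, 1), n_out, replace = TRUE) * (4 * s)
    }
  }
  # inflation relative to the deepest breath of the session (diagnostic log;
  # the simulator itself renders with the binding bellows->state mapping)
  true_state <- amps[cyc_idx] * stateFromCycle(frac) / max(amps)
  new("BellowsTrace", values = values, dt_s = tr_s,
      cycle_fraction = frac %% 1, true_state = true_state,
      outlier_log = out_idx)
}

#' Simulate smooth complex coil sensitivity maps
#'
#' Gaussian lobes placed around the body periphery with a small smooth phase
#' ramp per coil. A single coil returns a uniform map, so the forward model
#' reduces to a plain NUFFT.
#'
#' @param n_coils number of coils
#' @param grid_size voxels per axis
#' @return a \linkS4class{SensitivityMaps}
#' @export
makeCoilMaps <- function(n_coils, grid_size) {
  stopifnot(n_coils >= 1)
  n <- grid_size
  if (n_coils == 1) {
    maps <- array(1 + 0i, dim = c(n, n, n, 1))
    return(new("SensitivityMaps", maps = maps, grid = as.integer(rep(n, 3))))
  }
  cx <- (n + 1) / 2
  ix <- seq_len(n)
  X <- array(rep(ix, times = n * n), dim = c(n, n, n))
  Y <- array(rep(rep(ix, each = n), times = n), dim = c(n, n, n))
  Z <- array(rep(ix, each = n * n), dim = c(n, n, n))
  maps <- array(0 + 0i, dim = c(n, n, n, n_coils))
  sig <- 0.95 * n
  for (c0 in seq_len(n_coils)) {
    th <- 2 * pi * (c0 - 1) / n_coils
    px <- cx + 0.55 * n * cos(th)
    py <- cx + 0.55 * n * sin(th)
    pz <- cx + 0.1 * n * sin(2 * th)
    mag <- exp(-((X - px)^2 + (Y - py)^2 + (Z - pz)^2) / (2 * sig^2))
    ph <- 0.8 * pi * ((X - cx) * cos(th) + (Y - cx) * sin(th)) / n
    maps[, , , c0] <- mag * exp(1i * ph)
  }
  new("SensitivityMaps", maps = maps, grid = as.integer(rep(n, 3)))
}

# map a bellows trace to inflation states in [0, 1] using sliding
# 3-cycle quantile normalization of the trace (robust to drift and to
# sparse high-amplitude outliers)
bellowsToState <- function(trace, breathing_period_s) {
  v <- trace@values
  n <- length(v)
  cyc_len <- max(2, round(breathing_period_s / trace@dt_s))
  nb <- max(1, ceiling(n / cyc_len))
  blk <- rep(seq_len(nb), each = cyc_len)[seq_len(n)]
  bmin <- tapply(v, blk, stats::quantile, probs = 0.02, names = FALSE)
  bmax <- tapply(v, blk, stats::quantile, probs = 0.98, names = FALSE)
  lo <- hi <- numeric(nb)
  for (b in seq_len(nb)) {
    w <- max(1, b - 1):min(nb, b + 1)
    lo[b] <- min(bmin[w])
    hi[b] <- max(bmax[w])
  }
  a <- (v - lo[blk]) / pmax(hi[blk] - lo[blk], 1e-12)
  pmin(pmax(a, 0), 1)
}

# estimate per-excitation cycle fraction; uses the generator's log when
# present, otherwise the Hilbert instantaneous phase of the detrended trace
bellowsCycleFraction <- function(trace) {
  if (length(trace@cycle_fraction)) return(trace@cycle_fraction)
  v <- trace@values - mean(trace@values)
  ph <- Arg(analyticSignal(v))
  ((ph + pi) / (2 * pi)) %% 1
}

#' Simulate a non-Cartesian multicoil acquisition of the breathing phantom
#'
#' For each excitation the phantom is rendered at that excitation's
#' instantaneous respiratory state (bellows mapped to the inflation state by
#' sliding min-max normalization), multiplied by the coil maps, and the
#' NUFFT is evaluated at that readout's coordinates; complex Gaussian noise
#' is added. For tractability the cycle is quantized into
#' \code{n_states} rendered states; excitations share the FFT grid of their
#' state.
#'
#' @param model a \linkS4class{PhantomModel}
#' @param traj a \linkS4class{TrajectorySet} on the phantom FOV
#' @param bellows a \linkS4class{BellowsTrace} with one value per excitation
#' @param sens a \linkS4class{SensitivityMaps} on the phantom grid
#' @param noise_sd complex noise SD per sample component (default from spec)
#' @param n_states number of quantized respiratory states rendered
#' @return a \linkS4class{KSpaceData}
#' @export
simulateAcquisition <- function(model, traj, bellows, sens,
                                noise_sd = model@spec@noise_sd,
                                n_states = 16L) {
  I <- dim(traj@coords)[1]
  J <- dim(traj@coords)[2]
  if (length(bellows@values) != I)
    stop("bellows length must equal trajectory excitation count")
  C <- dim(sens@maps)[4]
  n <- model@spec@grid_size
  stopifnot(all(dim(sens@maps)[1:3] == n))

  # inflation state follows the binding bellows->state convention: sliding
  # 3-cycle min-max normalization of the smoothed trace (each ~3-cycle
  # window peak maps to full inspiration)
  win <- defaultSmoothingWindow(model@spec@breathing_period_s, bellows@dt_s)
  smooth_tr <- if (win > 1 && win < length(bellows@values))
    preprocessBellows(bellows, win) else bellows
  a_all <- bellowsToState(smooth_tr, model@spec@breathing_period_s)
  cyc_all <- bellowsCycleFraction(bellows)
  static <- model@spec@tidal_amplitude == 0 && all(model@lag_map == 0)
  state_id <- if (static) rep(1L, I) else
    (floor(cyc_all * n_states) %% n_states) + 1L

  plan <- nufftPlan(rep(n, 3), traj@fov_mm)
  samples <- array(0 + 0i, dim = c(C, I, J))
  for (s in sort(unique(state_id))) {
    idx <- which(state_id == s)
    cyc_s <- if (static) 0 else (s - 0.5) / n_states
    a_s <- if (static) 0 else mean(a_all[idx])
    vol <- evaluatePhantom(model, a_s, cyc_s)
    coords <- matrix(aperm(traj@coords[idx, , , drop = FALSE], c(2, 1, 3)),
                     ncol = 3)
    for (c0 in seq_len(C)) {
      vals <- nufftForward(plan, vol * sens@maps[, , , c0], coords)
      samples[c0, idx, ] <- matrix(vals, nrow = J)[, seq_along(idx),
                                                   drop = FALSE] |> t()
    }
  }
  if (noise_sd > 0)
    samples <- samples + noise_sd *
      (array(stats::rnorm(length(samples)), dim = dim(samples)) +
         1i * array(stats::rnorm(length(samples)), dim = dim(samples)))
  new("KSpaceData", samples = samples, traj = traj, bellows = bellows,
      noise_sd = noise_sd)
}
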