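#' @import methods
NULL

## ---- configuration objects -------------------------------------------------

#' Configuration for FLORET trajectory generation
#'
#' Holds the acquisition geometry of a 3-hub Fermat-spiral ("FLORET")
#' center-out 3D k-space trajectory: isotropic field of view, nominal
#' acquisition resolution, number of hubs, samples per readout, total number
#' of excitations, target Nyquist sampling percentage, cone half-angle of
#' each hub, and the interleave ordering used to spread azimuthal angles in
#' time.
#'
#' @slot fov_mm isotropic field of view in mm
#' @slot res_mm nominal acquisition resolution in mm
#' @slot n_hubs number of orthogonal hubs (1, 2 or 3)
#' @slot samples_per_readout samples along each center-out readout (J)
#' @slot n_excitations total number of excitations (readouts)
#' @slot nyquist_pct target Nyquist sampling fraction in (0, 2]
#' @slot hub_half_angle_deg cone half-angle of each hub in degrees
#' @slot interleave_order one of "golden", "sequential", "bit-reversed"
#' @exportClass TrajectoryConfig
setClass("TrajectoryConfig",
  representation(fov_mm = "numeric", res_mm = "numeric", n_hubs = "integer",
                 samples_per_readout = "integer", n_excitations = "integer",
                 nyquist_pct = "numeric", hub_half_angle_deg = "numeric",
                 interleave_order = "character"),
  validity = function(object) {
    msg <- character()
    if (object@fov_mm <= 0) msg <- c(msg, "fov_mm must be > 0")
    if (object@res_mm <= 0) msg <- c(msg, "res_mm must be > 0")
    if (!object@n_hubs %in% 1:3) msg <- c(msg, "n_hubs must be in {1,2,3}")
    if (object@nyquist_pct <= 0 || object@nyquist_pct > 2)
      msg <- c(msg, "nyquist_pct must be in (0, 2]")
    if (object@samples_per_readout < 2)
      msg <- c(msg, "samples_per_readout must be >= 2")
    if (object@n_excitations < 1) msg <- c(msg, "n_excitations must be >= 1")
    if (!object@interleave_order %in% c("golden", "sequential", "bit-reversed"))
      msg <- c(msg, "interleave_order must be golden, sequential or bit-reversed")
    if (length(msg)) msg else TRUE
  })

#' Constructor for \linkS4class{TrajectoryConfig}
#'
#' Defaults follow the acquisition geometry this package simulates:
#' 320 mm isotropic FOV, 1.6 mm nominal resolution, 3 orthogonal hubs and a
#' golden-angle interleave ordering so that any contiguous acquisition window
#' covers azimuthal angles quasi-uniformly.
#'
#' @param fov_mm,res_mm,n_hubs,samples_per_readout,n_excitations,nyquist_pct
#'   see \linkS4class{TrajectoryConfig}
#' @param hub_half_angle_deg,interleave_order see \linkS4class{TrajectoryConfig}
#' @return a \linkS4class{TrajectoryConfig}
#' @export
trajectoryConfig <- function(fov_mm = 320, res_mm = 1.6, n_hubs = 3L,
                             samples_per_readout = 64L, n_excitations = 20000L,
                             nyquist_pct = 1, hub_half_angle_deg = 45,
                             interleave_order = "golden") {
  new("TrajectoryConfig", fov_mm = as.numeric(fov_mm),
      res_mm = as.numeric(res_mm), n_hubs = as.integer(n_hubs),
      samples_per_readout = as.integer(samples_per_readout),
      n_excitations = as.integer(n_excitations),
      nyquist_pct = as.numeric(nyquist_pct),
      hub_half_angle_deg = as.numeric(hub_half_angle_deg),
      interleave_order = interleave_order)
}

#' Ventilation defect specification for the digital phantom
#'
#' A spherical region of the lung whose fractional-ventilation amplitude is
#' scaled down by \code{amplitude_scale} (0 = no filling at all) and/or whose
#' filling lags the rest of the lung by \code{phase_lag} cycle fractions
#' (delayed filling drives VTTP and FVL-CM abnormality without changing the
#' filling amplitude).
#'
#' @slot center_voxel 3D voxel index (1-based) of the sphere center
#' @slot radius_mm sphere radius in mm
#' @slot amplitude_scale ventilation reduction factor in [0, 1]
#' @slot phase_lag filling delay as a fraction of the cycle, in [0, 0.5)
#' @exportClass DefectSpec
setClass("DefectSpec",
  representation(center_voxel = "integer", radius_mm = "numeric",
                 amplitude_scale = "numeric", phase_lag = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(object@center_voxel) != 3) msg <- c(msg, "center_voxel must have 3 entries")
    if (object@amplitude_scale < 0 || object@amplitude_scale > 1)
      msg <- c(msg, "amplitude_scale must be in [0,1]")
    if (object@phase_lag < 0 || object@phase_lag >= 0.5)
      msg <- c(msg, "phase_lag must be in [0, 0.5)")
    if (object@radius_mm <= 0) msg <- c(msg, "radius_mm must be > 0")
    if (length(msg)) msg else TRUE
  })

#' @rdname DefectSpec-class
#' @param center_voxel,radius_mm,amplitude_scale,phase_lag see slots
#' @return a \linkS4class{DefectSpec}
#' @export
defectSpec <- function(center_voxel, radius_mm, amplitude_scale = 0,
                       phase_lag = 0) {
  new("DefectSpec", center_voxel = as.integer(center_voxel),
      radius_mm = as.numeric(radius_mm),
      amplitude_scale = as.numeric(amplitude_scale),
      phase_lag = as.numeric(phase_lag))
}

#' Specification of the dynamic breathing-thorax phantom
#'
#' @slot grid_size voxels per axis (isotropic grid)
#' @slot fov_mm field of view in mm
#' @slot breathing_period_s nominal breathing period in seconds
#' @slot tidal_amplitude diaphragm excursion as a fraction of lung height
#' @slot lung_density_ee parenchymal density at end-expiration (signal units;
#'   body soft tissue is 1)
#' @slot defects list of \linkS4class{DefectSpec}
#' @slot n_coils number of simulated receive coils
#' @slot noise_sd complex-Gaussian noise SD per k-space sample component
#' @slot seed RNG seed for all phantom randomness
#' @slot include_trachea logical; carve a low-signal trachea cylinder
#' @slot include_vessels logical; insert bright vessel cylinders in the lungs
#' @exportClass PhantomSpec
setClass("PhantomSpec",
  representation(grid_size = "integer", fov_mm = "numeric",
                 breathing_period_s = "numeric", tidal_amplitude = "numeric",
                 lung_density_ee = "numeric", defects = "list",
                 n_coils = "integer", noise_sd = "numeric", seed = "integer",
                 include_trachea = "logical", include_vessels = "logical"),
  validity = function(object) {
    msg <- character()
    if (object@grid_size < 16) msg <- c(msg, "grid_size must be >= 16")
    if (object@breathing_period_s <= 0) msg <- c(msg, "breathing_period_s must be > 0")
    if (object@tidal_amplitude < 0 || object@tidal_amplitude >= 0.5)
      msg <- c(msg, "tidal_amplitude must be in [0, 0.5)")
    if (object@noise_sd < 0) msg <- c(msg, "noise_sd must be >= 0")
    if (!all(vapply(object@defects, is, TRUE, class2 = "DefectSpec")))
      msg <- c(msg, "defects must be a list of DefectSpec")
    if (length(msg)) msg else TRUE
  })

#' Constructor for \linkS4class{PhantomSpec}
#'
#' The defaults define the desk-scale study configuration: a 48^3 grid,
#' 4 coils, 4 s breathing period and a tidal fractional-ventilation amplitude
#' of 0.25. \code{noise_sd} is calibrated so that default reconstructions
#' land at a parenchymal SNR in the mid-teens.
#'
#' @param grid_size,fov_mm,breathing_period_s,tidal_amplitude,lung_density_ee
#'   see \linkS4class{PhantomSpec}
#' @param defects,n_coils,noise_sd,seed,include_trachea,include_vessels
#'   see \linkS4class{PhantomSpec}
#' @return a \linkS4class{PhantomSpec}
#' @export
phantomSpec <- function(grid_size = 48L, fov_mm = 320,
                        breathing_period_s = 4, tidal_amplitude = 0.25,
                        lung_density_ee = 0.25, defects = list(),
                        n_coils = 4L, noise_sd = 0.02, seed = 1L,
                        include_trachea = TRUE, include_vessels = FALSE) {
  new("PhantomSpec", grid_size = as.integer(grid_size),
      fov_mm = as.numeric(fov_mm),
      breathing_period_s = as.numeric(breathing_period_s),
      tidal_amplitude = as.numeric(tidal_amplitude),
      lung_density_ee = as.numeric(lung_density_ee), defects = defects,
      n_coils = as.integer(n_coils), noise_sd = as.numeric(noise_sd),
      seed = as.integer(seed), include_trachea = isTRUE(include_trachea),
      include_vessels = isTRUE(include_vessels))
}

#' Respiratory binning configuration
#'
#' @slot n_bins number of respiratory-phase bins (B)
#' @slot smoothing_window moving-average window in excitations (0 = auto,
#'   a quarter of the breathing period)
#' @slot exclusion_k SD multiplier for bellows outlier exclusion
#' @slot total_budget total excitation budget T; per-bin count is
#'   \code{T \%/\% B}. Scaled down to twice the usable excitation count when
#'   fewer than 120000 usable excitations are available.
#' @slot max_share_fraction maximum fraction of a bin's members that may be
#'   shared with other bins (view sharing)
#' @exportClass BinningConfig
setClass("BinningConfig",
  representation(n_bins = "integer", smoothing_window = "integer",
                 exclusion_k = "numeric", total_budget = "integer",
                 max_share_fraction = "numeric"),
  validity = function(object) {
    msg <- character()
    if (object@n_bins < 2) msg <- c(msg, "n_bins must be >= 2")
    if (object@smoothing_window < 0) msg <- c(msg, "smoothing_window must be >= 0")
    if (object@exclusion_k <= 0) msg <- c(msg, "exclusion_k must be > 0")
    if (object@max_share_fraction < 0 || object@max_share_fraction > 0.5)
      msg <- c(msg, "max_share_fraction must be in [0, 0.5]")
    if (length(msg)) msg else TRUE
  })

#' @rdname BinningConfig-class
#' @param n_bins,smoothing_window,exclusion_k,total_budget,max_share_fraction
#'   see slots
#' @return a \linkS4class{BinningConfig}
#' @export
binningConfig <- function(n_bins = 8L, smoothing_window = 0L, exclusion_k = 2,
                          total_budget = 240000L, max_share_fraction = 0.5) {
  new("BinningConfig", n_bins = as.integer(n_bins),
      smoothing_window = as.integer(smoothing_window),
      exclusion_k = as.numeric(exclusion_k),
      total_budget = as.integer(total_budget),
      max_share_fraction = as.numeric(max_share_fraction))
}

#' Nonrigid registration parameters
#'
#' Multiresolution diffeomorphic-demons-style registration: per level,
#' shrink factor, update (fluid) smoothing sigma and iteration count. An
#' optional initial translation alignment (phase correlation) precedes the
#' nonrigid stage when \code{mode = "affine_then_nonrigid"}.
#'
#' @slot mode "affine_then_nonrigid" or "nonrigid_only"
#' @slot similarity "cross_correlation" (images z-scored in the mask before
#'   SSD forces) or "ssd"
#' @slot levels per-level shrink factors (coarse to fine)
#' @slot smoothing per-level update smoothing sigmas (voxels at full res)
#' @slot iterations per-level iteration counts
#' @slot field_sigma elastic smoothing sigma of the total field (voxels)
#' @slot mask optional logical array restricting the metric
#' @exportClass RegistrationParams
setClass("RegistrationParams",
  representation(mode = "character", similarity = "character",
                 levels = "integer", smoothing = "numeric",
                 iterations = "integer", field_sigma = "numeric",
                 mask = "ANY"),
  validity = function(object) {
    msg <- character()
    if (length(object@levels) != length(object@smoothing) ||
        length(object@levels) != length(object@iterations))
      msg <- c(msg, "levels, smoothing, iterations must have equal length")
    if (any(object@iterations <= 0)) msg <- c(msg, "iterations must be > 0")
    if (!object@mode %in% c("affine_then_nonrigid", "nonrigid_only"))
      msg <- c(msg, "unknown mode")
    if (!object@similarity %in% c("cross_correlation", "ssd"))
      msg <- c(msg, "unknown similarity")
    if (length(msg)) msg else TRUE
  })

#' @rdname RegistrationParams-class
#' @param mode,similarity,levels,smoothing,iterations,field_sigma,mask see slots
#' @return a \linkS4class{RegistrationParams}
#' @export
registrationParams <- function(mode = "affine_then_nonrigid",
                               similarity = "cross_correlation",
                               levels = c(4L, 2L, 1L),
                               smoothing = c(2, 1.5, 1),
                               iterations = c(60L, 40L, 20L),
                               field_sigma = 0.5, mask = NULL) {
  new("RegistrationParams", mode = mode, similarity = similarity,
      levels = as.integer(levels), smoothing = as.numeric(smoothing),
      iterations = as.integer(iterations),
      field_sigma = as.numeric(field_sigma), mask = mask)
}

#' Cheaper registration parameter set used inside the reconstruction loop
#' @return a \linkS4class{RegistrationParams}
#' @export
reconRegistrationParams <- function() {
  registrationParams(levels = c(4L, 2L), smoothing = c(2, 1.5),
                     iterations = c(30L, 15L))
}

#' Stiff registration parameter set (coarse levels only)
#'
#' Coarser multiresolution levels and stronger regularization than the
#' general-purpose default: bulk respiratory motion is compensated while
#' the field is too stiff to counterfeit small regional density-change
#' patterns as deformation. Preserves regional defect contrast at the cost
#' of residual fine-scale motion.
#'
#' @return a \linkS4class{RegistrationParams}
#' @export
stiffRegistrationParams <- function() {
  registrationParams(levels = c(4L, 2L), smoothing = c(2, 1.5),
                     iterations = c(80L, 40L), field_sigma = 1.0)
}

#' Motion-compensated low-rank reconstruction configuration
#'
#' @slot lambda_L low-rank regularization weight (relative to the largest
#'   singular value of the initial motion-registered phase stack)
#' @slot inner_iters gradient steps per proximal cycle
#' @slot outer_iters proximal cycles per motion re-estimation
#' @slot superior_iters motion re-estimations
#' @slot step_rho step-size scaling of the Lipschitz-normalized gradient step
#' @slot cg_init_iters CG-SENSE iterations used for initialization
#' @slot weighted_objective logical; include the preconditioning weights in
#'   the data-fidelity term (weighted residual) rather than using them only
#'   as a solver preconditioner
#' @exportClass ReconConfig
setClass("ReconConfig",
  representation(lambda_L = "numeric", inner_iters = "integer",
                 outer_iters = "integer", superior_iters = "integer",
                 step_rho = "numeric", cg_init_iters = "integer",
                 weighted_objective = "logical"),
  validity = function(object) {
    msg <- character()
    if (object@lambda_L < 0) msg <- c(msg, "lambda_L must be >= 0")
    if (object@inner_iters < 1 || object@outer_iters < 1 ||
        object@superior_iters < 1)
      msg <- c(msg, "iteration counts must be >= 1")
    if (object@step_rho <= 0) msg <- c(msg, "step_rho must be > 0")
    if (length(msg)) msg else TRUE
  })

#' @rdname ReconConfig-class
#' @param lambda_L,inner_iters,outer_iters,superior_iters,step_rho see slots
#' @param cg_init_iters,weighted_objective see slots
#' @return a \linkS4class{ReconConfig}
#' @export
reconConfig <- function(lambda_L = 0.01, inner_iters = 5L, outer_iters = 3L,
                        superior_iters = 3L, step_rho = 1,
                        cg_init_iters = 10L, weighted_objective = TRUE) {
  new("ReconConfig", lambda_L = as.numeric(lambda_L),
      inner_iters = as.integer(inner_iters),
      outer_iters = as.integer(outer_iters),
      superior_iters = as.integer(superior_iters),
      step_rho = as.numeric(step_rho),
      cg_init_iters = as.integer(cg_init_iters),
      weighted_objective = isTRUE(weighted_objective))
}

#' PREFUL postprocessing configuration
#'
#' @slot n_phases number of equidistant output phases of the ventilation cycle
#' @slot gauss_sigma Gaussian interpolation sigma in units of input phase
#'   spacing
#' @slot lowpass_hz temporal low-pass cutoff in Hz, converted to a cycle
#'   harmonic via the breathing period
#' @slot breathing_period_s mean breathing period in seconds
#' @slot fvl_cm_threshold defect threshold on FVL-CM
#' @slot rvent_pct percentile of the RVent distribution anchoring the RVent
#'   defect threshold
#' @slot rvent_frac fraction of that percentile used as the threshold
#' @slot ref_quantiles quantile band of rvent values defining the
#'   high-ventilation reference region
#' @slot cm_lag_search logical; maximize CM over circular lags instead of the
#'   zero-lag correlation (off by default so that delayed filling lowers CM)
#' @slot bilateral_range_sd range sigma of the edge-preserving filter as a
#'   multiple of the background noise SD
#' @exportClass PrefulConfig
setClass("PrefulConfig",
  representation(n_phases = "integer", gauss_sigma = "numeric",
                 lowpass_hz = "numeric", breathing_period_s = "numeric",
                 fvl_cm_threshold = "numeric", rvent_pct = "numeric",
                 rvent_frac = "numeric", ref_quantiles = "numeric",
                 cm_lag_search = "logical", bilateral_range_sd = "numeric"),
  validity = function(object) {
    msg <- character()
    if (object@n_phases < 4) msg <- c(msg, "n_phases must be >= 4")
    if (object@fvl_cm_threshold <= 0 || object@fvl_cm_threshold > 1)
      msg <- c(msg, "fvl_cm_threshold must be in (0,1]")
    if (object@rvent_frac <= 0 || object@rvent_frac > 1)
      msg <- c(msg, "rvent_frac must be in (0,1]")
    if (length(object@ref_quantiles) != 2 ||
        diff(object@ref_quantiles) <= 0)
      msg <- c(msg, "ref_quantiles must be an increasing pair")
    if (length(msg)) msg else TRUE
  })

#' @rdname PrefulConfig-class
#' @param n_phases,gauss_sigma,lowpass_hz,breathing_period_s see slots
#' @param fvl_cm_threshold,rvent_pct,rvent_frac,ref_quantiles see slots
#' @param cm_lag_search,bilateral_range_sd see slots
#' @return a \linkS4class{PrefulConfig}
#' @export
prefulConfig <- function(n_phases = 16L, gauss_sigma = 0.3, lowpass_hz = 0.7,
                         breathing_period_s = 4, fvl_cm_threshold = 0.9,
                         rvent_pct = 0.9, rvent_frac = 0.4,
                         ref_quantiles = c(0.75, 0.95),
                         cm_lag_search = FALSE, bilateral_range_sd = 2) {
  new("PrefulConfig", n_phases = as.integer(n_phases),
      gauss_sigma = as.numeric(gauss_sigma),
      lowpass_hz = as.numeric(lowpass_hz),
      breathing_period_s = as.numeric(breathing_period_s),
      fvl_cm_threshold = as.numeric(fvl_cm_threshold),
      rvent_pct = as.numeric(rvent_pct), rvent_frac = as.numeric(rvent_frac),
      ref_quantiles = as.numeric(ref_quantiles),
      cm_lag_search = isTRUE(cm_lag_search),
      bilateral_range_sd = as.numeric(bilateral_range_sd))
}

## ---- data containers -------------------------------------------------------

#' A set of 3D k-space trajectories
#'
#' @slot coords array (n_excitations, samples_per_readout, 3) of k-space
#'   coordinates in cycles/mm
#' @slot excitation_order acquisition-time ordering of the readouts
#' @slot kmax spatial frequency bound 1/(2 res_mm), cycles/mm
#' @slot fov_mm,res_mm geometry the trajectory was designed for
#' @slot hub_axes 3x3 matrix of hub cone-axis unit vectors (rows)
#' @slot hub_assign per-excitation hub index
#' @exportClass TrajectorySet
setClass("TrajectorySet",
  representation(coords = "array", excitation_order = "integer",
                 kmax = "numeric", fov_mm = "numeric", res_mm = "numeric",
                 hub_axes = "matrix", hub_assign = "integer"),
  validity = function(object) {
    d <- dim(object@coords)
    if (length(d) != 3 || d[3] != 3)
      return("coords must be (excitations, samples, 3)")
    if (!all(is.finite(object@coords))) return("coords must be finite")
    TRUE
  })

#' A respiratory bellows trace
#'
#' @slot values per-excitation bellows amplitude (arbitrary units)
#' @slot dt_s time per excitation (TR), seconds
#' @slot cycle_fraction optional per-excitation true cycle fraction in
#'   [0, 1) logged by the simulator (phantom ground truth; empty for real
#'   data)
#' @slot true_state optional per-excitation true inflation state in [0, 1]
#'   logged by the simulator (empty for real data, where the state is
#'   estimated from the trace)
#' @slot outlier_log indices where outliers were injected by the simulator
#' @exportClass BellowsTrace
setClass("BellowsTrace",
  representation(values = "numeric", dt_s = "numeric",
                 cycle_fraction = "numeric", true_state = "numeric",
                 outlier_log = "integer"),
  validity = function(object) {
    if (object@dt_s <= 0) return("dt_s must be > 0")
    if (length(object@cycle_fraction) &&
        length(object@cycle_fraction) != length(object@values))
      return("cycle_fraction length must match values")
    TRUE
  })

#' Raw multicoil non-Cartesian k-space data
#'
#' @slot samples complex array (coils, excitations, samples)
#' @slot traj the \linkS4class{TrajectorySet} the data were sampled on
#' @slot bellows the per-excitation \linkS4class{BellowsTrace}
#' @slot noise_sd noise level used at simulation time (NA for real data)
#' @exportClass KSpaceData
setClass("KSpaceData",
  representation(samples = "array", traj = "TrajectorySet",
                 bellows = "BellowsTrace", noise_sd = "numeric"),
  validity = function(object) {
    d <- dim(object@samples)
    if (length(d) != 3) return("samples must be (coils, excitations, samples)")
    dt <- dim(object@traj@coords)
    if (d[2] != dt[1] || d[3] != dt[2])
      return("samples and trajectory shapes are inconsistent")
    if (length(object@bellows@values) != d[2])
      return("bellows length must equal excitation count")
    TRUE
  })

#' Respiratory bin assignments with view-sharing bookkeeping
#'
#' @slot bin_indices list of per-bin excitation index vectors (equal length)
#' @slot phase_targets per-bin target phase in (-pi, pi]
#' @slot excluded excitation indices excluded as bellows outliers
#' @slot share_matrix B x B view-sharing bookkeeping: entry (b, b2) counts
#'   members of bin b borrowed from bin b2's primary (nearest-phase) pool;
#'   row sums are bounded by max_share_fraction times the bin size
#' @slot phases per-excitation instantaneous phase used for the allocation
#' @exportClass RespiratoryBinSet
setClass("RespiratoryBinSet",
  representation(bin_indices = "list", phase_targets = "numeric",
                 excluded = "integer", share_matrix = "matrix",
                 phases = "numeric"),
  validity = function(object) {
    n <- lengths(object@bin_indices)
    if (length(unique(n)) > 1) return("all bins must have equal cardinality")
    if (length(object@excluded) &&
        any(object@excluded %in% unlist(object@bin_indices)))
      return("excluded excitations must not appear in any bin")
    TRUE
  })

#' Respiratory-binned k-space data
#'
#' @slot samples list of per-bin complex arrays (coils, n, samples)
#' @slot coords list of per-bin coordinate arrays (n, samples, 3)
#' @slot bins the \linkS4class{RespiratoryBinSet} used
#' @slot bin_amplitude per-bin mean (smoothed) bellows amplitude
#' @slot fov_mm,res_mm trajectory geometry carried through
#' @exportClass KSpaceBins
setClass("KSpaceBins",
  representation(samples = "list", coords = "list",
                 bins = "RespiratoryBinSet", bin_amplitude = "numeric",
                 fov_mm = "numeric", res_mm = "numeric"))

#' Coil sensitivity maps
#'
#' @slot maps complex array (nx, ny, nz, coils)
#' @slot grid image grid dimensions
#' @exportClass SensitivityMaps
setClass("SensitivityMaps",
  representation(maps = "array", grid = "integer"),
  validity = function(object) {
    if (!all(is.finite(Mod(object@maps)))) return("maps must be finite")
    TRUE
  })

#' Diagonal k-space preconditioning weights
#'
#' @slot weights list of per-bin nonnegative weight matrices (n, samples)
#' @exportClass Preconditioner
setClass("Preconditioner", representation(weights = "list"),
  validity = function(object) {
    ok <- vapply(object@weights, function(w) all(is.finite(w)) && all(w >= 0),
                 TRUE)
    if (!all(ok)) return("weights must be finite and >= 0")
    TRUE
  })

#' A respiratory-resolved image series
#'
#' @slot volumes complex or real array (nx, ny, nz, B)
#' @slot bin_phases per-volume respiratory phase label
#' @slot voxel_mm voxel spacing in mm
#' @exportClass ImageSeries
setClass("ImageSeries",
  representation(volumes = "array", bin_phases = "numeric",
                 voxel_mm = "numeric"),
  validity = function(object) {
    d <- dim(object@volumes)
    if (length(d) != 4) return("volumes must be a 4D array (x, y, z, phase)")
    if (length(object@bin_phases) &&
        length(object@bin_phases) != d[4])
      return("bin_phases length must equal number of volumes")
    TRUE
  })

#' A dense nonrigid deformation field
#'
#' @slot displacement array (nx, ny, nz, 3) of displacements in mm on the
#'   fixed image grid
#' @slot fixed_shape fixed image grid dims
#' @slot voxel_mm voxel spacing in mm
#' @slot interpolation "linear" (trilinear) warping
#' @slot converged logical convergence flag
#' @exportClass DeformationField
setClass("DeformationField",
  representation(displacement = "array", fixed_shape = "integer",
                 voxel_mm = "numeric", interpolation = "character",
                 converged = "logical"),
  validity = function(object) {
    d <- dim(object@displacement)
    if (length(d) != 4 || d[4] != 3)
      return("displacement must be (nx, ny, nz, 3)")
    if (!all(is.finite(object@displacement)))
      return("displacement must be finite everywhere")
    if (!all(d[1:3] == object@fixed_shape))
      return("displacement shape must match the fixed grid")
    TRUE
  })

#' The dynamic breathing-thorax phantom model
#'
#' Produced by \code{\link{buildPhantom}}; render states with
#' \code{\link{evaluatePhantom}}. Ground-truth maps (fractional-ventilation
#' amplitude, defect mask, phase-lag map, end-expiration lung mask) are
#' available via \code{\link{phantomTruth}}.
#'
#' @slot spec the \linkS4class{PhantomSpec}
#' @slot fv_map true per-voxel fractional-ventilation amplitude (EE grid)
#' @slot lag_map true per-voxel filling phase lag (cycle fraction, EE grid)
#' @slot defect_mask true defect mask (EE grid)
#' @slot lung_level continuous lung level-set function on the EE grid (<1 inside)
#' @slot body_density static body/mediastinum density template
#' @slot geometry internal geometric parameters
#' @exportClass PhantomModel
setClass("PhantomModel",
  representation(spec = "PhantomSpec", fv_map = "array", lag_map = "array",
                 defect_mask = "array", lung_level = "array",
                 body_density = "array", geometry = "list"))

#' Static and dynamic ventilation maps with defect summaries
#'
#' @slot rvent_ei end-inspiration regional ventilation map (mL/mL)
#' @slot rvent_cycle array (nx, ny, nz, n_phases) of per-phase RVent maps
#' @slot fvl_cm flow-volume-loop cross-correlation map in [-1, 1]
#' @slot vttp ventilation time-to-peak map, % of cycle
#' @slot defect_rvent,defect_fvlcm binary defect maps
#' @slot parenchyma_mask analysis mask
#' @slot vdp_rvent,vdp_fvlcm ventilation defect percentages (%)
#' @slot mean_vttp mask-mean VTTP (%)
#' @exportClass VentilationMaps
setClass("VentilationMaps",
  representation(rvent_ei = "array", rvent_cycle = "array", fvl_cm = "array",
                 vttp = "array", defect_rvent = "array",
                 defect_fvlcm = "array", parenchyma_mask = "array",
                 vdp_rvent = "numeric", vdp_fvlcm = "numeric",
                 mean_vttp = "numeric"),
  validity = function(object) {
    msg <- character()
    for (v in c(object@vdp_rvent, object@vdp_fvlcm))
      if (!is.na(v) && (v < 0 || v > 100))
        msg <- c(msg, "VDP values must be in [0, 100]")
    if (any(object@defect_rvent & !object@parenchyma_mask) ||
        any(object@defect_fvlcm & !object@parenchyma_mask))
      msg <- c(msg, "defect maps must be nested inside the parenchyma mask")
    if (length(msg)) msg else TRUE
  })

#' Image-quality and VDP-comparison metrics
#'
#' @slot snr lung-ROI mean over background-ROI SD
#' @slot sharpness mean Sobel gradient magnitude in the mask
#' @slot vdp_static static 60-percent-of-mean VDP (%)
#' @slot bias,loa_low,loa_high,pearson_r Bland-Altman and correlation summary
#'   of a VDP comparison (NA when not computed)
#' @exportClass MetricReport
setClass("MetricReport",
  representation(snr = "numeric", sharpness = "numeric",
                 vdp_static = "numeric", bias = "numeric", loa_low = "numeric",
                 loa_high = "numeric", pearson_r = "numeric"),
  prototype(snr = NA_real_, sharpness = NA_real_, vdp_static = NA_real_,
            bias = NA_real_, loa_low = NA_real_, loa_high = NA_real_,
            pearson_r = NA_real_))
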