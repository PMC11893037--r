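## Pipeline configuration and the staged driver gluing all modules:
## simulate -> bin -> recon -> analyze -> metrics. Each stage writes its
## artifacts under the configured output directory and is idempotent given
## cached upstream outputs.

PIPELINE_SECTIONS <- c("seed", "output_dir", "trajectory", "phantom",
                       "binning", "recon", "registration", "preful")

sectionArgs <- function(cfg, section, constructor) {
  args <- cfg[[section]]
  if (is.null(args)) args <- list()
  known <- setdiff(names(formals(constructor)), "...")
  unknown <- setdiff(names(args), known)
  if (length(unknown))
    stop(sprintf("unknown key(s) in section '%s': %s", section,
                 paste(unknown, collapse = ", ")))
  args
}

#' Load and validate a pipeline configuration
#'
#' YAML with sections \code{trajectory}, \code{phantom}, \code{binning},
#' \code{recon}, \code{registration}, \code{preful} plus top-level
#' \code{seed} and \code{output_dir}. Unknown keys are rejected.
#'
#' @param path YAML file path, or a pre-parsed list
#' @return validated configuration list with instantiated config objects
#' @export
loadPipelineConfig <- function(path) {
  cfg <- if (is.character(path)) yaml::read_yaml(path) else path
  unknown <- setdiff(names(cfg), PIPELINE_SECTIONS)
  if (length(unknown))
    stop(sprintf("unknown configuration section(s): %s",
                 paste(unknown, collapse = ", ")))
  defects <- NULL
  ph_args <- sectionArgs(cfg, "phantom", phantomSpec)
  if (!is.null(ph_args$defects)) {
    ph_args$defects <- lapply(ph_args$defects, function(d)
      do.call(defectSpec, d))
  }
  list(
    seed = if (is.null(cfg$seed)) 1L else as.integer(cfg$seed),
    output_dir = if (is.null(cfg$output_dir)) "prefulr_out" else cfg$output_dir,
    trajectory = do.call(trajectoryConfig, sectionArgs(cfg, "trajectory",
                                                       trajectoryConfig)),
    phantom = do.call(phantomSpec, ph_args),
    binning = do.call(binningConfig, sectionArgs(cfg, "binning",
                                                 binningConfig)),
    recon = do.call(reconConfig, sectionArgs(cfg, "recon", reconConfig)),
    registration = do.call(registrationParams,
                           sectionArgs(cfg, "registration",
                                       registrationParams)),
    preful = do.call(prefulConfig, sectionArgs(cfg, "preful", prefulConfig)),
    raw_yaml = cfg)
}

pipelineLog <- function(state, stage, t0) {
  message(sprintf("[%s] stage %-8s done in %.1f s (config %s, seed %d)",
                  format(Sys.time(), "%H:%M:%S"), stage,
                  as.numeric(Sys.time()) - t0, state$hash, state$seed))
}

#' Run the simulation-to-metrics pipeline
#'
#' Executes the requested stages in order: \code{simulate} (phantom +
#' bellows + acquisition, raw container on disk), \code{bin} (respiratory
#' binning), \code{recon} (sensitivities, preconditioner, MoCoLoR),
#' \code{analyze} (PREFUL ventilation maps as NIfTI), \code{metrics}
#' (SNR/sharpness/VDP JSON report). Stages reuse cached upstream artifacts
#' when present; requesting a stage whose upstream artifact is missing is
#' an error naming the dependency.
#'
#' @param config a list from \code{\link{loadPipelineConfig}}
#' @param stages character subset of
#'   \code{c("simulate", "bin", "recon", "analyze", "metrics")} or
#'   \code{"all"}
#' @param verbose print per-stage progress
#' @return invisible list of artifact paths and in-memory results
#' @export
runPipeline <- function(config, stages = "all", verbose = TRUE) {
  all_stages <- c("simulate", "bin", "recon", "analyze", "metrics")
  if (identical(stages, "all")) stages <- all_stages
  stopifnot(all(stages %in% all_stages))
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    raw = file.path(config$output_dir, "raw_data.rds"),
    bins = file.path(config$output_dir, "bins.json"),
    bins_rds = file.path(config$output_dir, "bins.rds"),
    series = file.path(config$output_dir, "recon_series.nii.gz"),
    series_rds = file.path(config$output_dir, "recon_series.rds"),
    maps = file.path(config$output_dir, "ventilation_maps.nii.gz"),
    maps_rds = file.path(config$output_dir, "ventilation_maps.rds"),
    metrics = file.path(config$output_dir, "metrics.json"))
  state <- list(
    hash = fnvHash(yaml::as.yaml(config$raw_yaml)),
    seed = config$seed)
  results <- list()

  if ("simulate" %in% stages && !file.exists(paths$raw)) {
    t0 <- as.numeric(Sys.time())
    set.seed(config$seed)
    spec <- config$phantom
    model <- buildPhantom(spec)
    traj <- generateFloret(config$trajectory)
    bell <- simulateBellows(spec, config$trajectory@n_excitations,
                            outlier_rate = 0.002)
    sens <- makeCoilMaps(spec@n_coils, spec@grid_size)
    kdata <- simulateAcquisition(model, traj, bell, sens)
    writeRawContainer(kdata, paths$raw, seed = config$seed)
    truth <- phantomTruth(model)
    writeImageNifti(truth$fv, file.path(config$output_dir, "truth_fv.nii.gz"),
                    truth$geometry$vox_mm)
    writeImageNifti(truth$lag * 1,
                    file.path(config$output_dir, "truth_lag.nii.gz"),
                    truth$geometry$vox_mm)
    writeImageNifti(truth$defect_mask * 1,
                    file.path(config$output_dir, "truth_defect.nii.gz"),
                    truth$geometry$vox_mm)
    saveRDS(list(model = model, sens = sens),
            file.path(config$output_dir, "phantom_model.rds"))
    if (verbose) pipelineLog(state, "simulate", t0)
  }

  if ("bin" %in% stages) {
    if (!file.exists(paths$raw))
      stop("stage 'bin' requires the raw container from stage 'simulate'")
    if (!file.exists(paths$bins_rds)) {
      t0 <- as.numeric(Sys.time())
      kdata <- readRawContainer(paths$raw)
      bcfg <- config$binning
      win <- if (bcfg@smoothing_window > 0) bcfg@smoothing_window else
        defaultSmoothingWindow(config$phantom@breathing_period_s,
                               kdata@bellows@dt_s)
      sm <- preprocessBellows(kdata@bellows, win)
      excl <- excludeOutliers(sm, bcfg@exclusion_k)
      phases <- instantaneousPhase(sm)
      bins <- allocateBins(phases, excl, bcfg)
      kbins <- binKspace(initialize(kdata, bellows = sm), bins)
      saveRDS(kbins, paths$bins_rds)
      jsonlite::write_json(
        list(config_hash = state$hash, seed = state$seed,
             bins = lapply(bins@bin_indices, identity),
             excluded = bins@excluded),
        paths$bins, auto_unbox = TRUE)
      if (verbose) pipelineLog(state, "bin", t0)
    }
  }

  if ("recon" %in% stages) {
    if (!file.exists(paths$bins_rds))
      stop("stage 'recon' requires bin assignments from stage 'bin'")
    if (!file.exists(paths$series_rds)) {
      t0 <- as.numeric(Sys.time())
      kbins <- readRDS(paths$bins_rds)
      n <- config$phantom@grid_size
      sens_true <- readRDS(file.path(config$output_dir,
                                     "phantom_model.rds"))$sens
      sens <- if (dim(sens_true@maps)[4] > 1)
        estimateSensitivities(kbins, grid = rep(n, 3)) else sens_true
      pre <- computePreconditioner(kbins, sens)
      rec <- mocolor(kbins, sens, pre, config$recon, grid = rep(n, 3))
      saveRDS(rec, paths$series_rds)
      writeImageNifti(rec$series, paths$series)
      if (verbose) pipelineLog(state, "recon", t0)
    }
  }

  if ("analyze" %in% stages) {
    if (!file.exists(paths$series_rds))
      stop("stage 'analyze' requires the reconstruction from stage 'recon'")
    if (!file.exists(paths$maps_rds)) {
      t0 <- as.numeric(Sys.time())
      rec <- readRDS(paths$series_rds)
      maps <- prefulAnalysis(rec$series, config$preful, config$registration)
      saveRDS(maps, paths$maps_rds)
      writeImageNifti(maps@rvent_ei, paths$maps,
                      rec$series@voxel_mm)
      if (verbose) pipelineLog(state, "analyze", t0)
    }
  }

  if ("metrics" %in% stages) {
    if (!file.exists(paths$maps_rds))
      stop("stage 'metrics' requires ventilation maps from stage 'analyze'")
    t0 <- as.numeric(Sys.time())
    rec <- readRDS(paths$series_rds)
    maps <- readRDS(paths$maps_rds)
    vols <- Mod(rec$series@volumes)
    rois <- phantomSnrRois(maps@parenchyma_mask)
    snr <- roiSnr(vols[, , , 1], rois$lung_roi, rois$background_roi)
    sharp <- sobelSharpness(maps@rvent_ei * maps@parenchyma_mask,
                            maps@parenchyma_mask)
    report <- list(config_hash = state$hash, seed = state$seed,
                   snr = snr, sharpness = sharp,
                   vdp_rvent = maps@vdp_rvent, vdp_fvlcm = maps@vdp_fvlcm,
                   mean_vttp = maps@mean_vttp)
    jsonlite::write_json(report, paths$metrics, auto_unbox = TRUE,
                         digits = NA)
    results$metrics <- report
    if (verbose) pipelineLog(state, "metrics", t0)
  }
  invisible(c(paths, results))
}
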