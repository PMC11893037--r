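# Shared fixtures, built in code at test time.

# small matched trajectory/phantom pair on an n^3 grid
smallTrajectory <- function(n = 24, n_exc = 3000, J = 48, fov = 320,
                            hubs = 3) {
  n_exc <- hubs * ceiling(n_exc / hubs)  # even hub partition
  cfg <- trajectoryConfig(fov_mm = fov, res_mm = fov / n, n_hubs = hubs,
                          samples_per_readout = J, n_excitations = n_exc)
  list(config = cfg, traj = generateFloret(cfg))
}

# flatten (excitations, samples, 3) coords to an (M, 3) matrix,
# sample index fastest (the layout used by the recon operators)
coordsMatrix <- function(traj) {
  matrix(aperm(traj@coords, c(2, 1, 3)), ncol = 3)
}

# flatten (coils, excitations, samples) data of coil c to a vector in the
# same ordering
samplesVector <- function(kdata, coil = 1) {
  as.vector(t(kdata@samples[coil, , ]))
}

# noise-free single-coil static phantom acquisition at small n
staticAcquisition <- function(n = 24, n_exc = 3000, seed = 2, J = 48) {
  st <- smallTrajectory(n = n, n_exc = n_exc, J = J)
  spec <- phantomSpec(grid_size = n, tidal_amplitude = 0, n_coils = 1,
                      noise_sd = 0, seed = seed)
  model <- buildPhantom(spec)
  bell <- simulateBellows(spec, dim(st$traj@coords)[1], amp_jitter = 0,
                          period_jitter = 0, noise_sd = 0)
  sens <- makeCoilMaps(1, n)
  kd <- simulateAcquisition(model, st$traj, bell, sens, noise_sd = 0)
  list(traj = st$traj, config = st$config, spec = spec, model = model,
       bellows = bell, sens = sens, kdata = kd,
       plan = nufftPlan(rep(n, 3), 320))
}

# smooth random test volume
smoothVolume <- function(n, sigma = 2, seed = 1) {
  set.seed(seed)
  prefulr:::gaussSmooth3(array(stats::rnorm(n^3), rep(n, 3)), sigma)
}

# synthetic 16-phase sinusoidal RVent cycle over a centered ball mask
sinusoidalRventCycle <- function(n = 32, n_phases = 16, amplitude = 0.25,
                                 lag_frac = 0) {
  mask <- array(FALSE, rep(n, 3))
  ix <- seq_len(n) - (n + 1) / 2
  R2 <- outer(outer(ix^2, ix^2, "+"), ix^2, "+")
  mask[R2 < (0.4 * n)^2] <- TRUE
  t0 <- 0:(n_phases - 1)
  rv <- array(0, c(rep(n, 3), n_phases))
  for (t in seq_len(n_phases)) {
    rv[, , , t][mask] <- amplitude *
      sin(pi * ((t0[t] / n_phases - lag_frac) %% 1))
  }
  list(rvent_cycle = rv, mask = mask)
}
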