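makeSeries <- function(vols, phases = NULL) {
  B <- dim(vols)[4]
  if (is.null(phases)) phases <- 2 * pi * (0:(B - 1)) / B - pi
  new("ImageSeries", volumes = vols, bin_phases = phases, voxel_mm = 1)
}

test_that("cycle sorting starts at end-expiration and is involutive", {
  n <- 12
  B <- 6
  # lung signal maximal at phase 3 (EE), minimal at phase 6 (EI)
  base <- array(0.5, rep(n, 3))
  base[4:9, 4:9, 4:9] <- 0.2
  vols <- array(0, c(rep(n, 3), B))
  lung_scale <- c(0.9, 0.95, 1.0, 0.9, 0.8, 0.75)
  for (b in 1:B) {
    v <- base
    v[4:9, 4:9, 4:9] <- 0.2 * lung_scale[b]
    vols[, , , b] <- v
  }
  mask <- array(FALSE, rep(n, 3))
  mask[4:9, 4:9, 4:9] <- TRUE
  s <- makeSeries(vols, phases = 2 * pi * (0:(B - 1)) / B - pi)
  out <- sortVentilationCycle(s, mask)
  ord <- attr(out, "ordering")
  expect_equal(ord[1], 3)  # EE first
  sig <- vapply(1:B, function(b) mean(out@volumes[, , , b][mask]),
                numeric(1))
  expect_equal(which.max(sig), 1)
  # already-ordered input maps to the identity
  out2 <- sortVentilationCycle(out, mask)
  expect_equal(attr(out2, "ordering"), 1:B)
  # reversed input comes back in cycle order
  rev_s <- makeSeries(out@volumes[, , , c(1, B:2), drop = FALSE],
                      phases = out@bin_phases[c(1, B:2)])
  out3 <- sortVentilationCycle(rev_s, mask)
  sig3 <- vapply(1:B, function(b) mean(out3@volumes[, , , b][mask]),
                 numeric(1))
  expect_equal(sig3, sig, tolerance = 1e-12)
  s@bin_phases <- rep(NA_real_, B)
  expect_error(sortVentilationCycle(s, mask), "labels")
})

test_that("bias-field correction recovers a smooth multiplicative field", {
  n <- 24
  set.seed(14)
  flat <- array(1, rep(n, 3)) + array(rnorm(n^3, sd = 0.02), rep(n, 3))
  co <- (seq_len(n) - (n + 1) / 2) / n
  grad <- exp(0.8 * array(rep(co, times = n * n), rep(n, 3)) +
              0.5 * array(rep(co, each = n * n), rep(n, 3)))
  biased <- flat * grad
  corr <- biasFieldCorrect(biased)
  inhomo <- function(v) sd(v) / mean(v)
  expect_lt(inhomo(corr), 0.5 * inhomo(biased))
  # output preserves the mean level
  expect_equal(mean(corr), mean(biased), tolerance = 0.02)
  # near-idempotent
  corr2 <- biasFieldCorrect(corr)
  expect_lt(sqrt(mean((corr2 - corr)^2)) / mean(corr), 0.01)
  # bias-free input passes through
  passthrough <- biasFieldCorrect(flat)
  expect_lt(sqrt(mean((passthrough - flat)^2)) / mean(flat), 0.02)
  neg <- flat
  neg[1:5] <- -0.1
  expect_warning(biasFieldCorrect(neg), "clamped")
})

test_that("Gaussian phase interpolation matches its analytic transfer function", {
  B <- 24
  n_out <- 16
  cfg <- prefulConfig(n_phases = n_out, gauss_sigma = 0.3)
  # one-voxel series with a sinusoidal cycle
  vols <- array(0, c(2, 2, 2, B))
  t_in <- 0:(B - 1)
  for (b in 1:B) vols[, , , b] <- sin(2 * pi * t_in[b] / B)
  s <- makeSeries(vols)
  out <- interpolateToPhases(s, cfg)
  expect_equal(nPhases(out), n_out)
  sig <- out@volumes[1, 1, 1, ]
  # fundamental amplitude after Gaussian kernel in phase:
  # attenuation = exp(-2 pi^2 sigma^2 / B^2) for a discrete kernel; compute
  # the exact discrete attenuation as an independent oracle
  d <- ((0:(B - 1)) + B / 2) %% B - B / 2
  w <- exp(-0.5 * (d / 0.3)^2)
  w <- w / sum(w)
  atten <- Mod(sum(w * exp(2i * pi * d / B)))
  fit_amp <- 2 * Mod(fft(sig)[2]) / n_out
  expect_equal(fit_amp, atten, tolerance = 0.02)
  # constant series stays constant; sigma -> 0 with n_out = B is identity
  cvols <- array(3, c(2, 2, 2, B))
  cout <- interpolateToPhases(makeSeries(cvols), cfg)
  expect_true(all(abs(cout@volumes - 3) < 1e-12))
  id <- interpolateToPhases(s, prefulConfig(n_phases = B, gauss_sigma = 1e-4))
  expect_equal(id@volumes, vols, tolerance = 1e-10)
  expect_error(interpolateToPhases(s, prefulConfig(gauss_sigma = 0)),
               "gauss_sigma")
})

test_that("temporal filter keeps low harmonics and removes high ones", {
  B <- 16
  t0 <- 0:(B - 1)
  fundamental <- sin(2 * pi * t0 / B)
  high <- 0.5 * sin(2 * pi * 5 * t0 / B)
  vols <- array(0, c(4, 4, 4, B))
  for (b in 1:B) vols[, , , b] <- 1 + fundamental[b] + high[b]
  cfg <- prefulConfig(breathing_period_s = 4)  # cutoff harmonic 2.8
  out <- temporalFilter(makeSeries(vols), cfg, spatial = FALSE)
  sig <- out@volumes[2, 2, 2, ]
  sp <- Mod(fft(sig)) / B
  expect_equal(2 * sp[2], 1, tolerance = 0.01)     # fundamental kept
  expect_lt(2 * sp[6], 0.05 * 0.5)                 # harmonic 5 removed
  expect_warning(
    temporalFilter(makeSeries(vols), prefulConfig(breathing_period_s = 0.5),
                   spatial = FALSE), "fundamental")
})

test_that("edge-preserving filter denoises without blurring edges", {
  n <- 32
  set.seed(15)
  step <- array(0, rep(n, 3))
  step[(n / 2 + 1):n, , ] <- 1
  noisy <- step + array(rnorm(n^3, sd = 0.08), rep(n, 3))
  filt <- array(prefulr:::cpp_bilateral3(as.double(noisy),
                                         as.integer(rep(n, 3)), 2L, 1.0,
                                         2 * 0.08), rep(n, 3))
  flat <- filt[5:12, 5:28, 5:28]
  expect_lt(sd(flat), 0.5 * 0.08)
  # 10-90% edge width along x on the mean profile stays below ~2 voxels
  prof <- apply(filt[, 5:28, 5:28], 1, mean)
  x10 <- approx(prof, seq_len(n), xout = 0.1)$y
  x90 <- approx(prof, seq_len(n), xout = 0.9)$y
  prof0 <- apply(noisy[, 5:28, 5:28], 1, mean)
  w0 <- diff(approx(prof0, seq_len(n), xout = c(0.1, 0.9))$y)
  expect_lt(abs(x90 - x10) - abs(w0), 1)
})

test_that("lung segmentation and vessel recognition on the phantom", {
  spec <- phantomSpec(grid_size = 48, tidal_amplitude = 0, noise_sd = 0,
                      seed = 16, include_vessels = TRUE)
  model <- buildPhantom(spec)
  vol <- evaluatePhantom(model, 0)
  mask <- segmentLungSimple(vol)
  truth <- phantomTruth(model)
  lung <- truth$lung_mask_ee
  dice <- 2 * sum(mask & lung) / (sum(mask) + sum(lung))
  expect_gt(dice, 0.9)
  # trachea cylinder is not part of the mask
  n <- 48
  cx <- 24:25
  trachea <- array(FALSE, rep(n, 3))
  trachea[cx, cx, 8:18] <- TRUE
  expect_lt(sum(mask & trachea) / sum(trachea), 0.1)
  expect_error(segmentLungSimple(array(1, rep(24, 3))), "uniform")

  vs <- vesselMask(vol, mask)
  vm <- truth$vessel_mask
  cavity <- vs$parenchyma_mask | vs$vessel_mask
  expect_gt(sum(vs$vessel_mask & vm) / sum(vm & cavity), 0.8)
  expect_true(!any(vs$vessel_mask & vs$parenchyma_mask))
  # vessel-free phantom: near-empty vessel mask
  spec2 <- phantomSpec(grid_size = 48, tidal_amplitude = 0, noise_sd = 0,
                       seed = 16, include_vessels = FALSE)
  vol2 <- evaluatePhantom(buildPhantom(spec2), 0)
  mask2 <- segmentLungSimple(vol2)
  vs2 <- vesselMask(vol2, mask2)
  expect_lt(sum(vs2$vessel_mask) / sum(mask2), 0.01)
})

test_that("RVent formula and parameter maps behave as specified", {
  n <- 10
  B <- 8
  vols <- array(1.2, c(rep(n, 3), B))
  mask <- array(TRUE, rep(n, 3))
  s <- makeSeries(vols)
  rv <- computeRvent(s, mask)
  expect_true(all(rv$rvent_cycle == 0))
  # S_EE = 1.2, S_EI = 1.0 -> RVent_EI = 0.2
  vols2 <- vols
  vols2[, , , 5] <- 1.0
  rv2 <- computeRvent(makeSeries(vols2), mask)
  expect_equal(rv2$ee_phase %in% c(1:4, 6:8), TRUE)
  expect_equal(rv2$ei_phase, 5)
  expect_equal(unname(rv2$rvent_ei[1, 1, 1]), 0.2, tolerance = 1e-12)
})

test_that("FVL-CM is 1 on the reference and penalizes half-cycle shifts", {
  fx <- sinusoidalRventCycle(n = 16, amplitude = 0.2)
  cfg <- prefulConfig()
  rv_ei <- fx$rvent_cycle[, , , 9]
  cm <- flowVolumeCm(fx$rvent_cycle, rv_ei, fx$mask, cfg)
  expect_true(all(abs(cm[fx$mask] - 1) < 1e-6))
  # half-cycle shifted voxels anticorrelate
  lagged <- sinusoidalRventCycle(n = 16, amplitude = 0.2, lag_frac = 0.5)
  mixed <- fx$rvent_cycle
  w <- which(fx$mask, arr.ind = TRUE)
  half <- w[w[, 1] <= 8, , drop = FALSE]
  for (t in 1:16) {
    sl <- mixed[, , , t]
    sl[half] <- lagged$rvent_cycle[, , , t][half]
    mixed[, , , t] <- sl
  }
  ei2 <- mixed[, , , 9]
  cm2 <- flowVolumeCm(mixed, ei2, fx$mask, cfg)
  sel <- array(FALSE, rep(16, 3))
  sel[half] <- TRUE
  expect_true(all(cm2[sel & fx$mask] < 0, na.rm = TRUE))
  expect_error(flowVolumeCm(fx$rvent_cycle, rv_ei * NA, fx$mask, cfg),
               "reference")
})

test_that("phase-lagged voxels get low CM and delayed VTTP", {
  fx <- sinusoidalRventCycle(n = 16, amplitude = 0.2)
  lag <- sinusoidalRventCycle(n = 16, amplitude = 0.2, lag_frac = 0.25)
  mixed <- fx$rvent_cycle
  w <- which(fx$mask, arr.ind = TRUE)
  lag_sel <- w[w[, 3] <= 8, , drop = FALSE]
  for (t in 1:16) {
    sl <- mixed[, , , t]
    sl[lag_sel] <- lag$rvent_cycle[, , , t][lag_sel]
    mixed[, , , t] <- sl
  }
  cm <- flowVolumeCm(mixed, mixed[, , , 9], fx$mask, prefulConfig())
  sel <- array(FALSE, rep(16, 3))
  sel[lag_sel] <- TRUE
  expect_true(all(cm[sel & fx$mask] < 0.9, na.rm = TRUE))
  expect_true(all(cm[fx$mask & !sel] > 0.95, na.rm = TRUE))
  vt <- computeVttp(mixed, fx$mask)
  # normal voxels peak mid-cycle; a 0.25-cycle lag peaks at 75% +- one step
  expect_equal(mean(vt$vttp[fx$mask & !sel], na.rm = TRUE), 50,
               tolerance = 0.07)
  expect_equal(mean(vt$vttp[fx$mask & sel], na.rm = TRUE), 75,
               tolerance = 0.09)
  # constant cycles are flagged undefined
  const <- mixed
  const[, , , ] <- 1
  vtc <- computeVttp(const, fx$mask)
  expect_true(all(is.na(vtc$vttp[fx$mask])))
})

test_that("defect maps apply the printed thresholds", {
  n <- 20
  mask <- array(TRUE, rep(n, 3))
  cfg <- prefulConfig()
  uniform <- array(0.3, rep(n, 3))
  cm1 <- array(1, rep(n, 3))
  m <- defectMaps(uniform, cm1, mask, cfg)
  expect_equal(m@vdp_rvent, 0)
  expect_equal(m@vdp_fvlcm, 0)
  # exactly 20% of voxels at 0.1 x P90, rest at P90
  rv <- array(0.5, rep(n, 3))
  idx <- seq_len(round(0.2 * n^3))
  rv[idx] <- 0.05
  m2 <- defectMaps(rv, cm1, mask, cfg)
  expect_equal(m2@vdp_rvent, 100 * length(idx) / n^3, tolerance = 1e-9)
  expect_error(defectMaps(rv, cm1, array(FALSE, rep(n, 3)), cfg), "empty")
})

test_that("pipeline maps are invariant to global intensity scaling", {
  set.seed(17)
  n <- 16
  B <- 8
  vols <- array(0, c(rep(n, 3), B))
  base <- 0.5 + smoothVolume(n, 2, seed = 18) * 0.05
  for (b in 1:B) vols[, , , b] <- base / (1 + 0.2 * sin(pi * (b - 1) / B)^2)
  mask <- array(TRUE, rep(n, 3))
  s <- makeSeries(vols)
  rv1 <- computeRvent(s, mask)
  rv2 <- computeRvent(makeSeries(7 * vols), mask)
  expect_equal(rv1$rvent_cycle, rv2$rvent_cycle, tolerance = 1e-12)
  cfg <- prefulConfig()
  cm1 <- flowVolumeCm(rv1$rvent_cycle, rv1$rvent_ei, mask, cfg)
  cm2 <- flowVolumeCm(rv2$rvent_cycle, rv2$rvent_ei, mask, cfg)
  expect_equal(cm1, cm2, tolerance = 1e-10)
  m1 <- defectMaps(rv1$rvent_ei, cm1, mask, cfg)
  m2 <- defectMaps(rv2$rvent_ei, cm2, mask, cfg)
  expect_equal(m1@vdp_rvent, m2@vdp_rvent)
  expect_equal(m1@vdp_fvlcm, m2@vdp_fvlcm)
})
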