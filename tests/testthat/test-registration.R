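test_that("apply_field: identity, integer shift and round trip", {
  n <- 16
  vol <- smoothVolume(n, 1, seed = 8)
  zf <- prefulr:::zeroField(rep(n, 3))
  expect_equal(applyField(vol, zf), vol)

  # integer-shift field on a delta image produces the shifted delta
  delta <- array(0, rep(n, 3))
  delta[8, 8, 8] <- 1
  f <- zf
  f@displacement[, , , 1] <- 2   # sample at x + 2: image moves -x
  out <- applyField(delta, f)
  expect_equal(out[6, 8, 8], 1)
  expect_equal(sum(out), 1)

  # smooth small field round trip via the inverse
  set.seed(9)
  sm <- zf
  for (ax in 1:3)
    sm@displacement[, , , ax] <-
      prefulr:::gaussSmooth3(array(rnorm(n^3, sd = 0.6), rep(n, 3)), 3)
  inv <- invertField(sm)
  rt <- applyField(applyField(vol, sm), inv)
  expect_lt(sqrt(mean((rt - vol)^2)) / sd(vol), 0.05)

  expect_error(applyField(vol[1:8, , ], zf), "shape")
})

test_that("pair registration recovers a known translation", {
  n <- 32
  x <- smoothVolume(n, 2, seed = 10)
  moving <- prefulr:::shift3(x, c(3, 0, 0))
  f <- registerPair(moving, x, registrationParams())
  interior <- array(FALSE, rep(n, 3))
  interior[8:24, 8:24, 8:24] <- TRUE
  expect_lt(abs(mean(f@displacement[, , , 1][interior]) - 3), 0.5)
  expect_lt(abs(mean(f@displacement[, , , 2][interior])), 0.3)
  # metric must not worsen
  expect_lte(mean((x - applyField(moving, f))^2), mean((x - moving)^2))
  # moving == fixed: near-zero field
  f0 <- registerPair(x, x, registrationParams())
  expect_lt(max(abs(f0@displacement)), 0.1)
  expect_error(registerPair(array(1, rep(n, 3)), x), "constant")
})

test_that("registration is deterministic", {
  n <- 24
  x <- smoothVolume(n, 2, seed = 11)
  m <- prefulr:::shift3(x, c(0, 2, 0))
  f1 <- registerPair(m, x)
  f2 <- registerPair(m, x)
  expect_identical(f1@displacement, f2@displacement)
})

test_that("phantom diaphragm excursion is recovered within 20%", {
  spec <- phantomSpec(grid_size = 48, tidal_amplitude = 0.25, noise_sd = 0,
                      seed = 3)
  model <- buildPhantom(spec)
  ee <- evaluatePhantom(model, 0)
  ei <- evaluatePhantom(model, 1)
  f <- registerPair(ei, ee, registrationParams())
  g <- phantomTruth(model)$geometry
  cx <- round(g$center + 0.19 * 48)
  cy <- round(g$center)
  # displacement at the diaphragm dome (lung base) vs prescribed excursion
  zq <- round(g$z_base) - 1
  rec <- mean(f@displacement[cx + (-1:1), cy + (-1:1), zq, 3])
  prescribed <- spec@tidal_amplitude * (zq - g$z_apex)
  expect_lt(abs(rec - prescribed) / prescribed, 0.2)
})

test_that("stepwise series registration composes and reduces motion", {
  n <- 24
  base <- smoothVolume(n, 2, seed = 12)
  B <- 4
  vols <- array(0, c(rep(n, 3), B))
  shifts <- c(0, 1, 2, 3)
  for (b in 1:B) vols[, , , b] <- prefulr:::shift3(base, c(0, 0, shifts[b]))
  series <- new("ImageSeries", volumes = vols, bin_phases = 1:B,
                voxel_mm = 1)
  out <- stepwiseRegisterSeries(series, ref = 1)
  interior <- array(FALSE, rep(n, 3))
  interior[6:18, 6:18, 6:18] <- TRUE
  for (b in 2:B) {
    dz <- mean(out$fields[[b]]@displacement[, , , 3][interior])
    expect_lt(abs(dz - shifts[b]), 0.6)
  }
  # identical volumes give near-zero fields
  same <- new("ImageSeries", volumes = array(rep(base, B), c(rep(n, 3), B)),
              bin_phases = 1:B, voxel_mm = 1)
  out2 <- stepwiseRegisterSeries(same, ref = 2)
  for (b in 1:B) expect_lt(max(abs(out2$fields[[b]]@displacement)), 0.15)
  # registered series has lower temporal variance than the input
  v_pre <- apply(vols, 1:3, var)
  v_post <- apply(out$series@volumes, 1:3, var)
  expect_lt(mean(v_post[interior]), mean(v_pre[interior]))
  expect_error(stepwiseRegisterSeries(series, ref = 9), "out of range")
})

test_that("two-phase stepwise registration equals direct pair registration", {
  n <- 24
  base <- smoothVolume(n, 2, seed = 13)
  vols <- array(0, c(rep(n, 3), 2))
  vols[, , , 1] <- base
  vols[, , , 2] <- prefulr:::shift3(base, c(2, 0, 0))
  series <- new("ImageSeries", volumes = vols, bin_phases = 1:2, voxel_mm = 1)
  out <- stepwiseRegisterSeries(series, ref = 1)
  direct <- registerPair(vols[, , , 2], vols[, , , 1])
  expect_equal(out$fields[[2]]@displacement, direct@displacement,
               tolerance = 1e-10)
})
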