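test_that("forward NUFFT agrees with the direct DFT oracle", {
  set.seed(1)
  n <- 12
  fov <- 320
  plan <- nufftPlan(rep(n, 3), fov)
  kmax <- n / (2 * fov)
  coords <- matrix(runif(900, -kmax, kmax), ncol = 3)
  x <- array(complex(real = rnorm(n^3), imaginary = rnorm(n^3)), rep(n, 3))
  v <- nufftForward(plan, x, coords)
  oracle <- prefulr:::nufftDirect(x, coords, fov, scale = plan$scale)
  expect_lt(sqrt(sum(Mod(v - oracle)^2) / sum(Mod(oracle)^2)), 0.02)
})

test_that("NUFFT adjoint test holds to machine precision at 24^3", {
  set.seed(2)
  n <- 24
  plan <- nufftPlan(rep(n, 3), 320)
  kmax <- n / (2 * 320)
  coords <- matrix(runif(3 * 2000, -kmax, kmax), ncol = 3)
  x <- array(complex(real = rnorm(n^3), imaginary = rnorm(n^3)), rep(n, 3))
  y <- complex(real = rnorm(2000), imaginary = rnorm(2000))
  lhs <- sum(Conj(y) * nufftForward(plan, x, coords))
  rhs <- sum(Conj(nufftAdjoint(plan, y, coords)) * x)
  rel <- Mod(lhs - rhs) / (sqrt(sum(Mod(x)^2)) * sqrt(sum(Mod(y)^2)))
  expect_lt(rel, 1e-6)
})

test_that("nuclear prox equals the full-SVD soft-threshold oracle", {
  set.seed(3)
  for (rep in 1:3) {
    X <- matrix(rnorm(300), nrow = 6)
    tau <- c(0.5, 2, 10)[rep]
    sv <- svd(X)
    oracle <- sv$u %*% diag(pmax(sv$d - tau, 0)) %*% t(sv$v)
    expect_lt(max(abs(nuclearProx(X, tau) - oracle)), 1e-10)
  }
  X <- matrix(rnorm(300), nrow = 6)
  expect_identical(nuclearProx(X, 0), X)
  expect_true(all(nuclearProx(X, 2 * max(svd(X)$d)) == 0))
  expect_error(nuclearProx(matrix(c(NA, 1, 2, 3), 2), 1), "non-finite")
})

test_that("preconditioning weights are flat on Cartesian and ramp on radial", {
  n <- 16
  fov <- 320
  g <- (-(n / 2):(n / 2 - 1)) / fov
  cart <- as.matrix(expand.grid(g, g, g))
  w <- densityWeights(array(cart, c(nrow(cart), 1, 3)), fov_mm = fov,
                      grid = rep(n, 3))
  expect_lt(sd(w) / mean(w), 0.05)
  expect_true(all(w >= 0) && all(is.finite(w)))

  # center-out radial toy: weights increase with |k|
  set.seed(4)
  dirs <- matrix(rnorm(600), ncol = 3)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  radial <- array(0, c(200, 24, 3))
  r <- seq(0, n / (2 * fov), length.out = 24)
  for (j in 1:24) radial[, j, ] <- dirs * r[j]
  wr <- densityWeights(radial, fov_mm = fov, grid = rep(n, 3))
  kr <- rep(r, each = 200)
  expect_gt(cor(as.vector(t(wr)), rep(r, times = 200), method = "spearman")
            , 0.9)
  expect_error(densityWeights(array(0, c(10, 4, 3)), fov_mm = fov,
                              grid = rep(n, 3)), "degenerate")
})

test_that("CG-SENSE: linearity, zero data, monotone objective", {
  set.seed(5)
  n <- 12
  fov <- 320
  st <- smallTrajectory(n = n, n_exc = 500, J = 24)
  coords <- coordsMatrix(st$traj)
  plan <- nufftPlan(rep(n, 3), fov)
  sens <- makeCoilMaps(1, n)
  w <- as.vector(t(densityWeights(st$traj, grid = rep(n, 3))))
  x0 <- smoothVolume(n, 1.5) + 0i
  y <- nufftForward(plan, x0, coords)
  cg <- cgsenseRecon(matrix(y, ncol = 1), coords, sens, w, plan, 12,
                     track_objective = TRUE)
  expect_true(all(diff(cg$objective) <= 1e-8 * cg$objective[1]))
  cg2 <- cgsenseRecon(matrix(3 * y, ncol = 1), coords, sens, w, plan, 12)
  rel <- sqrt(sum(Mod(cg2$image - 3 * cg$image)^2) /
                sum(Mod(3 * cg$image)^2))
  expect_lt(rel, 1e-8)
  z <- cgsenseRecon(matrix(y * 0, ncol = 1), coords, sens, w, plan, 5)
  expect_true(all(z$image == 0))
})

test_that("coil sensitivity estimation recovers simulated maps", {
  set.seed(6)
  n <- 16
  st <- smallTrajectory(n = n, n_exc = 1500, J = 24)
  spec <- phantomSpec(grid_size = n, tidal_amplitude = 0, n_coils = 3,
                      noise_sd = 0, seed = 6)
  model <- buildPhantom(spec)
  bell <- simulateBellows(spec, 1500, amp_jitter = 0, period_jitter = 0,
                          noise_sd = 0)
  sens <- makeCoilMaps(3, n)
  kd <- simulateAcquisition(model, st$traj, bell, sens, noise_sd = 0)
  set.seed(7)
  phases <- runif(1500, -pi, pi)
  bs <- allocateBins(phases, integer(0), binningConfig(n_bins = 2))
  kb <- binKspace(kd, bs)
  est <- estimateSensitivities(kb, grid = rep(n, 3))
  sos <- sqrt(apply(Mod(sens@maps)^2, 1:3, sum))
  body <- evaluatePhantom(model, 0) > 0.3
  for (c0 in 1:3) {
    truth_n <- Mod(sens@maps[, , , c0]) / sos
    err <- abs(Mod(est@maps[, , , c0]) - truth_n) / pmax(truth_n, 1e-3)
    expect_lt(median(err[body]), 0.10)
  }
  # coil permutation permutes the output
  kb2 <- kb
  for (b in seq_along(kb2@samples)) kb2@samples[[b]] <-
    kb2@samples[[b]][c(2, 1, 3), , , drop = FALSE]
  est2 <- estimateSensitivities(kb2, grid = rep(n, 3))
  expect_equal(est2@maps[, , , 1], est@maps[, , , 2], tolerance = 1e-10)
  # single coil falls back to a uniform map
  kb1 <- kb
  for (b in seq_along(kb1@samples)) kb1@samples[[b]] <-
    kb1@samples[[b]][1, , , drop = FALSE]
  expect_true(all(estimateSensitivities(kb1, grid = rep(n, 3))@maps == 1))
})
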