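test_that("moving-average smoothing preserves length and reduces variance", {
  tr <- new("BellowsTrace", values = rnorm(5000), dt_s = 0.004,
            cycle_fraction = numeric(0), outlier_log = integer(0))
  expect_identical(preprocessBellows(tr, 1)@values, tr@values)
  const <- initialize(tr, values = rep(3, 5000))
  expect_equal(preprocessBellows(const, 37)@values, rep(3, 5000))
  sm <- preprocessBellows(tr, 51)
  expect_length(sm@values, 5000)
  expect_lt(var(sm@values), var(tr@values))
  expect_error(preprocessBellows(tr, 5000), "shorter")
})

test_that("outlier exclusion follows the k-SD rule", {
  set.seed(4)
  v <- rnorm(1000)
  v[500] <- mean(v) + 10 * sd(v)
  tr <- new("BellowsTrace", values = v, dt_s = 0.004,
            cycle_fraction = numeric(0), outlier_log = integer(0))
  expect_true(500 %in% excludeOutliers(tr, 2))

  # pure sinusoid: peak deviation is amplitude < 2 SD = 2 amplitude/sqrt(2)
  s <- sin(2 * pi * (1:4000) / 200)
  expect_length(excludeOutliers(initialize(tr, values = s), 2), 0)

  # gaussian trace: expect about 2 * pnorm(-2) = 4.55% excluded
  set.seed(10)
  g <- initialize(tr, values = rnorm(100000))
  frac <- length(excludeOutliers(g, 2)) / 100000
  expect_equal(frac, 2 * pnorm(-2), tolerance = 0.05)

  expect_warning(out <- excludeOutliers(initialize(tr, values = rep(1, 100))),
                 "zero-variance")
  expect_length(out, 0)
})

test_that("Hilbert instantaneous phase is linear and uniform for a sinusoid", {
  n <- 8192
  period <- 256
  tr <- new("BellowsTrace", values = sin(2 * pi * ((1:n) + 0.35) / period),
            dt_s = 0.004, cycle_fraction = numeric(0),
            outlier_log = integer(0))
  ph <- instantaneousPhase(tr)
  dph <- diff(ph)
  dph[dph < -pi] <- dph[dph < -pi] + 2 * pi
  interior <- 257:(257 + 31 * 256 - 1)  # exactly 31 full cycles
  # slope 2 pi / period, deviation from linear below 0.05 rad
  unwrapped <- cumsum(c(ph[1], dph))
  lin <- lm(unwrapped[interior] ~ interior)
  expect_equal(unname(coef(lin)[2]), 2 * pi / period, tolerance = 1e-3)
  expect_lt(max(abs(residuals(lin))), 0.05)
  # uniform phase histogram (constant angular velocity); edges excluded
  counts <- table(cut(ph[interior], breaks = seq(-pi, pi, length.out = 17)))
  expect_lt(max(abs(counts / mean(counts) - 1)), 0.02)
  # negating the trace shifts the phase by pi
  ph2 <- instantaneousPhase(initialize(tr, values = -tr@values))
  d <- abs(prefulr:::circDiff(ph2, (ph + pi)))
  expect_lt(max(d[interior]), 0.05)
  expect_error(instantaneousPhase(initialize(tr, values = rep(1, n))),
               "constant")
})

test_that("equal-count allocation reproduces the printed per-bin counts", {
  set.seed(2)
  phases <- runif(150000, -pi, pi)
  counts <- c(30000, 20000, 15000, 12000, 10000, 7500, 6000)
  bins_list <- c(8, 12, 16, 20, 24, 32, 40)
  for (i in seq_along(bins_list)) {
    bs <- allocateBins(phases, integer(0),
                       binningConfig(n_bins = bins_list[i]))
    n <- lengths(bs@bin_indices)
    expect_true(all(n == counts[i]))
    expect_equal(sum(n), 240000)
    shared <- rowSums(bs@share_matrix)
    expect_true(all(shared <= 0.5 * counts[i]))
  }
})

test_that("toy allocation uses every excitation with bounded sharing", {
  set.seed(3)
  phases <- runif(1000, -pi, pi)
  bs <- allocateBins(phases, integer(0), binningConfig(n_bins = 8))
  used <- sort(unique(unlist(bs@bin_indices)))
  expect_identical(used, 1:1000)
  n <- lengths(bs@bin_indices)[1]
  expect_true(all(rowSums(bs@share_matrix) <= 0.5 * n))
  # phase coherence: circular mean within one target spacing
  for (b in seq_len(8)) {
    p <- phases[bs@bin_indices[[b]]]
    mu <- atan2(mean(sin(p)), mean(cos(p)))
    expect_lt(abs(prefulr:::circDiff(mu, bs@phase_targets[b])), 2 * pi / 8)
  }
})

test_that("allocation errors name the deficit and respects exclusions", {
  phases <- runif(100, -pi, pi)
  expect_error(allocateBins(phases, 1:95, binningConfig(n_bins = 8)),
               "deficit|insufficient")
  bs <- allocateBins(phases, 1:10, binningConfig(n_bins = 4))
  expect_false(any(1:10 %in% unlist(bs@bin_indices)))
  expect_identical(bs@excluded, 1:10)
})

test_that("binned k-space slices data consistently with sharing", {
  fx <- staticAcquisition(n = 16, n_exc = 400, J = 24)
  sm <- preprocessBellows(fx$kdata@bellows, 21)
  # synthetic phases: uniform
  set.seed(5)
  phases <- runif(400, -pi, pi)
  bs <- allocateBins(phases, integer(0), binningConfig(n_bins = 4))
  kb <- binKspace(fx$kdata, bs)
  n <- lengths(bs@bin_indices)[1]
  expect_equal(dim(kb@samples[[1]]), c(1, n, 24))
  expect_equal(dim(kb@coords[[2]]), c(n, 24, 3))
  for (b in 1:4) {
    ii <- bs@bin_indices[[b]]
    expect_identical(kb@samples[[b]][1, , ], fx$kdata@samples[1, ii, ])
    expect_identical(kb@coords[[b]], fx$kdata@traj@coords[ii, , ])
  }
  total <- sum(lengths(bs@bin_indices))
  uniq <- length(unique(unlist(bs@bin_indices)))
  expect_gte(uniq, total * 0.5)
  bad <- bs
  bad@bin_indices[[1]][1] <- 10000L
  expect_error(binKspace(fx$kdata, bad), "out of range")
})

test_that("bins traverse expiration to inspiration in mean amplitude", {
  spec <- phantomSpec(grid_size = 16, seed = 3)
  bell <- simulateBellows(spec, 10000, amp_jitter = 0, period_jitter = 0,
                          noise_sd = 0)
  ph <- instantaneousPhase(bell)
  bs <- allocateBins(ph, integer(0), binningConfig(n_bins = 8))
  amp <- vapply(bs@bin_indices, function(ii) mean(bell@values[ii]),
                numeric(1))
  # ordered by target phase the amplitudes rise then fall (one cycle):
  # exactly one sign change in the circular difference sequence
  d <- diff(c(amp, amp[1]))
  expect_equal(sum(diff(sign(d)) != 0), 2)
})
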