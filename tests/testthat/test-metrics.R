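test_that("ROI SNR is the lung mean over background SD", {
  n <- 16
  set.seed(20)
  vol <- array(rnorm(n^3, sd = 1), rep(n, 3))
  lung <- array(FALSE, rep(n, 3))
  lung[6:10, 6:10, 6:10] <- TRUE
  vol[lung] <- vol[lung] * 0 + 10
  bg <- array(FALSE, rep(n, 3))
  bg[1:4, 1:4, 1:4] <- TRUE
  snr <- roiSnr(vol, lung, bg)
  expect_equal(snr, 10 / sd(vol[bg]), tolerance = 1e-12)
  # halving the noise doubles the SNR
  vol2 <- vol
  vol2[bg] <- vol2[bg] / 2
  expect_equal(roiSnr(vol2, lung, bg), 2 * snr, tolerance = 1e-12)
  expect_error(roiSnr(vol, lung, lung), "disjoint")
  expect_error(roiSnr(array(1, rep(n, 3)), lung, bg), "zero background")
})

test_that("Sobel sharpness: zero for constants, analytic step response,
           decreasing under blur, translation invariant", {
  n <- 24
  mask <- array(FALSE, rep(n, 3))
  mask[6:18, 6:18, 6:18] <- TRUE
  expect_equal(sobelSharpness(array(5, rep(n, 3)), mask), 0)

  # unit step along x: brute-force 3D Sobel at each voxel as oracle
  step <- array(0, rep(n, 3))
  step[13:n, , ] <- 1
  sobel1d <- c(-1, 0, 1)
  smooth1d <- c(1, 2, 1)
  kx <- outer(outer(sobel1d, smooth1d), smooth1d)
  ky <- aperm(kx, c(2, 1, 3))
  kz <- aperm(kx, c(3, 2, 1))
  conv_at <- function(vol, kern, p) {
    acc <- 0
    for (a in -1:1) for (b in -1:1) for (c in -1:1) {
      q <- pmin(pmax(p + c(a, b, c), 1), dim(vol))
      # kernel centered: weight at offset (a,b,c), flipped for convolution
      acc <- acc + kern[2 - a, 2 - b, 2 - c] * vol[q[1], q[2], q[3]]
    }
    acc
  }
  oracle <- 0
  pts <- which(mask, arr.ind = TRUE)
  gs <- apply(pts, 1, function(p)
    sqrt(conv_at(step, kx, p)^2 + conv_at(step, ky, p)^2 +
           conv_at(step, kz, p)^2))
  expect_equal(sobelSharpness(step, mask), mean(gs), tolerance = 1e-10)

  set.seed(21)
  vol <- array(rnorm(n^3), rep(n, 3))
  s0 <- sobelSharpness(vol, mask)
  s1 <- sobelSharpness(prefulr:::gaussSmooth3(vol, 1), mask)
  s2 <- sobelSharpness(prefulr:::gaussSmooth3(vol, 2), mask)
  expect_gt(s0, s1)
  expect_gt(s1, s2)
  # translation invariance for an interior mask
  sm <- prefulr:::gaussSmooth3(vol, 1.5)
  expect_equal(sobelSharpness(prefulr:::shift3(sm, c(2, 0, 0)),
                              prefulr:::shift3(mask, c(2, 0, 0))),
               sobelSharpness(sm, mask), tolerance = 0.02)
})

test_that("static VDP matches brute-force enumeration and is scale invariant", {
  n <- 20
  set.seed(22)
  vol <- array(runif(n^3, 0.5, 1.5), rep(n, 3))
  mask <- array(FALSE, rep(n, 3))
  mask[4:16, 4:16, 4:16] <- TRUE
  # 30% of masked voxels at a tenth of the rest
  idx <- which(mask)
  low <- sample(idx, round(0.3 * length(idx)))
  vol[low] <- vol[low] * 0.1
  res <- staticVdp(vol, mask, 0.6, bias_correct = FALSE)
  # brute-force oracle
  thr <- 0.6 * mean(vol[mask])
  expect_equal(res$vdp, 100 * sum(vol[mask] < thr) / sum(mask))
  expect_true(all(res$defect_mask[!mask] == FALSE))
  # scaling invariance
  res2 <- staticVdp(5 * vol, mask, 0.6, bias_correct = FALSE)
  expect_equal(res2$vdp, res$vdp)
  # uniform image and zero threshold give 0%
  expect_equal(staticVdp(array(1, rep(n, 3)) +
                           array(rnorm(n^3, sd = 1e-9), rep(n, 3)),
                         mask, 0.6, bias_correct = FALSE)$vdp, 0)
  expect_equal(staticVdp(vol, mask, 0, bias_correct = FALSE)$vdp, 0)
  expect_error(staticVdp(vol, array(FALSE, rep(n, 3))), "mask")
})

test_that("VDP comparison reports bias, limits of agreement and r", {
  a <- c(5, 10, 15, 20, 25)
  r <- compareVdp(a, a)
  expect_equal(r@bias, 0)
  expect_equal(r@pearson_r, 1)
  r2 <- compareVdp(a, a + 10)
  expect_equal(r2@bias, -10)
  expect_equal(r2@loa_low, -10)
  expect_equal(r2@loa_high, -10)
  # simulated bivariate normal with correlation 0.8
  set.seed(23)
  z <- matrix(rnorm(400), ncol = 2)
  x <- z[, 1]
  y <- 0.8 * z[, 1] + sqrt(1 - 0.64) * z[, 2]
  r3 <- compareVdp(x, y)
  expect_gt(r3@pearson_r, 0.72)
  expect_lt(r3@pearson_r, 0.87)
  expect_error(compareVdp(1:2, 1:2), "at least 3")
  expect_error(compareVdp(1:4, 1:5), "equal length")
})
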