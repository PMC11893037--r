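## Gridding NUFFT (type 1/2) with a Kaiser-Bessel kernel.
##
## Forward: deapodize -> zero-pad to the oversampled grid -> FFT -> kernel
## interpolation at the sample coordinates. The adjoint is the exact
## transpose (kernel spreading -> unnormalized inverse FFT -> crop ->
## deapodize), so <F x, y> == <x, F* y> to machine precision by construction.

#' Plan a gridding NUFFT
#'
#' @param img_dims image grid dimensions (length 3)
#' @param fov_mm isotropic field of view in mm (converts cycles/mm
#'   coordinates to grid units)
#' @param os oversampling factor of the gridding grid
#' @param width Kaiser-Bessel kernel width in oversampled grid units (odd)
#' @return a plan object consumed by \code{\link{nufftForward}} and
#'   \code{\link{nufftAdjoint}}
#' @export
nufftPlan <- function(img_dims, fov_mm, os = 1.5, width = 5L) {
  img_dims <- as.integer(img_dims)
  stopifnot(length(img_dims) == 3, width %% 2 == 1)
  grid_dims <- as.integer(2 * ceiling(os * img_dims / 2))
  os_eff <- mean(grid_dims / img_dims)
  beta <- pi * sqrt((width / os_eff)^2 * (os_eff - 0.5)^2 - 0.8)
  # image-domain apodization: continuous FT of the kernel at pixel offsets
  apod1 <- function(N, G) {
    t <- seq(-width / 2, width / 2, length.out = 801)
    kbv <- cpp_kb_profile(t, as.integer(width), beta)
    p <- (0:(N - 1)) - N %/% 2
    vapply(p, function(pp) {
      integrand <- kbv * cos(2 * pi * t * pp / G)
      sum((integrand[-1] + integrand[-length(integrand)]) / 2) * diff(t[1:2])
    }, numeric(1))
  }
  ap <- lapply(1:3, function(ax) apod1(img_dims[ax], grid_dims[ax]))
  apod <- outer(outer(ap[[1]], ap[[2]]), ap[[3]])
  list(img_dims = img_dims, grid_dims = grid_dims, fov_mm = fov_mm,
       width = as.integer(width), beta = beta, apod = apod,
       scale = 1 / sqrt(prod(grid_dims)))
}

# convert k-space coordinates (M x 3, cycles/mm) to 0-based oversampled grid
# units with DC at index 0 (wrapped)
nufftGridCoords <- function(plan, coords) {
  stopifnot(ncol(coords) == 3)
  g <- coords * plan$fov_mm  # cycles per FOV
  for (ax in 1:3) {
    osd <- plan$grid_dims[ax] / plan$img_dims[ax]
    g[, ax] <- (g[, ax] * osd) %% plan$grid_dims[ax]
  }
  g
}

#' Forward NUFFT: image volume to non-Cartesian k-space samples
#'
#' @param plan a plan from \code{\link{nufftPlan}}
#' @param x complex (or real) 3D array on the plan's image grid
#' @param coords M x 3 matrix of k-space coordinates in cycles/mm
#' @return complex vector of M samples
#' @export
nufftForward <- function(plan, x, coords) {
  stopifnot(all(dim(x) == plan$img_dims))
  xa <- (x + 0i) / plan$apod
  G <- plan$grid_dims
  N <- plan$img_dims
  X <- array(0 + 0i, G)
  s <- (G - N) %/% 2
  X[s[1] + seq_len(N[1]), s[2] + seq_len(N[2]), s[3] + seq_len(N[3])] <- xa
  K <- fft(ifftshift3(X))
  gc <- nufftGridCoords(plan, coords)
  cpp_kb_gather(as.vector(K), G, gc, plan$width, plan$beta) * plan$scale
}

#' Adjoint NUFFT: non-Cartesian k-space samples to an image volume
#'
#' @inheritParams nufftForward
#' @param y complex vector of M samples
#' @return complex 3D array on the plan's image grid
#' @export
nufftAdjoint <- function(plan, y, coords) {
  G <- plan$grid_dims
  N <- plan$img_dims
  gc <- nufftGridCoords(plan, coords)
  K <- array(cpp_kb_spread(as.complex(y), gc, G, plan$width, plan$beta), G)
  X <- fftshift3(fft(K, inverse = TRUE)) * plan$scale
  s <- (G - N) %/% 2
  X[s[1] + seq_len(N[1]), s[2] + seq_len(N[2]), s[3] + seq_len(N[3])] /
    plan$apod
}

# locality order of samples: sorting by oversampled-grid cell makes the
# scattered gather/spread memory access near-sequential (~4x faster)
nufftCellOrder <- function(plan, gc) {
  G <- plan$grid_dims
  order(floor(gc[, 1]) + G[1] * (floor(gc[, 2]) + G[2] * floor(gc[, 3])))
}

# batched forward/adjoint over C channels sharing one coordinate set
# (kernel weights computed once per sample); xs is a list of volumes,
# ymat an M x C complex matrix. The *G variants take pre-converted
# oversampled-grid coordinates.
nufftForwardMultiG <- function(plan, xs, gc) {
  G <- plan$grid_dims
  N <- plan$img_dims
  s <- (G - N) %/% 2
  C <- length(xs)
  grids_t <- matrix(0 + 0i, nrow = C, ncol = prod(G))
  for (c0 in seq_len(C)) {
    X <- array(0 + 0i, G)
    X[s[1] + seq_len(N[1]), s[2] + seq_len(N[2]), s[3] + seq_len(N[3])] <-
      (xs[[c0]] + 0i) / plan$apod
    grids_t[c0, ] <- as.vector(fft(ifftshift3(X)))
  }
  t(cpp_kb_gather_multi(grids_t, G, gc, plan$width, plan$beta)) * plan$scale
}

nufftAdjointMultiG <- function(plan, ymat, gc) {
  G <- plan$grid_dims
  N <- plan$img_dims
  s <- (G - N) %/% 2
  grids <- cpp_kb_spread_multi(t(ymat), gc, G, plan$width, plan$beta)
  lapply(seq_len(ncol(ymat)), function(c0) {
    X <- fftshift3(fft(array(grids[c0, ], G), inverse = TRUE)) * plan$scale
    X[s[1] + seq_len(N[1]), s[2] + seq_len(N[2]), s[3] + seq_len(N[3])] /
      plan$apod
  })
}

nufftForwardMulti <- function(plan, xs, coords) {
  nufftForwardMultiG(plan, xs, nufftGridCoords(plan, coords))
}

nufftAdjointMulti <- function(plan, ymat, coords) {
  nufftAdjointMultiG(plan, ymat, nufftGridCoords(plan, coords))
}

# direct-summation discrete Fourier transform at arbitrary frequencies;
# the slow exact oracle used to validate the gridding operators on tiny grids
nufftDirect <- function(x, coords, fov_mm, scale = 1) {
  d <- dim(x)
  idx <- lapply(1:3, function(ax) (0:(d[ax] - 1)) - d[ax] %/% 2)
  grid <- expand.grid(idx[[1]], idx[[2]], idx[[3]])
  u <- coords * fov_mm  # cycles per FOV
  ph <- outer(u[, 1], grid[, 1] / d[1]) + outer(u[, 2], grid[, 2] / d[2]) +
    outer(u[, 3], grid[, 3] / d[3])
  exp(-2i * pi * ph) %*% as.vector(x) * scale
}
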