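## Motion-compensated low-rank reconstruction of respiratory-resolved
## image series:
##
##   x = argmin_x 1/2 || P (F S x - y) ||_2^2 + lambda_L || M x ||_*
##
## with F the NUFFT on each bin's trajectory subset, S the coil maps, P
## diagonal k-space preconditioning weights, M interpolation-based warping
## of each phase onto a reference phase, and ||.||_* the nuclear norm of
## the phase-by-voxel matrix. Solved by proximal gradient steps on the
## weighted normal equations with singular-value soft-thresholding of the
## motion-registered stack, alternating with motion re-estimation.

#' Estimate coil sensitivity maps from binned k-space data
#'
#' Iterative (JSENSE/NLINV-style) estimation: low-resolution per-coil
#' images are reconstructed jointly by conjugate-gradient least squares on
#' the bin with the most central data, smoothed, and normalized by their
#' root-sum-of-squares so that sum-of-squares = 1 inside the support.
#' Single-coil data return a uniform map.
#'
#' @param kbins a \linkS4class{KSpaceBins}
#' @param grid image grid dimensions (default: from the trajectory
#'   resolution and FOV)
#' @param frac spatial smoothing of the estimated maps, as a fraction of
#'   the grid (smoothing sigma = frac * grid / 4)
#' @param n_iters CG iterations for the per-coil images
#' @return a \linkS4class{SensitivityMaps}
#' @export
estimateSensitivities <- function(kbins, grid = NULL, frac = 0.35,
                                  n_iters = 8L) {
  C <- dim(kbins@samples[[1]])[1]
  if (is.null(grid)) {
    n <- round(kbins@fov_mm / kbins@res_mm)
    grid <- rep(as.integer(n), 3)
  }
  grid <- as.integer(grid)
  if (C == 1) {
    return(new("SensitivityMaps",
               maps = array(1 + 0i, dim = c(grid, 1)), grid = grid))
  }
  # calibrate on a low-resolution grid: the central k-space ball is many
  # times oversampled there, so the per-coil least-squares images are well
  # conditioned; the smooth maps are then resampled to the target grid
  calib_n <- as.integer(min(min(grid), max(12, round(min(grid) / 2))))
  calib_grid <- rep(calib_n, 3)
  plan <- nufftPlan(calib_grid, kbins@fov_mm)
  kmax_cal <- calib_n / (2 * kbins@fov_mm)
  b <- which.max(vapply(kbins@samples, function(x) dim(x)[2], numeric(1)))
  coords <- matrix(aperm(kbins@coords[[b]], c(2, 1, 3)), ncol = 3)
  keep <- sqrt(rowSums(coords^2)) <= kmax_cal
  coords <- coords[keep, , drop = FALSE]
  gc <- nufftGridCoords(plan, coords)
  ord <- nufftCellOrder(plan, gc)
  gc <- gc[ord, , drop = FALSE]
  ymat <- binSamplesMatrix(kbins, b)[keep, , drop = FALSE][ord, , drop = FALSE]
  wv <- as.vector(t(densityWeights(
    array(coords, dim = c(nrow(coords), 1, 3)), fov_mm = kbins@fov_mm,
    grid = calib_grid)))[ord]

  # joint per-coil CG on the weighted normal equations (plain NUFFT)
  toArr <- function(lst) array(unlist(lst), dim = c(calib_grid, C))
  normal <- function(xarr) {
    xs <- lapply(seq_len(C), function(c0) xarr[, , , c0])
    y <- nufftForwardMultiG(plan, xs, gc) * wv
    toArr(nufftAdjointMultiG(plan, y, gc))
  }
  rhs <- toArr(nufftAdjointMultiG(plan, ymat * wv, gc))
  x <- array(0 + 0i, dim = c(calib_grid, C))
  r <- rhs
  p <- r
  rs <- vapply(seq_len(C), function(c0) sum(Mod(r[, , , c0])^2), numeric(1))
  for (it in seq_len(n_iters)) {
    Ap <- normal(p)
    for (c0 in seq_len(C)) {
      if (rs[c0] <= 0) next
      alpha <- rs[c0] / Re(sum(Conj(p[, , , c0]) * Ap[, , , c0]))
      x[, , , c0] <- x[, , , c0] + alpha * p[, , , c0]
      r[, , , c0] <- r[, , , c0] - alpha * Ap[, , , c0]
      rs_new <- sum(Mod(r[, , , c0])^2)
      p[, , , c0] <- r[, , , c0] + (rs_new / rs[c0]) * p[, , , c0]
      rs[c0] <- rs_new
    }
  }
  sigma <- frac * calib_n / 4
  maps <- array(0 + 0i, dim = c(grid, C))
  for (c0 in seq_len(C)) {
    sm <- gaussSmooth3(x[, , , c0], sigma)
    maps[, , , c0] <- resample3(Re(sm), grid) + 1i * resample3(Im(sm), grid)
  }
  sos <- sqrt(apply(Mod(maps)^2, 1:3, sum))
  sos[sos < 1e-9 * max(sos)] <- Inf
  maps <- maps / as.vector(sos)
  new("SensitivityMaps", maps = maps, grid = grid)
}

#' Single-channel diagonal k-space preconditioning weights
#'
#' Density-compensation-like weights approximating the inverse frequency
#' response of the gridding gram operator: the kernel autocorrelation is
#' sampled by spreading unit weights onto the oversampled grid and
#' re-interpolating at the sample locations; the weight is its reciprocal.
#'
#' @param coords either a \linkS4class{TrajectorySet} or an (n, J, 3) array
#'   of k-space coordinates in cycles/mm
#' @param fov_mm field of view (taken from the trajectory when omitted)
#' @param grid image grid dims used to scale the gridding grid
#' @return matrix (n, J) of nonnegative weights
#' @export
densityWeights <- function(coords, fov_mm = NULL, grid = NULL) {
  if (is(coords, "TrajectorySet")) {
    if (is.null(fov_mm)) fov_mm <- coords@fov_mm
    if (is.null(grid)) grid <- rep(round(fov_mm / coords@res_mm), 3)
    coords <- coords@coords
  }
  stopifnot(!is.null(fov_mm), !is.null(grid))
  d <- dim(coords)
  cm <- matrix(aperm(coords, c(2, 1, 3)), ncol = 3)
  if (all(cm == 0)) stop("degenerate all-zero trajectory")
  plan <- nufftPlan(as.integer(grid), fov_mm)
  gc <- nufftGridCoords(plan, cm)
  ones <- complex(real = rep(1, nrow(cm)))
  spread <- cpp_kb_spread(ones, gc, plan$grid_dims, plan$width, plan$beta)
  dens <- Re(cpp_kb_gather(spread, plan$grid_dims, gc, plan$width, plan$beta))
  w <- 1 / pmax(dens, 1e-6 * max(dens))
  matrix(w, nrow = d[1], ncol = d[2], byrow = TRUE)
}

#' Compute the k-space preconditioner for binned data
#'
#' @param kbins a \linkS4class{KSpaceBins}
#' @param sens optional \linkS4class{SensitivityMaps} (sets the grid)
#' @return a \linkS4class{Preconditioner} with per-bin weight matrices
#' @export
computePreconditioner <- function(kbins, sens = NULL) {
  grid <- if (!is.null(sens)) sens@grid else
    rep(round(kbins@fov_mm / kbins@res_mm), 3)
  w <- lapply(kbins@coords, densityWeights, fov_mm = kbins@fov_mm,
              grid = grid)
  new("Preconditioner", weights = w)
}

# internal: per-bin forward/adjoint SENSE operators on a shared plan;
# coordinates are pre-converted oversampled-grid coordinates (see
# nufftGridCoords), ideally in cell order for memory locality
senseOps <- function(plan, sens) {
  C <- dim(sens@maps)[4]
  list(
    forward = function(x, gc) {
      xs <- lapply(seq_len(C), function(c0) x * sens@maps[, , , c0])
      nufftForwardMultiG(plan, xs, gc)
    },
    adjoint = function(y, gc) {
      imgs <- nufftAdjointMultiG(plan, y, gc)
      x <- array(0 + 0i, dim = plan$img_dims)
      for (c0 in seq_len(C))
        x <- x + Conj(sens@maps[, , , c0]) * imgs[[c0]]
      x
    })
}

binCoordsMatrix <- function(kbins, b)
  matrix(aperm(kbins@coords[[b]], c(2, 1, 3)), ncol = 3)

binSamplesMatrix <- function(kbins, b) {
  s <- kbins@samples[[b]]
  C <- dim(s)[1]
  out <- matrix(0 + 0i, nrow = dim(s)[2] * dim(s)[3], ncol = C)
  for (c0 in seq_len(C)) out[, c0] <- as.vector(t(matrix(s[c0, , ],
                                                         nrow = dim(s)[2])))
  out
}

#' CG-SENSE reconstruction of one respiratory bin
#'
#' Conjugate-gradient solution of the weighted normal equations
#' \eqn{S^H F^H W (F S x) = S^H F^H W y}. The quadratic objective is
#' non-increasing over iterations.
#'
#' @param ybin matrix (samples, coils) of k-space data for the bin
#' @param coords matrix (samples, 3) of coordinates in cycles/mm
#' @param sens a \linkS4class{SensitivityMaps}
#' @param weights vector of nonnegative preconditioning weights per sample
#' @param plan a NUFFT plan on the reconstruction grid
#' @param n_iters CG iterations
#' @param track_objective record the weighted residual objective per
#'   iteration (costs one extra forward evaluation per iteration)
#' @return list with \code{image} (complex volume) and \code{objective}
#'   (per-iteration weighted residual objective; empty when not tracked)
#' @export
cgsenseRecon <- function(ybin, coords, sens, weights, plan, n_iters = 10L,
                         track_objective = FALSE) {
  gc <- nufftGridCoords(plan, coords)
  ord <- nufftCellOrder(plan, gc)
  cgsenseReconG(ybin[ord, , drop = FALSE], gc[ord, , drop = FALSE], sens,
                as.vector(weights)[ord], plan, n_iters, track_objective)
}

# internal variant on pre-converted, locality-ordered grid coordinates
cgsenseReconG <- function(ybin, gc, sens, wv, plan, n_iters = 10L,
                          track_objective = FALSE) {
  ops <- senseOps(plan, sens)
  coords <- gc
  normal <- function(x) ops$adjoint(ops$forward(x, coords) * wv, coords)
  rhs <- ops$adjoint(ybin * wv, coords)
  x <- array(0 + 0i, dim = plan$img_dims)
  r <- rhs
  p <- r
  rs <- sum(Mod(r)^2)
  obj <- if (track_objective) numeric(n_iters) else numeric(0)
  if (rs == 0) return(list(image = x, objective = obj))
  for (it in seq_len(n_iters)) {
    Ap <- normal(p)
    alpha <- rs / Re(sum(Conj(p) * Ap))
    x <- x + alpha * p
    r <- r - alpha * Ap
    rs_new <- sum(Mod(r)^2)
    if (track_objective) {
      res <- ops$forward(x, coords) - ybin
      obj[it] <- 0.5 * sum(wv * Mod(res)^2)
    }
    if (rs_new < 1e-14 * rs) {
      if (track_objective) obj <- obj[seq_len(it)]
      break
    }
    p <- r + (rs_new / rs) * p
    rs <- rs_new
  }
  list(image = x, objective = obj)
}

#' Singular-value soft-thresholding (nuclear-norm proximal operator)
#'
#' @param stack matrix (B phases x N voxels), or a 4D array reshaped
#'   internally
#' @param tau threshold
#' @return the thresholded stack, same shape as the input
#' @export
nuclearProx <- function(stack, tau) {
  stopifnot(tau >= 0)
  dims <- dim(stack)
  X <- if (length(dims) == 4) {
    matrix(stack, nrow = prod(dims[1:3]), ncol = dims[4])
  } else stack
  if (!all(is.finite(Mod(X)))) stop("non-finite input to nuclearProx")
  if (tau == 0) return(stack)
  sv <- svd(X)
  s <- pmax(sv$d - tau, 0)
  keep <- s > 0
  out <- if (!any(keep)) X * 0 else
    sv$u[, keep, drop = FALSE] %*% (s[keep] * Conj(t(sv$v[, keep, drop = FALSE])))
  if (length(dims) == 4) array(out, dim = dims) else out
}

# nuclear norm of the phase stack (B small): sum of singular values
nuclearNorm <- function(X) sum(svd(X, nu = 0, nv = 0)$d)

stackMatrix <- function(vols) {
  d <- dim(vols)
  matrix(vols, nrow = prod(d[1:3]), ncol = d[4])
}

# largest singular value via the small (B x B) Gram matrix
topSingularValue <- function(X) {
  G <- Conj(t(X)) %*% X
  sqrt(max(Re(eigen(G, only.values = TRUE)$values)))
}

#' Motion-compensated low-rank reconstruction (MoCoLoR)
#'
#' Alternates motion re-estimation (registration of the current phase
#' magnitudes to the end-expiration reference) with proximal-gradient
#' cycles: \code{inner_iters} Lipschitz-normalized gradient steps on the
#' preconditioned data-fidelity term per bin, then singular-value
#' soft-thresholding of the motion-warped phase stack, then unwarping.
#' The composite objective at the end of each superior iteration is
#' non-increasing within tolerance.
#'
#' @param kbins a \linkS4class{KSpaceBins}
#' @param sens a \linkS4class{SensitivityMaps}
#' @param precond a \linkS4class{Preconditioner}
#' @param config a \linkS4class{ReconConfig}
#' @param grid reconstruction grid dims (default: sensitivity grid)
#' @param reg_params registration parameters for motion estimation
#' @param verbose print objective values per superior iteration
#' @return list with \code{series} (an \linkS4class{ImageSeries}),
#'   \code{fields} (last motion fields), \code{objective} (per superior
#'   iteration), \code{ref_bin}
#' @export
mocolor <- function(kbins, sens, precond, config = reconConfig(),
                    grid = NULL, reg_params = reconRegistrationParams(),
                    verbose = FALSE) {
  B <- length(kbins@samples)
  if (is.null(grid)) grid <- sens@grid
  grid <- as.integer(grid)
  vox <- kbins@fov_mm / grid[1]
  plan <- nufftPlan(grid, kbins@fov_mm)
  ops <- senseOps(plan, sens)
  if (B == 1 && config@lambda_L > 0)
    warning("single bin: reconstruction degenerates to preconditioned SENSE")

  coords <- vector("list", B)
  ydata <- vector("list", B)
  wts <- vector("list", B)
  for (b in seq_len(B)) {
    gc <- nufftGridCoords(plan, binCoordsMatrix(kbins, b))
    ord <- nufftCellOrder(plan, gc)
    coords[[b]] <- gc[ord, , drop = FALSE]
    ydata[[b]] <- binSamplesMatrix(kbins, b)[ord, , drop = FALSE]
    wts[[b]] <- as.vector(precond@weights[[b]])[ord]
  }

  # CG-SENSE initialization
  vols <- array(0 + 0i, dim = c(grid, B))
  for (b in seq_len(B))
    vols[, , , b] <- cgsenseReconG(ydata[[b]], coords[[b]], sens, wts[[b]],
                                   plan, config@cg_init_iters)$image

  # end-expiration reference: bin with the lowest mean bellows amplitude
  ref_bin <- which.min(kbins@bin_amplitude)

  # per-bin Lipschitz constants of the weighted normal operator
  L <- numeric(B)
  for (b in seq_len(B)) {
    v <- vols[, , , ref_bin]
    if (sum(Mod(v)) == 0) v <- array(1 + 0i, dim = grid)
    v <- v / sqrt(sum(Mod(v)^2))
    for (p in 1:4) {
      u <- ops$adjoint(ops$forward(v, coords[[b]]) * wts[[b]], coords[[b]])
      nu <- sqrt(sum(Mod(u)^2))
      v <- u / nu
    }
    L[b] <- nu
  }
  step <- config@step_rho / L

  identityFields <- replicate(B, NULL, simplify = FALSE)
  fields <- identityFields
  inv_fields <- identityFields

  warpStack <- function(vols, fields) {
    out <- vols
    for (b in seq_len(B)) if (!is.null(fields[[b]]))
      out[, , , b] <- applyField(vols[, , , b], fields[[b]])
    out
  }

  gradStep <- function(vols) {
    for (b in seq_len(B)) {
      res <- ops$forward(vols[, , , b], coords[[b]]) - ydata[[b]]
      g <- ops$adjoint(res * wts[[b]], coords[[b]])
      vols[, , , b] <- vols[, , , b] - step[b] * g
    }
    vols
  }

  dataObj <- function(vols) {
    s <- 0
    for (b in seq_len(B)) {
      res <- ops$forward(vols[, , , b], coords[[b]]) - ydata[[b]]
      w <- if (config@weighted_objective) wts[[b]] else 1
      s <- s + 0.5 * sum(w * Mod(res)^2)
    }
    s
  }

  lambda_abs <- NA_real_
  objective <- numeric(config@superior_iters)
  use_lr <- config@lambda_L > 0 && B >= 2
  for (sup in seq_len(config@superior_iters)) {
    if (use_lr) {
      mags <- Mod(vols)
      fixed <- mags[, , , ref_bin]
      for (b in seq_len(B)) {
        if (b == ref_bin) {
          fields[b] <- list(NULL)
          inv_fields[b] <- list(NULL)
          next
        }
        f <- registerPair(mags[, , , b], fixed, reg_params, vox)
        fields[[b]] <- f
        inv_fields[[b]] <- invertField(f)
      }
      if (is.na(lambda_abs)) {
        # anchor the dimensionless lambda_L to the intensity scale of the
        # initialized images (absolute-threshold convention: the nuclear
        # prox threshold is lambda_L * peak intensity * step), which keeps
        # the ventilation dynamics while shrinking noise-level singular
        # values; the singular spectrum itself is problem-sized
        lambda_abs <- config@lambda_L * max(Mod(vols)) * sqrt(prod(grid))
      }
    }
    for (o in seq_len(config@outer_iters)) {
      for (i in seq_len(config@inner_iters)) vols <- gradStep(vols)
      if (use_lr) {
        # apply the soft-thresholding as an increment computed in the
        # motion-registered frame: only the (small) low-rank correction is
        # warped back, so a near-identity prox does not incur the
        # interpolation blur of a full warp/unwarp round trip
        z <- warpStack(vols, fields)
        dz <- nuclearProx(z, lambda_abs * mean(step)) - z
        vols <- vols + warpStack(dz, inv_fields)
      }
    }
    obj <- dataObj(vols)
    if (use_lr)
      obj <- obj + lambda_abs * nuclearNorm(stackMatrix(warpStack(vols, fields)))
    objective[sup] <- obj
    if (verbose)
      message(sprintf("superior %d: objective %.6g", sup, obj))
    if (sup >= 3 && objective[sup] > 1.1 * objective[sup - 1] &&
        objective[sup - 1] > 1.1 * objective[sup - 2])
      stop(sprintf(
        "reconstruction diverging: objective rose >10%% twice (%.4g -> %.4g -> %.4g)",
        objective[sup - 2], objective[sup - 1], objective[sup]))
  }
  phases <- if (length(kbins@bins@phase_targets) == B)
    kbins@bins@phase_targets else rep(NA_real_, B)
  series <- new("ImageSeries", volumes = vols, bin_phases = phases,
                voxel_mm = vox)
  list(series = series, fields = fields, objective = objective,
       ref_bin = ref_bin)
}
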