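## FLORET-style trajectory generation: Fermat-spiral interleaves projected
## center-out onto cones, cones grouped into up to three orthogonal hubs.

GOLDEN_ANGLE <- pi * (3 - sqrt(5))      # azimuthal increment, ~137.51 deg
# cone-angle stratifier: an irrational increment independent of the golden
# azimuthal increment, so (cone angle, azimuth) pairs fill the 2D torus
SILVER_FRAC <- sqrt(2) - 1
BASE_TURNS <- 3                         # spiral turns at nyquist_pct = 1

bitReverse <- function(m, n) {
  # fractional van der Corput (base 2) sequence over n items
  vapply(m, function(i) {
    f <- 0
    b <- 0.5
    while (i > 0) {
      f <- f + b * (i %% 2)
      i <- i %/% 2
      b <- b / 2
    }
    f
  }, numeric(1))
}

#' Generate a FLORET-style center-out 3D k-space trajectory
#'
#' Each excitation is one Fermat-spiral interleave,
#' \eqn{r(\theta) = k_{max}\sqrt{\theta/\theta_{max}}}, traced center-out on a
#' cone of half-angle up to \code{hub_half_angle_deg}. Interleaves are
#' partitioned evenly across mutually orthogonal hubs and rotated
#' azimuthally by the configured ordering (golden-angle by default) so that
#' any contiguous time window covers azimuthal angles quasi-uniformly.
#'
#' @param config a \linkS4class{TrajectoryConfig}
#' @return a \linkS4class{TrajectorySet}
#' @export
generateFloret <- function(config) {
  validObject(config)
  I <- config@n_excitations
  J <- config@samples_per_readout
  H <- config@n_hubs
  kmax <- 1 / (2 * config@res_mm)
  if (I %% H != 0)
    warning("n_excitations not divisible by n_hubs; remainder allocated round-robin")
  hub_assign <- ((seq_len(I) - 1L) %% H) + 1L
  # interleave index within hub, in acquisition order
  m_in_hub <- integer(I)
  for (h in seq_len(H)) m_in_hub[hub_assign == h] <- seq_len(sum(hub_assign == h)) - 1L
  n_in_hub <- tabulate(hub_assign, H)

  half <- config@hub_half_angle_deg * pi / 180
  turns <- BASE_TURNS * config@nyquist_pct
  # Fermat spiral r(theta) = kmax sqrt(theta/theta_max), traversed with
  # samples spaced uniformly in radius so the center-out readout leaves no
  # radial gap at low spatial frequencies
  sr <- seq(0, 1, length.out = J)         # normalized radius
  r <- kmax * sr
  theta <- 2 * pi * turns * sr^2          # spiral angle along the readout

  phi <- switch(config@interleave_order,
    golden = m_in_hub * GOLDEN_ANGLE,
    sequential = 2 * pi * m_in_hub / pmax(1, n_in_hub[hub_assign]),
    `bit-reversed` = 2 * pi * bitReverse(m_in_hub, max(n_in_hub)))
  # cone half-angle per interleave, stratified uniformly in sin(alpha)
  sina <- (2 * ((m_in_hub * SILVER_FRAC) %% 1) - 1) * sin(half)
  alpha <- asin(sina)

  coords <- array(0, dim = c(I, J, 3))
  cosA <- cos(alpha)
  sinA <- sin(alpha)
  for (j in seq_len(J)) {
    psi <- phi + theta[j]
    u <- r[j] * cosA * cos(psi)
    v <- r[j] * cosA * sin(psi)
    w <- r[j] * sinA
    # hub rotations: cyclic permutations of the hub-frame axes
    h1 <- hub_assign == 1
    h2 <- hub_assign == 2
    h3 <- hub_assign == 3
    coords[h1, j, 1] <- u[h1]; coords[h1, j, 2] <- v[h1]; coords[h1, j, 3] <- w[h1]
    coords[h2, j, 1] <- w[h2]; coords[h2, j, 2] <- u[h2]; coords[h2, j, 3] <- v[h2]
    coords[h3, j, 1] <- v[h3]; coords[h3, j, 2] <- w[h3]; coords[h3, j, 3] <- u[h3]
  }
  axes <- rbind(c(0, 0, 1), c(1, 0, 0), c(0, 1, 0))[seq_len(H), , drop = FALSE]
  new("TrajectorySet", coords = coords, excitation_order = seq_len(I),
      kmax = kmax, fov_mm = config@fov_mm, res_mm = config@res_mm,
      hub_axes = axes, hub_assign = hub_assign)
}

#' Achieved Nyquist sampling coverage of a trajectory
#'
#' Counts k-space cells of width 1/FOV that contain at least one sample,
#' over all cells inside the kmax ball, and returns the occupied fraction.
#'
#' @param traj a \linkS4class{TrajectorySet}
#' @param config the \linkS4class{TrajectoryConfig} defining FOV/resolution
#' @return fraction in [0, 1]
#' @export
nyquistCoverage <- function(traj, config) {
  coords <- traj@coords
  if (length(coords) == 0 || dim(coords)[1] == 0)
    stop("empty trajectory")
  fov <- config@fov_mm
  kmax_cells <- (1 / (2 * config@res_mm)) * fov
  cells <- round(matrix(coords, ncol = 3) * fov)
  inside <- rowSums(cells^2) <= kmax_cells^2 + 1e-9
  cells <- cells[inside, , drop = FALSE]
  occupied <- length(unique(
    (cells[, 1] + kmax_cells) +
      (2 * kmax_cells + 1) * ((cells[, 2] + kmax_cells) +
                              (2 * kmax_cells + 1) * (cells[, 3] + kmax_cells))))
  rng <- -ceiling(kmax_cells):ceiling(kmax_cells)
  ball <- expand.grid(rng, rng, rng)
  total <- sum(rowSums(ball^2) <= kmax_cells^2 + 1e-9)
  occupied / total
}
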