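## Respiratory binning: moving-average smoothing, +/- k SD outlier
## exclusion, Hilbert instantaneous phase, and equal-count allocation to B
## phase-centered bins with bounded dynamic view sharing.

#' Moving-average smoothing of a bellows trace
#'
#' Centered moving average; the window shrinks at the boundaries so the
#' output has the same length as the input.
#'
#' @param trace a \linkS4class{BellowsTrace}
#' @param window window length in excitations
#' @return a smoothed \linkS4class{BellowsTrace}
#' @export
preprocessBellows <- function(trace, window) {
  n <- length(trace@values)
  stopifnot(window >= 1)
  if (window >= n) stop("smoothing window must be shorter than the trace")
  if (window == 1) return(trace)
  hw <- (window - 1) %/% 2
  cs <- cumsum(c(0, trace@values))
  lo <- pmax(seq_len(n) - hw, 1)
  hi <- pmin(seq_len(n) + hw, n)
  sm <- (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
  initialize(trace, values = sm)
}

#' Bellows outlier exclusion
#'
#' Indices whose (smoothed) bellows value deviates from the mean by more
#' than \code{k} standard deviations.
#'
#' @param trace a \linkS4class{BellowsTrace} (typically smoothed)
#' @param k SD multiplier (2 excludes high/low-amplitude oscillations beyond
#'   two standard deviations of the mean reading)
#' @return integer vector of excluded excitation indices
#' @export
excludeOutliers <- function(trace, k = 2) {
  v <- trace@values
  stopifnot(length(v) >= 2)
  s <- stats::sd(v)
  if (s == 0) {
    warning("zero-variance trace; no outliers excluded")
    return(integer(0))
  }
  which(abs(v - mean(v)) > k * s)
}

#' Instantaneous respiratory phase by Hilbert transformation
#'
#' Phase of the analytic signal of the mean-detrended trace, in (-pi, pi].
#' For a pure sinusoid the unwrapped phase advances by 2 pi per period.
#'
#' @param trace a \linkS4class{BellowsTrace}
#' @return numeric vector of phases in (-pi, pi]
#' @export
instantaneousPhase <- function(trace) {
  v <- trace@values
  stopifnot(length(v) >= 8)
  if (stats::sd(v) == 0) stop("phase undefined for a constant trace")
  Arg(analyticSignal(v - mean(v)))
}

#' Equal-count respiratory bin allocation with bounded view sharing
#'
#' Bins are centered on B equispaced phase targets. Each bin takes the
#' \code{n = T \%/\% B} excitations nearest its target phase (circular
#' distance), drawing first on unclaimed excitations and then sharing
#' members already claimed by other bins, never exceeding
#' \code{max_share_fraction * n} shared members per bin. The total budget T
#' defaults to the configured value and is scaled to twice the usable
#' excitation count when fewer than 120000 usable excitations are
#' available, which keeps the equal-count-with-50-percent-sharing geometry
#' intact at desk scale.
#'
#' @param phases per-excitation instantaneous phase in (-pi, pi]
#' @param excluded integer vector of excluded excitation indices
#' @param config a \linkS4class{BinningConfig}
#' @return a \linkS4class{RespiratoryBinSet}
#' @export
allocateBins <- function(phases, excluded, config) {
  validObject(config)
  B <- config@n_bins
  usable <- setdiff(seq_along(phases), excluded)
  n_usable <- length(usable)
  targets <- -pi + (seq_len(B) - 0.5) * 2 * pi / B
  ph_u <- phases[usable]
  primary <- max.col(-abs(vapply(targets, function(t0) circDiff(ph_u, t0),
                                 numeric(length(ph_u)))), ties.method = "first")
  total <- config@total_budget
  if (n_usable < 120000) {
    # desk-scale budget: about twice the usable count, capped so that the
    # smallest primary pool can still supply the unique (non-shared) quota
    min_pool <- min(tabulate(primary, B))
    n_cap <- floor(min_pool / (1 - config@max_share_fraction))
    total <- max(B, min(2L * n_usable, B * n_cap))
  }
  n_per <- total %/% B
  if (n_per < 1) stop("insufficient usable excitations: need at least ", B)
  max_share <- floor(config@max_share_fraction * n_per)
  need_unique <- B * (n_per - max_share)
  if (n_usable < need_unique)
    stop(sprintf(
      "insufficient usable excitations: %d available, %d unique needed (deficit %d)",
      n_usable, need_unique, need_unique - n_usable))

  # unclaimed-first allocation: every usable excitation belongs primarily to
  # its nearest target; each bin keeps its n_per nearest primaries as unique
  # members and fills the remainder with the nearest neighbors' members
  bin_indices <- vector("list", B)
  for (b in seq_len(B)) {
    d <- abs(circDiff(ph_u, targets[b]))
    own <- which(primary == b)
    own <- own[order(d[own], usable[own])]
    unique_take <- own[seq_len(min(length(own), n_per))]
    deficit <- n_per - length(unique_take)
    if (deficit > max_share)
      stop(sprintf(
        "bin %d deficit: %d unique members, %d shared needed but only %d allowed",
        b, length(unique_take), deficit, max_share))
    shared_take <- integer(0)
    if (deficit > 0) {
      others <- which(primary != b)
      others <- others[order(d[others], usable[others])]
      shared_take <- others[seq_len(deficit)]
    }
    bin_indices[[b]] <- sort(usable[c(unique_take, shared_take)])
  }
  # share_matrix[b, b2]: members of bin b borrowed from bin b2's primary pool
  prim_of <- integer(length(phases))
  prim_of[usable] <- primary
  share <- matrix(0L, B, B)
  for (b in seq_len(B)) {
    borrowed <- prim_of[bin_indices[[b]]]
    cnt <- tabulate(borrowed, B)
    cnt[b] <- 0L
    share[b, ] <- cnt
  }
  new("RespiratoryBinSet", bin_indices = bin_indices,
      phase_targets = targets, excluded = as.integer(sort(excluded)),
      share_matrix = share, phases = phases)
}

#' Apply respiratory bin assignments to raw k-space data
#'
#' @param kdata a \linkS4class{KSpaceData}
#' @param bins a \linkS4class{RespiratoryBinSet}
#' @param smoothing_window moving-average window used for the per-bin mean
#'   amplitude bookkeeping (defaults to a quarter breathing period estimated
#'   from the phases)
#' @return a \linkS4class{KSpaceBins}
#' @export
binKspace <- function(kdata, bins, smoothing_window = NULL) {
  I <- dim(kdata@samples)[2]
  idx_all <- unlist(bins@bin_indices)
  if (any(idx_all < 1 | idx_all > I)) stop("bin index out of range")
  v <- kdata@bellows@values
  samples <- lapply(bins@bin_indices, function(ii)
    kdata@samples[, ii, , drop = FALSE])
  coords <- lapply(bins@bin_indices, function(ii)
    kdata@traj@coords[ii, , , drop = FALSE])
  amp <- vapply(bins@bin_indices, function(ii) mean(v[ii]), numeric(1))
  new("KSpaceBins", samples = samples, coords = coords, bins = bins,
      bin_amplitude = amp, fov_mm = kdata@traj@fov_mm,
      res_mm = kdata@traj@res_mm)
}

# default smoothing window: a quarter of the breathing period in excitations
defaultSmoothingWindow <- function(breathing_period_s, tr_s) {
  max(1L, as.integer(round(0.25 * breathing_period_s / tr_s)))
}
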