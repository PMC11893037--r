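## Internal array helpers shared across modules.

# circular shift of a 3D array along every axis
circshift3 <- function(x, s) {
  d <- dim(x)
  i1 <- ((seq_len(d[1]) - 1 - s[1]) %% d[1]) + 1
  i2 <- ((seq_len(d[2]) - 1 - s[2]) %% d[2]) + 1
  i3 <- ((seq_len(d[3]) - 1 - s[3]) %% d[3]) + 1
  x[i1, i2, i3, drop = FALSE]
}

fftshift3 <- function(x) circshift3(x, floor(dim(x) / 2))
ifftshift3 <- function(x) circshift3(x, -floor(dim(x) / 2))

# DFT sample frequencies (cycles per grid length), DC first
fftfreq <- function(n) c(0:(n - n %/% 2 - 1), -(n %/% 2):-1) / n

# Gaussian smoothing of a 3D array via the FFT (periodic boundaries).
# sigma in voxels; sigma = 0 returns the input.
gaussSmooth3 <- function(x, sigma) {
  if (sigma <= 0) return(x)
  d <- dim(x)
  g <- lapply(1:3, function(ax) exp(-2 * pi^2 * sigma^2 * fftfreq(d[ax])^2))
  tf <- outer(outer(g[[1]], g[[2]]), g[[3]])
  out <- fft(fft(x) * tf, inverse = TRUE) / prod(d)
  if (is.complex(x)) out else Re(out)
}

# shift a 3D array by integer voxels with edge replication
shift3 <- function(x, s) {
  d <- dim(x)
  idx <- function(n, k) pmin(pmax(seq_len(n) - k, 1), n)
  x[idx(d[1], s[1]), idx(d[2], s[2]), idx(d[3], s[3]), drop = FALSE]
}

# central-difference spatial gradient, edge replicated; returns list(gx,gy,gz)
gradient3 <- function(x) {
  list(gx = (shift3(x, c(-1, 0, 0)) - shift3(x, c(1, 0, 0))) / 2,
       gy = (shift3(x, c(0, -1, 0)) - shift3(x, c(0, 1, 0))) / 2,
       gz = (shift3(x, c(0, 0, -1)) - shift3(x, c(0, 0, 1))) / 2)
}

# trilinear resampling of a 3D array to new dims (grid-aligned corners)
resample3 <- function(x, newdims) {
  d <- dim(x)
  g <- function(n, m) if (m == 1) 0 else (seq_len(m) - 1) * (n - 1) / (m - 1)
  pts <- as.matrix(expand.grid(g(d[1], newdims[1]), g(d[2], newdims[2]),
                               g(d[3], newdims[3])))
  array(cpp_trilinear(as.double(x), as.integer(d), pts), dim = newdims)
}

# block-like downsampling by integer factor: Gaussian prefilter + resample
downsample3 <- function(x, f) {
  if (f == 1) return(x)
  resample3(gaussSmooth3(x, f / 2), pmax(2, round(dim(x) / f)))
}

# analytic signal via FFT; x must be mean-detrended by the caller
analyticSignal <- function(x) {
  n <- length(x)
  X <- fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  fft(X * h, inverse = TRUE) / n
}

# circular (wrapped) difference of phases, result in (-pi, pi]
circDiff <- function(a, b) {
  d <- (a - b) %% (2 * pi)
  d[d > pi] <- d[d > pi] - 2 * pi
  d
}

# deterministic FNV-1a-style hash of a character string, hex output
fnvHash <- function(s) {
  bytes <- utf8ToInt(s)
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), as.integer(b))
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}
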