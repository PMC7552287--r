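# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths for the quantities they check.

# Render a bright-background frame with dark Gaussian blobs at the given
# sub-pixel centres (0-based x = column, y = row).
render_blobs <- function(centres, width, height, sigma = 2, depth = 5000,
                         bg = 30000) {
  img <- matrix(bg, height, width)
  xg <- 0:(width - 1)
  yg <- 0:(height - 1)
  for (i in seq_len(nrow(centres))) {
    gx <- exp(-((xg - centres[i, 1])^2) / (2 * sigma^2))
    gy <- exp(-((yg - centres[i, 2])^2) / (2 * sigma^2))
    img <- img - depth * (gy %o% gx)
  }
  img
}

# Voxel-counting ellipsoid volume: counts voxel centres of an h-spaced grid
# inside the ellipsoid (dl along x, ds along y and z), times voxel volume.
# Row-counting form: exact voxel count, no floating-geometry shortcuts.
voxel_ellipsoid_volume <- function(dl, ds, h = 0.5) {
  a <- dl / 2
  b <- ds / 2
  # voxel centres at +/- h/2, +/- 3h/2, ... ; count per (x, z) column
  xs <- seq(h / 2, a - h / 2 + h, by = h)
  xs <- c(-xs, xs)
  zs <- seq(h / 2, b - h / 2 + h, by = h)
  zs <- c(-zs, zs)
  total <- 0
  for (z in zs) {
    rem <- 1 - (z / b)^2 - (xs / a)^2
    ylim <- b * sqrt(pmax(rem, 0))
    total <- total + sum(pmax(floor(ylim / h + 0.5), 0) * 2)
  }
  total * h^3
}

# Exact two-sided Mann-Whitney p-value by full enumeration of all
# choose(n + m, n) group assignments of the pooled sample (tie-free data).
mw_perm_p <- function(a, b) {
  pooled <- c(a, b)
  n <- length(a)
  m <- length(b)
  u_stat <- function(idx) {
    r <- rank(pooled)
    sum(r[idx]) - n * (n + 1) / 2
  }
  obs <- u_stat(seq_len(n))
  all_u <- apply(utils::combn(n + m, n), 2, u_stat)
  mu <- n * m / 2
  # two-sided: total probability of |U - nm/2| >= |obs - nm/2|
  mean(abs(all_u - mu) >= abs(obs - mu) - 1e-12)
}

# Dominant frequency of a uniformly sampled signal by plain periodogram.
fft_dominant_freq <- function(v, fs) {
  v <- v - mean(v)
  n <- length(v)
  p <- Mod(stats::fft(v))^2
  half <- 2:(floor(n / 2) + 1)
  freqs <- (half - 1) * fs / n
  freqs[which.max(p[half])]
}

# Population (1/N) SD, written out independently of the package internals.
sd_pop_oracle <- function(x) sqrt(mean((x - mean(x))^2))
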