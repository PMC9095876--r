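# Shared fixtures, generated in code.

# noise-free 2D imaging config in abstract pixel units
pixelConfig2d <- function(grid = c(32, 32), fwhm = 4, noise = 0)
  ImagingConfig(grid, pixelSize = c(1, 1), psfFWHM = rep(fwhm, 2),
                noiseSD = noise)

pixelConfig3d <- function(grid = c(16, 16, 16), fwhm = 4, noise = 0)
  ImagingConfig(grid, pixelSize = c(1, 1, 1), psfFWHM = rep(fwhm, 3),
                noiseSD = noise)

# deterministic smooth 2D test images (the frozen-oracle fixtures)
fixtureImage2d <- function(n = 16) {
  i <- matrix(seq_len(n) - 1, n, n)
  j <- t(i)
  (sin(0.3 * i) * cos(0.2 * j) + 1) / 2
}

fixtureImage2dB <- function(n = 16) {
  i <- matrix(seq_len(n) - 1, n, n)
  j <- t(i)
  a <- fixtureImage2d(n)
  pmin(pmax(a + 0.1 * sin(0.9 * i * j + 1), 0), 1)
}

fixtureVolume3d <- function(n = 12) {
  a <- array(0, c(n, n, n))
  for (x in 0:(n - 1)) for (y in 0:(n - 1)) for (z in 0:(n - 1))
    a[x + 1, y + 1, z + 1] <- (sin(0.3 * x) * cos(0.2 * y) * sin(0.15 * z + 0.4) + 1) / 2
  a
}

fixtureVolume3dB <- function(n = 12) {
  a <- fixtureVolume3d(n)
  for (x in 0:(n - 1)) for (y in 0:(n - 1)) for (z in 0:(n - 1))
    a[x + 1, y + 1, z + 1] <- min(max(a[x + 1, y + 1, z + 1] +
                                        0.05 * cos(0.5 * x + 0.3 * y * z), 0), 1)
  a
}

# hand-built two-parallel-vessel phantom: centers 2 px apart in x
twoVesselTree <- function(sep = 2, x0 = 30.5, n = 64) {
  seg <- data.frame(x0 = c(x0, x0 + sep), y0 = 2, z0 = 0,
                    x1 = c(x0, x0 + sep), y1 = n - 2, z1 = 0,
                    radius = 0.4, depth = 0L, parent = NA_integer_)
  new("VesselTree", segments = seg, region = c(n, n), dim = 2L)
}

# tiny paired-sample set for training bookkeeping tests
tinyPairs <- function(n = 4, size = 16, seed = 1) {
  withr::with_seed(seed, {
    lapply(seq_len(n), function(i) {
      y <- matrix(runif(size * size), size)
      x <- array(pmin(pmax(y + rnorm(size^2, 0, 0.05), 0), 1),
                 c(size, size, 1))
      new("PairedSample", x = x, y = y)
    })
  })
}

# index of local maxima of a 1D profile
profilePeaks <- function(p) which(diff(sign(diff(p))) == -2) + 1

# replace zero-initialized (residual-closing) weight matrices with small
# noise: gradient checks and one-step tests need a point away from the
# leaky-rectifier kink that the all-zero start sits on
jitterZeroLayers <- function(net, sd = 0.05, seed = 1) {
  withr::with_seed(seed, {
    net@params <- lapply(net@params, function(p) {
      if (is.matrix(p) && all(p == 0)) p[] <- rnorm(length(p), 0, sd)
      p
    })
  })
  net
}
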