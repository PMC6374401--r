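mkField <- function(Ex, px = 0.05, n = 1.37, lambda = 550) {
  new("ExitPlaneField", Ex = Ex, Ey = matrix(complex(real = 0), 0, 0),
      pixelSize = px, polarization = "x", wavelength = lambda,
      mediumIndex = n, incident = 1 + 0i, extras = list())
}

planeWave <- function(thetaDeg, N = 128, px = 0.05, n = 1.37,
                      lambda = 0.550) {
  kx <- 2 * pi * n / lambda * sin(thetaDeg * pi / 180)
  m <- round(kx * N * px / (2 * pi))       # snap to a periodic grid mode
  kx <- 2 * pi * m / (N * px)
  outer(exp(1i * kx * (0:(N - 1)) * px), rep(1 + 0i, N))
}

test_that("NA filter passes the axis and rejects beyond the aperture cone", {
  img <- imagingConfig()
  expect_equal(naCutoffAngle(img), asin(0.15) * 180 / pi)
  f0 <- mkField(planeWave(0))
  expect_equal(angularSpectrumFilter(f0, img)@Ex, f0@Ex, tolerance = 1e-12)
  f10 <- mkField(planeWave(10))              # beyond the 8.6 degree cutoff
  expect_lt(max(Mod(angularSpectrumFilter(f10, img)@Ex)), 1e-12)
  # superposition: only the on-axis component survives, with its energy
  fs <- mkField(planeWave(0) + planeWave(10))
  g <- angularSpectrumFilter(fs, img)
  expect_equal(g@Ex, planeWave(0), tolerance = 1e-12)
  expect_equal(sum(Mod(g@Ex)^2) / sum(Mod(fs@Ex)^2), 0.5, tolerance = 1e-12)
})

test_that("NA filter is idempotent and never increases energy", {
  img <- imagingConfig()
  set.seed(1)
  f <- mkField(matrix(complex(real = rnorm(64^2), imaginary = rnorm(64^2)),
                      64, 64))
  g1 <- angularSpectrumFilter(f, img)
  g2 <- angularSpectrumFilter(g1, img)
  expect_equal(g2@Ex, g1@Ex, tolerance = 1e-12)
  expect_lte(sum(Mod(g1@Ex)^2), sum(Mod(f@Ex)^2))
})

test_that("detector intensity conserves flux and averages over the lens", {
  img <- imagingConfig()
  # uniform amplitude A -> uniform intensity A^2
  u <- mkField(matrix(2 + 0i, 64, 64))
  Iu <- detectorIntensity(u, img)
  expect_equal(range(gridValues(Iu)), c(4, 4), tolerance = 1e-12)
  # delta -> disc of the microlens footprint with conserved total flux
  d <- mkField(matrix(complex(real = 0), 64, 64))
  d@Ex[32, 32] <- 1
  Id <- gridValues(detectorIntensity(d, img))
  expect_equal(sum(Id), 1, tolerance = 1e-9)
  lit <- Id > 1e-15
  rad <- sqrt(outer((1:64 - 32)^2, (1:64 - 32)^2, `+`)) * 0.05
  expect_true(all(rad[lit] <= img@microlensDiameter / 2 + 0.05 * 1.5))
  # short-period fringe: contrast suppressed toward the discrete kernel
  # response (oracle: mean of the cosine over the disc mask)
  N <- 128; px <- 0.05
  kx <- 2 * pi * 16 / (N * px)                # period 0.4 um << 1.33 um
  f <- mkField(outer(sqrt(1 + cos(kx * (0:(N - 1)) * px)) + 0i,
                     rep(1 + 0i, N)))
  If <- gridValues(detectorIntensity(f, img))
  off <- ((-13):13) * px
  mask <- outer(off^2, off^2, `+`) <= (img@microlensDiameter / 2)^2
  resp <- sum(cos(kx * off) * rowSums(mask)) / sum(mask)
  got <- (max(If[, 64]) - min(If[, 64])) / mean(If[, 64])
  expect_equal(got, 2 * abs(resp), tolerance = 1e-6)
})

test_that("diattenuation map implements the two-run contrast", {
  mkI <- function(v) new("IntensityImage", values = v, pixelSize = 1,
                         polarization = "x")
  Ix <- mkI(matrix(3, 4, 4)); Iy <- mkI(matrix(1, 4, 4))
  m <- diattenuationMap(Ix, Iy)
  expect_true(all(gridValues(m) == 0.5))
  # antisymmetry under swapping the runs
  expect_equal(gridValues(diattenuationMap(Iy, Ix)), -gridValues(m))
  # equality -> zero
  expect_true(all(gridValues(diattenuationMap(Ix, Ix)) == 0))
  # zero-sum pixels are masked and counted
  Iz <- mkI(matrix(0, 4, 4))
  mz <- diattenuationMap(Iz, Iz)
  expect_equal(mz@maskedCount, 16L)
  expect_true(all(is.na(gridValues(mz))))
  # bounded by construction
  set.seed(2)
  r1 <- mkI(matrix(runif(64), 8, 8)); r2 <- mkI(matrix(runif(64), 8, 8))
  expect_true(all(abs(gridValues(diattenuationMap(r1, r2))) <= 1))
})

test_that("map summary statistics agree with an independent two-pass oracle", {
  mkMap <- function(v) new("DiattenuationMap", values = v, pixelSize = 0.1,
                           maskedCount = 0L)
  s <- summarizeMap(mkMap(matrix(0.3, 5, 5)))
  expect_equal(s$mean, 0.3); expect_equal(s$sd, 0)
  two <- summarizeMap(mkMap(matrix(c(-0.2, 0.2), 10, 10)))
  expect_equal(two$mean, 0, tolerance = 1e-14)
  expect_equal(two$sd, 0.2 * sqrt(100 / 99), tolerance = 1e-12)
  set.seed(3)
  v <- matrix(runif(400, -1, 1), 20, 20)
  s3 <- summarizeMap(mkMap(v))
  mu <- sum(v) / 400
  expect_equal(s3$mean, mu, tolerance = 1e-12)
  expect_equal(s3$sd, sqrt(sum((v - mu)^2) / 399), tolerance = 1e-12)
  expect_equal(sum(s3$histogram$counts), 400)
  # margin exclusion drops the border
  sm <- summarizeMap(mkMap(v), marginUm = 0.1)
  expect_equal(sm$n, 18 * 18)
  expect_error(summarizeMap(mkMap(v), mask = matrix(FALSE, 20, 20)), "empty")
})
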