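test_that("stable time step follows the Courant bound", {
  cLight <- 299792458
  expect_equal(stableTimeStep(fdtdConfig()),
               0.8 * 25e-9 / (cLight * sqrt(3)), tolerance = 1e-12)
  c2 <- fdtdConfig(dimensionality = "2D-TM")
  expect_equal(stableTimeStep(c2) / stableTimeStep(fdtdConfig()),
               sqrt(3) / sqrt(2), tolerance = 1e-12)
  expect_equal(stableTimeStep(fdtdConfig(courantFactor = 1e-6)) /
                 stableTimeStep(fdtdConfig(courantFactor = 0.5)), 2e-6,
               tolerance = 1e-9)
})

test_that("monochromatic extraction projects out the source frequency", {
  lambda <- 550; period <- 0.550
  times <- seq(0, 4 * period, length.out = 401)[-401]
  omega <- 2 * pi / 0.550
  # pure cosine at the source frequency: amplitude 1, phase 0
  z <- extractMonochromaticField(cos(omega * times), times, lambda)
  expect_equal(Mod(z), 1, tolerance = 1e-10)
  expect_equal(Arg(z), 0, tolerance = 1e-10)
  # second harmonic projects to (near) zero
  z2 <- extractMonochromaticField(cos(2 * omega * times), times, lambda)
  expect_lt(Mod(z2), 1e-10)
  # white noise: amplitude error within 3 sigma / sqrt(N)
  set.seed(4)
  zn <- extractMonochromaticField(cos(omega * times) +
                                    rnorm(length(times), sd = 0.01),
                                  times, lambda)
  expect_lt(abs(Mod(zn) - 1), 3 * 0.01 / sqrt(length(times) / 2))
  expect_error(extractMonochromaticField(cos(omega * times[1:100]),
                                         times[1:100], lambda), "periods")
})

test_that("slab transmittance matches the analytic thin-film formula", {
  n1 <- 1.37; n2 <- 1.47; d <- 1.0; lambda <- 0.550
  Tana <- airyTransmittance(n1, n2, d, lambda)
  vol <- refractiveIndexVolume(matrix(n2, 8, 40), 0.025)
  for (mode in c("2D-TM", "2D-TE")) {
    cfg <- fdtdConfig(nPeriods = 60, dimensionality = mode)
    f <- runFDTD(vol, cfg, padIndex = n1)
    Tf <- fieldTransmittance(f)
    Rf <- fieldReflectance(f)
    expect_lt(abs(Tf - Tana) / Tana, 0.01)
    # energy accounting for the lossless stack
    expect_lt(abs(Tf + Rf - 1), 0.02)
  }
})

test_that("slab error decreases monotonically under mesh refinement", {
  n1 <- 1.37; n2 <- 1.47; lambda <- 0.550
  Tana <- airyTransmittance(n1, n2, 1.0, lambda)
  errAt <- function(meshNm) {
    dx <- meshNm * 1e-3
    vol <- refractiveIndexVolume(matrix(n2, 4, round(1 / dx)), dx)
    cfg <- fdtdConfig(meshSize = meshNm, nPeriods = 60,
                      dimensionality = "2D-TM")
    f <- suppressWarnings(runFDTD(vol, cfg, padIndex = n1))
    abs(fieldTransmittance(f) - Tana)
  }
  errs <- vapply(c(50, 25, 12.5), errAt, 0)
  expect_true(all(diff(errs) < 0))
})

test_that("cylinder scattering matches the analytic series solution", {
  n1 <- 1.37; n2 <- 1.47; a <- 0.5; lambda <- 0.550; dx <- 0.025
  vol <- cylinderVolume2D(a, n1, n2, extentUm = 8, dx = dx)
  cfg <- fdtdConfig(nPeriods = 60, dimensionality = "2D-TM",
                    lateralBoundary = "pml")
  f <- runFDTD(vol, cfg, padIndex = n1, tfsf = "box", boxHalfUm = 1.5)
  ph <- f@extras$domainPhasor
  lay <- f@extras$layout
  nxs <- dim(gridValues(vol))[1]
  # the staircased cylinder seen by the out-of-plane E nodes is centred
  # half a cell below the voxel-centre origin
  ic <- lay$xpad + nxs / 2 - 0.5
  kc <- lay$k0 + nxs / 2 - 0.5
  th <- seq(0, 2 * pi, length.out = 73)[-73]
  ii <- round(ic + 3.0 * sin(th) / dx)
  kk <- round(kc + 3.0 * cos(th) / dx)
  rex <- sqrt((ii - ic)^2 + (kk - kc)^2) * dx
  thex <- atan2(ii - ic, kk - kc)
  sim <- Mod(ph[cbind(ii + 1, kk + 1)]) / Mod(f@incident)
  ana <- Mod(mapply(function(r, t)
    cylinderScatteredField(r, t, a, n1, n2, lambda), rex, thex))
  main <- ana > 0.5 * max(ana)
  expect_lt(max(abs(sim - ana)[main] / ana[main]), 0.05)
})

test_that("homogeneous media transmit the plane wave unchanged", {
  vol <- refractiveIndexVolume(matrix(1.37, 8, 30), 0.025)
  f <- runFDTD(vol, fdtdConfig(nPeriods = 50, dimensionality = "2D-TM"),
               padIndex = 1.37)
  expect_lt(abs(fieldTransmittance(f) - 1), 0.01)
  expect_lt(fieldReflectance(f), 1e-4)
  # uniform exit field
  amp <- Mod(f@Ey)
  expect_lt(diff(range(amp)) / mean(amp), 1e-6)
})

test_that("instability and invalid media are rejected", {
  vol <- refractiveIndexVolume(matrix(1.37, 8, 30), 0.025)
  expect_error(refractiveIndexVolume(matrix(0.5, 8, 30), 0.025), ">= 1")
  bad <- fdtdConfig(nPeriods = 50, dimensionality = "2D-TM")
  bad@courantFactor <- 2.5     # far beyond the stability bound; bypasses validation
  expect_error(runFDTD(vol, bad, padIndex = 1.37), "instability")
})

test_that("mirror symmetry swaps the two polarised runs exactly", {
  # x <-> y mirrored volume with swapped polarisation gives the transposed
  # intensity pattern (discrete scheme symmetry, so equality is exact)
  set.seed(6)
  nx <- 12
  vals <- array(1.37, c(nx, nx, 30))
  blob <- array(runif(nx * nx * 10) < 0.2, c(nx, nx, 10))
  vals[, , 11:20][blob] <- 1.47
  volA <- refractiveIndexVolume(vals, 0.05)
  volB <- refractiveIndexVolume(aperm(vals, c(2, 1, 3)), 0.05)
  cfg <- fdtdConfig(meshSize = 50, nPeriods = 40)
  cfgx <- cfg; cfgx@polarizationAxis <- "x"
  cfgy <- cfg; cfgy@polarizationAxis <- "y"
  fx <- suppressWarnings(runFDTD(volA, cfgx, padIndex = 1.37))
  fy <- suppressWarnings(runFDTD(volB, cfgy, padIndex = 1.37))
  Ix <- Mod(fx@Ex)^2 + Mod(fx@Ey)^2
  Iy <- Mod(fy@Ex)^2 + Mod(fy@Ey)^2
  expect_equal(Ix, t(Iy), tolerance = 1e-10)
})
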