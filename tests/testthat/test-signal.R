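rho <- seq(0, 170, by = 10)

seriesFrom <- function(I, dims = c(2, 2), modality = "DI") {
  rotationSeries(array(rep(I, each = prod(dims)), c(dims, length(I))),
                 modality = modality)
}

test_that("harmonic Fourier analysis is exact for 0th/2nd-harmonic signals", {
  cf <- fourierCoefficients(seriesFrom(rep(5, 18)))
  expect_equal(cf@a0[1, 1], 5, tolerance = 1e-14)
  expect_equal(cf@a2[1, 1], 0, tolerance = 1e-14)
  expect_equal(cf@b2[1, 1], 0, tolerance = 1e-14)

  cf2 <- fourierCoefficients(seriesFrom(1 + 0.1 * cos(2 * rho * pi / 180)))
  expect_equal(cf2@a0[1, 1], 1, tolerance = 1e-14)
  expect_equal(cf2@a2[1, 1], 0.1, tolerance = 1e-14)
  expect_equal(cf2@b2[1, 1], 0, tolerance = 1e-14)

  # trigonometric-identity oracle: 2 + 0.3 sin(2 (rho - 30deg)) expands to
  # a2 = -0.3 sin(60deg), b2 = 0.3 cos(60deg)
  cf3 <- fourierCoefficients(seriesFrom(
    2 + 0.3 * sin(2 * (rho - 30) * pi / 180)))
  expect_equal(cf3@a2[1, 1], -0.3 * sin(60 * pi / 180), tolerance = 1e-12)
  expect_equal(cf3@b2[1, 1], 0.3 * cos(60 * pi / 180), tolerance = 1e-12)
})

test_that("birefringence-signal parameters follow the arctangent form", {
  mk <- function(a0, a2, b2)
    new("FourierCoefficients", a0 = matrix(a0), a2 = matrix(a2),
        b2 = matrix(b2), modality = "PLI")
  expect_equal(pliParameters(mk(1, 0, 0.5))$phiP[1, 1], 0)
  expect_equal(pliParameters(mk(1, -0.3, 0))$phiP[1, 1], 45)
  p <- pliParameters(mk(2, 0.1, 0.2))
  expect_equal(p$sinDelta[1, 1], sqrt(0.01 + 0.04) / 2, tolerance = 1e-14)
  expect_equal(p$transmittance[1, 1], 2)
  expect_true(is.na(pliParameters(mk(0, 0.1, 0.2))$phiP[1, 1]))
})

test_that("diattenuation parameters invert the forward signal", {
  I <- 1 * (1 + 0.05 * cos(2 * (rho - 70) * pi / 180))
  d <- diattenuationParameters(fourierCoefficients(seriesFrom(I)))
  expect_equal(d$strength[1, 1], 0.05, tolerance = 1e-12)
  expect_equal(d$phiD[1, 1], 70, tolerance = 1e-10)
  # scale invariance
  d2 <- diattenuationParameters(fourierCoefficients(seriesFrom(2 * I)))
  expect_equal(d2$strength[1, 1], d$strength[1, 1], tolerance = 1e-12)
  expect_equal(d2$phiD[1, 1], d$phiD[1, 1], tolerance = 1e-10)
  # vanishing second harmonic: strength 0, phase masked
  d0 <- diattenuationParameters(fourierCoefficients(seriesFrom(rep(3, 18))))
  expect_equal(d0$strength[1, 1], 0)
  expect_true(is.na(d0$phiD[1, 1]))
})

test_that("extremal-intensity form agrees with the Fourier form", {
  expect_equal(diattenuationFromExtrema(3, 1), 0.5)
  expect_equal(diattenuationFromExtrema(2, 2), 0)
  expect_equal(diattenuationFromExtrema(5, 0), 1)
  expect_error(diattenuationFromExtrema(1, 2))
  # for a pure second-harmonic signal the two routes are identical: here
  # the 18-angle grid contains the exact extrema (phase a multiple of 10)
  I <- 4 * (1 + 0.07 * cos(2 * (rho - 110) * pi / 180))
  dF <- diattenuationParameters(fourierCoefficients(seriesFrom(I)))
  expect_equal(diattenuationFromExtrema(max(I), min(I)),
               dF$strength[1, 1], tolerance = 1e-12)
})

test_that("phase-difference classification uses the two 20-degree bands", {
  expect_equal(classifyDiattenuation(30, 30), "D+")
  expect_equal(classifyDiattenuation(30, 120), "D-")
  expect_equal(classifyDiattenuation(30, 75), "unclassified")
  # inclusive band edges
  expect_equal(classifyDiattenuation(0, 20), "D+")
  expect_equal(classifyDiattenuation(0, 70), "D-")
  expect_equal(classifyDiattenuation(0, 110 - 180), "D-")
  expect_equal(classifyDiattenuation(0, 21), "unclassified")
  # 180-degree periodicity of direction angles
  for (dphi in c(0, 45, 90, 130)) {
    expect_equal(classifyDiattenuation(10, 10 + dphi),
                 classifyDiattenuation(10, 10 + dphi + 180))
    expect_equal(classifyDiattenuation(10, 10 + dphi),
                 classifyDiattenuation(10 + 180, 10 + dphi))
  }
  expect_equal(classifyDiattenuation(NA_real_, 30), "unclassified")
})

test_that("coloured map rendering follows the classification", {
  n <- 4
  res <- new("DIResult",
             phiP = matrix(0, n, n), phiD = matrix(0, n, n),
             strength = matrix(0.5, n, n), sinDelta = matrix(0, n, n),
             transmittance = matrix(1, n, n),
             label = matrix("D+", n, n))
  img <- renderDIMap(res, clipPercentile = 1)
  expect_true(all(img[, , 2] > 0))
  expect_true(all(img[, , c(1, 3)] == 0))

  res@label <- matrix("unclassified", n, n)
  expect_true(all(renderDIMap(res) == 0))

  chk <- matrix(c("D+", "D-"), n, n)         # column-wise checkerboard
  res@label <- chk
  img <- renderDIMap(res, clipPercentile = 1)
  expect_true(all((img[, , 2] > 0) == (chk == "D+")))
  expect_true(all((img[, , 1] > 0) == (chk == "D-")))
  expect_true(all(img[, , 1] == img[, , 3]))
})

test_that("series validation catches missing angles and bad stacks", {
  expect_error(rotationSeries(array(1, c(2, 2, 17))), "angles")
  expect_error(analyzeSeries(di = rotationSeries(array(1, c(2, 2, 9)),
                                                 angles = seq(0, 160, 20))),
               "missing: 10")
})
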