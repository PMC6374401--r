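test_that("retardation follows the cos^2 law", {
  p <- opticalTissueParams(wavelength = 525, thickness = 60,
                           birefringence = 1e-3)
  expect_equal(retardationDeltaP(90, p), 0, tolerance = 1e-12)
  expect_equal(retardationDeltaP(0, p) / retardationDeltaP(60, p), 4,
               tolerance = 1e-12)
  # independent re-evaluation at 30 degrees
  expect_equal(retardationDeltaP(30, p),
               2 * pi / 0.525 * 60 * 1e-3 * cos(pi / 6)^2,
               tolerance = 1e-12)
  a <- seq(0, 90, by = 5)
  expect_true(all(diff(retardationDeltaP(a, p)) <= 0))
})

test_that("dichroism model evaluates, decays and vanishes as expected", {
  p <- opticalTissueParams()
  expect_equal(dichroismDK(0, p), tanh(0.05), tolerance = 1e-12)
  expect_lt(abs(dichroismDK(90, p)), 1e-30)
  pz <- opticalTissueParams(deltaKappa = 0)
  expect_true(all(dichroismDK(seq(0, 90, 10), pz) == 0))
  a <- seq(0, 90, by = 5)
  v <- dichroismDK(a, p)
  expect_true(all(diff(v) < 0))
  expect_true(all(v >= 0 & v < 1))
})

test_that("dichroism matches its first-order expansion for small arguments", {
  p <- opticalTissueParams()   # argument 0.05 at alpha = 0: small
  a <- seq(0, 80, by = 10)
  lin <- -(2 * pi / (p@wavelength * 1e-3)) * p@thickness * p@deltaKappa *
    cos(a * pi / 180)^2
  expect_true(all(abs(dichroismDK(a, p) - lin) / lin < 0.01))
})

test_that("dichroism is even in cos(alpha)", {
  p <- opticalTissueParams(deltaKappa = -2e-4)
  # cos^2 is unchanged under alpha -> 180 - alpha; within [0, 90] check
  # symmetry of the argument against direct evaluation with |cos|
  a <- c(10, 45, 70)
  expect_equal(dichroismDK(a, p),
               tanh(-(2 * pi / (p@wavelength * 1e-3)) * p@thickness *
                      p@deltaKappa * abs(cos(a * pi / 180))^2),
               tolerance = 1e-14)
})

test_that("diattenuation type prediction combines the two mechanisms", {
  a <- seq(0, 90, by = 15)
  dkPos <- inclinationCurve(a, rep(0.04, length(a)), "DK")
  zero <- inclinationCurve(a, rep(0, length(a)), "DS")
  expect_true(all(predictType(dkPos, zero) == "D+"))
  # steep-fibre regime: both positive -> D+
  dk <- inclinationCurve(c(70, 75, 80), dichroismDK(c(70, 75, 80)), "DK")
  ds <- inclinationCurve(c(70, 75, 80), c(0.01, 0.02, 0.03), "DS")
  expect_true(all(predictType(dk, ds) == "D+"))
  # negative scattering dominating -> D-
  dsNeg <- inclinationCurve(a, rep(-0.2, length(a)), "DS")
  expect_true(all(predictType(dkPos, dsNeg) == "D-"))
  # exact tie -> mixed; both tiny -> near-zero
  tie <- predictType(inclinationCurve(c(0, 45), c(0.1, 0.1)),
                     inclinationCurve(c(0, 45), c(-0.1, -0.1)))
  expect_true(all(tie == "mixed"))
  nz <- predictType(inclinationCurve(90, 1e-5), inclinationCurve(90, -1e-5))
  expect_equal(nz, "near-zero")
  expect_error(predictType(inclinationCurve(c(0, 10), c(0, 0)),
                           inclinationCurve(c(0, 20), c(0, 0))),
               "alpha grid")
})
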