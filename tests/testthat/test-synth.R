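test_that("noiseless generation followed by analysis is the identity", {
  sc <- phantomScene(phi = 70, delta = 0.9, strength = 0.05, dims = c(3, 3))
  di <- generateSeries(sc, "DI")
  d <- diattenuationParameters(fourierCoefficients(di))
  expect_equal(max(abs(d$strength - 0.05)), 0, tolerance = 1e-12)
  expect_equal(max(abs(d$phiD - 70)), 0, tolerance = 1e-9)

  pli <- generateSeries(sc, "PLI")
  p <- pliParameters(fourierCoefficients(pli))
  expect_equal(max(abs(p$phiP - 70)), 0, tolerance = 1e-9)
  expect_equal(max(abs(p$sinDelta - sin(0.9))), 0, tolerance = 1e-12)

  # zero diattenuation: constant series
  s0 <- generateSeries(phantomScene(phi = 0, delta = 0, strength = 0,
                                    dims = c(2, 2)), "DI")
  expect_equal(diff(range(s0@data)), 0)

  # perpendicular mode shifts the diattenuation phase by 90 degrees
  scp <- phantomScene(phi = 70, delta = 0, strength = 0.05,
                      mode = "perpendicular", dims = c(2, 2))
  dp <- diattenuationParameters(fourierCoefficients(generateSeries(scp, "DI")))
  expect_equal(dp$phiD[1, 1], 160, tolerance = 1e-9)
})

test_that("generation is deterministic per seed", {
  mk <- function() generateSeries(
    phantomScene(phi = 10, delta = 0.5, strength = 0.03,
                 noise = list(type = "gaussian", sigma = 0.05),
                 repeats = 5L, seed = 42L, dims = c(4, 4)), "DI")
  expect_identical(mk()@data, mk()@data)
})

test_that("recovered strength noise matches linear error propagation", {
  # additive sigma per exposure, averaged over R repeats: the projection
  # noise on each 2nd-harmonic coefficient has sd sigma sqrt(2/N) / sqrt(R),
  # which is the sd of |D| when the signal dominates the noise
  sigma <- 0.01; reps <- 20L; N <- 18
  sc <- phantomScene(phi = 70, delta = 0, strength = 0.05, baseline = 1,
                     noise = list(type = "gaussian", sigma = sigma),
                     repeats = reps, seed = 3L, dims = c(32, 32))
  d <- diattenuationParameters(fourierCoefficients(generateSeries(sc, "DI")))
  predicted <- sigma * sqrt(2 / N) / sqrt(reps)
  expect_lt(abs(sd(d$strength) - predicted) / predicted, 0.2)
})

test_that("averaging repeats reduces coefficient noise as 1/sqrt(R)", {
  sdFor <- function(reps, seed) {
    sc <- phantomScene(phi = 70, delta = 0, strength = 0.05,
                       noise = list(type = "gaussian", sigma = 0.02),
                       repeats = reps, seed = seed, dims = c(24, 24))
    sd(diattenuationParameters(
      fourierCoefficients(generateSeries(sc, "DI")))$strength)
  }
  for (seed in 1:3) {
    r1 <- sdFor(1L, seed); r5 <- sdFor(5L, seed); r20 <- sdFor(20L, seed)
    expect_lt(abs(r1 / r5 - sqrt(5)) / sqrt(5), 0.25)
    expect_lt(abs(r1 / r20 - sqrt(20)) / sqrt(20), 0.25)
  }
})

test_that("two-region phantom classifies exactly under noiseless analysis", {
  ph <- makePhantom("two-region", dims = c(8, 8), phi = 30, delta = 0.8,
                    strength = 0.05)
  res <- analyzeSeries(pli = generateSeries(ph, "PLI"),
                       di = generateSeries(ph, "DI"))
  expect_true(all(res@label[, 1:4] == "D+"))
  expect_true(all(res@label[, 5:8] == "D-"))
})

test_that("inclination-ramp phantom returns the canonical dichroism curve", {
  ph <- makePhantom("inclination-ramp", dims = c(2, 19))
  alpha <- attr(ph, "alpha")
  d <- diattenuationParameters(fourierCoefficients(generateSeries(ph, "DI")))
  expect_equal(max(abs(d$strength[1, ] - tanh(0.05 * cos(alpha * pi / 180)^2))),
               0, tolerance = 1e-6)
})

test_that("poisson shot noise is unbiased at high counts", {
  sc <- phantomScene(phi = 0, delta = 0, strength = 0, baseline = 100,
                     noise = list(type = "poisson", scale = 50),
                     repeats = 20L, seed = 9L, dims = c(16, 16))
  s <- generateSeries(sc, "DI")
  expect_lt(abs(mean(s@data) - 100) / 100, 0.01)
})
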