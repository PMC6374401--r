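smallSpec <- function(seed = 1L, d = 1, nf = 10L, area = c(10, 8),
                      len = 25) {
  fiberBundleSpec(nFibers = nf, seedArea = area, maxDisplacement = d,
                  fiberLength = len, seed = seed)
}

test_that("zero displacement gives straight, parallel, collision-free fibres", {
  b <- generateFiberBundle(smallSpec(d = 0))
  expect_equal(modeAngleDifference(b), 0.5)   # all angles in the first bin
  expect_true(all(segmentAngles(b) < 1e-9))
  expect_equal(predominantOrientation(b), c(1, 0, 0), tolerance = 1e-12)
  expect_equal(countCollisions(b), 0L)
})

test_that("small bundles are collision-free by the independent R oracle", {
  b <- generateFiberBundle(smallSpec(seed = 3L))
  expect_equal(collisionsR(b), 0L)
  o <- bruteForceCollisions(b)
  expect_equal(o$count, 0)
  expect_gte(o$minClearance, -1e-9)
})

test_that("generation is deterministic given the spec seed", {
  b1 <- generateFiberBundle(smallSpec(seed = 7L))
  b2 <- generateFiberBundle(smallSpec(seed = 7L))
  expect_identical(fiberPoints(b1), fiberPoints(b2))
  expect_identical(fiberRadii(b1), fiberRadii(b2))
})

test_that("segment lengths and adjacent angles respect the spec bounds", {
  for (seed in 1:2) {
    b <- generateFiberBundle(smallSpec(seed = seed, d = 10, nf = 15L))
    lens <- unlist(lapply(fiberPoints(b),
                          function(p) sqrt(rowSums(diff(p)^2))))
    expect_true(all(lens >= 2 - 1e-6 & lens <= 5 + 1e-6))
    expect_lte(maxAdjacentAngle(b), 20 + 1e-6)
    expect_equal(countCollisions(b), 0L)
  }
})

test_that("orientation dispersion grows with the displacement amplitude", {
  for (seed in 1:5) {
    modes <- vapply(c(0, 1, 10), function(d)
      modeAngleDifference(generateFiberBundle(
        smallSpec(seed = seed, d = d, nf = 20L, area = c(12, 9)))), 0)
    expect_true(all(diff(modes) >= 0))
  }
})

test_that("collision resolution separates overlapping parallel fibres", {
  spec <- smallSpec(nf = 2L, d = 0)
  p1 <- cbind(seq(-6, 6, by = 3), 0, 0)
  # no contact: separation exceeds the radius sum
  far <- new("FiberBundle",
             points = list(p1, cbind(seq(-6, 6, by = 3), 2.5, 0)),
             radii = c(0.6, 0.6), predominantOrientation = c(1, 0, 0),
             inclination = 0, boundingVolume = matrix(numeric(0), 0, 0),
             spec = spec)
  expect_equal(countCollisions(far), 0L)
  kept <- resolveCollisions(far)
  expect_equal(kept@points[[1]], unname(p1), tolerance = 1e-12)

  # overlapping: axis separation 0.5 < r1 + r2 = 1.2; the pair must be
  # pushed apart along the closest-approach line (here the y axis) to at
  # least the radius sum
  over <- new("FiberBundle",
              points = list(p1, cbind(seq(-6, 6, by = 3), 0.5, 0)),
              radii = c(0.6, 0.6), predominantOrientation = c(1, 0, 0),
              inclination = 0, boundingVolume = matrix(numeric(0), 0, 0),
              spec = spec)
  expect_gt(countCollisions(over), 0L)
  sep <- resolveCollisions(over)
  expect_equal(countCollisions(sep), 0L)
  o <- bruteForceCollisions(sep)
  expect_gte(o$minClearance, -1e-9)
  # motion is transverse: x extents barely change
  expect_lt(abs(mean(sep@points[[1]][, 3])), 0.2)
})

test_that("rotation and cropping behave geometrically", {
  b <- generateFiberBundle(smallSpec(seed = 2L, d = 0, len = 60))
  # identity at zero rotation with a generous box
  big <- rotateAndCrop(b, 0, volume = c(200, 200, 200))
  expect_equal(do.call(rbind, fiberPoints(big)),
               do.call(rbind, fiberPoints(b)), tolerance = 1e-9)
  # quarter turn maps the x axis onto z
  q <- rotateAndCrop(b, 90, volume = c(100, 100, 100))
  expect_equal(abs(predominantOrientation(q)[3]), 1, tolerance = 1e-9)
  expect_equal(inclination(q), 90)
  # a centred straight fibre clipped at 45 degrees ends on the box faces
  one <- new("FiberBundle", points = list(cbind(seq(-30, 30, 5), 0, 0)),
             radii = 0.5, predominantOrientation = c(1, 0, 0),
             inclination = 0, boundingVolume = matrix(numeric(0), 0, 0),
             spec = smallSpec(nf = 1L))
  cr <- rotateAndCrop(one, 45, volume = c(10, 10, 10))
  pts <- fiberPoints(cr)[[1]]
  ends <- pts[c(1, nrow(pts)), ]
  expect_true(all(apply(abs(abs(ends) - 5) < 1e-9, 1, any)))
  expect_true(all(pts >= -5 - 1e-9 & pts <= 5 + 1e-9))
  # empty crop errors
  expect_error(rotateAndCrop(far <- new("FiberBundle",
    points = list(cbind(c(50, 55), 50, 50)), radii = 0.5,
    predominantOrientation = c(1, 0, 0), inclination = 0,
    boundingVolume = matrix(numeric(0), 0, 0), spec = smallSpec(nf = 1L)),
    0, volume = c(10, 10, 10)), "empty")
})

test_that("mode angle difference uses 1-degree bins with low-tie rule", {
  # hand-built fibre with segment angles 10.2, 10.4 and 40 degrees to x
  mkseg <- function(angles) {
    p <- matrix(0, length(angles) + 1, 3)
    for (i in seq_along(angles)) {
      a <- angles[i] * pi / 180
      p[i + 1, ] <- p[i, ] + 3 * c(cos(a), sin(a), 0)
    }
    p
  }
  b <- new("FiberBundle", points = list(mkseg(c(10.2, 10.4, 40))),
           radii = 0.5, predominantOrientation = c(1, 0, 0),
           inclination = 0, boundingVolume = matrix(numeric(0), 0, 0),
           spec = smallSpec(nf = 1L))
  expect_equal(modeAngleDifference(b), 10.5)
  # tie between two bins resolves to the lower angle
  b2 <- b; b2@points <- list(mkseg(c(10.2, 40.7)))
  expect_equal(modeAngleDifference(b2), 10.5)
})

test_that("mode angle difference is rotation invariant up to cropping", {
  b <- generateFiberBundle(smallSpec(seed = 5L, d = 1, nf = 12L))
  m0 <- modeAngleDifference(b)
  m45 <- modeAngleDifference(rotateAndCrop(b, 45, volume = c(300, 300, 300)))
  expect_equal(m45, m0)
})

test_that("bundle JSON serialization round-trips", {
  b <- generateFiberBundle(smallSpec(seed = 4L, nf = 3L))
  path <- tempfile(fileext = ".json")
  writeBundleJSON(b, path)
  b2 <- readBundleJSON(path)
  expect_equal(fiberPoints(b2), lapply(fiberPoints(b), unname),
               tolerance = 1e-12)
  expect_equal(fiberRadii(b2), fiberRadii(b), tolerance = 1e-12)
  expect_equal(predominantOrientation(b2), predominantOrientation(b),
               tolerance = 1e-12)
})
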