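# Independent oracles used across the suite.

# Minimum distance between two 3D segments by numerical optimisation of the
# convex quadratic |P(s) - Q(t)|^2 over the unit square (independent of the
# package's closest-point code).
segDistOracle <- function(p0, p1, q0, q1) {
  f <- function(u) sum(((p0 + u[1] * (p1 - p0)) - (q0 + u[2] * (q1 - q0)))^2)
  o <- stats::optim(c(0.5, 0.5), f, method = "L-BFGS-B",
                    lower = c(0, 0), upper = c(1, 1))
  sqrt(o$value)
}

# All-pairs collision check in plain R (small bundles only).
collisionsR <- function(bundle) {
  pts <- fiberPoints(bundle)
  radii <- fiberRadii(bundle)
  n <- length(pts)
  hits <- 0L
  for (f in seq_len(n)) for (g in f:n) {
    pf <- pts[[f]]; pg <- pts[[g]]
    for (s in seq_len(nrow(pf) - 1)) {
      t0 <- if (g == f) s + 3L else 1L
      if (t0 > nrow(pg) - 1) next
      for (t in t0:(nrow(pg) - 1)) {
        d <- segDistOracle(pf[s, ], pf[s + 1, ], pg[t, ], pg[t + 1, ])
        if (d < radii[f] + radii[g] - 1e-7) hits <- hits + 1L
      }
    }
  }
  hits
}

# Analytic thin-film (Airy) intensity transmittance of a slab n2, thickness
# d, embedded in n1, at normal incidence (same entry and exit medium).
airyTransmittance <- function(n1, n2, d, lambda) {
  r12 <- (n1 - n2) / (n1 + n2)
  t12 <- 2 * n1 / (n1 + n2)
  t21 <- 2 * n2 / (n1 + n2)
  ph <- exp(1i * 2 * pi * n2 * d / lambda)
  Mod(t12 * t21 * ph / (1 - r12^2 * ph^2))^2
}

# Analytic scattered field of a plane wave on an infinite dielectric
# cylinder (E parallel to the axis), exp(-i w t) convention: series in
# Bessel/Hankel functions, evaluated outside the cylinder.
cylinderScatteredField <- function(r, theta, a, n1, n2, lambda) {
  k1 <- 2 * pi * n1 / lambda
  k2 <- 2 * pi * n2 / lambda
  M <- ceiling(k1 * a + 12)
  H <- function(m, x) besselJ(x, m) + 1i * besselY(x, m)
  Jd <- function(m, x) besselJ(x, m - 1) - m / x * besselJ(x, m)
  Hd <- function(m, x) (besselJ(x, m - 1) + 1i * besselY(x, m - 1)) -
    m / x * H(m, x)
  Es <- 0
  for (m in -M:M) {
    bm <- (k2 * Jd(m, k2 * a) * besselJ(k1 * a, m) -
             k1 * besselJ(k2 * a, m) * Jd(m, k1 * a)) /
      (k1 * besselJ(k2 * a, m) * Hd(m, k1 * a) -
         k2 * Jd(m, k2 * a) * H(m, k1 * a))
    Es <- Es + (1i)^m * bm * H(m, k1 * r) * exp(1i * m * theta)
  }
  Es
}

# Build a 2D cross-section volume of a dielectric cylinder centred on the
# grid (axis out of plane).
cylinderVolume2D <- function(a, n1, n2, extentUm, dx) {
  n <- round(extentUm / dx)
  cs <- ((1:n) - 0.5 - n / 2) * dx
  vals <- matrix(n1, n, n)
  vals[sqrt(outer(cs^2, cs^2, `+`)) <= a] <- n2
  refractiveIndexVolume(vals, dx)
}
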