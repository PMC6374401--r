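# Generation of dense, collision-free fibre bundles.
#
# Fibres start as straight x-aligned polylines whose cross-sections are
# packed free of overlap, are divided into random segments and perturbed by
# per-segment random displacements, and are then iteratively repaired:
# segments split or merged until every length is back in range and
# adjacent-segment angles are below the bound, and colliding segment pairs
# pushed apart along their line of closest approach until no collisions
# remain.

withSeed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

# Force-biased 2D packing of the seed circles: overlapping pairs are pushed
# apart along their centre line until the straight seed fibres are disjoint
# in cross-section (a small gap eases the later 3D resolution).
packSeedCircles <- function(yz, radii, gapFrac = 0.06, maxIter = 6000L) {
  if (nrow(yz) < 2L) return(yz)
  cpp_pack_circles(yz, radii * (1 + gapFrac), as.integer(maxIter))
}

# principal orientation of a set of weighted axial vectors: leading
# eigenvector of the length-weighted orientation tensor, sign-aligned with x
principalOrientation <- function(dirs, weights) {
  M <- crossprod(dirs * sqrt(weights))
  v <- eigen(M, symmetric = TRUE)$vectors[, 1]
  if (v[1] < 0) v <- -v
  v / sqrt(sum(v^2))
}

segmentDirections <- function(points) {
  d <- diff(points)
  len <- sqrt(rowSums(d^2))
  list(dirs = d / len, lengths = len)
}

#' Generate a collision-free fibre bundle
#'
#' Grows \code{nFibers} fibres from the specification: straight x-aligned
#' polylines are seeded over the y-z seed rectangle (their cross-sections
#' packed free of overlap), divided into segments of random length within
#' the segment range, and each segment is assigned a random displacement of
#' up to \code{maxDisplacement} in x, y and z (averaged at shared
#' vertices). The displaced polylines are repaired (split/merge plus angle
#' relaxation) so that segment lengths stay in range and adjacent-segment
#' angles stay below \code{maxAdjacentAngle}, and colliding segment pairs
#' are repeatedly pushed apart along their mutual closest-approach
#' direction until the bundle is collision-free.
#'
#' Displacements at the scale of the packing gap are applied
#' quasi-statically (small increments, each followed by collision
#' resolution), which keeps the dense bundle smooth; displacements beyond
#' the fibre diameter disperse the bundle, and are applied at once and
#' resolved with staged radius growth.
#'
#' The result is deterministic for a given spec (including its seed).
#'
#' @param spec a \linkS4class{FiberBundleSpec}.
#' @param iterationBudget maximum number of repel-and-repair iterations.
#' @return A \linkS4class{FiberBundle} with predominant orientation along x
#'   and zero inclination.
#' @examples
#' b <- generateFiberBundle(fiberBundleSpec(nFibers = 10, seedArea = c(20, 20),
#'                                          fiberLength = 20))
#' modeAngleDifference(b)
#' @export
generateFiberBundle <- function(spec, iterationBudget = 50000L) {
  validObject(spec)
  lmin <- spec@segmentLengthRange[1]
  lmax <- spec@segmentLengthRange[2]
  L <- spec@fiberLength
  d <- spec@maxDisplacement
  gen <- withSeed(spec@seed, {
    radii <- stats::runif(spec@nFibers, spec@radiusRange[1],
                          spec@radiusRange[2])
    yz <- cbind(stats::runif(spec@nFibers, -spec@seedArea[1] / 2,
                             spec@seedArea[1] / 2),
                stats::runif(spec@nFibers, -spec@seedArea[2] / 2,
                             spec@seedArea[2] / 2))
    yz <- packSeedCircles(yz, radii)
    pts <- list(); offs <- list()
    for (f in seq_len(spec@nFibers)) {
      xs <- -L / 2
      repeat {
        nxt <- xs[length(xs)] + stats::runif(1, lmin, lmax)
        if (nxt >= L / 2) { xs <- c(xs, L / 2); break }
        xs <- c(xs, nxt)
      }
      pts[[f]] <- cbind(x = xs, y = yz[f, 1], z = yz[f, 2])
      # one random displacement per segment, averaged at shared vertices,
      # recorded as a piecewise-linear offset function of arclength
      ns <- length(xs) - 1L
      off <- matrix(stats::runif(3 * ns, -d, d), ns, 3)
      offs[[f]] <- list(s = xs + L / 2,
                        u = (rbind(off[1, ], off) + rbind(off, off[ns, ])) / 2)
    }
    list(radii = radii, pts = pts, offs = offs)
  })
  radii <- gen$radii
  pts <- gen$pts
  budget <- as.integer(iterationBudget)
  pack <- function(pts, margin, growth, polish, skin = 0.8) {
    packed <- cpp_pack_bundle(pts, radii, lmin, lmax,
                              spec@maxAdjacentAngle, budget, margin, 2L,
                              growth, polish, skin)
    if (packed$collisions > 0L)
      stop("collision resolution did not converge within ", budget,
           " iterations: ", packed$collisions, " collisions remain")
    packed$points
  }
  if (d == 0) {
    pts <- pack(pts, 0.01, FALSE, 0L)
  } else if (d > 2 * mean(radii)) {
    # a displacement beyond the fibre diameter disperses the bundle and
    # lowers its density: apply it at once and resolve the (then shallow
    # relative to the dispersed spacing) overlaps with radius growth
    pts <- lapply(seq_along(pts), function(f) pts[[f]] + gen$offs[[f]]$u)
    pts <- pack(pts, 0.05, TRUE, 6L, skin = 0.8)
  } else {
    # displacements at the scale of the packing gap are applied
    # quasi-statically: small increments, each followed by a resolution
    # pass, keep the bundle on a near-feasible path and avoid accumulating
    # short-wavelength deformation from violent overlap resolution
    nInc <- max(1L, min(25L, ceiling(d / 0.04)))
    for (k in seq_len(nInc)) {
      pts <- lapply(seq_along(pts), function(f) {
        p <- pts[[f]]
        seg <- sqrt(rowSums(diff(p)^2))
        s <- c(0, cumsum(seg))
        s <- s / s[length(s)] * gen$offs[[f]]$s[length(gen$offs[[f]]$s)]
        u <- apply(gen$offs[[f]]$u, 2, function(col)
          stats::approx(gen$offs[[f]]$s, col, xout = s, rule = 2)$y)
        p + u / nInc
      })
      pts <- pack(pts, 0.01, FALSE, if (k == nInc) 10L else 0L)
    }
  }
  bundleFromPoints(pts, radii, spec)
}

bundleFromPoints <- function(pts, radii, spec, inclination = 0,
                             boundingVolume = matrix(numeric(0), 0, 0)) {
  segs <- lapply(pts, segmentDirections)
  dirs <- do.call(rbind, lapply(segs, `[[`, "dirs"))
  lens <- unlist(lapply(segs, `[[`, "lengths"))
  new("FiberBundle", points = pts, radii = radii,
      predominantOrientation = principalOrientation(dirs, lens),
      inclination = inclination, boundingVolume = boundingVolume,
      spec = spec)
}

#' Resolve collisions in a fibre bundle
#'
#' Applies the repelling-force iteration to a bundle that may contain
#' overlapping segments: each colliding pair is displaced apart along the
#' closest-approach direction by half the overlap plus a small margin, then
#' segment lengths and adjacent angles are repaired, until no collisions
#' remain or the budget is exhausted (an error reporting the remaining
#' collision count).
#'
#' @param bundle a \linkS4class{FiberBundle}, possibly with overlaps.
#' @param iterationBudget maximum iterations.
#' @return A collision-free \linkS4class{FiberBundle}.
#' @export
resolveCollisions <- function(bundle, iterationBudget = 10000L) {
  spec <- bundle@spec
  packed <- cpp_pack_bundle(bundle@points, bundle@radii,
                            spec@segmentLengthRange[1],
                            spec@segmentLengthRange[2],
                            spec@maxAdjacentAngle,
                            as.integer(iterationBudget), 0.05, 2L,
                            TRUE, 2L, 0.8)
  if (packed$collisions > 0L)
    stop("collision resolution did not converge within ", iterationBudget,
         " iterations: ", packed$collisions, " collisions remain")
  bundleFromPoints(packed$points, bundle@radii, spec, bundle@inclination,
                   bundle@boundingVolume)
}

# clip one polyline to an axis-aligned box; returns a list of sub-polylines
clipPolylineToBox <- function(p, lo, hi) {
  out <- list()
  cur <- NULL
  n <- nrow(p)
  for (i in seq_len(n - 1)) {
    a <- p[i, ]; b <- p[i + 1, ]
    d <- b - a
    # Liang-Barsky parametric clipping of segment a + t d, t in [0, 1]
    t0 <- 0; t1 <- 1; ok <- TRUE
    for (ax in 1:3) {
      if (abs(d[ax]) < 1e-14) {
        if (a[ax] < lo[ax] || a[ax] > hi[ax]) { ok <- FALSE; break }
      } else {
        ta <- (lo[ax] - a[ax]) / d[ax]
        tb <- (hi[ax] - a[ax]) / d[ax]
        if (ta > tb) { tmp <- ta; ta <- tb; tb <- tmp }
        t0 <- max(t0, ta); t1 <- min(t1, tb)
        if (t0 > t1) { ok <- FALSE; break }
      }
    }
    if (!ok) { if (!is.null(cur)) { out <- c(out, list(cur)); cur <- NULL }
               next }
    qa <- a + t0 * d; qb <- a + t1 * d
    if (is.null(cur)) cur <- rbind(qa) else if (t0 > 0) {
      out <- c(out, list(cur)); cur <- rbind(qa)
    }
    cur <- rbind(cur, qb)
    if (t1 < 1) { out <- c(out, list(cur)); cur <- NULL }
  }
  if (!is.null(cur)) out <- c(out, list(cur))
  out[vapply(out, nrow, 1L) >= 2L]
}

#' Rotate a bundle about the y axis and crop it to a box
#'
#' Rotates every fibre about the y axis through the bundle centre so that an
#' x-aligned bundle acquires out-of-plane inclination \code{alpha} (90
#' degrees maps the x axis onto z), then clips the fibres to an axis-aligned
#' box centred on the origin.
#'
#' @param bundle a \linkS4class{FiberBundle}.
#' @param alpha inclination angle in degrees, in [0, 90].
#' @param volume box edge lengths \code{c(x, y, z)} in um (default 30^3).
#' @param allowEmpty return an empty (zero-fibre) bundle instead of an error
#'   when no fibre intersects the crop volume.
#' @return The rotated, cropped \linkS4class{FiberBundle}.
#' @export
rotateAndCrop <- function(bundle, alpha, volume = c(30, 30, 30),
                          allowEmpty = FALSE) {
  stopifnot(alpha >= 0, alpha <= 90)
  a <- alpha * pi / 180
  R <- matrix(c(cos(a), 0, sin(a),
                0, 1, 0,
                -sin(a), 0, cos(a)), 3, 3)  # columns: images of x, y, z
  lo <- -volume / 2; hi <- volume / 2
  newPts <- list(); newRad <- numeric(0)
  for (f in seq_along(bundle@points)) {
    rp <- bundle@points[[f]] %*% t(R)
    pieces <- clipPolylineToBox(rp, lo, hi)
    for (pc in pieces) {
      newPts <- c(newPts, list(unname(pc)))
      newRad <- c(newRad, bundle@radii[f])
    }
  }
  if (!length(newPts) && !allowEmpty)
    stop("empty result: no fibre intersects the crop volume")
  po <- as.vector(R %*% bundle@predominantOrientation)
  if (po[1] < 0 && abs(po[1]) > 1e-9) po <- -po
  new("FiberBundle", points = newPts, radii = newRad,
      predominantOrientation = po / sqrt(sum(po^2)),
      inclination = alpha, boundingVolume = cbind(lo, hi),
      spec = bundle@spec)
}

#' Mode of the segment-to-bundle angle differences
#'
#' Computes the 3D angle (degrees, in [0, 90]) between every fibre-segment
#' orientation vector and the predominant orientation of the bundle,
#' histograms the angles in 1-degree bins over [0, 90], and returns the
#' centre of the highest bin (ties resolved towards the lowest angle).
#'
#' @param bundle a non-empty \linkS4class{FiberBundle}.
#' @param binWidth histogram bin width in degrees.
#' @return The mode angle difference in degrees.
#' @export
modeAngleDifference <- function(bundle, binWidth = 1) {
  angles <- segmentAngles(bundle)
  breaks <- seq(0, 90 + binWidth, by = binWidth)
  h <- graphics::hist(pmin(angles, 90), breaks = breaks, plot = FALSE)
  h$mids[which.max(h$counts)]
}

#' Angles between segment orientations and the predominant orientation
#'
#' @param bundle a \linkS4class{FiberBundle}.
#' @return Numeric vector of axial angles in degrees, one per segment.
#' @export
segmentAngles <- function(bundle) {
  po <- bundle@predominantOrientation
  unlist(lapply(bundle@points, function(p) {
    s <- segmentDirections(p)
    cosang <- abs(s$dirs %*% po)
    acos(pmin(1, cosang)) * 180 / pi
  }))
}

#' Maximum angle between adjacent segments over all fibres
#'
#' @param bundle a \linkS4class{FiberBundle}.
#' @return The largest adjacent-segment angle in degrees (0 for bundles of
#'   single-segment fibres).
#' @export
maxAdjacentAngle <- function(bundle) {
  mx <- 0
  for (p in bundle@points) {
    if (nrow(p) < 3) next
    s <- segmentDirections(p)
    d <- s$dirs
    cosang <- rowSums(d[-nrow(d), , drop = FALSE] * d[-1, , drop = FALSE])
    mx <- max(mx, acos(pmin(1, pmax(-1, cosang))) * 180 / pi)
  }
  mx
}

#' Count segment-pair collisions
#'
#' \code{countCollisions} uses the production broad-phase (spatial hashing);
#' \code{bruteForceCollisions} is an independent all-pairs oracle that also
#' reports the minimum clearance (negative means overlap). Pairs of adjacent
#' segments on the same fibre are excluded from both.
#'
#' @param bundle a \linkS4class{FiberBundle}.
#' @param tol overlap depth below which a contact is not counted (um).
#' @return \code{countCollisions}: integer count. \code{bruteForceCollisions}:
#'   list with \code{count} and \code{minClearance}.
#' @export
countCollisions <- function(bundle) {
  cpp_count_collisions(bundle@points, bundle@radii,
                       bundle@spec@segmentLengthRange[2])
}

#' @rdname countCollisions
#' @export
bruteForceCollisions <- function(bundle, tol = 1e-9) {
  cpp_collisions_bruteforce(bundle@points, bundle@radii, tol)
}
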