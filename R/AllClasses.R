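#' @import methods
NULL

# ---------------------------------------------------------------------------
# Fibre geometry
# ---------------------------------------------------------------------------

#' Specification of a synthetic fibre bundle
#'
#' Describes how a dense bundle of myelinated fibres is grown: the number of
#' fibres, the seed rectangle they are planted in, the range of fibre radii,
#' the segment-length range the polylines are divided into, the maximum random
#' per-vertex displacement that controls orientation dispersion, the maximum
#' angle allowed between adjacent segments, and the fractional diameter
#' shrink applied at voxelization so discretised fibres never touch.
#'
#' All lengths are in micrometres, angles in degrees.
#'
#' @slot nFibers number of fibres.
#' @slot seedArea extent \code{c(width, height)} of the seed rectangle in the
#'   y-z plane, micrometres.
#' @slot radiusRange \code{c(rmin, rmax)} fibre radii, micrometres.
#' @slot segmentLengthRange \code{c(lmin, lmax)} segment lengths, micrometres.
#' @slot maxDisplacement maximum per-vertex random displacement (micrometres)
#'   applied independently in x, y and z.
#' @slot maxAdjacentAngle maximum angle between adjacent segments, degrees.
#' @slot diameterShrinkFraction fraction by which diameters are reduced at
#'   voxelization.
#' @slot fiberLength total length of each straight seed fibre, micrometres.
#' @slot seed integer random seed; identical spec and seed give an identical
#'   bundle.
#' @export
setClass("FiberBundleSpec",
  representation(nFibers = "integer", seedArea = "numeric",
                 radiusRange = "numeric", segmentLengthRange = "numeric",
                 maxDisplacement = "numeric", maxAdjacentAngle = "numeric",
                 diameterShrinkFraction = "numeric", fiberLength = "numeric",
                 seed = "integer"),
  validity = function(object) {
    msg <- NULL
    if (object@nFibers < 1L) msg <- c(msg, "nFibers must be positive")
    if (length(object@seedArea) != 2L || any(object@seedArea <= 0))
      msg <- c(msg, "seedArea must be two positive extents")
    r <- object@radiusRange
    if (length(r) != 2L || r[1] <= 0 || r[1] > r[2])
      msg <- c(msg, "radiusRange must satisfy 0 < rmin <= rmax")
    s <- object@segmentLengthRange
    if (length(s) != 2L || s[1] <= 0 || s[1] > s[2])
      msg <- c(msg, "segmentLengthRange must be positive and ordered")
    if (object@maxDisplacement < 0)
      msg <- c(msg, "maxDisplacement must be non-negative")
    if (object@maxAdjacentAngle <= 0 || object@maxAdjacentAngle > 180)
      msg <- c(msg, "maxAdjacentAngle must be in (0, 180]")
    f <- object@diameterShrinkFraction
    if (f < 0 || f >= 1)
      msg <- c(msg, "diameterShrinkFraction must be in [0, 1)")
    if (object@fiberLength <= 0) msg <- c(msg, "fiberLength must be positive")
    if (is.null(msg)) TRUE else msg
  })

#' A collision-free bundle of polyline fibres
#'
#' @slot points list of numeric matrices (one per fibre, columns x, y, z in
#'   micrometres) holding the ordered polyline vertices.
#' @slot radii numeric vector of per-fibre radii, micrometres.
#' @slot predominantOrientation unit 3-vector, the predominant orientation of
#'   the bundle.
#' @slot inclination out-of-plane inclination angle of the bundle, degrees in
#'   [0, 90].
#' @slot boundingVolume 3 x 2 matrix of box extents (rows x, y, z; columns
#'   lower, upper) or a 0 x 0 matrix when the bundle is uncropped.
#' @slot spec the \linkS4class{FiberBundleSpec} the bundle was grown from.
#' @export
setClass("FiberBundle",
  representation(points = "list", radii = "numeric",
                 predominantOrientation = "numeric", inclination = "numeric",
                 boundingVolume = "matrix", spec = "FiberBundleSpec"),
  validity = function(object) {
    msg <- NULL
    if (length(object@points) != length(object@radii))
      msg <- c(msg, "points and radii must have the same length")
    for (p in object@points) {
      if (!is.matrix(p) || ncol(p) != 3L || nrow(p) < 2L) {
        msg <- c(msg, "each fibre needs a matrix of >= 2 xyz points")
        break
      }
    }
    if (abs(sqrt(sum(object@predominantOrientation^2)) - 1) > 1e-6)
      msg <- c(msg, "predominantOrientation must be a unit vector")
    if (object@inclination < 0 || object@inclination > 90)
      msg <- c(msg, "inclination must be in [0, 90] degrees")
    if (is.null(msg)) TRUE else msg
  })

#' Layered optical model of a myelinated fibre
#'
#' Radial structure of each fibre of radius r: an axon core of radius
#' \code{axonRadiusFraction * r}, then a sheath of thickness
#' \code{sheathThicknessFraction * r} built from an inner myelin layer, a
#' glycerine layer, and an outer myelin layer (fractions of the sheath
#' thickness). Everything outside is the surrounding medium.
#'
#' @slot axonRadiusFraction axon core radius as a fraction of r (default 0.65).
#' @slot sheathThicknessFraction sheath thickness as a fraction of r
#'   (default 0.35; 0.6 models thick sheaths).
#' @slot myelinLayerFraction thickness of each myelin layer as a fraction of
#'   the sheath (default 3/7).
#' @slot glycerineLayerFraction thickness of the glycerine layer as a fraction
#'   of the sheath (default 1/7).
#' @slot nAxon,nMyelin,nGlycerine,nSurround real refractive indices (defaults
#'   1.35, 1.47, 1.37, 1.37; a long-embedded sample is modelled by
#'   \code{nMyelin = 1.39}).
#' @export
setClass("TissueOpticalModel",
  representation(axonRadiusFraction = "numeric",
                 sheathThicknessFraction = "numeric",
                 myelinLayerFraction = "numeric",
                 glycerineLayerFraction = "numeric",
                 nAxon = "numeric", nMyelin = "numeric",
                 nGlycerine = "numeric", nSurround = "numeric"),
  validity = function(object) {
    msg <- NULL
    fr <- c(object@axonRadiusFraction, object@sheathThicknessFraction,
            object@myelinLayerFraction, object@glycerineLayerFraction)
    if (any(fr <= 0 | fr >= 1)) msg <- c(msg, "fractions must lie in (0, 1)")
    if (abs(object@axonRadiusFraction + object@sheathThicknessFraction - 1) > 1e-9)
      msg <- c(msg, "axonRadiusFraction + sheathThicknessFraction must equal 1")
    if (abs(2 * object@myelinLayerFraction + object@glycerineLayerFraction - 1) > 1e-9)
      msg <- c(msg, "2 * myelinLayerFraction + glycerineLayerFraction must equal 1")
    if (any(c(object@nAxon, object@nMyelin, object@nGlycerine,
              object@nSurround) < 1))
      msg <- c(msg, "refractive indices must be >= 1")
    if (is.null(msg)) TRUE else msg
  })

#' Voxel grid of real refractive index
#'
#' @slot values numeric array (2D slice or 3D volume) of refractive indices.
#' @slot voxelSize voxel edge length, micrometres.
#' @slot origin coordinates of the lower corner of the grid, micrometres.
#' @export
setClass("RefractiveIndexVolume",
  representation(values = "array", voxelSize = "numeric", origin = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (object@voxelSize <= 0) msg <- c(msg, "voxelSize must be positive")
    nd <- length(dim(object@values))
    if (!nd %in% c(2L, 3L)) msg <- c(msg, "values must be a 2D or 3D array")
    if (length(object@origin) != nd)
      msg <- c(msg, "origin length must match array dimensionality")
    if (any(object@values < 1)) msg <- c(msg, "refractive indices must be >= 1")
    if (is.null(msg)) TRUE else msg
  })

# ---------------------------------------------------------------------------
# FDTD
# ---------------------------------------------------------------------------

#' FDTD solver configuration
#'
#' @slot wavelength source vacuum wavelength, nanometres (default 550).
#' @slot meshSize Yee mesh size, nanometres (default 25).
#' @slot courantFactor Courant stability factor in (0, 1) (default 0.8).
#' @slot nPeriods number of optical periods to time-step (default 200).
#' @slot pmlThickness absorbing-layer thickness, micrometres (default 1).
#' @slot lateralBoundary \code{"periodic"} or \code{"pml"} lateral boundaries.
#' @slot polarizationAxis \code{"x"} or \code{"y"} linear source polarisation.
#' @slot dimensionality \code{"3D"}, \code{"2D-TM"} (out-of-plane E) or
#'   \code{"2D-TE"} (in-plane E).
#' @slot rampPeriods cosine-taper turn-on time of the source, periods.
#' @export
setClass("FDTDConfig",
  representation(wavelength = "numeric", meshSize = "numeric",
                 courantFactor = "numeric", nPeriods = "numeric",
                 pmlThickness = "numeric", lateralBoundary = "character",
                 polarizationAxis = "character", dimensionality = "character",
                 rampPeriods = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (object@courantFactor <= 0 || object@courantFactor >= 1)
      msg <- c(msg, "courantFactor must be in (0, 1)")
    if (object@wavelength <= 0 || object@meshSize <= 0)
      msg <- c(msg, "wavelength and meshSize must be positive")
    if (!object@lateralBoundary %in% c("pml", "periodic"))
      msg <- c(msg, "lateralBoundary must be 'pml' or 'periodic'")
    if (!object@polarizationAxis %in% c("x", "y"))
      msg <- c(msg, "polarizationAxis must be 'x' or 'y'")
    if (!object@dimensionality %in% c("2D-TE", "2D-TM", "3D"))
      msg <- c(msg, "dimensionality must be '2D-TE', '2D-TM' or '3D'")
    if (object@nPeriods < 4) msg <- c(msg, "nPeriods must be >= 4")
    if (is.null(msg)) TRUE else msg
  })

#' Complex monochromatic field on the exit plane
#'
#' Transverse electric-field phasors sampled on the plane behind the sample
#' for one illumination polarisation, plus the matching incident-wave phasor
#' used for normalisation and, in \code{extras}, the reflected-field monitor
#' and the per-period field-energy trace.
#'
#' @slot Ex,Ey complex matrices of the transverse field components (for 2D
#'   runs one of them is a single-column matrix and the other empty).
#' @slot pixelSize sample spacing, micrometres.
#' @slot polarization source polarisation label.
#' @slot wavelength vacuum wavelength, nanometres.
#' @slot mediumIndex refractive index of the exit medium.
#' @slot incident complex incident-field phasor at the exit plane.
#' @slot extras list of solver by-products (reflection monitors, energy
#'   trace, full-domain phasors for 2D runs).
#' @export
setClass("ExitPlaneField",
  representation(Ex = "matrix", Ey = "matrix", pixelSize = "numeric",
                 polarization = "character", wavelength = "numeric",
                 mediumIndex = "numeric", incident = "complex",
                 extras = "list"),
  validity = function(object) {
    msg <- NULL
    if (length(object@Ex) && any(!is.finite(Mod(object@Ex))))
      msg <- c(msg, "Ex contains non-finite values")
    if (length(object@Ey) && any(!is.finite(Mod(object@Ey))))
      msg <- c(msg, "Ey contains non-finite values")
    if (object@pixelSize <= 0) msg <- c(msg, "pixelSize must be positive")
    if (is.null(msg)) TRUE else msg
  })

# ---------------------------------------------------------------------------
# Virtual imaging
# ---------------------------------------------------------------------------

#' Polarising-microscope imaging model parameters
#'
#' @slot numericalAperture NA of the objective (default 0.15); plane-wave
#'   components beyond \code{asin(NA)} are rejected.
#' @slot microlensDiameter camera microlens diameter, micrometres
#'   (default 1.33); intensities are disc-averaged over this footprint.
#' @slot cameraPixelSize camera pixel size in object space, micrometres;
#'   \code{NA} keeps the native simulation grid.
#' @export
setClass("ImagingConfig",
  representation(numericalAperture = "numeric", microlensDiameter = "numeric",
                 cameraPixelSize = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (object@numericalAperture <= 0 || object@numericalAperture >= 1)
      msg <- c(msg, "numericalAperture must be in (0, 1)")
    if (object@microlensDiameter <= 0)
      msg <- c(msg, "microlensDiameter must be positive")
    if (is.null(msg)) TRUE else msg
  })

#' Non-negative intensity image
#'
#' @slot values numeric matrix of intensities.
#' @slot pixelSize pixel spacing, micrometres.
#' @slot polarization role label (e.g. \code{"x"}, \code{"y"}).
#' @export
setClass("IntensityImage",
  representation(values = "matrix", pixelSize = "numeric",
                 polarization = "character"),
  validity = function(object) {
    if (any(object@values < 0, na.rm = TRUE))
      "intensities must be non-negative" else TRUE
  })

#' Per-pixel scattering-diattenuation map
#'
#' Values are \code{(Ix - Iy) / (Ix + Iy)} in [-1, 1]; pixels where the
#' intensity sum vanishes are masked (\code{NA}).
#'
#' @slot values numeric matrix in [-1, 1] (NA where masked).
#' @slot pixelSize pixel spacing, micrometres.
#' @slot maskedCount number of masked pixels.
#' @export
setClass("DiattenuationMap",
  representation(values = "matrix", pixelSize = "numeric",
                 maskedCount = "integer"),
  validity = function(object) {
    v <- object@values
    if (any(v < -1 - 1e-12 | v > 1 + 1e-12, na.rm = TRUE))
      "diattenuation values must lie in [-1, 1]" else TRUE
  })

# ---------------------------------------------------------------------------
# Analytic models
# ---------------------------------------------------------------------------

#' Optical parameters of a tissue section for the closed-form models
#'
#' @slot wavelength light wavelength, nanometres.
#' @slot thickness section thickness d, micrometres (default 60).
#' @slot deltaKappa dichroism (anisotropic absorption) coefficient; the sign
#'   convention is \code{deltaKappa < 0} for positive dichroic diattenuation.
#' @slot birefringence birefringence magnitude used to weight the thickness
#'   in the retardation model.
#' @export
setClass("OpticalTissueParams",
  representation(wavelength = "numeric", thickness = "numeric",
                 deltaKappa = "numeric", birefringence = "numeric"),
  validity = function(object) {
    if (object@wavelength <= 0 || object@thickness <= 0)
      "wavelength and thickness must be positive" else TRUE
  })

#' A curve of a dimensionless quantity against fibre inclination
#'
#' @slot alpha inclination angles, degrees, strictly increasing in [0, 90].
#' @slot values curve values in [-1, 1].
#' @slot label what the values are (e.g. \code{"DK"}, \code{"DS"}).
#' @export
setClass("InclinationCurve",
  representation(alpha = "numeric", values = "numeric", label = "character"),
  validity = function(object) {
    msg <- NULL
    a <- object@alpha
    if (length(a) != length(object@values))
      msg <- c(msg, "alpha and values must have the same length")
    if (any(diff(a) <= 0)) msg <- c(msg, "alpha must be strictly increasing")
    if (any(a < 0 | a > 90)) msg <- c(msg, "alpha must lie in [0, 90]")
    if (any(abs(object@values) > 1 + 1e-12, na.rm = TRUE))
      msg <- c(msg, "values must lie in [-1, 1]")
    if (is.null(msg)) TRUE else msg
  })

# ---------------------------------------------------------------------------
# Signal analysis
# ---------------------------------------------------------------------------

#' Rotating-polariser intensity series
#'
#' A stack of intensity images indexed by polariser rotation angle rho,
#' normally 18 equally spaced angles {0, 10, ..., 170} degrees.
#'
#' @slot angles rotation angles, degrees, equally spaced spanning [0, 180).
#' @slot data numeric array (rows x cols x angles) of intensities.
#' @slot modality \code{"PLI"} (birefringence signal) or \code{"DI"}
#'   (diattenuation signal).
#' @slot repeatsAveraged whether the stack is an average over repeated
#'   exposures.
#' @export
setClass("RotationSeries",
  representation(angles = "numeric", data = "array", modality = "character",
                 repeatsAveraged = "logical"),
  validity = function(object) {
    msg <- NULL
    n <- length(object@angles)
    if (n < 4L) msg <- c(msg, "need at least 4 rotation angles")
    step <- 180 / n
    if (max(abs(object@angles - seq(0, by = step, length.out = n))) > 1e-9)
      msg <- c(msg, sprintf(
        "angles must be %d equally spaced values 0, %g, ... spanning [0, 180)",
        n, step))
    d <- dim(object@data)
    if (length(d) != 3L || d[3] != n)
      msg <- c(msg, "data must be rows x cols x angles")
    if (any(object@data < 0)) msg <- c(msg, "intensities must be >= 0")
    if (!object@modality %in% c("PLI", "DI"))
      msg <- c(msg, "modality must be 'PLI' or 'DI'")
    if (is.null(msg)) TRUE else msg
  })

#' Harmonic Fourier coefficients of a rotation series
#'
#' Per-pixel coefficients of I(rho) = a0 + a2 cos(2 rho) + b2 sin(2 rho).
#'
#' @slot a0,a2,b2 numeric matrices.
#' @slot modality modality of the series the coefficients came from.
#' @export
setClass("FourierCoefficients",
  representation(a0 = "matrix", a2 = "matrix", b2 = "matrix",
                 modality = "character"),
  validity = function(object) {
    if (!all(dim(object@a0) == dim(object@a2)) ||
        !all(dim(object@a0) == dim(object@b2)))
      "a0, a2, b2 must share one shape" else TRUE
  })

#' Combined diattenuation-imaging result grid
#'
#' @slot phiP birefringence-signal phase (fibre direction), degrees [0, 180).
#' @slot phiD diattenuation-signal phase, degrees [0, 180).
#' @slot strength diattenuation strength |D| in [0, 1].
#' @slot sinDelta birefringence amplitude |sin delta| in [0, 1].
#' @slot transmittance mean transmitted intensity.
#' @slot label character matrix: \code{"D+"}, \code{"D-"} or
#'   \code{"unclassified"} (all-NA when classification was skipped).
#' @export
setClass("DIResult",
  representation(phiP = "matrix", phiD = "matrix", strength = "matrix",
                 sinDelta = "matrix", transmittance = "matrix",
                 label = "matrix"))

# ---------------------------------------------------------------------------
# Synthetic signals
# ---------------------------------------------------------------------------

#' Parameter maps for the forward signal generator
#'
#' @slot phi in-plane fibre direction map, degrees.
#' @slot delta retardation map, radians.
#' @slot strength diattenuation strength map in [0, 1].
#' @slot mode character matrix: \code{"parallel"} (maximal transmission
#'   parallel to the fibre) or \code{"perpendicular"}.
#' @slot baseline transmitted baseline intensity I0 (scalar or matrix).
#' @slot noise list with element \code{type} in \code{none}, \code{gaussian}
#'   (element \code{sigma}) or \code{poisson} (element \code{scale}).
#' @slot repeats number of repeated exposures averaged per angle (default 20).
#' @slot seed integer random seed.
#' @export
setClass("PhantomScene",
  representation(phi = "matrix", delta = "matrix", strength = "matrix",
                 mode = "matrix", baseline = "matrix", noise = "list",
                 repeats = "integer", seed = "integer"),
  validity = function(object) {
    msg <- NULL
    dm <- dim(object@phi)
    for (s in c("delta", "strength", "mode", "baseline"))
      if (!all(dim(slot(object, s)) == dm))
        msg <- c(msg, "all maps must share one shape")
    if (any(object@strength < 0 | object@strength > 1))
      msg <- c(msg, "strength must lie in [0, 1]")
    if (any(object@baseline <= 0)) msg <- c(msg, "baseline must be positive")
    if (!all(object@mode %in% c("parallel", "perpendicular")))
      msg <- c(msg, "mode must be 'parallel' or 'perpendicular'")
    if (!object@noise$type %in% c("none", "gaussian", "poisson"))
      msg <- c(msg, "noise type must be none, gaussian or poisson")
    if (object@repeats < 1L) msg <- c(msg, "repeats must be >= 1")
    if (is.null(msg)) TRUE else msg
  })

# ---------------------------------------------------------------------------
# show methods
# ---------------------------------------------------------------------------

setMethod("show", "FiberBundleSpec", function(object) {
  cat("FiberBundleSpec:", object@nFibers, "fibres, seed area",
      paste(object@seedArea, collapse = " x "), "um\n")
  cat("  radii [", paste(object@radiusRange, collapse = ", "),
      "] um; segments [", paste(object@segmentLengthRange, collapse = ", "),
      "] um\n", sep = "")
  cat("  max displacement", object@maxDisplacement,
      "um; max adjacent angle", object@maxAdjacentAngle,
      "deg; seed", object@seed, "\n")
})

setMethod("show", "FiberBundle", function(object) {
  nseg <- sum(vapply(object@points, nrow, 1L) - 1L)
  cat("FiberBundle:", length(object@points), "fibres,", nseg, "segments\n")
  cat("  predominant orientation (",
      paste(signif(object@predominantOrientation, 3), collapse = ", "),
      "), inclination ", object@inclination, " deg\n", sep = "")
  if (length(object@boundingVolume))
    cat("  cropped to box",
        paste(apply(object@boundingVolume, 1, diff), collapse = " x "), "um\n")
})

setMethod("show", "RefractiveIndexVolume", function(object) {
  cat("RefractiveIndexVolume:", paste(dim(object@values), collapse = " x "),
      "voxels at", object@voxelSize, "um\n")
  cat("  indices:", paste(sort(unique(as.vector(object@values))),
                          collapse = ", "), "\n")
})

setMethod("show", "FDTDConfig", function(object) {
  cat("FDTDConfig:", object@dimensionality, "| lambda", object@wavelength,
      "nm | mesh", object@meshSize, "nm | Courant", object@courantFactor,
      "|", object@nPeriods, "periods\n")
  cat("  PML", object@pmlThickness, "um, lateral", object@lateralBoundary,
      ", polarisation", object@polarizationAxis, "\n")
})

setMethod("show", "ExitPlaneField", function(object) {
  d <- if (length(object@Ex)) dim(object@Ex) else dim(object@Ey)
  cat("ExitPlaneField:", paste(d, collapse = " x "), "samples at",
      signif(object@pixelSize, 4), "um, polarisation", object@polarization,
      "\n")
})

setMethod("show", "DiattenuationMap", function(object) {
  cat("DiattenuationMap:", paste(dim(object@values), collapse = " x "),
      "px | mean", signif(mean(object@values, na.rm = TRUE), 4),
      "| sd", signif(stats::sd(as.vector(object@values), na.rm = TRUE), 4),
      "|", object@maskedCount, "masked\n")
})

setMethod("show", "RotationSeries", function(object) {
  d <- dim(object@data)
  cat("RotationSeries (", object@modality, "): ", d[1], " x ", d[2],
      " px, ", d[3], " angles (", object@angles[1], "..",
      object@angles[length(object@angles)], " deg)\n", sep = "")
})

setMethod("show", "DIResult", function(object) {
  cat("DIResult:", paste(dim(object@phiP), collapse = " x "), "px\n")
  if (!all(is.na(object@label))) {
    tab <- table(factor(object@label, c("D+", "D-", "unclassified")))
    cat("  labels:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  } else cat("  classification skipped\n")
})

setMethod("show", "InclinationCurve", function(object) {
  cat("InclinationCurve (", object@label, "): ", length(object@alpha),
      " angles in [", min(object@alpha), ", ", max(object@alpha), "] deg\n",
      sep = "")
})
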