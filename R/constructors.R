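# User-facing constructors and accessors.

#' Create a fibre-bundle specification
#'
#' Defaults follow the dense-bundle configuration used throughout the package
#' examples: 700 straight fibres seeded uniformly in a 45 x 30 um rectangle,
#' radii drawn uniformly from [0.5, 0.8] um, polylines divided into 2-5 um
#' segments, a maximum per-segment displacement of 1 um (use 10 um for a
#' broad orientation distribution), adjacent-segment angles below 20 degrees,
#' and a 5 per cent diameter shrink at voxelization.
#'
#' @param nFibers number of fibres.
#' @param seedArea seed rectangle extents \code{c(width, height)} in um.
#' @param radiusRange fibre radius range \code{c(rmin, rmax)} in um.
#' @param segmentLengthRange segment length range in um.
#' @param maxDisplacement maximum per-segment displacement in um.
#' @param maxAdjacentAngle maximum adjacent-segment angle in degrees.
#' @param diameterShrinkFraction diameter reduction applied at voxelization.
#' @param fiberLength seed fibre length in um; long enough by default to span
#'   a 30 um crop box at any inclination.
#' @param seed integer random seed.
#' @return A \linkS4class{FiberBundleSpec}.
#' @examples
#' fiberBundleSpec(nFibers = 20, seedArea = c(10, 10))
#' @export
fiberBundleSpec <- function(nFibers = 700L, seedArea = c(45, 30),
                            radiusRange = c(0.5, 0.8),
                            segmentLengthRange = c(2, 5),
                            maxDisplacement = 1,
                            maxAdjacentAngle = 20,
                            diameterShrinkFraction = 0.05,
                            fiberLength = 70,
                            seed = 1L) {
  new("FiberBundleSpec", nFibers = as.integer(nFibers), seedArea = seedArea,
      radiusRange = radiusRange, segmentLengthRange = segmentLengthRange,
      maxDisplacement = maxDisplacement, maxAdjacentAngle = maxAdjacentAngle,
      diameterShrinkFraction = diameterShrinkFraction,
      fiberLength = fiberLength, seed = as.integer(seed))
}

#' Create a layered tissue optical model
#'
#' @param axonRadiusFraction axon core radius fraction of r.
#' @param sheathThicknessFraction sheath thickness fraction of r.
#' @param myelinLayerFraction each myelin layer as a fraction of the sheath.
#' @param glycerineLayerFraction glycerine layer as a fraction of the sheath.
#' @param nAxon,nMyelin,nGlycerine,nSurround real refractive indices.
#' @return A \linkS4class{TissueOpticalModel}.
#' @examples
#' tissueOpticalModel()                 # fresh tissue, nMyelin = 1.47
#' tissueOpticalModel(nMyelin = 1.39)   # long embedding time
#' @export
tissueOpticalModel <- function(axonRadiusFraction = 0.65,
                               sheathThicknessFraction = 1 - axonRadiusFraction,
                               myelinLayerFraction = 3 / 7,
                               glycerineLayerFraction = 1 / 7,
                               nAxon = 1.35, nMyelin = 1.47,
                               nGlycerine = 1.37, nSurround = 1.37) {
  new("TissueOpticalModel", axonRadiusFraction = axonRadiusFraction,
      sheathThicknessFraction = sheathThicknessFraction,
      myelinLayerFraction = myelinLayerFraction,
      glycerineLayerFraction = glycerineLayerFraction,
      nAxon = nAxon, nMyelin = nMyelin, nGlycerine = nGlycerine,
      nSurround = nSurround)
}

#' Create an FDTD configuration
#'
#' @param wavelength vacuum wavelength in nm.
#' @param meshSize Yee mesh size in nm.
#' @param courantFactor Courant factor in (0, 1).
#' @param nPeriods optical periods to time-step.
#' @param pmlThickness absorbing-boundary thickness in um.
#' @param lateralBoundary \code{"periodic"} or \code{"pml"}.
#' @param polarizationAxis \code{"x"} or \code{"y"}.
#' @param dimensionality \code{"3D"}, \code{"2D-TM"} or \code{"2D-TE"}.
#' @param rampPeriods source turn-on taper length in periods.
#' @return An \linkS4class{FDTDConfig}.
#' @export
fdtdConfig <- function(wavelength = 550, meshSize = 25, courantFactor = 0.8,
                       nPeriods = 200, pmlThickness = 1,
                       lateralBoundary = c("periodic", "pml"),
                       polarizationAxis = c("x", "y"),
                       dimensionality = c("3D", "2D-TM", "2D-TE"),
                       rampPeriods = 2) {
  new("FDTDConfig", wavelength = wavelength, meshSize = meshSize,
      courantFactor = courantFactor, nPeriods = nPeriods,
      pmlThickness = pmlThickness,
      lateralBoundary = match.arg(lateralBoundary),
      polarizationAxis = match.arg(polarizationAxis),
      dimensionality = match.arg(dimensionality), rampPeriods = rampPeriods)
}

#' Create a virtual polarising-microscope imaging configuration
#'
#' @param numericalAperture objective NA.
#' @param microlensDiameter camera microlens diameter in um.
#' @param cameraPixelSize camera pixel size in um (\code{NA} = native grid).
#' @return An \linkS4class{ImagingConfig}.
#' @export
imagingConfig <- function(numericalAperture = 0.15, microlensDiameter = 1.33,
                          cameraPixelSize = NA_real_) {
  new("ImagingConfig", numericalAperture = numericalAperture,
      microlensDiameter = microlensDiameter,
      cameraPixelSize = cameraPixelSize)
}

#' Create a refractive-index volume
#'
#' @param values 2D or 3D numeric array of refractive indices.
#' @param voxelSize voxel edge length in um.
#' @param origin lower-corner coordinates in um (defaults to a grid centred
#'   on the coordinate origin).
#' @return A \linkS4class{RefractiveIndexVolume}.
#' @export
refractiveIndexVolume <- function(values, voxelSize,
                                  origin = -dim(values) * voxelSize / 2) {
  new("RefractiveIndexVolume", values = values, voxelSize = voxelSize,
      origin = origin)
}

#' Optical parameters for the closed-form tissue models
#'
#' The default dichroism coefficient is calibrated so that the dichroic
#' diattenuation at zero inclination is \code{tanh(0.05)}: the scale of the
#' dichroism is a free parameter of the model and this canonical value makes
#' the curve \code{tanh(0.05 * cos^2(alpha))}.
#'
#' @param wavelength wavelength in nm.
#' @param thickness section thickness d in um.
#' @param deltaKappa dichroism coefficient (negative for positive dichroic
#'   diattenuation).
#' @param birefringence birefringence magnitude weighting the thickness in
#'   the retardation model; only the cos^2 shape of the retardation is used
#'   by the package, so this is a documented placeholder scale.
#' @return An \linkS4class{OpticalTissueParams}.
#' @examples
#' p <- opticalTissueParams()
#' dichroismDK(0, p)   # tanh(0.05)
#' @export
opticalTissueParams <- function(wavelength = 525, thickness = 60,
                                deltaKappa = -0.05 * (wavelength / 1000) /
                                  (2 * pi * thickness),
                                birefringence = 1e-3) {
  new("OpticalTissueParams", wavelength = wavelength, thickness = thickness,
      deltaKappa = deltaKappa, birefringence = birefringence)
}

#' Create a rotation series from an intensity stack
#'
#' @param data array (rows x cols x angles) of non-negative intensities.
#' @param angles rotation angles in degrees; default 18 angles 0, 10, ... 170.
#' @param modality \code{"PLI"} or \code{"DI"}.
#' @param repeatsAveraged whether repeated exposures were averaged.
#' @return A \linkS4class{RotationSeries}.
#' @export
rotationSeries <- function(data, angles = seq(0, 170, by = 10),
                           modality = c("DI", "PLI"),
                           repeatsAveraged = FALSE) {
  new("RotationSeries", angles = angles, data = data,
      modality = match.arg(modality), repeatsAveraged = repeatsAveraged)
}

#' Create a phantom scene for the forward signal generator
#'
#' @param phi direction map in degrees (matrix, or scalar with \code{dims}).
#' @param delta retardation map in radians.
#' @param strength diattenuation strength map in [0, 1].
#' @param mode \code{"parallel"} (maximal transmission parallel to the fibre)
#'   or \code{"perpendicular"}; scalar or matrix.
#' @param baseline baseline intensity I0.
#' @param noise \code{list(type = "none")}, \code{list(type = "gaussian",
#'   sigma = ...)} or \code{list(type = "poisson", scale = ...)}.
#' @param repeats exposures averaged per angle.
#' @param seed integer random seed.
#' @param dims image size used to expand scalar arguments.
#' @return A \linkS4class{PhantomScene}.
#' @export
phantomScene <- function(phi, delta, strength, mode = "parallel",
                         baseline = 1, noise = list(type = "none"),
                         repeats = 20L, seed = 1L, dims = c(8L, 8L)) {
  expand <- function(x, what) {
    if (is.matrix(x)) return(x)
    matrix(x, dims[1], dims[2])
  }
  if (is.matrix(phi)) dims <- dim(phi)
  new("PhantomScene", phi = expand(phi), delta = expand(delta),
      strength = expand(strength), mode = expand(mode),
      baseline = expand(baseline), noise = noise,
      repeats = as.integer(repeats), seed = as.integer(seed))
}

# ---- accessors -------------------------------------------------------------

#' Accessors for fibre bundles
#'
#' @param bundle a \linkS4class{FiberBundle}.
#' @return \code{fiberPoints}: list of point matrices; \code{fiberRadii}:
#'   numeric vector; \code{nFibers}: count; \code{predominantOrientation}:
#'   unit 3-vector; \code{inclination}: degrees.
#' @name bundle-accessors
NULL

#' @rdname bundle-accessors
#' @export
fiberPoints <- function(bundle) bundle@points

#' @rdname bundle-accessors
#' @export
fiberRadii <- function(bundle) bundle@radii

#' @rdname bundle-accessors
#' @export
nFibers <- function(bundle) length(bundle@points)

#' @rdname bundle-accessors
#' @export
predominantOrientation <- function(bundle) bundle@predominantOrientation

#' @rdname bundle-accessors
#' @export
inclination <- function(bundle) bundle@inclination

#' Values, spacing and origin of grid-like objects
#'
#' @param x a \linkS4class{RefractiveIndexVolume},
#'   \linkS4class{IntensityImage} or \linkS4class{DiattenuationMap}.
#' @return \code{gridValues}: the numeric array; \code{pixelSize} /
#'   \code{voxelSize}: spacing in um.
#' @name grid-accessors
NULL

#' @rdname grid-accessors
#' @export
gridValues <- function(x) x@values

#' @rdname grid-accessors
#' @export
voxelSize <- function(x) x@voxelSize

#' @rdname grid-accessors
#' @export
pixelSize <- function(x) x@pixelSize
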