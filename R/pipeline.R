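# End-to-end orchestration of the two workflows: the simulation chain
# (bundle -> volume -> FDTD x/y -> imaging -> DS map -> curve) and the
# measurement-side analysis chain (rotation series -> parameter maps ->
# classification).

#' Desk-scale fibre-bundle specification
#'
#' A scaled-down bundle for mini-volume FDTD runs: the fibre density, radii,
#' segment lengths and displacement defaults of the full dense bundle, seeded
#' over a small rectangle so the cropped volume fits a desk-scale 3D grid.
#'
#' @param seedArea seed rectangle in um.
#' @param nFibers fibre count (default scales the full 700-fibre density to
#'   the seed area).
#' @param maxDisplacement per-vertex displacement in um.
#' @param fiberLength seed fibre length in um.
#' @param seed random seed.
#' @param ... further arguments to \code{\link{fiberBundleSpec}}.
#' @return A \linkS4class{FiberBundleSpec}.
#' @export
miniBundleSpec <- function(seedArea = c(6, 6), nFibers = NULL,
                           maxDisplacement = 1, fiberLength = 16,
                           seed = 1L, ...) {
  if (is.null(nFibers))
    nFibers <- max(2L, as.integer(round(700 / (45 * 30) * prod(seedArea))))
  fiberBundleSpec(nFibers = nFibers, seedArea = seedArea,
                  maxDisplacement = maxDisplacement,
                  fiberLength = fiberLength, seed = seed, ...)
}

#' Simulate scattering diattenuation versus fibre inclination
#'
#' For every requested inclination angle: rotate and crop the bundle,
#' voxelize it with the tissue optical model, run the FDTD solver once for
#' x- and once for y-polarised illumination, image both exit fields through
#' the virtual microscope, form the scattering-diattenuation map
#' \code{DS = (Ix - Iy)/(Ix + Iy)}, and summarise its mean. Returns the
#' mean-DS inclination curve together with the per-angle maps and a manifest
#' recording the configuration.
#'
#' @param bundle a \linkS4class{FiberBundle} (uncropped, x-aligned), or a
#'   \linkS4class{FiberBundleSpec} from which one is generated.
#' @param alphas inclination angles in degrees.
#' @param model a \linkS4class{TissueOpticalModel}.
#' @param fdtd an \linkS4class{FDTDConfig} (3D).
#' @param imaging an \linkS4class{ImagingConfig}.
#' @param cropVolume crop box edge lengths \code{c(x, y, z)} in um.
#' @param marginUm border excluded from the map summary, um.
#' @return List with \code{curve} (an \linkS4class{InclinationCurve} of mean
#'   DS), \code{maps} (list of \linkS4class{DiattenuationMap}s),
#'   \code{summaries}, and \code{manifest}.
#' @export
simulateDI <- function(bundle, alphas = c(0, 80),
                       model = tissueOpticalModel(),
                       fdtd = fdtdConfig(meshSize = 50, nPeriods = 60),
                       imaging = imagingConfig(),
                       cropVolume = c(4, 4, 4), marginUm = 1) {
  if (is(bundle, "FiberBundleSpec")) bundle <- generateFiberBundle(bundle)
  if (fdtd@dimensionality != "3D")
    stop("simulateDI drives the 3D solver; use runFDTD directly for 2D")
  voxel <- fdtd@meshSize * 1e-3
  maps <- list(); summaries <- list()
  means <- numeric(length(alphas))
  for (i in seq_along(alphas)) {
    a <- alphas[i]
    cropped <- rotateAndCrop(bundle, a, cropVolume, allowEmpty = TRUE)
    vol <- suppressWarnings(voxelize(cropped, model, voxelSize = voxel))
    cfgx <- fdtd; cfgx@polarizationAxis <- "x"
    cfgy <- fdtd; cfgy@polarizationAxis <- "y"
    fx <- runFDTD(vol, cfgx, padIndex = model@nSurround)
    fy <- runFDTD(vol, cfgy, padIndex = model@nSurround)
    Ix <- detectorIntensity(angularSpectrumFilter(fx, imaging), imaging)
    Iy <- detectorIntensity(angularSpectrumFilter(fy, imaging), imaging)
    m <- diattenuationMap(Ix, Iy)
    s <- summarizeMap(m, marginUm = marginUm)
    maps[[i]] <- m; summaries[[i]] <- s
    means[i] <- s$mean
  }
  names(maps) <- names(summaries) <- paste0("alpha", alphas)
  manifest <- list(
    alphas = alphas, cropVolume = cropVolume,
    seed = bundle@spec@seed, nFibers = length(bundle@points),
    meshSizeNm = fdtd@meshSize, wavelengthNm = fdtd@wavelength,
    nPeriods = fdtd@nPeriods, nMyelin = model@nMyelin,
    numericalAperture = imaging@numericalAperture, marginUm = marginUm)
  ord <- order(alphas)
  list(curve = inclinationCurve(alphas[ord], means[ord], label = "DS"),
       maps = maps, summaries = summaries, manifest = manifest)
}

#' Analyse rotating-polariser stacks into a diattenuation-imaging result
#'
#' Runs the full measurement-side chain: harmonic Fourier analysis of the
#' birefringence (PLI) and diattenuation (DI) series, parameter extraction,
#' and D+/D- classification of every pixel. Either series may be omitted;
#' with only a DI stack the diattenuation parameters are computed and
#' classification is skipped (all-NA label).
#'
#' @param pli a \linkS4class{RotationSeries} of modality \code{"PLI"}, or
#'   \code{NULL}.
#' @param di a \linkS4class{RotationSeries} of modality \code{"DI"}, or
#'   \code{NULL}.
#' @param bandHalfWidth classification band half-width, degrees.
#' @return A \linkS4class{DIResult}.
#' @export
analyzeSeries <- function(pli = NULL, di = NULL, bandHalfWidth = 20) {
  if (is.null(pli) && is.null(di)) stop("need at least one series")
  checkAngles <- function(s) {
    want <- seq(0, 170, by = 10)
    missing <- setdiff(want, s@angles)
    if (length(s@angles) != 18L || length(missing))
      stop("series must contain the 18 rotation angles 0..170; missing: ",
           paste(missing, collapse = ", "))
  }
  dm <- NULL
  empty <- function() matrix(NA_real_, dm[1], dm[2])
  if (!is.null(pli)) { checkAngles(pli); dm <- dim(pli@data)[1:2] }
  if (!is.null(di)) {
    checkAngles(di)
    if (!is.null(dm) && any(dim(di@data)[1:2] != dm))
      stop("PLI and DI stacks must share one pixel grid")
    dm <- dim(di@data)[1:2]
  }
  phiP <- sinD <- it <- strength <- phiD <- NULL
  if (!is.null(pli)) {
    pp <- pliParameters(fourierCoefficients(pli))
    phiP <- pp$phiP; sinD <- pp$sinDelta; it <- pp$transmittance
  } else { phiP <- empty(); sinD <- empty(); it <- empty() }
  if (!is.null(di)) {
    dd <- diattenuationParameters(fourierCoefficients(di))
    strength <- dd$strength; phiD <- dd$phiD
    if (is.null(pli)) it <- fourierCoefficients(di)@a0
  } else { strength <- empty(); phiD <- empty() }
  lab <- if (!is.null(pli) && !is.null(di)) {
    classifyDiattenuation(phiP, phiD, bandHalfWidth)
  } else matrix(NA_character_, dm[1], dm[2])
  new("DIResult", phiP = phiP, phiD = phiD, strength = strength,
      sinDelta = sinD, transmittance = it, label = lab)
}
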