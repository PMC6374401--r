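# Serialization: rotation series as multipage float TIFF with a JSON
# sidecar, fibre bundles as JSON, index volumes as raw binary with a JSON
# sidecar, and inclination curves as CSV.

sidecarPath <- function(path) paste0(tools::file_path_sans_ext(path), ".json")

#' Read and write rotation series
#'
#' Stacks are stored as multipage 32-bit float TIFF (one page per rotation
#' angle) with a JSON sidecar of the same base name carrying the angles,
#' modality and repeats-averaged flag.
#'
#' @param series a \linkS4class{RotationSeries}.
#' @param path TIFF file path.
#' @return \code{writeRotationSeries}: the path, invisibly.
#'   \code{readRotationSeries}: a \linkS4class{RotationSeries}.
#' @export
writeRotationSeries <- function(series, path) {
  # TIFF storage is [0, 1]; rescale by the stack maximum (kept in the
  # sidecar) so intensities of any magnitude round-trip
  scale <- max(series@data, 1e-300)
  pages <- lapply(seq_along(series@angles),
                  function(k) series@data[, , k, drop = TRUE] / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  jsonlite::write_json(
    list(angles = series@angles, modality = series@modality,
         repeatsAveraged = series@repeatsAveraged, scale = scale),
    sidecarPath(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeRotationSeries
#' @export
readRotationSeries <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  meta <- jsonlite::read_json(sidecarPath(path), simplifyVector = TRUE)
  scale <- if (is.null(meta$scale)) 1 else meta$scale
  data <- array(0, c(dim(pages[[1]]), length(pages)))
  for (k in seq_along(pages)) data[, , k] <- pages[[k]] * scale
  rotationSeries(data, angles = meta$angles, modality = meta$modality,
                 repeatsAveraged = isTRUE(meta$repeatsAveraged))
}

#' Read and write fibre bundles as JSON
#'
#' @param bundle a \linkS4class{FiberBundle}.
#' @param path JSON file path.
#' @return \code{writeBundleJSON}: the path, invisibly.
#'   \code{readBundleJSON}: a \linkS4class{FiberBundle}.
#' @export
writeBundleJSON <- function(bundle, path) {
  sp <- bundle@spec
  jsonlite::write_json(list(
    spec = list(nFibers = sp@nFibers, seedArea = sp@seedArea,
                radiusRange = sp@radiusRange,
                segmentLengthRange = sp@segmentLengthRange,
                maxDisplacement = sp@maxDisplacement,
                maxAdjacentAngle = sp@maxAdjacentAngle,
                diameterShrinkFraction = sp@diameterShrinkFraction,
                fiberLength = sp@fiberLength, seed = sp@seed),
    predominantOrientation = bundle@predominantOrientation,
    inclination = bundle@inclination,
    boundingVolume = bundle@boundingVolume,
    radii = bundle@radii,
    points = lapply(bundle@points, function(p) unname(p))),
    path, digits = NA, matrix = "rowmajor")
  invisible(path)
}

#' @rdname writeBundleJSON
#' @export
readBundleJSON <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE,
                           simplifyMatrix = FALSE)
  spec <- do.call(fiberBundleSpec, as.list(j$spec))
  pts <- lapply(j$points, function(p) matrix(unlist(p), ncol = 3,
                                             byrow = TRUE))
  bv <- if (length(j$boundingVolume)) matrix(unlist(j$boundingVolume),
                                             nrow = 3, byrow = TRUE)
        else matrix(numeric(0), 0, 0)
  new("FiberBundle", points = pts, radii = j$radii,
      predominantOrientation = j$predominantOrientation,
      inclination = j$inclination, boundingVolume = bv, spec = spec)
}

#' Read and write refractive-index volumes as raw binary plus JSON sidecar
#'
#' @param volume a \linkS4class{RefractiveIndexVolume}.
#' @param path binary file path (double precision, column-major).
#' @return \code{writeVolumeRaw}: the path, invisibly.
#'   \code{readVolumeRaw}: a \linkS4class{RefractiveIndexVolume}.
#' @export
writeVolumeRaw <- function(volume, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.vector(volume@values), con, size = 8)
  jsonlite::write_json(list(dims = dim(volume@values),
                            voxelSize = volume@voxelSize,
                            origin = volume@origin),
                       sidecarPath(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeVolumeRaw
#' @export
readVolumeRaw <- function(path) {
  meta <- jsonlite::read_json(sidecarPath(path), simplifyVector = TRUE)
  con <- file(path, "rb")
  on.exit(close(con))
  vals <- readBin(con, "double", n = prod(meta$dims), size = 8)
  new("RefractiveIndexVolume", values = array(vals, meta$dims),
      voxelSize = meta$voxelSize, origin = meta$origin)
}

#' Write an inclination curve as CSV
#'
#' @param curve an \linkS4class{InclinationCurve}.
#' @param path CSV file path.
#' @return The path, invisibly.
#' @export
writeCurveCSV <- function(curve, path) {
  utils::write.csv(data.frame(alpha = curve@alpha, value = curve@values,
                              label = curve@label),
                   path, row.names = FALSE)
  invisible(path)
}
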