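#' Voxelize a fibre bundle into a refractive-index volume
#'
#' Assigns each voxel centre by its radial distance to the nearest fibre
#' axis, measured in units of the shrunk fibre radius
#' \code{r' = r * (1 - diameterShrinkFraction)}: axon core, inner myelin
#' layer, glycerine layer and outer myelin layer (concentric shells with the
#' fractions of the tissue model), and the surrounding medium elsewhere.
#' Assignment is by voxel-centre sampling without antialiasing, matching the
#' staircase material model of a Yee grid.
#'
#' @param bundle a collision-free \linkS4class{FiberBundle}; its bounding
#'   volume (or the bounding box of its points) defines the grid extents.
#' @param model a \linkS4class{TissueOpticalModel}.
#' @param voxelSize voxel edge length in um (default 0.025). A warning is
#'   issued when it exceeds the thinnest optical layer, which may then vanish
#'   from the discretised volume.
#' @param volume optional 3 x 2 matrix of box extents overriding the bundle's
#'   bounding volume.
#' @return A \linkS4class{RefractiveIndexVolume}.
#' @examples
#' spec <- fiberBundleSpec(nFibers = 1, seedArea = c(1e-9, 1e-9),
#'                         maxDisplacement = 0, fiberLength = 6)
#' b <- generateFiberBundle(spec)
#' v <- voxelize(b, tissueOpticalModel(), voxelSize = 0.1,
#'               volume = cbind(c(-2, -2, -2), c(2, 2, 2)))
#' table(gridValues(v))
#' @export
voxelize <- function(bundle, model, voxelSize = 0.025, volume = NULL) {
  if (is.null(volume)) {
    if (length(bundle@boundingVolume)) {
      volume <- bundle@boundingVolume
    } else {
      allp <- do.call(rbind, bundle@points)
      pad <- max(bundle@radii)
      volume <- cbind(apply(allp, 2, min) - pad, apply(allp, 2, max) + pad)
    }
  }
  if (length(bundle@radii)) {
    shrunk <- min(bundle@radii) * (1 - bundle@spec@diameterShrinkFraction)
    thinnest <- shrunk * model@sheathThicknessFraction *
      model@glycerineLayerFraction
    if (voxelSize > thinnest)
      warning("voxelSize (", voxelSize, " um) exceeds the thinnest layer (",
              signif(thinnest, 3), " um); layers may vanish")
  }
  origin <- volume[, 1]
  dims <- as.integer(round((volume[, 2] - volume[, 1]) / voxelSize))
  vals <- cpp_voxelize(bundle@points, bundle@radii,
                       bundle@spec@diameterShrinkFraction,
                       model@axonRadiusFraction, model@myelinLayerFraction,
                       model@glycerineLayerFraction,
                       model@nAxon, model@nMyelin, model@nGlycerine,
                       model@nSurround, origin, dims, voxelSize)
  new("RefractiveIndexVolume", values = vals, voxelSize = voxelSize,
      origin = origin)
}
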