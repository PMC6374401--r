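# Forward generator of rotating-polariser intensity series from parameter
# maps: the fixture source for testing the measurement-side analysis without
# measured data.

#' Generate a rotation series from a phantom scene
#'
#' Evaluates the forward signal model per pixel and rotation angle:
#' \itemize{
#'   \item DI modality: \code{I(rho) = I0 (1 + D cos(2 (rho - phiD)))} with
#'     \code{phiD} equal to the fibre direction for \code{"parallel"}
#'     (D+) pixels and the direction + 90 degrees for
#'     \code{"perpendicular"} (D-) pixels;
#'   \item PLI modality: \code{I(rho) = (I0 / 2) (1 + sin(delta)
#'     sin(2 (rho - phi)))}, the crossed-polariser transmission of a
#'     birefringent section.
#' }
#' Noise is drawn independently for each of \code{repeats} exposures and the
#' exposures are averaged, emulating repeated low-SNR acquisitions.
#' Deterministic for a given scene seed.
#'
#' @param scene a \linkS4class{PhantomScene}.
#' @param modality \code{"DI"} or \code{"PLI"}.
#' @param angles rotation angles in degrees.
#' @return A \linkS4class{RotationSeries}.
#' @examples
#' sc <- phantomScene(phi = 70, delta = 0, strength = 0.05, dims = c(4, 4))
#' s <- generateSeries(sc, "DI")
#' diattenuationParameters(fourierCoefficients(s))$strength[1, 1]   # 0.05
#' @export
generateSeries <- function(scene, modality = c("DI", "PLI"),
                           angles = seq(0, 170, by = 10)) {
  modality <- match.arg(modality)
  d <- dim(scene@phi)
  rho <- angles * pi / 180
  phiD <- scene@phi + ifelse(scene@mode == "perpendicular", 90, 0)
  clean <- array(0, c(d, length(angles)))
  for (k in seq_along(rho)) {
    clean[, , k] <- if (modality == "DI") {
      scene@baseline *
        (1 + scene@strength * cos(2 * (rho[k] - phiD * pi / 180)))
    } else {
      (scene@baseline / 2) *
        (1 + sin(scene@delta) * sin(2 * (rho[k] - scene@phi * pi / 180)))
    }
  }
  noisy <- switch(scene@noise$type,
    none = clean,
    gaussian = withSeed(scene@seed, {
      acc <- array(0, dim(clean))
      for (r in seq_len(scene@repeats))
        acc <- acc + clean +
          stats::rnorm(length(clean), sd = scene@noise$sigma)
      acc / scene@repeats
    }),
    poisson = withSeed(scene@seed, {
      sc <- scene@noise$scale
      acc <- array(0, dim(clean))
      for (r in seq_len(scene@repeats))
        acc <- acc + stats::rpois(length(clean), sc * clean) / sc
      acc / scene@repeats
    }))
  noisy[noisy < 0] <- 0
  rotationSeries(noisy, angles, modality,
                 repeatsAveraged = scene@repeats > 1L)
}

#' Build standard phantom layouts
#'
#' \describe{
#'   \item{\code{uniform}}{constant parameter maps.}
#'   \item{\code{two-region}}{left half D+ (transmission maximum parallel to
#'     the fibre), right half D-.}
#'   \item{\code{inclination-ramp}}{fibre inclination ramps across columns
#'     from 0 to 90 degrees; retardation follows the cos^2 law and the
#'     diattenuation strength the dichroism model, so noiseless analysis of
#'     the generated series must recover the model curves.}
#' }
#'
#' @param layout layout name.
#' @param dims image size \code{c(rows, cols)}.
#' @param phi fibre direction in degrees.
#' @param delta retardation in radians (uniform/two-region layouts).
#' @param strength diattenuation strength (uniform/two-region layouts).
#' @param baseline baseline intensity I0.
#' @param noise,repeats,seed passed to \code{\link{phantomScene}}.
#' @param params an \linkS4class{OpticalTissueParams} used by the
#'   inclination-ramp layout.
#' @return A \linkS4class{PhantomScene}. For the inclination-ramp layout the
#'   per-column inclinations are attached as attribute \code{"alpha"}.
#' @export
makePhantom <- function(layout = c("uniform", "two-region",
                                   "inclination-ramp"),
                        dims = c(16L, 16L), phi = 30, delta = 0.8,
                        strength = 0.05, baseline = 1,
                        noise = list(type = "none"), repeats = 20L,
                        seed = 1L, params = opticalTissueParams()) {
  layout <- match.arg(layout)
  if (layout == "uniform") {
    return(phantomScene(phi = phi, delta = delta, strength = strength,
                        baseline = baseline, noise = noise,
                        repeats = repeats, seed = seed, dims = dims))
  }
  if (layout == "two-region") {
    mode <- matrix("perpendicular", dims[1], dims[2])
    mode[, seq_len(ceiling(dims[2] / 2))] <- "parallel"
    return(phantomScene(phi = phi, delta = delta, strength = strength,
                        mode = mode, baseline = baseline, noise = noise,
                        repeats = repeats, seed = seed, dims = dims))
  }
  alpha <- seq(0, 90, length.out = dims[2])
  deltaMap <- matrix(retardationDeltaP(alpha, params), dims[1], dims[2],
                     byrow = TRUE)
  dkMap <- matrix(dichroismDK(alpha, params), dims[1], dims[2], byrow = TRUE)
  sc <- phantomScene(phi = matrix(phi, dims[1], dims[2]), delta = deltaMap,
                     strength = dkMap, mode = "parallel",
                     baseline = baseline, noise = noise, repeats = repeats,
                     seed = seed)
  attr(sc, "alpha") <- alpha
  sc
}
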