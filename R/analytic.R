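# Closed-form models of retardation and dichroic diattenuation versus the
# out-of-plane fibre inclination angle.

#' Retardation of a birefringent section versus fibre inclination
#'
#' \code{deltaP = (2 pi / lambda) * d * dn * cos^2(alpha)}: the phase shift
#' between the polarisation components induced by a section of thickness
#' \code{d} with birefringence magnitude \code{dn}, for fibres inclined by
#' \code{alpha} out of the section plane. Monotonically non-increasing in
#' alpha and zero for vertical fibres.
#'
#' @param alpha inclination angle(s) in degrees, in [0, 90].
#' @param params an \linkS4class{OpticalTissueParams}.
#' @return Retardation in radians (vectorised over \code{alpha}).
#' @export
retardationDeltaP <- function(alpha, params = opticalTissueParams()) {
  stopifnot(all(alpha >= 0 & alpha <= 90))
  lambda <- params@wavelength * 1e-3     # um
  (2 * pi / lambda) * params@thickness * params@birefringence *
    cos(alpha * pi / 180)^2
}

#' Dichroic diattenuation versus fibre inclination
#'
#' \code{DK = tanh(-(2 pi / lambda) * d * deltaKappa * cos^2(alpha))}: the
#' diattenuation caused by anisotropic absorption of a section of thickness
#' \code{d}, for fibres inclined by \code{alpha}. With the sign convention
#' \code{deltaKappa < 0} the curve is non-negative, strictly decreasing on
#' (0, 90) degrees, and vanishes for vertical fibres. With the default
#' parameters the curve is the canonical \code{tanh(0.05 cos^2 alpha)}.
#'
#' @param alpha inclination angle(s) in degrees, in [0, 90].
#' @param params an \linkS4class{OpticalTissueParams}.
#' @return Dimensionless diattenuation in (-1, 1), vectorised over alpha.
#' @examples
#' dichroismDK(c(0, 90))   # tanh(0.05), 0
#' @export
dichroismDK <- function(alpha, params = opticalTissueParams()) {
  stopifnot(all(alpha >= 0 & alpha <= 90))
  lambda <- params@wavelength * 1e-3
  tanh(-(2 * pi / lambda) * params@thickness * params@deltaKappa *
         cos(alpha * pi / 180)^2)
}

#' Build an inclination curve from a model function
#'
#' @param alpha strictly increasing inclination angles in degrees.
#' @param values curve values in [-1, 1].
#' @param label curve label (e.g. \code{"DK"}, \code{"DS"}).
#' @return An \linkS4class{InclinationCurve}.
#' @export
inclinationCurve <- function(alpha, values, label = "DK") {
  new("InclinationCurve", alpha = alpha, values = values, label = label)
}

#' Predict the diattenuation type from combined dichroism and scattering
#'
#' Combines the dichroic curve (DK, non-negative) with the scattering curve
#' (DS, either sign) on a shared inclination grid and labels each angle:
#' \code{"D+"} when both contributions are non-negative or the dichroism
#' dominates a negative scattering term, \code{"D-"} when negative scattering
#' dominates, \code{"near-zero"} when both magnitudes are below \code{eps},
#' and \code{"mixed"} when the dominance margin is within \code{eps}.
#'
#' @param dk,ds \linkS4class{InclinationCurve}s on the same alpha grid.
#' @param eps dominance tolerance.
#' @return Character vector of labels, one per grid angle.
#' @export
predictType <- function(dk, ds, eps = 1e-3) {
  if (length(dk@alpha) != length(ds@alpha) ||
      any(abs(dk@alpha - ds@alpha) > 1e-9))
    stop("curves must share one alpha grid")
  mapply(function(k, s) {
    if (abs(k) < eps && abs(s) < eps) return("near-zero")
    if (s >= 0) return("D+")
    margin <- k + s          # dichroism minus |negative scattering|
    if (margin > eps) "D+" else if (margin < -eps) "D-" else "mixed"
  }, dk@values, ds@values, USE.NAMES = FALSE)
}
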