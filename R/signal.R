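# Measurement-side analysis of rotating-polariser intensity series:
# discrete harmonic Fourier analysis, parameter extraction, D+/D-
# classification, and coloured map rendering.

wrapDirection <- function(x) {
  # reduce a direction angle (180-degree periodic) to [0, 180)
  x %% 180
}

wrapDifference <- function(x) {
  # reduce a direction-angle difference to (-90, 90]
  d <- x %% 180
  d[!is.na(d) & d > 90] <- d[!is.na(d) & d > 90] - 180
  d
}

#' Harmonic Fourier coefficients of a rotation series
#'
#' Per image pixel, the coefficients of
#' \code{I(rho) = a0 + a2 cos(2 rho) + b2 sin(2 rho)}:
#' \code{a0} is the mean over the rotation angles, and
#' \code{a2 = (2/N) sum I cos(2 rho)}, \code{b2 = (2/N) sum I sin(2 rho)}.
#' For signals containing only the 0th and 2nd harmonics the discrete
#' orthogonality of the equally spaced angles makes this exact.
#'
#' @param series a \linkS4class{RotationSeries}.
#' @return A \linkS4class{FourierCoefficients}.
#' @examples
#' rho <- seq(0, 170, 10)
#' I <- 1 + 0.1 * cos(2 * rho * pi / 180)
#' s <- rotationSeries(array(rep(I, each = 4), c(2, 2, 18)))
#' fourierCoefficients(s)@a2[1, 1]   # 0.1
#' @export
fourierCoefficients <- function(series) {
  rho <- series@angles * pi / 180
  n <- length(rho)
  d <- dim(series@data)
  m <- matrix(series@data, ncol = n)
  a0 <- matrix(m %*% rep(1 / n, n), d[1], d[2])
  a2 <- matrix(m %*% (2 / n * cos(2 * rho)), d[1], d[2])
  b2 <- matrix(m %*% (2 / n * sin(2 * rho)), d[1], d[2])
  new("FourierCoefficients", a0 = a0, a2 = a2, b2 = b2,
      modality = series@modality)
}

#' Birefringence-signal parameters from Fourier coefficients
#'
#' Direction angle \code{phiP = atan2(-a2, b2) / 2} wrapped to [0, 180),
#' amplitude \code{|sin deltaP| = sqrt(a2^2 + b2^2) / a0}, and transmittance
#' \code{IT = a0}. Pixels with non-positive mean intensity are masked.
#'
#' @param coeffs a \linkS4class{FourierCoefficients} (PLI modality).
#' @return List of matrices \code{phiP} (degrees), \code{sinDelta},
#'   \code{transmittance}.
#' @export
pliParameters <- function(coeffs) {
  bad <- !(coeffs@a0 > 0)
  phi <- wrapDirection(atan2(-coeffs@a2, coeffs@b2) * 90 / pi)
  amp <- sqrt(coeffs@a2^2 + coeffs@b2^2) / coeffs@a0
  phi[bad] <- NA_real_; amp[bad] <- NA_real_
  it <- coeffs@a0; it[bad] <- NA_real_
  list(phiP = phi, sinDelta = amp, transmittance = it)
}

#' Diattenuation-signal parameters from Fourier coefficients
#'
#' Strength \code{|D| = sqrt(a2^2 + b2^2) / a0} and phase
#' \code{phiD = atan2(b2, a2) / 2} wrapped to [0, 180). The phase is masked
#' where the second-harmonic amplitude vanishes (undefined direction) and
#' both outputs are masked where the mean intensity is non-positive.
#'
#' @param coeffs a \linkS4class{FourierCoefficients} (DI modality).
#' @return List of matrices \code{strength}, \code{phiD} (degrees).
#' @export
diattenuationParameters <- function(coeffs) {
  bad <- !(coeffs@a0 > 0)
  amp2 <- sqrt(coeffs@a2^2 + coeffs@b2^2)
  strength <- amp2 / coeffs@a0
  phi <- wrapDirection(atan2(coeffs@b2, coeffs@a2) * 90 / pi)
  phi[amp2 < .Machine$double.eps * pmax(coeffs@a0, 1)] <- NA_real_
  strength[bad] <- NA_real_; phi[bad] <- NA_real_
  list(strength = strength, phiD = phi)
}

#' Diattenuation strength from extremal intensities
#'
#' \code{|D| = (Imax - Imin) / (Imax + Imin)}.
#'
#' @param iMax,iMin maximum and minimum transmitted intensities
#'   (\code{iMax >= iMin >= 0}, \code{iMax > 0}); vectorised.
#' @return Diattenuation strength in [0, 1].
#' @examples
#' diattenuationFromExtrema(3, 1)   # 0.5
#' @export
diattenuationFromExtrema <- function(iMax, iMin) {
  if (any(iMin < 0) || any(iMax < iMin) || any(iMax <= 0))
    stop("need iMax >= iMin >= 0 and iMax > 0")
  (iMax - iMin) / (iMax + iMin)
}

#' Classify diattenuation type from the two signal phases
#'
#' The wrapped phase difference \code{delta = phiD - phiP} (reduced 180-degree
#' periodically to (-90, 90]) selects the label: within [-20, 20] degrees the
#' transmission maximum is parallel to the fibre direction (\code{"D+"});
#' within 20 degrees of +/-90 (i.e. the wrapped image of [70, 110]) it is
#' perpendicular (\code{"D-"}); anything else, or an undefined phase, is
#' \code{"unclassified"}. Band edges are inclusive.
#'
#' @param phiP,phiD direction and diattenuation phases in degrees
#'   (matrices or vectors of matching shape).
#' @param bandHalfWidth half-width of the classification bands, degrees.
#' @return Character labels shaped like the inputs.
#' @examples
#' classifyDiattenuation(30, 30)    # "D+"
#' classifyDiattenuation(30, 120)   # "D-"
#' classifyDiattenuation(30, 75)    # "unclassified"
#' @export
classifyDiattenuation <- function(phiP, phiD, bandHalfWidth = 20) {
  d <- wrapDifference(phiD - phiP)
  lab <- ifelse(is.na(d), "unclassified",
         ifelse(abs(d) <= bandHalfWidth, "D+",
         ifelse(d >= 90 - bandHalfWidth | d <= -(90 - bandHalfWidth),
                "D-", "unclassified")))
  if (is.matrix(phiP)) lab <- matrix(lab, nrow(phiP), ncol(phiP))
  lab
}

#' Render a coloured diattenuation map
#'
#' Diattenuation strength shown in green for D+ pixels, magenta for D-,
#' black for unclassified pixels or pixels below the noise floor. Strengths
#' are scaled linearly with an upper clip at the given percentile of the
#' classified pixels.
#'
#' @param result a \linkS4class{DIResult}.
#' @param clipPercentile percentile of |D| mapped to full brightness.
#' @param noiseFloor minimum |D| rendered (default 0.001, i.e. 0.1 per cent).
#' @return Array rows x cols x 3 of RGB values in [0, 1].
#' @export
renderDIMap <- function(result, clipPercentile = 0.99, noiseFloor = 0.001) {
  lab <- result@label
  s <- result@strength
  keep <- !is.na(lab) & lab != "unclassified" & !is.na(s) & s >= noiseFloor
  img <- array(0, c(nrow(s), ncol(s), 3))
  if (any(keep)) {
    hi <- stats::quantile(s[keep], clipPercentile, names = FALSE)
    v <- pmin(s / max(hi, .Machine$double.eps), 1)
    g <- keep & lab == "D+"
    m <- keep & lab == "D-"
    r <- matrix(0, nrow(s), ncol(s)); gg <- r; b <- r
    gg[g] <- v[g]
    r[m] <- v[m]; b[m] <- v[m]
    img[, , 1] <- r; img[, , 2] <- gg; img[, , 3] <- b
  }
  img
}

#' Histogram of the wrapped phase difference
#'
#' @param result a \linkS4class{DIResult} with both phases present.
#' @param binWidth bin width in degrees.
#' @param minStrength only pixels with |D| at or above this enter the
#'   histogram.
#' @return A \code{\link[graphics]{hist}} object over (-90, 90].
#' @export
phaseDifferenceHistogram <- function(result, binWidth = 5, minStrength = 0) {
  d <- wrapDifference(result@phiD - result@phiP)
  keep <- !is.na(d) & !is.na(result@strength) & result@strength >= minStrength
  graphics::hist(d[keep], breaks = seq(-90, 90, by = binWidth), plot = FALSE)
}
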