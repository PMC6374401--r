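# Virtual polarising-microscope image formation: angular-spectrum NA filter,
# microlens averaging, camera intensities, and scattering-diattenuation maps.

fftFreqs <- function(n, d) {
  # angular spatial frequencies (rad/um) matching R's fft ordering
  2 * pi * c(0:(ceiling(n / 2) - 1), -(floor(n / 2):1)) / (n * d)
}

fft2 <- function(m) stats::fft(m)
ifft2 <- function(m) stats::fft(m, inverse = TRUE) / length(m)

#' Numerical-aperture cutoff angle
#'
#' The largest plane-wave propagation angle passed by the objective,
#' \code{asin(NA)}, in degrees.
#'
#' @param imaging an \linkS4class{ImagingConfig}.
#' @return Cutoff angle in degrees.
#' @examples
#' naCutoffAngle(imagingConfig())   # asin(0.15) = 8.6 degrees
#' @export
naCutoffAngle <- function(imaging) {
  asin(imaging@numericalAperture) * 180 / pi
}

#' Angular-spectrum filter modelling the objective aperture
#'
#' Decomposes the exit field into plane waves by 2D spatial Fourier
#' transform, removes every component whose propagation angle in the exit
#' medium exceeds \code{asin(NA)}, and transforms back. Energy never
#' increases; applying the filter twice equals applying it once.
#'
#' @param field an \linkS4class{ExitPlaneField} on a uniform grid.
#' @param imaging an \linkS4class{ImagingConfig}.
#' @return The filtered \linkS4class{ExitPlaneField}.
#' @export
angularSpectrumFilter <- function(field, imaging) {
  k0 <- 2 * pi / (field@wavelength * 1e-3) * field@mediumIndex
  filt <- function(m) {
    if (!length(m)) return(m)
    kx <- fftFreqs(nrow(m), field@pixelSize)
    ky <- if (ncol(m) > 1) fftFreqs(ncol(m), field@pixelSize) else 0
    sin2 <- outer(kx^2, ky^2, `+`) / k0^2
    if (length(kx) > 1 && min(sin2[sin2 > 0]) > imaging@numericalAperture^2)
      warning("grid too small to resolve the NA cone: only the axial ",
              "plane-wave component is retained")
    mask <- sqrt(sin2) <= imaging@numericalAperture
    ifft2(fft2(m) * mask)
  }
  field@Ex <- filt(field@Ex)
  field@Ey <- filt(field@Ey)
  field
}

discKernel <- function(diameter, pixel, nr, nc) {
  # circular averaging kernel on the image grid, wrapped for circular FFT
  # convolution; normalised to unit sum
  r <- diameter / 2
  xo <- c(0:(ceiling(nr / 2) - 1), -(floor(nr / 2):1)) * pixel
  yo <- if (nc > 1) c(0:(ceiling(nc / 2) - 1), -(floor(nc / 2):1)) * pixel
        else 0
  k <- outer(xo^2, yo^2, `+`) <= r^2
  k / sum(k)
}

#' Camera-plane intensity image
#'
#' Time-averaged intensity of the (filtered) monochromatic field: the squared
#' magnitude of the complex transverse E components, followed by a circular
#' moving average over the microlens footprint, and optional block-resampling
#' to the camera pixel size.
#'
#' @param field a filtered \linkS4class{ExitPlaneField}.
#' @param imaging an \linkS4class{ImagingConfig}.
#' @return An \linkS4class{IntensityImage}.
#' @export
detectorIntensity <- function(field, imaging) {
  I <- 0
  if (length(field@Ex)) I <- I + Mod(field@Ex)^2
  if (length(field@Ey)) I <- I + Mod(field@Ey)^2
  nr <- nrow(I); nc <- ncol(I)
  if (imaging@microlensDiameter > field@pixelSize) {
    k <- discKernel(imaging@microlensDiameter, field@pixelSize, nr, nc)
    I <- Re(ifft2(fft2(I) * fft2(k)))
    I[I < 0] <- 0   # clip FFT round-off
  }
  px <- field@pixelSize
  if (!is.na(imaging@cameraPixelSize) && imaging@cameraPixelSize > px) {
    f <- max(1L, as.integer(round(imaging@cameraPixelSize / px)))
    if (f > 1L) {
      nr2 <- nr %/% f; nc2 <- nc %/% f
      if (nr2 < 1L || nc2 < 1L)
        stop("camera pixel larger than the field of view")
      I <- I[seq_len(nr2 * f), seq_len(nc2 * f), drop = FALSE]
      ri <- rep(seq_len(nr2), each = f)
      ci <- rep(seq_len(nc2), each = f)
      I <- t(rowsum(t(rowsum(I, ri)), ci)) / f^2
      px <- px * f
    }
  }
  new("IntensityImage", values = I, pixelSize = px,
      polarization = field@polarization)
}

#' Scattering-diattenuation map from two polarised intensity images
#'
#' Computes \code{DS = (Ix - Iy) / (Ix + Iy)} per pixel from intensities
#' simulated with x- and y-polarised illumination, with the x axis aligned
#' with the in-plane projection of the bundle symmetry axis. Positive values
#' indicate stronger transmission for light polarised parallel to the fibre
#' structure (type D+), negative values type D-. Pixels where the intensity
#' sum vanishes are masked.
#'
#' @param Ix,Iy \linkS4class{IntensityImage}s on the same grid.
#' @return A \linkS4class{DiattenuationMap}.
#' @examples
#' Ix <- new("IntensityImage", values = matrix(3, 2, 2), pixelSize = 1,
#'           polarization = "x")
#' Iy <- new("IntensityImage", values = matrix(1, 2, 2), pixelSize = 1,
#'           polarization = "y")
#' gridValues(diattenuationMap(Ix, Iy))   # all 0.5
#' @export
diattenuationMap <- function(Ix, Iy) {
  stopifnot(all(dim(Ix@values) == dim(Iy@values)),
            isTRUE(all.equal(Ix@pixelSize, Iy@pixelSize)))
  s <- Ix@values + Iy@values
  d <- Ix@values - Iy@values
  v <- ifelse(s > 0, d / pmax(s, .Machine$double.xmin), NA_real_)
  new("DiattenuationMap", values = v, pixelSize = Ix@pixelSize,
      maskedCount = sum(!(s > 0)))
}

#' Summary statistics of a diattenuation map
#'
#' @param map a \linkS4class{DiattenuationMap}.
#' @param mask optional logical matrix selecting the region to summarise.
#' @param marginUm margin (um) excluded on every border before summarising.
#' @param nBins number of fixed histogram bins over [-1, 1].
#' @return List with \code{mean}, \code{sd}, \code{n} and \code{histogram}
#'   (an object from \code{\link[graphics]{hist}}).
#' @export
summarizeMap <- function(map, mask = NULL, marginUm = 0, nBins = 100L) {
  v <- map@values
  if (marginUm > 0) {
    m <- as.integer(floor(marginUm / map@pixelSize))
    if (2 * m >= min(dim(v))) stop("margin leaves no pixels")
    if (m > 0) v <- v[(m + 1):(nrow(v) - m), (m + 1):(ncol(v) - m),
                      drop = FALSE]
    if (!is.null(mask)) mask <- mask[(m + 1):(nrow(mask) - m),
                                     (m + 1):(ncol(mask) - m), drop = FALSE]
  }
  if (!is.null(mask)) v <- v[mask]
  v <- v[!is.na(v)]
  if (!length(v)) stop("empty region: nothing to summarise")
  h <- graphics::hist(v, breaks = seq(-1, 1, length.out = nBins + 1),
                      plot = FALSE)
  list(mean = mean(v), sd = stats::sd(v), n = length(v), histogram = h)
}
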