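# R driver for the Yee FDTD kernels: domain assembly (sample padding, PML
# and monitor layout), solver dispatch, and phasor bookkeeping.

#' Stable FDTD time step
#'
#' The Courant-bounded time step of the Yee scheme,
#' \code{dt = courantFactor * meshSize / (c * sqrt(D))}, with D the spatial
#' dimensionality of the configuration.
#'
#' @param config an \linkS4class{FDTDConfig}.
#' @return Time step in seconds.
#' @examples
#' stableTimeStep(fdtdConfig())   # 0.8 * 25e-9 / (c * sqrt(3))
#' @export
stableTimeStep <- function(config) {
  D <- if (config@dimensionality == "3D") 3 else 2
  cLight <- 299792458
  config@courantFactor * (config@meshSize * 1e-9) / (cLight * sqrt(D))
}

#' Propagate a polarised plane wave through a refractive-index volume
#'
#' Runs the Yee FDTD solver: a normally incident, linearly polarised
#' monochromatic plane wave is injected on a total-field/scattered-field
#' plane below the sample (fed by a 1D auxiliary grid, so injection is exact
#' at normal incidence), time-stepped for \code{nPeriods} optical periods
#' with convolutional-PML absorbers terminating the propagation axis, and the
#' steady-state complex field is extracted on the exit plane by discrete
#' Fourier projection at the source frequency over the final two periods.
#'
#' The volume is padded along the propagation axis (z, the last array
#' dimension) with \code{padUm} of embedding medium on both sides before the
#' absorbers, mirroring a sample mounted between glycerine layers.
#'
#' For 2D configurations the volume must be a 2D slice (lateral x by z);
#' \code{"2D-TM"} propagates the out-of-plane E component, \code{"2D-TE"}
#' the in-plane one. Lateral boundaries are periodic by default; 2D runs
#' also support lateral PML (\code{lateralBoundary = "pml"}) and, for
#' scattering studies, a rectangular total-field box
#' (\code{tfsf = "box"}). 3D runs use periodic lateral boundaries.
#'
#' @param volume a \linkS4class{RefractiveIndexVolume} (all values >= 1).
#' @param config an \linkS4class{FDTDConfig}; its \code{meshSize} must match
#'   the voxel size of the volume.
#' @param padUm embedding-medium padding on each side along z, um.
#' @param padIndex refractive index of the padding / incident medium.
#' @param tfsf \code{"plane"} (default) or \code{"box"} (2D only).
#' @param boxHalfUm for \code{tfsf = "box"}: half edge length of the
#'   total-field box centred on the volume centre, um; the box must enclose
#'   every non-background voxel.
#' @return An \linkS4class{ExitPlaneField}; its \code{extras} list carries
#'   the reflected-field monitor (scattered region), the per-period energy
#'   trace, and for 2D runs the full-domain phasor(s) and grid layout.
#' @export
runFDTD <- function(volume, config, padUm = 0.5, padIndex = 1.37,
                    tfsf = c("plane", "box"), boxHalfUm = 2) {
  tfsf <- match.arg(tfsf)
  stopifnot(all(volume@values >= 1))
  dx <- config@meshSize * 1e-3                  # um
  if (abs(volume@voxelSize - dx) > 1e-9)
    stop("config meshSize (", dx, " um) must match the voxel size (",
         volume@voxelSize, " um)")
  lambda <- config@wavelength * 1e-3            # um
  nmax <- max(volume@values)
  ppw <- lambda / nmax / dx
  if (ppw < 6)
    stop("mesh must resolve lambda/n_max by at least 6 points")
  if (ppw < 10)
    warning("mesh resolves lambda/n_max by only ", signif(ppw, 3),
            " points; expect noticeable numerical dispersion")
  npml <- max(4L, as.integer(round(config@pmlThickness / dx)))
  npad <- as.integer(round(padUm / dx))
  is3d <- config@dimensionality == "3D"

  d <- dim(volume@values)
  nzS <- d[length(d)]
  # z layout: [PML][3][krefl][2][ks][buffer 3][pad][sample][pad][2][kexit][3][PML]
  pre <- npml + 9L
  nz <- pre + npad + nzS + npad + 6L + npml
  ks <- npml + 6L
  krefl <- npml + 3L
  kexit <- nz - npml - 4L
  k0 <- pre + npad                               # sample start (0-based)

  if (is3d) {
    nx <- d[1]; ny <- d[2]
    full <- array(padIndex, dim = c(nx, ny, nz))
    full[, , (k0 + 1):(k0 + nzS)] <- volume@values
    res <- cpp_fdtd_3d(full, nx, ny, nz, dx, lambda, config@courantFactor,
                       config@nPeriods, npml, config@polarizationAxis,
                       ks, kexit, krefl, padIndex, config@rampPeriods)
    new("ExitPlaneField",
        Ex = res$exitEx, Ey = res$exitEy, pixelSize = dx,
        polarization = config@polarizationAxis,
        wavelength = config@wavelength, mediumIndex = padIndex,
        incident = res$incExit,
        extras = list(reflEx = res$reflEx, reflEy = res$reflEy,
                      incRefl = res$incRefl, energy = res$energy,
                      dt = res$dt, steps = res$steps))
  } else {
    nx <- d[1]
    latPml <- config@lateralBoundary == "pml"
    xpad <- if (latPml) npml + 4L else 0L
    full <- matrix(padIndex, nx + 2L * xpad, nz)
    full[(xpad + 1):(xpad + nx), (k0 + 1):(k0 + nzS)] <- volume@values
    mode <- if (config@dimensionality == "2D-TM") "TM" else "TE"
    boxCells <- c(0L, 0L, 0L, 0L)
    if (tfsf == "box") {
      if (!latPml) stop("tfsf = 'box' requires lateral PML boundaries")
      if (mode != "TM") stop("tfsf = 'box' is implemented for 2D-TM only")
      hb <- as.integer(round(boxHalfUm / dx))
      ic <- as.integer(xpad + nx / 2)
      kc <- as.integer(k0 + nzS / 2)
      boxCells <- c(ic - hb, ic + hb, kc - hb, kc + hb)
      if (boxCells[1] <= npml || boxCells[2] >= nrow(full) - 1L - npml ||
          boxCells[3] <= npml || boxCells[4] >= nz - 1L - npml)
        stop("total-field box does not fit inside the PML-free region")
    }
    res <- cpp_fdtd_2d(full, dx, lambda, config@courantFactor,
                       config@nPeriods, npml, latPml, mode, tfsf,
                       boxCells, ks, kexit, krefl, padIndex,
                       config@rampPeriods)
    sel <- (xpad + 1):(xpad + nx)
    exitLine <- res$Ephasor[sel, kexit + 1L, drop = FALSE]
    reflLine <- res$Ephasor[sel, krefl + 1L, drop = FALSE]
    ex <- matrix(complex(real = 0), 0, 0)
    ey <- matrix(complex(real = 0), 0, 0)
    if (mode == "TM") ey <- exitLine else ex <- exitLine
    new("ExitPlaneField",
        Ex = ex, Ey = ey, pixelSize = dx,
        polarization = if (mode == "TM") "out-of-plane" else "in-plane",
        wavelength = config@wavelength, mediumIndex = padIndex,
        incident = res$incExit,
        extras = list(refl = reflLine, incRefl = res$incRefl,
                      energy = res$energy, dt = res$dt, steps = res$steps,
                      domainPhasor = res$Ephasor,
                      domainPhasor2 = res$EzPhasor,
                      layout = list(npml = npml, xpad = xpad, ks = ks,
                                    kexit = kexit, krefl = krefl, k0 = k0,
                                    nz = nz, dx = dx, boxCells = boxCells)))
  }
}

#' Extract the monochromatic complex amplitude from a time series
#'
#' Discrete Fourier projection of sampled field values onto the source
#' frequency: \code{2/N * sum(s(t) * exp(1i * omega * t))}, exact for a pure
#' steady-state oscillation sampled over whole periods.
#'
#' @param series numeric vector, matrix or array whose \emph{last} dimension
#'   indexes time samples.
#' @param times sample times (same units as \code{1/frequency}).
#' @param wavelength vacuum wavelength in nm (defines the frequency together
#'   with \code{cLight}).
#' @param cLight speed of light in the unit system of \code{times}; defaults
#'   to micrometres-per-(micrometre/c) natural units, i.e. 1, so that
#'   \code{times} are in um of optical path.
#' @return Complex amplitude(s) with the time dimension dropped.
#' @export
extractMonochromaticField <- function(series, times, wavelength,
                                      cLight = 1) {
  lambda <- wavelength * 1e-3
  period <- lambda / cLight
  if (diff(range(times)) + (times[2] - times[1]) < 2 * period - 1e-9)
    stop("need at least 2 full periods of samples")
  omega <- 2 * pi * cLight / lambda
  w <- exp(1i * omega * times)
  if (is.null(dim(series))) {
    return(2 * mean(series * w))
  }
  d <- dim(series)
  nt <- d[length(d)]
  stopifnot(nt == length(times))
  m <- matrix(series, ncol = nt)
  out <- 2 * (m %*% w) / nt
  if (length(d) > 2) array(out, d[-length(d)]) else
    matrix(out, d[1], if (length(d) == 2) 1 else d[2])
}

#' Intensity transmittance of an exit field
#'
#' Ratio of the plane-averaged transmitted intensity |E|^2 to the incident
#' intensity at the same plane (entry and exit media share one index, so the
#' intensity ratio is the power transmittance for near-normal propagation).
#'
#' @param field an \linkS4class{ExitPlaneField}.
#' @return Transmittance (dimensionless).
#' @export
fieldTransmittance <- function(field) {
  num <- 0
  if (length(field@Ex)) num <- num + mean(Mod(field@Ex)^2)
  if (length(field@Ey)) num <- num + mean(Mod(field@Ey)^2)
  num / Mod(field@incident)^2
}

#' Reflectance measured in the scattered-field region
#'
#' @param field an \linkS4class{ExitPlaneField} from \code{\link{runFDTD}}.
#' @return Reflectance (dimensionless).
#' @export
fieldReflectance <- function(field) {
  ex <- field@extras
  inc2 <- Mod(ex$incRefl)^2
  if (!is.null(ex$refl)) return(mean(Mod(ex$refl)^2) / inc2)
  (mean(Mod(ex$reflEx)^2) + mean(Mod(ex$reflEy)^2)) / inc2
}
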