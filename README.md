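# diattsim

Simulation and analysis of **diattenuation imaging (DI)** of nerve fibre
tissue, for researchers modelling polarised-light microscopy of white
matter.

Thin brain sections attenuate polarised light anisotropically. Two
mechanisms contribute: *dichroism* of the myelin lipids, which favours
light polarised parallel to the fibres (type **D+**), and *anisotropic
scattering* by the fibre microstructure, which for in-plane fibres favours
the perpendicular polarisation (type **D-**). The balance of the two — and
hence the sign of the measured diattenuation — depends on fibre
inclination, fibre size, myelin sheath thickness, and embedding time.

`diattsim` implements both halves of a study of this effect:

* **Simulation.** Synthetic, collision-free bundles of myelinated fibres
  with controlled orientation dispersion; voxelization into layered
  axon/myelin/glycerine refractive-index volumes; a Yee-grid FDTD Maxwell
  solver (2D and 3D, convolutional PML, exact plane-wave injection from an
  auxiliary grid); a virtual polarising-microscope imaging model (angular
  spectrum filter at `asin(NA)`, microlens disc averaging); and the
  scattering-diattenuation map from two polarised runs,

  `DS = (Ix - Iy) / (Ix + Iy)`, with `DS > 0` for D+ and `DS < 0` for D-.

* **Analysis.** The measurement-side pipeline for rotating-polariser
  intensity series `I(rho)` over the 18 angles `rho = 0, 10, ..., 170`
  degrees: discrete harmonic Fourier analysis
  (`I = a0 + a2 cos 2 rho + b2 sin 2 rho`), direction phase
  `phiP = atan2(-a2, b2)/2`, diattenuation strength
  `|D| = sqrt(a2^2 + b2^2)/a0` and phase `phiD = atan2(b2, a2)/2`,
  classification of `phiD - phiP` into D+ (within 20 degrees) and D-
  (within 20 degrees of +/-90), and green/magenta map rendering.

* **Closed-form models.** Retardation
  `deltaP = (2 pi / lambda) d dn cos^2(alpha)` and dichroic diattenuation
  `DK = tanh(-(2 pi / lambda) d dkappa cos^2(alpha))` versus the fibre
  inclination `alpha`, plus a forward generator of synthetic rotation
  series with configurable noise and repeat averaging.

## Worked example

Generate a dense mini fibre bundle, simulate the diattenuation at two
inclinations, and analyse a synthetic measurement:

```r
library(diattsim)

## simulation side: mean scattering diattenuation at 0 and 80 degrees
res <- simulateDI(miniBundleSpec(seed = 5),
                  alphas = c(0, 80),
                  fdtd = fdtdConfig(meshSize = 50, nPeriods = 40),
                  cropVolume = c(4, 4, 4))
res$curve@values
#> [1] -0.02399722  0.01010241
```

The mean `DS` is about **-2.4 %** at zero inclination (in-plane fibres,
type D-) and **+1.0 %** at 80 degrees (steep fibres, type D+): scattering
alone flips the sign of the diattenuation with inclination, which is the
qualitative behaviour the full-scale study reports.

```r
## measurement side: a two-region phantom, noisy, 20 exposures averaged
ph <- makePhantom("two-region", dims = c(32, 32), strength = 0.05,
                  noise = list(type = "gaussian", sigma = 0.01),
                  repeats = 20L, seed = 7L)
out <- analyzeSeries(pli = generateSeries(ph, "PLI"),
                     di = generateSeries(ph, "DI"))
table(out@label)
#>  D-  D+
#> 512 512
```

Every pixel is classified into the correct half of the phantom; the
left half transmits maximally parallel to the fibre direction (D+, green),
the right half perpendicular (D-, magenta). `renderDIMap(out)` returns the
coloured map.

A thin command-line wrapper over these functions is installed at
`inst/scripts/diattsim.R` (subcommands `fibergen`, `voxelize`,
`simulate-di`, `synth`, `analyze`, `curves`).

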