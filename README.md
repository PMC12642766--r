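# opmtools

Computational toolkit for two-photon oblique plane microscopy (2P-OPM).

Oblique plane microscopes launch a tilted light sheet through a single
primary objective and re-image the tilted plane through a remote-focus
relay (a secondary objective O2 in air and a tilted tertiary objective O3
behind a solid-immersion interface). The raw data are therefore sheared:
each camera frame advances obliquely through the specimen, and every
quantitative step downstream — volume rendering, PSF benchmarking,
contrast analysis, single-molecule tracking — needs the instrument's
geometry and optics modeled explicitly. `opmtools` implements that stack
as a self-contained R package, testable end to end on synthetic data with
no instrument attached:

* **Volume reconstruction** (`deskewVolume`, `simulateObliqueAcquisition`).
  With scan step $y_{step}$, sheet tilt $\theta$ and pixel size $a$, the
  per-frame displacements along the oblique axes are
  $d_{skew} = y_{step}\cos\theta$ and $d_{scale} = y_{step}\sin\theta$,
  giving dimensionless shear factors $sk = d_{skew}/a$, $sc = d_{scale}/a$.
  Raw stacks are mapped to Cartesian volumes with isotropic voxels
  ($a^3$) by the homogeneous-coordinate composition
  $T_{post}\,R(\theta)\,T_{pre}\,S\,K$ — skew, axial scale, rotation about
  x — with pull-style trilinear resampling. The matching forward model
  closes the loop for testing.
* **Detection PSF** (`simulateDetectionPsf`, `psfFwhm`). The effective
  pupil of the remote relay is the overlap of the O2 exit cone
  (NA 0.95, air) and the tilted O3 acceptance cone (NA 1.0 behind
  n = 1.515) on the wavevector sphere; the 3D PSF follows by
  angular-spectrum propagation, is rotated to its principal axes, fit with
  1D Gaussians (FWHM $= 2\sqrt{2\ln 2}\,\sigma$) and scaled by the 1.515
  remote magnification. At a 45° tilt the pupil loses a crescent on the y
  side, making the PSF mildly anisotropic (y/x ≈ 1.14).
* **Layer-cake Bessel-sheet design** (`axialExtent`, `designLayerCake`,
  `simulateExcitationFocus`). An annular zone between aperture angles
  $\alpha_1, \alpha_2$ ($\alpha = \arcsin(\mathrm{NA}/n)$) produces a
  Bessel-like focus of axial extent
  $dz = \lambda / [n(\cos\alpha_1 - \cos\alpha_2)]$. The mask design tiles
  the pupil with L contiguous zones of equal $dz$; each zone's scalar
  Debye field is raised to $|E|^4$ (two-photon excitation) and the zones
  are summed incoherently into an extended-depth-of-focus profile.
* **Image metrics** (`imageContrast`, `depthContrastProfile`,
  `radialFourierSpectrum`, `heterogeneityIndex`). Contrast is the
  coefficient of variation $\sigma_I/\bar I$ (sample SD); depth profiles
  are normalized to the surface slice and summarized by their discrete
  mean and by the trapezoidal integral of $\max(\mathrm{Contrast}-1,0)$;
  the heterogeneity index $H = \sigma_I^2/R^2$ ($R = I_{max}-I_{min}$) is
  invariant to global gain and offset, isolating genuine clustering.
* **Single-molecule analysis** (`photonCounts`, `localizationPrecision`,
  `msdDiffusion`, `msdVsLag`). Spot intensities in camera digital numbers
  convert to photons via gain, offset and quantum efficiency; the
  Cramér–Rao bound for a 2D Gaussian PSF,
  $\sigma_{loc}^2 = (\sigma_{PSF}^2 + a^2/12)/N_\gamma +
  8\pi\sigma_{PSF}^4 b_\gamma/(a^2 N_\gamma^2)$, uses the tilt-mixed width
  $\sigma_{y'} = \sqrt{\sigma_y^2\cos^2\theta + \sigma_z^2\sin^2\theta}$
  along y′. MSD analysis subtracts the static localization variance
  $2(\sigma_x^2+\sigma_{y'}^2)$ and estimates $D$ from
  $\mathrm{MSD}(\tau)=4D\tau$ (slope of the first two lags / 4).
* **Synthetic fixtures** (`beadPhantom`, `hazeVolume`, `clusteredPuncta`,
  `simulateBrownianTracks`) — seeded, bit-reproducible generators with
  ground truth, plus a camera noise model (Poisson shot noise + Gaussian
  read noise + gain/offset).

## Worked example

```r
library(opmtools)

## five-bead phantom, oblique acquisition at 45 deg, reconstruction
ph <- beadPhantom(PhantomSpec(shape = c(48, 48, 28), nBeads = 5,
                              background = 0, amplitude = 100, seed = 2),
                  margin = 7)
stack <- simulateObliqueAcquisition(ph$volume,
                                    ScanGeometry(45, 0.2 / sqrt(2), 0.2))
stack
#> ObliqueStack: 106 frames of 48 x 68 (x, y')
#> ScanGeometry: theta = 45 deg, ystep = 0.141421 um, pixel = 0.2 um (fill 0)
deskewVolume(stack)
#> CartesianVolume: 48 x 49 x 123 voxels, 0.2 um isotropic

## layer-cake mask at 900 nm, NA 0.5, n = 1.515, four equal-dz zones
des <- designLayerCake(0.9, n = 1.515, naMax = 0.5, L = 4)
des
#> LayerCakeDesign: 4 zones, lambda 0.9 um, n 1.515, dz 42.410 um
#>   zone 1: NA 0.0000 - 0.2527
#>   zone 2: NA 0.2527 - 0.3561
#>   zone 3: NA 0.3561 - 0.4346
#>   zone 4: NA 0.4346 - 0.5000
simulateExcitationFocus(des, rMax = 1.5)
#> FocusProfile: 2P DOF 27.05 um (1P 37.57), waist 0.703 um, dz 42.41 um

## Brownian tracks at D = 1.04 um^2/s with anisotropic localization noise,
## recovered by the noise-corrected MSD-vs-lag estimator
ts <- simulateBrownianTracks(dCoeff = 1.04, dt = 0.05, nTracks = 500,
                             trackLen = 50, sigmaX = 0.0329,
                             sigmaY = 0.0584, seed = 1)
msdVsLag(ts, sigmaX = 0.0329, sigmaY = 0.0584)
#> MsdResult (lagfit): D = 1.055 +/- 0.016 um^2/s
#>   lag    msd corrected       se     n
#>  0.05 0.2196    0.2106 0.001399 24500
#>  0.10 0.4306    0.4216 0.002788 24000
#>  0.15 0.6393    0.6304 0.004189 23500
#>  0.20 0.8476    0.8386 0.005645 23000
```

The reconstruction places each bead's centroid within half a voxel of its
ground-truth position; the zone table shares one axial extent (42.41 µm)
across all four annuli; and the MSD fit returns the generating diffusion
coefficient within its standard error, with the corrected column sitting
the static noise floor $2(\sigma_x^2+\sigma_{y'}^2) \approx 0.009\,µm^2$
below the raw one.

## Command line

A thin wrapper over the same functions ships in `inst/cli/`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/opmtools.R", package="opmtools"))')" \
    deskew --theta 45 --ystep 0.4 --pixel-size 0.0867 in.tif out.tif
```

Subcommands: `deskew`, `simulate-acquisition`, `simulate-psf`,
`design-mask`, `simulate-focus`, `contrast`, `depth-contrast`, `spectrum`,
`hindex`, `photons`, `precision`, `msd`, `simulate-tracks`,
`simulate-beads`. Images travel as multi-page TIFF, tables as CSV,
configurations as JSON; every run writes a `<output>.run.json` provenance
sidecar (parameters, package version, seed).

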