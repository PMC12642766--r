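---
title: "opmtools: models, conventions and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{opmtools: models, conventions and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of the science it implements: the
models and their assumptions, the parameters that matter, the conventions
fixed where several were defensible, and what the synthetic fixtures do
and do not establish about real microscope data.

## 1. Oblique-volume reconstruction

An oblique plane microscope records 2D frames whose in-plane axes are the
camera x and the tilted y′; successive frames advance along the scan
direction, displaced both within the sheet plane and along its normal.
With scan increment $y_{step}$ (µm/frame), sheet tilt $\theta$ (degrees at
the interface, radians internally) and in-plane pixel size $a$ (µm/pixel),

$$d_{skew} = y_{step}\cos\theta,\qquad d_{scale} = y_{step}\sin\theta,
\qquad sk = d_{skew}/a,\qquad sc = d_{scale}/a .$$

`buildAffine()` composes, in homogeneous coordinates and in this
non-commutative order, a skew $K$ (y′ shifted by $sk$ per frame), an
axial scale $S$ (frame index stretched by $sc$) and the rotation
$R(\theta)$ about x that returns the stack to conventional microscope
coordinates. Conventions fixed by the package:

* voxel indices are 0-based and positions refer to voxel centers;
* the rotation acts about the geometric center of the skewed-and-scaled
  bounding box (pre-translation), and a post-translation places the
  minimum corner of the transformed bounding box at zero, so the output
  grid is the axis-aligned bounding box of the transformed input rounded
  outward to whole voxels;
* output voxels are isotropic with edge $a$, and `deskewVolume()`
  resamples by mapping each *output* voxel through the inverse transform
  (pull-style) with trilinear interpolation — pushing source voxels
  forward would leave holes wherever $sc > 1$. Coordinates outside the
  source domain take the geometry's fill value (default 0); NaNs
  propagate with a warning.

Two degenerate configurations deserve note. At $\theta = 0$ the formulas
give $sc = 0$ — the scan never advances axially and the transform is
singular — and no tilt angle reproduces a conventional z-stack exactly.
`buildAffine()` and `simulateObliqueAcquisition()` therefore accept
explicit `sk=`/`sc=` overrides so that identity-like and pure-z-step
configurations are expressible (they are used in the test-suite's
degenerate cases).

Trilinear pull-resampling redistributes intensity: the deskewed total
equals the source total times the Jacobian $sc$ of the mapping. In the
closed loop (forward acquisition followed by deskew) the two Jacobians
cancel, so round trips conserve the total intensity of compact interior
sources to better than 1%, and bead centroids are recovered within half a
voxel — both are asserted in the tests.

`simulateObliqueAcquisition()` is the exact adjoint sampling: frame
voxel $(i, j, k)$ samples the Cartesian volume at its affine image. It
sizes the stack from the inverse image of the volume's bounding box,
centers the volume in the scanned region, and stores the resulting
integer-offset bookkeeping in the stack so the deskewed output can be
aligned with the source (`origin()` on the reconstruction).

## 2. The tilted remote-focus detection PSF

The detection path relays the primary image through a secondary
objective O2 (NA 0.95, air, $n = 1.0$) into a tilted tertiary objective
O3 (NA 1.0 behind a solid-immersion interface, $n = 1.515$). The model:
a point in the remote replica emits a spherical wave whose directions are
limited by two cones on the wavevector sphere — the O2 exit cone
(transverse sine $\le \mathrm{NA}_{O2}/n_{O2}$ about the O2 axis) and the
acceptance cone of O3, whose numerical aperture is medium-invariant, so
its air-side half-angle is $\arcsin(\min(1, \mathrm{NA}_{O3}/n_{O2}))$
about the tilted axis: a full half-space for NA 1.0. The binary overlap
of the two is the effective pupil; transmission is taken as uniform
within it (no Fresnel or aplanatic apodization — those refinements move
the widths by a few percent but are not part of the contract).

One choice was genuinely open: in which space to evaluate the overlap and
propagate the field. Evaluating it in the O3 immersion medium (all
direction sines compressed by $1/1.515$, the O2 cone refracted through
the flat interface) yields a pupil whose y extent is cut on *both* sides
and a lateral anisotropy near 1.27; evaluating it on the air sphere of
the remote replica — whose coordinates map 1:1 onto the sample through
the O1→O2 remote magnification — trims only a crescent from the 0.95
disc and yields 1.14. Since the replica frame is the sample-referred one
(it is what a bead measurement reports), the package adopts it; the
measured in-plane bead anisotropy of high-NA tilted systems (~1.13)
agrees with this frame and not with the immersion-frame variant.

The 3D intensity follows by angular-spectrum propagation,
$E(\cdot, z) = \mathcal{F}\{P\,e^{2\pi i k_z z}\}$ with
$k_z = (n/\lambda)\sqrt{1 - s^2}$. `psfFwhm()` then reproduces the
standard benchmarking pipeline: the (y, z) principal axes are found from
the intensity second moments (5% support threshold), line profiles
through the maximum are interpolated trilinearly at one third of the
grid pitch, fit with 1D Gaussians (Levenberg–Marquardt on the raw
residuals, so noise-free profiles with zero residual fit cleanly), and
converted by $\mathrm{FWHM} = 2\sqrt{2\ln 2}\,\sigma$. A fit with
$R^2 < 0.9$ is a rejected measurement, mirroring bead-analysis practice.
All widths are finally multiplied by 1.515, the O1→O2 magnification
correction; the anisotropy ratio is scale-free. Of the two principal
directions in (y, z) the broader is reported as z (axial blur), the
narrower as y — at tilts below ~60° this matches the geometric
assignment.

Grid parameters and why: `pupilSamples = 256` across the pupil diameter
with `padFactor = 4` zero-padding gives a real-space pitch of
$\lambda/(8\,\mathrm{NA})$ (≈ 69 nm better than 4× Nyquist at
$\lambda$ = 550 nm) and converges the anisotropy ratio to the fourth
decimal (96/128/192/256 samples give 1.1401/1.1412/1.1409/1.1411); the
package uses 256 as its default working resolution, with the pitch guard
refusing anything coarser than $\lambda/(4\,\mathrm{NA})$. Axial
sampling is 50 nm over ±1.6 µm, and the stored volume is cropped to a
3 µm half-window around focus (the energy beyond it is negligible for
width fitting; the test suite checks plane-energy conservation — a
discrete Parseval identity — on an uncropped grid).

## 3. Layer-cake extended-focus design

A pupil-plane mask of concentric glass discs splits the aperture into
annular zones; step heights much larger than the femtosecond coherence
length make the zones mutually incoherent. Each zone, spanning aperture
angles $\alpha_1 < \alpha_2$ with $\alpha = \arcsin(\mathrm{NA}/n)$,
forms a Bessel-like focus of axial extent

$$dz = \frac{\lambda}{n\,(\cos\alpha_1 - \cos\alpha_2)} ,$$

the central disc ($\alpha_1 = 0$) being the Gaussian-like limit.
`designLayerCake()` tiles $(0, \mathrm{NA}_{max}]$ with $L$ contiguous
zones of equal $dz$. Because equal $dz$ means equal steps in
$\cos\alpha$, the tiling has the closed form
$\cos\alpha_i = 1 - i\,(1-\cos\alpha_{max})/L$ with
$dz = \lambda L/[n(1-\cos\alpha_{max})]$ — the fixed point the iterative
"choose the central zone, recurse outward" construction converges to,
solved exactly. Whether $L$ counts all zones or only the annuli around
the central disc is ambiguous in common usage; the package counts all
zones by default and exposes `countCentral = FALSE` for the other
reading. `zoneRadii()` converts NA boundaries to physical mask radii via
$r = f\,\mathrm{NA}$.

`simulateExcitationFocus()` computes each zone's focal field with a
scalar Debye integral over the annulus (uniform fill, aplanatic
$\sqrt{\cos\theta}$ apodization; trapezoidal quadrature with 1024 nodes
per zone — the scalar approximation is adequate for the axial-extent
ratios that matter here, while absolute high-NA lateral shapes would need
a vectorial treatment), forms the two-photon excitation intensity
$|E|^4$ per zone and sums the zones incoherently. Reported metrics:
**depth of focus** = FWHM of the summed on-axis 2P profile, **waist** =
lateral FWHM at best focus, plus the 1P ($|E|^2$) axial FWHM and the
design $dz$.

"Depth of focus" is definition-sensitive, and the package deliberately
reports several quantities rather than forcing one number. For the
900 nm / NA 0.5 / $n$ = 1.515 / $L$ = 4 configuration: the design
$dz$ is 42.41 µm per zone (Eq. above; first zeros of the sinc-like
envelope), the FWHM of the summed 2P profile is 27.05 µm, and the same
FWHM for the plain full aperture ($L = 1$) is 6.76 µm — exactly linear
scaling with $L$ (ratios 1:2:3:4), which, together with the equal-$dz$
invariant, is the property the design must satisfy. Absolute
depth-of-focus values quoted under other conventions (e.g. Gaussian-beam
confocal-parameter metrics, which give ≈ 2.2 µm for a 2P NA 0.5 beam) are
smaller by a convention-dependent factor of 2.5–4 and should only be
compared within one definition. The summed focus keeps a lateral waist
(0.70 µm) close to that of its highest-NA annulus and far from the
central low-NA zone's, as intended for a mask that extends depth without
sacrificing lateral confinement.

## 4. Image-quality metrics

All second moments use the sample ($N-1$) convention, everywhere —
including the heterogeneity index — so a single definition of
$\sigma_I$ serves contrast and H alike. Contrast is
$\sigma_I/\bar I$ and is undefined (an error, not NA) for non-positive
means. `depthContrastProfile()` computes it per one-voxel-thick
orthoslice along the depth axis (binning is deliberately not implicit;
callers may pre-bin), divides by the first slice so the surface reads 1
(`reverse = TRUE` for stacks recorded surface-last), excludes zero-mean
slices with a warning, and summarizes by the discrete mean and by the
trapezoidal integral of $\max(\mathrm{Contrast} - 1, 0)$ (µm). The
integral is bounded by $(\max - 1)$ times the depth span — a property
the tests enforce.

`radialFourierSpectrum()` reports the azimuthal mean of the centered DFT
magnitude in radial bins one DFT sample (of the smaller axis) wide, in
cycles/µm; windowing is off by default (`window = TRUE` applies Hann).

The heterogeneity index $H = \sigma_I^2 / R^2$ normalizes the variance
by the squared in-ROI dynamic range, so a global gain (which inflates
$\sigma_I^2$ quadratically) or offset leaves it unchanged — the reason
to prefer it over raw variance when illumination or detector gain vary
between the images being compared. $H$ grows when the *proportion* of
bright structure grows; if, instead, a single punctum brightens past the
rest, $R$ grows faster than $\sigma_I$ and $H$ falls. The clustering
fixture (below) is built to probe the first regime, which is the one a
clustering perturbation of many subcellular sites produces.

## 5. Photon calibration, precision and diffusion

Camera digital numbers convert to physical counts through the gain $g$
(e⁻/DN), electronic offset $O$ (DN, measured by `darkOffset()` as the
grand mean of shuttered frames) and quantum efficiency $\eta$:
photoelectrons are $g\,(\mathrm{DN} - O)$ and detected photons are
photoelectrons$/\eta$. For a spot with integrated intensity
$I_{spot}$ over an $N_{mask}$-pixel mask and local background $I_{bg}$
(total; $I_{bg} = N_{mask} I_{bg/pix}$ is validated), the offset cancels
in the signal:

$$N_\gamma = \tfrac{g}{\eta}(I_{spot} - I_{bg}),\qquad
  b_\gamma = \tfrac{g}{\eta}(I_{bg/pix} - O).$$

Negative photon estimates are possible under noise; they are flagged,
never clamped, and `meanPrecision()` excludes flagged spots (reporting
the count) when averaging per-spot precisions. This conversion sits in
one function (`photonCounts()`) so an alternative reading of the
calibration chain needs a one-line change.

Localization precision uses the closed-form Cramér–Rao bound for a 2D
Gaussian PSF on a pixelated detector with uniform background,
$$\sigma_{loc}^2 = \frac{\sigma_{PSF}^2 + a^2/12}{N_\gamma}
  + \frac{8\pi\,\sigma_{PSF}^4\, b_\gamma}{a^2 N_\gamma^2},$$
per axis. The tilted detection plane mixes lateral and axial blur along
y′, $\sigma_{PSF,y'} = \sqrt{\sigma_y^2\cos^2\theta +
\sigma_z^2\sin^2\theta}$, which is why precision along y′ is worse than
along x for identical photon budgets whenever $\sigma_z > \sigma_y$ —
the characteristic anisotropy of tilted-detection tracking. PSF widths
may be supplied as FWHMs (`PrecisionModel(fwhm = ...)`); they are
converted with $2\sqrt{2\ln 2}$.

MSD analysis pools squared displacements across tracks. For lag
$\tau = L\,\Delta t$ every within-track pair of positions $L$ frames
apart contributes (overlapping pairs included; at $L = 1$ this is
exactly the consecutive-step estimator, and the identity is asserted in
the tests). Static localization noise adds $2(\sigma_x^2 +
\sigma_{y'}^2)$ to every lag, so the corrected MSD subtracts it —
negative corrected values are reported as-is, since clamping would bias
ensemble averages. The ensemble $D$ comes either from the single-interval
estimator $D = \mathrm{MSD}^{corr}_{\Delta t}/(4\Delta t)$ or from the
slope/4 of an unweighted straight line through the first two lag points
(an intercept is fitted; `weighted = TRUE` uses $1/\mathrm{SE}^2$
weights). Standard errors are computed over the pooled squared
displacements; at lags beyond 1 the overlapping pairs are correlated, so
those SEs are mildly optimistic — a known property of this standard
estimator, acceptable because inference is drawn from the first two
lags. Repeated simulation at $D = 1\ µm^2/s$ (500 tracks × 50 steps,
$\Delta t$ = 50 ms, σ = 33/58 nm) recovers the truth within two standard
errors, with the uncorrected estimator biased high by
$2(\sigma_x^2+\sigma_{y'}^2)/(4\Delta t) \approx 0.045\ µm^2/s$ — the
test suite checks both.

## 6. Synthetic fixtures: what they emulate, and what they do not

All generators are pure functions of a `PhantomSpec` (including its
seed): reruns are bit-identical and the caller's RNG stream is restored.
The camera model is Poisson shot noise on expected photons plus Gaussian
read noise in electrons, divided by gain and shifted by the offset —
the same model the photon-calibration code inverts, so the
single-molecule chain can be exercised end to end from images.

* `beadPhantom()` — point-like emitters as 3D Gaussians at uniform
  interior positions with a ground-truth table; used for
  deskew round trips and width self-tests. It warns when beads sit
  closer than about two widths (centroid tests would be biased).
* `hazeVolume()` — nuclei-like blobs over a background that grows
  linearly with depth, $b(y) = b_0(1 + s\,y)$; $s = 0$ emulates tightly
  sectioned (two-photon-like) excitation, larger $s$ the accumulating
  out-of-focus haze of widefield one-photon excitation. The depth axis
  is populated edge to edge so the surface slice, which normalizes the
  contrast profile, carries the same signal statistics as the rest; the
  depth-integrated contrast then decreases monotonically with $s$.
* `clusteredPuncta()` — an unstimulated/stimulated image pair with
  shared punctum positions; the stimulated image multiplies the
  amplitudes of a random half of the puncta, drawn *dim* at baseline
  (5–15% of the bright population), by `clusterAmplitude`. Starting the
  brightening subset below the baseline maximum keeps the dynamic range
  fixed while the variance grows, so $H$ increases strictly with the
  amplitude parameter — the regime that models new puncta appearing and
  dim ones brightening. For amplitudes large enough that a boosted
  punctum overtakes the baseline maximum the index would turn over;
  sweeps should stay below that point (factor ≈ 5 with the default
  draw).

What passing these tests shows — and does not. The fixtures contain no
scattering, no depth-dependent aberrations, no fixed-pattern noise, no
photobleaching or blinking, Brownian motion only (plus one confined-walk
fixture for sublinearity), and Gaussian PSFs with fixed widths. Green
tests therefore certify the *estimators and transforms* — geometry,
conservation laws, closed forms, invariances, bias removal — not the
instrument corrections real tissue data additionally need (adaptive
optics, background models, detection/linking quality), which are out of
scope by design; spot detection and track linking themselves are
upstream concerns (TrackMate-style tables are consumed, not produced).

## 7. Problem sizes, tolerances, determinism

The working sizes were chosen as the smallest at which each quantity is
numerically converged: pupils of 96–128 samples in the test suite
(anisotropy already stable to <0.2%) and 256 in the acceptance script;
Debye quadrature at 1024 nodes; bead phantoms of $48^2×28$ voxels;
track ensembles of 200–500 × 40–50 steps (statistical assertions are
phrased in standard errors, not absolute bands). Scalar identities are
tested to 1e-12–1e-10, interpolation-mediated properties to 0.5 voxel or
1–2%, stochastic recoveries to 2–3 standard errors. Every stochastic
component takes an explicit integer seed; the optics simulations are
deterministic. The full test suite runs in well under a minute; the
acceptance script in seconds.

## 8. Known limitations

* The detection-PSF pupil is binary; Fresnel/aplanatic apodization and
  polarization (vectorial focusing) would shift absolute widths by a few
  percent at NA 0.95, though the anisotropy ratio moves little.
* The excitation simulation is scalar and ignores pulse dispersion and
  the finite coherence length (assumed far smaller than the mask step
  height, i.e. zones perfectly incoherent).
* Depth-of-focus numbers are convention-bound (see §3); compare only
  within one definition.
* TIFF output uses the `tiff` package's normalized 32-bit storage; data
  outside [0, 1] are rescaled on write with the original range in a
  `.range.json` sidecar that the package's own reader restores
  (quantization ~2e-10 relative). Third-party readers see the normalized
  values unless they apply the sidecar.
* MSD standard errors treat overlapping displacement pairs as
  independent (see §5).
* Track tables assume a single, shared frame interval; gap handling is
  limited to skipping missing pairs.
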