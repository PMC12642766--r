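#' @import methods
#' @importFrom stats coef complete.cases dist fft lm predict rnorm rpois
#'   runif sd var
#' @importFrom utils read.csv write.csv packageVersion
NULL

## ---------------------------------------------------------------------------
## Scan geometry and image containers
## ---------------------------------------------------------------------------

#' Scan geometry of an oblique acquisition
#'
#' Describes how successive light-sheet frames are displaced through the
#' specimen: the sheet/scan tilt angle \eqn{\theta} (degrees), the physical
#' scan increment per frame (\eqn{y_{step}}, um), the in-plane camera pixel
#' size \eqn{a} (um/pixel) and the fill value used for voxels that fall
#' outside the source domain during resampling.
#'
#' @slot theta numeric(1), sheet tilt angle in degrees, in [0, 90].
#' @slot ystep numeric(1), physical scan increment per frame in um (> 0).
#' @slot pixelSize numeric(1), in-plane pixel size in um/pixel (> 0).
#' @slot fillValue numeric(1), intensity assigned outside the source domain.
#' @export
setClass("ScanGeometry",
  slots = c(theta = "numeric", ystep = "numeric",
            pixelSize = "numeric", fillValue = "numeric"))

setValidity("ScanGeometry", function(object) {
  msg <- character()
  for (s in c("theta", "ystep", "pixelSize", "fillValue")) {
    v <- slot(object, s)
    if (length(v) != 1L || !is.finite(v))
      msg <- c(msg, sprintf("'%s' must be a single finite number", s))
  }
  if (length(msg)) return(msg)
  if (object@theta < 0 || object@theta > 90)
    msg <- c(msg, "'theta' must lie in [0, 90] degrees")
  if (object@ystep <= 0) msg <- c(msg, "'ystep' must be > 0")
  if (object@pixelSize <= 0) msg <- c(msg, "'pixelSize' must be > 0")
  if (length(msg)) msg else TRUE
})

#' @param theta,ystep,pixelSize,fillValue see the corresponding slots.
#' @return A \code{ScanGeometry} object.
#' @rdname ScanGeometry-class
#' @examples
#' ScanGeometry(theta = 45, ystep = 0.4, pixelSize = 0.0867)
#' @export
ScanGeometry <- function(theta = 45, ystep, pixelSize, fillValue = 0) {
  new("ScanGeometry", theta = as.numeric(theta), ystep = as.numeric(ystep),
      pixelSize = as.numeric(pixelSize), fillValue = as.numeric(fillValue))
}

#' Raw oblique frame stack
#'
#' An ordered sequence of 2D camera frames (axes x, y'), the frame index
#' advancing along the scan axis, together with its \code{\link{ScanGeometry}}.
#' The \code{offset} slot records, for stacks produced by
#' \code{\link{simulateObliqueAcquisition}}, the translation (in voxel units of
#' the deskewed frame) between the deskew output grid and the source volume.
#'
#' @slot frames 3D numeric array with dimensions (x, y', frame).
#' @slot geometry a \code{ScanGeometry}.
#' @slot offset numeric(3) provenance translation (voxels), default zero.
#' @export
setClass("ObliqueStack",
  slots = c(frames = "array", geometry = "ScanGeometry", offset = "numeric"))

setValidity("ObliqueStack", function(object) {
  d <- dim(object@frames)
  if (length(d) != 3L) return("'frames' must be a 3D array (x, y', frame)")
  if (any(d < 1L)) return("'frames' must have positive extents")
  if (length(object@offset) != 3L) return("'offset' must be numeric(3)")
  TRUE
})

#' @param frames,geometry,offset see the corresponding slots.
#' @rdname ObliqueStack-class
#' @export
ObliqueStack <- function(frames, geometry, offset = c(0, 0, 0)) {
  if (is.list(frames)) frames <- simplify2array(frames)
  new("ObliqueStack", frames = frames, geometry = geometry,
      offset = as.numeric(offset))
}

#' Reconstructed Cartesian volume with isotropic voxels
#'
#' @slot voxels 3D numeric array (x, y, z).
#' @slot voxelSize numeric(1), isotropic voxel edge in um.
#' @slot origin numeric(3); position, in voxel units of the deskew affine
#'   frame, that index (0,0,0) of \code{voxels} corresponds to. Zero for
#'   volumes that define their own frame.
#' @export
setClass("CartesianVolume",
  slots = c(voxels = "array", voxelSize = "numeric", origin = "numeric"))

setValidity("CartesianVolume", function(object) {
  if (length(dim(object@voxels)) != 3L) return("'voxels' must be a 3D array")
  if (length(object@voxelSize) != 1L || !is.finite(object@voxelSize) ||
      object@voxelSize <= 0)
    return("'voxelSize' must be a single positive number")
  if (length(object@origin) != 3L) return("'origin' must be numeric(3)")
  TRUE
})

#' @param voxels,voxelSize,origin see the corresponding slots.
#' @rdname CartesianVolume-class
#' @export
CartesianVolume <- function(voxels, voxelSize = 1, origin = c(0, 0, 0)) {
  new("CartesianVolume", voxels = voxels, voxelSize = as.numeric(voxelSize),
      origin = as.numeric(origin))
}

#' Homogeneous-coordinate affine transform
#'
#' The composed deskew transform T_post R(theta) T_pre S K together with its
#' factors. Coordinates are 0-based voxel indices; positions refer to voxel
#' centers.
#'
#' @slot matrix 4x4 homogeneous transform, last row (0,0,0,1).
#' @slot components named list with the factors \code{K} (skew), \code{S}
#'   (scale), \code{R} (rotation) and the recentering translations
#'   \code{pre}, \code{post} (4x4 each), plus the shear factors \code{sk},
#'   \code{sc} and \code{theta}.
#' @export
setClass("AffineTransform",
  slots = c(matrix = "matrix", components = "list"))

setValidity("AffineTransform", function(object) {
  m <- object@matrix
  if (!all(dim(m) == c(4L, 4L))) return("'matrix' must be 4x4")
  if (!isTRUE(all.equal(m[4, ], c(0, 0, 0, 1), tolerance = 1e-12)))
    return("last row of 'matrix' must be (0, 0, 0, 1)")
  TRUE
})

## ---------------------------------------------------------------------------
## Optics
## ---------------------------------------------------------------------------

#' Remote-focus detection model
#'
#' Parameters of the O2 -> O3 remote-focusing relay that forms the tilted
#' detection PSF: the secondary objective (O2, air immersion) and tertiary
#' objective (O3, solid immersion) numerical apertures and refractive
#' indices, the tilt between their optical axes, the emission wavelength and
#' the numerical grid used for the pupil/field simulation.
#'
#' @slot naO2,naO3 numerical apertures (defaults 0.95 and 1.0).
#' @slot nO2,nO3 immersion indices (defaults 1.0 air and 1.515 glass).
#' @slot tiltDeg angle between the O2 and O3 optical axes in degrees, [0, 90).
#' @slot wavelength emission wavelength in um.
#' @slot pupilSamples samples across the pupil diameter.
#' @slot padFactor zero-padding factor; the real-space pitch is
#'   wavelength / (nO3 * padFactor * 2 * NA_O3 / nO3).
#' @slot zMax,zStep axial simulation half-range and step in um (O3 space).
#' @slot cropRadius half-width in um of the real-space window kept per plane.
#' @export
setClass("RemoteFocusModel",
  slots = c(naO2 = "numeric", naO3 = "numeric", nO2 = "numeric",
            nO3 = "numeric", tiltDeg = "numeric", wavelength = "numeric",
            pupilSamples = "numeric", padFactor = "numeric",
            zMax = "numeric", zStep = "numeric", cropRadius = "numeric"))

setValidity("RemoteFocusModel", function(object) {
  msg <- character()
  if (object@naO2 > object@nO2) msg <- c(msg, "naO2 must be <= nO2")
  if (object@naO3 > object@nO3) msg <- c(msg, "naO3 must be <= nO3")
  if (object@tiltDeg < 0 || object@tiltDeg >= 90)
    msg <- c(msg, "tiltDeg must lie in [0, 90)")
  if (object@wavelength <= 0) msg <- c(msg, "wavelength must be > 0")
  if (object@pupilSamples < 16) msg <- c(msg, "pupilSamples too small")
  if (object@padFactor < 1) msg <- c(msg, "padFactor must be >= 1")
  if (length(msg)) msg else TRUE
})

#' @param naO2,naO3,nO2,nO3,tiltDeg,wavelength,pupilSamples,padFactor,zMax,zStep,cropRadius
#'   see the corresponding slots.
#' @rdname RemoteFocusModel-class
#' @export
RemoteFocusModel <- function(naO2 = 0.95, naO3 = 1.0, nO2 = 1.0, nO3 = 1.515,
                             tiltDeg = 45, wavelength = 0.55,
                             pupilSamples = 256, padFactor = 4,
                             zMax = 1.6, zStep = 0.05, cropRadius = 3) {
  new("RemoteFocusModel", naO2 = naO2, naO3 = naO3, nO2 = nO2, nO3 = nO3,
      tiltDeg = tiltDeg, wavelength = wavelength,
      pupilSamples = pupilSamples, padFactor = padFactor,
      zMax = zMax, zStep = zStep, cropRadius = cropRadius)
}

#' Simulated point spread function volume
#'
#' @slot intensity non-negative 3D array, peak normalized to 1.
#' @slot sampling numeric(3), voxel pitch in um per axis (x, y, z).
#' @slot frame "raw" (grid axes) or "principal" (rotated to principal axes).
#' @export
setClass("PsfVolume",
  slots = c(intensity = "array", sampling = "numeric", frame = "character"))

setValidity("PsfVolume", function(object) {
  if (length(dim(object@intensity)) != 3L)
    return("'intensity' must be a 3D array")
  if (min(object@intensity) < 0) return("'intensity' must be non-negative")
  if (abs(max(object@intensity) - 1) > 1e-6)
    return("'intensity' must be normalized to peak 1")
  if (length(object@sampling) != 3L || any(object@sampling <= 0))
    return("'sampling' must be three positive pitches")
  if (!object@frame %in% c("raw", "principal"))
    return("'frame' must be \"raw\" or \"principal\"")
  TRUE
})

#' Layer-cake annular-zone mask design
#'
#' Contiguous annular pupil zones (NA_inner, NA_outer), the first starting at
#' NA 0, every zone sharing the same Bessel-focus axial extent
#' \code{dzTarget} (um).
#'
#' @slot wavelength excitation wavelength in um.
#' @slot n immersion refractive index.
#' @slot zones L x 2 matrix of (NA_inner, NA_outer) per zone.
#' @slot dzTarget common per-zone axial extent in um.
#' @slot focalLength objective back focal length in mm (NA if unknown); used
#'   to convert NA boundaries to pupil radii r = f * NA.
#' @export
setClass("LayerCakeDesign",
  slots = c(wavelength = "numeric", n = "numeric", zones = "matrix",
            dzTarget = "numeric", focalLength = "numeric"))

setValidity("LayerCakeDesign", function(object) {
  z <- object@zones
  if (ncol(z) != 2L || nrow(z) < 1L) return("'zones' must be an L x 2 matrix")
  if (abs(z[1, 1]) > 1e-12) return("first zone must start at NA 0")
  if (any(z[, 2] <= z[, 1])) return("each zone needs NA_outer > NA_inner")
  if (nrow(z) > 1 && max(abs(z[-1, 1] - z[-nrow(z), 2])) > 1e-9)
    return("zones must be contiguous and non-overlapping")
  if (max(z) > object@n + 1e-12) return("zone NA exceeds refractive index")
  dz <- axialExtent(z[, 1], z[, 2], object@wavelength, object@n)
  if (max(abs(dz / object@dzTarget - 1)) > 1e-6)
    return("every zone's axial extent must equal dzTarget")
  TRUE
})

#' Axial/lateral two-photon focus profiles of a mask design
#'
#' @slot z axial coordinates in um.
#' @slot axial2p incoherently summed on-axis 2P profile (|E|^4), peak 1.
#' @slot axial1p matching 1P profile (|E|^2 summed), peak 1.
#' @slot r lateral radii in um.
#' @slot lateral2p summed 2P lateral profile at best focus, peak 1.
#' @slot zoneAxial2p matrix (length(z) x L) of per-zone |E|^4 axial profiles
#'   on the common (unnormalized) intensity scale.
#' @slot metrics list with \code{dof2p}, \code{dof1p} (axial FWHMs, um),
#'   \code{waist2p} (lateral FWHM at focus, um) and \code{dzTarget}.
#' @export
setClass("FocusProfile",
  slots = c(z = "numeric", axial2p = "numeric", axial1p = "numeric",
            r = "numeric", lateral2p = "numeric", zoneAxial2p = "matrix",
            metrics = "list"))

## ---------------------------------------------------------------------------
## Single-molecule analysis
## ---------------------------------------------------------------------------

#' Camera calibration for photon conversion
#'
#' @slot gain conversion gain g in electrons per digital number (> 0).
#' @slot qe quantum efficiency eta, in (0, 1].
#' @slot offset electronic offset O in digital numbers (>= 0).
#' @export
setClass("CameraCalibration",
  slots = c(gain = "numeric", qe = "numeric", offset = "numeric"))

setValidity("CameraCalibration", function(object) {
  if (object@gain <= 0) return("'gain' must be > 0")
  if (object@qe <= 0 || object@qe > 1) return("'qe' must lie in (0, 1]")
  if (object@offset < 0) return("'offset' must be >= 0")
  TRUE
})

#' @param gain,qe,offset see the corresponding slots.
#' @rdname CameraCalibration-class
#' @export
CameraCalibration <- function(gain, qe = 1, offset = 0) {
  new("CameraCalibration", gain = as.numeric(gain), qe = as.numeric(qe),
      offset = as.numeric(offset))
}

#' Gaussian-PSF localization precision model
#'
#' Pixel size and per-axis Gaussian PSF standard deviations feeding the
#' Cramer-Rao precision bound; the y' axis width is mixed from the lateral y
#' and axial z widths at the detection tilt.
#'
#' @slot pixelSize camera pixel size a in um (sample referred).
#' @slot sigmaX,sigmaY,sigmaZ Gaussian PSF standard deviations in um.
#' @slot tiltDeg detection-plane tilt in degrees (default 45).
#' @export
setClass("PrecisionModel",
  slots = c(pixelSize = "numeric", sigmaX = "numeric", sigmaY = "numeric",
            sigmaZ = "numeric", tiltDeg = "numeric"))

setValidity("PrecisionModel", function(object) {
  if (object@pixelSize <= 0) return("'pixelSize' must be > 0")
  if (any(c(object@sigmaX, object@sigmaY, object@sigmaZ) <= 0))
    return("PSF sigmas must be > 0")
  TRUE
})

#' @param pixelSize,sigmaX,sigmaY,sigmaZ,tiltDeg see the corresponding slots.
#' @param fwhm optional numeric(3) of PSF full widths at half maximum in um;
#'   when supplied, sigmas are derived as FWHM / (2 sqrt(2 ln 2)).
#' @rdname PrecisionModel-class
#' @export
PrecisionModel <- function(pixelSize, sigmaX, sigmaY, sigmaZ, tiltDeg = 45,
                           fwhm = NULL) {
  if (!is.null(fwhm)) {
    s <- fwhmToSigma(fwhm)
    sigmaX <- s[1]; sigmaY <- s[2]; sigmaZ <- s[3]
  }
  new("PrecisionModel", pixelSize = pixelSize, sigmaX = sigmaX,
      sigmaY = sigmaY, sigmaZ = sigmaZ, tiltDeg = tiltDeg)
}

#' Set of single-particle tracks
#'
#' A long-format table of localizations with columns \code{track},
#' \code{frame}, \code{x}, \code{y} (positions in um; y is the tilted in-plane
#' y' axis) and a shared frame interval \code{dt} in seconds.
#'
#' @slot tracks data.frame with columns track, frame, x, y.
#' @slot dt frame interval in seconds (> 0).
#' @export
setClass("TrackSet", slots = c(tracks = "data.frame", dt = "numeric"))

setValidity("TrackSet", function(object) {
  tr <- object@tracks
  need <- c("track", "frame", "x", "y")
  if (!all(need %in% names(tr)))
    return("tracks need columns track, frame, x, y")
  if (length(object@dt) != 1L || object@dt <= 0) return("'dt' must be > 0")
  if (nrow(tr)) {
    ok <- vapply(split(tr$frame, tr$track),
                 function(f) all(diff(f) > 0), logical(1))
    if (!all(ok)) return("frames must be strictly increasing within a track")
  }
  TRUE
})

#' @param tracks,dt see the corresponding slots.
#' @rdname TrackSet-class
#' @export
TrackSet <- function(tracks, dt) {
  tracks <- as.data.frame(tracks)
  tracks <- tracks[order(tracks$track, tracks$frame), , drop = FALSE]
  rownames(tracks) <- NULL
  new("TrackSet", tracks = tracks, dt = as.numeric(dt))
}

#' Mean-squared-displacement analysis result
#'
#' @slot lags time lags tau in seconds.
#' @slot msdRaw,msdCorrected MSD per lag in um^2; corrected subtracts the
#'   localization variance 2 (sigma_x^2 + sigma_y'^2).
#' @slot se standard error of the MSD per lag (um^2).
#' @slot nPairs number of displacement pairs per lag.
#' @slot d,dSe diffusion coefficient estimate and uncertainty (um^2/s).
#' @slot method "pooled" (single-interval) or "lagfit" (slope of first two
#'   lags / 4).
#' @slot negativeCorrected TRUE if any corrected MSD value is negative
#'   (reported as-is, never clamped).
#' @export
setClass("MsdResult",
  slots = c(lags = "numeric", msdRaw = "numeric", msdCorrected = "numeric",
            se = "numeric", nPairs = "numeric", d = "numeric",
            dSe = "numeric", method = "character",
            negativeCorrected = "logical"))

#' Contrast-vs-depth profile
#'
#' @slot depths sampled depths from the surface in um.
#' @slot values per-slice contrast normalized to the surface slice
#'   (values[1] == 1).
#' @slot depthAveraged discrete mean of the normalized profile.
#' @slot depthIntegrated trapezoidal integral of max(value - 1, 0) in um.
#' @slot excluded indices of slices dropped for zero mean.
#' @export
setClass("ContrastProfile",
  slots = c(depths = "numeric", values = "numeric",
            depthAveraged = "numeric", depthIntegrated = "numeric",
            excluded = "integer"))

setValidity("ContrastProfile", function(object) {
  if (length(object@depths) != length(object@values))
    return("'depths' and 'values' must have equal length")
  if (length(object@values) && abs(object@values[1] - 1) > 1e-9)
    return("profile must be normalized to the surface slice (values[1] == 1)")
  if (object@depthIntegrated < 0) return("'depthIntegrated' must be >= 0")
  TRUE
})

#' Heterogeneity index result
#'
#' @slot h dimensionless index sigma^2 / R^2.
#' @slot mean,sd,range the intensity mean, sample SD and dynamic range.
#' @slot n number of pixels.
#' @export
setClass("HeterogeneityResult",
  slots = c(h = "numeric", mean = "numeric", sd = "numeric",
            range = "numeric", n = "integer"))

## ---------------------------------------------------------------------------
## Fixtures
## ---------------------------------------------------------------------------

#' Specification for synthetic phantoms
#'
#' Parameters shared by the synthetic generators. All generators are pure
#' functions of the spec (including its seed): identical specs give
#' bit-identical output.
#'
#' @slot shape voxel (or pixel) dimensions of the generated array.
#' @slot voxelSize voxel edge in um.
#' @slot beadSigmas numeric(3), per-axis Gaussian bead widths in um.
#' @slot nBeads number of beads / nuclei / puncta.
#' @slot background baseline intensity (expected photons per voxel).
#' @slot amplitude peak expected photons of a bead/punctum above background.
#' @slot hazeSlope background growth per um of depth (fraction of
#'   \code{background} per um).
#' @slot clusterAmplitude stimulated-state amplitude scale of the clustered
#'   subset of puncta (>= 1).
#' @slot noise list(poisson = logical, readSd = electrons, gain = e-/DN,
#'   offset = DN) camera noise model; set \code{poisson = FALSE} and
#'   \code{readSd = 0} for noise-free ground truth.
#' @slot seed integer RNG seed.
#' @export
setClass("PhantomSpec",
  slots = c(shape = "numeric", voxelSize = "numeric", beadSigmas = "numeric",
            nBeads = "numeric", background = "numeric", amplitude = "numeric",
            hazeSlope = "numeric", clusterAmplitude = "numeric",
            noise = "list", seed = "numeric"))

#' @param shape,voxelSize,beadSigmas,nBeads,background,amplitude,hazeSlope,clusterAmplitude,noise,seed
#'   see the corresponding slots.
#' @rdname PhantomSpec-class
#' @export
PhantomSpec <- function(shape = c(64, 64, 32), voxelSize = 0.2,
                        beadSigmas = c(0.15, 0.17, 0.35), nBeads = 5,
                        background = 10, amplitude = 500, hazeSlope = 0,
                        clusterAmplitude = 1,
                        noise = list(poisson = FALSE, readSd = 0,
                                     gain = 1, offset = 0),
                        seed = 1L) {
  new("PhantomSpec", shape = shape, voxelSize = voxelSize,
      beadSigmas = beadSigmas, nBeads = nBeads, background = background,
      amplitude = amplitude, hazeSlope = hazeSlope,
      clusterAmplitude = clusterAmplitude, noise = noise, seed = seed)
}
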