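## Accessor generics. Slot access from user code should go through these.

#' @rdname ScanGeometry-class
#' @param object an object of the documented class.
#' @export
setGeneric("scanTheta", function(object) standardGeneric("scanTheta"))
#' @rdname ScanGeometry-class
#' @export
setGeneric("yStep", function(object) standardGeneric("yStep"))
#' @rdname ScanGeometry-class
#' @export
setGeneric("pixelSize", function(object) standardGeneric("pixelSize"))
#' @rdname ScanGeometry-class
#' @export
setGeneric("fillValue", function(object) standardGeneric("fillValue"))

#' @rdname ObliqueStack-class
#' @param object an object of the documented class.
#' @export
setGeneric("frames", function(object) standardGeneric("frames"))
#' @rdname ObliqueStack-class
#' @export
setGeneric("geometry", function(object) standardGeneric("geometry"))

#' @rdname CartesianVolume-class
#' @param object an object of the documented class.
#' @export
setGeneric("voxels", function(object) standardGeneric("voxels"))
#' @rdname CartesianVolume-class
#' @export
setGeneric("voxelSize", function(object) standardGeneric("voxelSize"))
#' @rdname CartesianVolume-class
#' @export
setGeneric("origin", function(object) standardGeneric("origin"))

#' @rdname AffineTransform-class
#' @param object an object of the documented class.
#' @export
setGeneric("affineMatrix", function(object) standardGeneric("affineMatrix"))
#' @rdname AffineTransform-class
#' @export
setGeneric("affineComponents",
           function(object) standardGeneric("affineComponents"))

#' @rdname LayerCakeDesign-class
#' @param object an object of the documented class.
#' @export
setGeneric("zones", function(object) standardGeneric("zones"))
#' @rdname LayerCakeDesign-class
#' @export
setGeneric("dzTarget", function(object) standardGeneric("dzTarget"))

#' @rdname TrackSet-class
#' @param object an object of the documented class.
#' @export
setGeneric("tracks", function(object) standardGeneric("tracks"))
#' @rdname TrackSet-class
#' @export
setGeneric("timeStep", function(object) standardGeneric("timeStep"))

#' @rdname MsdResult-class
#' @param object an object of the documented class.
#' @export
setGeneric("diffusionCoefficient",
           function(object) standardGeneric("diffusionCoefficient"))

setMethod("scanTheta", "ScanGeometry", function(object) object@theta)
setMethod("yStep", "ScanGeometry", function(object) object@ystep)
setMethod("pixelSize", "ScanGeometry", function(object) object@pixelSize)
setMethod("fillValue", "ScanGeometry", function(object) object@fillValue)

setMethod("frames", "ObliqueStack", function(object) object@frames)
setMethod("geometry", "ObliqueStack", function(object) object@geometry)

setMethod("voxels", "CartesianVolume", function(object) object@voxels)
setMethod("voxelSize", "CartesianVolume", function(object) object@voxelSize)
setMethod("origin", "CartesianVolume", function(object) object@origin)

setMethod("affineMatrix", "AffineTransform", function(object) object@matrix)
setMethod("affineComponents", "AffineTransform",
          function(object) object@components)

setMethod("zones", "LayerCakeDesign", function(object) object@zones)
setMethod("dzTarget", "LayerCakeDesign", function(object) object@dzTarget)

setMethod("tracks", "TrackSet", function(object) object@tracks)
setMethod("timeStep", "TrackSet", function(object) object@dt)

setMethod("diffusionCoefficient", "MsdResult",
          function(object) c(d = object@d, se = object@dSe))

## show() methods -----------------------------------------------------------

setMethod("show", "ScanGeometry", function(object) {
  cat(sprintf(
    "ScanGeometry: theta = %g deg, ystep = %g um, pixel = %g um (fill %g)\n",
    object@theta, object@ystep, object@pixelSize, object@fillValue))
})

setMethod("show", "ObliqueStack", function(object) {
  d <- dim(object@frames)
  cat(sprintf("ObliqueStack: %d frames of %d x %d (x, y')\n",
              d[3], d[1], d[2]))
  show(object@geometry)
})

setMethod("show", "CartesianVolume", function(object) {
  d <- dim(object@voxels)
  cat(sprintf("CartesianVolume: %d x %d x %d voxels, %g um isotropic\n",
              d[1], d[2], d[3], object@voxelSize))
})

setMethod("show", "AffineTransform", function(object) {
  cat("AffineTransform (T_post R T_pre S K), sk =",
      format(object@components$sk, digits = 6), " sc =",
      format(object@components$sc, digits = 6), "\n")
  print(round(object@matrix, 6))
})

setMethod("show", "RemoteFocusModel", function(object) {
  cat(sprintf(
    "RemoteFocusModel: O2 NA %.2f (n=%.3f) -> O3 NA %.2f (n=%.3f), tilt %g deg\n",
    object@naO2, object@nO2, object@naO3, object@nO3, object@tiltDeg))
  cat(sprintf("  lambda = %g um, %g samples across pupil (pad %g)\n",
              object@wavelength, object@pupilSamples, object@padFactor))
})

setMethod("show", "PsfVolume", function(object) {
  d <- dim(object@intensity)
  cat(sprintf("PsfVolume (%s frame): %d x %d x %d, pitch %s um\n",
              object@frame, d[1], d[2], d[3],
              paste(signif(object@sampling, 3), collapse = " x ")))
})

setMethod("show", "LayerCakeDesign", function(object) {
  z <- object@zones
  cat(sprintf(
    "LayerCakeDesign: %d zones, lambda %g um, n %.3f, dz %.3f um\n",
    nrow(z), object@wavelength, object@n, object@dzTarget))
  for (i in seq_len(nrow(z)))
    cat(sprintf("  zone %d: NA %.4f - %.4f\n", i, z[i, 1], z[i, 2]))
})

setMethod("show", "FocusProfile", function(object) {
  m <- object@metrics
  cat(sprintf(
    "FocusProfile: 2P DOF %.2f um (1P %.2f), waist %.3f um, dz %.2f um\n",
    m$dof2p, m$dof1p, m$waist2p, m$dzTarget))
})

setMethod("show", "CameraCalibration", function(object) {
  cat(sprintf("CameraCalibration: gain %g e-/DN, QE %g, offset %g DN\n",
              object@gain, object@qe, object@offset))
})

setMethod("show", "PrecisionModel", function(object) {
  cat(sprintf(
    "PrecisionModel: a = %g um, sigma (x,y,z) = (%g, %g, %g) um, tilt %g deg\n",
    object@pixelSize, object@sigmaX, object@sigmaY, object@sigmaZ,
    object@tiltDeg))
})

setMethod("show", "TrackSet", function(object) {
  tr <- object@tracks
  cat(sprintf("TrackSet: %d localizations in %d tracks, dt = %g s\n",
              nrow(tr), length(unique(tr$track)), object@dt))
})

setMethod("show", "MsdResult", function(object) {
  cat(sprintf("MsdResult (%s): D = %.4g +/- %.2g um^2/s\n",
              object@method, object@d, object@dSe))
  df <- data.frame(lag = object@lags, msd = object@msdRaw,
                   corrected = object@msdCorrected, se = object@se,
                   n = object@nPairs)
  print(df, row.names = FALSE, digits = 4)
  if (object@negativeCorrected)
    cat("  note: corrected MSD contains negative values (reported as-is)\n")
})

setMethod("show", "ContrastProfile", function(object) {
  cat(sprintf(
    "ContrastProfile: %d depths over %.2f um; mean %.3f, integrated %.3f um\n",
    length(object@depths), diff(range(object@depths)),
    object@depthAveraged, object@depthIntegrated))
  if (length(object@excluded))
    cat("  excluded zero-mean slices:", paste(object@excluded, collapse = ","),
        "\n")
})

setMethod("show", "HeterogeneityResult", function(object) {
  cat(sprintf(
    "HeterogeneityResult: H = %.4g (mean %.4g, sd %.4g, range %.4g, n = %d)\n",
    object@h, object@mean, object@sd, object@range, object@n))
})

setMethod("show", "PhantomSpec", function(object) {
  cat(sprintf("PhantomSpec: shape %s, %g beads, seed %d\n",
              paste(object@shape, collapse = "x"), object@nBeads,
              as.integer(object@seed)))
})
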