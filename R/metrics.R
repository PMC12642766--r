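## Image-quality statistics: coefficient-of-variation contrast, depth
## profiles, radial Fourier spectra, heterogeneity index.

#' Coefficient-of-variation image contrast
#'
#' Contrast of an intensity array, defined as the sample standard deviation
#' (N - 1 denominator) divided by the mean.
#'
#' @param image numeric array (any shape) with at least two pixels.
#' @return scalar contrast.
#' @examples
#' imageContrast(c(0, 0, 1, 1))  # 1.1547
#' @export
imageContrast <- function(image) {
  v <- as.numeric(image)
  v <- v[is.finite(v)]
  if (length(v) < 2L) stop("imageContrast: need at least two pixels")
  m <- mean(v)
  if (m <= 0) stop("imageContrast: undefined for non-positive mean")
  sd(v) / m
}

#' Depth-dependent contrast profile of a volume
#'
#' Computes the per-slice coefficient of variation along the illumination
#' depth axis, normalizes it to the surface slice so the profile starts at 1,
#' and summarizes it by the discrete mean (depth-averaged contrast) and by
#' the trapezoidal integral of max(contrast - 1, 0) (depth-integrated
#' contrast, um).
#'
#' @param volume a \code{\link{CartesianVolume}} or a plain 3D array.
#' @param axis depth axis along which slices are taken: 1, 2 or 3, or one of
#'   "x", "y", "z". Default 2 (the y' illumination-propagation axis).
#' @param reverse set TRUE for stacks acquired surface-last.
#' @param voxelSize slice spacing in um; taken from the volume when omitted.
#' @return a \code{\link{ContrastProfile}}. Slices with zero mean are
#'   excluded with a warning and recorded in the \code{excluded} slot.
#' @export
depthContrastProfile <- function(volume, axis = 2, reverse = FALSE,
                                 voxelSize = NULL) {
  if (is(volume, "CartesianVolume")) {
    arr <- volume@voxels
    if (is.null(voxelSize)) voxelSize <- volume@voxelSize
  } else {
    arr <- volume
    if (is.null(voxelSize)) voxelSize <- 1
  }
  if (is.character(axis)) axis <- match(tolower(axis), c("x", "y", "z"))
  stopifnot(axis %in% 1:3)
  n <- dim(arr)[axis]
  if (n < 2L) stop("depthContrastProfile: need at least two slices")
  ord <- if (reverse) rev(seq_len(n)) else seq_len(n)

  sliceAt <- switch(axis,
    function(i) arr[i, , ], function(i) arr[, i, ], function(i) arr[, , i])
  raw <- vapply(ord, function(i) {
    s <- as.numeric(sliceAt(i))
    if (mean(s) <= 0) NA_real_ else sd(s) / mean(s)
  }, numeric(1))

  excluded <- which(!is.finite(raw))
  if (length(excluded))
    warning("depthContrastProfile: excluding ", length(excluded),
            " zero-mean slice(s)")
  keep <- which(is.finite(raw))
  if (!length(keep)) stop("depthContrastProfile: no usable slices")
  vals <- raw[keep] / raw[keep][1]
  depths <- (keep - keep[1]) * voxelSize

  pos <- pmax(vals - 1, 0)
  integ <- if (length(depths) > 1)
    sum(diff(depths) * (pos[-1] + pos[-length(pos)]) / 2) else 0
  new("ContrastProfile", depths = depths, values = vals,
      depthAveraged = mean(vals), depthIntegrated = integ,
      excluded = as.integer(excluded))
}

#' Azimuthally averaged Fourier amplitude spectrum
#'
#' Magnitude of the centered 2D discrete Fourier transform of an image,
#' averaged into radial spatial-frequency bins one DFT sample (of the
#' smaller axis) wide.
#'
#' @param image 2D numeric matrix with finite values.
#' @param pixelSize pixel pitch in um; frequencies are reported in
#'   cycles/um.
#' @param window apply a Hann window before transforming (default FALSE).
#' @return data.frame with columns \code{frequency} (bin center, cycles/um)
#'   and \code{amplitude} (mean |F| in the bin).
#' @export
radialFourierSpectrum <- function(image, pixelSize = 1, window = FALSE) {
  if (length(dim(image)) != 2L) stop("radialFourierSpectrum: need a matrix")
  if (!all(is.finite(image)))
    stop("radialFourierSpectrum: non-finite pixels")
  d <- dim(image)
  if (window) {
    hann <- function(n) 0.5 - 0.5 * cos(2 * pi * seq(0, n - 1) / (n - 1))
    image <- image * outer(hann(d[1]), hann(d[2]))
  }
  amp <- abs(fft(image))
  fx <- (seq_len(d[1]) - 1) / d[1]
  fy <- (seq_len(d[2]) - 1) / d[2]
  fx <- ifelse(fx > 0.5, fx - 1, fx)
  fy <- ifelse(fy > 0.5, fy - 1, fy)
  fr <- sqrt(outer(fx^2, fy^2, `+`)) / pixelSize

  binw <- 1 / (min(d) * pixelSize)
  bin <- floor(as.numeric(fr) / binw + 0.5)
  mx <- floor(0.5 / pixelSize / binw + 0.5)
  keep <- bin <= mx
  m <- tapply(as.numeric(amp)[keep], bin[keep], mean)
  data.frame(frequency = as.numeric(names(m)) * binw,
             amplitude = as.numeric(m))
}

#' Gain-invariant heterogeneity index
#'
#' Quantifies spatial intensity unevenness of a region of interest as
#' \eqn{H = \sigma_I^2 / R^2}, the sample variance divided by the squared
#' dynamic range \eqn{R = I_{max} - I_{min}}. Multiplying all intensities by
#' a positive constant, or adding a constant offset, leaves H unchanged, so
#' H separates genuine clustering from global gain.
#'
#' @param roi numeric array (typically a 2D ROI of a maximum-intensity
#'   projection) with at least two pixels and non-zero dynamic range.
#' @return a \code{\link{HeterogeneityResult}}.
#' @export
heterogeneityIndex <- function(roi) {
  v <- as.numeric(roi)
  v <- v[is.finite(v)]
  if (length(v) < 2L) stop("heterogeneityIndex: need at least two pixels")
  r <- max(v) - min(v)
  if (r <= 0)
    stop("heterogeneityIndex: undefined for a constant ROI (R = 0)")
  new("HeterogeneityResult", h = var(v) / r^2, mean = mean(v), sd = sd(v),
      range = r, n = length(v))
}

#' Maximum-intensity projection helper
#'
#' @param volume a \code{\link{CartesianVolume}} or 3D array.
#' @param axis axis to project over (1, 2, 3 or "x", "y", "z").
#' @return 2D matrix of per-pixel maxima.
#' @export
maxProjection <- function(volume, axis = 3) {
  arr <- if (is(volume, "CartesianVolume")) volume@voxels else volume
  if (is.character(axis)) axis <- match(tolower(axis), c("x", "y", "z"))
  apply(arr, setdiff(1:3, axis), max)
}
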