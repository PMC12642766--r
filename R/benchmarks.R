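## Small closed-form benchmark helpers used when comparing imaging
## modalities from measured PSF width tables and acquisition rates.

#' Per-axis resolution reduction between two modalities
#'
#' Fractional FWHM reduction 1 - new/reference per axis.
#'
#' @param fwhmRef,fwhmNew FWHM vectors (same units, same axis order).
#' @return fractional reductions.
#' @examples
#' axisReduction(c(373, 458, 975), c(299, 377, 692))  # ~0.20, 0.18, 0.29
#' @export
axisReduction <- function(fwhmRef, fwhmNew) 1 - fwhmNew / fwhmRef

#' Three-dimensional resolution recovery factor
#'
#' Ratio of the resolution-volume products (the product of the per-axis
#' FWHMs, proportional to the focal-volume ellipsoid) of a reference
#' modality to an improved one: how many times smaller the blurred spot
#' volume becomes.
#'
#' @param fwhmRef,fwhmNew numeric(3) FWHMs per axis.
#' @return scalar volume ratio.
#' @export
resolutionRecovery <- function(fwhmRef, fwhmNew) {
  stopifnot(length(fwhmRef) == length(fwhmNew))
  prod(fwhmRef) / prod(fwhmNew)
}

#' Lateral anisotropy ratio
#'
#' y/x ratio of lateral FWHMs, the standard summary of the mild in-plane
#' anisotropy a tilted remote-focus relay imprints on the detection PSF.
#'
#' @param fwhm named or ordered numeric with x and y lateral widths first.
#' @return FWHM_y / FWHM_x.
#' @export
lateralAnisotropy <- function(fwhm) {
  if (!is.null(names(fwhm)) && all(c("x", "y") %in% names(fwhm)))
    unname(fwhm["y"] / fwhm["x"])
  else unname(fwhm[2] / fwhm[1])
}

#' Illumination-NA scaling of peak intensity and tolerable dwell
#'
#' Reducing the illumination NA by a factor alpha while keeping the average
#' power fixed lowers the peak intensity by alpha^2 (peak intensity scales
#' with NA^2); holding per-voxel SNR for two-photon signal
#' (S proportional to Ipeak^2 tau) then allows the per-voxel dwell to grow
#' by alpha^4.
#'
#' @param alpha NA reduction factor (> 0).
#' @return named numeric with \code{peakReduction} (alpha^2) and
#'   \code{dwellExtension} (alpha^4).
#' @examples
#' naScaling(4.3)  # ~19x lower peak, ~340x longer dwell
#' @export
naScaling <- function(alpha) {
  if (any(alpha <= 0)) stop("naScaling: alpha must be > 0")
  c(peakReduction = alpha^2, dwellExtension = alpha^4)
}
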