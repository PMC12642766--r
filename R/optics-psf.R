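## Tilted remote-focus detection PSF: effective pupil from the overlap of
## the O2 exit cone and the tilted O3 acceptance cone, then plane-by-plane
## angular-spectrum propagation.

## 2D FFT with centered (fftshift) conventions
fft2c <- function(m) {
  d <- dim(m)
  shift <- function(x) {
    i1 <- c((d[1] / 2 + 1):d[1], 1:(d[1] / 2))
    i2 <- c((d[2] / 2 + 1):d[2], 1:(d[2] / 2))
    x[i1, i2]
  }
  shift(fft(shift(m)))
}

#' Effective remote-focus pupil
#'
#' Binary effective pupil of the O2 -> O3 relay, evaluated on the wavevector
#' sphere of the remote (air) replica space, whose coordinates map 1:1 onto
#' the sample after the O1 -> O2 remote magnification. A direction is
#' transmitted when it lies (i) inside the O2 exit cone (transverse sine
#' within naO2/nO2 of the O2 axis) and (ii) inside the acceptance cone of
#' the tilted O3, whose numerical aperture is medium-invariant: the air-side
#' half-angle is arcsin(min(1, naO3/nO2)) about the tilted axis (a full
#' half-space for naO3 >= nO2). For tilt > 0 the overlap trims a crescent
#' from the y side of the O2 disc - the "compression of light in the tilted
#' (y) direction" that makes the PSF mildly wider along y.
#'
#' @param model a \code{\link{RemoteFocusModel}}.
#' @return list with the binary pupil matrix \code{P}, the direction-sine
#'   axes \code{sx}, \code{sy}, and the grid step \code{ds}.
#' @keywords internal
remoteFocusPupil <- function(model) {
  sMax <- model@naO2 / model@nO2
  N <- as.integer(round(model@pupilSamples * model@padFactor))
  if (N %% 2L) N <- N + 1L
  ds <- 2 * sMax / model@pupilSamples
  ax <- (seq_len(N) - 1 - N / 2) * ds
  sx <- matrix(ax, N, N)
  sy <- matrix(ax, N, N, byrow = TRUE)
  s2 <- sx^2 + sy^2

  inside2 <- s2 <= sMax^2
  sz <- sqrt(pmax(0, 1 - s2))
  t <- model@tiltDeg * pi / 180
  ## angle from the tilted O3 axis (tilt about x, toward +y)
  cosFromO3 <- sy * sin(t) + sz * cos(t)
  s3 <- min(1, model@naO3 / model@nO2)
  inside3 <- cosFromO3 >= sqrt(1 - s3^2)

  list(P = (inside2 & inside3) * 1, sx = ax, sy = ax, ds = ds)
}

#' Simulate the tilted remote-focus detection PSF
#'
#' Builds the effective pupil of the O2 -> O3 remote-focus pair (see
#' \code{\link{remoteFocusPupil}}) and propagates it plane by plane through
#' focus with the angular-spectrum defocus phase
#' \eqn{\exp(2\pi i\, k_z z)}, \eqn{k_z = (n/\lambda)\sqrt{1 - s^2}}, in the
#' remote replica space. For tilt = 0 the PSF is laterally isotropic; for
#' tilt > 0 the pupil compression along y widens the PSF along y and tilts
#' its principal axes in the (y, z) plane.
#'
#' @param model a \code{\link{RemoteFocusModel}}. The real-space pitch is
#'   \code{wavelength / (2 naO2 padFactor)}; a pitch coarser than
#'   \code{wavelength / (4 naO2)} (padFactor < 2) is refused as
#'   under-sampled.
#' @return a \code{\link{PsfVolume}} in the raw grid frame, cropped to
#'   \code{cropRadius} around the focal intensity maximum, peak normalized.
#' @examples
#' \donttest{
#' psf <- simulateDetectionPsf(RemoteFocusModel(tiltDeg = 0,
#'   pupilSamples = 64, padFactor = 4, zMax = 1, zStep = 0.25))
#' }
#' @export
simulateDetectionPsf <- function(model) {
  validObject(model)
  pitch <- model@wavelength / (2 * model@naO2 * model@padFactor)
  if (pitch > model@wavelength / (4 * model@naO2))
    stop("simulateDetectionPsf: real-space pitch ", signif(pitch, 3),
         " um exceeds lambda/(4 NA); increase padFactor")
  pup <- remoteFocusPupil(model)
  if (sum(pup$P) == 0)
    stop("simulateDetectionPsf: empty effective pupil (cones do not overlap)")
  N <- length(pup$sx)
  s2 <- outer(pup$sx^2, pup$sy^2, `+`)
  kz <- (model@nO2 / model@wavelength) * sqrt(pmax(0, 1 - s2))

  zs <- seq(-model@zMax, model@zMax, by = model@zStep)
  halfw <- min(round(model@cropRadius / pitch), N / 2 - 1)
  keep <- (N / 2 + 1) + (-halfw:halfw)

  stack <- vapply(zs, function(z) {
    field <- fft2c(pup$P * exp(2i * pi * kz * z))
    Mod(field[keep, keep])^2
  }, matrix(0, length(keep), length(keep)))
  stack <- stack / max(stack)
  new("PsfVolume", intensity = stack,
      sampling = c(pitch, pitch, model@zStep), frame = "raw")
}

## Profile through `center` along direction `u` (unit vector in um), by
## trilinear interpolation on the intensity grid.
lineProfile <- function(arr, sampling, center, u, tmax, dt) {
  tseq <- seq(-tmax, tmax, by = dt)
  px <- (center[1] + tseq * u[1]) / sampling[1]
  py <- (center[2] + tseq * u[2]) / sampling[2]
  pz <- (center[3] + tseq * u[3]) / sampling[3]
  list(t = tseq, v = trilinearSample(arr, px, py, pz, fill = 0))
}

## 1D Gaussian least-squares fit via Levenberg-Marquardt; returns sigma and
## R^2. The raw nls.lm optimizer is used because model-frame based fitters
## reject the zero-residual case (noise-free synthetic profiles).
fitGaussian1d <- function(t, v) {
  v <- pmax(v, 0)
  amp0 <- max(v)
  mu0 <- t[which.max(v)]
  above <- v >= amp0 / 2
  s0 <- max(diff(range(t[above])), diff(t)[1]) / 2.355
  resid <- function(p) v - p[1] * exp(-(t - p[2])^2 / (2 * p[3]^2))
  fit <- try(minpack.lm::nls.lm(
    par = c(amp0, mu0, s0), fn = resid,
    control = minpack.lm::nls.lm.control(maxiter = 200)), silent = TRUE)
  if (inherits(fit, "try-error")) return(list(sigma = NA_real_, r2 = 0))
  p <- fit$par
  r2 <- 1 - sum(resid(p)^2) / sum((v - mean(v))^2)
  list(sigma = abs(p[3]), r2 = r2, mu = p[2])
}

## Principal-axis angle of the intensity distribution in the (y, z) plane,
## from second moments about the intensity-weighted centroid.
principalAngleYZ <- function(arr, sampling, threshold = 0.05) {
  d <- dim(arr)
  w <- arr
  w[w < threshold * max(w)] <- 0
  ys <- (seq_len(d[2]) - 1) * sampling[2]
  zs <- (seq_len(d[3]) - 1) * sampling[3]
  wyz <- apply(w, c(2, 3), sum)
  tot <- sum(wyz)
  ybar <- sum(rowSums(wyz) * ys) / tot
  zbar <- sum(colSums(wyz) * zs) / tot
  yy <- sum(wyz * outer((ys - ybar)^2, rep(1, d[3]))) / tot
  zz <- sum(wyz * outer(rep(1, d[2]), (zs - zbar)^2)) / tot
  yz <- sum(wyz * outer(ys - ybar, zs - zbar)) / tot
  0.5 * atan2(2 * yz, yy - zz)
}

#' Per-axis PSF widths by principal-axis Gaussian fits
#'
#' Measures the full width at half maximum of a PSF along its three
#' principal axes. For a tilted detection PSF the principal axes in the
#' (y, z) plane are found from the intensity second moments and the PSF is
#' analyzed along them; line profiles through the intensity maximum are fit
#' with 1D Gaussians and sigma is converted to FWHM by 2 sqrt(2 ln 2). All
#' widths are finally multiplied by \code{scale} (default 1.515, the
#' O1 -> O2 remote-magnification correction; set 1 to disable).
#'
#' @param psf a \code{\link{PsfVolume}} with a single dominant maximum.
#' @param tiltDeg detection tilt in degrees; 0 keeps the grid axes.
#' @param scale width scale factor applied to all axes (default 1.515).
#' @param minR2 fit-quality threshold; a Gaussian fit with R^2 below it is a
#'   rejected measurement (error), mirroring bead-benchmarking practice.
#' @return named numeric c(x, y, z) of FWHMs in um, with attributes
#'   \code{r2} (per-axis fit quality) and \code{angle} (principal-axis
#'   rotation applied in the (y, z) plane, degrees).
#' @export
psfFwhm <- function(psf, tiltDeg = 0, scale = 1.515, minR2 = 0.9) {
  arr <- psf@intensity
  sp <- psf@sampling
  d <- dim(arr)
  pk <- which(arr == max(arr), arr.ind = TRUE)[1, ]
  center <- (pk - 1) * sp

  ang <- if (tiltDeg > 0) principalAngleYZ(arr, sp) else 0
  axes <- list(x = c(1, 0, 0),
               u1 = c(0, cos(ang), sin(ang)),
               u2 = c(0, -sin(ang), cos(ang)))

  ext <- (d - 1) * sp
  widths <- numeric(3); r2 <- numeric(3)
  for (i in 1:3) {
    u <- axes[[i]]
    lim <- min(ifelse(abs(u) > 1e-9,
                      pmin(center, ext - center) / pmax(abs(u), 1e-9),
                      Inf))
    prof <- lineProfile(arr, sp, center, u, tmax = lim,
                        dt = min(sp) / 3)
    fit <- fitGaussian1d(prof$t, prof$v)
    if (!is.finite(fit$sigma) || fit$r2 < minR2)
      stop("psfFwhm: Gaussian fit rejected on axis ", names(axes)[i],
           " (R^2 = ", signif(fit$r2, 3), " < ", minR2, ")")
    widths[i] <- sigmaToFwhm(fit$sigma) * scale
    r2[i] <- fit$r2
  }
  ## axis naming: at tilt 0 keep the grid axes; for a tilted PSF the broader
  ## principal direction in (y, z) is the axial blur (z), the narrower the
  ## in-plane lateral y
  if (tiltDeg > 0 && widths[2] > widths[3]) {
    widths[2:3] <- widths[3:2]
    r2[2:3] <- r2[3:2]
    ang <- ang - sign(ang + 1e-12) * pi / 2
  }
  out <- widths
  names(out) <- c("x", "y", "z")
  attr(out, "r2") <- r2
  attr(out, "angle") <- ang * 180 / pi
  out
}
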