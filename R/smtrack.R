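## Photon calibration, Cramer-Rao localization precision, and
## localization-noise-corrected MSD/diffusion analysis of track tables.

#' Gaussian FWHM / sigma conversion
#'
#' @param fwhm full width(s) at half maximum.
#' @param sigma standard deviation(s).
#' @return the converted width(s); the constant is 2 sqrt(2 ln 2) = 2.3548.
#' @export
fwhmToSigma <- function(fwhm) fwhm / (2 * sqrt(2 * log(2)))

#' @rdname fwhmToSigma
#' @export
sigmaToFwhm <- function(sigma) sigma * (2 * sqrt(2 * log(2)))

#' Electronic offset from dark frames
#'
#' Grand mean, over all pixels and frames, of dark images acquired with the
#' camera shuttered at the working exposure.
#'
#' @param darkFrames a 3D array, a list of matrices, or a single matrix of
#'   digital numbers.
#' @return offset in DN.
#' @export
darkOffset <- function(darkFrames) {
  if (is.list(darkFrames)) darkFrames <- simplify2array(darkFrames)
  if (!length(darkFrames)) stop("darkOffset: empty input")
  mean(as.numeric(darkFrames))
}

#' Convert spot intensities from digital numbers to photons
#'
#' Converts a localization's integrated spot and local background intensities
#' (camera digital numbers) to detected signal photons and background photons
#' per pixel: photoelectrons are \code{gain * (DN - offset)} and photons are
#' photoelectrons divided by the quantum efficiency. The offset cancels in
#' the background-subtracted signal, so
#' \eqn{N_\gamma = (g/\eta)(I_{spot} - I_{bg})} and
#' \eqn{b_\gamma = (g/\eta)(I_{bg/pix} - O)}.
#'
#' @param iSpot integrated spot intensity in DN over the integration mask.
#' @param iBgPerPix local background per pixel in DN.
#' @param nMask number of pixels in the integration mask (>= 1).
#' @param cal a \code{\link{CameraCalibration}}.
#' @param iBg optional total background in DN over the mask; defaults to
#'   \code{nMask * iBgPerPix} and must be consistent with it.
#' @return data.frame with columns \code{nGamma}, \code{bGamma} and a logical
#'   \code{flagged} marking non-positive photon counts (possible with noise;
#'   values are returned unclamped).
#' @examples
#' cal <- CameraCalibration(gain = 0.5, qe = 0.8, offset = 100)
#' photonCounts(iSpot = 200 * 9, iBgPerPix = 104, nMask = 9, cal = cal)
#' @export
photonCounts <- function(iSpot, iBgPerPix, nMask, cal, iBg = NULL) {
  validObject(cal)
  if (any(nMask < 1)) stop("photonCounts: nMask must be >= 1")
  if (is.null(iBg)) iBg <- nMask * iBgPerPix
  if (max(abs(iBg - nMask * iBgPerPix)) > 1e-6 * max(1, abs(iBg)))
    stop("photonCounts: iBg must equal nMask * iBgPerPix")
  f <- cal@gain / cal@qe
  nGamma <- f * (iSpot - iBg)
  bGamma <- f * (iBgPerPix - cal@offset)
  data.frame(nGamma = nGamma, bGamma = bGamma, flagged = nGamma <= 0)
}

#' Tilt-mixed effective PSF width along y'
#'
#' With the detection plane tilted by theta about x, the in-plane y' axis
#' mixes lateral and axial blur:
#' \eqn{\sigma_{y'} = \sqrt{\sigma_y^2\cos^2\theta + \sigma_z^2\sin^2\theta}}.
#'
#' @param sigmaY,sigmaZ lateral and axial Gaussian PSF widths in um.
#' @param thetaDeg tilt angle in degrees.
#' @return effective sigma along y' in um.
#' @export
tiltMixedSigma <- function(sigmaY, sigmaZ, thetaDeg) {
  if (any(c(sigmaY, sigmaZ) <= 0)) stop("tiltMixedSigma: sigmas must be > 0")
  th <- thetaDeg * pi / 180
  sqrt(sigmaY^2 * cos(th)^2 + sigmaZ^2 * sin(th)^2)
}

#' Cramer-Rao localization precision for a 2D Gaussian spot
#'
#' Closed-form lower bound on the standard deviation of a fitted emitter
#' position: per axis,
#' \deqn{\sigma_{loc}^2 = \frac{\sigma_{PSF}^2 + a^2/12}{N_\gamma}
#'   + \frac{8\pi\sigma_{PSF}^4 b_\gamma}{a^2 N_\gamma^2},}
#' with pixel size \eqn{a}, detected photons \eqn{N_\gamma} and background
#' photons per pixel \eqn{b_\gamma}. The y' axis uses the tilt-mixed width
#' from \code{\link{tiltMixedSigma}}.
#'
#' @param nGamma detected signal photons (> 0).
#' @param bGamma background photons per pixel (>= 0).
#' @param model a \code{\link{PrecisionModel}}.
#' @return data.frame with columns \code{sigmaLocX}, \code{sigmaLocY} in um.
#' @export
localizationPrecision <- function(nGamma, bGamma, model) {
  validObject(model)
  if (any(nGamma <= 0))
    stop("localizationPrecision: undefined for nGamma <= 0")
  if (any(bGamma < 0))
    stop("localizationPrecision: bGamma must be >= 0")
  a <- model@pixelSize
  sy <- tiltMixedSigma(model@sigmaY, model@sigmaZ, model@tiltDeg)
  crlb <- function(s) {
    (s^2 + a^2 / 12) / nGamma + 8 * pi * s^4 * bGamma / (a^2 * nGamma^2)
  }
  data.frame(sigmaLocX = sqrt(crlb(model@sigmaX)),
             sigmaLocY = sqrt(crlb(sy)))
}

#' Mean localization precision over a spot table
#'
#' Computes each spot's photon counts and Cramer-Rao precision and averages
#' over spots, excluding those flagged for non-positive signal photons.
#'
#' @param localizations data.frame with columns \code{iSpot},
#'   \code{iBgPerPix}, \code{nMask} (DN units, see \code{\link{photonCounts}}).
#' @param cal a \code{\link{CameraCalibration}}.
#' @param model a \code{\link{PrecisionModel}}.
#' @return list with \code{sigmaX}, \code{sigmaY} (mean precisions, um),
#'   \code{nUsed} and \code{nExcluded}.
#' @export
meanPrecision <- function(localizations, cal, model) {
  ph <- photonCounts(localizations$iSpot, localizations$iBgPerPix,
                     localizations$nMask, cal)
  ok <- !ph$flagged & ph$bGamma >= 0
  if (!any(ok)) stop("meanPrecision: no spot with positive signal photons")
  pr <- localizationPrecision(ph$nGamma[ok], ph$bGamma[ok], model)
  list(sigmaX = mean(pr$sigmaLocX), sigmaY = mean(pr$sigmaLocY),
       nUsed = sum(ok), nExcluded = sum(!ok))
}

## squared displacements at integer frame lag L within each track
stepSquares <- function(tr, lagFrames) {
  bys <- split(tr[c("frame", "x", "y")], tr$track)
  unlist(lapply(bys, function(b) {
    if (nrow(b) < 2L) return(numeric(0))
    i <- seq_len(nrow(b))
    ii <- match(b$frame + lagFrames, b$frame)
    ok <- !is.na(ii)
    (b$x[ii[ok]] - b$x[i[ok]])^2 + (b$y[ii[ok]] - b$y[i[ok]])^2
  }), use.names = FALSE)
}

#' Ensemble diffusion coefficient from consecutive steps
#'
#' Pools the squared displacements of all consecutive steps across tracks,
#' subtracts the static localization variance
#' \eqn{2(\sigma_x^2 + \sigma_{y'}^2)}, and converts to a 2D free-diffusion
#' coefficient \eqn{D = MSD_{corr} / (4\Delta t)}. The MSD uncertainty is the
#' standard error over the pooled squared displacements; the uncertainty on D
#' follows by the same scaling. Negative corrected values are reported as-is
#' (clamping would bias the estimator).
#'
#' @param trackSet a \code{\link{TrackSet}}.
#' @param sigmaX,sigmaY per-axis localization precisions in um.
#' @return an \code{\link{MsdResult}} with a single lag.
#' @export
msdDiffusion <- function(trackSet, sigmaX = 0, sigmaY = 0) {
  validObject(trackSet)
  sq <- stepSquares(trackSet@tracks, 1L)
  if (!length(sq)) stop("msdDiffusion: no valid consecutive steps")
  dt <- trackSet@dt
  corr <- 2 * (sigmaX^2 + sigmaY^2)
  msd <- mean(sq)
  se <- sd(sq) / sqrt(length(sq))
  msdc <- msd - corr
  new("MsdResult", lags = dt, msdRaw = msd, msdCorrected = msdc, se = se,
      nPairs = length(sq), d = msdc / (4 * dt), dSe = se / (4 * dt),
      method = "pooled", negativeCorrected = msdc < 0)
}

#' MSD versus time interval and slope-based diffusion estimate
#'
#' For each lag \eqn{\tau = L\Delta t} (L = 1..maxLag), averages the squared
#' displacements of all within-track position pairs separated by L frames,
#' subtracts the localization variance, and estimates D as slope/4 of an
#' unweighted straight-line fit through the first two lag points (an
#' intercept is fitted, absorbing residual static offsets). With
#' \code{maxLag = 1} the fit degenerates to a line through the origin and
#' the estimate equals \code{\link{msdDiffusion}}'s pooled value, which uses
#' exactly the same pairs.
#'
#' @param trackSet a \code{\link{TrackSet}}.
#' @param sigmaX,sigmaY per-axis localization precisions in um.
#' @param maxLag largest lag multiple (default 4).
#' @param weighted fit weighted by 1/SE^2 instead (default FALSE).
#' @return an \code{\link{MsdResult}}.
#' @export
msdVsLag <- function(trackSet, sigmaX = 0, sigmaY = 0, maxLag = 4,
                     weighted = FALSE) {
  validObject(trackSet)
  corr <- 2 * (sigmaX^2 + sigmaY^2)
  dt <- trackSet@dt
  res <- lapply(seq_len(maxLag), function(L) {
    sq <- stepSquares(trackSet@tracks, L)
    if (!length(sq)) return(NULL)
    c(lag = L * dt, msd = mean(sq), se = sd(sq) / sqrt(length(sq)),
      n = length(sq))
  })
  res <- do.call(rbind, res[!vapply(res, is.null, logical(1))])
  if (is.null(res) || nrow(res) < 1L)
    stop("msdVsLag: tracks too short for lag 1")
  msdc <- res[, "msd"] - corr

  if (nrow(res) >= 2L) {
    df <- data.frame(tau = res[1:2, "lag"], msd = msdc[1:2])
    w <- if (weighted) 1 / res[1:2, "se"]^2 else NULL
    fit <- lm(msd ~ tau, data = df, weights = w)
    slope <- coef(fit)[["tau"]]
    ## two-point line: slope variance from the two SEs
    slopeSe <- sqrt(sum(res[1:2, "se"]^2)) / diff(res[1:2, "lag"])
    d <- slope / 4
    dSe <- slopeSe / 4
  } else {
    if (maxLag > 1L)
      stop("msdVsLag: fewer than 2 usable lags for the slope fit")
    d <- msdc[1] / (4 * res[1, "lag"])
    dSe <- res[1, "se"] / (4 * res[1, "lag"])
  }
  new("MsdResult", lags = unname(res[, "lag"]), msdRaw = unname(res[, "msd"]),
      msdCorrected = unname(msdc), se = unname(res[, "se"]),
      nPairs = unname(res[, "n"]), d = unname(d), dSe = unname(dSe),
      method = "lagfit", negativeCorrected = any(msdc < 0))
}

#' Simulate 2D Brownian tracks with localization noise
#'
#' Generates tracks with Gaussian increments of per-axis variance
#' \eqn{2 D \Delta t} and adds independent Gaussian localization noise
#' (sigmaX, sigmaY) to every observed position. Fully reproducible from the
#' seed; the caller's RNG state is preserved.
#'
#' @param dCoeff diffusion coefficient in um^2/s (>= 0).
#' @param dt frame interval in seconds.
#' @param nTracks,trackLen number of tracks and localizations per track.
#' @param sigmaX,sigmaY localization noise SDs in um.
#' @param seed integer seed.
#' @return a \code{\link{TrackSet}}.
#' @export
simulateBrownianTracks <- function(dCoeff, dt, nTracks, trackLen,
                                   sigmaX = 0, sigmaY = 0, seed = 1L) {
  if (dCoeff < 0) stop("simulateBrownianTracks: dCoeff must be >= 0")
  if (trackLen < 1L || nTracks < 1L)
    stop("simulateBrownianTracks: need nTracks >= 1 and trackLen >= 1")
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))

  stepSd <- sqrt(2 * dCoeff * dt)
  n <- nTracks * trackLen
  dx <- matrix(rnorm(n, sd = stepSd), trackLen, nTracks)
  dy <- matrix(rnorm(n, sd = stepSd), trackLen, nTracks)
  dx[1, ] <- runif(nTracks, 0, 10)   # random starting positions
  dy[1, ] <- runif(nTracks, 0, 10)
  x <- apply(dx, 2, cumsum) + rnorm(n, sd = sigmaX)
  y <- apply(dy, 2, cumsum) + rnorm(n, sd = sigmaY)
  TrackSet(data.frame(track = rep(seq_len(nTracks), each = trackLen),
                      frame = rep(seq_len(trackLen), nTracks),
                      x = as.numeric(x), y = as.numeric(y)),
           dt = dt)
}
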