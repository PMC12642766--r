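## Seeded synthetic phantoms: bead fields, hazy nuclei volumes and
## clustered-puncta image pairs, with an optional camera noise model
## (Poisson shot noise on expected photons + Gaussian read noise in
## electrons, converted to DN with gain and offset).

withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

applyCameraNoise <- function(expected, noise) {
  out <- expected
  if (isTRUE(noise$poisson)) out <- rpois(length(out), lambda = out)
  if ((noise$readSd %||% 0) > 0)
    out <- out + rnorm(length(out), sd = noise$readSd)
  gain <- noise$gain %||% 1
  offset <- noise$offset %||% 0
  array(out / gain + offset, dim = dim(expected))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## Sum-of-Gaussians rendering on a voxel grid (positions/sigmas in voxels),
## evaluated on a +-4 sigma window per emitter.
renderGaussians <- function(shape, centers, sigmas, amplitudes) {
  arr <- array(0, dim = shape)
  if (!nrow(centers)) return(arr)
  nd <- length(shape)
  for (b in seq_len(nrow(centers))) {
    rng <- lapply(seq_len(nd), function(a) {
      lo <- max(1, floor(centers[b, a] - 4 * sigmas[a]) + 1)
      hi <- min(shape[a], ceiling(centers[b, a] + 4 * sigmas[a]) + 1)
      lo:hi
    })
    g <- lapply(seq_len(nd), function(a)
      exp(-((rng[[a]] - 1 - centers[b, a])^2) / (2 * sigmas[a]^2)))
    blob <- if (nd == 3L) {
      outer(outer(g[[1]], g[[2]]), g[[3]])
    } else {
      outer(g[[1]], g[[2]])
    }
    idx <- as.matrix(expand.grid(rng))
    arr[idx] <- arr[idx] + amplitudes[b] * as.numeric(blob)
  }
  arr
}

#' Bead phantom with ground-truth centroids
#'
#' Sub-diffractive beads rendered as 3D Gaussians at uniformly random
#' interior positions (kept \code{margin} voxels away from the faces), on a
#' constant background, with the spec's camera noise model. Deterministic
#' for a fixed spec.
#'
#' @param spec a \code{\link{PhantomSpec}}; \code{beadSigmas} are in um and
#'   are converted to voxels with \code{voxelSize}.
#' @param margin interior margin in voxels (default 6).
#' @return list with \code{volume} (a \code{\link{CartesianVolume}}) and
#'   \code{truth}, a data.frame of 0-based voxel centroids (x, y, z) and
#'   amplitudes. Warns when beads are packed closer than about two widths.
#' @export
beadPhantom <- function(spec, margin = 6) {
  shape <- spec@shape
  stopifnot(length(shape) == 3L)
  sig <- spec@beadSigmas / spec@voxelSize
  m <- pmin(margin, (shape - 1) / 2)   # thin axes get a reduced margin
  withSeed(spec@seed, {
    n <- spec@nBeads
    centers <- if (n > 0) {
      cbind(runif(n, m[1], shape[1] - 1 - m[1]),
            runif(n, m[2], shape[2] - 1 - m[2]),
            runif(n, m[3], shape[3] - 1 - m[3]))
    } else matrix(numeric(0), 0, 3)
    if (n > 1) {
      dmin <- min(dist(centers))
      if (dmin < 4 * max(sig))
        warning("beadPhantom: beads closer than ~2 widths (min distance ",
                signif(dmin, 3), " voxels) may not be resolvable")
    }
    amp <- rep(spec@amplitude, n)
    expected <- spec@background + renderGaussians(shape, centers, sig, amp)
    vol <- CartesianVolume(applyCameraNoise(expected, spec@noise),
                           voxelSize = spec@voxelSize)
    list(volume = vol,
         truth = data.frame(x = centers[, 1][seq_len(n)],
                            y = centers[, 2][seq_len(n)],
                            z = centers[, 3][seq_len(n)],
                            amplitude = amp))
  })
}

#' Nuclei-like volume with depth-dependent background haze
#'
#' Random ellipsoidal "nuclei" blobs over a background that grows linearly
#' with depth along y: \code{background * (1 + hazeSlope * depth_um)}. A
#' zero haze slope emulates tightly sectioned (2P-like) acquisition; larger
#' slopes emulate the depth-dependent out-of-focus background of widefield
#' 1P excitation, depressing the depth-contrast profile.
#'
#' @param spec a \code{\link{PhantomSpec}}; \code{nBeads} sets the number of
#'   nuclei and \code{beadSigmas} their per-axis widths (um).
#' @return a \code{\link{CartesianVolume}}.
#' @export
hazeVolume <- function(spec) {
  shape <- spec@shape
  stopifnot(length(shape) == 3L)
  sig <- spec@beadSigmas / spec@voxelSize
  withSeed(spec@seed, {
    n <- spec@nBeads
    ## the depth axis (y) is populated edge to edge so every orthoslice,
    ## including the surface one the profile is normalized to, carries the
    ## same signal statistics
    centers <- cbind(runif(n, 2 * sig[1], shape[1] - 1 - 2 * sig[1]),
                     runif(n, 0, shape[2] - 1),
                     runif(n, 2 * sig[3], shape[3] - 1 - 2 * sig[3]))
    signal <- renderGaussians(shape, centers, sig,
                              rep(spec@amplitude, n))
    depth <- (seq_len(shape[2]) - 1) * spec@voxelSize
    haze <- spec@background *
      (1 + spec@hazeSlope * depth)
    expected <- signal + rep(rep(haze, each = shape[1]), times = shape[3])
    CartesianVolume(applyCameraNoise(array(expected, shape), spec@noise),
                    voxelSize = spec@voxelSize)
  })
}

#' Clustered-puncta image pair (unstimulated / stimulated)
#'
#' Emulates light-induced protein clustering: both images share the same
#' puncta positions; in the stimulated image a random half of the puncta -
#' drawn dim at baseline, i.e. effectively invisible "pre-cluster" sites -
#' have their amplitudes multiplied by \code{clusterAmplitude}, emulating
#' the appearance of new puncta and the brightening of pre-existing ones.
#' Because the brightening subset starts well below the brightest baseline
#' punctum, the in-ROI dynamic range R is unchanged while the variance
#' grows, so the heterogeneity index of the stimulated image increases
#' monotonically with the cluster amplitude (up to the amplitude at which a
#' boosted punctum would overtake the baseline maximum); global gain leaves
#' it unchanged.
#'
#' @param spec a \code{\link{PhantomSpec}} with a 2D \code{shape};
#'   \code{beadSigmas[1:2]} set the punctum widths in um.
#' @return list of matrices \code{unstimulated} and \code{stimulated}.
#' @export
clusteredPuncta <- function(spec) {
  shape <- spec@shape[1:2]
  sig <- (spec@beadSigmas / spec@voxelSize)[1:2]
  if (spec@clusterAmplitude < 1)
    stop("clusteredPuncta: clusterAmplitude must be >= 1")
  withSeed(spec@seed, {
    n <- spec@nBeads
    centers <- cbind(runif(n, 2 * sig[1], shape[1] - 1 - 2 * sig[1]),
                     runif(n, 2 * sig[2], shape[2] - 1 - 2 * sig[2]))
    boosted <- sample(n, size = floor(n / 2))
    baseAmp <- spec@amplitude * runif(n, 0.7, 1)
    baseAmp[boosted] <- spec@amplitude * runif(length(boosted), 0.05, 0.15)
    stimAmp <- baseAmp
    stimAmp[boosted] <- stimAmp[boosted] * spec@clusterAmplitude
    un <- spec@background + renderGaussians(shape, centers, sig, baseAmp)
    st <- spec@background + renderGaussians(shape, centers, sig, stimAmp)
    list(unstimulated = applyCameraNoise(un, spec@noise),
         stimulated = applyCameraNoise(st, spec@noise))
  })
}
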