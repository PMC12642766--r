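## Layer-cake extended-focus design: annular pupil zones of equal axial
## extent, and scalar-Debye simulation of the incoherently summed
## two-photon focus.

#' Axial extent of an annular-aperture focus
#'
#' \deqn{dz = \frac{\lambda}{n(\cos\alpha_1 - \cos\alpha_2)},\qquad
#'       \alpha_i = \arcsin(NA_i / n).}
#' With \code{na1 = 0} this reduces to the full-aperture (Gaussian-like
#' focus) form \eqn{dz = \lambda / [n (1 - \cos\alpha_2)]}.
#'
#' @param na1,na2 inner and outer numerical apertures, 0 <= na1 < na2 <= n.
#' @param wavelength wavelength in um.
#' @param n immersion refractive index.
#' @return axial extent dz in um (vectorized over zones).
#' @examples
#' axialExtent(0, 0.5, wavelength = 0.9, n = 1.515)  # ~10.6 um
#' @export
axialExtent <- function(na1, na2, wavelength, n) {
  if (any(na1 < 0) || any(na2 <= na1))
    stop("axialExtent: need 0 <= na1 < na2")
  if (any(na2 > n)) stop("axialExtent: na2 exceeds the refractive index")
  a1 <- asin(na1 / n)
  a2 <- asin(na2 / n)
  wavelength / (n * (cos(a1) - cos(a2)))
}

#' Design a layer-cake mask with equal per-zone axial extent
#'
#' Partitions the pupil (0, naMax] into \code{L} contiguous annular zones
#' whose Bessel-like foci all share the same axial extent. Equal dz means
#' equal steps in cos(alpha), so the boundaries are
#' \eqn{\cos\alpha_i = 1 - i\,(1-\cos\alpha_{max})/L} and the common extent
#' is \eqn{dz = \lambda L / [n(1-\cos\alpha_{max})]}: the construction the
#' iterative outward recursion converges to, solved in closed form. The
#' central zone (NA 0 to NA_1) sets dz through the full-aperture formula and
#' every outer annulus reproduces it exactly.
#'
#' @param wavelength excitation wavelength in um.
#' @param n immersion refractive index.
#' @param naMax outermost numerical aperture (<= n).
#' @param L number of zones. By default L counts all zones including the
#'   central disc; set \code{countCentral = FALSE} to read L as the number
#'   of annuli surrounding the central disc (L + 1 zones in total).
#' @param focalLength optional back focal length (mm) to report mask radii
#'   r = f NA.
#' @param countCentral see \code{L}.
#' @return a \code{\link{LayerCakeDesign}}.
#' @examples
#' designLayerCake(0.9, n = 1.515, naMax = 0.5, L = 4)
#' @export
designLayerCake <- function(wavelength, n, naMax, L, focalLength = NA_real_,
                            countCentral = TRUE) {
  if (L < 1) stop("designLayerCake: need L >= 1")
  if (naMax <= 0 || naMax > n)
    stop("designLayerCake: need 0 < naMax <= n")
  nz <- if (countCentral) as.integer(L) else as.integer(L) + 1L
  cmax <- cos(asin(naMax / n))
  delta <- (1 - cmax) / nz
  if (delta <= 0) stop("designLayerCake: infeasible design (naMax ~ 0): ",
                       "zones would have zero angular width")
  cb <- 1 - (0:nz) * delta
  nab <- n * sin(acos(pmin(1, pmax(-1, cb))))
  nab[1] <- 0
  nab[nz + 1] <- naMax            # guard rounding at the ends
  z <- cbind(inner = nab[-(nz + 1)], outer = nab[-1])
  new("LayerCakeDesign", wavelength = wavelength, n = n, zones = z,
      dzTarget = wavelength / (n * delta), focalLength = focalLength)
}

#' Mask zone radii in the pupil plane
#'
#' Converts the design's NA boundaries to physical mask radii via
#' r = f NA (the back pupil diameter being 2 f NA).
#'
#' @param design a \code{\link{LayerCakeDesign}} with a finite focal length,
#'   or supply one via \code{focalLength}.
#' @param focalLength back focal length in mm.
#' @return matrix of inner/outer radii in mm per zone.
#' @export
zoneRadii <- function(design, focalLength = design@focalLength) {
  if (!is.finite(focalLength))
    stop("zoneRadii: no focal length available")
  design@zones * focalLength
}

## Scalar Debye focal field of one annular zone, uniform fill with the
## aplanatic sqrt(cos) apodization. Returns the complex field on the
## requested r and z grids (outer product structure: length(r) x length(z)).
debyeZoneField <- function(na1, na2, wavelength, n, r, z, nTheta = 1024) {
  a1 <- asin(na1 / n)
  a2 <- asin(na2 / n)
  th <- seq(a1, a2, length.out = nTheta)
  w <- rep(1, nTheta); w[c(1, nTheta)] <- 0.5   # trapezoid weights
  k <- 2 * pi * n / wavelength
  apod <- sqrt(cos(th)) * sin(th) * w * (th[2] - th[1])
  ## radial part: J0(k r sin(theta)), axial part: exp(i k z cos(theta))
  radial <- besselJ(outer(r, k * sin(th)), 0)       # nr x nTheta
  axial <- exp(1i * outer(k * cos(th), z))          # nTheta x nz
  radial %*% (apod * axial)
}

#' Simulate the incoherently summed two-photon excitation focus
#'
#' Computes each zone's focal field with a scalar Debye integral over its
#' annular aperture (uniform fill, aplanatic apodization), forms the
#' two-photon excitation intensity |E|^4 per zone, and sums the zones
#' incoherently (adjacent mask layers are mutually incoherent by design).
#' Reported metrics: \code{dof2p}, the FWHM of the summed on-axis 2P
#' profile ("depth of focus"); \code{dof1p}, the FWHM of the corresponding
#' 1P (|E|^2 summed) profile; and \code{waist2p}, the lateral FWHM of the
#' summed 2P profile at best focus.
#'
#' @param design a \code{\link{LayerCakeDesign}}.
#' @param zMax axial half-range in um (default 1.5 x dzTarget).
#' @param zStep axial step (default dzTarget / 400).
#' @param rMax,rStep lateral range/step in um for the waist profile.
#' @param nTheta quadrature points across each zone's angular range.
#' @return a \code{\link{FocusProfile}}.
#' @export
simulateExcitationFocus <- function(design, zMax = NULL, zStep = NULL,
                                    rMax = 3, rStep = 0.005,
                                    nTheta = 1024) {
  validObject(design)
  dz <- design@dzTarget
  if (is.null(zMax)) zMax <- 1.5 * dz
  if (is.null(zStep)) zStep <- dz / 400
  if (zMax < dz / 2)
    stop("simulateExcitationFocus: axial window smaller than the expected ",
         "axial extent (", signif(dz, 4), " um); increase zMax")
  z <- seq(-zMax, zMax, by = zStep)
  r <- seq(0, rMax, by = rStep)
  zn <- design@zones
  L <- nrow(zn)

  ax2 <- matrix(0, length(z), L)   # per-zone |E|^4 on axis
  ax1 <- matrix(0, length(z), L)
  lat2 <- matrix(0, length(r), L)
  for (i in seq_len(L)) {
    Ez <- debyeZoneField(zn[i, 1], zn[i, 2], design@wavelength, design@n,
                         r = 0, z = z, nTheta = nTheta)
    Er <- debyeZoneField(zn[i, 1], zn[i, 2], design@wavelength, design@n,
                         r = r, z = 0, nTheta = nTheta)
    ax1[, i] <- Mod(Ez[1, ])^2
    ax2[, i] <- Mod(Ez[1, ])^4
    lat2[, i] <- Mod(Er[, 1])^4
  }
  s2 <- rowSums(ax2); s1 <- rowSums(ax1); sl <- rowSums(lat2)

  new("FocusProfile", z = z, axial2p = s2 / max(s2),
      axial1p = s1 / max(s1), r = r, lateral2p = sl / max(sl),
      zoneAxial2p = ax2,
      metrics = list(dof2p = profileFwhm(z, s2),
                     dof1p = profileFwhm(z, s1),
                     waist2p = profileFwhm(c(-rev(r[-1]), r),
                                           c(rev(sl[-1]), sl)),
                     dzTarget = dz))
}

#' FWHM of a sampled profile by linear interpolation
#'
#' Width between the outermost half-maximum crossings adjacent to the peak.
#'
#' @param x ordinates (sorted increasing).
#' @param y profile values.
#' @return full width at half maximum in the units of \code{x}.
#' @export
profileFwhm <- function(x, y) {
  pk <- which.max(y)
  if (pk == 1L || pk == length(y))
    stop("profileFwhm: peak lies on the window edge")
  half <- y[pk] / 2
  left <- NA_real_; right <- NA_real_
  for (i in rev(seq_len(pk - 1))) {
    if (y[i] <= half) {
      left <- x[i] + (x[i + 1] - x[i]) * (half - y[i]) / (y[i + 1] - y[i])
      break
    }
  }
  for (i in (pk + 1):length(y)) {
    if (i > length(y)) break
    if (y[i] <= half) {
      right <- x[i - 1] +
        (x[i] - x[i - 1]) * (y[i - 1] - half) / (y[i - 1] - y[i])
      break
    }
  }
  if (!is.finite(left) || !is.finite(right))
    stop("profileFwhm: profile does not fall to half maximum inside the ",
         "sampled window")
  right - left
}

#' Transverse-plane energy of a zone focus
#'
#' Integrates 2 pi r |E(r, z)|^2 over the transverse plane at a given
#' defocus; for a propagating (loss-free) field this is independent of z, a
#' Parseval-type conservation check on the Debye quadrature.
#'
#' @param design a \code{\link{LayerCakeDesign}}.
#' @param zone zone index.
#' @param z defocus in um.
#' @param rMax,rStep integration range/step in um.
#' @return plane-integrated energy (arbitrary units common across z).
#' @export
zonePlaneEnergy <- function(design, zone, z = 0, rMax = 30, rStep = 0.005) {
  r <- seq(0, rMax, by = rStep)
  E <- debyeZoneField(design@zones[zone, 1], design@zones[zone, 2],
                      design@wavelength, design@n, r = r, z = z)
  v <- 2 * pi * r * Mod(E[, 1])^2
  sum((v[-1] + v[-length(v)]) / 2) * rStep
}
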