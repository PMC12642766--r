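## Oblique-volume reconstruction: skew/scale/rotate affine and trilinear
## resampling between the raw (x, y', frame) stack and Cartesian coordinates.

#' Per-frame shear factors of an oblique scan
#'
#' Successive frames of an oblique acquisition are displaced along the
#' in-plane y' axis by \eqn{d_{skew} = y_{step}\cos\theta} and along the
#' plane normal by \eqn{d_{scale} = y_{step}\sin\theta}. Expressed in pixel
#' units of the camera (pixel size \eqn{a}) these are the dimensionless
#' shear factors \eqn{sk = y_{step}\cos\theta / a} and
#' \eqn{sc = y_{step}\sin\theta / a}.
#'
#' @param geometry a \code{\link{ScanGeometry}}.
#' @return named numeric c(sk, sc).
#' @examples
#' shearFactors(ScanGeometry(45, ystep = sqrt(2), pixelSize = 1))  # (1, 1)
#' @export
shearFactors <- function(geometry) {
  validObject(geometry)
  th <- geometry@theta * pi / 180
  c(sk = geometry@ystep * cos(th) / geometry@pixelSize,
    sc = geometry@ystep * sin(th) / geometry@pixelSize)
}

translationMatrix <- function(t) {
  m <- diag(4)
  m[1:3, 4] <- t
  m
}

boxCorners <- function(shape) {
  e <- shape - 1
  as.matrix(expand.grid(x = c(0, e[1]), y = c(0, e[2]), z = c(0, e[3])))
}

#' Compose the deskew affine transform
#'
#' Builds the homogeneous transform mapping 0-based stack voxel indices
#' (x, y', frame) to the Cartesian output frame: skew K (y' shift per frame),
#' axial scale S (frame spacing), then rotation R(theta) about x, applied in
#' that non-commutative order, with a pre-translation moving the geometric
#' center of the skewed+scaled bounding box to the rotation origin and a
#' post-translation placing the minimum corner of the transformed bounding
#' box at zero.
#'
#' @param geometry a \code{\link{ScanGeometry}}.
#' @param volumeShape integer(3), extents of the input stack (x, y', frame).
#' @param sk,sc optional overrides of the shear factors (used for degenerate
#'   configurations in which the factors are not tied to theta).
#' @return an \code{\link{AffineTransform}}.
#' @seealso \code{\link{applyAffine}}, \code{\link{deskewVolume}}
#' @export
buildAffine <- function(geometry, volumeShape, sk = NULL, sc = NULL) {
  fac <- shearFactors(geometry)
  if (is.null(sk)) sk <- fac[["sk"]]
  if (is.null(sc)) sc <- fac[["sc"]]
  if (!all(is.finite(c(sk, sc))))
    stop("shear factors must be finite")
  th <- geometry@theta * pi / 180

  K <- diag(4); K[2, 3] <- sk
  S <- diag(4); S[3, 3] <- sc
  R <- diag(4)
  R[2, 2] <- cos(th); R[2, 3] <- -sin(th)
  R[3, 2] <- sin(th); R[3, 3] <- cos(th)

  corners <- boxCorners(volumeShape)
  skc <- t(S[1:3, 1:3] %*% K[1:3, 1:3] %*% t(corners))
  mid <- (apply(skc, 2, min) + apply(skc, 2, max)) / 2
  pre <- translationMatrix(-mid)

  rot <- t(R[1:3, 1:3] %*% t(sweep(skc, 2, mid)))
  post <- translationMatrix(-apply(rot, 2, min))

  m <- post %*% R %*% pre %*% S %*% K
  new("AffineTransform", matrix = m,
      components = list(K = K, S = S, R = R, pre = pre, post = post,
                        sk = unname(sk), sc = unname(sc),
                        theta = geometry@theta))
}

#' Apply an affine transform to 0-based voxel coordinates
#'
#' @param transform an \code{\link{AffineTransform}} (or a 4x4 matrix).
#' @param points numeric matrix n x 3 (or a length-3 vector).
#' @return n x 3 matrix of transformed coordinates.
#' @export
applyAffine <- function(transform, points) {
  m <- if (is(transform, "AffineTransform")) transform@matrix else transform
  if (is.null(dim(points))) points <- matrix(points, nrow = 1)
  h <- cbind(points, 1)
  out <- h %*% t(m)
  out[, 1:3, drop = FALSE]
}

## Vectorized trilinear interpolation at 0-based fractional coordinates.
## Coordinates outside [0, dim-1] on any axis return `fill`.
trilinearSample <- function(arr, px, py, pz, fill = 0) {
  d <- dim(arr)
  inside <- px >= 0 & px <= d[1] - 1 &
            py >= 0 & py <= d[2] - 1 &
            pz >= 0 & pz <= d[3] - 1
  out <- rep(fill, length(px))
  if (!any(inside)) return(out)
  px <- px[inside]; py <- py[inside]; pz <- pz[inside]

  i0 <- pmin(floor(px), d[1] - 2); i0 <- pmax(i0, 0)
  j0 <- pmin(floor(py), d[2] - 2); j0 <- pmax(j0, 0)
  k0 <- pmin(floor(pz), d[3] - 2); k0 <- pmax(k0, 0)
  if (d[1] == 1) i0 <- rep(0, length(px))
  if (d[2] == 1) j0 <- rep(0, length(py))
  if (d[3] == 1) k0 <- rep(0, length(pz))
  fx <- px - i0; fy <- py - j0; fz <- pz - k0

  i1 <- pmin(i0 + 1, d[1] - 1)
  j1 <- pmin(j0 + 1, d[2] - 1)
  k1 <- pmin(k0 + 1, d[3] - 1)

  idx <- function(i, j, k) 1 + i + d[1] * (j + d[2] * k)
  v000 <- arr[idx(i0, j0, k0)]; v100 <- arr[idx(i1, j0, k0)]
  v010 <- arr[idx(i0, j1, k0)]; v110 <- arr[idx(i1, j1, k0)]
  v001 <- arr[idx(i0, j0, k1)]; v101 <- arr[idx(i1, j0, k1)]
  v011 <- arr[idx(i0, j1, k1)]; v111 <- arr[idx(i1, j1, k1)]

  c00 <- v000 * (1 - fx) + v100 * fx
  c10 <- v010 * (1 - fx) + v110 * fx
  c01 <- v001 * (1 - fx) + v101 * fx
  c11 <- v011 * (1 - fx) + v111 * fx
  c0 <- c00 * (1 - fy) + c10 * fy
  c1 <- c01 * (1 - fy) + c11 * fy
  out[inside] <- c0 * (1 - fz) + c1 * fz
  out
}

#' Deskew an oblique stack into a Cartesian volume
#'
#' Resamples the sheared stack onto a regular Cartesian grid with isotropic
#' voxels of edge equal to the camera pixel size. Output voxels are mapped
#' back through the inverse of the composed affine (pull-style resampling)
#' and filled by trilinear interpolation of the source stack; coordinates
#' outside the source domain take the geometry's fill value. The output grid
#' is the axis-aligned bounding box of the transformed input, rounded
#' outward to whole voxels.
#'
#' @param stack an \code{\link{ObliqueStack}} with at least two frames.
#' @param sk,sc optional shear-factor overrides, see
#'   \code{\link{buildAffine}}.
#' @return a \code{\link{CartesianVolume}}. Its \code{origin} records the
#'   translation back to the source frame of a stack produced by
#'   \code{\link{simulateObliqueAcquisition}} (zero otherwise).
#' @examples
#' geom <- ScanGeometry(45, ystep = 0.5 * sqrt(2), pixelSize = 1)
#' arr <- array(1, dim = c(8, 8, 6))
#' vol <- deskewVolume(ObliqueStack(arr, geom))
#' @export
deskewVolume <- function(stack, sk = NULL, sc = NULL) {
  fr <- stack@frames
  d <- dim(fr)
  if (d[3] < 2L)
    stop("deskewVolume: need at least two frames (no scan axis)")
  if (anyNA(fr))
    warning("deskewVolume: NaN voxels in input propagate to the output")
  geom <- stack@geometry
  tf <- buildAffine(geom, d, sk = sk, sc = sc)
  m <- tf@matrix
  if (abs(det(m[1:3, 1:3])) < 1e-12)
    stop("deskewVolume: affine is singular (sc = 0?)")

  ext <- apply(applyAffine(tf, boxCorners(d)), 2, max)
  dimsOut <- pmax(as.integer(ceiling(ext - 1e-9)) + 1L, 1L)

  inv <- solve(m)
  g <- expand.grid(x = seq_len(dimsOut[1]) - 1,
                   y = seq_len(dimsOut[2]) - 1,
                   z = seq_len(dimsOut[3]) - 1)
  src <- applyAffine(inv, as.matrix(g))
  vals <- trilinearSample(fr, src[, 1], src[, 2], src[, 3],
                          fill = geom@fillValue)
  CartesianVolume(array(vals, dim = dimsOut),
                  voxelSize = geom@pixelSize,
                  origin = -stack@offset)
}

#' Simulate an oblique acquisition of a Cartesian volume
#'
#' Forward model of the scan: samples the volume along oblique planes
#' displaced per frame by (d_skew, d_scale), i.e. evaluates the volume at the
#' affine image of each stack voxel. Deskewing the result reproduces the
#' source volume up to interpolation blur and edge cropping; the integer
#' part of the alignment between the two frames is recorded in the returned
#' stack's \code{offset} slot.
#'
#' @param volume a \code{\link{CartesianVolume}}.
#' @param geometry a \code{\link{ScanGeometry}}; its pixel size should equal
#'   the volume's voxel size.
#' @param sk,sc optional shear-factor overrides, see
#'   \code{\link{buildAffine}}.
#' @return an \code{\link{ObliqueStack}}.
#' @export
simulateObliqueAcquisition <- function(volume, geometry, sk = NULL,
                                       sc = NULL) {
  vox <- volume@voxels
  d <- dim(vox)
  if (any(d < 1L) || sum(vox != 0) == 0 && prod(d) == 0)
    stop("simulateObliqueAcquisition: empty volume")
  fac <- shearFactors(geometry)
  skv <- if (is.null(sk)) fac[["sk"]] else sk
  scv <- if (is.null(sc)) fac[["sc"]] else sc
  if (scv <= 0)
    stop("simulateObliqueAcquisition: scan planes never advance through ",
         "the volume (sc <= 0)")

  ## linear part determines how many frames / in-plane samples are needed
  probe <- buildAffine(geometry, d, sk = skv, sc = scv)
  lin <- probe@components$R[1:3, 1:3] %*%
         probe@components$S[1:3, 1:3] %*% probe@components$K[1:3, 1:3]
  src <- t(solve(lin) %*% t(boxCorners(d)))
  span <- apply(src, 2, max) - apply(src, 2, min)
  shape <- pmax(as.integer(ceiling(span - 1e-6)) + 1L, c(1L, 1L, 2L))

  tf <- buildAffine(geometry, shape, sk = skv, sc = scv)
  ext <- apply(applyAffine(tf, boxCorners(shape)), 2, max)
  off <- (ext - (d - 1)) / 2

  g <- expand.grid(x = seq_len(shape[1]) - 1,
                   y = seq_len(shape[2]) - 1,
                   z = seq_len(shape[3]) - 1)
  pos <- applyAffine(tf, as.matrix(g))
  vals <- trilinearSample(vox, pos[, 1] - off[1], pos[, 2] - off[2],
                          pos[, 3] - off[3], fill = geometry@fillValue)
  if (all(vals == geometry@fillValue))
    stop("simulateObliqueAcquisition: no scan plane intersects the volume")
  ObliqueStack(array(vals, dim = shape), geometry, offset = off)
}
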