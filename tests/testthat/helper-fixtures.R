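# Shared fixture builders. Everything is generated in code at test time.

# bead phantom whose beads are comfortably separated (checked: min pairwise
# centroid distance > 10 voxels at this seed)
separatedBeadPhantom <- function() {
  beadPhantom(PhantomSpec(shape = c(48, 48, 28), nBeads = 5, background = 0,
                          amplitude = 100, seed = 2), margin = 7)
}

# noise-free synthetic 3D Gaussian PSF volume, optionally rotated in (y, z)
syntheticGaussianPsf <- function(sigma, pitch = 0.02, halfSize = c(24, 40, 60),
                                 angleDeg = 0) {
  dims <- 2 * halfSize + 1
  xs <- (seq_len(dims[1]) - 1 - halfSize[1]) * pitch
  ys <- (seq_len(dims[2]) - 1 - halfSize[2]) * pitch
  zs <- (seq_len(dims[3]) - 1 - halfSize[3]) * pitch
  a <- angleDeg * pi / 180
  arr <- array(0, dims)
  gy <- outer(ys, zs, function(y, z) {
    yr <- cos(a) * y + sin(a) * z
    zr <- -sin(a) * y + cos(a) * z
    exp(-yr^2 / (2 * sigma[2]^2) - zr^2 / (2 * sigma[3]^2))
  })
  gx <- exp(-xs^2 / (2 * sigma[1]^2))
  for (i in seq_len(dims[1])) arr[i, , ] <- gx[i] * gy
  new("PsfVolume", intensity = arr / max(arr),
      sampling = rep(pitch, 3), frame = "raw")
}

# intensity-weighted centroid in a window around a 0-based position guess
localCentroid <- function(arr, guess, halfWidth = 4) {
  lo <- pmax(round(guess) - halfWidth, 0)
  hi <- pmin(round(guess) + halfWidth, dim(arr) - 1)
  idx <- as.matrix(expand.grid(lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]))
  v <- arr[idx + 1]
  colSums(idx * v) / sum(v)
}

# apply the affine factors one by one (independent brute-force oracle for
# the composed matrix)
applyComponentsSequentially <- function(tf, pts) {
  cmp <- affineComponents(tf)
  t(apply(pts, 1, function(p) {
    h <- c(p, 1)
    h <- cmp$K %*% h
    h <- cmp$S %*% h
    h <- cmp$pre %*% h
    h <- cmp$R %*% h
    h <- cmp$post %*% h
    h[1:3]
  }))
}
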