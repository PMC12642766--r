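test_that("shear factors follow the oblique-scan trigonometry", {
  expect_equal(shearFactors(ScanGeometry(45, sqrt(2), 1)),
               c(sk = 1, sc = 1), tolerance = 1e-12)
  expect_equal(shearFactors(ScanGeometry(90, 2, 1))[["sc"]], 2)
  expect_equal(shearFactors(ScanGeometry(90, 2, 1))[["sk"]], 0,
               tolerance = 1e-12)
  expect_equal(shearFactors(ScanGeometry(30, 1, 0.5)),
               c(sk = sqrt(3), sc = 1), tolerance = 1e-12)

  # homogeneity: doubling both ystep and pixel size changes nothing
  f1 <- shearFactors(ScanGeometry(37, 0.8, 0.11))
  f2 <- shearFactors(ScanGeometry(37, 1.6, 0.22))
  expect_equal(f1, f2)

  expect_error(ScanGeometry(45, -1, 1), "ystep")
  expect_error(ScanGeometry(45, 1, 0), "pixelSize")
  expect_error(ScanGeometry(120, 1, 1), "theta")
})

test_that("composed affine equals sequential K, S, R application", {
  set.seed(11)
  for (i in 1:4) {
    geom <- ScanGeometry(runif(1, 20, 70), runif(1, 0.2, 1.5),
                         runif(1, 0.1, 0.5))
    shape <- sample(4:16, 3, replace = TRUE)
    tf <- buildAffine(geom, shape)
    pts <- as.matrix(expand.grid(0:(shape[1] - 1), 0:(shape[2] - 1),
                                 0:(shape[3] - 1)))
    expect_equal(applyAffine(tf, pts), applyComponentsSequentially(tf, pts),
                 tolerance = 1e-10)
    # determinant of the linear part equals the axial scale factor
    expect_equal(det(affineMatrix(tf)[1:3, 1:3]),
                 unname(shearFactors(geom)[["sc"]]), tolerance = 1e-10)
  }
})

test_that("degenerate identity configuration gives the identity transform", {
  geom <- ScanGeometry(0, ystep = 1, pixelSize = 1)
  tf <- buildAffine(geom, c(8, 8, 8), sk = 0, sc = 1)
  expect_equal(affineMatrix(tf), diag(4), tolerance = 1e-12)
})

test_that("deskew maps a uniform stack to a uniform interior", {
  geom <- ScanGeometry(45, 0.5 * sqrt(2), 1)
  stack <- ObliqueStack(array(3, c(10, 10, 8)), geom)
  vol <- deskewVolume(stack)
  expect_equal(voxelSize(vol), 1)
  vx <- voxels(vol)
  # constant interpolation: nothing exceeds the source value
  expect_lte(max(vx), 3 + 1e-9)
  # the affine images of interior source voxels carry the constant value
  tf <- buildAffine(geom, c(10, 10, 8))
  pts <- applyAffine(tf, as.matrix(expand.grid(2:7, 3:6, 3:4)))
  vals <- opmtools:::trilinearSample(vx, pts[, 1], pts[, 2], pts[, 3],
                                     fill = NA)
  expect_equal(vals, rep(3, length(vals)), tolerance = 1e-9)
  # outside the mapped region the fill value appears
  expect_equal(vx[1, 1, dim(vx)[3]], 0)
})

test_that("a single bright voxel lands at its affine image", {
  geom <- ScanGeometry(45, 0.7, 0.9)
  arr <- array(0, c(12, 14, 9))
  src <- c(6, 7, 4)
  arr[src[1] + 1, src[2] + 1, src[3] + 1] <- 10
  stack <- ObliqueStack(arr, geom)
  vol <- deskewVolume(stack)
  expected <- drop(applyAffine(buildAffine(geom, dim(arr)), src))
  got <- localCentroid(voxels(vol), expected, halfWidth = 3)
  expect_lt(sqrt(sum((got - expected)^2)), 0.5)
})

test_that("deskew refuses single frames and warns on NaN", {
  geom <- ScanGeometry(45, 0.5, 1)
  expect_error(deskewVolume(ObliqueStack(array(1, c(4, 4, 1)), geom)),
               "two frames")
  bad <- array(1, c(6, 6, 4)); bad[2, 2, 2] <- NaN
  expect_warning(deskewVolume(ObliqueStack(bad, geom)), "NaN")
})

test_that("acquisition followed by deskew recovers bead centroids", {
  ph <- separatedBeadPhantom()
  geom <- ScanGeometry(45, ystep = 0.2 / sqrt(2), pixelSize = 0.2)
  stack <- simulateObliqueAcquisition(ph$volume, geom)
  vol <- deskewVolume(stack)
  arr <- voxels(vol)
  for (i in seq_len(nrow(ph$truth))) {
    truth <- as.numeric(ph$truth[i, c("x", "y", "z")])
    got <- localCentroid(arr, truth - origin(vol)) + origin(vol)
    expect_lt(sqrt(sum((got - truth)^2)), 0.5)
  }
})

test_that("deskew preserves the intensity of an interior compact source", {
  ph <- separatedBeadPhantom()
  # unit-determinant geometry: plane spacing equals the voxel size
  geom <- ScanGeometry(45, ystep = 0.2 * sqrt(2), pixelSize = 0.2)
  stack <- simulateObliqueAcquisition(ph$volume, geom)
  vol <- deskewVolume(stack)
  expect_equal(sum(voxels(vol)), sum(voxels(ph$volume)), tolerance = 0.01)
  # oversampled scan (sc = 0.5): the acquisition and deskew Jacobians
  # cancel, so the round-trip total is conserved too
  geom2 <- ScanGeometry(45, ystep = 0.1 * sqrt(2), pixelSize = 0.2)
  stack2 <- simulateObliqueAcquisition(ph$volume, geom2)
  expect_equal(sum(voxels(deskewVolume(stack2))),
               sum(voxels(ph$volume)), tolerance = 0.01)
})

test_that("beads along the in-plane scan axis reconstruct at 45 degrees", {
  geom <- ScanGeometry(45, sqrt(2), 1)
  arr <- array(0, c(5, 24, 6))
  js <- c(4, 9, 14, 19)
  for (j in js) arr[3, j + 1, 3] <- 1   # a line of beads along y'
  vol <- deskewVolume(ObliqueStack(arr, geom))
  tf <- buildAffine(geom, dim(arr))
  pos <- t(vapply(js, function(j) {
    localCentroid(voxels(vol), drop(applyAffine(tf, c(2, j, 2))), 2)
  }, numeric(3)))
  steps <- diff(pos)
  ang <- atan2(steps[, 3], steps[, 2]) * 180 / pi
  expect_equal(ang, rep(45, nrow(steps)), tolerance = 0.5)
})

test_that("the forward acquisition model handles degenerate geometries", {
  vol <- CartesianVolume(array(seq_len(6 * 6 * 4) / 10, c(6, 6, 4)),
                         voxelSize = 1)
  geom <- ScanGeometry(0, 1, 1)
  # identity-like override: frames are the volume's z-slices
  stack <- simulateObliqueAcquisition(vol, geom, sk = 0, sc = 1)
  expect_equal(dim(frames(stack)), dim(voxels(vol)))
  expect_equal(frames(stack), voxels(vol), tolerance = 1e-9)
  # constant volume gives constant frames (fill value or the constant)
  cvol <- CartesianVolume(array(7, c(6, 6, 4)), voxelSize = 1)
  cst <- simulateObliqueAcquisition(cvol, ScanGeometry(45, sqrt(2) / 2, 1))
  fr <- frames(cst)
  expect_setequal(round(unique(as.numeric(fr)), 9), c(0, 7))
  expect_gt(mean(fr == 7), 0.2)   # a substantial core samples the volume
  # planes that never advance into the volume are refused
  expect_error(simulateObliqueAcquisition(vol, geom), "sc <= 0")
})

test_that("oblique stacks round-trip through TIFF with their geometry", {
  geom <- ScanGeometry(45, 0.4, 0.0867)
  arr <- array(runif(6 * 5 * 4) * 1000, c(6, 5, 4))
  path <- tempfile(fileext = ".tif")
  writeObliqueStack(ObliqueStack(arr, geom), path)
  back <- readObliqueStack(path)
  expect_equal(frames(back), arr, tolerance = 1e-6)
  expect_equal(scanTheta(geometry(back)), 45)
  expect_equal(pixelSize(geometry(back)), 0.0867)
  unlink(c(path, paste0(path, ".json")))
})
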