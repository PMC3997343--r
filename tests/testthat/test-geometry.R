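test_that("turntable kinematics form the expected rotation group", {
  d <- 200
  fixed <- poseFromTurntable(turntableState(0, 0, d))
  ## pan 0, tilt 0 is the fixed rig pose
  expect_equal(fixed@rotation,
               rbind(c(1, 0, 0), c(0, 0, -1), c(0, 1, 0)))
  expect_equal(fixed@translation, c(0, 0, d))
  ## periodicity
  p360 <- poseFromTurntable(turntableState(360, 0, d))
  expect_lt(max(abs(p360@rotation - fixed@rotation)), 1e-9)
  ## composition: applying pan 90 twice equals pan 180 (specimen rotations
  ## composed numerically)
  S90 <- insecthull:::specimenRotation(90, 0)
  S180 <- insecthull:::specimenRotation(180, 0)
  expect_lt(max(abs(S90 %*% S90 - S180)), 1e-12)
  p90twice <- rigidPose(fixed@rotation %*% S90 %*% S90, fixed@translation)
  p180 <- poseFromTurntable(turntableState(180, 0, d))
  expect_lt(max(abs(p90twice@rotation - p180@rotation)), 1e-12)
})

test_that("camera centres of a pan sweep lie on a circle", {
  d <- 200
  for (tilt in c(0, 25, -40)) {
    C <- vapply(seq(0, 359, by = 7.2), function(p)
      cameraCentre(poseFromTurntable(turntableState(p, tilt, d))),
      numeric(3))
    radii <- sqrt(colSums(C^2))
    expect_lt(max(abs(radii - d)), 1e-9)
    ## at fixed tilt the pan sweep orbits the world z axis: constant
    ## height, constant axial radius
    expect_lt(diff(range(C[3, ])), 1e-9)
    expect_lt(diff(range(sqrt(colSums(C[1:2, , drop = FALSE]^2)))), 1e-9)
  }
})

test_that("pinhole projection matches geometry and a homogeneous-matrix oracle", {
  intr <- cameraIntrinsics(800, c(640, 480), c(320, 240))
  d <- 150
  v <- cameraView(intr, poseFromTurntable(turntableState(0, 0, d)))
  ## point at the origin (on the optical axis) hits the principal point
  pr <- projectPoints(c(0, 0, 0), v)
  expect_equal(c(pr$x, pr$y), c(320, 240))
  expect_equal(pr$depth, d)
  ## similar triangles: world +x offset of 3 mm
  pr <- projectPoints(c(3, 0, 0), v)
  expect_equal(pr$x, 320 + 800 * 3 / d)
  expect_equal(pr$y, 240)
  ## independent oracle: 3x4 homogeneous projection matrix
  set.seed(11)
  v2 <- cameraView(intr, poseFromTurntable(turntableState(123, -31, d)))
  K <- rbind(c(800, 0, 320), c(0, 800, 240), c(0, 0, 1))
  P <- K %*% cbind(v2@pose@rotation, v2@pose@translation)
  X <- matrix(rnorm(40, sd = 10), 10, 4)
  X[, 4] <- 1
  hom <- X %*% t(P)
  got <- projectPoints(X[, 1:3], v2)
  expect_equal(got$x, hom[, 1] / hom[, 3], tolerance = 1e-12)
  expect_equal(got$y, hom[, 2] / hom[, 3], tolerance = 1e-12)
  ## behind-camera flag
  pr <- projectPoints(c(0, 0, 2 * d), v)  # behind after rig rotation? no:
  pr <- projectPoints(cameraCentre(v@pose) * 2, v)  # beyond the camera
  expect_true(pr$behind)
  expect_true(is.na(pr$x))
})

test_that("pose tables round-trip through the plain-text format", {
  intr <- cameraIntrinsics(800, c(640, 480))
  views <- makeViews(intr, c(0, 72, 144), c(-15, 15), 120)
  f <- tempfile(fileext = ".tsv")
  writePoseTable(views, f)
  back <- posesFromTable(readPoseTable(f), intr)
  expect_length(back, length(views))
  for (i in seq_along(views)) {
    expect_lt(max(abs(back[[i]]@pose@rotation - views[[i]]@pose@rotation)),
              1e-10)
    expect_lt(max(abs(back[[i]]@pose@translation -
                      views[[i]]@pose@translation)), 1e-10)
  }
  unlink(f)
})

## camera looking straight down at the mat plane, tilted by tiltDeg
matView <- function(intr, tiltDeg = 0, dist = 120, id = 1L) {
  a <- tiltDeg * pi / 180
  R <- rbind(c(1, 0, 0), c(0, -cos(a), sin(a)), c(0, -sin(a), -cos(a)))
  cameraView(intr, rigidPose(R, c(0, 0, dist)), id)
}

test_that("fiducial markers are detected and decoded from renders", {
  spec <- fiducialMatSpec(50, 12, 8)
  scene <- syntheticScene(list(), mat = spec, matZ = 0)
  intr <- cameraIntrinsics(900, c(800, 800))
  ## fronto-parallel: all markers, sub-pixel centroids
  v <- matView(intr)
  rv <- renderView(scene, v)
  det <- detectFiducialMarkers(rv$image, spec)
  expect_equal(det$id, 1:12)
  gt <- projectPoints(matMarkerPositions(spec), v)
  err <- sqrt((det$x - gt$x[det$id])^2 + (det$y - gt$y[det$id])^2)
  expect_lt(max(err), 0.5)
  ## uniform image has no structure
  flat <- array(0.5, c(64, 64, 3))
  expect_error(detectFiducialMarkers(flat, spec), "insufficient markers")
  ## oblique view at 60 degrees still yields at least 4 markers
  v60 <- matView(intr, 60, 130)
  det60 <- detectFiducialMarkers(renderView(scene, v60)$image, spec)
  expect_gte(nrow(det60), 4)
})

test_that("planar pose estimation recovers known poses", {
  spec <- fiducialMatSpec(50, 12, 8)
  intr <- cameraIntrinsics(900, c(800, 800))
  Rt <- matView(intr, 55, 125)@pose@rotation %*%
    insecthull:::rodrigues(c(0.03, -0.05, 0.1))
  tt <- c(2, -3, 125)
  v <- cameraView(intr, rigidPose(Rt, tt))
  gt <- projectPoints(matMarkerPositions(spec), v)
  mk <- data.frame(id = 1:12, x = gt$x, y = gt$y)
  ## noiseless: rotation within 0.1 degree, translation within 0.1%
  est <- estimatePoseFromMat(mk, spec, intr)
  expect_lt(rotationErrDeg(est$pose@rotation, Rt), 0.1)
  expect_lt(sqrt(sum((est$pose@translation - tt)^2)) / sqrt(sum(tt^2)),
            0.001)
  expect_lt(est$rmsPx, 1e-8)
  ## 0.5 px Gaussian noise (seeded): rotation within 0.5 degree
  set.seed(301)
  for (rep in 1:5) {
    mkn <- mk
    mkn$x <- mkn$x + rnorm(12, 0, 0.5)
    mkn$y <- mkn$y + rnorm(12, 0, 0.5)
    e <- estimatePoseFromMat(mkn, spec, intr)
    expect_lt(rotationErrDeg(e$pose@rotation, Rt), 0.5)
  }
  ## collinear image points are degenerate
  mk3 <- data.frame(id = 1:4, x = c(0, 10, 20, 30), y = c(0, 5, 10, 15))
  expect_error(estimatePoseFromMat(mk3, spec, intr),
               "degenerate configuration")
  ## matZ offset is folded back into the world-frame pose
  gtZ <- projectPoints(matMarkerPositions(spec, matZ = -6), v)
  mkZ <- data.frame(id = 1:12, x = gtZ$x, y = gtZ$y)
  estZ <- estimatePoseFromMat(mkZ, spec, intr, matZ = -6)
  expect_lt(rotationErrDeg(estZ$pose@rotation, Rt), 0.1)
  expect_lt(max(abs(estZ$pose@translation - tt)), 0.01)
})

test_that("joint pose refinement never increases reprojection RMS", {
  spec <- fiducialMatSpec(50, 12, 8)
  intr <- cameraIntrinsics(900, c(800, 800))
  tt <- c(0, 0, 125)
  set.seed(77)
  truePoses <- lapply(1:4, function(i)
    matView(intr, 40, 125, i)@pose@rotation %*%
      insecthull:::rodrigues(c(0, 0, 0.5 * i)))
  mks <- lapply(1:4, function(i) {
    g <- projectPoints(matMarkerPositions(spec),
                       cameraView(intr, rigidPose(truePoses[[i]], tt), i))
    data.frame(id = 1:12, x = g$x, y = g$y)
  })
  ## already-optimal poses stay put
  exact <- lapply(1:4, function(i)
    cameraView(intr, rigidPose(truePoses[[i]], tt), i))
  rf0 <- refinePoses(exact, mks, spec)
  expect_lt(rf0$rmsAfter, 1e-6)
  for (i in 1:4)
    expect_lt(max(abs(rf0$views[[i]]@pose@rotation -
                      truePoses[[i]])), 1e-6)
  ## poses perturbed by about 1 degree: RMS must not increase
  pert <- lapply(1:4, function(i)
    cameraView(intr, rigidPose(truePoses[[i]] %*%
      insecthull:::rodrigues(rnorm(3, 0, 0.017)), tt + rnorm(3, 0, 0.3)), i))
  rf <- refinePoses(pert, mks, spec)
  expect_lte(rf$rmsAfter, rf$rmsBefore)
  expect_lt(rf$rmsAfter, 0.01)
  ## a single view is returned unchanged
  rf1 <- refinePoses(pert[1], mks[1], spec)
  expect_identical(rf1$views[[1]]@pose@rotation,
                   pert[[1]]@pose@rotation)
})
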