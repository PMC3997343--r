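test_that("carving against one all-foreground mask removes nothing visible", {
  intr <- cameraIntrinsics(300, c(64, 64))
  v <- cameraView(intr, poseFromTurntable(turntableState(0, 0, 50)), 1L)
  allFg <- new("SilhouetteMask", mask = matrix(1, 64, 64), viewId = 1L,
               exclusions = list())
  g <- carve(list(allFg), list(v), voxelGrid(5, 16), dilatePx = 0)
  ## every voxel whose centre projects into the image stays occupied
  ctr <- insecthull:::voxelCentres(g)
  pr <- projectPoints(ctr, v)
  inFrustum <- !pr$behind & pr$x >= 0 & pr$x < 64 & pr$y >= 0 & pr$y < 64
  expect_true(all(g@occupancy[inFrustum]))
  ## no views is an error
  expect_error(carve(list(), list(), voxelGrid(5, 8)), "no views")
})

test_that("the carved sphere approximates the analytic ball", {
  scene <- sphereScene(5)
  intr <- cameraIntrinsics(1200, c(360, 360))
  views <- makeViews(intr, seq(0, 345, 15), c(-30, 0, 30), 50)
  masks <- matteMasks(scene, views)
  g <- carve(masks, views, voxelGrid(8, 96))
  trueVol <- 4 / 3 * pi * 125
  expect_lt(abs(voxelVolume(g) - trueVol) / trueVol, 0.05)
  ## SUPERSET: every voxel centre inside the true sphere stays occupied
  ctr <- insecthull:::voxelCentres(g)
  inside <- rowSums(ctr^2) < 25
  expect_equal(sum(inside & !as.logical(g@occupancy)), 0)
  ## the mesh volume agrees with the voxel volume
  m <- meshFromGrid(g)
  expect_lt(abs(meshVolume(m) - trueVol) / trueVol, 0.05)
  expect_equal(boundaryEdgeCount(m), 0)  # watertight
})

test_that("occupancy is monotone non-increasing in view count", {
  set.seed(19)
  scene <- syntheticScene(list(
    scenePrimitive("ellipsoid", c(0.3, -0.2, 0.1), c(4, 2.5, 2),
                   colour = c(0.6, 0.3, 0.2))))
  intr <- cameraIntrinsics(600, c(128, 128))
  pans <- seq(0, 315, 45)
  tilts <- c(-35, 0, 35)
  views <- makeViews(intr, pans, tilts, 50)
  masks <- matteMasks(scene, views)
  counts <- integer(0)
  prev <- NULL
  for (k in c(3, 6, 12, 24)) {
    g <- carve(masks[1:k], views[1:k], voxelGrid(6, 48))
    counts <- c(counts, sum(g@occupancy))
    if (!is.null(prev))
      expect_true(all(prev | !g@occupancy) ||
                  sum(g@occupancy & !prev) == 0)
    prev <- g@occupancy
  }
  expect_true(all(diff(counts) <= 0))
  ## CONVERGENCE: volume stays above the analytic lower bound
  expect_gte(voxelVolume(carve(masks, views, voxelGrid(6, 48))),
             4 / 3 * pi * 4 * 2.5 * 2 * 0.95)
})

test_that("superset invariant holds over a seeded random-pose sweep", {
  set.seed(23)
  scene <- sphereScene(3.5, centre = c(0.5, -0.4, 0.3))
  intr <- cameraIntrinsics(500, c(96, 96))
  views <- lapply(1:15, function(i)
    cameraView(intr, poseFromTurntable(turntableState(
      runif(1, 0, 360), runif(1, -45, 45), 45)), i))
  masks <- matteMasks(scene, views)
  g <- carve(masks, views, voxelGrid(6, 48))
  ctr <- insecthull:::voxelCentres(g)
  inside <- (ctr[, 1] - 0.5)^2 + (ctr[, 2] + 0.4)^2 +
            (ctr[, 3] - 0.3)^2 < 3.5^2
  expect_equal(sum(inside & !as.logical(g@occupancy)), 0)
})

test_that("octree carving matches dense carving bit for bit", {
  set.seed(5)
  intr <- cameraIntrinsics(600, c(128, 128))
  for (rep in 1:3) {
    centre <- runif(3, -1, 1)
    scene <- syntheticScene(list(scenePrimitive(
      sample(c("sphere", "ellipsoid", "box"), 1), centre,
      if (rep == 1) 4 else c(4, 3, 2.5), colour = c(0.5, 0.4, 0.3))))
    views <- makeViews(intr, seq(0, 300, 60), c(-25, 25), 50)
    masks <- matteMasks(scene, views)
    dense <- carve(masks, views, voxelGrid(7, 32))
    oct <- carveOctree(masks, views, 7, 5)
    expect_identical(oct@occupancy, dense@occupancy)
  }
  ## all-background mask whose frustum covers the whole grid: empty at
  ## every depth
  blank <- list(new("SilhouetteMask", mask = matrix(0, 128, 128),
                    viewId = 1L, exclusions = list()))
  wideIntr <- cameraIntrinsics(300, c(128, 128))
  v1 <- makeViews(wideIntr, 0, 0, 50)
  expect_warning(e1 <- carveOctree(blank, v1, 7, 3, dilatePx = 0),
                 "empty hull")
  expect_false(any(e1@occupancy))
  ## depth 1 equals dense 2^3
  scene <- sphereScene(4)
  views <- makeViews(intr, c(0, 90), 0, 50)
  masks <- matteMasks(scene, views)
  d1 <- carveOctree(masks, views, 4, 1)
  d2 <- carve(masks, views, voxelGrid(4, 2))
  expect_identical(d1@occupancy, d2@occupancy)
  expect_true(any(d1@occupancy))
})

test_that("meshFromGrid produces closed, well-formed surfaces", {
  ## a single occupied voxel in a 3^3 grid is a topological sphere
  g <- voxelGrid(1.5, 3, occupied = FALSE)
  occ <- g@occupancy; occ[2, 2, 2] <- TRUE
  g <- new("VoxelGrid", bbox = g@bbox, resolution = g@resolution,
           occupancy = occ)
  m <- meshFromGrid(g)
  expect_equal(eulerCharacteristic(m), 2)
  expect_equal(boundaryEdgeCount(m), 0)
  expect_gt(meshVolume(m), 0)
  ## degenerate grids are rejected
  expect_error(meshFromGrid(voxelGrid(1, 4, occupied = TRUE)),
               "degenerate grid")
  expect_error(meshFromGrid(voxelGrid(1, 4, occupied = FALSE)),
               "degenerate grid")
})

test_that("largest-component filtering follows the stated tie rules", {
  ## sphere plus a small distant cube, carved into one grid
  mkBlock <- function(lo, hi, g) {
    occ <- g@occupancy
    ctr <- insecthull:::voxelCentres(g)
    sel <- ctr[, 1] >= lo[1] & ctr[, 1] <= hi[1] &
           ctr[, 2] >= lo[2] & ctr[, 2] <= hi[2] &
           ctr[, 3] >= lo[3] & ctr[, 3] <= hi[3]
    occ[sel] <- TRUE
    new("VoxelGrid", bbox = g@bbox, resolution = g@resolution,
        occupancy = occ)
  }
  base <- voxelGrid(8, 32, occupied = FALSE)
  g <- mkBlock(c(-5, -5, -5), c(1, 1, 1), base)
  g <- mkBlock(c(5, 5, 5), c(7, 7, 7), g)
  m <- meshFromGrid(g)
  expect_equal(max(meshComponents(m)), 2)
  kept <- keepLargestComponent(m)
  expect_equal(max(meshComponents(kept)), 1)
  expect_lt(nrow(kept@faces), nrow(m@faces))
  ## big block centre is retained, small block gone
  expect_true(all(faceCentroids(kept)[, 1] < 3))
  ## single component: unchanged face count
  m1 <- keepLargestComponent(kept)
  expect_equal(nrow(m1@faces), nrow(kept@faces))
  ## equal components: the one containing the lowest vertex index wins
  gEq <- mkBlock(c(-6, -6, -6), c(-4, -4, -4), base)
  gEq <- mkBlock(c(4, 4, 4), c(6, 6, 6), gEq)
  mEq <- meshFromGrid(gEq)
  compEq <- meshComponents(mEq)
  expect_equal(max(compEq), 2)
  sizes <- tabulate(compEq)
  expect_equal(sizes[1], sizes[2])
  keptEq <- keepLargestComponent(mEq)
  lowVertex <- mEq@vertices[1, ]
  expect_true(any(apply(keptEq@vertices, 1, function(v)
    all(abs(v - lowVertex) < 1e-12))))
})
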