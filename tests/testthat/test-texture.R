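## shared small carved sphere for the texturing tests
texFixture <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    scene <- sphereScene(5, two_tone = TRUE)
    intr <- cameraIntrinsics(600, c(200, 200))
    views <- makeViews(intr, seq(0, 330, 30), c(-50, -20, 20, 50), 50)
    rvs <- lapply(views, function(v) renderView(scene, v))
    masks <- lapply(seq_along(views), function(i)
      new("SilhouetteMask", mask = rvs[[i]]$matte, viewId = i,
          exclusions = list()))
    g <- carve(masks, views, voxelGrid(6, 32))
    mesh <- meshFromGrid(g)
    cache <<- list(scene = scene, intr = intr, views = views, rvs = rvs,
                   mesh = mesh)
    cache
  }
})

test_that("view selection respects visibility and tie rules", {
  fx <- texFixture()
  ## single view on a convex object: faces pointing at the camera get it,
  ## the rest are unseen
  one <- fx$views[13]  # tilt -20, pan 0
  a1 <- selectBestView(fx$mesh, one)
  expect_true(any(!is.na(a1)))
  expect_true(any(is.na(a1)))
  C <- cameraCentre(one[[1]]@pose)
  fn <- smoothedFaceNormals(fx$mesh)
  ctr <- faceCentroids(fx$mesh)
  toC <- sweep(-ctr, 2, C, "+")
  q <- rowSums(fn * toC / sqrt(rowSums(toC^2)))
  ## faces pointing away are never assigned
  expect_true(all(is.na(a1[q < 0])))
  ## two identical candidate views: the lower index wins
  twin <- list(one[[1]], one[[1]])
  a2 <- selectBestView(fx$mesh, twin)
  expect_true(all(a2[!is.na(a2)] == 1L))
  ## full coverage leaves no face unseen
  aFull <- selectBestView(fx$mesh, fx$views)
  expect_equal(sum(is.na(aFull)), 0)
})

test_that("baking conserves colour from the source images", {
  ## uniformly red object: every textured texel is red
  scene <- sphereScene(5)
  intr <- cameraIntrinsics(600, c(200, 200))
  views <- makeViews(intr, seq(0, 300, 60), c(-30, 30), 50)
  rvs <- lapply(views, function(v) renderView(scene, v))
  masks <- lapply(seq_along(views), function(i)
    new("SilhouetteMask", mask = rvs[[i]]$matte, viewId = i,
        exclusions = list()))
  g <- carve(masks, views, voxelGrid(6, 16))
  mesh <- meshFromGrid(g)
  assign <- selectBestView(mesh, views)
  tm <- bakeAtlas(mesh, assign, lapply(rvs, function(r) r$image), views,
                  512)
  fc <- faceMeanColour(tm)
  seen <- !is.na(tm@sourceView)
  expect_true(all(abs(fc[seen, 1] - 0.9) <= 2 / 255 + 1e-9))
  expect_true(all(abs(fc[seen, 2] - 0.1) <= 2 / 255 + 1e-9))
  ## unseen faces carry the magenta flag colour
  if (any(!seen)) {
    expect_true(all(abs(fc[!seen, 1] - 1) < 1e-9))
    expect_true(all(abs(fc[!seen, 2] - 0) < 1e-9))
  }
  ## atlas overflow is reported
  expect_error(bakeAtlas(mesh, assign, lapply(rvs, function(r) r$image),
                         views, 8), "atlas overflow")
})

test_that("two-tone texture recovery needs full pose coverage", {
  fx <- texFixture()
  images <- lapply(fx$rvs, function(r) r$image)
  aFull <- selectBestView(fx$mesh, fx$views)
  tm <- bakeAtlas(fx$mesh, aFull, images, fx$views, 1024)
  fc <- faceMeanColour(tm)
  ctr <- faceCentroids(fx$mesh)
  truth <- ifelse(ctr[, 3] >= 0, "red", "blue")
  pred <- ifelse(fc[, 1] > fc[, 3], "red", "blue")
  accFull <- mean(pred == truth)
  expect_gte(accFull, 0.98)
  ## hemisphere-only coverage: accuracy strictly lower
  upper <- fx$views[25:48]  # tilts +20 and +50 only
  aHemi <- selectBestView(fx$mesh, upper)
  tmH <- bakeAtlas(fx$mesh, aHemi, images[25:48], upper, 1024)
  fcH <- faceMeanColour(tmH)
  predH <- ifelse(fcH[, 1] > fcH[, 3], "red", "blue")
  accHemi <- mean(predH == truth)
  expect_lt(accHemi, accFull)
  expect_gt(sum(is.na(aHemi)), 0)
})

test_that("pin removal separates the mounting pin from the specimen", {
  ## fused body + detached pin: the pin reconstructs as its own component
  scene <- syntheticScene(list(
    scenePrimitive("ellipsoid", c(0, 0, 0), c(1.2, 0.6, 0.5),
                   colour = c(0.45, 0.25, 0.1)),
    scenePrimitive("sphere", c(1.1, 0, 0.1), 0.4,
                   colour = c(0.35, 0.2, 0.1)),
    scenePrimitive("cylinder", c(0, 0, 1.1), c(0.12, 0.45),
                   colour = c(0.75, 0.75, 0.78))))
  intr <- cameraIntrinsics(1400, c(200, 200))
  views <- makeViews(intr, seq(0, 330, 30), c(-30, 0, 30), 60)
  rvs <- lapply(views, function(v) renderView(scene, v))
  masks <- lapply(seq_along(views), function(i)
    new("SilhouetteMask", mask = rvs[[i]]$matte, viewId = i,
        exclusions = list()))
  g <- carve(masks, views, voxelGrid(2.2, 64), dilatePx = 0)
  mesh <- meshFromGrid(g)
  expect_equal(max(meshComponents(mesh)), 2)
  assign <- selectBestView(mesh, views)
  tm <- bakeAtlas(mesh, assign, lapply(rvs, function(r) r$image), views,
                  1024)
  out <- removePin(tm, "component")
  expect_equal(max(meshComponents(out@mesh)), 1)
  ctr <- faceCentroids(out@mesh)
  expect_equal(sum(ctr[, 3] > 0.6 &
                   sqrt(ctr[, 1]^2 + ctr[, 2]^2) < 0.3), 0)
  ## the body is intact (same faces as the largest input component)
  comp <- meshComponents(tm@mesh)
  expect_equal(nrow(out@mesh@faces), max(tabulate(comp)))
  ## pinless mesh: warns and returns unchanged
  expect_warning(again <- removePin(out, "component"), "nothing removed")
  expect_equal(nrow(again@mesh@faces), nrow(out@mesh@faces))
  ## cylinder mode on a pin fused to the body
  fused <- syntheticScene(list(
    scenePrimitive("ellipsoid", c(0, 0, 0), c(1.2, 0.6, 0.5),
                   colour = c(0.45, 0.25, 0.1)),
    scenePrimitive("cylinder", c(0, 0, 0.8), c(0.12, 0.45),
                   colour = c(0.75, 0.75, 0.78))))
  rvs2 <- lapply(views, function(v) renderView(fused, v))
  masks2 <- lapply(seq_along(views), function(i)
    new("SilhouetteMask", mask = rvs2[[i]]$matte, viewId = i,
        exclusions = list()))
  g2 <- carve(masks2, views, voxelGrid(2.2, 64), dilatePx = 0)
  mesh2 <- meshFromGrid(g2)
  expect_equal(max(meshComponents(mesh2)), 1)
  tm2 <- bakeAtlas(mesh2, selectBestView(mesh2, views),
                   lapply(rvs2, function(r) r$image), views, 1024)
  cut <- removePin(tm2, "cylinder", axisPoint = c(0, 0, 0.6),
                   axisDir = c(0, 0, 1), radius = 0.3)
  ctr2 <- faceCentroids(cut@mesh)
  expect_equal(sum(ctr2[, 3] > 0.7 &
                   sqrt(ctr2[, 1]^2 + ctr2[, 2]^2) < 0.3), 0)
  ## the hole is reported as a boundary-edge count
  expect_gt(cut@metadata$boundaryEdges, 0)
})

test_that("exports round-trip and unsupported formats error", {
  g <- voxelGrid(1.5, 3, occupied = FALSE)
  occ <- g@occupancy; occ[2, 2, 2] <- TRUE
  cube <- meshFromGrid(new("VoxelGrid", bbox = g@bbox,
                           resolution = g@resolution, occupancy = occ))
  d <- tempfile(); dir.create(d)
  ## OBJ round trip: exact topology, coordinates to 1e-5 mm
  exportMesh(cube, file.path(d, "m.obj"))
  backO <- readOBJ(file.path(d, "m.obj"))
  expect_equal(nrow(backO@vertices), nrow(cube@vertices))
  expect_identical(backO@faces, cube@faces)
  expect_lt(max(abs(backO@vertices - cube@vertices)), 1e-5)
  ## PLY round trip
  exportMesh(cube, file.path(d, "m.ply"))
  backP <- readPLY(file.path(d, "m.ply"))
  expect_equal(nrow(backP@vertices), nrow(cube@vertices))
  expect_identical(backP@faces, cube@faces)
  expect_lt(max(abs(backP@vertices - cube@vertices)), 1e-5)
  ## binary STL has the defined size
  exportMesh(cube, file.path(d, "m.stl"))
  expect_equal(file.size(file.path(d, "m.stl")),
               84 + 50 * nrow(cube@faces))
  ## textured export: OBJ+MTL+PNG and well-formed X3D
  fx <- texFixture()
  aFull <- selectBestView(fx$mesh, fx$views)
  tm <- bakeAtlas(fx$mesh, aFull, lapply(fx$rvs, function(r) r$image),
                  fx$views, 512)
  files <- exportMesh(tm, file.path(d, "t.obj"))
  expect_true(all(file.exists(files)))
  expect_length(files, 3)  # obj + mtl + atlas png
  backT <- readOBJ(file.path(d, "t.obj"))
  expect_equal(nrow(backT@faces), nrow(tm@mesh@faces))
  uv <- attr(backT, "uv")
  expect_equal(dim(uv), dim(tm@uv))
  expect_lt(max(abs(uv - tm@uv)), 1e-6)
  exportMesh(tm, file.path(d, "t.x3d"))
  x <- xml2::read_xml(file.path(d, "t.x3d"))
  expect_equal(xml2::xml_name(x), "X3D")
  expect_length(xml2::xml_find_all(x, "//IndexedFaceSet"), 1)
  expect_length(xml2::xml_find_all(x, "//Coordinate"), 1)
  expect_length(xml2::xml_find_all(x, "//TextureCoordinate"), 1)
  expect_length(xml2::xml_find_all(x, "//ImageTexture"), 1)
  ## 3DS is not supported
  expect_error(exportMesh(cube, file.path(d, "m.3ds")),
               "unsupported format")
  unlink(d, recursive = TRUE)
})
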