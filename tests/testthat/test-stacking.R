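test_that("sharpness map responds to focus, not to brightness", {
  ## constant image: zero everywhere
  flat <- array(0.37, c(32, 32, 3))
  expect_true(all(sharpnessMap(flat) == 0))
  ## adding a DC offset leaves the map unchanged (Laplacian kills DC)
  img <- texturedImage(32, 32)
  off <- pmin(img + 0.2, 1)  # stay in range; offset is constant where unclipped
  s1 <- sharpnessMap(img)
  s2 <- sharpnessMap(img * 1)  # determinism
  expect_identical(s1, s2)
  shifted <- img
  shifted[] <- img + 0.1
  expect_equal(sharpnessMap(shifted), s1, tolerance = 1e-10)
  ## a blurred step edge is strictly less sharp at the edge
  step <- greyScale <- matrix(0, 40, 40)
  step[, 21:40] <- 1
  stepRGB <- array(rep(step, 3), c(40, 40, 3))
  blurRGB <- stepRGB
  for (ch in 1:3)
    blurRGB[, , ch] <- insecthull:::fromEB(EBImage::gblur(
      insecthull:::toEB(stepRGB[, , ch]), sigma = 2))
  sSharp <- sharpnessMap(stepRGB)
  sBlur <- sharpnessMap(blurRGB)
  expect_gt(sSharp[20, 20], sBlur[20, 20])
  ## window validation
  expect_error(sharpnessMap(img, window = 4), "odd")
})

test_that("depth selection picks the in-focus frame per region", {
  base <- texturedImage(48, 64)
  blur <- base
  for (ch in 1:3)
    blur[, , ch] <- insecthull:::fromEB(EBImage::gblur(
      insecthull:::toEB(base[, , ch]), sigma = 3))
  ## frame 1 sharp on the left half, frame 2 sharp on the right
  f1 <- base; f1[, 33:64, ] <- blur[, 33:64, ]
  f2 <- base; f2[, 1:32, ] <- blur[, 1:32, ]
  st <- focusStack(list(f1, f2), c(0, 1))
  depth <- selectDepth(st, window = 7, smoothRadius = 3)
  away <- cbind(rep(5:44, 2), rep(c(10, 54), each = 40))
  expected <- ifelse(away[, 2] <= 32, 1L, 2L)
  expect_gte(mean(depth$index[away] == expected), 0.99)
  ## identical frames: ties break to the first frame
  st2 <- focusStack(list(base, base, base), 1:3)
  d2 <- selectDepth(st2, smoothRadius = 0)
  expect_true(all(d2$index == 1L))
})

test_that("compositing is a hard per-pixel selection", {
  base <- texturedImage(30, 30, seed = 3)
  st <- focusStack(list(base, base), c(0, 1))
  idx <- matrix(1L, 30, 30)
  expect_identical(compositeStack(st, idx), base)
  ## stacking an all-identical stack returns the frame bit-exactly
  out <- stackFocus(st)
  expect_identical(out$image, base)
  ## single-frame stacks pass through
  st1 <- focusStack(list(base))
  expect_identical(stackFocus(st1)$image, base)
  ## colour conservation: every output pixel equals some input frame's
  ## pixel at that location
  dark <- base * 0.3
  stm <- focusStack(list(base, dark), c(0, 1))
  idx2 <- matrix(sample(1:2, 900, replace = TRUE), 30, 30)
  comp <- compositeStack(stm, idx2)
  fromA <- abs(comp - base) < 1e-15
  fromB <- abs(comp - dark) < 1e-15
  expect_true(all(fromA | fromB))
})

test_that("synthetic defocus stacks recover a sharp composite", {
  ## a tilted box fills the frame with depth variation; 31 frames at
  ## 0.25 mm as in macro capture
  scene <- weevilScene()
  intr <- cameraIntrinsics(3200, c(128, 128))
  v <- cameraView(intr, poseFromTurntable(turntableState(40, 20, 60)), 1L)
  fs <- renderFocusStack(scene, v, defocusModel(60, 2),
                         seq(-3.75, 3.75, by = 0.25))
  expect_length(fs$stack@frames, 31)
  st <- stackFocus(fs$stack)
  expect_gte(psnr(st$image, fs$sharp), 30)
  ## the composite clearly beats the best single frame
  bestFrame <- max(vapply(fs$stack@frames, function(f) psnr(f, fs$sharp),
                          numeric(1)))
  expect_gt(psnr(st$image, fs$sharp), bestFrame)
})

test_that("depth indices follow scene depth on a tilted plane", {
  ## a tilted thin box: depth increases monotonically across the image,
  ## so each frame's in-focus strip sweeps across and the recovered
  ## median depth index increases along the gradient
  rot <- insecthull:::rotX(35 * pi / 180)
  scene <- syntheticScene(list(
    scenePrimitive("box", c(0, 0, 0), c(6, 6, 0.2), rotation = rot,
                   colour = c(0.5, 0.5, 0.5))))
  intr <- cameraIntrinsics(1200, c(96, 96))
  v <- cameraView(intr, poseFromTurntable(turntableState(0, 0, 40)), 1L)
  rv <- renderView(scene, v)
  ## paint deterministic texture on the box so sharpness has signal
  tex <- texturedImage(96, 96, seed = 5)
  img <- rv$image
  for (ch in 1:3) {
    m <- img[, , ch]
    m[rv$matte == 1] <- tex[, , ch][rv$matte == 1]
    img[, , ch] <- m
  }
  sceneImg <- list(image = img, matte = rv$matte, depth = rv$depth)
  ## build the defocus stack directly from the textured render
  d0 <- 40
  positions <- seq(-2, 2, length.out = 9)
  stack <- local({
    rvmod <- sceneImg
    frames <- lapply(positions, function(f) {
      out <- rvmod$image
      sig <- 2 * abs(rvmod$depth - (d0 + f))
      for (ch in 1:3) {
        bl <- insecthull:::fromEB(EBImage::gblur(
          insecthull:::toEB(rvmod$image[, , ch]), sigma = max(mean(sig), 0.5)))
        sel <- abs(rvmod$depth - (d0 + f)) > 0.4
        o <- out[, , ch]; o[sel] <- bl[sel]; out[, , ch] <- o
      }
      out
    })
    focusStack(frames, d0 + positions)
  })
  depth <- selectDepth(stack, window = 7, smoothRadius = 3)
  ## median index per row should increase down the image (nearer rows
  ## focus earlier in the sweep)
  rows <- seq(15, 80, by = 5)
  med <- vapply(rows, function(r)
    stats::median(depth$index[r, rv$matte[r, ] == 1]), numeric(1))
  expect_true(all(diff(med) >= 0) || all(diff(med) <= 0))
  expect_gt(abs(med[length(med)] - med[1]), 3)
})
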