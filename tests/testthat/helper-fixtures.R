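## Shared fixture builders. Everything is generated in code at test time;
## the synthetic renderer provides ground truth.

## views on the turntable schedule: one CameraView per (pan, tilt)
makeViews <- function(intr, pans, tilts, distanceMm = 50) {
  vs <- list()
  id <- 1L
  for (t in tilts) for (p in pans) {
    vs[[id]] <- cameraView(intr, poseFromTurntable(
      turntableState(p, t, distanceMm)), id)
    id <- id + 1L
  }
  vs
}

## exact silhouette masks from the renderer's mattes
matteMasks <- function(scene, views) {
  lapply(views, function(v)
    new("SilhouetteMask", mask = renderView(scene, v)$matte,
        viewId = v@viewId, exclusions = list()))
}

## angular difference between two rotations, degrees
rotationErrDeg <- function(R1, R2) {
  c <- (sum(diag(crossprod(R1, R2))) - 1) / 2
  acos(min(1, max(-1, c))) * 180 / pi
}

## single-sphere test scene
sphereScene <- function(r = 5, centre = c(0, 0, 0), two_tone = FALSE) {
  if (two_tone)
    syntheticScene(list(scenePrimitive("sphere", centre, r,
      colour = c(0.9, 0.1, 0.1), colour2 = c(0.1, 0.1, 0.9))))
  else
    syntheticScene(list(scenePrimitive("sphere", centre, r,
      colour = c(0.9, 0.1, 0.1))))
}

## textured flat image (deterministic pseudo-noise), for stacking tests
texturedImage <- function(h, w, seed = 7) {
  set.seed(seed)
  base <- matrix(runif(h * w), h, w)
  array(c(base, 0.5 * base + 0.25, 1 - base), c(h, w, 3))
}

## Euler characteristic V - E + F of a mesh
eulerCharacteristic <- function(mesh) {
  e <- rbind(mesh@faces[, 1:2], mesh@faces[, 2:3], mesh@faces[, c(1, 3)])
  E <- nrow(unique(cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))))
  nrow(mesh@vertices) - E + nrow(mesh@faces)
}
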