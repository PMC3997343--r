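#' @import methods
NULL

## Central S4 containers for the digitization pipeline. Conventions used
## throughout the package (stated once, here):
##  * world frame: right-handed, specimen-centred, +Z up along the pin axis,
##    lengths in mm;
##  * camera frame: +X right, +Y down, +Z forward (optical axis), so that
##    pixel x grows right and pixel y grows down;
##  * pose maps world to camera: p_cam = R p_world + t;
##  * pixel coordinates are continuous with origin at the top-left image
##    corner; the centre of pixel (row r, col c) is (x = c - 0.5, y = r - 0.5);
##  * raster images are arrays [row, col, channel] with values in [0, 1]
##    (the layout produced by png::readPNG);
##  * angles are degrees at API boundaries, radians internally.

#' Pinhole camera intrinsics
#'
#' Focal length in pixels, principal point and image size of a
#' distortion-free pinhole camera. Square pixels are assumed (one focal
#' length serves both axes), which matches pre-rectified DSLR captures.
#'
#' @slot focalPx focal length in pixels (> 0).
#' @slot principalPoint numeric length-2, principal point (x, y) in pixels;
#'   must lie inside the image.
#' @slot imageSize integer length-2, (width, height) in pixels.
#' @export
setClass("CameraIntrinsics", representation(
  focalPx = "numeric",
  principalPoint = "numeric",
  imageSize = "integer"
))

setValidity("CameraIntrinsics", function(object) {
  msg <- character()
  if (length(object@focalPx) != 1L || !is.finite(object@focalPx) ||
      object@focalPx <= 0)
    msg <- c(msg, "focalPx must be a single finite positive number")
  if (length(object@principalPoint) != 2L ||
      any(!is.finite(object@principalPoint)))
    msg <- c(msg, "principalPoint must be a finite 2-vector")
  if (length(object@imageSize) != 2L || any(object@imageSize < 1L))
    msg <- c(msg, "imageSize must be two positive integers")
  if (length(msg) == 0L &&
      (object@principalPoint[1] < 0 ||
       object@principalPoint[1] >= object@imageSize[1] ||
       object@principalPoint[2] < 0 ||
       object@principalPoint[2] >= object@imageSize[2]))
    msg <- c(msg, "principalPoint must lie inside [0,width) x [0,height)")
  if (length(msg)) msg else TRUE
})

#' Rigid camera pose (world to camera)
#'
#' @slot rotation 3x3 rotation matrix (orthonormal, det +1).
#' @slot translation numeric length-3 translation in mm.
#' @export
setClass("RigidPose", representation(
  rotation = "matrix",
  translation = "numeric"
))

setValidity("RigidPose", function(object) {
  R <- object@rotation
  if (!is.numeric(R) || !all(dim(R) == c(3L, 3L)))
    return("rotation must be a numeric 3x3 matrix")
  if (max(abs(crossprod(R) - diag(3))) > 1e-9)
    return("rotation must be orthonormal (R'R = I within 1e-9)")
  if (abs(det(R) - 1) > 1e-9)
    return("rotation must be proper (det = +1 within 1e-9)")
  if (length(object@translation) != 3L || any(!is.finite(object@translation)))
    return("translation must be a finite 3-vector")
  TRUE
})

#' Calibrated camera view
#'
#' One capture: intrinsics plus rigid pose, with an identifying view id.
#'
#' @slot intrinsics a \linkS4class{CameraIntrinsics}.
#' @slot pose a \linkS4class{RigidPose}.
#' @slot viewId integer view identifier.
#' @export
setClass("CameraView", representation(
  intrinsics = "CameraIntrinsics",
  pose = "RigidPose",
  viewId = "integer"
))

#' Turntable state
#'
#' Pan/tilt angles of the two-axis turntable plus the fixed camera-to-
#' specimen distance. Rotating the specimen by (pan, tilt) under a fixed
#' camera is equivalent to orbiting the camera; \code{\link{poseFromTurntable}}
#' performs that conversion.
#'
#' @slot panDeg pan angle in degrees, [0, 360).
#' @slot tiltDeg tilt angle in degrees, [-90, 90].
#' @slot cameraDistanceMm distance from camera centre to the specimen
#'   origin, in mm (> 0; must exceed the specimen bounding radius).
#' @export
setClass("TurntableState", representation(
  panDeg = "numeric",
  tiltDeg = "numeric",
  cameraDistanceMm = "numeric"
))

setValidity("TurntableState", function(object) {
  msg <- character()
  if (object@panDeg < 0 || object@panDeg >= 360)
    msg <- c(msg, "panDeg must lie in [0, 360)")
  if (object@tiltDeg < -90 || object@tiltDeg > 90)
    msg <- c(msg, "tiltDeg must lie in [-90, 90]")
  if (object@cameraDistanceMm <= 0)
    msg <- c(msg, "cameraDistanceMm must be positive")
  if (length(msg)) msg else TRUE
})

#' Fiducial mat specification
#'
#' A printed calibration mat: \code{markerCount} filled discs evenly spaced
#' on a ring, each disc punched with a distinctive pattern of small holes
#' that encodes its identity. Marker k (1-based) carries \code{idCoding[k]}
#' holes; hole counting is a topological property, so decoding survives any
#' projective distortion of the mat without knowing the camera pose.
#'
#' @slot ringDiameterMm diameter of the circle on which marker centres lie.
#' @slot markerCount number of markers (4..18).
#' @slot markerDiameterMm diameter of each marker disc in mm.
#' @slot idCoding integer vector, holes per marker; all codes distinct.
#' @export
setClass("FiducialMatSpec", representation(
  ringDiameterMm = "numeric",
  markerCount = "integer",
  markerDiameterMm = "numeric",
  idCoding = "integer"
))

setValidity("FiducialMatSpec", function(object) {
  msg <- character()
  if (object@ringDiameterMm <= 0 || object@markerDiameterMm <= 0)
    msg <- c(msg, "ring and marker diameters must be positive")
  if (object@markerCount < 4L)
    msg <- c(msg, "markerCount must be at least 4")
  if (object@markerCount > 18L)
    msg <- c(msg, "markerCount above 18 is not supported by the hole coding")
  if (length(object@idCoding) != object@markerCount)
    msg <- c(msg, "idCoding must have one code per marker")
  if (anyDuplicated(object@idCoding))
    msg <- c(msg, "all marker codes must be distinct")
  if (object@markerDiameterMm >= pi * object@ringDiameterMm /
        object@markerCount)
    msg <- c(msg, "markers would overlap on the ring")
  if (length(msg)) msg else TRUE
})

#' Acquisition plan
#'
#' The capture schedule driving both the synthetic renderer and real-rig
#' file ingestion. Normal mode takes one image per view; macro mode takes
#' one image per (view, focus position) pair, the focus positions being a
#' uniformly spaced sweep along the camera axis.
#'
#' @slot mode "normal" or "macro".
#' @slot views data.frame with columns view (1-based id), panDeg, tiltDeg.
#' @slot focusPositionsMm strictly increasing, uniformly spaced focus
#'   offsets in mm (empty in normal mode), relative to the specimen origin.
#' @slot totalCaptures number of capture events the plan implies.
#' @slot cameraDistanceMm rig camera distance carried with the plan.
#' @export
setClass("AcquisitionPlan", representation(
  mode = "character",
  views = "data.frame",
  focusPositionsMm = "numeric",
  totalCaptures = "integer",
  cameraDistanceMm = "numeric"
))

setValidity("AcquisitionPlan", function(object) {
  msg <- character()
  if (!object@mode %in% c("normal", "macro"))
    msg <- c(msg, "mode must be 'normal' or 'macro'")
  if (!all(c("view", "panDeg", "tiltDeg") %in% names(object@views)))
    msg <- c(msg, "views must have columns view, panDeg, tiltDeg")
  nf <- length(object@focusPositionsMm)
  if (object@mode == "normal" && nf != 0L)
    msg <- c(msg, "normal mode must have no focus positions")
  if (object@mode == "macro" && nf < 2L)
    msg <- c(msg, "macro mode needs at least 2 focus positions")
  if (nf >= 2L) {
    d <- diff(object@focusPositionsMm)
    if (any(d <= 0)) msg <- c(msg, "focus positions must be strictly increasing")
    else if (max(d) - min(d) > 1e-9 * max(abs(d)))
      msg <- c(msg, "focus positions must be uniformly spaced")
  }
  expected <- nrow(object@views) * max(1L, nf)
  if (object@totalCaptures != expected)
    msg <- c(msg, sprintf("totalCaptures must equal |views| x max(1,|focus|) = %d",
                          expected))
  if (length(msg)) msg else TRUE
})

#' Multi-focus image stack
#'
#' Ordered partially-focused frames captured at one pose, with the focus
#' distance of each frame. All frames share one raster geometry.
#'
#' @slot frames list of [row, col, 3] arrays in [0, 1], equal dimensions.
#' @slot focusMm strictly increasing focus distances in mm.
#' @export
setClass("FocusStack", representation(
  frames = "list",
  focusMm = "numeric"
))

setValidity("FocusStack", function(object) {
  if (length(object@frames) < 1L) return("stack needs at least one frame")
  if (length(object@frames) != length(object@focusMm))
    return("one focus distance per frame required")
  if (length(object@focusMm) > 1L && any(diff(object@focusMm) <= 0))
    return("focusMm must be strictly increasing")
  d1 <- dim(object@frames[[1]])
  for (f in object@frames)
    if (!identical(dim(f), d1)) return("all frames must share dimensions")
  TRUE
})

#' Binary silhouette mask
#'
#' Foreground mask for one view, with the exclusion polygons (e.g. over the
#' mounting pin) that were forced to background.
#'
#' @slot mask numeric matrix of 0/1, [row, col].
#' @slot viewId integer provenance view id.
#' @slot exclusions list of n x 2 polygon vertex matrices (x, y in pixels).
#' @export
setClass("SilhouetteMask", representation(
  mask = "matrix",
  viewId = "integer",
  exclusions = "list"
))

setValidity("SilhouetteMask", function(object) {
  if (!all(object@mask %in% c(0, 1)))
    return("mask values must be 0 or 1")
  h <- nrow(object@mask); w <- ncol(object@mask)
  for (p in object@exclusions) {
    if (!is.matrix(p) || ncol(p) != 2L)
      return("exclusion polygons must be n x 2 matrices")
    if (any(p[, 1] < 0 | p[, 1] > w | p[, 2] < 0 | p[, 2] > h))
      return("exclusion polygons must lie within image bounds")
  }
  TRUE
})

#' Voxel occupancy grid
#'
#' Axis-aligned occupancy volume in specimen (mm) coordinates, carved by
#' silhouettes. Voxel (i, j, k) occupies the cell
#' \code{lo + ((i,j,k) - 1) * h .. lo + (i,j,k) * h} with h the voxel pitch.
#'
#' @slot bbox 2 x 3 matrix, rows = (lo, hi) corners in mm.
#' @slot resolution integer length-3 (nx, ny, nz).
#' @slot occupancy logical array nx x ny x nz.
#' @export
setClass("VoxelGrid", representation(
  bbox = "matrix",
  resolution = "integer",
  occupancy = "array"
))

setValidity("VoxelGrid", function(object) {
  if (!all(dim(object@bbox) == c(2L, 3L)))
    return("bbox must be a 2 x 3 matrix")
  if (any(object@bbox[2, ] <= object@bbox[1, ]))
    return("bbox must have positive extent on all axes")
  if (length(object@resolution) != 3L || any(object@resolution < 1L))
    return("resolution must be three integers >= 1")
  if (!identical(dim(object@occupancy), as.integer(object@resolution)))
    return("occupancy dimensions must match resolution")
  TRUE
})

#' Triangle surface mesh
#'
#' Marching-tetrahedra isosurface of a voxel grid (or any triangle soup
#' after editing), with per-vertex normals.
#'
#' @slot vertices n x 3 matrix of mm coordinates.
#' @slot faces m x 3 integer matrix of 1-based vertex indices.
#' @slot normals n x 3 per-vertex unit normals.
#' @export
setClass("IsoMesh", representation(
  vertices = "matrix",
  faces = "matrix",
  normals = "matrix"
))

setValidity("IsoMesh", function(object) {
  nv <- nrow(object@vertices)
  if (ncol(object@vertices) != 3L) return("vertices must be n x 3")
  if (nrow(object@faces) > 0L) {
    if (ncol(object@faces) != 3L) return("faces must be m x 3")
    if (min(object@faces) < 1L || max(object@faces) > nv)
      return("face indices out of range")
  }
  if (nrow(object@normals) > 0L && !all(dim(object@normals) ==
      c(nv, 3L)))
    return("normals must match vertices")
  TRUE
})

#' Textured mesh
#'
#' A triangle mesh with a packed texture atlas, per-face-corner UV
#' coordinates and the source view each face's colour was sampled from.
#' Faces visible in no view are flagged unseen (NA source view) and filled
#' with the flag colour recorded in \code{metadata$unseenColour}.
#'
#' @slot mesh an \linkS4class{IsoMesh}.
#' @slot atlas [row, col, 3] atlas raster in [0, 1].
#' @slot uv (3m) x 2 matrix of per-face-corner UVs in [0,1]^2 (rows grouped
#'   by face: corners 1..3 of face 1, then face 2, ...).
#' @slot sourceView integer per-face source view id; NA = unseen.
#' @slot metadata list (unseenColour, atlas packing parameters).
#' @export
setClass("TexturedMesh", representation(
  mesh = "IsoMesh",
  atlas = "array",
  uv = "matrix",
  sourceView = "integer",
  metadata = "list"
))

setValidity("TexturedMesh", function(object) {
  m <- nrow(object@mesh@faces)
  if (length(object@sourceView) != m)
    return("sourceView must have one entry per face")
  if (nrow(object@uv) != 3L * m || ncol(object@uv) != 2L)
    return("uv must be (3 * nfaces) x 2")
  if (nrow(object@uv) > 0L) {
    uvok <- object@uv >= -1e-9 & object@uv <= 1 + 1e-9
    if (!all(uvok)) return("uv coordinates must lie in [0,1]^2")
  }
  TRUE
})

#' Synthetic scene description
#'
#' A parametric stand-in for a mounted specimen: quadric/box primitives
#' (body, head, legs, pin), an optional fiducial mat on the plane
#' z = matZ, and a uniform background colour. Rendered by
#' \code{\link{renderView}} with exact analytic silhouettes.
#'
#' @slot primitives list of primitive descriptions (see
#'   \code{\link{scenePrimitive}}).
#' @slot mat a \linkS4class{FiducialMatSpec} or NULL.
#' @slot matZ height of the mat plane in mm.
#' @slot background RGB background colour in [0, 1].
#' @export
setClass("SyntheticScene", representation(
  primitives = "list",
  mat = "ANY",
  matZ = "numeric",
  background = "numeric"
))

setValidity("SyntheticScene", function(object) {
  for (p in object@primitives) {
    if (!p$shape %in% c("sphere", "ellipsoid", "cylinder", "box"))
      return(sprintf("unknown primitive shape '%s'", p$shape))
    if (any(p$size <= 0)) return("primitive sizes must be positive")
    if (any(p$colour < 0 | p$colour > 1))
      return("primitive colours must lie in [0,1]")
  }
  if (any(object@background < 0 | object@background > 1))
    return("background colour must lie in [0,1]")
  if (!is.null(object@mat) && !is(object@mat, "FiducialMatSpec"))
    return("mat must be NULL or a FiducialMatSpec")
  TRUE
})

#' Thin-lens defocus model
#'
#' Defocus blur grows linearly with distance from the focal plane: a point
#' at camera depth z is blurred with a Gaussian of sigma =
#' blurGain * |z - focalPlaneMm| pixels (circle-of-confusion proxy). Used
#' by \code{\link{renderFocusStack}} to emulate macro-rail capture.
#'
#' @slot focalPlaneMm camera-frame depth of the focal plane in mm.
#' @slot blurGain blur in px per mm of defocus (>= 0).
#' @export
setClass("DefocusModel", representation(
  focalPlaneMm = "numeric",
  blurGain = "numeric"
))

setValidity("DefocusModel", function(object) {
  if (object@blurGain < 0) return("blurGain must be non-negative")
  TRUE
})
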