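## Camera model and turntable kinematics.

#' Construct camera intrinsics
#'
#' @param focalPx focal length in pixels.
#' @param imageSize (width, height) in pixels.
#' @param principalPoint (x, y) in pixels; defaults to the image centre.
#' @return a \linkS4class{CameraIntrinsics}.
#' @examples
#' intr <- cameraIntrinsics(800, c(640, 480))
#' @export
cameraIntrinsics <- function(focalPx, imageSize,
                             principalPoint = imageSize / 2) {
  new("CameraIntrinsics", focalPx = as.numeric(focalPx),
      principalPoint = as.numeric(principalPoint),
      imageSize = as.integer(imageSize))
}

#' Construct a rigid pose
#'
#' @param rotation 3x3 rotation matrix (world to camera).
#' @param translation length-3 translation in mm.
#' @return a \linkS4class{RigidPose}.
#' @export
rigidPose <- function(rotation, translation) {
  new("RigidPose", rotation = rotation, translation = as.numeric(translation))
}

#' Construct a calibrated camera view
#'
#' @param intrinsics a \linkS4class{CameraIntrinsics}.
#' @param pose a \linkS4class{RigidPose}.
#' @param viewId integer view id.
#' @return a \linkS4class{CameraView}.
#' @export
cameraView <- function(intrinsics, pose, viewId = 1L) {
  new("CameraView", intrinsics = intrinsics, pose = pose,
      viewId = as.integer(viewId))
}

#' Construct a turntable state
#'
#' @param panDeg pan angle in degrees, [0, 360).
#' @param tiltDeg tilt angle in degrees, [-90, 90].
#' @param cameraDistanceMm camera-to-origin distance in mm.
#' @return a \linkS4class{TurntableState}.
#' @export
turntableState <- function(panDeg, tiltDeg = 0, cameraDistanceMm = 200) {
  new("TurntableState", panDeg = as.numeric(panDeg %% 360),
      tiltDeg = as.numeric(tiltDeg),
      cameraDistanceMm = as.numeric(cameraDistanceMm))
}

## elementary rotations (radians), world axes
rotZ <- function(a) {
  c <- cos(a); s <- sin(a)
  matrix(c(c, s, 0, -s, c, 0, 0, 0, 1), 3, 3)
}
rotX <- function(a) {
  c <- cos(a); s <- sin(a)
  matrix(c(1, 0, 0, 0, c, s, 0, -s, c), 3, 3)
}

## Fixed rig camera: centre at (0, -d, 0) looking along +Y at the origin,
## camera up = world +Z. Rows of R are the camera axes (x right, y down,
## z forward) expressed in world coordinates.
fixedRigPose <- function(cameraDistanceMm) {
  R <- rbind(c(1, 0, 0),
             c(0, 0, -1),
             c(0, 1, 0))
  rigidPose(R, c(0, 0, cameraDistanceMm))
}

## Specimen rotation for a turntable state: the turntable pans the specimen
## about the world +Z (pin) axis, then the whole table tilts about the
## world +X axis.
specimenRotation <- function(panDeg, tiltDeg) {
  rotX(tiltDeg * pi / 180) %*% rotZ(panDeg * pi / 180)
}

#' Camera pose from turntable angles
#'
#' Converts a turntable state into the equivalent camera pose in specimen
#' coordinates. Rotating the specimen by (pan, tilt) under a fixed camera is
#' the same as composing the specimen rotation with the fixed rig pose:
#' if the specimen rotation is S, a specimen point p appears at S p in rig
#' coordinates, so the world-to-camera map becomes
#' R = R_rig S, t = t_rig. Over a full pan sweep at fixed tilt the camera
#' centres therefore lie on a circle of radius equal to the camera distance.
#'
#' @param state a \linkS4class{TurntableState}.
#' @param viewId optional view id for the returned pose's bookkeeping.
#' @return a \linkS4class{RigidPose}.
#' @examples
#' p0 <- poseFromTurntable(turntableState(0, 0, 200))
#' @export
poseFromTurntable <- function(state, viewId = 1L) {
  stopifnot(is(state, "TurntableState"))
  fixed <- fixedRigPose(state@cameraDistanceMm)
  S <- specimenRotation(state@panDeg, state@tiltDeg)
  rigidPose(fixed@rotation %*% S, fixed@translation)
}

#' Camera centre in world coordinates
#'
#' @param pose a \linkS4class{RigidPose}.
#' @return length-3 camera centre, -R't.
#' @export
cameraCentre <- function(pose) {
  as.numeric(-crossprod(pose@rotation, pose@translation))
}

#' Project 3D points into a view
#'
#' Standard pinhole projection. Points with camera-frame depth <= 0 are
#' flagged as behind the camera and get NA pixel coordinates.
#'
#' @param p n x 3 matrix (or length-3 vector) of world points in mm.
#' @param view a \linkS4class{CameraView}, or a list with elements
#'   \code{intrinsics} and \code{pose}.
#' @return data.frame with columns x, y (pixels), depth (mm) and behind
#'   (logical).
#' @export
projectPoints <- function(p, view) {
  if (is.null(dim(p))) p <- matrix(p, ncol = 3)
  intr <- if (is(view, "CameraView")) view@intrinsics else view$intrinsics
  pose <- if (is(view, "CameraView")) view@pose else view$pose
  pc <- p %*% t(pose@rotation)
  pc <- sweep(pc, 2, pose@translation, "+")
  z <- pc[, 3]
  behind <- z <= 0
  x <- intr@focalPx * pc[, 1] / z + intr@principalPoint[1]
  y <- intr@focalPx * pc[, 2] / z + intr@principalPoint[2]
  x[behind] <- NA_real_
  y[behind] <- NA_real_
  data.frame(x = x, y = y, depth = z, behind = behind)
}

#' Write / read a plain-text pose table
#'
#' Interchange format: one row per view, the 3x4 [R | t] matrix row-major,
#' tab-separated, preceded by the view id.
#'
#' @param views list of \linkS4class{CameraView}.
#' @param path file path.
#' @return \code{writePoseTable} returns \code{path} invisibly;
#'   \code{readPoseTable} returns a data.frame with viewId and the 12
#'   matrix entries r11..r33, t1..t3.
#' @export
writePoseTable <- function(views, path) {
  rows <- vapply(views, function(v) {
    M <- cbind(v@pose@rotation, v@pose@translation)
    paste(c(v@viewId, sprintf("%.12g", t(M))), collapse = "\t")
  }, character(1))
  hdr <- paste(c("view", "r11", "r12", "r13", "t1", "r21", "r22", "r23",
                 "t2", "r31", "r32", "r33", "t3"), collapse = "\t")
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' @rdname writePoseTable
#' @export
readPoseTable <- function(path) {
  utils::read.delim(path, check.names = FALSE)
}

#' Rebuild camera views from a pose table
#'
#' @param tab data.frame from \code{\link{readPoseTable}}.
#' @param intrinsics shared \linkS4class{CameraIntrinsics}.
#' @return list of \linkS4class{CameraView}.
#' @export
posesFromTable <- function(tab, intrinsics) {
  lapply(seq_len(nrow(tab)), function(i) {
    r <- as.numeric(tab[i, -1])
    M <- matrix(r, 3, 4, byrow = TRUE)
    cameraView(intrinsics, rigidPose(M[, 1:3], M[, 4]),
               viewId = tab$view[i])
  })
}

setMethod("show", "RigidPose", function(object) {
  C <- cameraCentre(object)
  cat("RigidPose: camera centre (", paste(sprintf("%.3f", C), collapse = ", "),
      ") mm\n", sep = "")
})

setMethod("show", "CameraView", function(object) {
  cat("CameraView", object@viewId, "|",
      paste(object@intrinsics@imageSize, collapse = "x"), "px, f =",
      object@intrinsics@focalPx, "px\n")
})
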