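## Fiducial mat: a documented, printable substitute for proprietary
## calibration mats. markerCount black discs sit evenly on a ring; each
## disc is punched with a distinctive number of small white holes. Hole
## count is preserved by any projective view of the plane, so marker ids
## decode without pose knowledge; the disc centroids then feed planar pose
## estimation (homography + nonlinear refinement).

#' Construct a fiducial mat specification
#'
#' @param ringDiameterMm diameter of the marker-centre ring in mm.
#' @param markerCount number of markers (4..18).
#' @param markerDiameterMm marker disc diameter in mm.
#' @param idCoding integer holes-per-marker codes; defaults to 1..markerCount.
#' @return a \linkS4class{FiducialMatSpec}.
#' @examples
#' spec <- fiducialMatSpec(50, 12, 8)
#' @export
fiducialMatSpec <- function(ringDiameterMm = 50, markerCount = 12L,
                            markerDiameterMm = 8,
                            idCoding = seq_len(markerCount)) {
  new("FiducialMatSpec", ringDiameterMm = as.numeric(ringDiameterMm),
      markerCount = as.integer(markerCount),
      markerDiameterMm = as.numeric(markerDiameterMm),
      idCoding = as.integer(idCoding))
}

#' Marker centres on the mat plane
#'
#' @param spec a \linkS4class{FiducialMatSpec}.
#' @param matZ height of the mat plane in mm (specimen frame).
#' @return markerCount x 3 matrix of marker centres in mm.
#' @export
matMarkerPositions <- function(spec, matZ = 0) {
  ang <- 2 * pi * (seq_len(spec@markerCount) - 1) / spec@markerCount
  r <- spec@ringDiameterMm / 2
  cbind(r * cos(ang), r * sin(ang), matZ)
}

## hole centres relative to a marker centre, in the marker's local frame
## (rotated with the marker's ring angle; orientation is irrelevant for
## count decoding). Up to 12 holes on an outer ring, 6 more on an inner one.
matHoleOffsets <- function(nHoles, markerDiameterMm) {
  d <- markerDiameterMm
  nOuter <- min(nHoles, 12L)
  ang <- 2 * pi * (seq_len(nOuter) - 1) / 12
  off <- cbind(0.30 * d * cos(ang), 0.30 * d * sin(ang))
  if (nHoles > 12L) {
    nInner <- nHoles - 12L
    ang2 <- 2 * pi * (seq_len(nInner) - 1) / 6 + pi / 6
    off <- rbind(off, cbind(0.14 * d * cos(ang2), 0.14 * d * sin(ang2)))
  }
  off
}

#' Evaluate the printed mat pattern
#'
#' Returns the ink value of the mat at planar coordinates (x, y) mm on the
#' mat plane: 0 inside a marker disc (outside its holes), 1 on the white
#' mat, NA outside the mat's outer radius.
#'
#' @param spec a \linkS4class{FiducialMatSpec}.
#' @param x,y numeric vectors of planar mm coordinates.
#' @return numeric vector of 0 / 1 / NA.
#' @export
matPattern <- function(spec, x, y) {
  val <- rep(1, length(x))
  matR <- spec@ringDiameterMm / 2 + spec@markerDiameterMm
  val[x^2 + y^2 > matR^2] <- NA_real_
  ctr <- matMarkerPositions(spec)
  rr <- spec@markerDiameterMm / 2
  holeR <- 0.055 * spec@markerDiameterMm
  for (k in seq_len(spec@markerCount)) {
    dx <- x - ctr[k, 1]; dy <- y - ctr[k, 2]
    inDisc <- !is.na(val) & (dx^2 + dy^2 <= rr^2)
    if (!any(inDisc)) next
    val[inDisc] <- 0
    ang <- atan2(ctr[k, 2], ctr[k, 1])
    cs <- cos(ang); sn <- sin(ang)
    off <- matHoleOffsets(spec@idCoding[k], spec@markerDiameterMm)
    for (j in seq_len(nrow(off))) {
      hx <- ctr[k, 1] + cs * off[j, 1] - sn * off[j, 2]
      hy <- ctr[k, 2] + sn * off[j, 1] + cs * off[j, 2]
      inHole <- inDisc & ((x - hx)^2 + (y - hy)^2 <= holeR^2)
      val[inHole] <- 1
    }
  }
  val
}

## matrix <-> EBImage helpers (EBImage stores images [x, y])
toEB <- function(m) EBImage::Image(t(m))
fromEB <- function(img) t(EBImage::imageData(img))

#' Detect fiducial markers in an image
#'
#' Thresholds dark ink, labels connected components, fills their holes and
#' decodes each candidate disc's identity from its hole count. Centroids
#' are sub-pixel means over the filled disc.
#'
#' @param image [row, col, 3] raster in [0, 1] (or a greyscale matrix).
#' @param spec the \linkS4class{FiducialMatSpec} the mat was printed from.
#' @param threshold luminance below which a pixel counts as ink.
#' @param minAreaPx minimum disc area in pixels.
#' @return data.frame with columns id, x, y (pixel centroid), holes, areaPx.
#'   Errors with "insufficient markers" when fewer than 4 decode.
#' @export
detectFiducialMarkers <- function(image, spec, threshold = 0.25,
                                  minAreaPx = 30L) {
  lum <- if (length(dim(image)) == 3L) luminance(image) else image
  dark <- (lum < threshold) * 1
  if (!any(dark == 1)) stop("insufficient markers: no ink-coloured pixels")
  filled <- fromEB(EBImage::fillHull(toEB(dark)))
  labF <- fromEB(EBImage::bwlabel(toEB(filled)))
  holes <- (filled == 1) & (dark == 0)
  labH <- fromEB(EBImage::bwlabel(toEB(holes * 1)))
  nH <- max(labH)
  holeOwner <- integer(0)
  if (nH > 0) {
    holeSize <- tabulate(labH[labH > 0], nH)
    ## owner blob of each hole = filled-component label at its pixels
    idx <- which(labH > 0)
    holeOwner <- vapply(seq_len(nH), function(h) {
      px <- idx[labH[idx] == h]
      as.integer(labF[px[1]])
    }, integer(1))
    holeOwner <- holeOwner[holeSize >= 2]
  }
  nB <- max(labF)
  out <- NULL
  for (b in seq_len(nB)) {
    px <- which(labF == b, arr.ind = TRUE)
    if (nrow(px) < minAreaPx) next
    nh <- sum(holeOwner == b)
    id <- match(nh, spec@idCoding)
    if (is.na(id)) next
    out <- rbind(out, data.frame(id = id,
                                 x = mean(px[, 2]) - 0.5,
                                 y = mean(px[, 1]) - 0.5,
                                 holes = nh, areaPx = nrow(px)))
  }
  if (is.null(out) || nrow(out) < 4L)
    stop(sprintf("insufficient markers: %d decoded, need at least 4",
                 if (is.null(out)) 0L else nrow(out)))
  out[order(out$id), , drop = FALSE]
}

## --- planar pose estimation -------------------------------------------

skewMat <- function(w) {
  matrix(c(0, w[3], -w[2], -w[3], 0, w[1], w[2], -w[1], 0), 3, 3)
}

## Rodrigues axis-angle -> rotation matrix
rodrigues <- function(w) {
  th <- sqrt(sum(w^2))
  if (th < 1e-12) return(diag(3) + skewMat(w))
  K <- skewMat(w / th)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

## rotation matrix -> axis-angle
rodriguesInv <- function(R) {
  cth <- (sum(diag(R)) - 1) / 2
  cth <- min(1, max(-1, cth))
  th <- acos(cth)
  if (th < 1e-12) return(c(0, 0, 0))
  if (abs(pi - th) < 1e-6) {
    ## near-pi: extract axis from R + I
    A <- (R + diag(3)) / 2
    axis <- sqrt(pmax(diag(A), 0))
    i <- which.max(axis)
    axis <- A[, i] / axis[i]
    return(th * axis / sqrt(sum(axis^2)))
  }
  v <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2])
  th / (2 * sin(th)) * v
}

kMatrix <- function(intr) {
  matrix(c(intr@focalPx, 0, 0,
           0, intr@focalPx, 0,
           intr@principalPoint[1], intr@principalPoint[2], 1), 3, 3)
}

## normalized DLT homography from planar (X, Y) -> (u, v)
homographyDLT <- function(XY, uv) {
  normalise <- function(P) {
    mu <- colMeans(P)
    d <- sqrt(rowSums(sweep(P, 2, mu)^2))
    s <- sqrt(2) / mean(d)
    T <- diag(c(s, s, 1)); T[1:2, 3] <- -s * mu
    list(T = T, P = sweep(P, 2, mu) * s)
  }
  na <- normalise(XY); nb <- normalise(uv)
  n <- nrow(XY)
  A <- matrix(0, 2 * n, 9)
  for (i in seq_len(n)) {
    X <- c(na$P[i, ], 1); u <- nb$P[i, 1]; v <- nb$P[i, 2]
    A[2 * i - 1, ] <- c(-X, 0, 0, 0, u * X)
    A[2 * i, ] <- c(0, 0, 0, -X, v * X)
  }
  h <- svd(A, nu = 0)$v[, 9]
  H <- matrix(h, 3, 3, byrow = TRUE)
  solve(nb$T) %*% H %*% na$T
}

reprojResidual <- function(par, XY3, uv, K) {
  R <- rodrigues(par[1:3])
  t <- par[4:6]
  pc <- XY3 %*% t(R)
  pc <- sweep(pc, 2, t, "+")
  u <- K[1, 1] * pc[, 1] / pc[, 3] + K[1, 3]
  v <- K[2, 2] * pc[, 2] / pc[, 3] + K[2, 3]
  c(u - uv[, 1], v - uv[, 2])
}

#' Estimate the camera pose from detected mat markers
#'
#' Planar pose estimation: a direct linear homography estimate between the
#' known marker centres on the mat plane and their detected image
#' centroids, decomposed into rotation and translation, then refined by
#' nonlinear least squares on the reprojection error (cost-change
#' tolerance 1e-10, at most 100 iterations).
#'
#' @param markers data.frame from \code{\link{detectFiducialMarkers}}
#'   (columns id, x, y); at least 4 markers.
#' @param spec the \linkS4class{FiducialMatSpec}.
#' @param intrinsics a \linkS4class{CameraIntrinsics}.
#' @param matZ height of the mat plane in the specimen frame, mm.
#' @return list with elements \code{pose} (\linkS4class{RigidPose}) and
#'   \code{rmsPx} (reprojection RMS in pixels). Errors with "degenerate
#'   configuration" when the image points are collinear.
#' @export
estimatePoseFromMat <- function(markers, spec, intrinsics, matZ = 0) {
  if (nrow(markers) < 4L) stop("need at least 4 markers")
  uv <- cbind(markers$x, markers$y)
  sv <- svd(sweep(uv, 2, colMeans(uv)))$d
  if (sv[2] < 1e-6 * max(sv[1], 1))
    stop("degenerate configuration: markers are collinear in the image")
  XYZ <- matMarkerPositions(spec, matZ)[markers$id, , drop = FALSE]
  K <- kMatrix(intrinsics)
  H <- homographyDLT(XYZ[, 1:2, drop = FALSE], uv)
  M <- solve(K) %*% H
  lam <- 2 / (sqrt(sum(M[, 1]^2)) + sqrt(sum(M[, 2]^2)))
  ## points must land in front of the camera
  if ((lam * (M[3, 1] * XYZ[1, 1] + M[3, 2] * XYZ[1, 2] + M[3, 3])) < 0)
    lam <- -lam
  r1 <- lam * M[, 1]; r2 <- lam * M[, 2]
  Rapprox <- cbind(r1, r2, pracmaCross(r1, r2))
  sv2 <- svd(Rapprox)
  R0 <- sv2$u %*% t(sv2$v)
  if (det(R0) < 0) R0 <- sv2$u %*% diag(c(1, 1, -1)) %*% t(sv2$v)
  t0 <- lam * M[, 3]
  ## the homography only constrains the plane z = 0; fold matZ into t
  XY3 <- cbind(XYZ[, 1:2], 0)
  par0 <- c(rodriguesInv(R0), t0)
  fit <- minpack.lm::nls.lm(par0, fn = reprojResidual, XY3 = XY3, uv = uv,
                            K = K,
                            control = minpack.lm::nls.lm.control(
                              ftol = 1e-10, maxiter = 100))
  par <- fit$par
  R <- rodrigues(par[1:3])
  t <- par[4:6] - as.numeric(R %*% c(0, 0, matZ))
  res <- reprojResidual(par, XY3, uv, K)
  rigid <- rigidPose(R, t)
  list(pose = rigid, rmsPx = sqrt(mean(res^2)))
}

pracmaCross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

viewRms <- function(view, markers, spec, matZ = 0) {
  XYZ <- matMarkerPositions(spec, matZ)[markers$id, , drop = FALSE]
  pr <- projectPoints(XYZ, view)
  sqrt(mean((pr$x - markers$x)^2 + (pr$y - markers$y)^2))
}

#' Jointly refine camera poses against fiducial reprojection
#'
#' Re-optimizes every view's pose (intrinsics shared and fixed) to minimize
#' the total marker reprojection error. Because the mat geometry is known
#' and intrinsics are fixed, the objective decouples per view; each view's
#' pose is accepted only when its reprojection RMS does not increase, so
#' the total RMS is non-increasing by construction. With fewer than two
#' views there is nothing to refine jointly and the input is returned
#' unchanged.
#'
#' @param views list of \linkS4class{CameraView}.
#' @param markersList list of per-view marker data.frames (same order).
#' @param spec the \linkS4class{FiducialMatSpec}.
#' @param matZ mat plane height, mm.
#' @return list with \code{views} (updated list), \code{rmsBefore},
#'   \code{rmsAfter} (total RMS in px).
#' @export
refinePoses <- function(views, markersList, spec, matZ = 0) {
  before <- vapply(seq_along(views), function(i)
    viewRms(views[[i]], markersList[[i]], spec, matZ), numeric(1))
  if (length(views) < 2L)
    return(list(views = views, rmsBefore = mean(before),
                rmsAfter = mean(before)))
  out <- views
  after <- before
  for (i in seq_along(views)) {
    mk <- markersList[[i]]
    intr <- views[[i]]@intrinsics
    est <- tryCatch(
      estimatePoseFromMat(mk, spec, intr, matZ),
      error = function(e) NULL)
    if (is.null(est)) {
      warning(sprintf("view %d: refinement failed, keeping input pose",
                      views[[i]]@viewId))
      next
    }
    cand <- cameraView(intr, est$pose, views[[i]]@viewId)
    r <- viewRms(cand, mk, spec, matZ)
    if (r <= before[i]) {
      out[[i]] <- cand
      after[i] <- r
    }
  }
  list(views = out, rmsBefore = sqrt(mean(before^2)),
       rmsAfter = sqrt(mean(after^2)))
}
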