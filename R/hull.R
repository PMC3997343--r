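## Shape-from-silhouette reconstruction. Every calibrated silhouette
## back-projects to a cone containing the specimen; the visual hull is the
## intersection of those cones and is always a superset of the true
## surface. Here the hull is realized on a voxel grid: a voxel survives
## carving iff, in every view, at least one of its sample points projects
## inside the (conservatively dilated) silhouette. Voxels a view cannot
## see (projection outside the image, or behind the camera) are never
## carved by that view - the physical mat occludes the specimen underside,
## so absence of evidence must not remove volume.

#' Construct a voxel grid
#'
#' @param bbox 2 x 3 matrix (rows lo, hi) in mm, or a single half-extent
#'   \code{c} meaning the cube [-c, c]^3.
#' @param resolution integer length-3 (or scalar for a cube) voxel counts.
#' @param occupied initial occupancy (default all occupied, ready to carve).
#' @return a \linkS4class{VoxelGrid}.
#' @export
voxelGrid <- function(bbox, resolution, occupied = TRUE) {
  if (length(bbox) == 1L) bbox <- rbind(rep(-bbox, 3), rep(bbox, 3))
  if (length(resolution) == 1L) resolution <- rep(resolution, 3)
  resolution <- as.integer(resolution)
  new("VoxelGrid", bbox = bbox, resolution = resolution,
      occupancy = array(occupied, resolution))
}

#' Voxel pitch of a grid
#'
#' @param grid a \linkS4class{VoxelGrid}.
#' @return length-3 voxel edge lengths in mm.
#' @export
voxelPitch <- function(grid) {
  (grid@bbox[2, ] - grid@bbox[1, ]) / grid@resolution
}

#' Occupied volume of a grid
#'
#' @param grid a \linkS4class{VoxelGrid}.
#' @return occupied-voxel volume in mm^3.
#' @export
voxelVolume <- function(grid) {
  sum(grid@occupancy) * prod(voxelPitch(grid))
}

#' Occupancy accessor
#'
#' @param grid a \linkS4class{VoxelGrid}.
#' @return the logical occupancy array.
#' @export
occupancy <- function(grid) grid@occupancy

## voxel-centre coordinates (n x 3), column-major voxel order
voxelCentres <- function(grid) {
  h <- voxelPitch(grid)
  lo <- grid@bbox[1, ]
  r <- grid@resolution
  xs <- lo[1] + (seq_len(r[1]) - 0.5) * h[1]
  ys <- lo[2] + (seq_len(r[2]) - 0.5) * h[2]
  zs <- lo[3] + (seq_len(r[3]) - 0.5) * h[3]
  cbind(rep(xs, times = r[2] * r[3]),
        rep(rep(ys, each = r[1]), times = r[3]),
        rep(zs, each = r[1] * r[2]))
}

dilateMask <- function(mask, dilatePx) {
  if (dilatePx <= 0) return(mask@mask)
  brush <- EBImage::makeBrush(2L * as.integer(dilatePx) + 1L, "box")
  fromEB(EBImage::dilate(toEB(mask@mask), brush))
}

sampleOffsets <- function(samplesPerVoxel, h) {
  if (samplesPerVoxel == 1L) return(matrix(0, 1, 3))
  if (samplesPerVoxel == 8L) {
    s <- expand.grid(x = c(-0.5, 0.5), y = c(-0.5, 0.5), z = c(-0.5, 0.5))
    return(sweep(as.matrix(s), 2, h, "*"))
  }
  stop("samplesPerVoxel must be 1 (voxel centre) or 8 (corners)")
}

## TRUE where the sample points survive one view's silhouette: inside the
## dilated mask, outside the image bounds, or behind the camera.
pointsInsideView <- function(pts, view, maskM) {
  pc <- pts %*% t(view@pose@rotation)
  pc1 <- pc[, 1] + view@pose@translation[1]
  pc2 <- pc[, 2] + view@pose@translation[2]
  pc3 <- pc[, 3] + view@pose@translation[3]
  intr <- view@intrinsics
  inside <- rep(TRUE, nrow(pts))
  vis <- pc3 > 0
  if (any(vis)) {
    x <- intr@focalPx * pc1[vis] / pc3[vis] + intr@principalPoint[1]
    y <- intr@focalPx * pc2[vis] / pc3[vis] + intr@principalPoint[2]
    col <- floor(x) + 1
    row <- floor(y) + 1
    h <- nrow(maskM); w <- ncol(maskM)
    inb <- col >= 1 & col <= w & row >= 1 & row <= h
    insideVis <- rep(TRUE, sum(vis))
    if (any(inb))
      insideVis[inb] <- maskM[cbind(row[inb], col[inb])] == 1
    inside[vis] <- insideVis
  }
  inside
}

#' Carve a voxel grid by silhouettes
#'
#' Dense visual-hull carving: each view's silhouette is dilated by
#' \code{dilatePx} (a conservative bias - an over-large silhouette only
#' inflates the hull, never truncates the specimen) and every occupied
#' voxel is tested against every view.
#'
#' @param masks list of \linkS4class{SilhouetteMask}, one per view.
#' @param views list of \linkS4class{CameraView}, same order.
#' @param grid a \linkS4class{VoxelGrid} (its occupancy is the starting
#'   volume; the default constructor starts fully occupied).
#' @param samplesPerVoxel 1 (voxel centre) or 8 (voxel corners; a voxel
#'   survives a view when any sample does).
#' @param dilatePx silhouette dilation radius in px.
#' @return the carved \linkS4class{VoxelGrid}. Errors with "no views";
#'   warns "empty hull" when every voxel is carved.
#' @export
carve <- function(masks, views, grid, samplesPerVoxel = 1L, dilatePx = 1L) {
  if (length(views) == 0L) stop("no views")
  if (length(masks) != length(views))
    stop("need one mask per view")
  h <- voxelPitch(grid)
  offs <- sampleOffsets(as.integer(samplesPerVoxel), h)
  centres <- voxelCentres(grid)
  occ <- as.logical(grid@occupancy)
  for (v in seq_along(views)) {
    active <- which(occ)
    if (!length(active)) break
    maskM <- dilateMask(masks[[v]], dilatePx)
    keep <- rep(FALSE, length(active))
    for (s in seq_len(nrow(offs))) {
      todo <- which(!keep)
      if (!length(todo)) break
      pts <- sweep(centres[active[todo], , drop = FALSE], 2, offs[s, ], "+")
      keep[todo] <- pointsInsideView(pts, views[[v]], maskM)
    }
    occ[active[!keep]] <- FALSE
  }
  if (!any(occ)) warning("empty hull: all voxels carved")
  new("VoxelGrid", bbox = grid@bbox, resolution = grid@resolution,
      occupancy = array(occ, grid@resolution))
}

#' Carve with octree acceleration
#'
#' Hierarchical carving with the same contract as \code{\link{carve}}:
#' occupancy is bit-identical to dense carving at resolution
#' \code{2^maxDepth} cubed. Nodes whose projected bounding rectangle
#' contains no silhouette pixel in some view (and lies fully inside that
#' image) are pruned empty without descending; nodes whose rectangle is
#' fully silhouette in every view are pruned occupied. Both tests are
#' conservative, so pruning never changes a leaf decision.
#'
#' @param masks,views as in \code{\link{carve}}.
#' @param bbox grid bounding box (2 x 3 mm matrix, or scalar half-extent).
#' @param maxDepth octree depth >= 1; resolution is 2^maxDepth per axis.
#' @param samplesPerVoxel,dilatePx as in \code{\link{carve}}.
#' @return the carved \linkS4class{VoxelGrid}.
#' @export
carveOctree <- function(masks, views, bbox, maxDepth, samplesPerVoxel = 1L,
                        dilatePx = 1L) {
  if (length(views) == 0L) stop("no views")
  maxDepth <- as.integer(maxDepth)
  if (maxDepth < 1L) stop("maxDepth must be >= 1")
  n <- 2L^maxDepth
  grid <- voxelGrid(bbox, n)
  h <- voxelPitch(grid)
  lo <- grid@bbox[1, ]
  offs <- sampleOffsets(as.integer(samplesPerVoxel), h)
  maskMs <- lapply(masks, dilateMask, dilatePx = dilatePx)
  ## integral images (I[r+1, c+1] = sum of mask[1..r, 1..c])
  ints <- lapply(maskMs, function(m) {
    I <- matrix(0, nrow(m) + 1L, ncol(m) + 1L)
    I[-1, -1] <- t(apply(apply(m, 2, cumsum), 1, cumsum))
    I
  })
  rectSum <- function(I, r0, r1, c0, c1)
    I[r1 + 1, c1 + 1] - I[r0, c1 + 1] - I[r1 + 1, c0] + I[r0, c0]
  occ <- array(FALSE, dim = c(n, n, n))

  leafTest <- function(i, j, k) {
    ctr <- lo + (c(i, j, k) - 0.5) * h
    for (v in seq_along(views)) {
      insideAny <- FALSE
      for (s in seq_len(nrow(offs))) {
        if (pointsInsideView(matrix(ctr + offs[s, ], 1, 3), views[[v]],
                             maskMs[[v]])) { insideAny <- TRUE; break }
      }
      if (!insideAny) return(FALSE)
    }
    TRUE
  }

  ## classify a node spanning voxels i0..i1 etc.: "empty", "full", "mixed"
  classifyNode <- function(i0, i1, j0, j1, k0, k1) {
    boxLo <- lo + c(i0 - 1, j0 - 1, k0 - 1) * h
    boxHi <- lo + c(i1, j1, k1) * h
    corners <- as.matrix(expand.grid(x = c(boxLo[1], boxHi[1]),
                                     y = c(boxLo[2], boxHi[2]),
                                     z = c(boxLo[3], boxHi[3])))
    allFull <- TRUE
    for (v in seq_along(views)) {
      pose <- views[[v]]@pose
      intr <- views[[v]]@intrinsics
      pc <- corners %*% t(pose@rotation)
      pc <- sweep(pc, 2, pose@translation, "+")
      if (any(pc[, 3] <= 0)) { allFull <- FALSE; next }
      x <- intr@focalPx * pc[, 1] / pc[, 3] + intr@principalPoint[1]
      y <- intr@focalPx * pc[, 2] / pc[, 3] + intr@principalPoint[2]
      ## the box projects inside the convex hull of its corner projections,
      ## hence inside this pixel rectangle
      c0 <- floor(min(x)) + 1; c1 <- floor(max(x)) + 1
      r0 <- floor(min(y)) + 1; r1 <- floor(max(y)) + 1
      m <- maskMs[[v]]
      hh <- nrow(m); ww <- ncol(m)
      cc0 <- max(c0, 1L); cc1 <- min(c1, ww)
      rr0 <- max(r0, 1L); rr1 <- min(r1, hh)
      if (cc0 > cc1 || rr0 > rr1) next  # fully outside image: uncarvable
      s <- rectSum(ints[[v]], rr0, rr1, cc0, cc1)
      inImage <- (c0 >= 1 && c1 <= ww && r0 >= 1 && r1 <= hh)
      if (inImage && s == 0) return("empty")
      if (s < (rr1 - rr0 + 1) * (cc1 - cc0 + 1)) allFull <- FALSE
    }
    if (allFull) "full" else "mixed"
  }

  recurse <- function(i0, i1, j0, j1, k0, k1) {
    cls <- classifyNode(i0, i1, j0, j1, k0, k1)
    if (cls == "empty") return(invisible())
    if (cls == "full") {
      occ[i0:i1, j0:j1, k0:k1] <<- TRUE
      return(invisible())
    }
    if (i0 == i1 && j0 == j1 && k0 == k1) {
      occ[i0, j0, k0] <<- leafTest(i0, j0, k0)
      return(invisible())
    }
    im <- (i0 + i1 - 1L) %/% 2L; jm <- (j0 + j1 - 1L) %/% 2L
    km <- (k0 + k1 - 1L) %/% 2L
    for (ii in list(c(i0, im), c(im + 1L, i1)))
      for (jj in list(c(j0, jm), c(jm + 1L, j1)))
        for (kk in list(c(k0, km), c(km + 1L, k1)))
          recurse(ii[1], ii[2], jj[1], jj[2], kk[1], kk[2])
    invisible()
  }
  recurse(1L, n, 1L, n, 1L, n)
  if (!any(occ)) warning("empty hull: all voxels carved")
  new("VoxelGrid", bbox = grid@bbox, resolution = grid@resolution,
      occupancy = occ)
}
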