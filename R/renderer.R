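## Synthetic capture rig. Scenes are unions of quadric/box primitives
## (insect body parts, mounting pin) over an optional fiducial mat, ray
## cast with exact analytic intersections, so silhouettes, depth maps and
## volumes come with ground truth. This replaces the physical camera,
## turntable and macro rail during development and testing.

#' Describe a scene primitive
#'
#' @param shape "sphere", "ellipsoid", "cylinder" or "box".
#' @param centre length-3 centre in mm.
#' @param size shape size in mm: sphere radius; ellipsoid semi-axes
#'   (a, b, c); cylinder (radius, halfLength) with the axis along local z;
#'   box half-extents (a, b, c).
#' @param colour RGB in [0, 1].
#' @param rotation 3x3 local-to-world rotation.
#' @param colour2 optional second RGB colour; when given, the primitive is
#'   two-toned, coloured \code{colour} where the local-frame hit point has
#'   positive component along \code{splitAxis} and \code{colour2} elsewhere.
#' @param splitAxis local-frame axis for the two-tone split.
#' @return a primitive description list for \code{\link{syntheticScene}}.
#' @export
scenePrimitive <- function(shape, centre, size, colour = c(0.8, 0.2, 0.2),
                           rotation = diag(3), colour2 = NULL,
                           splitAxis = c(0, 0, 1)) {
  list(shape = shape, centre = as.numeric(centre), size = as.numeric(size),
       colour = as.numeric(colour), rotation = rotation,
       colour2 = if (is.null(colour2)) NULL else as.numeric(colour2),
       splitAxis = as.numeric(splitAxis))
}

#' Construct a synthetic scene
#'
#' @param primitives list of \code{\link{scenePrimitive}} descriptions.
#' @param mat optional \linkS4class{FiducialMatSpec} rendered on the plane
#'   z = matZ.
#' @param matZ mat plane height in mm.
#' @param background RGB background (chroma-key green by default).
#' @return a \linkS4class{SyntheticScene}.
#' @export
syntheticScene <- function(primitives, mat = NULL, matZ = -6,
                           background = c(0, 0.6, 0)) {
  new("SyntheticScene", primitives = primitives, mat = mat,
      matZ = as.numeric(matZ), background = as.numeric(background))
}

#' Construct a defocus model
#'
#' @param focalPlaneMm camera-frame depth of the focal plane, mm.
#' @param blurGain Gaussian blur sigma in px per mm of defocus.
#' @return a \linkS4class{DefocusModel}.
#' @export
defocusModel <- function(focalPlaneMm, blurGain) {
  new("DefocusModel", focalPlaneMm = as.numeric(focalPlaneMm),
      blurGain = as.numeric(blurGain))
}

## ray-primitive intersection, vectorized over rays in the local frame.
## o: n x 3 origins, d: n x 3 directions. Returns parameter t (Inf = miss).
intersectLocal <- function(shape, size, o, d) {
  n <- nrow(o)
  tHit <- rep(Inf, n)
  if (shape %in% c("sphere", "ellipsoid")) {
    ax <- if (shape == "sphere") rep(size[1], 3) else size
    os <- sweep(o, 2, ax, "/"); ds <- sweep(d, 2, ax, "/")
    A <- rowSums(ds^2); B <- 2 * rowSums(os * ds); C <- rowSums(os^2) - 1
    disc <- B^2 - 4 * A * C
    ok <- disc >= 0
    if (any(ok)) {
      sq <- sqrt(disc[ok])
      t1 <- (-B[ok] - sq) / (2 * A[ok])
      t2 <- (-B[ok] + sq) / (2 * A[ok])
      t1[t1 <= 1e-9] <- Inf
      t2[t2 <= 1e-9] <- Inf
      tHit[ok] <- pmin(t1, t2)
    }
  } else if (shape == "cylinder") {
    r <- size[1]; hh <- size[2]
    A <- d[, 1]^2 + d[, 2]^2
    B <- 2 * (o[, 1] * d[, 1] + o[, 2] * d[, 2])
    C <- o[, 1]^2 + o[, 2]^2 - r^2
    disc <- B^2 - 4 * A * C
    ok <- disc >= 0 & A > 1e-18
    if (any(ok)) {
      sq <- sqrt(disc[ok])
      for (sgn in c(-1, 1)) {
        tt <- (-B[ok] + sgn * sq) / (2 * A[ok])
        z <- o[ok, 3] + tt * d[ok, 3]
        tt[tt <= 1e-9 | abs(z) > hh] <- Inf
        tHit[ok] <- pmin(tHit[ok], tt)
      }
    }
    ## caps
    for (zc in c(-hh, hh)) {
      dz <- d[, 3]
      tt <- (zc - o[, 3]) / dz
      x <- o[, 1] + tt * d[, 1]; y <- o[, 2] + tt * d[, 2]
      tt[!is.finite(tt) | tt <= 1e-9 | x^2 + y^2 > r^2] <- Inf
      tHit <- pmin(tHit, tt)
    }
  } else if (shape == "box") {
    tlo <- rep(1e-9, n); thi <- rep(Inf, n)
    for (ax in 1:3) {
      par <- abs(d[, ax]) < 1e-12
      dd <- d[, ax]; dd[par] <- 1  # placeholder, overwritten below
      t1 <- (-size[ax] - o[, ax]) / dd
      t2 <- (size[ax] - o[, ax]) / dd
      lo <- pmin(t1, t2); hi <- pmax(t1, t2)
      inSlab <- abs(o[, ax]) <= size[ax]
      lo[par] <- ifelse(inSlab[par], -Inf, Inf)
      hi[par] <- ifelse(inSlab[par], Inf, -Inf)
      tlo <- pmax(tlo, lo); thi <- pmin(thi, hi)
    }
    hit <- !is.na(tlo) & !is.na(thi) & tlo <= thi
    tHit[hit] <- tlo[hit]
  } else stop(sprintf("unknown primitive shape '%s'", shape))
  tHit
}

#' Render a synthetic scene into a calibrated view
#'
#' Ray casts every pixel centre: exact quadric/box intersections give the
#' colour image, a binary matte of the specimen primitives (the mat plane
#' and background are not matte foreground) and the per-pixel camera
#' depth. Pixels hitting nothing get the background colour and, as a
#' reference depth, the camera-to-origin distance. Rendering is
#' deterministic: identical inputs give bit-identical rasters.
#'
#' @param scene a \linkS4class{SyntheticScene}.
#' @param view a \linkS4class{CameraView}.
#' @return list with \code{image} ([row, col, 3]), \code{matte}
#'   ([row, col] 0/1) and \code{depth} ([row, col] mm).
#' @export
renderView <- function(scene, view) {
  intr <- view@intrinsics
  w <- intr@imageSize[1]; h <- intr@imageSize[2]
  xs <- (seq_len(w) - 0.5 - intr@principalPoint[1]) / intr@focalPx
  ys <- (seq_len(h) - 0.5 - intr@principalPoint[2]) / intr@focalPx
  ## rays in camera frame with z = 1, so the ray parameter equals camera depth
  dc <- cbind(rep(xs, each = h), rep(ys, times = w), 1)
  Rw <- t(view@pose@rotation)
  dirW <- dc %*% t(Rw)
  C <- cameraCentre(view@pose)
  n <- nrow(dirW)
  tBest <- rep(Inf, n)
  prim <- rep(0L, n)
  for (k in seq_along(scene@primitives)) {
    p <- scene@primitives[[k]]
    Rl <- t(p$rotation)
    oL <- matrix(as.numeric((C - p$centre) %*% t(Rl)), n, 3, byrow = TRUE)
    dL <- dirW %*% t(Rl)
    tt <- intersectLocal(p$shape, p$size, oL, dL)
    better <- tt < tBest
    tBest[better] <- tt[better]
    prim[better] <- k
  }
  matte <- as.numeric(prim > 0)
  depth <- tBest
  img <- matrix(rep(scene@background, each = n), n, 3)
  for (k in seq_along(scene@primitives)) {
    sel <- prim == k
    if (!any(sel)) next
    p <- scene@primitives[[k]]
    if (is.null(p$colour2)) {
      img[sel, ] <- matrix(rep(p$colour, each = sum(sel)), ncol = 3)
    } else {
      hit <- sweep(dirW[sel, , drop = FALSE] * tBest[sel], 2, C, "+")
      hitL <- sweep(hit, 2, p$centre) %*% p$rotation
      side <- as.numeric(hitL %*% p$splitAxis) >= 0
      cols <- matrix(0, sum(sel), 3)
      cols[side, ] <- matrix(p$colour, sum(side), 3, byrow = TRUE)
      cols[!side, ] <- matrix(p$colour2, sum(!side), 3, byrow = TRUE)
      img[sel, ] <- cols
    }
  }
  ## fiducial mat on the plane z = matZ, behind the primitives
  if (!is.null(scene@mat)) {
    tPlane <- (scene@matZ - C[3]) / dirW[, 3]
    hitMat <- is.finite(tPlane) & tPlane > 1e-9 & tPlane < tBest
    if (any(hitMat)) {
      hx <- C[1] + dirW[hitMat, 1] * tPlane[hitMat]
      hy <- C[2] + dirW[hitMat, 2] * tPlane[hitMat]
      ink <- matPattern(scene@mat, hx, hy)
      on <- !is.na(ink)
      idx <- which(hitMat)[on]
      img[idx, ] <- rep(ink[on], 3)  # greyscale pattern on all channels
      depth[idx] <- tPlane[hitMat][on]
    }
  }
  bg <- !is.finite(depth)
  depth[bg] <- view@pose@translation[3]
  toMat <- function(v) matrix(v, h, w)
  list(image = array(c(toMat(img[, 1]), toMat(img[, 2]), toMat(img[, 3])),
                     c(h, w, 3)),
       matte = toMat(matte),
       depth = toMat(depth))
}

#' Render a macro-rail focus stack
#'
#' Each frame is the sharp render blurred per pixel with a Gaussian whose
#' sigma is blurGain * |depth - focal plane|. The depth map is quantized
#' into \code{depthBins} bins and one blurred copy is made per bin (a
#' documented approximation: blur error is bounded by the bin width times
#' blurGain). Frame j focuses at camera depth
#' (camera distance + focusPositions[j]).
#'
#' @param scene a \linkS4class{SyntheticScene}.
#' @param view a \linkS4class{CameraView}.
#' @param defocus a \linkS4class{DefocusModel} (its blurGain is used; the
#'   per-frame focal planes come from \code{focusPositionsMm}).
#' @param focusPositionsMm focus offsets along the camera axis, mm,
#'   relative to the specimen origin (>= 2 positions).
#' @param depthBins number of depth quantization bins.
#' @return list with \code{stack} (a \linkS4class{FocusStack}),
#'   \code{sharp} (ground-truth all-in-focus raster) and \code{depth}.
#' @export
renderFocusStack <- function(scene, view, defocus, focusPositionsMm,
                             depthBins = 16L) {
  if (length(focusPositionsMm) < 2L)
    stop("need at least 2 focus positions")
  rv <- renderView(scene, view)
  d0 <- view@pose@translation[3]
  dep <- rv$depth
  rng <- range(dep)
  if (diff(rng) < 1e-12) {
    binOf <- matrix(1L, nrow(dep), ncol(dep))
    binDepth <- mean(rng)
  } else {
    edges <- seq(rng[1], rng[2], length.out = depthBins + 1L)
    binOf <- matrix(findInterval(dep, edges, rightmost.closed = TRUE),
                    nrow(dep), ncol(dep))
    binDepth <- (edges[-1] + edges[-length(edges)]) / 2
  }
  ## the Gaussian brush must fit in the raster; beyond this the blur is
  ## effectively uniform anyway
  sigmaCap <- max((min(dim(rv$depth)) - 3) / 7, 0.5)
  frames <- lapply(focusPositionsMm, function(f) {
    focal <- d0 + f
    out <- rv$image
    for (b in seq_along(binDepth)) {
      sel <- binOf == b
      if (!any(sel)) next
      sigma <- min(defocus@blurGain * abs(binDepth[b] - focal), sigmaCap)
      if (sigma < 0.3) {
        blurred <- rv$image
      } else {
        blurred <- rv$image
        for (ch in 1:3)
          blurred[, , ch] <- fromEB(EBImage::gblur(toEB(rv$image[, , ch]),
                                                   sigma = sigma))
      }
      for (ch in 1:3) {
        o <- out[, , ch]; bl <- blurred[, , ch]
        o[sel] <- bl[sel]
        out[, , ch] <- o
      }
    }
    pmin(pmax(out, 0), 1)
  })
  list(stack = focusStack(frames, d0 + focusPositionsMm),
       sharp = rv$image, depth = rv$depth)
}

#' Analytic volume of a scene
#'
#' Closed-form volumes of the primitives, valid when they do not overlap.
#' Overlap is checked conservatively with world axis-aligned bounding
#' boxes: any AABB intersection raises "overlapping primitives".
#'
#' @param scene a \linkS4class{SyntheticScene}.
#' @param exclude integer indices of primitives to leave out (e.g. the
#'   mounting pin when comparing against a pin-removed model).
#' @return total volume in mm^3.
#' @export
analyticVolume <- function(scene, exclude = integer(0)) {
  prims <- scene@primitives
  keep <- setdiff(seq_along(prims), exclude)
  boxes <- lapply(prims, primitiveAABB)
  if (length(prims) > 1L) {
    for (i in seq_along(prims)[-1]) for (j in seq_len(i - 1L)) {
      a <- boxes[[i]]; b <- boxes[[j]]
      if (all(a$lo <= b$hi) && all(b$lo <= a$hi))
        stop(sprintf("overlapping primitives: %d and %d (bounding boxes)",
                     j, i))
    }
  }
  sum(vapply(prims[keep], function(p) switch(p$shape,
    sphere = 4 / 3 * pi * p$size[1]^3,
    ellipsoid = 4 / 3 * pi * prod(p$size[1:3]),
    cylinder = pi * p$size[1]^2 * 2 * p$size[2],
    box = 8 * prod(p$size[1:3])), numeric(1)))
}

primitiveAABB <- function(p) {
  half <- switch(p$shape,
    sphere = rep(p$size[1], 3),
    ellipsoid = as.numeric(sqrt((p$rotation^2) %*% (p$size[1:3]^2))),
    cylinder = as.numeric(sqrt((p$rotation^2) %*%
                 c(p$size[1], p$size[1], p$size[2])^2)),
    box = as.numeric(abs(p$rotation) %*% p$size[1:3]))
  list(lo = p$centre - half, hi = p$centre + half)
}

#' Bounding radius of a scene
#'
#' @param scene a \linkS4class{SyntheticScene}.
#' @return radius in mm of the smallest origin-centred sphere containing
#'   all primitive bounding boxes.
#' @export
sceneBoundingRadius <- function(scene) {
  max(vapply(scene@primitives, function(p) {
    b <- primitiveAABB(p)
    sqrt(max(rowSums(expand.grid(x = c(b$lo[1], b$hi[1]),
                                 y = c(b$lo[2], b$hi[2]),
                                 z = c(b$lo[3], b$hi[3]))^2)))
  }, numeric(1)))
}

#' Default synthetic weevil scene
#'
#' A 3 mm specimen phantom: ellipsoid body, sphere head, six thin
#' cylinder legs and an optional 0.2 mm mounting pin below the body,
#' sized to the small end of the specimens this pipeline targets. Parts
#' are deliberately separated by small gaps so the analytic volume oracle
#' (which forbids overlapping primitives) applies and so the pin forms its
#' own visual-hull component for component-mode pin removal.
#'
#' @param bodyLengthMm body length in mm.
#' @param pin include the mounting pin primitive.
#' @return a \linkS4class{SyntheticScene}.
#' @export
weevilScene <- function(bodyLengthMm = 3, pin = TRUE) {
  s <- bodyLengthMm / 3
  prims <- list(
    scenePrimitive("ellipsoid", c(-0.3, 0, 0) * s, c(1.2, 0.55, 0.5) * s,
                   colour = c(0.45, 0.25, 0.1)),
    scenePrimitive("sphere", c(1.48, 0, 0) * s, 0.38 * s,
                   colour = c(0.35, 0.2, 0.1)))
  legX <- c(-1.1, -0.45, 0.2)
  for (i in 0:5) {
    side <- if (i %% 2 == 0) 1 else -1
    prims[[length(prims) + 1L]] <- scenePrimitive(
      "cylinder", c(legX[i %/% 2 + 1], side * 0.45, -1.0) * s,
      c(0.1, 0.3) * s, colour = c(0.2, 0.12, 0.06))
  }
  if (pin)
    prims[[length(prims) + 1L]] <- scenePrimitive(
      "cylinder", c(-0.3, 0, 1.2) * s, c(0.1, 0.5) * s,
      colour = c(0.75, 0.75, 0.78))
  syntheticScene(prims)
}
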