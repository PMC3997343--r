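## Texture baking. Each face gets its colour from the single calibrated
## view that sees it most frontally (no multi-view blending; seams are
## visible but every texel is traceable to one photograph). Visibility is
## a depth-buffer test of the face centroid against a rasterization of
## the whole mesh; faces seen by no view are flagged unseen and filled
## with a flag colour.

## Rasterize all faces of a mesh into one view's depth buffer.
## Returns list(zbuf = named min-depth per pixel key, scale, bufW, bufH).
meshDepthBuffer <- function(mesh, view, bufWidth = 256L) {
  intr <- view@intrinsics
  scale <- bufWidth / intr@imageSize[1]
  bufW <- as.integer(ceiling(intr@imageSize[1] * scale))
  bufH <- as.integer(ceiling(intr@imageSize[2] * scale))
  pr <- projectPoints(mesh@vertices, view)
  px <- pr$x * scale; py <- pr$y * scale
  f <- mesh@faces
  ok <- !(pr$behind[f[, 1]] | pr$behind[f[, 2]] | pr$behind[f[, 3]])
  f <- f[ok, , drop = FALSE]
  x1 <- px[f[, 1]]; x2 <- px[f[, 2]]; x3 <- px[f[, 3]]
  y1 <- py[f[, 1]]; y2 <- py[f[, 2]]; y3 <- py[f[, 3]]
  z1 <- pr$depth[f[, 1]]; z2 <- pr$depth[f[, 2]]; z3 <- pr$depth[f[, 3]]
  c0 <- pmax(floor(pmin(x1, x2, x3)), 0)
  c1 <- pmin(floor(pmax(x1, x2, x3)), bufW - 1)
  r0 <- pmax(floor(pmin(y1, y2, y3)), 0)
  r1 <- pmin(floor(pmax(y1, y2, y3)), bufH - 1)
  w <- pmax(c1 - c0 + 1, 0); hgt <- pmax(r1 - r0 + 1, 0)
  area <- as.integer(w * hgt)
  keepF <- area > 0
  idxF <- which(keepF)
  if (!length(idxF))
    return(list(zbuf = numeric(0), keys = numeric(0), scale = scale,
                bufW = bufW, bufH = bufH))
  fid <- rep(idxF, area[idxF])
  off <- sequence(area[idxF]) - 1L
  wv <- w[fid]
  dx <- off %% wv
  dy <- off %/% wv
  sx <- c0[fid] + dx + 0.5
  sy <- r0[fid] + dy + 0.5
  ## barycentric coordinates in buffer space
  d <- (y2[fid] - y3[fid]) * (x1[fid] - x3[fid]) +
       (x3[fid] - x2[fid]) * (y1[fid] - y3[fid])
  b1 <- ((y2[fid] - y3[fid]) * (sx - x3[fid]) +
         (x3[fid] - x2[fid]) * (sy - y3[fid])) / d
  b2 <- ((y3[fid] - y1[fid]) * (sx - x3[fid]) +
         (x1[fid] - x3[fid]) * (sy - y3[fid])) / d
  b3 <- 1 - b1 - b2
  eps <- -1e-9
  inside <- is.finite(b1) & b1 >= eps & b2 >= eps & b3 >= eps
  z <- b1 * z1[fid] + b2 * z2[fid] + b3 * z3[fid]
  key <- (c0[fid] + dx) + bufW * (r0[fid] + dy)
  key <- key[inside]; z <- z[inside]
  o <- order(key, z)
  key <- key[o]; z <- z[o]
  first <- !duplicated(key)
  list(zbuf = z[first], keys = key[first], scale = scale,
       bufW = bufW, bufH = bufH)
}

#' Choose the best source view per face
#'
#' For each face, among the views where the face centroid is unoccluded
#' (its depth matches the mesh's own depth buffer within \code{visTolMm})
#' and the face is front-facing, picks the view maximizing the dot product
#' between the face normal and the direction to the camera. Ties break to
#' the lower view index. Faces visible in no view get NA ("unseen").
#'
#' @param mesh an \linkS4class{IsoMesh}.
#' @param views list of \linkS4class{CameraView}.
#' @param visTolMm visibility depth tolerance in mm; default 3x the median
#'   edge length of the mesh.
#' @param bufWidth depth-buffer width in px.
#' @return integer vector, index into \code{views} per face (NA = unseen).
#' @export
selectBestView <- function(mesh, views, visTolMm = NULL, bufWidth = 256L) {
  if (!length(views)) stop("need at least 1 view")
  if (is.null(visTolMm)) {
    e <- mesh@vertices[mesh@faces[, 1], ] - mesh@vertices[mesh@faces[, 2], ]
    visTolMm <- 3 * stats::median(sqrt(rowSums(e^2)))
  }
  ctr <- faceCentroids(mesh)
  fn <- smoothedFaceNormals(mesh)
  m <- nrow(mesh@faces)
  best <- rep(NA_integer_, m)
  bestQ <- rep(-Inf, m)
  for (v in seq_along(views)) {
    view <- views[[v]]
    C <- cameraCentre(view@pose)
    toCam <- sweep(-ctr, 2, C, "+")
    dist <- sqrt(rowSums(toCam^2))
    toCam <- toCam / dist
    q <- rowSums(fn * toCam)
    pr <- projectPoints(ctr, view)
    db <- meshDepthBuffer(mesh, view, bufWidth)
    col <- floor(pr$x * db$scale)
    row <- floor(pr$y * db$scale)
    inImg <- !pr$behind & col >= 0 & col < db$bufW & row >= 0 & row < db$bufH
    key <- col + db$bufW * row
    zref <- rep(Inf, m)
    hit <- match(key, db$keys)
    zref[!is.na(hit)] <- db$zbuf[hit[!is.na(hit)]]
    visible <- inImg & q > 0 & pr$depth <= zref + visTolMm
    take <- visible & q > bestQ
    best[take] <- v
    bestQ[take] <- q[take]
  }
  best
}

bilinearSample <- function(image, x, y) {
  h <- dim(image)[1]; w <- dim(image)[2]
  ## continuous pixel coords; pixel (r, c) centre at (c - 0.5, r - 0.5)
  fx <- pmin(pmax(x - 0.5, 0), w - 1)
  fy <- pmin(pmax(y - 0.5, 0), h - 1)
  c0 <- pmin(floor(fx), w - 2); r0 <- pmin(floor(fy), h - 2)
  tx <- fx - c0; ty <- fy - r0
  out <- matrix(0, length(x), 3)
  for (ch in 1:3) {
    M <- image[, , ch]
    i00 <- M[cbind(r0 + 1, c0 + 1)]; i01 <- M[cbind(r0 + 1, c0 + 2)]
    i10 <- M[cbind(r0 + 2, c0 + 1)]; i11 <- M[cbind(r0 + 2, c0 + 2)]
    out[, ch] <- (1 - ty) * ((1 - tx) * i00 + tx * i01) +
                 ty * ((1 - tx) * i10 + tx * i11)
  }
  out
}

#' Bake a texture atlas
#'
#' Packs every face into half of a square atlas cell (two right triangles
#' per cell) and fills its texels by mapping atlas barycentrics to the 3D
#' face, projecting into the face's assigned source view and bilinearly
#' sampling that image. Unseen faces are filled with the flag colour
#' (magenta by default) recorded in the metadata.
#'
#' @param mesh an \linkS4class{IsoMesh}.
#' @param assignments per-face view index from \code{\link{selectBestView}}.
#' @param images list of [row, col, 3] rasters, parallel to \code{views}.
#' @param views list of \linkS4class{CameraView}.
#' @param atlasSize atlas edge in px. Errors with "atlas overflow" when
#'   the faces cannot be packed at this size.
#' @param unseenColour RGB flag colour for unseen faces.
#' @param sampleInsetMm how far to pull each 3D sample point inward along
#'   the face normal before projecting into the source image. The carved
#'   hull surface lies slightly outside the true object (conservative
#'   silhouette dilation plus voxel quantization), so sampling exactly on
#'   the staircase surface can land on background pixels for oblique
#'   faces; a small inward inset keeps samples on the object. Default:
#'   1.5x the median edge length.
#' @return a \linkS4class{TexturedMesh}.
#' @export
bakeAtlas <- function(mesh, assignments, images, views, atlasSize = 1024L,
                      unseenColour = c(1, 0, 1), sampleInsetMm = NULL) {
  if (is.null(sampleInsetMm)) {
    ed <- mesh@vertices[mesh@faces[, 1], , drop = FALSE] -
          mesh@vertices[mesh@faces[, 2], , drop = FALSE]
    sampleInsetMm <- 2 * stats::median(sqrt(rowSums(ed^2)))
  }
  fnUnit <- smoothedFaceNormals(mesh)
  m <- nrow(mesh@faces)
  nCells <- ceiling(m / 2)
  gridN <- ceiling(sqrt(nCells))
  cell <- floor(atlasSize / gridN)
  if (cell < 4L)
    stop(sprintf("atlas overflow: %d faces cannot be packed into %d px",
                 m, atlasSize))
  atlas <- array(0, c(atlasSize, atlasSize, 3))
  fidx <- seq_len(m) - 1L
  cellIdx <- fidx %/% 2L
  upper <- fidx %% 2L == 1L
  x0 <- (cellIdx %% gridN) * cell
  y0 <- (cellIdx %/% gridN) * cell
  ## UV corner positions (continuous atlas coords, y down)
  in1 <- 1; in2 <- cell - 2
  cornerLower <- rbind(c(in1, in1), c(in2, in1), c(in1, in2))
  cornerUpper <- rbind(c(cell - 1 - in1, cell - 1 - in1),
                       c(cell - 1 - in2, cell - 1 - in1),
                       c(cell - 1 - in1, cell - 1 - in2))
  ## local texel pattern shared by every cell
  g <- expand.grid(dx = seq_len(cell) - 1L, dy = seq_len(cell) - 1L)
  lowSel <- g$dx + g$dy <= cell - 2L
  upSel <- g$dx + g$dy >= cell
  baryOf <- function(corners, gx, gy) {
    x1 <- corners[1, 1]; y1 <- corners[1, 2]
    x2 <- corners[2, 1]; y2 <- corners[2, 2]
    x3 <- corners[3, 1]; y3 <- corners[3, 2]
    d <- (y2 - y3) * (x1 - x3) + (x3 - x2) * (y1 - y3)
    b1 <- ((y2 - y3) * (gx - x3) + (x3 - x2) * (gy - y3)) / d
    b2 <- ((y3 - y1) * (gx - x3) + (x1 - x3) * (gy - y3)) / d
    B <- cbind(b1, b2, 1 - b1 - b2)
    ## texels just outside the UV triangle (cell corners) are clamped onto
    ## it so every sample stays on the 3D face
    B <- pmax(B, 0)
    B / rowSums(B)
  }
  texel <- list(
    lower = list(dx = g$dx[lowSel], dy = g$dy[lowSel],
                 B = baryOf(cornerLower, g$dx[lowSel], g$dy[lowSel]),
                 corners = cornerLower),
    upper = list(dx = g$dx[upSel], dy = g$dy[upSel],
                 B = baryOf(cornerUpper, g$dx[upSel], g$dy[upSel]),
                 corners = cornerUpper))
  V1 <- mesh@vertices[mesh@faces[, 1], , drop = FALSE]
  V2 <- mesh@vertices[mesh@faces[, 2], , drop = FALSE]
  V3 <- mesh@vertices[mesh@faces[, 3], , drop = FALSE]
  fillFaces <- function(faceIds, colours = NULL) {
    ## faceIds grouped by half; colours NULL -> sample their source view
    for (half in c("lower", "upper")) {
      sel <- faceIds[if (half == "lower") !upper[faceIds]
                     else upper[faceIds]]
      if (!length(sel)) next
      tx <- texel[[half]]
      nt <- length(tx$dx)
      ## absolute atlas texel indices (row, col), one block per face
      cols <- rep(x0[sel], each = nt) + tx$dx + 1L
      rows <- rep(y0[sel], each = nt) + tx$dy + 1L
      if (is.null(colours)) {
        P <- matrix(0, nt * length(sel), 3)
        for (ax in 1:3)
          P[, ax] <- as.numeric(tx$B %*%
            rbind(V1[sel, ax], V2[sel, ax], V3[sel, ax])) -
            sampleInsetMm * rep(fnUnit[sel, ax], each = nt)
        vlist <- assignments[sel]
        colOut <- matrix(0, nrow(P), 3)
        for (v in unique(vlist)) {
          rowsSel <- rep(vlist == v, each = nt)
          pr <- projectPoints(P[rowsSel, , drop = FALSE], views[[v]])
          colOut[rowsSel, ] <- bilinearSample(images[[v]], pr$x, pr$y)
        }
      } else {
        colOut <- matrix(colours, nt * length(sel), 3, byrow = TRUE)
      }
      for (ch in 1:3)
        atlas[cbind(rows, cols, ch)] <<- colOut[, ch]
    }
  }
  seen <- which(!is.na(assignments))
  unseen <- which(is.na(assignments))
  if (length(seen)) fillFaces(seen)
  if (length(unseen)) fillFaces(unseen, colours = unseenColour)
  ## per-face-corner UVs (normalized, y down)
  uv <- matrix(0, 3 * m, 2)
  for (k in 1:3) {
    cx <- ifelse(upper, cornerUpper[k, 1], cornerLower[k, 1]) + x0 + 0.5
    cy <- ifelse(upper, cornerUpper[k, 2], cornerLower[k, 2]) + y0 + 0.5
    uv[seq(k, by = 3, length.out = m), ] <- cbind(cx, cy) / atlasSize
  }
  new("TexturedMesh", mesh = mesh, atlas = atlas, uv = uv,
      sourceView = as.integer(assignments),
      metadata = list(unseenColour = unseenColour, cellPx = cell,
                      gridN = gridN))
}

#' Mean atlas colour per face
#'
#' @param tm a \linkS4class{TexturedMesh}.
#' @return m x 3 matrix of mean texel colours.
#' @export
faceMeanColour <- function(tm) {
  m <- nrow(tm@mesh@faces)
  cell <- tm@metadata$cellPx
  N <- dim(tm@atlas)[1]
  in1 <- 1
  g <- expand.grid(dx = seq_len(cell) - 1L, dy = seq_len(cell) - 1L)
  lowSel <- g$dx + g$dy <= cell - 2L
  upSel <- g$dx + g$dy >= cell
  out <- matrix(0, m, 3)
  for (f in seq_len(m)) {
    ## recover the face's atlas cell from its first two UV corners
    c1 <- tm@uv[3 * (f - 1) + 1, ] * N - 0.5
    c2 <- tm@uv[3 * (f - 1) + 2, ] * N - 0.5
    if (c2[1] > c1[1]) {  # lower-left triangle
      x0 <- round(c1[1] - in1); y0 <- round(c1[2] - in1); sel <- lowSel
    } else {              # upper-right triangle
      x0 <- round(c1[1] - (cell - 1 - in1))
      y0 <- round(c1[2] - (cell - 1 - in1)); sel <- upSel
    }
    rows <- y0 + g$dy[sel] + 1L
    cols <- x0 + g$dx[sel] + 1L
    for (ch in 1:3)
      out[f, ch] <- mean(tm@atlas[cbind(rows, cols, ch)])
  }
  out
}

#' Remove the mounting pin from a textured mesh
#'
#' Two strategies. \code{"component"}: the pin usually reconstructs as its
#' own visual-hull component, so delete every component except the
#' largest. \code{"cylinder"}: delete faces whose centroids lie within a
#' given cylinder around the known pin axis, then keep the largest
#' remaining component. The hole left behind is reported as the
#' boundary-edge count in the result's metadata.
#'
#' @param tm a \linkS4class{TexturedMesh}.
#' @param method "component" or "cylinder".
#' @param axisPoint,axisDir,radius cylinder-mode parameters: a point on
#'   the pin axis (mm), the axis direction, and the removal radius (mm).
#' @return the edited \linkS4class{TexturedMesh}; its
#'   \code{metadata$boundaryEdges} counts the hole boundary. Warns
#'   "nothing removed" when no face matched.
#' @export
removePin <- function(tm, method = c("component", "cylinder"),
                      axisPoint = c(0, 0, 0), axisDir = c(0, 0, 1),
                      radius = 0.3) {
  method <- match.arg(method)
  mesh <- tm@mesh
  comp <- meshComponents(mesh)
  if (method == "component") {
    if (max(comp) == 1L) {
      warning("nothing removed: mesh has a single component")
      tm@metadata$boundaryEdges <- boundaryEdgeCount(mesh)
      return(tm)
    }
    counts <- tabulate(comp)
    best <- which(counts == max(counts))
    if (length(best) > 1L) {
      minVert <- vapply(best, function(b) min(mesh@faces[comp == b, ]),
                        numeric(1))
      best <- best[which.min(minVert)]
    }
    keep <- comp == best
  } else {
    ctr <- faceCentroids(mesh)
    a <- axisDir / sqrt(sum(axisDir^2))
    rel <- sweep(ctr, 2, axisPoint)
    along <- as.numeric(rel %*% a)
    perp2 <- rowSums(rel^2) - along^2
    inCyl <- perp2 <= radius^2
    if (!any(inCyl)) {
      warning("nothing removed: no face centroid inside the cylinder")
      tm@metadata$boundaryEdges <- boundaryEdgeCount(mesh)
      return(tm)
    }
    keep <- !inCyl
    ## keep the largest remaining component
    sub <- subsetTexturedFaces(tm, keep)
    comp2 <- meshComponents(sub@mesh)
    counts <- tabulate(comp2)
    best <- which.max(counts)
    out <- subsetTexturedFaces(sub, comp2 == best)
    out@metadata$boundaryEdges <- boundaryEdgeCount(out@mesh)
    return(out)
  }
  out <- subsetTexturedFaces(tm, keep)
  out@metadata$boundaryEdges <- boundaryEdgeCount(out@mesh)
  out
}

## subset a textured mesh by a logical face filter, keeping uv/source
## alignment and the shared atlas
subsetTexturedFaces <- function(tm, keep) {
  mesh2 <- subsetFaces(tm@mesh, keep)
  uvRows <- rep(keep, each = 3)
  meta <- tm@metadata
  meta$faceFilterApplied <- TRUE
  new("TexturedMesh", mesh = mesh2, atlas = tm@atlas,
      uv = tm@uv[uvRows, , drop = FALSE],
      sourceView = tm@sourceView[keep], metadata = meta)
}

setMethod("show", "TexturedMesh", function(object) {
  cat(sprintf("TexturedMesh: %d faces (%d unseen), atlas %dx%d px\n",
              nrow(object@mesh@faces), sum(is.na(object@sourceView)),
              dim(object@atlas)[2], dim(object@atlas)[1]))
})
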