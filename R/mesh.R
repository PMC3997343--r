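## Isosurface extraction and mesh utilities. The occupancy field is
## sampled at voxel centres (padded with one empty layer so hulls that
## stay off the grid boundary yield watertight surfaces) and triangulated
## by marching tetrahedra: each lattice cube is split into six tetrahedra
## along its main diagonal and each tetrahedron contributes 0, 1 or 2
## triangles with vertices at the midpoints of its sign-changing edges
## (the iso-0.5 crossing of a 0/1 field). Triangles are wound so normals
## point from occupied to empty, i.e. outward.

#' Extract a triangle mesh from a voxel grid
#'
#' @param grid a \linkS4class{VoxelGrid} with at least one occupied and
#'   one empty voxel (otherwise "degenerate grid").
#' @param isoLevel iso value on the binary occupancy field; with 0/1
#'   occupancy any level in (0, 1) yields the same edge-midpoint surface,
#'   and the conventional 0.5 is the default.
#' @return an \linkS4class{IsoMesh} in mm coordinates; watertight whenever
#'   the occupancy does not touch the grid boundary.
#' @export
meshFromGrid <- function(grid, isoLevel = 0.5) {
  o <- grid@occupancy
  if (all(o) || !any(o))
    stop("degenerate grid: occupancy is uniformly ",
         if (all(o)) "occupied" else "empty")
  r <- grid@resolution
  h <- voxelPitch(grid)
  lo <- grid@bbox[1, ]
  p <- array(FALSE, r + 2L)
  p[seq_len(r[1]) + 1L, seq_len(r[2]) + 1L, seq_len(r[3]) + 1L] <- o
  nc <- r + 1L
  ## corner order: bit 1 = +x, bit 2 = +y, bit 3 = +z
  dxyz <- cbind(c(0, 1, 0, 1, 0, 1, 0, 1),
                c(0, 0, 1, 1, 0, 0, 1, 1),
                c(0, 0, 0, 0, 1, 1, 1, 1))
  code <- array(0, nc)
  vals <- vector("list", 8L)
  for (ci in 1:8) {
    v <- p[seq_len(nc[1]) + dxyz[ci, 1],
           seq_len(nc[2]) + dxyz[ci, 2],
           seq_len(nc[3]) + dxyz[ci, 3], drop = FALSE]
    vals[[ci]] <- v
    code <- code + v * 2^(ci - 1)
  }
  mixed <- which(code > 0 & code < 255)
  idx <- arrayInd(mixed, nc)
  M <- nrow(idx)
  V <- vapply(vals, function(a) as.logical(a[mixed]), logical(M))
  if (M == 1L) V <- matrix(V, 1L, 8L)
  ## corner coordinates per mixed cell, one matrix per axis (M x 8)
  CX <- outer(idx[, 1], dxyz[, 1], "+") ; CX <- lo[1] + (CX - 1.5) * h[1]
  CY <- outer(idx[, 2], dxyz[, 2], "+") ; CY <- lo[2] + (CY - 1.5) * h[2]
  CZ <- outer(idx[, 3], dxyz[, 3], "+") ; CZ <- lo[3] + (CZ - 1.5) * h[3]
  ## six tetrahedra along the 1-8 diagonal (corner ids 1..8)
  tets <- rbind(c(1, 2, 4, 8), c(1, 2, 6, 8), c(1, 3, 4, 8),
                c(1, 3, 7, 8), c(1, 5, 6, 8), c(1, 5, 7, 8))
  caseTable <- lapply(0:15, function(cd) {
    S <- which(bitwAnd(cd, 2^(0:3)) > 0)
    O <- setdiff(1:4, S)
    if (length(S) %in% c(0L, 4L)) return(NULL)
    tris <- if (length(S) == 1L) {
      list(rbind(c(S, O[1]), c(S, O[2]), c(S, O[3])))
    } else if (length(S) == 3L) {
      list(rbind(c(S[1], O), c(S[2], O), c(S[3], O)))
    } else {
      a <- S[1]; b <- S[2]; cc <- O[1]; d <- O[2]
      list(rbind(c(a, cc), c(a, d), c(b, d)),
           rbind(c(a, cc), c(b, d), c(b, cc)))
    }
    list(inside = S, tris = tris)
  })
  triA <- list(); triB <- list(); triC <- list(); refP <- list()
  nacc <- 0L
  for (t in 1:6) {
    q <- tets[t, ]
    Vt <- V[, q, drop = FALSE]
    cd <- Vt %*% c(1, 2, 4, 8)
    for (code4 in 1:14) {
      sel <- which(cd == code4)
      if (!length(sel)) next
      cs <- caseTable[[code4 + 1L]]
      ## reference point inside the occupied part of this tet
      ins <- q[cs$inside]
      rx <- rowMeans(CX[sel, ins, drop = FALSE])
      ry <- rowMeans(CY[sel, ins, drop = FALSE])
      rz <- rowMeans(CZ[sel, ins, drop = FALSE])
      for (tr in cs$tris) {
        mid <- function(e) {
          i <- q[tr[e, 1]]; j <- q[tr[e, 2]]
          cbind((CX[sel, i] + CX[sel, j]) / 2,
                (CY[sel, i] + CY[sel, j]) / 2,
                (CZ[sel, i] + CZ[sel, j]) / 2)
        }
        nacc <- nacc + 1L
        triA[[nacc]] <- mid(1L)
        triB[[nacc]] <- mid(2L)
        triC[[nacc]] <- mid(3L)
        refP[[nacc]] <- cbind(rx, ry, rz)
      }
    }
  }
  A <- do.call(rbind, triA); B <- do.call(rbind, triB)
  C <- do.call(rbind, triC); Rp <- do.call(rbind, refP)
  ## orient: normal = (B-A) x (C-A) must point away from the occupied side
  e1 <- B - A; e2 <- C - A
  nx <- e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2]
  ny <- e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3]
  nz <- e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
  ctr <- (A + B + C) / 3
  ref <- ctr - Rp
  flip <- (nx * ref[, 1] + ny * ref[, 2] + nz * ref[, 3]) < 0
  tmp <- B[flip, , drop = FALSE]
  B[flip, ] <- C[flip, , drop = FALSE]
  C[flip, ] <- tmp
  ## merge vertices: all coordinates are lattice half-steps
  pts <- rbind(A, B, C)
  key <- vertexKey(pts, lo, h, r)
  uKey <- key[!duplicated(key)]
  vid <- match(key, uKey)
  verts <- pts[!duplicated(key), , drop = FALSE]
  nt <- nrow(A)
  faces <- cbind(vid[seq_len(nt)], vid[nt + seq_len(nt)],
                 vid[2L * nt + seq_len(nt)])
  ## drop degenerate faces (duplicate vertices after merge)
  good <- faces[, 1] != faces[, 2] & faces[, 2] != faces[, 3] &
          faces[, 1] != faces[, 3]
  faces <- faces[good, , drop = FALSE]
  newMesh(verts, faces)
}

vertexKey <- function(pts, lo, h, r) {
  K <- 2 * max(r) + 8
  kx <- round((pts[, 1] - lo[1]) / (h[1] / 2))
  ky <- round((pts[, 2] - lo[2]) / (h[2] / 2))
  kz <- round((pts[, 3] - lo[3]) / (h[3] / 2))
  (kx + 3) + K * ((ky + 3) + K * (kz + 3))
}

## assemble an IsoMesh, computing area-weighted per-vertex normals
newMesh <- function(vertices, faces) {
  storage.mode(faces) <- "integer"
  n <- faceNormals(vertices, faces)
  vn <- matrix(0, nrow(vertices), 3)
  for (j in 1:3) {
    for (c in 1:3) {
      acc <- rowsum(n[, c], faces[, j], reorder = FALSE)
      vn[as.integer(rownames(acc)), c] <-
        vn[as.integer(rownames(acc)), c] + acc[, 1]
    }
  }
  len <- sqrt(rowSums(vn^2))
  len[len == 0] <- 1
  new("IsoMesh", vertices = vertices, faces = faces, normals = vn / len)
}

## per-face normal vectors, length = 2 * face area
faceNormals <- function(vertices, faces) {
  A <- vertices[faces[, 1], , drop = FALSE]
  B <- vertices[faces[, 2], , drop = FALSE]
  C <- vertices[faces[, 3], , drop = FALSE]
  e1 <- B - A; e2 <- C - A
  cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
        e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
        e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
}

#' Smoothed per-face normals
#'
#' Marching-tetrahedra surfaces of a binary field are staircases: raw face
#' normals take only a handful of axis-diagonal directions and are poor
#' estimates of the underlying smooth surface normal. This averages
#' normals over the face's neighbourhood (face to vertex to face,
#' repeated) to recover a smooth field, which drives texture view
#' selection and inward sampling offsets.
#'
#' @param mesh an \linkS4class{IsoMesh}.
#' @param iterations smoothing rounds.
#' @return m x 3 matrix of unit normals.
#' @export
smoothedFaceNormals <- function(mesh, iterations = 2L) {
  f <- mesh@faces
  nv <- nrow(mesh@vertices)
  fn <- faceNormals(mesh@vertices, f)
  for (it in seq_len(iterations)) {
    vn <- matrix(0, nv, 3)
    for (j in 1:3) for (c in 1:3) {
      acc <- rowsum(fn[, c], f[, j], reorder = FALSE)
      ids <- as.integer(rownames(acc))
      vn[ids, c] <- vn[ids, c] + acc[, 1]
    }
    fn <- (vn[f[, 1], , drop = FALSE] + vn[f[, 2], , drop = FALSE] +
           vn[f[, 3], , drop = FALSE])
    fn <- fn / pmax(sqrt(rowSums(fn^2)), 1e-30)
  }
  fn
}

#' Face centroids
#'
#' @param mesh an \linkS4class{IsoMesh}.
#' @return m x 3 matrix of triangle centroids in mm.
#' @export
faceCentroids <- function(mesh) {
  (mesh@vertices[mesh@faces[, 1], , drop = FALSE] +
   mesh@vertices[mesh@faces[, 2], , drop = FALSE] +
   mesh@vertices[mesh@faces[, 3], , drop = FALSE]) / 3
}

#' Enclosed volume of a closed mesh
#'
#' Divergence-theorem volume: the sum of signed tetrahedron volumes from
#' the origin to each outward-wound face. Positive for closed meshes with
#' outward normals (the orientation \code{\link{meshFromGrid}} produces).
#'
#' @param mesh an \linkS4class{IsoMesh}.
#' @return volume in mm^3.
#' @export
meshVolume <- function(mesh) {
  A <- mesh@vertices[mesh@faces[, 1], , drop = FALSE]
  B <- mesh@vertices[mesh@faces[, 2], , drop = FALSE]
  C <- mesh@vertices[mesh@faces[, 3], , drop = FALSE]
  sum(A[, 1] * (B[, 2] * C[, 3] - B[, 3] * C[, 2]) +
      A[, 2] * (B[, 3] * C[, 1] - B[, 1] * C[, 3]) +
      A[, 3] * (B[, 1] * C[, 2] - B[, 2] * C[, 1])) / 6
}

#' Connected components of a mesh
#'
#' Components under shared-vertex connectivity.
#'
#' @param mesh an \linkS4class{IsoMesh}.
#' @return integer vector, component id per face.
#' @export
meshComponents <- function(mesh) {
  edges <- rbind(mesh@faces[, 1:2], mesh@faces[, 2:3],
                 mesh@faces[, c(1, 3)])
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  memb <- igraph::components(g)$membership
  as.integer(memb[mesh@faces[, 1]])
}

#' Keep only the largest connected component
#'
#' Drops all faces outside the largest component (by face count); among
#' equally large components the one containing the lowest vertex index
#' wins. Unreferenced vertices are removed and faces re-indexed.
#'
#' @param mesh an \linkS4class{IsoMesh}.
#' @return the reduced \linkS4class{IsoMesh}.
#' @export
keepLargestComponent <- function(mesh) {
  comp <- meshComponents(mesh)
  counts <- tabulate(comp)
  best <- which(counts == max(counts))
  if (length(best) > 1L) {
    minVert <- vapply(best, function(b)
      min(mesh@faces[comp == b, ]), numeric(1))
    best <- best[which.min(minVert)]
  }
  subsetFaces(mesh, comp == best)
}

## subset a mesh to the given faces, re-indexing vertices
subsetFaces <- function(mesh, keep) {
  faces <- mesh@faces[keep, , drop = FALSE]
  used <- sort(unique(as.integer(faces)))
  remap <- integer(nrow(mesh@vertices))
  remap[used] <- seq_along(used)
  faces[] <- remap[faces]
  newMesh(mesh@vertices[used, , drop = FALSE], faces)
}

#' Count boundary edges of a mesh
#'
#' Edges referenced by exactly one face; zero for a watertight mesh.
#'
#' @param mesh an \linkS4class{IsoMesh}.
#' @return integer boundary-edge count.
#' @export
boundaryEdgeCount <- function(mesh) {
  e <- rbind(mesh@faces[, 1:2], mesh@faces[, 2:3], mesh@faces[, c(1, 3)])
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  key <- paste(e[, 1], e[, 2])
  sum(table(key) == 1L)
}

setMethod("show", "IsoMesh", function(object) {
  cat(sprintf("IsoMesh: %d vertices, %d faces\n", nrow(object@vertices),
              nrow(object@faces)))
})

setMethod("show", "VoxelGrid", function(object) {
  cat(sprintf("VoxelGrid: %s voxels, %.1f%% occupied, bbox [%s] mm\n",
              paste(object@resolution, collapse = "x"),
              100 * mean(object@occupancy),
              paste(sprintf("%.2f..%.2f", object@bbox[1, ], object@bbox[2, ]),
                    collapse = ", ")))
})
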