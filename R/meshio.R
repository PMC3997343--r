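## Mesh writers/readers. OBJ (+ MTL + atlas PNG) and X3D carry texture;
## PLY (binary little-endian) and STL (binary) carry geometry; STL drops
## connectivity by format definition. OBJ and PLY have matching readers
## so export -> import round-trips are testable.

#' Export a mesh to a standard format
#'
#' @param x an \linkS4class{IsoMesh} or \linkS4class{TexturedMesh}.
#' @param path output file path; companion files (.mtl, atlas .png) are
#'   written next to it for textured OBJ.
#' @param format "obj", "ply", "stl" or "x3d" (default: from the file
#'   extension). Unknown formats raise "unsupported format".
#' @return invisible character vector of the files written.
#' @export
exportMesh <- function(x, path, format = tools::file_ext(path)) {
  format <- tolower(format)
  tm <- if (is(x, "TexturedMesh")) x else NULL
  mesh <- if (is.null(tm)) x else tm@mesh
  switch(format,
    obj = writeOBJ(mesh, tm, path),
    ply = writePLY(mesh, path),
    stl = writeSTL(mesh, path),
    x3d = writeX3D(mesh, tm, path),
    stop(sprintf("unsupported format '%s'", format)))
}

writeOBJ <- function(mesh, tm, path) {
  files <- path
  con <- file(path, "w")
  on.exit(close(con))
  v <- mesh@vertices
  hasTex <- !is.null(tm)
  if (hasTex) {
    base <- sub("\\.obj$", "", basename(path), ignore.case = TRUE)
    mtlPath <- file.path(dirname(path), paste0(base, ".mtl"))
    texPath <- file.path(dirname(path), paste0(base, "_atlas.png"))
    writeLines(c("newmtl atlas", "Ka 1 1 1", "Kd 1 1 1",
                 sprintf("map_Kd %s", basename(texPath))), mtlPath)
    png::writePNG(tm@atlas, texPath)
    writeLines(sprintf("mtllib %s", basename(mtlPath)), con)
    files <- c(files, mtlPath, texPath)
  }
  writeLines(sprintf("v %.9g %.9g %.9g", v[, 1], v[, 2], v[, 3]), con)
  f <- mesh@faces
  if (hasTex) {
    ## OBJ vt has v pointing up; internal uv has y down
    writeLines(sprintf("vt %.9g %.9g", tm@uv[, 1], 1 - tm@uv[, 2]), con)
    writeLines("usemtl atlas", con)
    vt <- seq_len(3 * nrow(f))
    writeLines(sprintf("f %d/%d %d/%d %d/%d",
                       f[, 1], vt[seq(1, by = 3, length.out = nrow(f))],
                       f[, 2], vt[seq(2, by = 3, length.out = nrow(f))],
                       f[, 3], vt[seq(3, by = 3, length.out = nrow(f))]),
               con)
  } else {
    writeLines(sprintf("f %d %d %d", f[, 1], f[, 2], f[, 3]), con)
  }
  invisible(files)
}

#' Read a Wavefront OBJ mesh
#'
#' @param path OBJ file.
#' @return an \linkS4class{IsoMesh} (texture coordinates, if present, are
#'   attached as the "uv" attribute).
#' @export
readOBJ <- function(path) {
  ln <- readLines(path)
  vs <- ln[startsWith(ln, "v ")]
  fs <- ln[startsWith(ln, "f ")]
  vts <- ln[startsWith(ln, "vt ")]
  verts <- do.call(rbind, lapply(strsplit(trimws(sub("^v", "", vs)), "\\s+"),
                                 function(s) as.numeric(s[1:3])))
  faceTok <- strsplit(trimws(sub("^f", "", fs)), "\\s+")
  faces <- do.call(rbind, lapply(faceTok, function(s)
    as.integer(sub("/.*", "", s[1:3]))))
  mesh <- newMesh(verts, faces)
  if (length(vts)) {
    uvAll <- do.call(rbind, lapply(strsplit(trimws(sub("^vt", "", vts)),
                                            "\\s+"),
                                   function(s) as.numeric(s[1:2])))
    vtIdx <- do.call(rbind, lapply(faceTok, function(s)
      vapply(strsplit(s[1:3], "/"), function(z) as.integer(z[2]),
             integer(1))))
    uv <- uvAll[as.integer(t(vtIdx)), , drop = FALSE]
    uv[, 2] <- 1 - uv[, 2]
    attr(mesh, "uv") <- uv
  }
  mesh
}

writePLY <- function(mesh, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  nv <- nrow(mesh@vertices); nf <- nrow(mesh@faces)
  hdr <- c("ply", "format binary_little_endian 1.0",
           "comment exported by insecthull",
           sprintf("element vertex %d", nv),
           "property float x", "property float y", "property float z",
           sprintf("element face %d", nf),
           "property list uchar int vertex_indices", "end_header")
  writeLines(hdr, con, sep = "\n")
  writeBin(as.numeric(t(mesh@vertices)), con, size = 4, endian = "little")
  if (nf > 0) {
    f0 <- t(mesh@faces) - 1L
    for (i in seq_len(nf)) {
      writeBin(as.raw(3L), con)
      writeBin(as.integer(f0[, i]), con, size = 4, endian = "little")
    }
  }
  invisible(path)
}

#' Read a binary little-endian PLY mesh
#'
#' Supports the vertex/face layout this package writes (float xyz,
#' uchar-counted int face lists).
#'
#' @param path PLY file.
#' @return an \linkS4class{IsoMesh}.
#' @export
readPLY <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- character()
  repeat {
    l <- readLines(con, n = 1)
    hdr <- c(hdr, l)
    if (l == "end_header") break
  }
  nv <- as.integer(sub("element vertex ", "",
                       grep("^element vertex", hdr, value = TRUE)))
  nf <- as.integer(sub("element face ", "",
                       grep("^element face", hdr, value = TRUE)))
  verts <- matrix(readBin(con, numeric(), n = 3 * nv, size = 4,
                          endian = "little"), nv, 3, byrow = TRUE)
  faces <- matrix(0L, nf, 3)
  for (i in seq_len(nf)) {
    cnt <- as.integer(readBin(con, raw(), n = 1))
    idx <- readBin(con, integer(), n = cnt, size = 4, endian = "little")
    faces[i, ] <- idx[1:3] + 1L
  }
  newMesh(verts, faces)
}

writeSTL <- function(mesh, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  header <- charToRaw(sprintf("%-80s", "insecthull binary STL"))
  writeBin(header[1:80], con)
  nf <- nrow(mesh@faces)
  writeBin(as.integer(nf), con, size = 4, endian = "little")
  n <- faceNormals(mesh@vertices, mesh@faces)
  len <- pmax(sqrt(rowSums(n^2)), 1e-30)
  n <- n / len
  for (i in seq_len(nf)) {
    tri <- rbind(n[i, ], mesh@vertices[mesh@faces[i, ], ])
    writeBin(as.numeric(t(tri)), con, size = 4, endian = "little")
    writeBin(as.integer(0), con, size = 2, endian = "little")
  }
  invisible(path)
}

writeX3D <- function(mesh, tm, path) {
  files <- path
  doc <- xml2::xml_new_root("X3D", profile = "Interchange", version = "3.2")
  scene <- xml2::xml_add_child(doc, "Scene")
  shape <- xml2::xml_add_child(scene, "Shape")
  app <- xml2::xml_add_child(shape, "Appearance")
  if (!is.null(tm)) {
    base <- sub("\\.x3d$", "", basename(path), ignore.case = TRUE)
    texPath <- file.path(dirname(path), paste0(base, "_atlas.png"))
    png::writePNG(tm@atlas, texPath)
    xml2::xml_add_child(app, "ImageTexture", url = basename(texPath))
    files <- c(files, texPath)
  } else {
    xml2::xml_add_child(app, "Material", diffuseColor = "0.7 0.7 0.7")
  }
  f <- mesh@faces
  coordIndex <- paste(apply(cbind(f - 1L, -1L), 1, paste, collapse = " "),
                      collapse = " ")
  ifsAttrs <- list(coordIndex = coordIndex, solid = "true")
  if (!is.null(tm)) {
    m <- nrow(f)
    ti <- matrix(seq_len(3 * m) - 1L, ncol = 3, byrow = TRUE)
    ifsAttrs$texCoordIndex <- paste(apply(cbind(ti, -1L), 1, paste,
                                          collapse = " "), collapse = " ")
  }
  ifs <- xml2::xml_add_child(shape, "IndexedFaceSet")
  for (a in names(ifsAttrs)) xml2::xml_set_attr(ifs, a, ifsAttrs[[a]])
  xml2::xml_add_child(ifs, "Coordinate",
    point = paste(sprintf("%.9g %.9g %.9g", mesh@vertices[, 1],
                          mesh@vertices[, 2], mesh@vertices[, 3]),
                  collapse = " "))
  if (!is.null(tm))
    xml2::xml_add_child(ifs, "TextureCoordinate",
      point = paste(sprintf("%.9g %.9g", tm@uv[, 1], 1 - tm@uv[, 2]),
                    collapse = " "))
  xml2::write_xml(doc, path)
  invisible(files)
}
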