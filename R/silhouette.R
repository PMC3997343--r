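## Silhouette extraction by chroma-key distance from a known background
## (uniform colour in synthetic mode, per-pixel reference image on a real
## rig), followed by morphological cleanup. Pin/adhesive artifacts can be
## masked out in 2D with exclusion polygons before carving (the price is a
## texture defect on the surface patches those views no longer constrain).

#' Extract a binary silhouette mask
#'
#' Pixels whose Euclidean RGB distance from the background exceeds
#' \code{threshold} form the raw foreground. The mask is then closed with
#' a 3 px brush, components smaller than \code{minBlobPx} are dropped, and
#' the largest component is retained together with any component that
#' touches it after closing.
#'
#' @param image [row, col, 3] raster in [0, 1].
#' @param background either an RGB triple in [0, 1] or a reference
#'   background raster of the image's size.
#' @param threshold colour-distance threshold in (0, 1] (RGB distance is
#'   normalized by sqrt(3) so a black/white difference is 1).
#' @param minBlobPx minimum component size in px.
#' @param viewId provenance view id.
#' @param keepAll keep every component that survives the size filter,
#'   instead of only the largest one and its neighbours. The default
#'   (FALSE) suits real captures where everything belonging to the
#'   specimen is physically connected and stray blobs are background
#'   debris; synthetic phantoms whose parts are deliberately separated
#'   (e.g. a detached pin) need TRUE.
#' @return a \linkS4class{SilhouetteMask}. Errors with "empty silhouette"
#'   when no foreground survives.
#' @export
extractSilhouette <- function(image, background, threshold = 0.12,
                              minBlobPx = 10L, viewId = 1L,
                              keepAll = FALSE) {
  if (threshold <= 0 || threshold > 1)
    stop("threshold must lie in (0, 1]")
  if (is.null(dim(background))) {
    d2 <- (image[, , 1] - background[1])^2 +
          (image[, , 2] - background[2])^2 +
          (image[, , 3] - background[3])^2
  } else {
    d2 <- (image[, , 1] - background[, , 1])^2 +
          (image[, , 2] - background[, , 2])^2 +
          (image[, , 3] - background[, , 3])^2
  }
  fg <- (sqrt(d2 / 3) > threshold) * 1
  if (!any(fg == 1)) stop("empty silhouette: no pixel differs from background")
  brush <- EBImage::makeBrush(3, "box")
  closed <- fromEB(EBImage::closing(toEB(fg), brush))
  lab <- fromEB(EBImage::bwlabel(toEB(closed)))
  n <- max(lab)
  sizes <- tabulate(lab[lab > 0], n)
  keepSize <- which(sizes >= minBlobPx)
  if (!length(keepSize)) stop("empty silhouette: no component survives size filter")
  if (keepAll) {
    keep <- keepSize
  } else {
    largest <- keepSize[which.max(sizes[keepSize])]
    ## retain the largest component plus any surviving component that
    ## touches it after a further closing pass (fragments reconnected by
    ## morphology belong to the specimen)
    big <- (lab == largest) * 1
    bigGrown <- fromEB(EBImage::dilate(toEB(big), brush))
    touching <- unique(lab[bigGrown == 1 & lab > 0])
    keep <- intersect(keepSize, union(largest, touching))
  }
  mask <- matrix(0, nrow(lab), ncol(lab))
  mask[lab %in% keep] <- 1
  new("SilhouetteMask", mask = mask, viewId = as.integer(viewId),
      exclusions = list())
}

#' Force exclusion polygons to background
#'
#' Interior pixels of each polygon (pixel-centre point-in-polygon test)
#' are set to background; the polygons are recorded in the mask's
#' provenance. Used to mask mounting pins or adhesive in 2D before
#' carving.
#'
#' @param mask a \linkS4class{SilhouetteMask}.
#' @param polygons list of n x 2 matrices of (x, y) pixel vertices.
#' @return the updated \linkS4class{SilhouetteMask}.
#' @export
applyExclusions <- function(mask, polygons) {
  if (!length(polygons)) return(mask)
  m <- mask@mask
  h <- nrow(m); w <- ncol(m)
  cx <- rep(seq_len(w) - 0.5, each = h)
  cy <- rep(seq_len(h) - 0.5, times = w)
  pts <- cbind(cx, cy)
  for (p in polygons) {
    inside <- mgcv::in.out(rbind(p, p[1, ]), pts)
    m[matrix(inside, h, w)] <- 0
  }
  new("SilhouetteMask", mask = m, viewId = mask@viewId,
      exclusions = c(mask@exclusions, polygons))
}

#' Write / read a silhouette mask as PNG
#'
#' @param mask a \linkS4class{SilhouetteMask}.
#' @param path file path.
#' @param viewId view id to attach on read.
#' @return \code{readMask} returns a \linkS4class{SilhouetteMask} (without
#'   exclusion provenance, which lives in the plan file).
#' @export
writeMask <- function(mask, path) {
  png::writePNG(mask@mask, path)
  invisible(path)
}

#' @rdname writeMask
#' @export
readMask <- function(path, viewId = 1L) {
  m <- png::readPNG(path)
  if (length(dim(m)) == 3L) m <- m[, , 1]
  new("SilhouetteMask", mask = (m > 0.5) * 1, viewId = as.integer(viewId),
      exclusions = list())
}

setMethod("show", "SilhouetteMask", function(object) {
  cat(sprintf("SilhouetteMask view %d: %dx%d px, %.1f%% foreground, %d exclusion(s)\n",
              object@viewId, ncol(object@mask), nrow(object@mask),
              100 * mean(object@mask), length(object@exclusions)))
})
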