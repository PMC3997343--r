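## Extended depth-of-field focus stacking. Macro lenses leave only a thin
## slab of the specimen in focus; a rail sweep captures the specimen at
## uniformly spaced focal planes and this module collapses each sweep into
## one all-in-focus image: per-pixel sharpness (local variance of the
## Laplacian of luminance), per-pixel argmax over the stack, median
## smoothing of the winning index, then hard colour selection, which
## conserves the input colours exactly.

#' Construct a focus stack
#'
#' @param frames list of [row, col, 3] arrays in [0, 1].
#' @param focusMm strictly increasing focus distances in mm.
#' @return a \linkS4class{FocusStack}.
#' @export
focusStack <- function(frames, focusMm = seq_along(frames)) {
  new("FocusStack", frames = frames, focusMm = as.numeric(focusMm))
}

#' Read a focus stack from files
#'
#' @param paths image files in focus order.
#' @param focusMm focus distances (defaults to the file index).
#' @return a \linkS4class{FocusStack}.
#' @export
readFocusStack <- function(paths, focusMm = seq_along(paths)) {
  focusStack(lapply(paths, readImage), focusMm)
}

boxKernel <- function(window) {
  matrix(1 / (window * window), window, window)
}

#' Per-pixel sharpness map
#'
#' Local variance of the Laplacian of the luminance channel over a square
#' window: high where fine detail is in focus, zero on constant regions,
#' and invariant to a constant intensity offset.
#'
#' @param image [row, col, 3] array (or a luminance matrix).
#' @param window odd window size in px (>= 3).
#' @return non-negative [row, col] matrix.
#' @export
sharpnessMap <- function(image, window = 9L) {
  window <- as.integer(window)
  if (window < 3L || window %% 2L == 0L)
    stop("window must be an odd integer >= 3")
  lum <- if (length(dim(image)) == 3L) luminance(image) else image
  lap <- matrix(c(0, 1, 0, 1, -4, 1, 0, 1, 0), 3, 3)
  L <- fromEB(EBImage::filter2(toEB(lum), lap))
  k <- boxKernel(window)
  m1 <- fromEB(EBImage::filter2(toEB(L), k))
  m2 <- fromEB(EBImage::filter2(toEB(L * L), k))
  pmax(m2 - m1 * m1, 0)
}

#' Select the best-focused frame per pixel
#'
#' Per-pixel argmax of sharpness across the stack (ties to the lower
#' index), median-filtered with the given radius to suppress speckle.
#' Pixels that are textureless in every frame (sharpness below
#' \code{floorTol}) carry no focus evidence of their own; they inherit the
#' index chosen by the median smoothing of their neighbourhood.
#'
#' @param stack a \linkS4class{FocusStack} with >= 2 frames.
#' @param window sharpness window in px.
#' @param smoothRadius median filter radius in px (0 disables smoothing).
#' @param floorTol sharpness below which a pixel counts as textureless.
#' @return list with \code{index} ([row, col] integer matrix, 1-based
#'   frame indices) and \code{confidence} (winning sharpness values).
#' @export
selectDepth <- function(stack, window = 9L, smoothRadius = 5L,
                        floorTol = 1e-6) {
  n <- length(stack@frames)
  if (n < 2L) stop("need at least 2 frames to select depth")
  d <- dim(stack@frames[[1]])[1:2]
  sharp <- vapply(stack@frames, sharpnessMap, matrix(0, d[1], d[2]),
                  window = window)
  flat <- matrix(sharp, nrow = d[1] * d[2], ncol = n)
  idx <- max.col(flat, ties.method = "first")
  conf <- flat[cbind(seq_along(idx), idx)]
  index <- matrix(idx, d[1], d[2])
  confidence <- matrix(conf, d[1], d[2])
  if (smoothRadius > 0L) {
    sm <- fromEB(EBImage::medianFilter(toEB((index - 1) / max(n - 1, 1)),
                                       as.integer(smoothRadius)))
    index <- matrix(as.integer(round(sm * (n - 1))) + 1L, d[1], d[2])
    index[index < 1L] <- 1L
    index[index > n] <- as.integer(n)
  }
  list(index = index, confidence = confidence)
}

#' Composite an all-in-focus image
#'
#' Hard per-pixel selection: each output pixel is copied verbatim from the
#' frame named by the depth-index map, so every output colour is a colour
#' present in the stack at that location.
#'
#' @param stack a \linkS4class{FocusStack}.
#' @param depth result of \code{\link{selectDepth}} (or any integer matrix
#'   of frame indices with the frame dimensions).
#' @return [row, col, 3] all-in-focus array.
#' @export
compositeStack <- function(stack, depth) {
  index <- if (is.list(depth)) depth$index else depth
  d <- dim(stack@frames[[1]])
  if (!all(dim(index) == d[1:2]))
    stop("depth index dimensions do not match the frames")
  out <- array(0, d)
  flatFrames <- vapply(stack@frames, function(f) as.numeric(f),
                       numeric(prod(d)))
  npix <- d[1] * d[2]
  sel <- as.integer(index)
  for (ch in 1:3) {
    rows <- (ch - 1L) * npix + seq_len(npix)
    out[, , ch] <- matrix(flatFrames[cbind(rows, sel)], d[1], d[2])
  }
  out
}

#' Stack one focus sweep end to end
#'
#' @param stack a \linkS4class{FocusStack}.
#' @param window,smoothRadius see \code{\link{selectDepth}}.
#' @return list with \code{image} (all-in-focus raster) and \code{depth}
#'   (the depth-index map). Single-frame stacks pass through unchanged.
#' @export
stackFocus <- function(stack, window = 9L, smoothRadius = 5L) {
  if (length(stack@frames) == 1L)
    return(list(image = stack@frames[[1]],
                depth = list(index = matrix(1L,
                  nrow(stack@frames[[1]]), ncol(stack@frames[[1]])),
                  confidence = NULL)))
  depth <- selectDepth(stack, window, smoothRadius)
  list(image = compositeStack(stack, depth), depth = depth)
}

setMethod("show", "FocusStack", function(object) {
  d <- dim(object@frames[[1]])
  cat(sprintf("FocusStack: %d frames of %dx%d px, focus %.3g..%.3g mm\n",
              length(object@frames), d[2], d[1], min(object@focusMm),
              max(object@focusMm)))
})
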