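## Small shared raster helpers.

#' Luminance of an RGB raster
#'
#' ITU-R BT.601 weights (0.299, 0.587, 0.114), the convention used by the
#' sharpness measure of the focus stacker.
#'
#' @param image [row, col, 3] array in [0, 1].
#' @return [row, col] matrix in [0, 1].
#' @export
luminance <- function(image) {
  0.299 * image[, , 1] + 0.587 * image[, , 2] + 0.114 * image[, , 3]
}

#' Read / write an RGB raster as PNG
#'
#' @param path file path.
#' @param image [row, col, 3] array in [0, 1].
#' @return \code{readImage} returns a [row, col, 3] array; greyscale and
#'   RGBA files are promoted/truncated to 3 channels.
#' @export
readImage <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 2L) img <- array(rep(img, 3), c(dim(img), 3L))
  if (dim(img)[3] > 3L) img <- img[, , 1:3, drop = FALSE]
  img
}

#' @rdname readImage
#' @export
writeImage <- function(image, path) {
  png::writePNG(image, path)
  invisible(path)
}

## grey [0,1] matrix -> 3-channel array
greyToRGB <- function(m) array(rep(m, 3), c(dim(m), 3L))

#' Peak signal-to-noise ratio between two rasters
#'
#' @param a,b arrays of identical dimension, values in [0, 1].
#' @return PSNR in dB (Inf for identical inputs).
#' @export
psnr <- function(a, b) {
  mse <- mean((a - b)^2)
  if (mse == 0) return(Inf)
  -10 * log10(mse)
}
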