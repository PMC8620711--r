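#' Read an RGB image file
#'
#' PNG files are decoded with the png package; JPEGs fall back to EBImage.
#' Gray images are replicated to three channels; an alpha channel is
#' dropped.
#'
#' @param path Path to a PNG or JPEG file.
#' @return An H x W x 3 integer array in [0, 255].
#' @export
read_rgb_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    a <- png::readPNG(path)
  } else {
    im <- EBImage::readImage(path)
    a <- EBImage::imageData(im)
    # EBImage stores (x, y[, c]); transpose to (row, col[, c])
    a <- if (length(dim(a)) == 3L) aperm(a, c(2, 1, 3)) else t(a)
  }
  if (length(dim(a)) == 2L) a <- array(rep(a, 3), c(dim(a), 3))
  if (dim(a)[3] > 3L) a <- a[, , 1:3, drop = FALSE]
  as_rgb_image(floor(a * 255 + 0.5))
}

#' Write an RGB image array as PNG
#'
#' @param img H x W x 3 array in [0, 255].
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_rgb_png <- function(img, path) {
  img <- as_rgb_image(img)
  png::writePNG(img / 255, path)
  invisible(path)
}

#' Write a binary mask as an 8-bit PNG (0 = background, 255 = plant)
#'
#' @param mask Logical matrix.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_mask_png <- function(mask, path) {
  stopifnot(is.logical(mask), is.matrix(mask))
  png::writePNG(mask * 1, path)
  invisible(path)
}

#' Read a mask PNG back as a logical matrix
#'
#' Any nonzero pixel is treated as plant.
#'
#' @param path Path to a PNG written by \code{\link{write_mask_png}}.
#' @return Logical matrix.
#' @export
read_mask_png <- function(path) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 3L) a <- a[, , 1]
  a > 0
}
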