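#' Validate and coerce an RGB image array
#'
#' Images are plain H x W x 3 arrays with 8-bit values in [0, 255], channel
#' order R, G, B (row = image row, column = image column).
#'
#' @param x Numeric or integer array.
#' @return The array, validated, with storage mode integer.
#' @export
as_rgb_image <- function(x) {
  if (!is.array(x) || length(dim(x)) != 3L || dim(x)[3] != 3L)
    stop("an RGB image must be an H x W x 3 array")
  if (dim(x)[1] < 1L || dim(x)[2] < 1L)
    stop("image dimensions must be at least 1 x 1")
  if (!is.numeric(x) || anyNA(x))
    stop("image values must be numeric with no NAs")
  if (any(x < 0) || any(x > 255))
    stop("image values must lie in [0, 255]")
  if (any(x != round(x)))
    stop("image values must be 8-bit integers")
  storage.mode(x) <- "integer"
  x
}

#' Chromatic (sum-normalized) RGB coordinates
#'
#' Each pixel's channels are divided by their sum: r = R/(R+G+B) and
#' likewise for g and b, so r + g + b = 1 wherever the sum is nonzero.
#' Pure-black pixels (R+G+B = 0) map to (0, 0, 0), which sends all the
#' excess indices to 0 and lets thresholding class them as background.
#'
#' @param img An RGB image array (see \code{\link{as_rgb_image}}).
#' @return An object of class \code{"normalized_rgb"}: a list of three
#'   H x W double matrices \code{r}, \code{g}, \code{b}.
#' @examples
#' px <- array(c(0L, 255L, 0L), c(1, 1, 3))
#' normalize_rgb(px)$g  # 1
#' @export
normalize_rgb <- function(img) {
  img <- as_rgb_image(img)
  R <- img[, , 1, drop = TRUE]; G <- img[, , 2, drop = TRUE]
  B <- img[, , 3, drop = TRUE]
  dm <- dim(img)[1:2]
  dim(R) <- dim(G) <- dim(B) <- dm
  s <- as.double(R) + as.double(G) + as.double(B)
  dim(s) <- dm
  s[s == 0] <- Inf          # zero-sum pixels -> 0/Inf = 0
  structure(list(r = R / s, g = G / s, b = B / s),
            class = "normalized_rgb")
}

index_range <- function(kind) {
  switch(kind,
         ExG = c(-1, 2),
         ExR = c(-1, 1.4),
         ExV = c(-2.4, 3),
         stop("unknown index kind: ", kind))
}

new_index_map <- function(values, kind) {
  structure(list(values = values, kind = kind), class = "index_map")
}

#' @export
print.index_map <- function(x, ...) {
  cat(sprintf("<index_map %s, %d x %d, range [%.3f, %.3f]>\n",
              x$kind, nrow(x$values), ncol(x$values),
              min(x$values), max(x$values)))
  invisible(x)
}

#' Excess green index, ExG = 2g - r - b
#'
#' High for green vegetation, near zero for achromatic pixels, negative for
#' red-dominated soil tones. Values lie in [-1, 2].
#'
#' @param n A \code{"normalized_rgb"} object from \code{\link{normalize_rgb}}.
#' @return An \code{"index_map"} with \code{kind = "ExG"}.
#' @export
excess_green <- function(n) {
  stopifnot(inherits(n, "normalized_rgb"))
  new_index_map(2 * n$g - n$r - n$b, "ExG")
}

#' Excess red index, ExR = 1.4r - g
#'
#' High for reddish soil-toned pixels; values lie in [-1, 1.4].
#'
#' @inheritParams excess_green
#' @return An \code{"index_map"} with \code{kind = "ExR"}.
#' @export
excess_red <- function(n) {
  stopifnot(inherits(n, "normalized_rgb"))
  new_index_map(1.4 * n$r - n$g, "ExR")
}

#' Excess vegetation index, ExV = ExG - ExR
#'
#' The segmentation feature: green enhancement minus red suppression,
#' ExV = 3g - 2.4r - b, in [-2.4, 3]. Strongly positive for green blades,
#' negative for soil, withered (yellow-white) tissue and shadow.
#'
#' @inheritParams excess_green
#' @return An \code{"index_map"} with \code{kind = "ExV"}.
#' @export
excess_veg <- function(n) {
  stopifnot(inherits(n, "normalized_rgb"))
  new_index_map(3 * n$g - 2.4 * n$r - n$b, "ExV")
}

#' Render an index map as an 8-bit grayscale image
#'
#' Affinely rescales the index's fixed theoretical range onto [0, 255]
#' (rounding half-up), so the same gray level means the same index value in
#' every image and Otsu thresholds are comparable across a batch. For ExV,
#' -2.4 maps to 0 and 3.0 to 255; ExV = 0 lands at gray 113.
#'
#' @param map An \code{"index_map"}.
#' @return An H x W integer matrix of gray levels in [0, 255].
#' @examples
#' n <- normalize_rgb(array(c(0L, 255L, 0L), c(1, 1, 3)))
#' to_gray(excess_veg(n))  # 255
#' @export
to_gray <- function(map) {
  stopifnot(inherits(map, "index_map"))
  rng <- index_range(map$kind)
  # the 1e-9 guards exact .5 midpoints against float round-down
  g <- floor(255 * (map$values - rng[1]) / (rng[2] - rng[1]) + 0.5 + 1e-9)
  g[g < 0L] <- 0L; g[g > 255L] <- 255L
  storage.mode(g) <- "integer"
  g
}

# gray level corresponding to an index value of 0 (ExV by default);
# used by segment() as a vegetation floor for the threshold
gray_of_index <- function(value, kind = "ExV") {
  rng <- index_range(kind)
  as.integer(floor(255 * (value - rng[1]) / (rng[2] - rng[1]) + 0.5 + 1e-9))
}
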