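#' 256-bin gray-level histogram
#'
#' @param gray H x W integer matrix of gray levels in [0, 255].
#' @return Integer vector of 256 counts (bin i = gray level i - 1).
#' @export
gray_histogram <- function(gray) {
  if (!is.numeric(gray) || anyNA(gray) || any(gray < 0) || any(gray > 255))
    stop("gray image must contain levels in [0, 255]")
  tabulate(as.integer(gray) + 1L, nbins = 256L)
}

#' Otsu's automatic threshold from a gray-level histogram
#'
#' Selects the gray level t that maximizes the between-class variance
#' sigma_b^2(t) = w0 * w1 * (mu0 - mu1)^2 between the classes
#' {level <= t} and {level > t}. Candidate thresholds span the occupied
#' gray range; ties are broken by the smallest maximizing t, so the result
#' is deterministic (and a single-level histogram returns that level).
#'
#' @param counts Integer vector of 256 non-negative bin counts.
#' @return The threshold, a gray level in [0, 255].
#' @examples
#' h <- integer(256); h[11] <- 8L; h[201] <- 8L  # levels 10 and 200
#' otsu_threshold(h)
#' @export
otsu_threshold <- function(counts) {
  if (length(counts) != 256L || any(counts < 0) || anyNA(counts))
    stop("histogram must be 256 non-negative counts")
  n <- sum(counts)
  if (n == 0) stop("histogram is empty")
  levels <- 0:255
  occupied <- which(counts > 0) - 1L
  lo <- occupied[1]; hi <- occupied[length(occupied)]
  p <- counts / n
  w0 <- cumsum(p)                       # P(level <= t), t = 0..255
  m0 <- cumsum(p * levels)              # first moment up to t
  mu <- m0[256]
  w1 <- 1 - w0
  # sigma_b^2 = (mu*w0 - m0)^2 / (w0*w1); 0 where a class is empty
  num <- (mu * w0 - m0)^2
  den <- w0 * w1
  sigma <- ifelse(den > 0, num / den, 0)
  cand <- (lo:hi) + 1L                  # restrict to occupied range
  best <- cand[which.max(sigma[cand])]  # which.max -> smallest maximizer
  as.integer(best - 1L)
}

#' Binarize a gray image at a threshold
#'
#' Plant where gray > t, background where gray <= t: on an ExV rendering,
#' higher gray means greener, so the upper class is vegetation.
#'
#' @param gray H x W integer matrix of gray levels.
#' @param t Threshold gray level in [0, 255].
#' @return H x W logical matrix, TRUE = plant.
#' @export
binarize <- function(gray, t) {
  if (!is.numeric(t) || length(t) != 1L || t < 0 || t > 255)
    stop("threshold must be a single gray level in [0, 255]")
  m <- gray > t
  storage.mode(m) <- "logical"
  m
}

# 8-connected component labels. EBImage::bwlabel is 4-connectivity, so
# labels touching only diagonally are merged with a union-find over ids.
label_components <- function(mask) {
  if (!any(mask)) return(matrix(0L, nrow(mask), ncol(mask)))
  lab <- EBImage::bwlabel(mask * 1L)
  lab <- matrix(as.integer(lab), nrow(mask), ncol(mask))
  nr <- nrow(lab); nc <- ncol(lab)
  pairs <- NULL
  if (nr > 1L && nc > 1L) {
    a1 <- lab[-nr, -nc]; b1 <- lab[-1, -1]    # \ diagonal
    a2 <- lab[-1, -nc];  b2 <- lab[-nr, -1]   # / diagonal
    sel1 <- a1 > 0L & b1 > 0L & a1 != b1
    sel2 <- a2 > 0L & b2 > 0L & a2 != b2
    pairs <- unique(rbind(cbind(a1[sel1], b1[sel1]),
                          cbind(a2[sel2], b2[sel2])))
  }
  if (!is.null(pairs) && nrow(pairs) > 0L) {
    parent <- seq_len(max(lab))
    find <- function(x) { while (parent[x] != x) { parent[x] <<- parent[parent[x]]; x <- parent[x] }; x }
    for (k in seq_len(nrow(pairs))) {
      ra <- find(pairs[k, 1]); rb <- find(pairs[k, 2])
      if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    }
    root <- vapply(seq_along(parent), find, integer(1))
    relab <- match(root, sort(unique(root)))
    nz <- lab > 0L
    lab[nz] <- relab[lab[nz]]
  }
  lab
}

#' Clean a binary plant mask
#'
#' Removes 8-connected plant components smaller than \code{min_object_px}
#' and optionally fills enclosed background holes. Idempotent.
#'
#' @param mask H x W logical matrix, TRUE = plant.
#' @param min_object_px Minimum component size in pixels to keep
#'   (0 disables removal).
#' @param fill_holes Fill background holes enclosed by plant tissue?
#' @return Cleaned logical mask of the same dimensions.
#' @export
clean_mask <- function(mask, min_object_px = 16L, fill_holes = TRUE) {
  stopifnot(is.logical(mask), is.matrix(mask))
  if (!is.numeric(min_object_px) || length(min_object_px) != 1L ||
      is.na(min_object_px) || min_object_px < 0)
    stop("min_object_px must be a non-negative integer")
  out <- mask
  if (min_object_px > 0 && any(out)) {
    lab <- label_components(out)
    sizes <- tabulate(lab[lab > 0L])
    drop <- which(sizes < min_object_px)
    if (length(drop)) out[lab %in% drop] <- FALSE
  }
  if (isTRUE(fill_holes) && any(out)) {
    filled <- EBImage::fillHull(out * 1L)
    out <- matrix(as.integer(filled) > 0L, nrow(out), ncol(out))
  }
  out
}

#' Extract plant contours and the background-removed image
#'
#' Traces the outer boundary of every 8-connected plant component and
#' blanks background pixels of the source image to (0, 0, 0).
#'
#' @param mask H x W logical plant mask.
#' @param img The source RGB image array, same H x W.
#' @return A list: \code{contours} (list of n x 2 matrices of (row, col)
#'   boundary coordinates, one per component), \code{masked} (the RGB image
#'   with background zeroed), \code{n_components}.
#' @export
extract_roi <- function(mask, img) {
  img <- as_rgb_image(img)
  if (!identical(dim(mask), dim(img)[1:2]))
    stop("mask and image dimensions differ")
  lab <- label_components(mask)
  ncomp <- max(lab)
  contours <- list()
  if (ncomp > 0L) {
    oc <- EBImage::ocontour(lab)
    # ocontour indexes (x, y) from 0 on the matrix as given; report 1-based
    # (row, col)
    contours <- lapply(oc, function(m) {
      out <- m[, c(1, 2), drop = FALSE] + 1L
      colnames(out) <- c("row", "col")
      out
    })
  }
  masked <- img
  bg <- !mask
  for (ch in 1:3) { plane <- masked[, , ch]; plane[bg] <- 0L; masked[, , ch] <- plane }
  list(contours = contours, masked = masked, n_components = ncomp)
}

#' Default segmentation parameters
#'
#' @param index_kind Index whose gray rendering is thresholded
#'   (\code{"ExV"}, the default, or \code{"ExG"}).
#' @param min_object_px Minimum plant-component size kept by
#'   \code{\link{clean_mask}}.
#' @param fill_holes Fill enclosed holes after size filtering?
#' @param min_gray Floor on the effective threshold: plant pixels must also
#'   exceed this gray level. The default is the gray level of index value 0
#'   (for ExV, 113), so scenes with no vegetation signal produce an
#'   (almost) empty mask instead of Otsu splitting the soil distribution.
#'   Set to 0 to disable.
#' @return A list of class \code{"segment_params"}.
#' @export
segment_params <- function(index_kind = "ExV", min_object_px = 16L,
                           fill_holes = TRUE, min_gray = NULL) {
  index_kind <- match.arg(index_kind, c("ExV", "ExG"))
  if (is.null(min_gray)) min_gray <- gray_of_index(0, index_kind)
  structure(list(index_kind = index_kind,
                 min_object_px = as.integer(min_object_px),
                 fill_holes = isTRUE(fill_holes),
                 min_gray = as.integer(min_gray)),
            class = "segment_params")
}

#' Segment a canopy image into plant and background
#'
#' The full chain: chromatic normalization, excess-vegetation index,
#' gray rendering, Otsu threshold, binarization, mask cleaning.
#' Deterministic for fixed input and parameters. Withered (yellow-white)
#' tissue has low ExV and intentionally segments as background: frozen
#' tissue does not count toward coverage.
#'
#' @param img An RGB image array.
#' @param params A \code{\link{segment_params}} list.
#' @return A list of class \code{"segmentation"}: \code{mask} (logical
#'   H x W, TRUE = plant), \code{threshold} (the Otsu gray level),
#'   \code{effective_threshold} (after the \code{min_gray} floor),
#'   \code{gray} (the index rendering), \code{params}.
#' @examples
#' sc <- generate_scene(scene_params(target_coverage_pct = 12, seed = 1))
#' seg <- segment(sc$image)
#' mean(seg$mask) * 100  # ~12
#' @export
segment <- function(img, params = segment_params()) {
  stopifnot(inherits(params, "segment_params"))
  n <- normalize_rgb(img)
  idx <- if (params$index_kind == "ExG") excess_green(n) else excess_veg(n)
  gray <- to_gray(idx)
  t <- otsu_threshold(gray_histogram(gray))
  t_eff <- max(t, params$min_gray)
  mask <- binarize(gray, t_eff)
  mask <- clean_mask(mask, params$min_object_px, params$fill_holes)
  structure(list(mask = mask, threshold = t, effective_threshold = t_eff,
                 gray = gray, params = params),
            class = "segmentation")
}

#' @export
print.segmentation <- function(x, ...) {
  cat(sprintf("<segmentation %d x %d: otsu t=%d (effective %d), foreground %.2f%%>\n",
              nrow(x$mask), ncol(x$mask), x$threshold, x$effective_threshold,
              100 * mean(x$mask)))
  invisible(x)
}
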