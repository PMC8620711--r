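#' Vegetation coverage of a plant mask
#'
#' Coverage is the percentage of image pixels classed as green plant: the
#' vertical-projection fraction of the plot covered by living canopy.
#'
#' @param mask H x W logical plant mask (or a \code{"segmentation"} object).
#' @return A list of class \code{"coverage_result"}: \code{coverage_pct},
#'   \code{plant_px}, \code{total_px}.
#' @export
coverage <- function(mask) {
  if (inherits(mask, "segmentation")) mask <- mask$mask
  stopifnot(is.logical(mask), is.matrix(mask))
  total <- length(mask)
  if (total == 0L) stop("mask has zero pixels")
  plant <- sum(mask)
  structure(list(coverage_pct = 100 * plant / total,
                 plant_px = plant, total_px = total),
            class = "coverage_result")
}

#' @export
print.coverage_result <- function(x, ...) {
  cat(sprintf("coverage %.2f%% (%d / %d px)\n",
              x$coverage_pct, x$plant_px, x$total_px))
  invisible(x)
}

grade_labels <- c("no obvious", "slight", "severe", "most severe")

#' Frost-damage grade from vegetation coverage
#'
#' Maps coverage to an ordinal four-grade frost-injury score. Under the
#' default \code{"severity"} mapping, grade 1 is the lightest injury:
#' grade 1 for coverage >= 15\%, grade 2 for [10, 15), grade 3 for [5, 10),
#' grade 4 (most severe) below 5\%. Interval boundaries go to the
#' less-severe grade so the mapping is total over [0, 100]. The
#' \code{"literal"} variant numbers the same intervals in the opposite
#' order (grade 1 = coverage < 5\%).
#'
#' @param cov Coverage percentage in [0, 100], a \code{"coverage_result"},
#'   or a numeric vector of percentages.
#' @param mapping \code{"severity"} (default; grade 1 = lightest) or
#'   \code{"literal"} (grade 1 = most severe).
#' @return For scalar input, a list of class \code{"frost_grade"} with
#'   \code{grade} and \code{label}; for vector input, an integer vector of
#'   grades.
#' @examples
#' grade(21)$grade  # 1: no obvious injury
#' grade(2)$grade   # 4: most severe
#' @export
grade <- function(cov, mapping = c("severity", "literal")) {
  mapping <- match.arg(mapping)
  if (inherits(cov, "coverage_result")) cov <- cov$coverage_pct
  if (!is.numeric(cov) || anyNA(cov) || any(cov < 0) || any(cov > 100))
    stop("coverage must be in [0, 100] percent")
  g <- ifelse(cov >= 15, 1L, ifelse(cov >= 10, 2L, ifelse(cov >= 5, 3L, 4L)))
  if (mapping == "literal") g <- 5L - g
  if (length(cov) > 1L) return(as.integer(g))
  lab_idx <- if (mapping == "severity") g else 5L - g
  structure(list(grade = as.integer(g), label = grade_labels[lab_idx],
                 mapping = mapping),
            class = "frost_grade")
}

#' @export
print.frost_grade <- function(x, ...) {
  cat(sprintf("frost grade %d (%s injury)\n", x$grade, x$label))
  invisible(x)
}

#' Convert an RGB image to HSI (hue, saturation, intensity)
#'
#' The classical geometric transform: intensity I = (R+G+B)/(3*255),
#' saturation S = 1 - 3*min(r,g,b) on chromatic coordinates, hue from the
#' arccos formula, reflected to (180, 360) degrees when B > G. Achromatic
#' pixels (S = 0, including pure black) take H = 0 by convention.
#'
#' @param img An RGB image array.
#' @return A list of class \code{"hsi_image"} of three H x W matrices:
#'   \code{H} in degrees [0, 360), \code{S} and \code{I} in [0, 1].
#' @examples
#' px <- array(c(255L, 255L, 0L), c(1, 1, 3))
#' rgb_to_hsi(px)$H  # 60 (pure yellow)
#' @export
rgb_to_hsi <- function(img) {
  img <- as_rgb_image(img)
  n <- normalize_rgb(img)
  r <- n$r; g <- n$g; b <- n$b
  I <- (img[, , 1] + img[, , 2] + img[, , 3]) / (3 * 255)
  dim(I) <- dim(r)
  mn <- pmin(r, g, b)
  S <- 1 - 3 * mn
  S[S < 0] <- 0                          # guard float fuzz
  zero_sum <- (r + g + b) == 0           # pure black: S = 0
  S[zero_sum] <- 0
  num <- 0.5 * ((r - g) + (r - b))
  den <- sqrt((r - g)^2 + (r - b) * (g - b))
  cosv <- ifelse(den > 0, pmin(1, pmax(-1, num / den)), 1)
  H <- acos(cosv) * 180 / pi
  H <- ifelse(b > g, 360 - H, H)
  H[H >= 360] <- 0
  H[S == 0] <- 0
  structure(list(H = H, S = S, I = I), class = "hsi_image")
}

#' Default HSI thresholds for withered (yellow-white) leaf tissue
#'
#' Withered tips are yellow to white: the detector takes pixels in a hue
#' window with enough intensity (the yellow branch), or nearly achromatic
#' bright pixels (the white branch). Values are calibration choices exposed
#' for tuning; field scenes with specular reflection or pale buds may need
#' adjustment.
#'
#' @param h_lo,h_hi Hue window in degrees (default 40-75, yellow).
#' @param i_min Minimum intensity for the hue branch (default 0.35).
#' @param s_max_white Maximum saturation for the white branch (default 0.15).
#' @param i_min_white Minimum intensity for the white branch (default 0.7).
#' @return A list of class \code{"withered_thresholds"}.
#' @export
withered_thresholds <- function(h_lo = 40, h_hi = 75, i_min = 0.35,
                                s_max_white = 0.15, i_min_white = 0.7) {
  vals <- c(h_lo = h_lo, h_hi = h_hi, i_min = i_min,
            s_max_white = s_max_white, i_min_white = i_min_white)
  if (anyNA(vals) || !is.numeric(vals))
    stop("thresholds must be numeric and non-missing")
  if (h_lo < 0 || h_hi >= 360 || h_lo > h_hi)
    stop("hue window must satisfy 0 <= h_lo <= h_hi < 360")
  if (i_min < 0 || i_min > 1 || s_max_white < 0 || s_max_white > 1 ||
      i_min_white < 0 || i_min_white > 1)
    stop("intensity/saturation thresholds must lie in [0, 1]")
  structure(as.list(vals), class = "withered_thresholds")
}

#' Extract withered (yellow-white) leaf pixels by HSI thresholding
#'
#' A pixel is withered if its hue falls in [h_lo, h_hi] with intensity
#' >= i_min (yellowed tissue), or if it is nearly achromatic and bright
#' (S <= s_max_white and I >= i_min_white; bleached-white tips). When a
#' plant-region mask is supplied, detection is restricted to it. The
#' fraction is over all image pixels.
#'
#' @param img An RGB image array.
#' @param plant_region Optional logical mask restricting the search.
#' @param thresholds A \code{\link{withered_thresholds}} list.
#' @return A list of class \code{"withered_result"}: \code{withered_px},
#'   \code{withered_fraction} (of total pixels), \code{mask}.
#' @export
withered_extract <- function(img, plant_region = NULL,
                             thresholds = withered_thresholds()) {
  if (!inherits(thresholds, "withered_thresholds"))
    stop("thresholds must be built with withered_thresholds()")
  hsi <- rgb_to_hsi(img)
  yellow <- hsi$H >= thresholds$h_lo & hsi$H <= thresholds$h_hi &
    hsi$S > 0 & hsi$I >= thresholds$i_min
  white <- hsi$S <= thresholds$s_max_white & hsi$I >= thresholds$i_min_white
  m <- yellow | white
  if (!is.null(plant_region)) {
    stopifnot(is.logical(plant_region),
              identical(dim(plant_region), dim(m)))
    m <- m & plant_region
  }
  structure(list(withered_px = sum(m),
                 withered_fraction = sum(m) / length(m),
                 mask = m),
            class = "withered_result")
}

#' @export
print.withered_result <- function(x, ...) {
  cat(sprintf("withered fraction %.4f (%d px)\n",
              x$withered_fraction, x$withered_px))
  invisible(x)
}

#' Aggregate image-level coverages to a plot-level phenotype
#'
#' Plot coverage is the arithmetic mean of its images' coverages; the frost
#' grade is recomputed on the mean.
#'
#' @param coverages Numeric vector of coverage percentages, or a list of
#'   \code{"coverage_result"} objects, one per image of the plot.
#' @param mapping Grade mapping variant, see \code{\link{grade}}.
#' @return A list: \code{mean_coverage_pct}, \code{n_images},
#'   \code{grade}, \code{grade_label}.
#' @examples
#' aggregate_plot(c(10, 12, 14))  # mean 12, grade 2
#' @export
aggregate_plot <- function(coverages, mapping = "severity") {
  if (is.list(coverages))
    coverages <- vapply(coverages, function(x) {
      if (inherits(x, "coverage_result")) x$coverage_pct else as.numeric(x)
    }, numeric(1))
  if (length(coverages) < 1L) stop("need at least one image coverage")
  if (!is.numeric(coverages) || anyNA(coverages))
    stop("coverages must be numeric and non-missing")
  m <- mean(coverages)
  g <- grade(m, mapping)
  list(mean_coverage_pct = m, n_images = length(coverages),
       grade = g$grade, grade_label = g$label)
}

#' Which treatment gives the lowest (and highest) coverage, by variety
#'
#' For a per-variety-by-treatment coverage table, counts for each treatment
#' the fraction of varieties in which it has the minimum (and maximum)
#' mean coverage. Ties are counted for all tied treatments
#' and flagged, so tied fractions can sum above 1.
#'
#' @param table A data.frame with columns \code{variety}, \code{treatment},
#'   \code{coverage} (one row per cell), or a varieties x treatments
#'   numeric matrix with dimnames.
#' @return A list of class \code{"treatment_ranking"}: \code{lowest} and
#'   \code{highest} (named fractions in [0, 1] per treatment),
#'   \code{n_varieties}, \code{ties_lowest}, \code{ties_highest}
#'   (variety names with tied extrema).
#' @export
treatment_ranking_summary <- function(table) {
  if (is.data.frame(table)) {
    need <- c("variety", "treatment", "coverage")
    if (!all(need %in% names(table)))
      stop("data.frame must have columns variety, treatment, coverage")
    mat <- tapply(table$coverage, list(table$variety, table$treatment),
                  function(x) x[1])
    dup <- duplicated(table[, c("variety", "treatment")])
    if (any(dup)) stop("duplicate variety x treatment cells")
  } else if (is.matrix(table)) {
    mat <- table
  } else stop("table must be a data.frame or matrix")
  if (anyNA(mat)) {
    idx <- which(is.na(mat), arr.ind = TRUE)
    miss <- paste(rownames(mat)[idx[, 1]], colnames(mat)[idx[, 2]], sep = ":")
    stop("missing coverage cells: ", paste(miss, collapse = ", "))
  }
  trts <- colnames(mat)
  nv <- nrow(mat)
  lo_hits <- hi_hits <- stats::setNames(numeric(length(trts)), trts)
  ties_lo <- ties_hi <- character(0)
  for (i in seq_len(nv)) {
    row <- mat[i, ]
    lo <- which(row == min(row)); hi <- which(row == max(row))
    lo_hits[lo] <- lo_hits[lo] + 1
    hi_hits[hi] <- hi_hits[hi] + 1
    if (length(lo) > 1L) ties_lo <- c(ties_lo, rownames(mat)[i])
    if (length(hi) > 1L) ties_hi <- c(ties_hi, rownames(mat)[i])
  }
  structure(list(lowest = lo_hits / nv, highest = hi_hits / nv,
                 n_varieties = nv,
                 ties_lowest = ties_lo, ties_highest = ties_hi),
            class = "treatment_ranking")
}

#' @export
print.treatment_ranking <- function(x, ...) {
  cat(sprintf("Treatment ranking over %d varieties\n", x$n_varieties))
  cat("  lowest coverage: ",
      paste(sprintf("%s %.1f%%", names(x$lowest), 100 * x$lowest),
            collapse = ", "), "\n")
  cat("  highest coverage:",
      paste(sprintf("%s %.1f%%", names(x$highest), 100 * x$highest),
            collapse = ", "), "\n")
  if (length(x$ties_lowest) || length(x$ties_highest))
    cat(sprintf("  ties flagged in %d (lowest) / %d (highest) varieties\n",
                length(x$ties_lowest), length(x$ties_highest)))
  invisible(x)
}
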