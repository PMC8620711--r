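#' Parameters for a synthetic canopy scene
#'
#' The generator emulates what the segmentation pipeline sees in the field:
#' green wheat blades clustered into sowing rows over brown textured soil,
#' optionally with yellow-white withered blade tips, under small
#' illumination drift and sensor noise. Blades are drawn as oriented
#' elongated strips with hard (non-antialiased) pixel membership so the
#' ground-truth masks and coverage are exact by construction.
#'
#' @param width,height Image size in pixels.
#' @param target_coverage_pct Green-pixel coverage to aim for, in [0, 95];
#'   the generator adds blades until within +0.5 points of the target.
#' @param n_rows Number of sowing-row bands blades cluster into (default 6).
#' @param blade_length_px,blade_width_px Length-2 ranges blades are drawn
#'   from, in pixels.
#' @param withered_tip_fraction Fraction of each blade's pixels (at the far
#'   end of the strip) recolored as withered tissue and excluded from the
#'   plant truth, in [0, 1].
#' @param green_palette,soil_palette,withered_palette Lists/matrices of RGB
#'   triples (0-255) drawn from per blade / soil patch.
#' @param illumination_jitter Half-width of the global multiplicative
#'   brightness factor, drawn uniformly from 1 +/- this value per scene
#'   (default 0.04, mimicking a narrow controlled-light band).
#' @param noise_sd Per-channel Gaussian sensor noise, gray levels.
#' @param seed Integer RNG seed; scenes are byte-identical for equal seeds.
#' @return A list of class \code{"scene_params"}.
#' @export
scene_params <- function(width = 320L, height = 320L,
                         target_coverage_pct = 12,
                         n_rows = 6L,
                         blade_length_px = c(18, 32),
                         blade_width_px = c(2, 4),
                         withered_tip_fraction = 0,
                         green_palette = rbind(c(10, 140, 30),
                                               c(25, 160, 40),
                                               c(45, 180, 60),
                                               c(15, 125, 35)),
                         soil_palette = rbind(c(120, 80, 40),
                                              c(130, 90, 50),
                                              c(110, 75, 45),
                                              c(125, 85, 55)),
                         withered_palette = rbind(c(230, 220, 120),
                                                  c(235, 225, 150),
                                                  c(245, 240, 210)),
                         illumination_jitter = 0.04,
                         noise_sd = 2,
                         seed = 1L) {
  width <- as.integer(width); height <- as.integer(height)
  if (width < 8L || height < 8L) stop("scene must be at least 8 x 8")
  if (target_coverage_pct < 0 || target_coverage_pct > 95)
    stop("target_coverage_pct must be in [0, 95]")
  if (withered_tip_fraction < 0 || withered_tip_fraction > 1)
    stop("withered_tip_fraction must be in [0, 1]")
  pal <- function(x) {
    m <- if (is.list(x)) do.call(rbind, x) else rbind(x)
    if (nrow(m) < 1L || ncol(m) != 3L || any(m < 0) || any(m > 255))
      stop("palettes must be non-empty lists of RGB triples in [0, 255]")
    m
  }
  structure(list(width = width, height = height,
                 target_coverage_pct = as.numeric(target_coverage_pct),
                 n_rows = as.integer(n_rows),
                 blade_length_px = as.numeric(blade_length_px),
                 blade_width_px = as.numeric(blade_width_px),
                 withered_tip_fraction = as.numeric(withered_tip_fraction),
                 green_palette = pal(green_palette),
                 soil_palette = pal(soil_palette),
                 withered_palette = pal(withered_palette),
                 illumination_jitter = as.numeric(illumination_jitter),
                 noise_sd = as.numeric(noise_sd),
                 seed = as.integer(seed)),
            class = "scene_params")
}

# pixel membership of one blade strip: center (cy, cx), direction theta,
# length L, width W. Returns linear indices plus each pixel's axial
# position in [0, 1] (1 = blade tip).
blade_pixels <- function(h, w, cy, cx, theta, L, W) {
  ct <- cos(theta); st <- sin(theta)
  half <- L / 2
  r <- ceiling(half + W)
  ys <- max(1L, floor(cy - r)):min(h, ceiling(cy + r))
  xs <- max(1L, floor(cx - r)):min(w, ceiling(cx + r))
  if (!length(ys) || !length(xs)) return(NULL)
  dy <- rep(ys - cy, times = length(xs))
  dx <- rep(xs - cx, each = length(ys))
  u <- dx * ct + dy * st
  v <- -dx * st + dy * ct
  keep <- abs(u) <= half & abs(v) <= W / 2
  if (!any(keep)) return(NULL)
  rows <- rep(ys, times = length(xs))[keep]
  cols <- rep(xs, each = length(ys))[keep]
  list(idx = rows + (cols - 1L) * h,
       axial = (u[keep] + half) / L)
}

# smooth multiplicative field in 1 +/- amp, from a coarse random grid
# blurred to low frequency
value_noise <- function(h, w, amp, cell = 16L) {
  gh <- ceiling(h / cell); gw <- ceiling(w / cell)
  coarse <- matrix(stats::runif(gh * gw, -1, 1), gh, gw)
  big <- coarse[rep(seq_len(gh), each = cell), rep(seq_len(gw), each = cell)]
  big <- big[seq_len(h), seq_len(w), drop = FALSE]
  sm <- EBImage::gblur(big, sigma = cell / 2)
  sm <- matrix(as.numeric(sm), h, w)
  1 + amp * sm
}

#' Generate one synthetic canopy scene with ground truth
#'
#' Draws blades into row bands until the green coverage reaches the target
#' (never exceeding it by more than 0.5 points), recolors each blade's tip
#' portion from the withered palette, renders soil texture, illumination
#' jitter and sensor noise, and returns the image along with exact plant
#' and withered truth masks. Deterministic for a fixed seed.
#'
#' @param p A \code{\link{scene_params}} list.
#' @return A list of class \code{"synthetic_scene"}: \code{image} (RGB
#'   array), \code{plant_truth} and \code{withered_truth} (disjoint logical
#'   masks; the plant truth holds green pixels only), \code{true_coverage_pct},
#'   \code{true_withered_fraction}, \code{params}.
#' @examples
#' sc <- generate_scene(scene_params(target_coverage_pct = 8, seed = 42))
#' sc$true_coverage_pct  # within [8, 8.5]
#' @export
generate_scene <- function(p = scene_params()) {
  stopifnot(inherits(p, "scene_params"))
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(p$seed)

  h <- p$height; w <- p$width
  total <- h * w
  target_px <- p$target_coverage_pct / 100 * total
  cap_px <- (p$target_coverage_pct + 0.5) / 100 * total

  # blade ownership: 0 = soil, else blade id; tip flag per pixel
  owner <- matrix(0L, h, w)
  tip <- matrix(FALSE, h, w)
  blade_color <- list()
  band_centers <- (seq_len(p$n_rows) - 0.5) / p$n_rows * h
  band_sd <- h / p$n_rows / 4

  n_green <- function() sum(owner > 0L & !tip)
  green_px <- 0L
  iter <- 0L
  len_range <- sort(p$blade_length_px); wid_range <- sort(p$blade_width_px)
  while (green_px < target_px) {
    iter <- iter + 1L
    if (iter > 50000L)
      stop("target coverage unreachable with the given blade geometry")
    L <- stats::runif(1, len_range[1], len_range[2])
    W <- stats::runif(1, wid_range[1], wid_range[2])
    # near the cap, shrink blades so no addition overshoots
    gap_px <- cap_px - green_px
    while (L * W > gap_px && L > 3) { L <- L / 1.5; W <- max(1, W / 1.2) }
    cy <- stats::rnorm(1, sample(band_centers, 1), band_sd)
    cx <- stats::runif(1, 1, w)
    theta <- stats::runif(1, 0, 2 * pi)
    bp <- blade_pixels(h, w, cy, cx, theta, L, W)
    if (is.null(bp)) next
    # would this blade push green coverage past the cap?
    is_tip <- bp$axial > 1 - p$withered_tip_fraction
    new_green <- bp$idx[!is_tip]
    gain <- sum(owner[new_green] == 0L | tip[new_green])
    if (green_px + gain > cap_px) next
    id <- length(blade_color) + 1L
    blade_color[[id]] <- p$green_palette[sample(nrow(p$green_palette), 1), ]
    owner[bp$idx] <- id
    tip[bp$idx] <- is_tip
    green_px <- n_green()
  }

  plant_truth <- owner > 0L & !tip
  withered_truth <- owner > 0L & tip

  # render: textured soil, per-blade green, withered palette on tips
  img <- array(0, dim = c(h, w, 3))
  soil_pick <- matrix(sample(nrow(p$soil_palette), ceiling(h / 16) * ceiling(w / 16),
                             replace = TRUE),
                      ceiling(h / 16), ceiling(w / 16))
  soil_idx <- soil_pick[cbind(pmin(ceiling(as.vector(row(owner)) / 16), nrow(soil_pick)),
                              pmin(ceiling(as.vector(col(owner)) / 16), ncol(soil_pick)))]
  tex <- value_noise(h, w, amp = 0.10)
  for (ch in 1:3)
    img[, , ch] <- p$soil_palette[soil_idx, ch] * tex
  if (length(blade_color)) {
    cols <- do.call(rbind, blade_color)
    sel <- owner > 0L & !tip
    for (ch in 1:3) {
      plane <- img[, , ch]
      plane[sel] <- cols[owner[sel], ch]
      img[, , ch] <- plane
    }
    if (any(withered_truth)) {
      wpick <- p$withered_palette[
        1L + (owner[withered_truth] %% nrow(p$withered_palette)), , drop = FALSE]
      for (ch in 1:3) {
        plane <- img[, , ch]
        plane[withered_truth] <- wpick[, ch]
        img[, , ch] <- plane
      }
    }
  }
  gain_f <- stats::runif(1, 1 - p$illumination_jitter, 1 + p$illumination_jitter)
  img <- img * gain_f
  if (p$noise_sd > 0)
    img <- img + array(stats::rnorm(total * 3, 0, p$noise_sd), dim(img))
  img <- floor(img + 0.5)
  img[img < 0] <- 0; img[img > 255] <- 255
  storage.mode(img) <- "integer"

  nw <- sum(withered_truth); np <- sum(plant_truth)
  structure(list(image = img,
                 plant_truth = plant_truth,
                 withered_truth = withered_truth,
                 true_coverage_pct = 100 * np / total,
                 true_withered_fraction = if (np + nw > 0) nw / (np + nw) else 0,
                 params = p),
            class = "synthetic_scene")
}

#' @export
print.synthetic_scene <- function(x, ...) {
  cat(sprintf("<synthetic_scene %d x %d: coverage %.2f%%, withered %.3f of blade px, seed %d>\n",
              x$params$height, x$params$width, x$true_coverage_pct,
              x$true_withered_fraction, x$params$seed))
  invisible(x)
}

#' @export
plot.synthetic_scene <- function(x, ...) {
  op <- graphics::par(mar = c(0.5, 0.5, 2, 0.5)); on.exit(graphics::par(op))
  graphics::plot(0, 0, type = "n", xlim = c(0, 1), ylim = c(0, 1),
                 axes = FALSE, xlab = "", ylab = "",
                 main = sprintf("synthetic canopy, coverage %.1f%%",
                                x$true_coverage_pct), ...)
  graphics::rasterImage(x$image / 255, 0, 0, 1, 1)
  invisible(x)
}

#' Default per-grade target coverage ranges
#'
#' Coverage ranges (percent) scenes are drawn from for each frost grade,
#' kept away from the 5/10/15 interval boundaries so a scene's true grade
#' is unambiguous.
#'
#' @return Named list of length-2 ranges for grades "1".."4".
#' @export
default_coverage_by_grade <- function() {
  list(`1` = c(15.8, 21), `2` = c(10.8, 14.2),
       `3` = c(5.8, 9.2), `4` = c(2, 4.2))
}

#' Generate a full synthetic experiment image set
#'
#' Emits one PNG per (plot, image index) of the layout into a directory,
#' with per-plot frost grades sampled uniformly and per-plot target
#' coverages drawn from the grade's range, plus a ground-truth CSV.
#' Filenames follow \code{{variety}_{treatment}_{replicate}_{k}.png}, the
#' convention the batch pipeline parses.
#'
#' @param layout An \code{"experiment_layout"}.
#' @param dir Output directory (created if needed).
#' @param coverage_by_grade Named list of per-grade target coverage ranges.
#' @param seed Integer seed; per-scene seeds derive from it.
#' @param width,height Scene size in pixels.
#' @param withered_tip_fraction Withered tip fraction for every scene.
#' @param write_truth_masks Also write plant-truth masks as PNG?
#' @return Invisibly, the truth data.frame (also written to
#'   \code{truth.csv} in \code{dir}): plot_id, variety, treatment,
#'   replicate, image (filename), true_coverage_pct, true_grade.
#' @export
generate_experiment <- function(layout, dir,
                                coverage_by_grade = default_coverage_by_grade(),
                                seed = 1L, width = 320L, height = 320L,
                                withered_tip_fraction = 0,
                                write_truth_masks = FALSE) {
  stopifnot(inherits(layout, "experiment_layout"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  plots <- enumerate_plots(layout)
  k <- layout$images_per_plot
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  grades <- sample(names(coverage_by_grade), nrow(plots), replace = TRUE)
  targets <- vapply(grades, function(g) {
    rng <- coverage_by_grade[[g]]
    stats::runif(1, rng[1], rng[2])
  }, numeric(1))
  scene_seeds <- sample.int(.Machine$integer.max - 1L, nrow(plots) * k)
  rows <- vector("list", nrow(plots) * k)
  idx <- 0L
  for (i in seq_len(nrow(plots))) {
    for (j in seq_len(k)) {
      idx <- idx + 1L
      fname <- sprintf("%s_%s_%d_%d.png", plots$variety[i],
                       plots$treatment[i], plots$replicate[i], j)
      sc <- generate_scene(scene_params(
        width = width, height = height,
        target_coverage_pct = targets[i],
        withered_tip_fraction = withered_tip_fraction,
        seed = scene_seeds[idx]))
      write_rgb_png(sc$image, file.path(dir, fname))
      if (write_truth_masks)
        write_mask_png(sc$plant_truth,
                       file.path(dir, sub("\\.png$", "_truth.png", fname)))
      rows[[idx]] <- data.frame(
        plot_id = plots$plot_id[i], variety = plots$variety[i],
        treatment = plots$treatment[i], replicate = plots$replicate[i],
        image = fname,
        true_coverage_pct = sc$true_coverage_pct,
        true_grade = grade(sc$true_coverage_pct)$grade,
        stringsAsFactors = FALSE)
    }
  }
  truth <- do.call(rbind, rows)
  utils::write.csv(truth, file.path(dir, "truth.csv"), row.names = FALSE)
  invisible(truth)
}
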