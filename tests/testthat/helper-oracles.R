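# Independent oracles and tiny fixture builders used across the suite.

# Brute-force Otsu: loop over every threshold 0..255, compute class weights
# and means directly, keep the smallest t maximizing between-class variance.
otsu_oracle <- function(counts) {
  n <- sum(counts)
  best_t <- 0L; best_s <- -Inf
  for (t in 0:255) {
    c0 <- counts[seq_len(t + 1)]
    c1 <- if (t < 255) counts[(t + 2):256] else numeric(0)
    n0 <- sum(c0); n1 <- n - n0
    if (n0 == 0 || n1 == 0) { s <- 0 } else {
      mu0 <- sum(c0 * (0:t)) / n0
      mu1 <- sum(c1 * ((t + 1):255)) / n1
      s <- (n0 / n) * (n1 / n) * (mu0 - mu1)^2
    }
    if (s > best_s + 1e-12) { best_s <- s; best_t <- t }
  }
  as.integer(best_t)
}

# Naive inverse of the geometric HSI transform (sector formula), returning
# RGB in [0, 255]. Used only to check rgb_to_hsi round-trips.
hsi_to_rgb_px <- function(H, S, I) {
  h <- H %% 360
  sector <- if (h < 120) 0 else if (h < 240) 120 else 240
  hh <- (h - sector) * pi / 180
  x <- I * (1 - S)
  y <- I * (1 + S * cos(hh) / cos(pi / 3 - hh))
  z <- 3 * I - x - y
  rgb <- switch(as.character(sector),
                "0" = c(y, z, x), "120" = c(x, y, z), "240" = c(z, x, y))
  pmin(pmax(rgb, 0), 1) * 255
}

# single-pixel image from an RGB triple
px_img <- function(r, g, b) array(as.integer(c(r, g, b)), c(1, 1, 3))

# uniform solid-color image
solid_img <- function(r, g, b, h = 8, w = 8) {
  array(rep(as.integer(c(r, g, b)), each = h * w), c(h, w, 3))
}

# random valid RGB image
random_img <- function(h = 16, w = 16) {
  array(sample(0:255, h * w * 3, replace = TRUE), c(h, w, 3))
}

# small layout for pipeline tests
tiny_layout <- function(nv = 2, reps = 1, imgs = 2) {
  experiment_layout(
    varieties = sprintf("TV%02d", seq_len(nv)),
    treatments = list(nitrogen_treatment("N1", 0),
                      nitrogen_treatment("N2", 180)),
    replicates = reps, images_per_plot = imgs)
}
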