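test_that("coverage is the exact plant-pixel percentage", {
  m <- matrix(FALSE, 10, 10); m[1:5, 1:5] <- TRUE
  cov <- coverage(m)
  expect_equal(cov$coverage_pct, 25)
  expect_equal(cov$plant_px, 25L)
  expect_equal(coverage(matrix(TRUE, 3, 3))$coverage_pct, 100)
  expect_error(coverage(matrix(logical(0), 0, 0)), "zero")
})

test_that("grade partitions [0,100] into exactly four total, monotone intervals", {
  sweep <- seq(0, 100, by = 0.1)
  g <- grade(sweep)
  expect_setequal(unique(g), 1:4)
  expect_true(all(diff(g) <= 0))           # higher coverage never worse grade
  expect_true(all(g %in% 1:4))             # total
  # the paper's extremes and the decided boundary assignments
  expect_equal(grade(2)$grade, 4L)
  expect_equal(grade(21)$grade, 1L)
  expect_equal(grade(12)$grade, 2L)
  expect_equal(grade(7)$grade, 3L)
  expect_equal(grade(5)$grade, 3L)
  expect_equal(grade(10)$grade, 2L)
  expect_equal(grade(15)$grade, 1L)
  expect_equal(grade(15)$label, "no obvious")
  expect_equal(grade(2)$label, "most severe")
})

test_that("the literal mapping variant reverses the grade numbering", {
  expect_equal(grade(2, mapping = "literal")$grade, 1L)
  expect_equal(grade(21, mapping = "literal")$grade, 4L)
  sweep <- seq(0, 100, by = 0.5)
  expect_equal(grade(sweep, "literal"), 5L - grade(sweep, "severity"))
})

test_that("rgb_to_hsi matches the geometric transform on reference colors", {
  red <- rgb_to_hsi(px_img(255, 0, 0))
  expect_equal(red$H[1], 0)
  expect_equal(red$S[1], 1)
  expect_equal(red$I[1], 1 / 3)
  yellow <- rgb_to_hsi(px_img(255, 255, 0))
  expect_equal(yellow$H[1], 60, tolerance = 1e-9)
  expect_equal(yellow$S[1], 1)
  expect_equal(yellow$I[1], 2 / 3, tolerance = 1e-12)
  gray <- rgb_to_hsi(px_img(100, 100, 100))
  expect_equal(gray$S[1], 0)
  expect_equal(gray$H[1], 0)               # convention for achromatic
  expect_equal(gray$I[1], 100 / 255)
  blue <- rgb_to_hsi(px_img(0, 0, 255))
  expect_equal(blue$H[1], 240, tolerance = 1e-9)
})

test_that("HSI round-trips through the naive inverse within one gray level", {
  set.seed(44)
  n_px <- 10000
  rgb <- matrix(sample(0:255, 3 * n_px, replace = TRUE), ncol = 3)
  # drop (near-)achromatic pixels: hue is undefined there
  keep <- apply(rgb, 1, function(x) max(x) - min(x) > 3) & rowSums(rgb) > 0
  rgb <- rgb[keep, , drop = FALSE]
  img <- array(as.integer(t(rgb)), c(3, 1, nrow(rgb)))
  img <- aperm(img, c(3, 2, 1))            # n x 1 x 3
  hsi <- rgb_to_hsi(img)
  back <- t(mapply(hsi_to_rgb_px, hsi$H, hsi$S, hsi$I))
  expect_lt(max(abs(back - rgb)), 1 + 1e-6)
})

test_that("withered extraction finds yellow-white tissue and nothing on green", {
  expect_equal(withered_extract(solid_img(0, 200, 0))$withered_fraction, 0)
  expect_equal(withered_extract(solid_img(255, 255, 0))$withered_fraction, 1)
  # near-white bright pixels hit the low-saturation branch
  expect_equal(withered_extract(solid_img(245, 240, 230))$withered_fraction, 1)
  # dark soil does not
  expect_equal(withered_extract(solid_img(120, 80, 40))$withered_fraction, 0)
  expect_error(withered_extract(solid_img(1, 1, 1), thresholds = list(h_lo = 40)),
               "withered_thresholds")
  expect_error(withered_thresholds(h_lo = 80, h_hi = 40), "hue window")
})

test_that("withered recovery on generator scenes is within 3 points of truth", {
  for (s in c(3, 14)) {
    sc <- generate_scene(scene_params(target_coverage_pct = 12,
                                      withered_tip_fraction = 0.1, seed = s))
    w <- withered_extract(sc$image)
    truth_frac <- sum(sc$withered_truth) / length(sc$withered_truth)
    expect_lt(abs(w$withered_fraction - truth_frac), 0.03)
    # share of blade pixels that are withered, vs the 0.1 dialed in
    seg <- segment(sc$image)
    blade_share <- w$withered_px / (w$withered_px + sum(seg$mask))
    expect_lt(abs(blade_share - 0.1), 0.03)
  }
})

test_that("withered and coverage pixels are disjoint under defaults", {
  sc <- generate_scene(scene_params(target_coverage_pct = 12,
                                    withered_tip_fraction = 0.15, seed = 8))
  seg <- segment(sc$image)
  w <- withered_extract(sc$image)
  expect_lt(sum(seg$mask & w$mask) / max(1, sum(w$mask)), 0.01)
})

test_that("plot aggregation takes the mean and regrades it", {
  a <- aggregate_plot(c(10, 12, 14))
  expect_equal(a$mean_coverage_pct, 12)
  expect_equal(a$grade, 2L)
  b <- aggregate_plot(8)
  expect_equal(b$mean_coverage_pct, 8)
  expect_equal(b$grade, 3L)
  for (k in c(2, 5)) expect_equal(aggregate_plot(rep(7.5, k))$mean_coverage_pct, 7.5)
  expect_error(aggregate_plot(numeric(0)), "at least one")
})

test_that("treatment ranking counts argmin/argmax varieties like a brute-force loop", {
  tab <- data.frame(
    variety = rep(c("A", "B", "C"), each = 3),
    treatment = rep(c("N1", "N2", "N3"), 3),
    coverage = c(12, 10, 6,  15, 11, 9,  7, 8, 9))
  r <- treatment_ranking_summary(tab)
  expect_equal(unname(r$lowest["N3"]), 2 / 3)
  expect_equal(unname(r$lowest["N1"]), 1 / 3)
  expect_equal(unname(r$highest["N1"]), 2 / 3)
  expect_equal(sum(r$lowest), 1)
  expect_length(r$ties_lowest, 0)

  # degenerate: all treatments tied in every variety, flagged
  tied <- tab; tied$coverage <- 10
  rt <- treatment_ranking_summary(tied)
  expect_true(all(rt$lowest == 1))
  expect_length(rt$ties_lowest, 3)

  set.seed(66)
  for (i in 1:10) {
    m <- matrix(runif(5 * 3, 0, 20), 5, 3,
                dimnames = list(paste0("v", 1:5), paste0("N", 1:3)))
    r2 <- treatment_ranking_summary(m)
    lo <- colSums(t(apply(m, 1, function(x) x == min(x)))) / 5
    hi <- colSums(t(apply(m, 1, function(x) x == max(x)))) / 5
    expect_equal(unname(r2$lowest), unname(lo))
    expect_equal(unname(r2$highest), unname(hi))
  }

  bad <- tab[-2, ]
  expect_error(treatment_ranking_summary(bad), "missing")
})
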