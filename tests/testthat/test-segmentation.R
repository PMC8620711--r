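test_that("Otsu threshold matches the exhaustive-search oracle on random histograms", {
  set.seed(7)
  for (i in 1:200) {
    h <- integer(256)
    # bimodal-ish mixtures plus occasional uniform noise, the regimes the
    # pipeline actually meets
    k <- sample(2:5, 1)
    centers <- sample(0:255, k)
    for (c0 in centers) {
      lv <- pmin(255, pmax(0, round(rnorm(sample(20:200, 1), c0, sample(2:20, 1)))))
      tab <- tabulate(lv + 1L, 256L)
      h <- h + tab
    }
    if (runif(1) < 0.3) h <- h + tabulate(sample(0:255, 50, TRUE) + 1L, 256L)
    expect_identical(otsu_threshold(h), otsu_oracle(h))
  }
})

test_that("degenerate and two-level histograms threshold as specified", {
  h <- integer(256); h[101] <- 17L        # all mass at level 100
  expect_identical(otsu_threshold(h), 100L)
  h2 <- integer(256); h2[11] <- 8L; h2[201] <- 8L
  t <- otsu_threshold(h2)
  expect_identical(t, otsu_oracle(h2))
  gray <- matrix(c(rep(10L, 8), rep(200L, 8)), 4, 4)
  mask <- binarize(gray, t)
  expect_equal(sum(mask), 8L)             # the 8 bright pixels are foreground
  expect_true(all(mask[gray == 200L]))
  expect_error(otsu_threshold(integer(256)), "empty")
})

test_that("binarize splits at the threshold with the upper class as plant", {
  expect_false(any(binarize(matrix(0L, 4, 4), 0)))
  expect_true(all(binarize(matrix(255L, 4, 4), 0)))
  g <- matrix(c(10L, 200L), 1, 2)
  m <- binarize(g, otsu_threshold(gray_histogram(g)))
  expect_equal(as.vector(m), c(FALSE, TRUE))
  expect_error(binarize(g, 300), "threshold")
})

test_that("clean_mask removes small specks, fills holes, and is idempotent", {
  m <- matrix(FALSE, 20, 20)
  m[3:5, 3] <- TRUE                         # 3-px speck
  expect_false(any(clean_mask(m, min_object_px = 5, fill_holes = FALSE)))
  expect_identical(clean_mask(m, min_object_px = 0, fill_holes = FALSE), m)

  ring <- matrix(FALSE, 20, 20)
  ring[5:12, 5:12] <- TRUE; ring[8:9, 8:9] <- FALSE
  filled <- clean_mask(ring, min_object_px = 0, fill_holes = TRUE)
  expect_true(all(filled[5:12, 5:12]))

  set.seed(5)
  for (i in 1:10) {
    r <- matrix(runif(400) < 0.3, 20, 20)
    once <- clean_mask(r, 4, TRUE)
    expect_identical(clean_mask(once, 4, TRUE), once)
  }
  expect_error(clean_mask(m, min_object_px = -1), "non-negative")
})

test_that("clean_mask treats diagonal-only neighbors as one component", {
  m <- matrix(FALSE, 10, 10)
  # staircase of 6 diagonally-linked pixels: one 8-connected component
  for (i in 1:6) m[i, i] <- TRUE
  kept <- clean_mask(m, min_object_px = 5, fill_holes = FALSE)
  expect_identical(kept, m)
})

test_that("extract_roi counts 8-connected components and blanks the background", {
  img <- solid_img(50, 120, 60, 12, 12)
  empty <- extract_roi(matrix(FALSE, 12, 12), img)
  expect_equal(empty$n_components, 0L)
  expect_true(all(empty$masked == 0L))

  m <- matrix(FALSE, 12, 12)
  m[2:4, 2:4] <- TRUE; m[8:10, 8:11] <- TRUE
  roi <- extract_roi(m, img)
  expect_equal(roi$n_components, 2L)
  expect_equal(length(roi$contours), 2L)
  expect_true(all(roi$masked[, , 2][m] == 120L))
  expect_true(all(roi$masked[, , 2][!m] == 0L))
  expect_error(extract_roi(matrix(FALSE, 3, 3), img), "dimensions")
})

test_that("segment recovers blade pixels on well-separated synthetic scenes", {
  sc <- generate_scene(scene_params(target_coverage_pct = 10, seed = 101,
                                    noise_sd = 0, illumination_jitter = 0))
  seg <- segment(sc$image)
  agree <- mean(seg$mask == sc$plant_truth)
  expect_gte(agree, 0.99)
  expect_identical(segment(sc$image)$mask, seg$mask)  # determinism

  soil <- generate_scene(scene_params(target_coverage_pct = 0, seed = 17))
  expect_lte(coverage(segment(soil$image)$mask)$coverage_pct, 1)
})

test_that("adding soil area does not flip blade pixels on clean scenes", {
  sc <- generate_scene(scene_params(width = 160, height = 160,
                                    target_coverage_pct = 12, seed = 9,
                                    noise_sd = 0, illumination_jitter = 0))
  seg1 <- segment(sc$image)
  # pad the scene with more soil-colored border
  pad <- 40
  big <- array(0L, c(160 + 2 * pad, 160 + 2 * pad, 3))
  soil_col <- as.integer(sc$params$soil_palette[1, ])
  for (ch in 1:3) big[, , ch] <- soil_col[ch]
  big[pad + 1:160, pad + 1:160, ] <- sc$image
  seg2 <- segment(big)
  inner <- seg2$mask[pad + 1:160, pad + 1:160]
  blades <- sc$plant_truth & seg1$mask
  expect_gte(mean(inner[blades]), 0.999)
})
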