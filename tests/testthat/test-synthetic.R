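test_that("scenes are deterministic under a fixed seed and leave the RNG alone", {
  p <- scene_params(width = 128, height = 128, target_coverage_pct = 8,
                    seed = 123)
  set.seed(1); before <- runif(1)
  a <- generate_scene(p)
  b <- generate_scene(p)
  expect_identical(a$image, b$image)
  expect_identical(a$plant_truth, b$plant_truth)
  set.seed(1); expect_identical(runif(1), before)
  # a different seed gives a different field
  c <- generate_scene(scene_params(width = 128, height = 128,
                                   target_coverage_pct = 8, seed = 124))
  expect_false(identical(a$image, c$image))
})

test_that("zero-coverage scenes have no blades and empty truths", {
  sc <- generate_scene(scene_params(target_coverage_pct = 0, seed = 2,
                                    width = 96, height = 96))
  expect_equal(sc$true_coverage_pct, 0)
  expect_false(any(sc$plant_truth))
  expect_false(any(sc$withered_truth))
})

test_that("true coverage lands within 0.5 points of target across a sweep", {
  for (target in c(2, 8, 18, 40)) {
    sc <- generate_scene(scene_params(width = 160, height = 160,
                                      target_coverage_pct = target,
                                      seed = target + 1))
    expect_gte(sc$true_coverage_pct, target)
    expect_lte(sc$true_coverage_pct, target + 0.5)
    # truth arithmetic is exact by construction
    expect_equal(sc$true_coverage_pct,
                 100 * sum(sc$plant_truth) / length(sc$plant_truth))
  }
})

test_that("withered tips occupy the requested share of blade pixels, disjoint from plant truth", {
  sc <- generate_scene(scene_params(target_coverage_pct = 12,
                                    withered_tip_fraction = 0.1, seed = 31))
  expect_false(any(sc$plant_truth & sc$withered_truth))
  share <- sum(sc$withered_truth) /
    (sum(sc$plant_truth) + sum(sc$withered_truth))
  expect_lt(abs(share - 0.1), 0.02)
})

test_that("blades and soil are separable in ExV by at least 0.5 under default palettes", {
  sc <- generate_scene(scene_params(target_coverage_pct = 15, seed = 77))
  exv <- excess_veg(normalize_rgb(sc$image))$values
  soil <- !(sc$plant_truth | sc$withered_truth)
  expect_gte(mean(exv[sc$plant_truth]) - mean(exv[soil]), 0.5)
})

test_that("generate_experiment emits one image per plot-image slot plus a truth table", {
  dir <- withr::local_tempdir()
  lay <- tiny_layout(nv = 2, reps = 1, imgs = 2)
  truth <- generate_experiment(lay, dir, seed = 3, width = 96, height = 96)
  pngs <- list.files(dir, pattern = "\\.png$")
  expect_equal(length(pngs), count_images(lay))
  expect_equal(nrow(truth), count_images(lay))
  expect_true(file.exists(file.path(dir, "truth.csv")))
  expect_true(all(truth$true_grade %in% 1:4))
  # filenames follow the pipeline convention and map back to plots
  expect_true(all(truth$image %in% pngs))
  # per-plot targets: all images of a plot share a grade
  per_plot <- tapply(truth$true_grade, truth$plot_id, function(x) length(unique(x)))
  expect_true(all(per_plot == 1))

  one <- withr::local_tempdir()
  lay1 <- experiment_layout("A", list(nitrogen_treatment("N1", 0)),
                            replicates = 1, images_per_plot = 1)
  t1 <- generate_experiment(lay1, one, seed = 4, width = 64, height = 64)
  expect_equal(nrow(t1), 1L)
  expect_equal(length(list.files(one, pattern = "\\.png$")), 1L)
})

test_that("the default experiment design implies the full 2304-image batch", {
  # counts are closed-form; image emission is exercised on small layouts
  lay <- default_layout()
  expect_equal(count_images(lay), 2304L)
  expect_equal(nrow(enumerate_plots(lay)) * lay$images_per_plot, 2304L)
})

test_that("written scenes survive a PNG round trip bit-exactly", {
  sc <- generate_scene(scene_params(width = 80, height = 80,
                                    target_coverage_pct = 10, seed = 55))
  f <- withr::local_tempfile(fileext = ".png")
  write_rgb_png(sc$image, f)
  back <- read_rgb_image(f)
  expect_identical(back, sc$image)
  fm <- withr::local_tempfile(fileext = ".png")
  write_mask_png(sc$plant_truth, fm)
  expect_identical(read_mask_png(fm), sc$plant_truth)
})
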