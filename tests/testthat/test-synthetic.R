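test_that("tile generation hits the cellularity target and partitions pixels", {
  for (target in c(10, 30, 50, 70, 95)) {
    tile <- generate_tile(tile_spec(
      tile_size = 64, target_cellularity = target,
      ignore_fraction = 0.15, seed = 100 + target
    ))
    m <- tile$mask
    counts <- c(sum(m == 0L), sum(m == 1L), sum(m == 2L))
    expect_identical(sum(counts), 64L * 64L)
    expect_lt(abs(mask_cellularity(m) - target), 5)
    expect_equal(dim(tile$image), c(64L, 64L, 3L))
    expect_true(all(tile$image >= 0 & tile$image <= 1))
  }
})

test_that("degenerate cellularity targets give pure-class tiles", {
  all_h <- generate_tile(tile_spec(tile_size = 64, target_cellularity = 100,
                                   ignore_fraction = 0, seed = 1))
  expect_true(all(all_h$mask == 0L))
  expect_equal(all_h$true_cellularity, 100)
  all_a <- generate_tile(tile_spec(tile_size = 64, target_cellularity = 0,
                                   ignore_fraction = 0, seed = 1))
  expect_true(all(all_a$mask == 1L))
  expect_equal(all_a$true_cellularity, 0)
})

test_that("tile generation is bit-identical given the same seed", {
  s <- tile_spec(tile_size = 64, target_cellularity = 70,
                 ignore_fraction = 0.1, seed = 1)
  expect_identical(generate_tile(s), generate_tile(s))
})

test_that("invalid tile specs name the offending field", {
  expect_error(tile_spec(target_cellularity = 130), "target_cellularity",
               class = "mm_validation_error")
  expect_error(tile_spec(tile_size = 16), "tile_size",
               class = "mm_validation_error")
  expect_error(tile_spec(ignore_fraction = 0.5), "ignore_fraction",
               class = "mm_validation_error")
  expect_error(tile_spec(adipocyte_radius_range = c(10, 5)),
               "adipocyte_radius_range", class = "mm_validation_error")
})

test_that("slide truth is mask-derived and close to target across seeds", {
  targets <- withr::with_seed(7, runif(20, 10, 95))
  for (i in seq_along(targets)) {
    sl <- generate_slide(slide_spec(128, 128, target_cellularity = targets[i],
                                    scale = 0.25, seed = 200 + i))
    expect_identical(sum(sl$mask == 0L) + sum(sl$mask == 1L) + sum(sl$mask == 2L),
                     128L * 128L)
    expect_equal(sl$true_cellularity, mask_cellularity(sl$mask))
    expect_lt(abs(sl$true_cellularity - targets[i]), 5)
  }
})

test_that("slide generation handles boundary targets and is deterministic", {
  s <- slide_spec(96, 96, target_cellularity = 100, scale = 0.25, seed = 5)
  expect_equal(generate_slide(s)$true_cellularity, 100)
  s50 <- slide_spec(128, 160, target_cellularity = 50, scale = 0.25, seed = 6)
  expect_identical(generate_slide(s50)$true_cellularity,
                   generate_slide(s50)$true_cellularity)
  expect_error(slide_spec(16, 128), class = "mm_validation_error")
})

test_that("rescan keeps geometry, bounds colour shifts, and is deterministic", {
  sl <- fixture_slide(60, seed = 31, size = 128)
  ref <- rescan_variant(sl$image, "reference", seed = 1)
  expect_identical(ref, sl$image)
  alt <- rescan_variant(sl$image, "alt", seed = 1)
  expect_identical(dim(alt), dim(sl$image))
  for (c in 1:3) {
    shift <- abs(mean(alt[, , c]) - mean(sl$image[, , c])) * 255
    expect_lt(shift, 15)
  }
  expect_identical(alt, rescan_variant(sl$image, "alt", seed = 1))
  expect_false(identical(alt, rescan_variant(sl$image, "alt", seed = 2)))
})

test_that("rater simulation rounds half-up to the reporting increment", {
  p0 <- rater_profile(bias = 0, noise_sd = 0, rounding_increment = 5, seed = 1)
  expect_equal(simulate_rater(62, p0), 60)
  expect_equal(simulate_rater(62.5, p0), 65)
  multiples <- seq(0, 100, by = 5)
  expect_equal(simulate_rater(multiples, p0), multiples)
  expect_error(simulate_rater(c(20, 104), p0), class = "mm_validation_error")
  expect_error(rater_profile(rounding_increment = 0), class = "mm_validation_error")
})

test_that("noiseless unbiased rating with a vanishing increment is the identity", {
  x <- withr::with_seed(3, runif(25, 0, 100))
  p <- rater_profile(bias = 0, noise_sd = 0, rounding_increment = 1e-6, seed = 1)
  expect_equal(simulate_rater(x, p), x, tolerance = 1e-5)
})

test_that("rater noise and bias shift ratings as configured", {
  truth <- rep(50, 400)
  biased <- simulate_rater(truth, rater_profile(bias = 10, noise_sd = 0, seed = 2))
  expect_equal(unique(biased), 60)
  noisy <- simulate_rater(truth, rater_profile(bias = 0, noise_sd = 8, seed = 2))
  expect_true(all(noisy %% 5 == 0))
  expect_gt(sd(noisy), 4)
  expect_lt(abs(mean(noisy) - 50), 2)
})

test_that("training-set writer produces decodable matched pairs with sidecars", {
  dir <- withr::local_tempdir()
  synth_training_set(dir, n_tiles = 6, tile_size = 64, seed = 9)
  imgs <- list.files(file.path(dir, "images"), pattern = "\\.png$")
  labs <- list.files(file.path(dir, "labels"), pattern = "\\.png$")
  expect_length(imgs, 6)
  expect_length(labs, 6)
  sidecar <- jsonlite::read_json(
    file.path(dir, "labels", "tile_0001.json"), simplifyVector = TRUE
  )
  mask <- decode_label_png(file.path(dir, "labels", "tile_0001.png"))
  expect_equal(sidecar$true_cellularity, mask_cellularity(mask))
})
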