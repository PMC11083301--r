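# Shared fixtures, built once per test session.
#
# The segmentation fixture emulates the study design at desk scale: 64-px
# tiles (quarter of the 256-px/20x patches, with texture geometry scaled
# accordingly), 200 training tiles spanning 5-95% cellularity, and a compact
# FCN trained for 10 epochs with mild colour jitter. Training takes on the
# order of a minute, so the model is cached and reused across test files.

.fixture_cache <- new.env(parent = emptyenv())

fixture_tile_size <- 64L
fixture_scale <- fixture_tile_size / 256
fixture_seed <- 42L

fixture_training_dir <- function() {
  if (is.null(.fixture_cache$dir)) {
    dir <- file.path(tempdir(), "mm_fixture_trainset")
    synth_training_set(dir, n_tiles = 200, tile_size = fixture_tile_size,
                       seed = fixture_seed)
    .fixture_cache$dir <- dir
  }
  .fixture_cache$dir
}

fixture_manifest <- function() {
  if (is.null(.fixture_cache$manifest)) {
    .fixture_cache$manifest <- build_manifest(fixture_training_dir(),
                                              val_fraction = 0.2,
                                              seed = fixture_seed)
  }
  .fixture_cache$manifest
}

fixture_config <- function(epochs = 10L) {
  model_config(
    backbone = "small_cnn", input_size = fixture_tile_size, epochs = epochs,
    learning_rate = 2e-3, batch_size = 4L, color_jitter = 0.02,
    seed = fixture_seed
  )
}

# trained model + history (10 epochs, mild colour jitter)
fixture_fit <- function() {
  if (is.null(.fixture_cache$fit)) {
    .fixture_cache$fit <- train_model(build_model(fixture_config()),
                                      fixture_manifest())
  }
  .fixture_cache$fit
}

fixture_model <- function() fixture_fit()$model

fixture_slide <- function(target, seed, size = 256L, profile = "reference") {
  generate_slide(slide_spec(
    width = size, height = size, target_cellularity = target,
    scanner_profile = profile, scale = fixture_scale, seed = seed
  ))
}

# small helper for quick random label masks
random_mask <- function(h, w, seed = 1L) {
  withr::with_seed(seed, label_mask(matrix(sample(0:2, h * w, TRUE), h, w)))
}
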