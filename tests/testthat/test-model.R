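test_that("model output has the contracted shape and softmax rows sum to 1", {
  m <- build_model(model_config(backbone = "small_cnn", input_size = 64, seed = 1))
  tile <- withr::with_seed(1, array(runif(64 * 64 * 3), dim = c(64, 64, 3)))
  prob <- predict_probabilities(m, tile)
  expect_equal(dim(prob), c(64L, 64L, 2L))
  expect_true(all(abs(prob[, , 1] + prob[, , 2] - 1) < 1e-5))
  expect_gt(m$n_params, 0)
})

test_that("inception-style backbone maps 256-px tiles to 256x256x2", {
  m <- build_model(model_config(backbone = "inception_mixed7",
                                input_size = 256, seed = 1))
  tile <- withr::with_seed(2, array(runif(256 * 256 * 3), dim = c(256, 256, 3)))
  prob <- predict_probabilities(m, tile)
  expect_equal(dim(prob), c(256L, 256L, 2L))
  expect_true(all(abs(prob[, , 1] + prob[, , 2] - 1) < 1e-5))
})

test_that("incompatible input sizes report the required divisibility", {
  expect_error(build_model(model_config(input_size = 66)), "divisible by 4",
               class = "mm_validation_error")
  expect_error(build_model(model_config(backbone = "inception_mixed7",
                                        input_size = 72)),
               "divisible by 16", class = "mm_validation_error")
})

test_that("analytic gradients match numeric differentiation on a tiny net", {
  mm <- asNamespace("marrowmeter")
  cfg <- model_config(input_size = 8, seed = 3)
  m <- build_model(cfg)
  x <- withr::with_seed(9, array(runif(8 * 8 * 3), dim = c(8, 8, 3)))
  mask <- random_mask(8, 8, 4)
  loss_of <- function(model) {
    mm$masked_softmax_ce(mm$forward_logits(model, x)$logits, mask)$loss
  }
  fwd <- mm$forward_logits(m, x, keep_cache = TRUE)
  ce <- mm$masked_softmax_ce(fwd$logits, mask)
  g <- mm$backprop(m$layers, fwd$caches, ce$dlogits)
  eps <- 1e-6
  base <- loss_of(m)
  idx <- withr::with_seed(5, lapply(seq_along(m$layers), function(li) {
    sample(length(m$layers[[li]]$W), 3)
  }))
  for (li in seq_along(m$layers)) {
    for (i in idx[[li]]) {
      m2 <- m
      m2$layers[[li]]$W[i] <- m2$layers[[li]]$W[i] + eps
      num <- (loss_of(m2) - base) / eps
      ana <- g[[li]]$dW[i]
      expect_lt(abs(num - ana) / max(1e-6, abs(num) + abs(ana)), 1e-3)
    }
  }
})

test_that("masked loss has its closed forms and ignores the ignore class", {
  mask <- label_mask(matrix(c(0L, 1L, 2L, 0L), 2, 2))
  # perfect one-hot predictions -> loss 0
  perfect <- array(0, dim = c(2, 2, 2))
  perfect[, , 1] <- (mask == 0L) * 1
  perfect[, , 2] <- 1 - perfect[, , 1]
  expect_equal(masked_loss(perfect, mask), 0, tolerance = 1e-9)
  # uniform predictions -> ln 2 regardless of labels
  uniform <- array(0.5, dim = c(8, 8, 2))
  for (seed in 1:3) {
    expect_equal(masked_loss(uniform, random_mask(8, 8, seed)), log(2),
                 tolerance = 1e-12)
  }
  # predicted probabilities at ignored pixels are irrelevant
  prob <- withr::with_seed(5, {
    p1 <- matrix(runif(64), 8, 8)
    array(c(p1, 1 - p1), dim = c(8, 8, 2))
  })
  m1 <- random_mask(8, 8, 7)
  prob2 <- prob
  ign <- unclass(m1) == 2L
  for (k in 1:2) {
    ch <- prob2[, , k]
    ch[ign] <- withr::with_seed(k, runif(sum(ign)))
    prob2[, , k] <- ch
  }
  expect_identical(masked_loss(prob2, m1), masked_loss(prob, m1))
  # all-ignore mask -> 0 with warning
  expect_warning(l0 <- masked_loss(uniform, label_mask(matrix(2L, 8, 8))),
                 "ignored")
  expect_equal(l0, 0)
  # shape mismatch
  expect_error(masked_loss(uniform, label_mask(matrix(0L, 4, 4))),
               "shape mismatch", class = "mm_validation_error")
})

test_that("ignored pixels contribute neither loss nor gradient", {
  mm <- asNamespace("marrowmeter")
  logits <- withr::with_seed(11, array(rnorm(8 * 8 * 2), dim = c(8, 8, 2)))
  mask <- matrix(2L, 8, 8)
  mask[1:4, ] <- withr::with_seed(12, matrix(sample(0:1, 32, TRUE), 4, 8))
  out <- mm$masked_softmax_ce(logits, mask)
  # gradient vanishes exactly on the ignored half
  expect_true(all(out$dlogits[5:8, , ] == 0))
  # perturbing logits on the ignored half changes neither loss nor gradient
  logits2 <- logits
  logits2[5:8, , ] <- withr::with_seed(13, rnorm(8 * 4 * 2))
  out2 <- mm$masked_softmax_ce(logits2, mask)
  expect_identical(out2$loss, out$loss)
  expect_identical(out2$dlogits[1:4, , ], out$dlogits[1:4, , ])
  # the loss equals the unmasked loss computed on the valid half alone
  sub <- mm$masked_softmax_ce(logits[1:4, , , drop = FALSE], mask[1:4, ])
  expect_equal(out$loss, sub$loss, tolerance = 1e-12)
})

test_that("argmax prediction breaks ties toward the hematopoietic class", {
  mm <- asNamespace("marrowmeter")
  cfg <- model_config(input_size = 8, seed = 1)
  m <- build_model(cfg)
  # zero the classifier so logits tie everywhere
  last <- length(m$layers)
  m$layers[[last]]$W[] <- 0
  m$layers[[last]]$b[] <- 0
  tile <- withr::with_seed(3, array(runif(8 * 8 * 3), dim = c(8, 8, 3)))
  pred <- predict_tile(m, tile)
  expect_true(all(pred == 0L))
  # and a hard bias toward adipose flips every pixel
  m$layers[[last]]$b <- c(-5, 5)
  expect_true(all(predict_tile(m, tile) == 1L))
  expect_error(predict_tile(m, array(0, dim = c(16, 16, 3))),
               class = "mm_validation_error")
})

test_that("short training runs are deterministic and usually reduce the loss", {
  dir <- withr::local_tempdir()
  synth_training_set(dir, n_tiles = 20, tile_size = 64, seed = 77)
  man <- build_manifest(dir, val_fraction = 0.2, seed = 77)
  non_increasing <- 0L
  for (seed in 1:10) {
    cfg <- model_config(backbone = "small_cnn", input_size = 64, epochs = 2,
                        learning_rate = 2e-3, batch_size = 4, seed = seed)
    fit <- train_model(build_model(cfg), man)
    expect_equal(nrow(fit$history), 2)
    if (fit$history$train_loss[2] <= fit$history$train_loss[1]) {
      non_increasing <- non_increasing + 1L
    }
  }
  expect_gte(non_increasing, 8L)
  # determinism: identical seed, identical final loss
  cfg <- model_config(backbone = "small_cnn", input_size = 64, epochs = 2,
                      learning_rate = 2e-3, batch_size = 4, seed = 1)
  f1 <- train_model(build_model(cfg), man)
  f2 <- train_model(build_model(cfg), man)
  expect_identical(f1$history$train_loss, f2$history$train_loss)
  expect_identical(f1$model$layers, f2$model$layers)
})

test_that("the trained fixture model reaches high masked validation accuracy", {
  fit <- fixture_fit()
  n <- nrow(fit$history)
  expect_gte(fit$history$val_acc[n], 0.95)
  # loss falls by at least an order of magnitude over the schedule
  expect_gte(fit$history$train_loss[1] / fit$history$train_loss[n], 10)
})

test_that("a trained model classifies pure-class tiles correctly", {
  model <- fixture_model()
  pure_a <- generate_tile(tile_spec(tile_size = 64, target_cellularity = 0,
                                    ignore_fraction = 0, seed = 5))
  expect_gte(mean(predict_tile(model, pure_a$image) == 1L), 0.95)
  pure_h <- generate_tile(tile_spec(tile_size = 64, target_cellularity = 100,
                                    ignore_fraction = 0, seed = 6))
  expect_gte(mean(predict_tile(model, pure_h$image) == 0L), 0.95)
})

test_that("model checkpoints round-trip through disk", {
  model <- fixture_model()
  path <- withr::local_tempfile(fileext = ".rds")
  save_model(model, path)
  expect_true(file.exists(paste0(path, ".json")))
  m2 <- load_model(path)
  tile <- generate_tile(tile_spec(tile_size = 64, target_cellularity = 40,
                                  seed = 8))$image
  expect_identical(predict_tile(m2, tile), predict_tile(model, tile))
})
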