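#' Segmentation model configuration
#'
#' The network is a fully convolutional encoder-decoder ending in a 1x1
#' convolution with per-pixel softmax over two tissue classes (hematopoietic,
#' adipose). The ignore class exists only in the labels and the loss mask; it
#' is never a prediction target. Two backbones are available:
#'
#' * `"small_cnn"` (default): three convolutional blocks with two stride-2
#'   downsampling steps (overall factor 4) and a mirrored transposed-conv
#'   decoder. Compact enough to train on a desktop CPU in minutes.
#' * `"inception_mixed7"`: a deeper, randomly initialized sequential encoder
#'   with overall downsampling factor 16 (the stride an InceptionV3 trunk
#'   reaches at its mixed7 stage on 256-px tiles), followed by a
#'   `decoder_layers`-layer custom decoder. No pretrained weights are bundled.
#'
#' Training uses the Adam optimizer with ignore-masked categorical
#' cross-entropy. No data augmentation is applied unless `color_jitter` > 0,
#' which adds a uniform per-channel offset in `[-color_jitter, color_jitter]`
#' to each training tile (a cheap proxy for stain/scanner variation).
#'
#' @param backbone `"small_cnn"` or `"inception_mixed7"`.
#' @param input_size Tile edge in pixels (default 256); must be divisible by
#'   the backbone's downsampling factor (4 or 16).
#' @param epochs Training epochs (default 25).
#' @param learning_rate Adam learning rate (default 1e-3).
#' @param batch_size Minibatch size.
#' @param decoder_layers Number of main decoder layers for the
#'   `inception_mixed7` backbone (>= 5; default 9: four x2 upsampling
#'   transposed convs, interleaved convs, and the final 1x1 classifier).
#' @param color_jitter Half-width of the uniform per-channel training-time
#'   colour jitter, in `[0,1]` intensity units (0 = off, the default).
#' @param presmooth_sigma Gaussian pre-smoothing applied to every input tile,
#'   identically at training and inference (pixels; default 0.5; 0 = off).
#'   Decisions then rest on local colour context rather than pixel-level
#'   sharpness, which stabilises cellularity across scanner point-spread
#'   differences.
#' @param seed Integer seed for weight initialization and batch shuffling.
#' @return A `model_config` list. `n_classes` is fixed at 2.
#' @export
model_config <- function(backbone = c("small_cnn", "inception_mixed7"),
                         input_size = 256L, epochs = 25L,
                         learning_rate = 1e-3, batch_size = 8L,
                         decoder_layers = 9L, color_jitter = 0,
                         presmooth_sigma = 0.5, seed = 1L) {
  backbone <- match.arg(backbone)
  assert_number(input_size, "input_size", 8, 4096)
  assert_number(epochs, "epochs", 1, 1e4)
  assert_number(learning_rate, "learning_rate", 1e-8, 1)
  assert_number(batch_size, "batch_size", 1, 1024)
  assert_number(decoder_layers, "decoder_layers", 1, 64)
  assert_number(color_jitter, "color_jitter", 0, 0.5)
  assert_number(presmooth_sigma, "presmooth_sigma", 0, 5)
  assert_number(seed, "seed")
  structure(list(
    backbone = backbone, input_size = as.integer(input_size),
    n_classes = 2L, epochs = as.integer(epochs),
    learning_rate = learning_rate, batch_size = as.integer(batch_size),
    decoder_layers = as.integer(decoder_layers), color_jitter = color_jitter,
    presmooth_sigma = presmooth_sigma, seed = as.integer(seed)
  ), class = "model_config")
}

# ---- layer constructors -----------------------------------------------------

he_init <- function(nr, nc, fan_in) {
  matrix(rnorm(nr * nc, 0, sqrt(2 / fan_in)), nr, nc)
}

new_conv <- function(cin, cout, k = 3L, stride = 1L, act = "relu") {
  pad <- (k - 1L) %/% 2L
  list(
    kind = "conv", k = k, stride = stride, pad = pad, act = act,
    W = he_init(k * k * cin, cout, k * k * cin), b = numeric(cout)
  )
}

# transposed conv (x2 upsampling); weights have the underlying-conv layout
# (k*k*cout) x cin so the forward pass is the conv input-gradient kernel
new_tconv <- function(cin, cout, k = 3L, stride = 2L, act = "relu") {
  pad <- (k - 1L) %/% 2L
  list(
    kind = "tconv", k = k, stride = stride, pad = pad, act = act,
    W = he_init(k * k * cout, cin, k * k * cin), b = numeric(cout)
  )
}

backbone_stride <- function(backbone) {
  switch(backbone, small_cnn = 4L, inception_mixed7 = 16L)
}

#' Build the fully convolutional segmentation network
#'
#' Maps an `input_size x input_size x 3` RGB tile to per-pixel probabilities
#' over the two tissue classes (`input_size x input_size x 2`, rows summing to
#' 1 via softmax). Weights are randomly initialized (He) from the config seed.
#'
#' @param config A [model_config()].
#' @return A `marrow_fcn` model object; `print()` reports the parameter count.
#' @export
build_model <- function(config) {
  if (!inherits(config, "model_config")) stop_validation("'config' must be a model_config")
  f <- backbone_stride(config$backbone)
  if (config$input_size %% f != 0L) {
    stop_validation(sprintf(
      "input_size %d is incompatible with backbone '%s': it must be divisible by %d",
      config$input_size, config$backbone, f
    ))
  }
  layers <- with_seed(config$seed, {
    if (config$backbone == "small_cnn") {
      list(
        new_conv(3L, 12L),                # block 1
        new_conv(12L, 24L, stride = 2L),  # block 2 (x2 down)
        new_conv(24L, 24L),
        new_conv(24L, 48L, stride = 2L),  # block 3 (x2 down)
        new_conv(48L, 48L),
        new_tconv(48L, 24L),              # decoder mirrors the two-conv blocks
        new_conv(24L, 24L),
        new_tconv(24L, 12L),
        new_conv(12L, 12L),
        new_conv(12L, 2L, k = 1L, act = "linear")
      )
    } else {
      enc <- list(
        new_conv(3L, 16L, stride = 2L),
        new_conv(16L, 24L),
        new_conv(24L, 32L, stride = 2L),
        new_conv(32L, 48L),
        new_conv(48L, 64L, stride = 2L),
        new_conv(64L, 96L),
        new_conv(96L, 128L, stride = 2L),
        new_conv(128L, 128L)
      )
      # decoder: 4 transposed convs for x16 upsampling, interleaved convs,
      # final 1x1 classifier; decoder_layers >= 5
      if (config$decoder_layers < 5L) {
        stop_validation("'decoder_layers' must be >= 5 for inception_mixed7 (4 upsampling steps + classifier)")
      }
      chans <- c(128L, 96L, 64L, 32L, 16L)
      n_inter <- config$decoder_layers - 5L
      dec <- list()
      for (i in 1:4) {
        dec <- c(dec, list(new_tconv(chans[i], chans[i + 1L])))
        if (n_inter > 0L) {
          dec <- c(dec, list(new_conv(chans[i + 1L], chans[i + 1L])))
          n_inter <- n_inter - 1L
        }
      }
      dec <- c(dec, list(new_conv(16L, 2L, k = 1L, act = "linear")))
      c(enc, dec)
    }
  })
  n_params <- sum(vapply(layers, function(l) length(l$W) + length(l$b), numeric(1)))
  structure(list(config = config, layers = layers, n_params = n_params),
            class = "marrow_fcn")
}

#' @export
print.marrow_fcn <- function(x, ...) {
  cat(sprintf(
    "<marrow_fcn> backbone %s, input %dx%d, %d layers, %s parameters\n",
    x$config$backbone, x$config$input_size, x$config$input_size,
    length(x$layers), format(x$n_params, big.mark = ",")
  ))
  invisible(x)
}

# ---- forward / backward -----------------------------------------------------

layer_forward <- function(layer, x) {
  if (layer$kind == "conv") {
    z <- nn_conv_fw(x, layer$W, layer$b, layer$k, layer$stride, layer$pad)
  } else {
    hout <- dim(x)[1] * layer$stride
    wout <- dim(x)[2] * layer$stride
    z <- nn_conv_gx(x, layer$W, layer$k, layer$stride, layer$pad, hout, wout)
    z <- sweep(z, 3L, layer$b, "+")
  }
  a <- if (layer$act == "relu") pmax(z, 0) else z
  list(a = a, z = z, x = x)
}

layer_backward <- function(layer, cache, da) {
  dz <- if (layer$act == "relu") da * (cache$z > 0) else da
  if (layer$kind == "conv") {
    g <- nn_conv_gw(cache$x, dz, layer$k, layer$stride, layer$pad)
    dx <- nn_conv_gx(dz, layer$W, layer$k, layer$stride, layer$pad,
                     dim(cache$x)[1], dim(cache$x)[2])
    list(dx = dx, dW = g$dW, db = g$db)
  } else {
    # tconv forward is the conv input-gradient, so roles swap in the backward
    g <- nn_conv_gw(dz, cache$x, layer$k, layer$stride, layer$pad)
    dx <- nn_conv_fw(dz, layer$W, numeric(ncol(layer$W)),
                     layer$k, layer$stride, layer$pad)
    list(dx = dx, dW = g$dW, db = apply(dz, 3L, sum))
  }
}

forward_logits <- function(model, x, keep_cache = FALSE) {
  caches <- if (keep_cache) vector("list", length(model$layers))
  for (i in seq_along(model$layers)) {
    out <- layer_forward(model$layers[[i]], x)
    if (keep_cache) caches[[i]] <- out
    x <- out$a
  }
  list(logits = x, caches = caches)
}

softmax2 <- function(logits) {
  m <- pmax(logits[, , 1], logits[, , 2])
  e1 <- exp(logits[, , 1] - m)
  e2 <- exp(logits[, , 2] - m)
  s <- e1 + e2
  array(c(e1 / s, e2 / s), dim = dim(logits))
}

# loss, accuracy and logit gradient over non-ignored pixels
masked_softmax_ce <- function(logits, mask) {
  prob <- softmax2(logits)
  valid <- mask != 2L
  n_valid <- sum(valid)
  if (n_valid == 0L) {
    return(list(loss = 0, acc = NA_real_, dlogits = array(0, dim(logits)), prob = prob))
  }
  p_true <- ifelse(mask == 0L, prob[, , 1], prob[, , 2])
  loss <- -mean(log(pmax(p_true[valid], 1e-12)))
  pred <- (prob[, , 2] > prob[, , 1]) * 1L
  acc <- mean((pred == mask)[valid])
  y1 <- (mask == 0L) * 1
  d1 <- (prob[, , 1] - y1) * valid / n_valid
  d2 <- (prob[, , 2] - (1 - y1)) * valid / n_valid
  list(loss = loss, acc = acc, dlogits = array(c(d1, d2), dim = dim(logits)), prob = prob)
}

#' Ignore-masked categorical cross-entropy
#'
#' Mean categorical cross-entropy over the non-ignored pixels only: pixels
#' labelled with the ignore class contribute neither to the loss nor (during
#' training) to the gradient, so arbitrary relabelling inside ignore regions
#' leaves both unchanged. If every pixel is ignored the loss is defined as 0
#' with a warning.
#'
#' @param probabilities `H x W x 2` array of per-pixel class probabilities.
#' @param mask A [label_mask()] of matching spatial dimensions.
#' @return Scalar loss.
#' @export
masked_loss <- function(probabilities, mask) {
  d <- dim(probabilities)
  if (length(d) != 3L || d[3] != 2L) {
    stop_validation("'probabilities' must be an H x W x 2 array")
  }
  if (d[1] != nrow(mask) || d[2] != ncol(mask)) {
    stop_validation(sprintf(
      "shape mismatch: probabilities %dx%d vs mask %dx%d",
      d[1], d[2], nrow(mask), ncol(mask)
    ))
  }
  valid <- mask != 2L
  if (!any(valid)) {
    warning("all pixels are ignored; masked loss defined as 0")
    return(0)
  }
  p_true <- ifelse(mask == 0L, probabilities[, , 1], probabilities[, , 2])
  -mean(log(pmax(p_true[valid], 1e-12)))
}

# ---- Adam -------------------------------------------------------------------

adam_init <- function(layers) {
  lapply(layers, function(l) list(
    mW = array(0, dim(l$W)), vW = array(0, dim(l$W)),
    mb = numeric(length(l$b)), vb = numeric(length(l$b))
  ))
}

adam_step <- function(layers, state, grads, lr, t,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  bc1 <- 1 - beta1^t
  bc2 <- 1 - beta2^t
  for (i in seq_along(layers)) {
    s <- state[[i]]; g <- grads[[i]]
    s$mW <- beta1 * s$mW + (1 - beta1) * g$dW
    s$vW <- beta2 * s$vW + (1 - beta2) * g$dW^2
    layers[[i]]$W <- layers[[i]]$W - lr * (s$mW / bc1) / (sqrt(s$vW / bc2) + eps)
    s$mb <- beta1 * s$mb + (1 - beta1) * g$db
    s$vb <- beta2 * s$vb + (1 - beta2) * g$db^2
    layers[[i]]$b <- layers[[i]]$b - lr * (s$mb / bc1) / (sqrt(s$vb / bc2) + eps)
    state[[i]] <- s
  }
  list(layers = layers, state = state)
}

# ---- training ---------------------------------------------------------------

load_pairs <- function(manifest, input_size, presmooth_sigma = 0) {
  n <- nrow(manifest$pairs)
  images <- vector("list", n)
  masks <- vector("list", n)
  for (i in seq_len(n)) {
    img <- read_image(manifest$pairs$image[i])
    msk <- decode_label_png(manifest$pairs$label[i])
    if (dim(img)[1] != input_size || dim(img)[2] != input_size) {
      stop_validation(sprintf(
        "tile '%s' is %dx%d but the model input size is %d",
        manifest$pairs$stem[i], dim(img)[1], dim(img)[2], input_size
      ))
    }
    if (presmooth_sigma > 0) img <- blur_gaussian(img, presmooth_sigma)
    images[[i]] <- img
    masks[[i]] <- msk
  }
  list(images = images, masks = masks)
}

eval_set <- function(model, images, masks) {
  losses <- numeric(length(images))
  accs <- numeric(length(images))
  for (i in seq_along(images)) {
    out <- forward_logits(model, images[[i]])
    r <- masked_softmax_ce(out$logits, masks[[i]])
    losses[i] <- r$loss
    accs[i] <- r$acc
  }
  c(loss = mean(losses), acc = mean(accs, na.rm = TRUE))
}

#' Train the segmentation network
#'
#' Minibatch Adam on ignore-masked categorical cross-entropy. The run is
#' deterministic given the config seed (weight init, shuffling and colour
#' jitter all flow from it). Training aborts with a diagnostic if the loss
#' becomes non-finite.
#'
#' @param model A `marrow_fcn` from [build_model()].
#' @param manifest A `dataset_manifest` from [build_manifest()] pointing at
#'   the training tiles; its train/val split is honoured.
#' @param epochs Number of epochs (default: the model config's).
#' @param verbose Print per-epoch metrics.
#' @return List with `model` (trained) and `history`, a data.frame with one
#'   row per epoch: `epoch`, `train_loss`, `train_acc`, `val_loss`, `val_acc`
#'   (validation columns are `NA` when the manifest has no validation split).
#' @export
train_model <- function(model, manifest, epochs = NULL, verbose = FALSE) {
  if (!inherits(model, "marrow_fcn")) stop_validation("'model' must be a marrow_fcn")
  if (!inherits(manifest, "dataset_manifest")) stop_validation("'manifest' must be a dataset_manifest")
  cfg <- model$config
  epochs <- as.integer(epochs %||% cfg$epochs)
  data <- load_pairs(manifest, cfg$input_size, cfg$presmooth_sigma)
  tr <- which(manifest$split == "train")
  va <- which(manifest$split == "val")
  if (length(tr) == 0L) stop_validation("manifest has an empty training split")
  layers <- model$layers
  state <- adam_init(layers)
  t <- 0L
  hist <- data.frame(
    epoch = seq_len(epochs), train_loss = NA_real_, train_acc = NA_real_,
    val_loss = NA_real_, val_acc = NA_real_
  )
  with_seed(cfg$seed + 1L, {
    for (ep in seq_len(epochs)) {
      ord <- sample(tr)
      batch_starts <- seq(1L, length(ord), by = cfg$batch_size)
      ep_loss <- 0
      ep_acc <- 0
      ep_n <- 0L
      for (bs in batch_starts) {
        idx <- ord[bs:min(bs + cfg$batch_size - 1L, length(ord))]
        grads <- NULL
        b_loss <- 0
        for (i in idx) {
          img <- data$images[[i]]
          if (cfg$color_jitter > 0) {
            off <- runif(3, -cfg$color_jitter, cfg$color_jitter)
            for (c in 1:3) img[, , c] <- clamp01(img[, , c] + off[c])
          }
          fwd <- forward_logits(model_with(model, layers), img, keep_cache = TRUE)
          ce <- masked_softmax_ce(fwd$logits, data$masks[[i]])
          if (!is.finite(ce$loss)) {
            stop(sprintf(
              "training aborted: non-finite loss at epoch %d (tile %s); try a lower learning rate",
              ep, manifest$pairs$stem[i]
            ))
          }
          b_loss <- b_loss + ce$loss
          ep_acc <- ep_acc + if (is.na(ce$acc)) 0 else ce$acc
          g <- backprop(layers, fwd$caches, ce$dlogits)
          grads <- if (is.null(grads)) g else add_grads(grads, g)
        }
        grads <- scale_grads(grads, 1 / length(idx))
        t <- t + 1L
        upd <- adam_step(layers, state, grads, cfg$learning_rate, t)
        layers <- upd$layers
        state <- upd$state
        ep_loss <- ep_loss + b_loss
        ep_n <- ep_n + length(idx)
      }
      hist$train_loss[ep] <- ep_loss / ep_n
      hist$train_acc[ep] <- ep_acc / ep_n
      if (length(va) > 0L) {
        ev <- eval_set(model_with(model, layers), data$images[va], data$masks[va])
        hist$val_loss[ep] <- ev["loss"]
        hist$val_acc[ep] <- ev["acc"]
      }
      if (verbose) {
        message(sprintf(
          "epoch %d/%d  loss %.4f  acc %.4f  val_loss %s  val_acc %s",
          ep, epochs, hist$train_loss[ep], hist$train_acc[ep],
          formatC(hist$val_loss[ep], format = "f", digits = 4),
          formatC(hist$val_acc[ep], format = "f", digits = 4)
        ))
      }
    }
  })
  list(model = model_with(model, layers), history = hist)
}

model_with <- function(model, layers) {
  model$layers <- layers
  model
}

backprop <- function(layers, caches, dlogits) {
  grads <- vector("list", length(layers))
  da <- dlogits
  for (i in rev(seq_along(layers))) {
    bk <- layer_backward(layers[[i]], caches[[i]], da)
    grads[[i]] <- list(dW = bk$dW, db = bk$db)
    da <- bk$dx
  }
  grads
}

add_grads <- function(a, b) {
  for (i in seq_along(a)) {
    a[[i]]$dW <- a[[i]]$dW + b[[i]]$dW
    a[[i]]$db <- a[[i]]$db + b[[i]]$db
  }
  a
}

scale_grads <- function(g, s) {
  for (i in seq_along(g)) {
    g[[i]]$dW <- g[[i]]$dW * s
    g[[i]]$db <- g[[i]]$db * s
  }
  g
}

#' Per-pixel class probabilities for a tile
#'
#' @param model A trained `marrow_fcn`.
#' @param tile RGB array matching the model's input size.
#' @return `H x W x 2` array of softmax probabilities (hemato, adipose).
#' @export
predict_probabilities <- function(model, tile) {
  cfg <- model$config
  d <- dim(tile)
  if (length(d) != 3L || d[1] != cfg$input_size || d[2] != cfg$input_size || d[3] != 3L) {
    stop_validation(sprintf(
      "tile must be %dx%dx3, got %s", cfg$input_size, cfg$input_size,
      paste(d, collapse = "x")
    ))
  }
  sigma <- cfg$presmooth_sigma %||% 0
  if (sigma > 0) tile <- blur_gaussian(tile, sigma)
  softmax2(forward_logits(model, tile)$logits)
}

#' Segment a single tile
#'
#' Argmax over the two class probabilities per pixel; ties resolve to the
#' hematopoietic class (lowest class index), so prediction is deterministic.
#'
#' @inheritParams predict_probabilities
#' @return A [label_mask()] containing only hemato (0) / adipose (1) pixels.
#' @export
predict_tile <- function(model, tile) {
  prob <- predict_probabilities(model, tile)
  label_mask(matrix((prob[, , 2] > prob[, , 1]) * 1L, dim(prob)[1], dim(prob)[2]))
}

#' Save / load a trained model
#'
#' The checkpoint is a serialized model object plus a human-readable JSON
#' sidecar (`<path>.json`) recording the configuration and parameter count.
#'
#' @param model A `marrow_fcn`.
#' @param path Checkpoint path (e.g. `model.rds`).
#' @return `path` (for `save_model`) or the model (for `load_model`).
#' @export
save_model <- function(model, path) {
  saveRDS(model, path)
  jsonlite::write_json(
    list(config = unclass(model$config), n_params = model$n_params,
         package_version = as.character(utils::packageVersion("marrowmeter"))),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "marrow_fcn")) stop_validation("'", path, "' is not a marrow_fcn checkpoint")
  model
}

#' Plot a training history
#'
#' Loss and masked pixel accuracy per epoch, for the training and validation
#' splits.
#'
#' @param history History data.frame from [train_model()].
#' @param path Optional output image path (png); when given, the plot is
#'   written there.
#' @return The ggplot object, invisibly.
#' @export
plot_history <- function(history, path = NULL) {
  df <- rbind(
    data.frame(epoch = history$epoch, value = history$train_loss, metric = "loss", split = "train"),
    data.frame(epoch = history$epoch, value = history$val_loss, metric = "loss", split = "val"),
    data.frame(epoch = history$epoch, value = history$train_acc, metric = "accuracy", split = "train"),
    data.frame(epoch = history$epoch, value = history$val_acc, metric = "accuracy", split = "val")
  )
  df <- df[is.finite(df$value), ]
  p <- ggplot2::ggplot(df, ggplot2::aes(x = epoch, y = value, colour = split)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "epoch", y = NULL) +
    ggplot2::theme_minimal()
  if (!is.null(path)) ggplot2::ggsave(path, p, width = 7, height = 3.2, dpi = 120)
  invisible(p)
}
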