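#' Tissue class codes
#'
#' Integer codes used throughout the package for per-pixel tissue classes.
#' The codes are stable across platforms and releases: hematopoietic tissue is
#' `0`, adipose tissue `1`, and ignore (bone, erythrocytes, artifacts,
#' background glass) `2`. Ignore is a label/loss concept only; the model never
#' predicts it.
#'
#' @return Named integer vector `c(hemato = 0, adipose = 1, ignore = 2)`.
#' @export
class_codes <- function() {
  c(hemato = 0L, adipose = 1L, ignore = 2L)
}

#' Label-mask colour palette
#'
#' The QuPath-export convention for colour-coded label PNGs: black for
#' hematopoietic tissue, yellow for adipose tissue, white for regions to be
#' ignored during training.
#'
#' @return Integer matrix (3 x 3) of 0-255 RGB values, rows named
#'   `hemato`, `adipose`, `ignore`.
#' @export
label_palette <- function() {
  rbind(
    hemato  = c(0L, 0L, 0L),
    adipose = c(255L, 255L, 0L),
    ignore  = c(255L, 255L, 255L)
  )
}

#' Construct a label mask
#'
#' @param classes Integer matrix with values in `{0, 1, 2}` (see
#'   [class_codes()]).
#' @return A `label_mask`: integer matrix with class attribute.
#' @export
label_mask <- function(classes) {
  if (!is.matrix(classes) || nrow(classes) < 1L || ncol(classes) < 1L) {
    stop_validation("'classes' must be a non-empty matrix")
  }
  m <- matrix(as.integer(classes), nrow(classes), ncol(classes))
  if (anyNA(m) || any(!m %in% 0:2)) {
    stop_validation("label mask values must all be in {0 (hemato), 1 (adipose), 2 (ignore)}")
  }
  structure(m, class = c("label_mask", "matrix"))
}

#' @export
print.label_mask <- function(x, ...) {
  tab <- tabulate(as.integer(x) + 1L, nbins = 3L)
  cat(sprintf(
    "<label_mask %d x %d>  hemato: %d  adipose: %d  ignore: %d\n",
    nrow(x), ncol(x), tab[1], tab[2], tab[3]
  ))
  invisible(x)
}

#' Mask-derived cellularity
#'
#' Ground-truth cellularity of a label mask: the hematopoietic fraction of all
#' non-ignored tissue pixels, in percent.
#'
#' @param mask A [label_mask()].
#' @return Percent in `[0, 100]`.
#' @export
mask_cellularity <- function(mask) {
  h <- sum(mask == 0L)
  a <- sum(mask == 1L)
  compute_cellularity(h, a)
}

#' Decode a colour-coded label PNG
#'
#' Maps each pixel to the nearest palette colour (black/yellow/white, see
#' [label_palette()]) in max-channel (Chebyshev) distance. A per-channel
#' tolerance absorbs anti-aliasing artifacts at region borders in exported
#' annotations; pixels farther than the tolerance from every palette colour
#' raise an error reporting the first offending pixel (0-based row/col,
#' origin top-left) and its RGB value.
#'
#' @param path PNG file path. Alpha channels are ignored.
#' @param tolerance Per-channel tolerance in 0-255 units (default 16).
#' @return A [label_mask()].
#' @export
decode_label_png <- function(path, tolerance = 16) {
  if (!file.exists(path)) stop_validation("label file does not exist: ", path)
  img <- png::readPNG(path)
  if (is.matrix(img)) img <- array(rep(img, 3L), dim = c(dim(img), 3L))
  img <- img[, , 1:3, drop = FALSE]
  rgb255 <- round(img * 255)
  pal <- label_palette()
  d <- array(0, dim = c(dim(img)[1], dim(img)[2], 3L))
  for (k in 1:3) {
    d[, , k] <- pmax(
      abs(rgb255[, , 1] - pal[k, 1]),
      abs(rgb255[, , 2] - pal[k, 2]),
      abs(rgb255[, , 3] - pal[k, 3])
    )
  }
  dmin <- pmin(d[, , 1], d[, , 2], d[, , 3])
  if (any(dmin > tolerance)) {
    bad <- which(dmin > tolerance, arr.ind = TRUE)[1L, ]
    stop_validation(sprintf(
      "off-palette pixel at (row=%d, col=%d): RGB(%d, %d, %d) is farther than %s from every palette colour",
      bad[1] - 1L, bad[2] - 1L,
      rgb255[bad[1], bad[2], 1], rgb255[bad[1], bad[2], 2], rgb255[bad[1], bad[2], 3],
      format(tolerance)
    ))
  }
  cls <- (d[, , 2] < d[, , 1] & d[, , 2] <= d[, , 3]) * 1L +
    (d[, , 3] < d[, , 1] & d[, , 3] < d[, , 2]) * 2L
  label_mask(matrix(cls, nrow(dmin), ncol(dmin)))
}

#' Encode a label mask as a colour-coded PNG
#'
#' Writes exact palette colours so that `decode_label_png(encode_label_png(m))`
#' reproduces `m` bit for bit.
#'
#' @param mask A [label_mask()] (or plain integer matrix of class codes).
#' @param path Output PNG path.
#' @return `path`, invisibly.
#' @export
encode_label_png <- function(mask, path) {
  mask <- label_mask(mask)
  pal <- label_palette() / 255
  img <- array(0, dim = c(nrow(mask), ncol(mask), 3L))
  for (k in 1:3) img[, , k] <- matrix(pal[as.integer(mask) + 1L, k], nrow(mask), ncol(mask))
  png::writePNG(img, path)
  invisible(path)
}

#' Build a training-set manifest from a directory of image/label pairs
#'
#' Expects `dir/images/<stem>.(png|tif|tiff)` and `dir/labels/<stem>.png`
#' matched by filename stem. Orphan files (an image without a label or vice
#' versa) are reported in the `warnings` field and excluded. Each retained
#' pair is checked for matching raster dimensions. The train/validation split
#' is deterministic given `seed`.
#'
#' @param dir Dataset directory containing `images/` and `labels/`.
#' @param val_fraction Fraction of pairs assigned to the validation split.
#' @param seed Integer seed for the split.
#' @return A `dataset_manifest`: list with `pairs` (data.frame: stem,
#'   image, label, tile_size, magnification), `split` (character vector
#'   "train"/"val"), `seed`, `val_fraction`, `warnings`.
#' @export
build_manifest <- function(dir, val_fraction = 0.2, seed = 1L) {
  assert_number(val_fraction, "val_fraction", 0, 1)
  img_dir <- file.path(dir, "images")
  lab_dir <- file.path(dir, "labels")
  if (!dir.exists(img_dir) || !dir.exists(lab_dir)) {
    stop_validation("'", dir, "' must contain images/ and labels/ subdirectories")
  }
  imgs <- list.files(img_dir, pattern = "\\.(png|tif|tiff)$", ignore.case = TRUE)
  labs <- list.files(lab_dir, pattern = "\\.png$", ignore.case = TRUE)
  img_stems <- tools::file_path_sans_ext(imgs)
  lab_stems <- tools::file_path_sans_ext(labs)
  common <- intersect(img_stems, lab_stems)
  warnings <- character()
  for (s in setdiff(img_stems, lab_stems)) {
    warnings <- c(warnings, sprintf("image '%s' has no label; excluded", s))
  }
  for (s in setdiff(lab_stems, img_stems)) {
    warnings <- c(warnings, sprintf("label '%s' has no image; excluded", s))
  }
  if (length(common) == 0L) stop_validation("no matched image/label pairs found in ", dir)
  common <- sort(common)
  image_paths <- file.path(img_dir, imgs[match(common, img_stems)])
  label_paths <- file.path(lab_dir, labs[match(common, lab_stems)])
  sizes <- integer(length(common))
  for (i in seq_along(common)) {
    di <- dim(read_image(image_paths[i]))
    dl <- dim(decode_label_png(label_paths[i]))
    if (di[1] != dl[1] || di[2] != dl[2]) {
      stop_validation(sprintf(
        "shape mismatch for '%s': image %dx%d vs label %dx%d",
        common[i], di[1], di[2], dl[1], dl[2]
      ))
    }
    sizes[i] <- di[1]
  }
  n <- length(common)
  n_val <- round(val_fraction * n)
  split <- rep("train", n)
  if (n_val > 0) split[with_seed(seed, sample.int(n, n_val))] <- "val"
  structure(list(
    pairs = data.frame(
      stem = common, image = image_paths, label = label_paths,
      tile_size = sizes, magnification = "20x", stringsAsFactors = FALSE
    ),
    split = split, seed = as.integer(seed), val_fraction = val_fraction,
    warnings = warnings
  ), class = "dataset_manifest")
}

#' @export
print.dataset_manifest <- function(x, ...) {
  cat(sprintf(
    "<dataset_manifest> %d pairs (%d train / %d val), seed %d\n",
    nrow(x$pairs), sum(x$split == "train"), sum(x$split == "val"), x$seed
  ))
  if (length(x$warnings)) cat("  warnings:", length(x$warnings), "\n")
  invisible(x)
}

#' Write a manifest to JSON
#' @param manifest A `dataset_manifest`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(unclass(manifest), path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a manifest from JSON
#' @param path JSON path written by [write_manifest()].
#' @return A `dataset_manifest`.
#' @export
read_manifest <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$pairs <- as.data.frame(x$pairs, stringsAsFactors = FALSE)
  x$warnings <- as.character(x$warnings %||% character())
  structure(x, class = "dataset_manifest")
}
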