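#' Read an RGB image (PNG or TIFF)
#'
#' Returns a `height x width x 3` numeric array with values in `[0, 1]`.
#' Alpha channels are dropped; grayscale images are replicated to three
#' channels. Pyramidal/proprietary WSI containers are out of scope; slides are
#' expected as single plain raster images.
#'
#' @param path Path to a `.png`, `.tif` or `.tiff` file.
#' @return Numeric array `H x W x 3` in `[0, 1]`.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop_validation("image file does not exist: ", path)
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop_validation("unsupported image format '", ext, "' (use png/tif/tiff): ", path)
  )
  if (is.matrix(img)) img <- array(rep(img, 3L), dim = c(dim(img), 3L))
  if (dim(img)[3] > 3L) img <- img[, , 1:3, drop = FALSE]
  img
}

#' Write an RGB image (PNG or TIFF)
#'
#' @param image Numeric array `H x W x 3` with values in `[0, 1]`.
#' @param path Output path; format chosen from the extension.
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path) {
  if (length(dim(image)) != 3L || dim(image)[3] != 3L) {
    stop_validation("'image' must be an H x W x 3 array")
  }
  image <- clamp01(image)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = png::writePNG(image, path),
    tif = ,
    tiff = tiff::writeTIFF(image, path, compression = "none"),
    stop_validation("unsupported image format '", ext, "' (use png/tif/tiff)")
  )
  invisible(path)
}

# separable Gaussian blur with edge replication, used for the rescan
# simulation; sigma in pixels, kernel truncated at ~2.5 sigma
blur_gaussian <- function(image, sigma) {
  if (sigma <= 0) return(image)
  r <- max(1L, ceiling(2.5 * sigma))
  w <- exp(-((-r:r)^2) / (2 * sigma^2))
  w <- w / sum(w)
  blur_mat <- function(m) {
    h <- nrow(m); wd <- ncol(m)
    # pad by replication, then accumulate shifted copies
    pm <- m[c(rep(1L, r), seq_len(h), rep(h, r)), c(rep(1L, r), seq_len(wd), rep(wd, r))]
    out <- matrix(0, h + 2L * r, wd + 2L * r)
    tmp <- matrix(0, h + 2L * r, wd + 2L * r)
    # rows
    for (k in -r:r) {
      idx <- seq_len(h) + r
      tmp[idx, ] <- tmp[idx, ] + w[k + r + 1L] * pm[idx + k, ]
    }
    # cols
    for (k in -r:r) {
      idx <- seq_len(wd) + r
      out[, idx] <- out[, idx] + w[k + r + 1L] * tmp[, idx + k]
    }
    out[seq_len(h) + r, seq_len(wd) + r]
  }
  for (c in 1:3) image[, , c] <- blur_mat(image[, , c])
  image
}
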