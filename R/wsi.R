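#' Tile a slide image into fixed-size patches
#'
#' Partitions the slide into a `ceiling(H/ts) x ceiling(W/ts)` grid of
#' `tile_size`-square tiles. Edge tiles are padded with white; the padding is
#' flagged in a per-tile validity mask so padded pixels can be excluded from
#' all downstream area counts. Reassembling the tiles (ignoring padding)
#' reproduces the slide exactly.
#'
#' @param image RGB array `H x W x 3`.
#' @param tile_size Tile edge in pixels (default 256, the 20x patch size).
#' @return List with `grid` (tile_size, origins matrix of 1-based row/col
#'   offsets, slide `dim`, `pad_policy = "white"`), `tiles` (list of
#'   `ts x ts x 3` arrays) and `valid` (list of logical `ts x ts` matrices,
#'   `FALSE` on padding).
#' @export
tile_slide <- function(image, tile_size = 256L) {
  d <- dim(image)
  if (is.null(d) || length(d) != 3L || d[1] < 1L || d[2] < 1L || d[3] != 3L) {
    stop_validation("'image' must be a non-empty H x W x 3 array")
  }
  ts <- as.integer(tile_size)
  h <- d[1]; w <- d[2]
  nr <- ceiling(h / ts); nc <- ceiling(w / ts)
  origins <- cbind(
    row = rep(seq_len(nr) * ts - ts + 1L, times = nc),
    col = rep(seq_len(nc) * ts - ts + 1L, each = nr)
  )
  tiles <- vector("list", nrow(origins))
  valid <- vector("list", nrow(origins))
  for (k in seq_len(nrow(origins))) {
    r0 <- origins[k, "row"]; c0 <- origins[k, "col"]
    rr <- r0:min(r0 + ts - 1L, h)
    cc <- c0:min(c0 + ts - 1L, w)
    tile <- array(1, dim = c(ts, ts, 3L))  # white padding
    tile[seq_along(rr), seq_along(cc), ] <- image[rr, cc, , drop = FALSE]
    vm <- matrix(FALSE, ts, ts)
    vm[seq_along(rr), seq_along(cc)] <- TRUE
    tiles[[k]] <- tile
    valid[[k]] <- vm
  }
  list(
    grid = list(tile_size = ts, origins = origins, dim = c(h, w),
                pad_policy = "white"),
    tiles = tiles, valid = valid
  )
}

#' Stitch per-tile class matrices back to slide dimensions
#'
#' @param grid The `grid` element returned by [tile_slide()].
#' @param tile_maps List of `ts x ts` matrices, one per tile, in grid order.
#' @return A matrix with the slide's dimensions (padding cropped).
#' @export
stitch_tiles <- function(grid, tile_maps) {
  h <- grid$dim[1]; w <- grid$dim[2]; ts <- grid$tile_size
  out <- matrix(tile_maps[[1]][1], h, w)
  for (k in seq_len(nrow(grid$origins))) {
    r0 <- grid$origins[k, "row"]; c0 <- grid$origins[k, "col"]
    rr <- r0:min(r0 + ts - 1L, h)
    cc <- c0:min(c0 + ts - 1L, w)
    out[rr, cc] <- tile_maps[[k]][seq_along(rr), seq_along(cc)]
  }
  out
}

#' Cellularity from segmented areas
#'
#' The cellularity ratio: hematopoietic area over total tissue
#' (hematopoietic + adipose) area, in percent. Scale-invariant: multiplying
#' both areas by the same positive factor leaves it unchanged.
#'
#' @param area_hemato,area_adipose Pixel counts (>= 0, not both 0).
#' @return Percent in `[0, 100]`.
#' @export
compute_cellularity <- function(area_hemato, area_adipose) {
  assert_number(area_hemato, "area_hemato", 0)
  assert_number(area_adipose, "area_adipose", 0)
  if (area_hemato + area_adipose == 0) {
    stop_validation("cellularity is undefined: both tissue areas are zero")
  }
  100 * area_hemato / (area_hemato + area_adipose)
}

#' Segment a slide and compute its cellularity
#'
#' Tiles the slide at the model's input size, classifies each tile per pixel,
#' stitches the label map back to slide dimensions, and computes the
#' cellularity ratio. Glass background is excluded from both areas before the
#' ratio: pixels whose three channels all exceed `background_threshold`
#' (0-255 scale) count as non-tissue, as does edge-tile padding. The stitched
#' per-tile pixel counts and the slide-level areas agree exactly by
#' construction.
#'
#' @param model A trained `marrow_fcn`.
#' @param image RGB slide array `H x W x 3` in `[0,1]`.
#' @param background_threshold Glass-background intensity threshold on the
#'   0-255 scale (default 235); set above 255 to disable exclusion.
#' @return A `segmentation_result`: list with `class_map` (integer matrix,
#'   0 = hemato, 1 = adipose, `NA` = excluded background), `area_hemato`,
#'   `area_adipose` (pixel counts), `cellularity` (percent), `tile_size`,
#'   `background_threshold`.
#' @export
segment_slide <- function(model, image, background_threshold = 235) {
  if (!inherits(model, "marrow_fcn")) stop_validation("'model' must be a marrow_fcn")
  ts <- model$config$input_size
  d <- dim(image)
  if (length(d) != 3L || d[3] != 3L) stop_validation("'image' must be an H x W x 3 array")
  tl <- tile_slide(image, ts)
  maps <- lapply(tl$tiles, function(tile) unclass(predict_tile(model, tile)))
  pred <- stitch_tiles(tl$grid, maps)
  thr <- background_threshold / 255
  tissue <- !(image[, , 1] > thr & image[, , 2] > thr & image[, , 3] > thr)
  class_map <- pred
  class_map[!tissue] <- NA_integer_
  a_h <- sum(class_map == 0L, na.rm = TRUE)
  a_a <- sum(class_map == 1L, na.rm = TRUE)
  structure(list(
    class_map = class_map, area_hemato = a_h, area_adipose = a_a,
    cellularity = compute_cellularity(a_h, a_a),
    tile_size = ts, background_threshold = background_threshold
  ), class = "segmentation_result")
}

#' @export
print.segmentation_result <- function(x, ...) {
  cat(sprintf(
    "<segmentation_result> %d x %d  hemato %d px  adipose %d px  cellularity %.2f%%\n",
    nrow(x$class_map), ncol(x$class_map), x$area_hemato, x$area_adipose,
    x$cellularity
  ))
  invisible(x)
}

#' Render a segmentation overlay
#'
#' Alpha-blends the class map onto the slide: green for hematopoietic tissue,
#' blue for adipose tissue; excluded (background) pixels are left untouched.
#'
#' @param image RGB slide array.
#' @param class_map Integer matrix from [segment_slide()] (`NA` = untouched).
#' @param alpha Blend weight in `[0,1]`; 0 returns the original image.
#' @return RGB array with the slide's dimensions.
#' @export
render_overlay <- function(image, class_map, alpha = 0.5) {
  d <- dim(image)
  if (length(d) != 3L || d[1] != nrow(class_map) || d[2] != ncol(class_map)) {
    stop_validation("image and class_map dimensions disagree")
  }
  assert_number(alpha, "alpha", 0, 1)
  overlay_colors <- list(`0` = c(0, 1, 0), `1` = c(0, 0, 1))  # green / blue
  out <- image
  for (cls in c(0L, 1L)) {
    sel <- !is.na(class_map) & class_map == cls
    col <- overlay_colors[[as.character(cls)]]
    for (c in 1:3) {
      ch <- out[, , c]
      ch[sel] <- (1 - alpha) * ch[sel] + alpha * col[c]
      out[, , c] <- ch
    }
  }
  out
}

#' Segment a batch of slide images
#'
#' @param model A trained `marrow_fcn`.
#' @param paths Character vector of slide image files (PNG/TIFF).
#' @param background_threshold See [segment_slide()].
#' @return Data frame with one row per slide: `slide_id`, `area_hemato`,
#'   `area_adipose`, `cellularity`. Plugs into [pairwise_ccc_table()] as the
#'   model's rater column.
#' @export
segment_slides <- function(model, paths, background_threshold = 235) {
  res <- lapply(paths, function(p) {
    r <- segment_slide(model, read_image(p), background_threshold)
    data.frame(
      slide_id = tools::file_path_sans_ext(basename(p)),
      area_hemato = r$area_hemato, area_adipose = r$area_adipose,
      cellularity = r$cellularity, stringsAsFactors = FALSE
    )
  })
  do.call(rbind, res)
}
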