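#' Texture parameters for synthetic marrow rendering
#'
#' Geometry of the synthetic H&E texture at a given spatial scale. The
#' reference scale (`scale = 1`) corresponds to a 20x scan at roughly
#' 0.5 um/pixel: adipocyte vacuoles 30-80 px in radius, nuclei 5-9 px, and a
#' nuclear density giving dense basophilic marrow. Desk-scale fixtures use
#' `scale = tile_size / 256`, e.g. `0.25` for 64-px tiles, with the density
#' scaled by `1 / scale^2` so area coverage is preserved.
#'
#' @param scale Spatial scale factor relative to 256-px / 20x tiles.
#' @return List of texture parameters.
#' @export
texture_params <- function(scale = 1) {
  assert_number(scale, "scale", 1e-3, 10)
  list(
    adipocyte_radius_range = pmax(2, c(30, 80) * scale),
    nucleus_radius_range = pmax(1, c(5, 9) * scale),
    nuclei_density = 3.3 / scale^2
  )
}

#' Specification of a synthetic training tile
#'
#' @param tile_size Tile edge in pixels (>= 32; default 256, the patch size
#'   used for 20x training tiles).
#' @param target_cellularity Target hematopoietic percentage among non-ignored
#'   pixels, in `[0, 100]`.
#' @param adipocyte_radius_range Numeric length-2, min/max adipocyte radius in
#'   pixels. Default scales with `tile_size` (see [texture_params()]).
#' @param nuclei_density Nuclei per 1000 px^2 of hematopoietic area.
#' @param nucleus_radius_range Numeric length-2, nucleus semi-major axis range
#'   in pixels.
#' @param ignore_fraction Fraction of pixels in `[0, 0.3]` assigned to the
#'   ignore class (trabecular bone band plus border background).
#' @param seed Integer seed; all randomness of the tile flows from it.
#' @return A `tile_spec` list.
#' @export
tile_spec <- function(tile_size = 256L, target_cellularity = 50,
                      adipocyte_radius_range = NULL, nuclei_density = NULL,
                      nucleus_radius_range = NULL, ignore_fraction = 0,
                      seed = 1L) {
  assert_number(tile_size, "tile_size", 32, 1e5)
  assert_number(target_cellularity, "target_cellularity", 0, 100)
  assert_number(ignore_fraction, "ignore_fraction", 0, 0.3)
  assert_number(seed, "seed")
  tx <- texture_params(tile_size / 256)
  adipocyte_radius_range <- adipocyte_radius_range %||% tx$adipocyte_radius_range
  nuclei_density <- nuclei_density %||% tx$nuclei_density
  nucleus_radius_range <- nucleus_radius_range %||% tx$nucleus_radius_range
  if (length(adipocyte_radius_range) != 2L ||
      adipocyte_radius_range[1] > adipocyte_radius_range[2]) {
    stop_validation("'adipocyte_radius_range' must be c(min, max) with min <= max")
  }
  if (length(nucleus_radius_range) != 2L ||
      nucleus_radius_range[1] > nucleus_radius_range[2]) {
    stop_validation("'nucleus_radius_range' must be c(min, max) with min <= max")
  }
  assert_number(nuclei_density, "nuclei_density", 0, 1e4)
  structure(list(
    tile_size = as.integer(tile_size),
    target_cellularity = target_cellularity,
    adipocyte_radius_range = adipocyte_radius_range,
    nuclei_density = nuclei_density,
    nucleus_radius_range = nucleus_radius_range,
    ignore_fraction = ignore_fraction,
    seed = as.integer(seed)
  ), class = "tile_spec")
}

#' Specification of a synthetic pseudo-slide
#'
#' @param width,height Slide dimensions in pixels (each >= 32).
#' @param target_cellularity Target hematopoietic percentage.
#' @param scanner_profile `"reference"` (no perturbation) or `"alt"`
#'   (simulated second scanner: bounded colour shift plus mild blur).
#' @param scale Texture scale; must match the scale the segmentation model was
#'   trained at (training and inference both happen at "20x").
#' @param seed Integer seed.
#' @return A `slide_spec` list.
#' @export
slide_spec <- function(width, height, target_cellularity = 50,
                       scanner_profile = c("reference", "alt"),
                       scale = 1, seed = 1L) {
  assert_number(width, "width", 32, 1e5)
  assert_number(height, "height", 32, 1e5)
  assert_number(target_cellularity, "target_cellularity", 0, 100)
  assert_number(seed, "seed")
  structure(list(
    width = as.integer(width), height = as.integer(height),
    target_cellularity = target_cellularity,
    scanner_profile = match.arg(scanner_profile),
    scale = scale, seed = as.integer(seed)
  ), class = "slide_spec")
}

#' Simulated human rater profile
#'
#' Human cellularity estimates in routine practice are reported in coarse
#' increments (typically 5%), with observer-specific bias and random error.
#'
#' @param bias Systematic offset in percentage points.
#' @param noise_sd Standard deviation of the random error, percentage points.
#' @param rounding_increment Reporting increment in percent (> 0; default 5).
#' @param seed Integer seed.
#' @return A `rater_profile` list.
#' @export
rater_profile <- function(bias = 0, noise_sd = 0, rounding_increment = 5, seed = 1L) {
  assert_number(bias, "bias", -100, 100)
  assert_number(noise_sd, "noise_sd", 0, Inf)
  assert_number(rounding_increment, "rounding_increment")
  if (rounding_increment <= 0) stop_validation("'rounding_increment' must be > 0")
  assert_number(seed, "seed")
  structure(list(
    bias = bias, noise_sd = noise_sd,
    rounding_increment = rounding_increment, seed = as.integer(seed)
  ), class = "rater_profile")
}

# ---- mask synthesis ---------------------------------------------------------

# Greedy vacuole placement: add discs (clipped to available hematopoietic
# pixels) until the adipose pixel count reaches the requested count within
# tol; candidate radii shrink when a disc would overshoot.
place_adipocytes <- function(mask, need_adip, radius_range) {
  h <- nrow(mask); w <- ncol(mask)
  n_adip <- 0L
  tol <- max(1, round(0.004 * (need_adip + sum(mask == 0L))))
  tries <- 0L
  max_tries <- 6000L
  while (need_adip - n_adip > tol && tries < max_tries) {
    tries <- tries + 1L
    cx <- runif(1, 1, h); cy <- runif(1, 1, w)
    r <- runif(1, radius_range[1], radius_range[2])
    repeat {
      i0 <- max(1L, floor(cx - r)); i1 <- min(h, ceiling(cx + r))
      j0 <- max(1L, floor(cy - r)); j1 <- min(w, ceiling(cy + r))
      ii <- i0:i1; jj <- j0:j1
      inside <- outer((ii - cx)^2, (jj - cy)^2, "+") <= r^2
      sub <- mask[ii, jj, drop = FALSE]
      cand <- inside & sub == 0L
      ncand <- sum(cand)
      if (n_adip + ncand <= need_adip + tol || r <= max(1.5, radius_range[1] / 4)) break
      r <- r * 0.8
    }
    if (ncand > 0L && n_adip + ncand <= need_adip + tol) {
      sub[cand] <- 1L
      mask[ii, jj] <- sub
      n_adip <- n_adip + ncand
    }
  }
  mask
}

# distance from every grid pixel to a segment (x1,y1)-(x2,y2)
segment_distance <- function(h, w, x1, y1, x2, y2) {
  px <- matrix(rep(seq_len(h), w), h, w)
  py <- matrix(rep(seq_len(w), each = h), h, w)
  vx <- x2 - x1; vy <- y2 - y1
  len2 <- vx^2 + vy^2
  t <- ((px - x1) * vx + (py - y1) * vy) / max(len2, 1e-9)
  t <- pmin(pmax(t, 0), 1)
  sqrt((px - (x1 + t * vx))^2 + (py - (y1 + t * vy))^2)
}

# ignore layout: a border background band plus (for tiles) an elongated
# trabecular bone band, sized to approximate the requested fraction
synth_ignore <- function(h, w, ignore_fraction, with_bone = TRUE) {
  mask <- matrix(0L, h, w)
  bone <- matrix(FALSE, h, w)
  if (ignore_fraction <= 0) return(list(mask = mask, bone = bone))
  n <- h * w
  f_border <- if (with_bone) ignore_fraction / 2 else ignore_fraction
  wb <- round(f_border * n / (2 * (h + w)))
  if (wb > 0) {
    idx <- c(seq_len(min(wb, h)), seq(h, by = -1L, length.out = min(wb, h)))
    mask[idx, ] <- 2L
    jdx <- c(seq_len(min(wb, w)), seq(w, by = -1L, length.out = min(wb, w)))
    mask[, jdx] <- 2L
  }
  if (with_bone) {
    remaining <- ignore_fraction * n - sum(mask == 2L)
    if (remaining > 0) {
      ang <- runif(1, 0, pi)
      cx <- runif(1, 0.35 * h, 0.65 * h); cy <- runif(1, 0.35 * w, 0.65 * w)
      len <- 0.45 * min(h, w)
      x1 <- cx - len * cos(ang); x2 <- cx + len * cos(ang)
      y1 <- cy - len * sin(ang); y2 <- cy + len * sin(ang)
      half_width <- max(1, remaining / (2 * 2 * len))
      band <- segment_distance(h, w, x1, y1, x2, y2) <= half_width
      bone <- band & mask != 2L
      mask[bone] <- 2L
    }
  }
  list(mask = mask, bone = bone)
}

synth_mask <- function(h, w, target_cellularity, radius_range, ignore_fraction,
                       with_bone = TRUE) {
  ig <- synth_ignore(h, w, ignore_fraction, with_bone)
  mask <- ig$mask
  n_tissue <- sum(mask == 0L)
  if (n_tissue > 0L) {
    if (target_cellularity <= 0) {
      mask[mask == 0L] <- 1L
    } else if (target_cellularity < 100) {
      need_adip <- round((100 - target_cellularity) / 100 * n_tissue)
      mask <- place_adipocytes(mask, need_adip, radius_range)
    }
  }
  list(mask = mask, bone = ig$bone)
}

# ---- rendering --------------------------------------------------------------

# base colours chosen so that (a) tissue never trips the glass-background
# rule (all channels > 235/255) even after a bounded rescan shift, and
# (b) background always does
mm_colors <- list(
  stroma = c(0.92, 0.68, 0.78),
  nucleus = c(0.32, 0.18, 0.48),
  adipose = c(0.93, 0.875, 0.91),
  rim = c(0.97, 0.64, 0.77),
  bone = c(0.92, 0.88, 0.70),
  background = c(0.975, 0.975, 0.975)
)

# 4-neighbourhood interior: TRUE where m and all 4 neighbours are TRUE
erode4 <- function(m) {
  h <- nrow(m); w <- ncol(m)
  up <- rbind(m[-1, , drop = FALSE], FALSE)
  down <- rbind(FALSE, m[-h, , drop = FALSE])
  left <- cbind(m[, -1, drop = FALSE], FALSE)
  right <- cbind(FALSE, m[, -w, drop = FALSE])
  m & up & down & left & right
}

paint_ellipses <- function(channels, region, centers, a, b, phi, color, shade) {
  h <- nrow(region); w <- ncol(region)
  for (n in seq_len(nrow(centers))) {
    cx <- centers[n, 1]; cy <- centers[n, 2]
    r <- a[n]
    i0 <- max(1L, floor(cx - r)); i1 <- min(h, ceiling(cx + r))
    j0 <- max(1L, floor(cy - r)); j1 <- min(w, ceiling(cy + r))
    ii <- i0:i1; jj <- j0:j1
    dx <- outer(ii - cx, rep(1, length(jj)))
    dy <- outer(rep(1, length(ii)), jj - cy)
    u <- (dx * cos(phi[n]) + dy * sin(phi[n])) / a[n]
    v <- (-dx * sin(phi[n]) + dy * cos(phi[n])) / b[n]
    inside <- (u^2 + v^2 <= 1) & region[ii, jj, drop = FALSE]
    if (!any(inside)) next
    for (c in 1:3) {
      sub <- channels[[c]][ii, jj, drop = FALSE]
      sub[inside] <- color[c] + shade[n]
      channels[[c]][ii, jj] <- sub
    }
  }
  channels
}

render_mask <- function(mask, bone, nuclei_density, nucleus_radius_range) {
  h <- nrow(mask); w <- ncol(mask)
  hem <- mask == 0L
  adi <- mask == 1L
  bg <- mask == 2L & !bone
  ch <- vector("list", 3L)
  for (c in 1:3) {
    base <- matrix(mm_colors$stroma[c], h, w)
    base[adi] <- mm_colors$adipose[c]
    base[bone] <- mm_colors$bone[c]
    base[bg] <- mm_colors$background[c]
    noise_sd <- c(0.02, 0.008, 0.01, 0.004)  # stroma, adipose, bone, background
    nz <- matrix(rnorm(h * w, 0, noise_sd[1]), h, w)
    nz[adi] <- rnorm(sum(adi), 0, noise_sd[2])
    nz[bone] <- rnorm(sum(bone), 0, noise_sd[3])
    nz[bg] <- rnorm(sum(bg), 0, noise_sd[4])
    ch[[c]] <- base + nz
  }
  # thin pink adipocyte rim (cell membrane) at adipose boundaries
  rim <- adi & !erode4(adi)
  for (c in 1:3) ch[[c]][rim] <- mm_colors$rim[c] + rnorm(sum(rim), 0, 0.015)
  # dense basophilic nuclei on the hematopoietic stroma
  n_hem <- sum(hem)
  n_nuc <- round(nuclei_density * n_hem / 1000)
  if (n_nuc > 0 && n_hem > 0) {
    pick <- sample.int(n_hem, n_nuc, replace = TRUE)
    pos <- which(hem, arr.ind = TRUE)[pick, , drop = FALSE]
    centers <- pos + matrix(runif(2 * n_nuc, -0.5, 0.5), ncol = 2)
    a <- runif(n_nuc, nucleus_radius_range[1], nucleus_radius_range[2])
    b <- a * runif(n_nuc, 0.55, 0.9)
    phi <- runif(n_nuc, 0, pi)
    shade <- rnorm(n_nuc, 0, 0.03)
    ch <- paint_ellipses(ch, hem, centers, a, b, phi, mm_colors$nucleus, shade)
  }
  # mild whole-tile colour jitter (scanner/stain variation between tiles)
  off <- runif(3, -0.015, 0.015)
  img <- array(0, dim = c(h, w, 3L))
  for (c in 1:3) img[, , c] <- clamp01(ch[[c]] + off[c])
  img
}

# ---- public generators ------------------------------------------------------

#' Generate a synthetic H&E-like training tile
#'
#' Produces an RGB tile and its ground-truth label mask. Hematopoietic regions
#' are rendered as dense blue-purple elliptical nuclei on pink stroma, adipose
#' regions as near-white vacuoles with thin pink rims, and ignore regions as a
#' pale-yellow trabecular bone band plus glass-white border background. By
#' construction the hematopoietic fraction of non-ignored pixels lands within
#' a fraction of a percentage point of `target_cellularity` (well inside the
#' guaranteed +/- 5 points). Bit-identical output for identical specs.
#'
#' @param spec A [tile_spec()].
#' @return List with `image` (`H x W x 3` in `[0,1]`), `mask`
#'   ([label_mask()]), and `true_cellularity` (mask-derived, percent).
#' @export
generate_tile <- function(spec) {
  if (!inherits(spec, "tile_spec")) spec <- do.call(tile_spec, spec)
  ts <- spec$tile_size
  with_seed(spec$seed, {
    sm <- synth_mask(ts, ts, spec$target_cellularity,
                     spec$adipocyte_radius_range, spec$ignore_fraction)
    img <- render_mask(sm$mask, sm$bone, spec$nuclei_density,
                       spec$nucleus_radius_range)
    mask <- label_mask(sm$mask)
    tc <- if (any(mask != 2L)) mask_cellularity(mask) else NA_real_
    list(image = img, mask = mask, true_cellularity = tc)
  })
}

#' Generate a synthetic pseudo-slide with known cellularity
#'
#' Builds a large marrow image with a glass-white background border and a few
#' white artifact blobs (the slide-level ignore content), places adipocyte
#' vacuoles to approximate the target cellularity, and recomputes the true
#' cellularity exactly from the emitted mask, so downstream recovery is always
#' measured against mask-derived truth rather than the target. With
#' `scanner_profile = "alt"` the rendered image (not the mask) is passed
#' through [rescan_variant()].
#'
#' @param spec A [slide_spec()].
#' @return List with `image`, `mask`, `true_cellularity`.
#' @export
generate_slide <- function(spec) {
  if (!inherits(spec, "slide_spec")) spec <- do.call(slide_spec, spec)
  tx <- texture_params(spec$scale)
  h <- spec$height; w <- spec$width
  with_seed(spec$seed, {
    border <- max(3L, round(0.03 * min(h, w)))
    mask <- matrix(0L, h, w)
    mask[c(seq_len(border), seq(h - border + 1L, h)), ] <- 2L
    mask[, c(seq_len(border), seq(w - border + 1L, w))] <- 2L
    # a couple of glass-white artifact blobs inside the tissue
    for (k in seq_len(2L)) {
      cx <- runif(1, 0.2 * h, 0.8 * h); cy <- runif(1, 0.2 * w, 0.8 * w)
      r <- runif(1, 0.02, 0.04) * min(h, w)
      ii <- max(1L, floor(cx - r)):min(h, ceiling(cx + r))
      jj <- max(1L, floor(cy - r)):min(w, ceiling(cy + r))
      sub <- mask[ii, jj, drop = FALSE]
      sub[outer((ii - cx)^2, (jj - cy)^2, "+") <= r^2] <- 2L
      mask[ii, jj] <- sub
    }
    n_tissue <- sum(mask == 0L)
    if (spec$target_cellularity <= 0) {
      mask[mask == 0L] <- 1L
    } else if (spec$target_cellularity < 100) {
      need <- round((100 - spec$target_cellularity) / 100 * n_tissue)
      mask <- place_adipocytes(mask, need, tx$adipocyte_radius_range)
    }
    img <- render_mask(mask, bone = matrix(FALSE, h, w),
                       tx$nuclei_density, tx$nucleus_radius_range)
    if (spec$scanner_profile == "alt") img <- alt_scan(img)
    list(
      image = img, mask = label_mask(mask),
      true_cellularity = mask_cellularity(label_mask(mask))
    )
  })
}

# the alt-scanner perturbation body; consumes the active RNG stream
alt_scan <- function(image) {
  off <- runif(3, -0.03, 0.03)
  for (c in 1:3) image[, , c] <- image[, , c] + off[c]
  clamp01(blur_gaussian(image, sigma = 0.5))
}

#' Simulate rescanning an image on a different scanner
#'
#' Applies a bounded per-channel brightness/hue shift (at most ~8 intensity
#' units out of 255) and a mild Gaussian blur, emulating colour and focus
#' differences between slide scanners. Geometry is unchanged, so any
#' ground-truth mask and its cellularity remain valid. `"reference"` returns
#' the image untouched. Deterministic given `seed`.
#'
#' @param image RGB array `H x W x 3` in `[0,1]`.
#' @param profile `"reference"` or `"alt"`.
#' @param seed Integer seed for the perturbation draw.
#' @return Perturbed RGB array of identical dimensions.
#' @export
rescan_variant <- function(image, profile = c("alt", "reference"), seed = 1L) {
  profile <- match.arg(profile)
  if (length(dim(image)) != 3L || dim(image)[3] != 3L) {
    stop_validation("'image' must be an H x W x 3 array")
  }
  if (profile == "reference") return(image)
  with_seed(seed, alt_scan(image))
}

#' Simulate a human rater's cellularity readings
#'
#' Each rating is `clamp(round_to_increment(true + bias + N(0, noise_sd)), 0,
#' 100)`, with rounding to the nearest reporting increment using the
#' round-half-up convention (62.5 with a 5% increment reports as 65).
#'
#' @param true_values Numeric vector of true cellularities in `[0, 100]`.
#' @param profile A [rater_profile()].
#' @return Numeric vector of simulated ratings.
#' @export
simulate_rater <- function(true_values, profile) {
  if (!inherits(profile, "rater_profile")) profile <- do.call(rater_profile, profile)
  if (any(!is.finite(true_values)) || any(true_values < 0 | true_values > 100)) {
    stop_validation("'true_values' must all be in [0, 100]")
  }
  with_seed(profile$seed, {
    x <- true_values + profile$bias + rnorm(length(true_values), 0, profile$noise_sd)
    inc <- profile$rounding_increment
    pmin(pmax(floor(x / inc + 0.5) * inc, 0), 100)
  })
}

#' Write a synthetic training set to disk
#'
#' Generates `n_tiles` seeded tiles spanning a cellularity range, writing
#' `images/<stem>.png`, `labels/<stem>.png` (palette-coded, see
#' [label_palette()]) and a JSON sidecar per tile recording the spec, seed and
#' mask-derived true cellularity. Roughly half the tiles carry an ignore
#' region (bone band + border) so ignore-masked training is exercised.
#'
#' @param dir Output directory (created if missing).
#' @param n_tiles Number of tiles.
#' @param tile_size Tile edge in pixels.
#' @param cellularity_range Range the per-tile targets are drawn from.
#' @param seed Integer seed; tile `i` uses `seed + i`.
#' @return The directory path, invisibly.
#' @export
synth_training_set <- function(dir, n_tiles = 200, tile_size = 64,
                               cellularity_range = c(5, 95), seed = 1L) {
  dir.create(file.path(dir, "images"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "labels"), recursive = TRUE, showWarnings = FALSE)
  draws <- with_seed(seed, list(
    targets = runif(n_tiles, cellularity_range[1], cellularity_range[2]),
    has_ignore = runif(n_tiles) < 0.5,
    ignore_frac = runif(n_tiles, 0.05, 0.25)
  ))
  for (i in seq_len(n_tiles)) {
    spec <- tile_spec(
      tile_size = tile_size,
      target_cellularity = draws$targets[i],
      ignore_fraction = if (draws$has_ignore[i]) draws$ignore_frac[i] else 0,
      seed = seed + i
    )
    tile <- generate_tile(spec)
    stem <- sprintf("tile_%04d", i)
    write_image(tile$image, file.path(dir, "images", paste0(stem, ".png")))
    encode_label_png(tile$mask, file.path(dir, "labels", paste0(stem, ".png")))
    jsonlite::write_json(
      list(spec = unclass(spec), true_cellularity = tile$true_cellularity),
      file.path(dir, "labels", paste0(stem, ".json")),
      auto_unbox = TRUE, digits = NA
    )
  }
  invisible(dir)
}
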