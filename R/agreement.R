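#' Paired cellularity measurements from two observers
#'
#' @param x,y Numeric vectors of paired percent measurements in `[0, 100]`,
#'   equal length >= 2 (>= 3 for [lin_ccc()]).
#' @param slide_ids Optional identifiers, one per pair.
#' @param labels Length-2 character: names of the two observers.
#' @return A `rater_series` list.
#' @export
rater_series <- function(x, y, slide_ids = NULL, labels = c("x", "y")) {
  if (length(x) != length(y)) {
    stop_validation(sprintf("series lengths differ: %d vs %d", length(x), length(y)))
  }
  if (length(x) < 2L) stop_validation("at least 2 paired measurements are required")
  if (any(!is.finite(x)) || any(!is.finite(y)) ||
      any(x < 0 | x > 100) || any(y < 0 | y > 100)) {
    stop_validation("measurements must all be finite and in [0, 100]")
  }
  slide_ids <- slide_ids %||% seq_along(x)
  if (length(slide_ids) != length(x)) stop_validation("'slide_ids' length mismatch")
  structure(list(slide_ids = slide_ids, values_x = as.numeric(x),
                 values_y = as.numeric(y), labels = labels),
            class = "rater_series")
}

as_series <- function(x, y) {
  if (inherits(x, "rater_series")) x else rater_series(x, y)
}

#' Lin's concordance correlation coefficient
#'
#' The standard Lin (1989) estimator
#' \deqn{\hat\rho_c = \frac{2 s_{xy}}{s_x^2 + s_y^2 + (\bar x - \bar y)^2}}
#' with population (1/n) variances, penalizing both random differences
#' (through the Pearson correlation) and systematic location/scale shifts.
#' The 95% confidence interval is obtained on the Fisher z scale using Lin's
#' asymptotic variance of the transformed estimate (with the usual 2000
#' erratum corrections), falling back to the Pearson-style `1/(n-3)` variance
#' in degenerate cases. The Altman grade (see [classify_agreement()]) is
#' attached.
#'
#' @param x A `rater_series`, or a numeric vector (then `y` is required).
#' @param y Second numeric vector when `x` is not a `rater_series`.
#' @param conf_level Confidence level (default 0.95).
#' @return A `ccc_result`: list with `ccc`, `pearson_rho`, `mu_x`, `mu_y`,
#'   `var_x`, `var_y` (population variances), `ci_low`, `ci_high`, `n`,
#'   `conf_level`, `grade`.
#' @export
lin_ccc <- function(x, y = NULL, conf_level = 0.95) {
  s <- as_series(x, y)
  xv <- s$values_x; yv <- s$values_y
  n <- length(xv)
  if (n < 3L) stop_validation("Lin's CCC requires at least 3 pairs")
  mx <- mean(xv); my <- mean(yv)
  vx <- mean((xv - mx)^2); vy <- mean((yv - my)^2)
  sxy <- mean((xv - mx) * (yv - my))
  if (vx == 0 && vy == 0) {
    stop_validation("CCC is undefined: both series are constant")
  }
  ccc <- 2 * sxy / (vx + vy + (mx - my)^2)
  r <- if (vx == 0 || vy == 0) 0 else sxy / sqrt(vx * vy)
  if (abs(ccc) >= 1 - 1e-12) {
    ci <- c(ccc, ccc)
  } else {
    z <- atanh(ccc)
    se2 <- NA_real_
    if (r != 0 && vx > 0 && vy > 0) {
      u <- (mx - my) / sqrt(sqrt(vx) * sqrt(vy))  # location shift / sqrt(sx * sy)
      se2 <- ((1 - r^2) * ccc^2 / ((1 - ccc^2) * r^2) +
                2 * ccc^3 * (1 - ccc) * u^2 / (r * (1 - ccc^2)^2) -
                ccc^4 * u^4 / (2 * r^2 * (1 - ccc^2)^2)) / (n - 2)
    }
    if (!is.finite(se2) || se2 <= 0) se2 <- 1 / max(n - 3, 1)
    q <- qnorm(1 - (1 - conf_level) / 2)
    ci <- tanh(c(z - q * sqrt(se2), z + q * sqrt(se2)))
  }
  structure(list(
    ccc = ccc, pearson_rho = r, mu_x = mx, mu_y = my, var_x = vx, var_y = vy,
    ci_low = ci[1], ci_high = ci[2], n = n, conf_level = conf_level,
    grade = classify_agreement(ccc)
  ), class = "ccc_result")
}

#' @export
print.ccc_result <- function(x, ...) {
  cat(sprintf(
    "Lin's CCC: %.4f  (%d%% CI %.4f, %.4f)  n = %d  grade: %s\n",
    x$ccc, round(100 * x$conf_level), x$ci_low, x$ci_high, x$n, x$grade
  ))
  invisible(x)
}

#' Grade a concordance coefficient on the Altman scale
#'
#' Agreement greater than 0.8 is graded optimal; between 0.6 and 0.8
#' (inclusive of both boundaries, since "greater than 0.8" is strict)
#' substantial; below 0.6, below-substantial.
#'
#' @param ccc Coefficient in `[-1, 1]`.
#' @return One of `"optimal"`, `"substantial"`, `"below_substantial"`.
#' @export
classify_agreement <- function(ccc) {
  assert_number(ccc, "ccc", -1, 1)
  if (ccc > 0.8) "optimal" else if (ccc >= 0.6) "substantial" else "below_substantial"
}

#' Bland-Altman bias and limits of agreement
#'
#' Differences `d_i = x_i - y_i`; bias is their mean, `Sd` their sample
#' standard deviation (`n - 1` denominator), and the limits of agreement are
#' `bias +/- 1.96 Sd`, covering ~95% of expected differences under
#' normality. Per-pair means `(x_i + y_i)/2` are returned for plotting.
#'
#' @inheritParams lin_ccc
#' @return A `bland_altman_result`: list with `bias`, `sd_diff`, `ula`,
#'   `lal`, `n`, and `data` (data.frame: slide_id, pair_mean, pair_diff).
#' @export
bland_altman <- function(x, y = NULL) {
  s <- as_series(x, y)
  d <- s$values_x - s$values_y
  bias <- mean(d)
  sd_d <- if (length(d) > 1L) sd(d) else 0
  structure(list(
    bias = bias, sd_diff = sd_d,
    ula = bias + 1.96 * sd_d, lal = bias - 1.96 * sd_d,
    n = length(d), labels = s$labels,
    data = data.frame(
      slide_id = s$slide_ids,
      pair_mean = (s$values_x + s$values_y) / 2,
      pair_diff = d
    )
  ), class = "bland_altman_result")
}

#' @export
print.bland_altman_result <- function(x, ...) {
  cat(sprintf(
    "Bland-Altman: bias %.3f  Sd %.3f  limits [%.3f, %.3f]  n = %d\n",
    x$bias, x$sd_diff, x$lal, x$ula, x$n
  ))
  invisible(x)
}

#' Bland-Altman plot
#'
#' Scatter of per-pair difference against per-pair mean, with horizontal
#' lines at the bias and the upper/lower limits of agreement.
#'
#' @param result A `bland_altman_result`.
#' @param path Optional output file (png/svg/pdf via `ggplot2::ggsave()`).
#' @param title Optional plot title.
#' @return The ggplot object, invisibly; the file is written when `path` is
#'   given.
#' @export
bland_altman_plot <- function(result, path = NULL, title = NULL) {
  if (!inherits(result, "bland_altman_result")) {
    stop_validation("'result' must come from bland_altman()")
  }
  p <- ggplot2::ggplot(result$data, ggplot2::aes(x = pair_mean, y = pair_diff)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::geom_hline(yintercept = result$bias, colour = "blue") +
    ggplot2::geom_hline(yintercept = c(result$lal, result$ula),
                        colour = "red", linetype = "dashed") +
    ggplot2::labs(
      x = "mean of paired measurements (%)",
      y = "difference (%)",
      title = title %||% sprintf("Bland-Altman: %s vs %s",
                                 result$labels[1], result$labels[2])
    ) +
    ggplot2::theme_minimal()
  if (!is.null(path)) ggplot2::ggsave(path, p, width = 5.5, height = 4, dpi = 120)
  invisible(p)
}

#' Pairwise concordance among a panel of raters
#'
#' Computes Lin's CCC for every pair of rater columns (a symmetric matrix
#' with unit diagonal) and, mirroring the model-vs-mean-of-panel comparison,
#' the CCC of each rater against the across-rater mean. For raters that are
#' themselves panel members the mean excludes their own column
#' (leave-one-out); columns outside `panel` (e.g. the automated model) are
#' compared against the mean of the full panel.
#'
#' @param ratings Data frame or matrix, one row per slide, one numeric column
#'   per rater. Ragged list input is rejected.
#' @param panel Character vector of column names forming the human panel used
#'   for the mean comparison (default: all columns).
#' @param conf_level Confidence level for the intervals.
#' @return List with `ccc`, `ci_low`, `ci_high` (numeric matrices), `grade`
#'   (character matrix), `pairs` (long data.frame: rater_a, rater_b, ccc,
#'   ci_low, ci_high, grade) and `vs_mean` (data.frame with the same columns
#'   per rater).
#' @export
pairwise_ccc_table <- function(ratings, panel = NULL, conf_level = 0.95) {
  if (is.list(ratings) && !is.data.frame(ratings)) {
    if (length(unique(lengths(ratings))) != 1L) {
      stop_validation("ragged input: all rater series must have equal length")
    }
    ratings <- as.data.frame(ratings)
  }
  ratings <- as.data.frame(ratings)
  if (ncol(ratings) < 2L) stop_validation("at least 2 raters are required")
  raters <- colnames(ratings)
  panel <- panel %||% raters
  if (!all(panel %in% raters)) stop_validation("'panel' must name columns of 'ratings'")
  k <- length(raters)
  ccc_m <- matrix(1, k, k, dimnames = list(raters, raters))
  lo_m <- matrix(1, k, k, dimnames = list(raters, raters))
  hi_m <- matrix(1, k, k, dimnames = list(raters, raters))
  gr_m <- matrix("optimal", k, k, dimnames = list(raters, raters))
  pairs <- NULL
  for (i in seq_len(k - 1L)) {
    for (j in seq((i + 1L), k)) {
      res <- lin_ccc(ratings[[i]], ratings[[j]], conf_level = conf_level)
      ccc_m[i, j] <- ccc_m[j, i] <- res$ccc
      lo_m[i, j] <- lo_m[j, i] <- res$ci_low
      hi_m[i, j] <- hi_m[j, i] <- res$ci_high
      gr_m[i, j] <- gr_m[j, i] <- res$grade
      pairs <- rbind(pairs, data.frame(
        rater_a = raters[i], rater_b = raters[j], ccc = res$ccc,
        ci_low = res$ci_low, ci_high = res$ci_high, grade = res$grade,
        stringsAsFactors = FALSE
      ))
    }
  }
  vs_mean <- NULL
  for (i in seq_len(k)) {
    ref <- setdiff(panel, raters[i])
    if (length(ref) == 0L) next
    panel_mean <- rowMeans(ratings[, ref, drop = FALSE])
    res <- lin_ccc(ratings[[i]], panel_mean, conf_level = conf_level)
    vs_mean <- rbind(vs_mean, data.frame(
      rater = raters[i], ccc = res$ccc, ci_low = res$ci_low,
      ci_high = res$ci_high, grade = res$grade, stringsAsFactors = FALSE
    ))
  }
  list(ccc = ccc_m, ci_low = lo_m, ci_high = hi_m, grade = gr_m,
       pairs = pairs, vs_mean = vs_mean)
}
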