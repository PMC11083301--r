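# brute-force concordance oracle: 1 - E[(X-Y)^2] / (sx^2 + sy^2 + (mx-my)^2),
# algebraically equal to Lin's estimator with population variances
ccc_oracle <- function(x, y) {
  msd <- mean((x - y)^2)
  denom <- mean((x - mean(x))^2) + mean((y - mean(y))^2) + (mean(x) - mean(y))^2
  1 - msd / denom
}

test_that("lin_ccc matches the expectation-form oracle on random series", {
  withr::with_seed(101, {
    for (rep in 1:100) {
      x <- runif(40, 0, 100)
      y <- pmin(pmax(x + rnorm(40, 0, runif(1, 1, 25)) +
                       runif(1, -10, 10), 0), 100)
      res <- lin_ccc(x, y)
      expect_lt(abs(res$ccc - ccc_oracle(x, y)), 1e-10)
    }
  })
})

test_that("known-value concordance cases are exact", {
  x <- c(10, 50, 90)
  expect_equal(lin_ccc(x, x)$ccc, 1)
  res <- lin_ccc(c(1, 2, 3), c(3, 2, 1))
  expect_equal(res$ccc, -1)
  expect_equal(res$pearson_rho, -1)
})

test_that("ccc result obeys its structural invariants", {
  withr::with_seed(7, {
    for (rep in 1:25) {
      x <- runif(30, 0, 100)
      y <- pmin(pmax(0.8 * x + rnorm(30, 5, 10), 0), 100)
      res <- lin_ccc(x, y)
      expect_lte(abs(res$ccc), abs(res$pearson_rho) + 1e-12)
      expect_lte(abs(res$pearson_rho), 1)
      expect_lte(res$ci_low, res$ccc)
      expect_gte(res$ci_high, res$ccc)
      # symmetry
      expect_equal(lin_ccc(y, x)$ccc, res$ccc, tolerance = 1e-12)
      # invariance under common permutation of pairs
      perm <- sample(30)
      expect_equal(lin_ccc(x[perm], y[perm])$ccc, res$ccc, tolerance = 1e-12)
    }
  })
})

test_that("a constant offset strictly degrades concordance, monotonically", {
  x <- withr::with_seed(9, runif(40, 20, 70))
  cccs <- vapply(c(0, 2, 5, 10, 20), function(offset) {
    lin_ccc(x, x + offset)$ccc
  }, numeric(1))
  expect_equal(cccs[1], 1)
  expect_true(all(diff(cccs) < 0))
})

test_that("fisher-z interval shrinks with sample size", {
  width <- function(n) {
    withr::with_seed(13, {
      x <- runif(n, 0, 100)
      y <- pmin(pmax(x + rnorm(n, 0, 8), 0), 100)
      res <- lin_ccc(x, y)
      res$ci_high - res$ci_low
    })
  }
  expect_lt(width(160), width(40))
})

test_that("degenerate concordance inputs are rejected", {
  expect_error(lin_ccc(c(1, 2), c(1, 2)), "at least 3",
               class = "mm_validation_error")
  expect_error(lin_ccc(rep(50, 5), rep(60, 5)), "constant",
               class = "mm_validation_error")
  expect_error(rater_series(1:4, 1:5), "lengths differ",
               class = "mm_validation_error")
  expect_error(rater_series(c(1, 2, 300), c(1, 2, 3)),
               class = "mm_validation_error")
})

test_that("agreement grading follows the Altman cutpoints", {
  expect_equal(classify_agreement(0.9400), "optimal")
  expect_equal(classify_agreement(0.7918), "substantial")
  expect_equal(classify_agreement(0.7785), "substantial")
  expect_equal(classify_agreement(0.8), "substantial")     # strict > 0.8
  expect_equal(classify_agreement(0.8 + 1e-9), "optimal")
  expect_equal(classify_agreement(0.6), "substantial")
  expect_equal(classify_agreement(0.6 - 1e-9), "below_substantial")
  expect_error(classify_agreement(1.2), class = "mm_validation_error")
})

test_that("bland-altman limits match hand computation and are symmetric", {
  res <- bland_altman(c(2, 0), c(1, 1))  # differences (1, -1)
  expect_equal(res$bias, 0)
  expect_equal(res$sd_diff, sqrt(2))
  expect_equal(res$ula, 1.96 * sqrt(2))
  expect_equal(res$lal, -1.96 * sqrt(2))
  x <- withr::with_seed(3, runif(20, 0, 100))
  y <- withr::with_seed(4, runif(20, 0, 100))
  r <- bland_altman(x, y)
  expect_equal(r$ula - r$bias, r$bias - r$lal, tolerance = 1e-12)
  expect_lte(r$lal, r$bias)
  ident <- bland_altman(x, x)
  expect_equal(ident$bias, 0)
  expect_equal(ident$ula, 0)
  expect_equal(ident$lal, 0)
})

test_that("limits of agreement cover ~95% of normal differences", {
  withr::with_seed(21, {
    base <- runif(10000, 20, 80)
    d <- rnorm(10000, 0, 4)
    res <- bland_altman(base + d / 2, base - d / 2)
    coverage <- mean(res$data$pair_diff >= res$lal & res$data$pair_diff <= res$ula)
    expect_gte(coverage, 0.94)
    expect_lte(coverage, 0.96)
  })
})

test_that("bland-altman plot writes a non-empty file with the right geometry", {
  x <- withr::with_seed(5, runif(15, 20, 80))
  res <- bland_altman(x, pmin(pmax(x + rnorm(15, 0, 3), 0), 100))
  path <- withr::local_tempfile(fileext = ".png")
  p <- bland_altman_plot(res, path)
  expect_true(file.exists(path) && file.size(path) > 0)
  # identical series put every point on the zero line
  p0 <- bland_altman_plot(bland_altman(x, x))
  expect_true(all(p0$data$pair_diff == 0))
})

test_that("pairwise table is symmetric with unit diagonal", {
  withr::with_seed(31, {
    ratings <- data.frame(
      a = runif(20, 0, 100), b = runif(20, 0, 100), c = runif(20, 0, 100)
    )
    ratings$b <- (ratings$a + ratings$b) / 2
    tab <- pairwise_ccc_table(ratings)
    expect_equal(tab$ccc, t(tab$ccc), tolerance = 1e-12)
    expect_equal(diag(tab$ccc), c(a = 1, b = 1, c = 1))
    dup <- pairwise_ccc_table(data.frame(a = ratings$a, b = ratings$a))
    expect_equal(dup$ccc["a", "b"], 1)
    expect_error(pairwise_ccc_table(list(a = 1:5, b = 1:4)), "ragged",
                 class = "mm_validation_error")
  })
})

test_that("panel means are leave-one-out for members, full for outsiders", {
  withr::with_seed(33, {
    truth <- runif(25, 10, 90)
    ratings <- data.frame(
      model = pmin(pmax(truth + rnorm(25, 0, 2), 0), 100),
      r1 = pmin(pmax(truth + rnorm(25, 0, 6), 0), 100),
      r2 = pmin(pmax(truth + rnorm(25, 0, 6), 0), 100),
      r3 = pmin(pmax(truth + rnorm(25, 0, 6), 0), 100)
    )
    tab <- pairwise_ccc_table(ratings, panel = c("r1", "r2", "r3"))
    vm <- tab$vs_mean
    # model row compares against the mean of all three panel members
    manual <- lin_ccc(ratings$model, rowMeans(ratings[, c("r1", "r2", "r3")]))
    expect_equal(vm$ccc[vm$rater == "model"], manual$ccc)
    # r1 row excludes r1 from the mean
    manual_r1 <- lin_ccc(ratings$r1, rowMeans(ratings[, c("r2", "r3")]))
    expect_equal(vm$ccc[vm$rater == "r1"], manual_r1$ccc)
  })
})
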