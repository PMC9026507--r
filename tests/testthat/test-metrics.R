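# PSNR / SSIM against brute-force oracles, summary tables, and the paired
# signed-rank comparison.

# Brute-force SSIM: explicit loops over every window position, direct
# evaluation of the local statistic. Independent of the package's
# im2col-based path.
ssim_brute <- function(x, y, k, sigma, c1, c2) {
  r <- (k - 1) / 2
  g1 <- exp(-((-r:r)^2) / (2 * sigma^2))
  w <- outer(g1, g1); w <- w / sum(w)
  vals <- c()
  for (i in 1:(nrow(x) - k + 1)) {
    for (j in 1:(ncol(x) - k + 1)) {
      px <- x[i:(i + k - 1), j:(j + k - 1)]
      py <- y[i:(i + k - 1), j:(j + k - 1)]
      mx <- sum(w * px); my <- sum(w * py)
      vx <- sum(w * px^2) - mx^2
      vy <- sum(w * py^2) - my^2
      cxy <- sum(w * px * py) - mx * my
      vals <- c(vals, ((2 * mx * my + c1) * (2 * cxy + c2)) /
                  ((mx^2 + my^2 + c1) * (vx + vy + c2)))
    }
  }
  mean(vals)
}

test_that("psnr closed forms", {
  x <- matrix(runif(64), 8)
  expect_identical(psnr(x, x), Inf)
  # MAX=1, uniform absolute error 0.1 -> 20 dB
  expect_equal(psnr(x, x + 0.1), 20)
  # MAX=255, RMSE=255 -> 0 dB
  cfg255 <- metric_config(L = 255)
  expect_equal(psnr(x * 255, x * 255 + 255, cfg255), 0)
  expect_error(psnr(x, matrix(0, 2, 2)), "shape")
})

test_that("psnr is strictly decreasing in RMSE", {
  x <- matrix(runif(64), 8)
  errs <- c(0.01, 0.05, 0.1, 0.3)
  ps <- vapply(errs, function(e) psnr(x, x + e), numeric(1))
  expect_true(all(diff(ps) < 0))
})

test_that("ssim equals 1 for identical images and is symmetric", {
  cfg <- metric_config(window = 5)
  x <- matrix(runif(64), 8)
  expect_equal(ssim(x, x, cfg), 1)
  y <- matrix(runif(64), 8)
  expect_equal(ssim(x, y, cfg), ssim(y, x, cfg))
  expect_error(ssim(x, y, metric_config(window = 11)), "larger than image")
})

test_that("ssim on constant images matches the zero-variance closed form", {
  cfg <- metric_config(window = 5)
  x <- matrix(0.5, 8, 8); y <- matrix(0.7, 8, 8)
  expected <- (2 * 0.5 * 0.7 + cfg$c1) / (0.5^2 + 0.7^2 + cfg$c1)
  expect_equal(ssim(x, y, cfg), expected, tolerance = 1e-12)
})

test_that("psnr and ssim agree with brute-force evaluation on 8x8 images", {
  set.seed(10)
  cfg <- metric_config(window = 5)
  for (rep in 1:5) {
    x <- matrix(runif(64), 8)
    y <- pmin(pmax(x + rnorm(64, 0, 0.1), 0), 1)
    # psnr brute force: direct formula
    expect_equal(psnr(x, y, cfg),
                 20 * log10(1 / sqrt(sum((x - y)^2) / 64)),
                 tolerance = 1e-6)
    expect_equal(ssim(x, y, cfg),
                 ssim_brute(x, y, 5, 1.5, cfg$c1, cfg$c2),
                 tolerance = 1e-6)
    expect_gte(ssim(x, y, cfg), -1)
    expect_lte(ssim(x, y, cfg), 1 + 1e-12)
  }
})

test_that("evaluate_synthesis produces per-image records and summaries", {
  set.seed(11)
  imgs <- lapply(1:4, function(i) matrix(runif(32 * 32, -1, 1), 32))
  records <- tibble::tibble(
    synthesized = imgs, target = imgs,
    direction = rep(c("a2b", "b2a"), each = 2)
  )
  ev <- suppressWarnings(evaluate_synthesis(records))
  expect_equal(nrow(ev), 4L)
  expect_equal(ev$ssim, rep(1, 4))
  sm <- suppressWarnings(summary(ev))
  expect_equal(sm$ssim_mean, c(1, 1))
  expect_equal(sm$ssim_sd, c(0, 0))
  # summary means equal arithmetic means of the per-image records
  noisy <- records
  noisy$synthesized <- lapply(imgs, function(m)
    pmin(pmax(m + rnorm(length(m), 0, 0.1), -1), 1))
  ev2 <- evaluate_synthesis(noisy)
  sm2 <- summary(ev2)
  for (d in c("a2b", "b2a")) {
    expect_equal(sm2$ssim_mean[sm2$direction == d],
                 mean(ev2$ssim[ev2$direction == d]))
    expect_equal(sm2$psnr_mean[sm2$direction == d],
                 mean(ev2$psnr[ev2$direction == d]))
  }
  expect_error(evaluate_synthesis(records[0, ]))
})

test_that("metrics are invariant to identical permutation of the pair list", {
  set.seed(12)
  imgs <- lapply(1:6, function(i) matrix(runif(16 * 16, -1, 1), 16))
  tgts <- lapply(1:6, function(i) matrix(runif(16 * 16, -1, 1), 16))
  rec <- tibble::tibble(synthesized = imgs, target = tgts, direction = "a2b")
  perm <- c(4, 2, 6, 1, 5, 3)
  ev1 <- evaluate_synthesis(rec, metric_config(window = 5))
  ev2 <- evaluate_synthesis(rec[perm, ], metric_config(window = 5))
  expect_equal(sort(ev1$ssim), sort(ev2$ssim))
  expect_equal(summary(ev1)$ssim_mean, summary(ev2)$ssim_mean)
})

test_that("signed-rank test: exact small-sample null", {
  # n = 6, all differences positive: exact two-sided p = 2/2^6
  a <- c(1.1, 2.2, 3.1, 4.5, 5.2, 6.8)
  b <- a - c(0.1, 0.2, 0.15, 0.3, 0.25, 0.4)
  res <- paired_signed_rank(a, b)
  expect_equal(res$p_value, 2 / 2^6)
  expect_equal(res$n, 6L)
})

test_that("signed-rank test: constant shift at n = 20 is highly significant", {
  set.seed(13)
  b <- rnorm(20)
  a <- b + 0.5
  expect_lt(paired_signed_rank(a, b)$p_value, 0.001)
})

test_that("signed-rank test: degenerate all-zero differences error", {
  a <- rnorm(10)
  expect_error(paired_signed_rank(a, a), "degenerate")
  expect_error(paired_signed_rank(1:3, 4:6), "length")
})

test_that("signed-rank type-I error rate is near the nominal 5%", {
  set.seed(14)
  n_rep <- 600
  rejections <- 0
  for (r in 1:n_rep) {
    a <- rnorm(12); b <- rnorm(12)
    if (paired_signed_rank(a, b)$p_value < 0.05) rejections <- rejections + 1
  }
  rate <- rejections / n_rep
  expect_gt(rate, 0.02)
  expect_lt(rate, 0.09)
})
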