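# AdaIN moment matching and the switchable style coder.

test_that("instance moments match direct formula evaluation", {
  # oracle: population mean/std computed element-wise
  ch <- c(2, 4, 6, 8)
  m <- instance_moments(matrix(ch, 2), eps = 0)
  expect_equal(m$mean, mean(ch))
  expect_equal(m$sd, sqrt(mean((ch - mean(ch))^2)))  # 2.23606...
  expect_equal(m$sd, 2.2360679775, tolerance = 1e-9)

  # multi-channel random map against the same oracle
  x <- random_fmap(5, 7, 3, seed = 2)
  m <- instance_moments(x, eps = 0)
  for (k in 1:3) {
    v <- as.numeric(x[, , k])
    expect_equal(m$mean[k], mean(v))
    expect_equal(m$sd[k], sqrt(mean((v - mean(v))^2)))
  }
})

test_that("degenerate channels get the eps-stabilized std", {
  m <- instance_moments(matrix(3.5, 4, 4), eps = 1e-5)
  expect_equal(m$mean, 3.5)
  expect_equal(m$sd, sqrt(1e-5))
  # single pixel
  m1 <- instance_moments(matrix(0.7, 1, 1), eps = 1e-5)
  expect_equal(m1$mean, 0.7)
  expect_equal(m1$sd, sqrt(1e-5))
})

test_that("instance_moments rejects non-finite input", {
  x <- matrix(c(1, NA, 3, 4), 2)
  expect_error(instance_moments(x), "non-finite")
  expect_error(instance_moments(matrix(c(1, Inf, 3, 4), 2)), "non-finite")
})

test_that("adain_transform matches the element-wise formula", {
  x <- matrix(c(2, 4, 6, 8), 2)
  z <- adain_transform(x, sigma = 1, mu = 0, eps = 0)
  expect_close(mean(z), 0, 1e-12)
  expect_close(sqrt(mean((z - mean(z))^2)), 1, 1e-12)

  # independent element-wise evaluation on a random map
  x <- random_fmap(6, 6, 2, seed = 3)
  sg <- c(1.7, 0.4); mu <- c(-0.2, 3)
  z <- adain_transform(x, sg, mu, eps = 0)
  for (k in 1:2) {
    v <- as.numeric(x[, , k])
    expect_close(as.numeric(z[, , k]),
                 sg[k] * (v - mean(v)) / sqrt(mean((v - mean(v))^2)) + mu[k],
                 1e-10)
  }
})

test_that("adain identity and zero-variance cases", {
  x <- random_fmap(4, 4, 3, seed = 4)
  m <- instance_moments(x)
  expect_close(adain_transform(x, m$sd, m$mean), x, 1e-6)
  # constant channel maps to the target mean everywhere
  z <- adain_transform(matrix(5, 3, 3), sigma = 2, mu = -0.3)
  expect_close(z, -0.3, 1e-2)  # sigma * (0 / sqrt(eps)) + mu
})

test_that("adain rejects mismatched style vectors and negative sigma", {
  x <- random_fmap(4, 4, 3)
  expect_error(adain_transform(x, sigma = c(1, 1), mu = c(0, 0)), "channels")
  expect_error(adain_transform(x, sigma = c(1, -1, 1), mu = numeric(3)),
               "negative sigma")
})

test_that("moment matching, idempotence, and affine equivariance hold", {
  set.seed(42)
  for (rep in 1:10) {
    x <- random_fmap(8, 8, 4)
    sg <- runif(4, 0.1, 3)
    mu <- rnorm(4)
    z <- adain_transform(x, sg, mu)
    mz <- instance_moments(z, eps = 0)
    expect_close(mz$mean, mu, 1e-4)
    expect_close(mz$sd, sg, 1e-4)
    # idempotence
    expect_close(adain_transform(z, sg, mu), z, 1e-3)
    # affine equivariance: input moments are divided out
    a <- runif(1, 0.5, 2); b <- rnorm(1)
    expect_close(adain_transform(a * x + b, sg, mu), z, 1e-4)
  }
})

test_that("style coder has 9 sites with the generator's channel widths", {
  g <- build_switchable_generator(generator_config(base_channels = 8), seed = 1)
  expect_length(g$site_channels, 9L)
  expect_equal(g$site_channels, c(8, 16, 32, 64, 32, 16, 8, 8, 8))
  st <- style_code(1, g$coder)
  expect_length(st, 9L)
  for (i in 1:9) expect_length(st[[i]]$sigma, g$site_channels[i])
})

test_that("style_code(0) is exactly (sigma = 1, mu = 0) at all sites", {
  coder <- build_style_coder(c(4, 8, 4), seed = 3)
  # perturb weights arbitrarily: gamma = 0 must not see them
  coder$params$fc2$w[] <- rnorm(length(coder$params$fc2$w), 0, 5)
  st <- style_code(0, coder)
  for (s in st) {
    expect_identical(s$sigma, rep(1, length(s$sigma)))
    expect_identical(s$mu, rep(0, length(s$mu)))
  }
})

test_that("style_code(1) returns the rectified coder outputs", {
  coder <- build_style_coder(c(3, 5), seed = 9)
  # force some raw sigma outputs negative through the bias
  coder$params$fc2$b[1:3] <- c(-10, 10, -0.5)
  st <- style_code(1, coder)
  expect_true(all(st[[1]]$sigma >= 0))
  expect_true(all(st[[2]]$sigma >= 0))
  expect_equal(st[[1]]$sigma[1], 0)  # strongly negative raw value clamps to 0
  # gamma in between interpolates linearly
  st_half <- style_code(0.5, coder)
  expect_close(st_half[[1]]$sigma, 0.5 * 1 + 0.5 * st[[1]]$sigma, 1e-12)
  expect_close(st_half[[1]]$mu, 0.5 * st[[1]]$mu, 1e-12)
})

test_that("style_code validates gamma", {
  coder <- build_style_coder(c(2), seed = 1)
  expect_error(style_code(-0.1, coder), "gamma")
  expect_error(style_code(1.5, coder), "gamma")
  expect_error(style_code(c(0, 1), coder), "gamma")
})

test_that("adain with style_code(0) equals plain instance normalization", {
  g <- build_switchable_generator(generator_config(base_channels = 4), seed = 2)
  st <- style_code(0, g$coder)
  x <- random_fmap(6, 6, 4, seed = 5)
  z <- adain_transform(x, st[[1]]$sigma, st[[1]]$mu)
  mz <- instance_moments(z, eps = 0)
  expect_close(mz$mean, rep(0, 4), 1e-4)
  expect_close(mz$sd, rep(1, 4), 1e-4)
})
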