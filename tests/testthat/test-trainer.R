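# Schedule, replay buffer, augmentation, and the training loop's
# bookkeeping, determinism and checkpoint round-trip.

test_that("learning-rate schedule matches the published protocol", {
  cfg <- train_config()  # 200 epochs, decay from 100, 2e-4
  expect_equal(lr_at_epoch(50, cfg), 2e-4)
  expect_equal(lr_at_epoch(100, cfg), 2e-4)
  expect_equal(lr_at_epoch(150, cfg), 1e-4)
  expect_equal(lr_at_epoch(200, cfg), 0)
  expect_error(lr_at_epoch(0, cfg), "out of range")
  expect_error(lr_at_epoch(201, cfg), "out of range")
})

test_that("schedule is continuous, non-increasing, and hits zero", {
  cfg <- train_config()
  lrs <- lr_at_epoch(1:200, cfg)
  expect_true(all(diff(lrs) <= 0))
  expect_equal(lrs[200], 0)
  # continuity at the knee: per-epoch decrement is lr/100 afterwards
  expect_close(lrs[101], 2e-4 * 0.99, 1e-12)
  expect_true(all(abs(diff(lrs[101:200]) + 2e-6) < 1e-12))
})

test_that("buffer fill phase returns inputs and capacity pins at 50", {
  set.seed(1)
  buf <- image_buffer(50)
  for (i in 1:50) {
    out <- buffer_query(buf, i)
    expect_identical(out, i)
    expect_length(buf$stored, i)
  }
  for (i in 51:120) buffer_query(buf, i)
  expect_length(buf$stored, 50L)
})

test_that("post-fill historical-return frequency is 0.5 within 0.02", {
  set.seed(2024)
  buf <- image_buffer(50)
  for (i in 1:50) buffer_query(buf, i)
  n <- 10000
  hist_returns <- 0
  for (i in 1:n) {
    out <- buffer_query(buf, 1e6 + i)
    if (!identical(out, 1e6 + i)) hist_returns <- hist_returns + 1
  }
  expect_lt(abs(hist_returns / n - 0.5), 0.02)
})

test_that("every stored image is eventually evicted (no starvation)", {
  set.seed(7)
  buf <- image_buffer(20)
  for (i in 1:20) buffer_query(buf, i)
  for (i in 21:2000) buffer_query(buf, i)
  expect_true(all(unlist(buf$stored) > 20))
})

test_that("augment crops and flips reproducibly", {
  img <- matrix(seq_len(64 * 64), 64)
  set.seed(3); a1 <- augment(img, 32)
  expect_identical(dim(a1), c(32L, 32L))
  set.seed(3); a2 <- augment(img, 32)
  expect_identical(a1, a2)
  # crop == image size: flips only, content preserved as a set
  set.seed(4); f <- augment(img, 64)
  expect_identical(sort(as.numeric(f)), as.numeric(img))
  expect_error(augment(img, 65), "exceeds")
})

test_that("toy training completes with full loss bookkeeping", {
  man <- toy_manifest()
  fit <- micro_fit(epochs = 2, manifest = man)
  steps <- min(sum(man$split == "train" & man$domain == "A"),
               sum(man$split == "train" & man$domain == "B"))
  expect_s3_class(fit$log, "tbl_df")
  expect_equal(nrow(fit$log), 2 * steps)
  expect_true(all(c("adv_g", "adv_d_a", "adv_d_b", "cyc", "id", "total", "lr")
                  %in% names(fit$log)))
  expect_true(all(is.finite(fit$log$total)))
  expect_true(all(fit$log$total >= 0))
  # generator-side identity: total = 1*adv + 10*cyc + 5*id
  expect_close(fit$log$total,
               fit$log$adv_g + 10 * fit$log$cyc + 5 * fit$log$id, 1e-10)
})

test_that("identical seeds give identical runs; different seeds differ", {
  man <- toy_manifest(n_subjects = 3, slices = 1)
  f1 <- micro_fit(epochs = 1, seed = 42, manifest = man)
  f2 <- micro_fit(epochs = 1, seed = 42, manifest = man)
  expect_identical(f1$log, f2$log)
  expect_identical(f1$generator$params, f2$generator$params)
  f3 <- micro_fit(epochs = 1, seed = 43, manifest = man)
  expect_false(identical(f1$log$total, f3$log$total))
})

test_that("both model variants train and the baseline has two generators", {
  man <- toy_manifest(n_subjects = 3, slices = 1)
  fit <- micro_fit(model = "cyclegan", epochs = 1, manifest = man)
  expect_null(fit$generator)
  expect_s3_class(fit$generators, "sg_generator_pair")
  y <- synthesize(fit, man$image[1], "a2b")
  expect_identical(dim(y[[1]]), dim(man$image[[1]]))
})

test_that("training errors are informative", {
  man <- toy_manifest(n_subjects = 3, slices = 1)
  man_a_only <- man[man$domain == "A", ]
  expect_error(
    train_translation(man_a_only, "switchable",
                      train_config(epochs = 1, crop = 32, seed = 1),
                      gen_config = generator_config(4), disc_base_channels = 4),
    "both domains")
  empty <- generate_dataset(2, 1, phantom_config(size = 32),
                            master_seed = 1, materialize = FALSE)
  expect_error(
    train_translation(empty, "switchable",
                      train_config(epochs = 1, crop = 32, seed = 1),
                      gen_config = generator_config(4), disc_base_channels = 4),
    "materialize")
})

test_that("checkpoint round-trip preserves forward outputs and the log", {
  man <- toy_manifest(n_subjects = 3, slices = 1)
  fit <- micro_fit(epochs = 1, manifest = man)
  x <- man$image[[1]]
  y_before <- generate(fit$generator, x, 0)
  path <- tempfile(fileext = ".rds")
  save_checkpoint(fit, path)
  fit2 <- load_checkpoint(path)
  expect_identical(generate(fit2$generator, x, 0), y_before)
  expect_identical(generate(fit2$generator, x, 1), generate(fit$generator, x, 1))
  expect_identical(fit2$log, fit$log)
  expect_identical(discriminate(fit2$d_a, x), discriminate(fit$d_a, x))
  unlink(path)
})

test_that("discriminator update leaves the generator unchanged and vice versa", {
  man <- toy_manifest(n_subjects = 3, slices = 1)
  set.seed(1)
  g <- build_switchable_generator(generator_config(4), seed = 1)
  d <- build_discriminator(seed = 2, base_channels = 4)
  gp_before <- g$params
  x <- switchgan:::as_feature_map(man$image[[1]])
  st <- switchgan:::disc_update(d, x, x * 0.5, switchgan:::adam_init(),
                                2e-4, train_config(epochs = 1))
  expect_identical(g$params, gp_before)      # generator untouched
  expect_gt(st$loss, 0)
})

test_that("tidy/glance/autoplot work on fits", {
  fit <- micro_fit(epochs = 1, manifest = toy_manifest(3, 1))
  expect_identical(tidy(fit), fit$log)
  gl <- glance(fit)
  expect_equal(gl$model, "switchable")
  expect_gt(gl$parameters, 0)
  p <- autoplot(fit)
  expect_s3_class(p, "ggplot")
})
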