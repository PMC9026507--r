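# Phantom simulator: determinism, contrast orderings, registration by
# construction, dataset bookkeeping, splits, and subsampling.

test_that("phantoms are deterministic given config and seed", {
  cfg <- phantom_config(size = 64)
  p1 <- generate_phantom(cfg, subject_seed = 12)
  p2 <- generate_phantom(cfg, subject_seed = 12)
  expect_identical(p1, p2)
  p3 <- generate_phantom(cfg, subject_seed = 13)
  expect_false(identical(p1$labels, p3$labels))
})

test_that("noiseless phantoms respect the contrast intensity orderings", {
  cfg <- phantom_config(size = 64, noise_sigma = 0, bias_amplitude = 0)
  for (sd in c(1, 7, 23, 101)) {
    p <- generate_phantom(cfg, subject_seed = sd)
    lab <- p$labels
    # T2-like: water bright - fluid above WM-like and GM above WM
    expect_gt(mean(p$contrast_b[lab == 4]), mean(p$contrast_b[lab == 2]))
    expect_gt(mean(p$contrast_b[lab == 3]), mean(p$contrast_b[lab == 2]))
    # T1-like: fat bright, fluid dark
    expect_gt(mean(p$contrast_a[lab == 1]), mean(p$contrast_a[lab == 4]))
    expect_gt(mean(p$contrast_a[lab == 2]), mean(p$contrast_a[lab == 3]))
    expect_true(all(p$contrast_a >= -1 & p$contrast_a <= 1))
  }
})

test_that("orderings also hold per seed with the default noise and bias", {
  cfg <- phantom_config(size = 64)
  for (sd in c(3, 17)) {
    p <- generate_phantom(cfg, subject_seed = sd)
    lab <- p$labels
    expect_gt(mean(p$contrast_b[lab == 4]), mean(p$contrast_b[lab == 2]))
    expect_gt(mean(p$contrast_a[lab == 1]), mean(p$contrast_a[lab == 4]))
  }
})

test_that("the two contrasts of a record share one label map (registration)", {
  p <- generate_phantom(phantom_config(size = 64, noise_sigma = 0,
                                       bias_amplitude = 0), 5)
  # class-mean rendering: within-class intensity is constant, so the label
  # geometry is recoverable identically from both contrasts
  expect_identical(dim(p$contrast_a), dim(p$contrast_b))
  for (cl in 0:4) {
    idx <- p$labels == cl
    expect_lt(sd(p$contrast_a[idx]), 1e-12)
    expect_lt(sd(p$contrast_b[idx]), 1e-12)
  }
})

test_that("phantom_config validates the contrast orderings", {
  bad_a <- c(background = 0.02, fat = 0.1, wm = 0.75, gm = 0.55, fluid = 0.15)
  expect_error(phantom_config(intensity_a = bad_a))
})

test_that("dataset bookkeeping: slice counts and per-domain balance", {
  man <- generate_dataset(3, 2, phantom_config(size = 32), master_seed = 1)
  expect_equal(nrow(man), 12L)   # 3 subjects x 2 slices x 2 contrasts
  expect_equal(sum(man$domain == "A"), 6L)
  expect_equal(sum(man$domain == "B"), 6L)
  # regeneration reproduces byte-identical images
  man2 <- generate_dataset(3, 2, phantom_config(size = 32), master_seed = 1)
  expect_identical(man$image, man2$image)
  expect_identical(man$seed, man2$seed)
})

test_that("large-scale bookkeeping without materialization", {
  man <- generate_dataset(1517, 10, master_seed = 1, materialize = FALSE)
  expect_equal(nrow(man), 30340L)
  expect_equal(length(unique(man$subject_id)), 1517L)
  counts <- table(man$split) / 20   # subjects per split
  expect_equal(as.numeric(counts[c("train", "val", "test")]),
               c(1063, 151, 303))
})

test_that("split follows the floor rule and is disjoint-exhaustive", {
  ids <- sprintf("x%04d", 1:1517)
  sp <- split_subjects(ids, master_seed = 3)
  expect_equal(lengths(sp), c(train = 1063L, val = 151L, test = 303L))
  expect_identical(sort(unname(unlist(sp))), sort(ids))
  sp10 <- split_subjects(letters[1:10], master_seed = 3)
  expect_equal(lengths(sp10), c(train = 7L, val = 1L, test = 2L))
  expect_error(split_subjects(letters[1:9]), "at least 10")
  # deterministic given the seed
  expect_identical(split_subjects(ids, 5), split_subjects(ids, 5))
})

test_that("subsampling balances domains and leaves test rows untouched", {
  man <- generate_dataset(20, 3, phantom_config(size = 32), master_seed = 2)
  n_test <- sum(man$split == "test")
  sub <- subsample_manifest(man, 20, seed = 4)
  expect_equal(sum(sub$split == "train" & sub$domain == "A"), 10L)
  expect_equal(sum(sub$split == "train" & sub$domain == "B"), 10L)
  expect_equal(sum(sub$split == "test"), n_test)
  # identity request
  n_train <- sum(man$split == "train")
  expect_equal(nrow(subsample_manifest(man, n_train, 1)), nrow(man))
  expect_error(subsample_manifest(man, n_train + 2, 1), "available")
  # reproducible
  expect_identical(subsample_manifest(man, 20, 9)$seed,
                   subsample_manifest(man, 20, 9)$seed)
})

test_that("pooled pixel histograms of the two domains differ", {
  man <- generate_dataset(6, 2, phantom_config(size = 64), master_seed = 8)
  a <- unlist(man$image[man$domain == "A"])
  b <- unlist(man$image[man$domain == "B"])
  ks <- suppressWarnings(stats::ks.test(a, b))
  expect_lt(ks$p.value, 1e-6)
})

test_that("synthesize_test_pairs joins registered pairs", {
  man <- toy_manifest(n_subjects = 4, slices = 1)
  fit <- micro_fit(epochs = 1, manifest = man)
  pairs <- synthesize_test_pairs(fit, man, split = "test")
  n_test_pairs <- sum(man$split == "test" & man$domain == "A")
  expect_equal(nrow(pairs), 2L * n_test_pairs)
  expect_setequal(unique(pairs$direction), c("a2b", "b2a"))
  expect_identical(dim(pairs$synthesized[[1]]), dim(pairs$target[[1]]))
})
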