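# Shared fixtures, built in code at test time.

# A tiny materialized two-domain manifest for fast unit tests.
toy_manifest <- function(n_subjects = 6, slices = 2, size = 32, seed = 11,
                         noise = 0.02) {
  man <- generate_dataset(n_subjects, slices,
                          phantom_config(size = size, noise_sigma = noise),
                          master_seed = seed)
  # tiny sets fall below the 10-subject split threshold: hold the last
  # subject out as a test pair manually
  if (all(man$split == "train")) {
    man$split[man$subject_id == max(man$subject_id)] <- "test"
  }
  man
}

# A micro training run used by smoke/determinism/checkpoint tests.
micro_fit <- function(model = "switchable", epochs = 2, seed = 5,
                      manifest = NULL) {
  if (is.null(manifest)) manifest <- toy_manifest()
  train_translation(
    manifest, model = model,
    config = train_config(epochs = epochs, crop = 32,
                          decay_start_epoch = epochs, seed = seed),
    gen_config = generator_config(base_channels = 4),
    disc_base_channels = 4
  )
}

# Random feature map with controlled channels.
random_fmap <- function(h = 8, w = 8, c = 4, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  array(rnorm(h * w * c), c(h, w, c))
}

expect_close <- function(actual, expected, tol = 1e-8) {
  expect_lt(max(abs(actual - expected)), tol)
}
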