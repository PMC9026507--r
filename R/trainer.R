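# Alternating adversarial training with the published protocol: Adam
# (beta1 = 0.5, beta2 = 0.999), lr 2e-4 held for the first half of training
# then linearly decayed to zero, batch size 1, random 128-crop plus
# horizontal/vertical flips, and a 50-image replay buffer feeding each
# discriminator.

#' Training configuration
#'
#' Defaults are the full-scale published protocol; toy CPU runs lower
#' `epochs` and `crop` (see the vignette).
#'
#' @param epochs Total epochs; one epoch is one pass over the smaller
#'   domain's slice list.
#' @param lr_initial Initial Adam learning rate.
#' @param beta1,beta2 Adam moment coefficients.
#' @param batch_size Mini-batch size (the method trains with 1).
#' @param crop Square crop size for augmentation.
#' @param buffer_capacity Replay-buffer capacity per discriminator.
#' @param decay_start_epoch Last epoch at the initial rate; the rate then
#'   decays linearly to exactly zero at `epochs`.
#' @param seed Master seed covering weight init, shuffling, cropping, flips
#'   and buffer coin-flips.
#' @param checkpoint_every If not `NULL` and `checkpoint_dir` is given to
#'   [train_translation()], save a checkpoint every this many epochs.
#' @return A `train_config` list.
#' @export
train_config <- function(epochs = 200L, lr_initial = 2e-4, beta1 = 0.5,
                         beta2 = 0.999, batch_size = 1L, crop = 128L,
                         buffer_capacity = 50L, decay_start_epoch = 100L,
                         seed = 1L, checkpoint_every = NULL) {
  stopifnot(epochs >= 1, decay_start_epoch >= 1)
  structure(list(epochs = as.integer(epochs), lr_initial = lr_initial,
                 beta1 = beta1, beta2 = beta2, batch_size = as.integer(batch_size),
                 crop = as.integer(crop), buffer_capacity = as.integer(buffer_capacity),
                 decay_start_epoch = as.integer(decay_start_epoch),
                 seed = as.integer(seed), checkpoint_every = checkpoint_every),
            class = "train_config")
}

#' Learning rate at a given epoch
#'
#' Constant at `lr_initial` through `decay_start_epoch`, then linearly
#' decayed, reaching exactly zero at the final epoch. With the defaults
#' (200 epochs, decay from 100): `lr(50) = 2e-4`, `lr(150) = 1e-4`,
#' `lr(200) = 0`.
#'
#' @param epoch 1-based epoch index.
#' @param config A [train_config()].
#' @return The learning rate (non-negative scalar).
#' @export
lr_at_epoch <- function(epoch, config = train_config()) {
  if (any(epoch < 1 | epoch > config$epochs)) {
    stop("epoch out of range [1, ", config$epochs, "]")
  }
  n_decay <- config$epochs - config$decay_start_epoch
  ifelse(epoch <= config$decay_start_epoch | n_decay <= 0L,
         config$lr_initial,
         config$lr_initial * (1 - (epoch - config$decay_start_epoch) / n_decay))
}

#' Create an image replay buffer
#'
#' Stores previously generated images so discriminators train against a
#' history of fakes rather than only the newest generator output.
#'
#' @param capacity Maximum number of stored images.
#' @return An `sg_image_buffer` object.
#' @export
image_buffer <- function(capacity = 50L) {
  b <- new.env(parent = emptyenv())
  b$capacity <- as.integer(capacity)
  b$stored <- vector("list", 0L)
  class(b) <- "sg_image_buffer"
  b
}

#' Query the replay buffer with a newly generated image
#'
#' While the buffer is filling, the new image is stored and returned
#' unchanged. Once full, with probability 0.5 the new image is returned;
#' otherwise a uniformly chosen stored image is returned and replaced by the
#' new one. Uses the session RNG, so a seeded run is reproducible.
#'
#' @param buffer An [image_buffer()].
#' @param new_image The latest generated image.
#' @return An image to present to the discriminator.
#' @export
buffer_query <- function(buffer, new_image) {
  stopifnot(inherits(buffer, "sg_image_buffer"))
  n <- length(buffer$stored)
  if (n < buffer$capacity) {
    buffer$stored[[n + 1L]] <- new_image
    return(new_image)
  }
  if (runif(1) < 0.5) return(new_image)
  i <- sample.int(buffer$capacity, 1L)
  old <- buffer$stored[[i]]
  buffer$stored[[i]] <- new_image
  old
}

#' Random crop-and-flip augmentation
#'
#' Uniformly positioned square crop followed by independent horizontal and
#' vertical flips, each with probability 0.5. When `crop` equals the image
#' size only the flips apply.
#'
#' @param image `H x W` matrix.
#' @param crop Crop side length; must not exceed either image dimension.
#' @return A `crop x crop` matrix.
#' @export
augment <- function(image, crop) {
  d <- dim(image)
  if (crop > d[1] || crop > d[2]) {
    stop("crop size ", crop, " exceeds image dimensions ", d[1], "x", d[2])
  }
  i0 <- if (d[1] > crop) sample.int(d[1] - crop + 1L, 1L) else 1L
  j0 <- if (d[2] > crop) sample.int(d[2] - crop + 1L, 1L) else 1L
  out <- image[i0:(i0 + crop - 1L), j0:(j0 + crop - 1L), drop = FALSE]
  if (runif(1) < 0.5) out <- out[, rev(seq_len(crop)), drop = FALSE]
  if (runif(1) < 0.5) out <- out[rev(seq_len(crop)), , drop = FALSE]
  out
}

# ---- Adam ------------------------------------------------------------------

adam_init <- function() list(t = 0L, m = list(), v = list())

adam_step <- function(params, grads, state, lr, beta1, beta2, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(grads)) {
    for (f in names(grads[[nm]])) {
      g <- grads[[nm]][[f]]
      m0 <- state$m[[nm]][[f]] %||% 0
      v0 <- state$v[[nm]][[f]] %||% 0
      m1 <- beta1 * m0 + (1 - beta1) * g
      v1 <- beta2 * v0 + (1 - beta2) * g^2
      state$m[[nm]][[f]] <- m1
      state$v[[nm]][[f]] <- v1
      params[[nm]][[f]] <- params[[nm]][[f]] -
        lr * (m1 / bc1) / (sqrt(v1 / bc2) + eps)
    }
  }
  list(params = params, state = state)
}

# ---- Training loop ---------------------------------------------------------

scale_dstyle <- function(dstyle, gamma) {
  lapply(dstyle, function(s) list(dsigma = gamma * s$dsigma, dmu = gamma * s$dmu))
}

sum_dstyle <- function(...) {
  parts <- list(...)
  out <- parts[[1]]
  for (p in parts[-1]) {
    for (i in seq_along(out)) {
      out[[i]]$dsigma <- out[[i]]$dsigma + p[[i]]$dsigma
      out[[i]]$dmu <- out[[i]]$dmu + p[[i]]$dmu
    }
  }
  out
}

#' Train a translation model on an unpaired two-domain manifest
#'
#' Runs the alternating adversarial protocol: per step one image is drawn
#' from each domain (the two streams are shuffled independently, so pairing
#' is never seen), both translation directions are formed, the generator
#' side (plus style coder, for the switchable model) is updated on the
#' weighted total loss, and each discriminator is then updated on real
#' versus replay-buffered fake patches.
#'
#' @param manifest A phantom manifest (see [generate_dataset()]) or any
#'   tibble with columns `domain` ("A"/"B"), `split`, and `image`
#'   (list-column of matrices in `[-1, 1]`). Only `split == "train"` rows
#'   are used.
#' @param model `"switchable"` (single AdaIN-switched generator) or
#'   `"cyclegan"` (two-generator baseline).
#' @param config A [train_config()].
#' @param weights A [loss_weights()].
#' @param gen_config A [generator_config()]; its `base_channels` sets model
#'   capacity.
#' @param disc_base_channels Discriminator width (64 at full scale).
#' @param checkpoint_dir Optional directory for periodic checkpoints.
#' @param verbose Print a line per epoch.
#' @return An `switchgan_fit` object: networks, the per-step loss log
#'   (a tibble; also available via [tidy()]), and the configuration.
#' @export
train_translation <- function(manifest, model = c("switchable", "cyclegan"),
                              config = train_config(), weights = loss_weights(),
                              gen_config = generator_config(),
                              disc_base_channels = 64L,
                              checkpoint_dir = NULL, verbose = FALSE) {
  model <- match.arg(model)
  train_rows <- manifest[manifest$split == "train", ]
  imgs_a <- train_rows$image[train_rows$domain == "A"]
  imgs_b <- train_rows$image[train_rows$domain == "B"]
  if (length(imgs_a) == 0L || length(imgs_b) == 0L) {
    stop("manifest must provide training images in both domains")
  }
  if (any(vapply(c(imgs_a[1], imgs_b[1]), is.null, logical(1)))) {
    stop("manifest images are not materialized; run generate_dataset() with materialize = TRUE")
  }

  set.seed(config$seed)
  if (model == "switchable") {
    gen <- build_switchable_generator(gen_config, seed = sample.int(1e6, 1))
    gens <- NULL
  } else {
    gens <- build_cyclegan_pair(gen_config, seed = sample.int(1e6, 1))
  }
  d_a <- build_discriminator(seed = sample.int(1e6, 1), base_channels = disc_base_channels)
  d_b <- build_discriminator(seed = sample.int(1e6, 1), base_channels = disc_base_channels)
  buf_a <- image_buffer(config$buffer_capacity)
  buf_b <- image_buffer(config$buffer_capacity)

  opt_g <- adam_init(); opt_coder <- adam_init()
  opt_g2 <- adam_init()          # second generator of the baseline pair
  opt_da <- adam_init(); opt_db <- adam_init()

  steps_per_epoch <- min(length(imgs_a), length(imgs_b))
  log_rows <- vector("list", config$epochs * steps_per_epoch)
  row_i <- 0L

  for (epoch in seq_len(config$epochs)) {
    lr <- lr_at_epoch(epoch, config)
    ord_a <- sample.int(length(imgs_a))
    ord_b <- sample.int(length(imgs_b))
    for (s in seq_len(steps_per_epoch)) {
      a <- as_feature_map(augment(imgs_a[[ord_a[s]]], config$crop))
      b <- as_feature_map(augment(imgs_b[[ord_b[s]]], config$crop))

      if (model == "switchable") {
        sres <- switchable_step(gen, d_a, d_b, a, b, weights)
      } else {
        sres <- cyclegan_step(gens, d_a, d_b, a, b, weights)
      }
      if (!is.finite(sres$report$total)) {
        stop("non-finite generator loss at epoch ", epoch, ", step ", s,
             " (components: adv=", sres$report$adv_g, ", cyc=", sres$report$cyc,
             ", id=", sres$report$id, ")")
      }

      # Generator-side update
      if (model == "switchable") {
        up <- adam_step(gen$params, sres$grads_g, opt_g, lr, config$beta1, config$beta2)
        gen$params <- up$params; opt_g <- up$state
        up <- adam_step(gen$coder$params, sres$grads_coder, opt_coder, lr,
                        config$beta1, config$beta2)
        gen$coder$params <- up$params; opt_coder <- up$state
      } else {
        up <- adam_step(gens$a2b$params, sres$grads_ab, opt_g, lr, config$beta1, config$beta2)
        gens$a2b$params <- up$params; opt_g <- up$state
        up <- adam_step(gens$b2a$params, sres$grads_ba, opt_g2, lr, config$beta1, config$beta2)
        gens$b2a$params <- up$params; opt_g2 <- up$state
      }

      # Discriminator updates with buffered fakes
      fb_use <- buffer_query(buf_b, sres$fake_b)
      fa_use <- buffer_query(buf_a, sres$fake_a)
      db_up <- disc_update(d_b, b, fb_use, opt_db, lr, config)
      opt_db <- db_up$state
      da_up <- disc_update(d_a, a, fa_use, opt_da, lr, config)
      opt_da <- da_up$state

      row_i <- row_i + 1L
      log_rows[[row_i]] <- tibble::tibble(
        epoch = epoch, step = s, adv_g = sres$report$adv_g,
        adv_d_a = da_up$loss, adv_d_b = db_up$loss,
        cyc = sres$report$cyc, id = sres$report$id,
        total = sres$report$total, lr = lr
      )
    }
    if (verbose) {
      last <- log_rows[[row_i]]
      message(sprintf("epoch %d/%d  lr %.2e  total %.4f (adv %.3f cyc %.3f id %.3f)",
                      epoch, config$epochs, lr, last$total, last$adv_g,
                      last$cyc, last$id))
    }
    if (!is.null(checkpoint_dir) && !is.null(config$checkpoint_every) &&
        epoch %% config$checkpoint_every == 0L) {
      fit <- make_fit(model, gen, gens, d_a, d_b, config, weights, gen_config,
                      dplyr::bind_rows(log_rows[seq_len(row_i)]), epoch)
      save_checkpoint(fit, file.path(checkpoint_dir, sprintf("epoch_%04d.rds", epoch)))
    }
  }

  make_fit(model, gen, gens, d_a, d_b, config, weights, gen_config,
           dplyr::bind_rows(log_rows), config$epochs)
}

make_fit <- function(model, gen, gens, d_a, d_b, config, weights, gen_config,
                     log, epoch) {
  structure(list(model = model,
                 generator = if (model == "switchable") gen,
                 generators = if (model == "cyclegan") gens,
                 d_a = d_a, d_b = d_b, config = config, weights = weights,
                 gen_config = gen_config, log = log, epoch = epoch),
            class = "switchgan_fit")
}

# One generator-side step of the switchable model. gamma = 0 styles the
# output as domain B (G_AB = G(.; F(0))); gamma = 1 as domain A.
switchable_step <- function(gen, d_a, d_b, a, b, weights) {
  cf <- coder_fw(gen$coder)
  style0 <- structure(lapply(gen$site_channels, function(ch)
    list(sigma = rep(1, ch), mu = numeric(ch))), class = "sg_style")
  style1 <- structure(lapply(cf$sites, function(s)
    list(sigma = s$sigma, mu = s$mu)), class = "sg_style")

  p_fb <- gen_forward(gen, a, style0)        # A -> B
  p_fa <- gen_forward(gen, b, style1)        # B -> A
  p_ra <- gen_forward(gen, p_fb$y, style1)   # back to A
  p_rb <- gen_forward(gen, p_fa$y, style0)   # back to B
  p_ib <- gen_forward(gen, b, style0)        # identity on B
  p_ia <- gen_forward(gen, a, style1)        # identity on A

  q_fb <- disc_forward(d_b, p_fb$y)
  q_fa <- disc_forward(d_a, p_fa$y)

  adv_g <- adversarial_loss_g(q_fb$y) + adversarial_loss_g(q_fa$y)
  cyc <- cycle_loss(a, p_ra$y, b, p_rb$y)
  id <- identity_loss(b, p_ib$y, a, p_ia$y)
  total <- total_generator_loss(adv_g, cyc, id, weights)

  bw_ra <- gen_backward(gen, p_ra$cache, weights$lambda_cyc * d_mae(p_ra$y, a))
  bw_rb <- gen_backward(gen, p_rb$cache, weights$lambda_cyc * d_mae(p_rb$y, b))
  d_fb <- bw_ra$dx + weights$lambda_adv *
    disc_backward(d_b, q_fb$cache, d_lsgan_toward(q_fb$y, 1), want_params = FALSE)$dx
  d_fa <- bw_rb$dx + weights$lambda_adv *
    disc_backward(d_a, q_fa$cache, d_lsgan_toward(q_fa$y, 1), want_params = FALSE)$dx
  bw_fb <- gen_backward(gen, p_fb$cache, d_fb)
  bw_fa <- gen_backward(gen, p_fa$cache, d_fa)
  bw_ib <- gen_backward(gen, p_ib$cache, weights$lambda_id * d_mae(p_ib$y, b))
  bw_ia <- gen_backward(gen, p_ia$cache, weights$lambda_id * d_mae(p_ia$y, a))

  grads_g <- Reduce(add_grads, list(bw_ra$grads, bw_rb$grads, bw_fb$grads,
                                    bw_fa$grads, bw_ib$grads, bw_ia$grads))
  # Only gamma = 1 passes reach the coder (the gamma = 0 style is constant).
  dstyle1 <- sum_dstyle(bw_ra$dstyle, bw_fa$dstyle, bw_ia$dstyle)
  grads_coder <- coder_bw(gen$coder, cf$cache, scale_dstyle(dstyle1, 1))

  list(report = list(adv_g = adv_g, cyc = cyc, id = id, total = total),
       grads_g = grads_g, grads_coder = grads_coder,
       fake_b = p_fb$y, fake_a = p_fa$y)
}

cyclegan_step <- function(gens, d_a, d_b, a, b, weights) {
  st_ab <- identity_style(gens$a2b$site_channels)
  st_ba <- st_ab
  g_ab <- gens$a2b; g_ba <- gens$b2a

  p_fb <- gen_forward(g_ab, a, st_ab)
  p_fa <- gen_forward(g_ba, b, st_ba)
  p_ra <- gen_forward(g_ba, p_fb$y, st_ba)
  p_rb <- gen_forward(g_ab, p_fa$y, st_ab)
  p_ib <- gen_forward(g_ab, b, st_ab)
  p_ia <- gen_forward(g_ba, a, st_ba)

  q_fb <- disc_forward(d_b, p_fb$y)
  q_fa <- disc_forward(d_a, p_fa$y)

  adv_g <- adversarial_loss_g(q_fb$y) + adversarial_loss_g(q_fa$y)
  cyc <- cycle_loss(a, p_ra$y, b, p_rb$y)
  id <- identity_loss(b, p_ib$y, a, p_ia$y)
  total <- total_generator_loss(adv_g, cyc, id, weights)

  bw_ra <- gen_backward(g_ba, p_ra$cache, weights$lambda_cyc * d_mae(p_ra$y, a))
  bw_rb <- gen_backward(g_ab, p_rb$cache, weights$lambda_cyc * d_mae(p_rb$y, b))
  d_fb <- bw_ra$dx + weights$lambda_adv *
    disc_backward(d_b, q_fb$cache, d_lsgan_toward(q_fb$y, 1), want_params = FALSE)$dx
  d_fa <- bw_rb$dx + weights$lambda_adv *
    disc_backward(d_a, q_fa$cache, d_lsgan_toward(q_fa$y, 1), want_params = FALSE)$dx
  bw_fb <- gen_backward(g_ab, p_fb$cache, d_fb)
  bw_fa <- gen_backward(g_ba, p_fa$cache, d_fa)
  bw_ib <- gen_backward(g_ab, p_ib$cache, weights$lambda_id * d_mae(p_ib$y, b))
  bw_ia <- gen_backward(g_ba, p_ia$cache, weights$lambda_id * d_mae(p_ia$y, a))

  grads_ab <- Reduce(add_grads, list(bw_rb$grads, bw_fb$grads, bw_ib$grads))
  grads_ba <- Reduce(add_grads, list(bw_ra$grads, bw_fa$grads, bw_ia$grads))

  list(report = list(adv_g = adv_g, cyc = cyc, id = id, total = total),
       grads_ab = grads_ab, grads_ba = grads_ba,
       fake_b = p_fb$y, fake_a = p_fa$y)
}

disc_update <- function(d, real, fake, state, lr, config) {
  qr <- disc_forward(d, real)
  qf <- disc_forward(d, fake)
  loss <- adversarial_loss_d(qr$y, qf$y)
  gr <- add_grads(
    disc_backward(d, qr$cache, 0.5 * d_lsgan_toward(qr$y, 1))$grads,
    disc_backward(d, qf$cache, 0.5 * d_lsgan_toward(qf$y, 0))$grads
  )
  up <- adam_step(d$params, gr, state, lr, config$beta1, config$beta2)
  d$params <- up$params
  list(state = up$state, loss = loss)
}

#' Translate a set of images with a fitted model
#'
#' @param fit A `switchgan_fit`.
#' @param images List of `H x W` matrices in `[-1, 1]`.
#' @param direction `"a2b"` or `"b2a"`.
#' @return List of translated matrices.
#' @export
synthesize <- function(fit, images, direction = c("a2b", "b2a")) {
  direction <- match.arg(direction)
  stopifnot(inherits(fit, "switchgan_fit"))
  g <- if (fit$model == "switchable") fit$generator
       else if (direction == "a2b") fit$generators$a2b else fit$generators$b2a
  gamma <- if (direction == "a2b") 0 else 1
  lapply(images, function(im) generate(g, im, gamma = gamma))
}

#' @export
print.switchgan_fit <- function(x, ...) {
  cat("<switchgan fit>", x$model, "model,", x$epoch, "epochs\n")
  last <- x$log[x$log$epoch == max(x$log$epoch), ]
  cat(sprintf("  final-epoch median losses: total %.4f, adv %.4f, cyc %.4f, id %.4f\n",
              stats::median(last$total), stats::median(last$adv_g),
              stats::median(last$cyc), stats::median(last$id)))
  invisible(x)
}
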