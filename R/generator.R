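# The switchable U-net generator.
#
# Contracting path: four stride-2 4x4 convolutions doubling the channel
# count (1 -> c -> 2c -> 4c -> 8c), each followed by an AdaIN site and a
# leaky rectifier. Expansive path: four stride-2 4x4 transposed convolutions
# halving channels, each followed by an AdaIN site and a leaky rectifier,
# with skip concatenation from the matching encoder stage before each of the
# last three up-steps; a 3x3 fusion convolution carries the ninth AdaIN
# site, and a final 1x1 convolution maps the c-channel features to one
# channel through a saturating tanh so outputs live in [-1, 1].

#' Generator architecture configuration
#'
#' @param base_channels Channels after the first convolution; each
#'   down-sampling step doubles this (default 64, the full-scale setting;
#'   toy CPU experiments use 8).
#' @param in_channels,out_channels Image channels (grayscale: 1).
#' @param eps Stabilizer used inside every AdaIN site.
#' @param slope Leaky-rectifier slope.
#' @return A `generator_config` list.
#' @export
generator_config <- function(base_channels = 64L, in_channels = 1L,
                             out_channels = 1L, eps = 1e-5, slope = 0.2) {
  stopifnot(base_channels >= 1)
  structure(list(base_channels = as.integer(base_channels),
                 in_channels = as.integer(in_channels),
                 out_channels = as.integer(out_channels),
                 eps = eps, slope = slope, depth = 4L),
            class = "generator_config")
}

# Channel width at each of the nine AdaIN sites for a given base width.
adain_site_channels <- function(c) as.integer(c(c, 2 * c, 4 * c, 8 * c,
                                                4 * c, 2 * c, c, c, c))

build_backbone <- function(config) {
  c <- config$base_channels
  list(
    enc1 = conv_init(config$in_channels, c, 4L),
    enc2 = conv_init(c, 2L * c, 4L),
    enc3 = conv_init(2L * c, 4L * c, 4L),
    enc4 = conv_init(4L * c, 8L * c, 4L),
    dec1 = tconv_init(8L * c, 4L * c, 4L),
    dec2 = tconv_init(8L * c, 2L * c, 4L),   # input: cat(up1, enc3)
    dec3 = tconv_init(4L * c, c, 4L),        # input: cat(up2, enc2)
    dec4 = tconv_init(2L * c, c, 4L),        # input: cat(up3, enc1)
    fuse = conv_init(c, c, 3L),
    out = conv_init(c, config$out_channels, 1L)
  )
}

#' Build the switchable generator
#'
#' One U-net backbone whose nine AdaIN sites are fed by an attached style
#' coder, so the single network serves both translation directions: the
#' domain code selects the style (`gamma = 0` synthesizes toward the second
#' contrast, `gamma = 1` toward the first, mirroring
#' `G_AB(x) = G(x; F(0))` and `G_BA(y) = G(y; F(1))`).
#'
#' @param config A [generator_config()].
#' @param seed Integer seed; two builds with the same seed have identical
#'   initial weights.
#' @return A generator object (class `sg_generator`).
#' @export
build_switchable_generator <- function(config = generator_config(), seed = 1L) {
  set.seed(seed)
  g <- new.env(parent = emptyenv())
  g$config <- config
  g$site_channels <- adain_site_channels(config$base_channels)
  g$params <- build_backbone(config)
  g$coder <- build_style_coder(g$site_channels, seed = seed + 1L)
  g$type <- "switchable"
  class(g) <- "sg_generator"
  g
}

#' Build the two-generator CycleGAN baseline
#'
#' Two independent generators with the same backbone as the switchable
#' generator but a fixed identity style (`sigma = 1`, `mu = 0`, i.e. plain
#' instance normalization) at every site and no style coder. Element one
#' maps A to B, element two maps B to A.
#'
#' @inheritParams build_switchable_generator
#' @return A list of two generators, class `sg_generator_pair`.
#' @export
build_cyclegan_pair <- function(config = generator_config(), seed = 1L) {
  build_one <- function(s) {
    set.seed(s)
    g <- new.env(parent = emptyenv())
    g$config <- config
    g$site_channels <- adain_site_channels(config$base_channels)
    g$params <- build_backbone(config)
    g$coder <- NULL
    g$type <- "plain"
    class(g) <- "sg_generator"
    g
  }
  structure(list(a2b = build_one(seed), b2a = build_one(seed + 1000L)),
            class = "sg_generator_pair")
}

# Full forward pass. style: sg_style with 9 sites. Returns list(y, cache).
gen_forward <- function(g, x, style, cache = TRUE) {
  p <- g$params
  eps <- g$config$eps
  sl <- g$config$slope
  st <- function(i) style[[i]]

  c1 <- conv_fw(p$enc1, x, 2L, 1L, cache)
  a1 <- adain_fw(c1$y, st(1)$sigma, st(1)$mu, eps, cache)
  r1 <- lrelu_fw(a1$y, sl)
  c2 <- conv_fw(p$enc2, r1$y, 2L, 1L, cache)
  a2 <- adain_fw(c2$y, st(2)$sigma, st(2)$mu, eps, cache)
  r2 <- lrelu_fw(a2$y, sl)
  c3 <- conv_fw(p$enc3, r2$y, 2L, 1L, cache)
  a3 <- adain_fw(c3$y, st(3)$sigma, st(3)$mu, eps, cache)
  r3 <- lrelu_fw(a3$y, sl)
  c4 <- conv_fw(p$enc4, r3$y, 2L, 1L, cache)
  a4 <- adain_fw(c4$y, st(4)$sigma, st(4)$mu, eps, cache)
  r4 <- lrelu_fw(a4$y, sl)

  t1 <- tconv_fw(p$dec1, r4$y, 2L, 1L, cache)
  a5 <- adain_fw(t1$y, st(5)$sigma, st(5)$mu, eps, cache)
  u1 <- lrelu_fw(a5$y, sl)
  k1 <- cat_channels(u1$y, r3$y)
  t2 <- tconv_fw(p$dec2, k1, 2L, 1L, cache)
  a6 <- adain_fw(t2$y, st(6)$sigma, st(6)$mu, eps, cache)
  u2 <- lrelu_fw(a6$y, sl)
  k2 <- cat_channels(u2$y, r2$y)
  t3 <- tconv_fw(p$dec3, k2, 2L, 1L, cache)
  a7 <- adain_fw(t3$y, st(7)$sigma, st(7)$mu, eps, cache)
  u3 <- lrelu_fw(a7$y, sl)
  k3 <- cat_channels(u3$y, r1$y)
  t4 <- tconv_fw(p$dec4, k3, 2L, 1L, cache)
  a8 <- adain_fw(t4$y, st(8)$sigma, st(8)$mu, eps, cache)
  u4 <- lrelu_fw(a8$y, sl)

  f1 <- conv_fw(p$fuse, u4$y, 1L, 1L, cache)
  a9 <- adain_fw(f1$y, st(9)$sigma, st(9)$mu, eps, cache)
  f2 <- lrelu_fw(a9$y, sl)
  o1 <- conv_fw(p$out, f2$y, 1L, 0L, cache)
  yo <- tanh_fw(o1$y)

  list(y = yo$y,
       cache = if (cache) list(
         c1 = c1, a1 = a1, r1 = r1, c2 = c2, a2 = a2, r2 = r2,
         c3 = c3, a3 = a3, r3 = r3, c4 = c4, a4 = a4, r4 = r4,
         t1 = t1, a5 = a5, u1 = u1, t2 = t2, a6 = a6, u2 = u2,
         t3 = t3, a7 = a7, u3 = u3, t4 = t4, a8 = a8, u4 = u4,
         f1 = f1, a9 = a9, f2 = f2, o1 = o1, yo = yo))
}

cat_channels <- function(a, b) {
  da <- dim(a); db <- dim(b)
  stopifnot(da[1] == db[1], da[2] == db[2])
  array(c(a, b), c(da[1], da[2], da[3] + db[3]))
}

split_channels <- function(x, n_first) {
  d <- dim(x)
  list(first = array(x[, , seq_len(n_first), drop = FALSE], c(d[1], d[2], n_first)),
       rest = array(x[, , (n_first + 1L):d[3], drop = FALSE],
                    c(d[1], d[2], d[3] - n_first)))
}

# Backward pass. Returns dx, backbone grads, and per-site style gradients
# (to be scaled by gamma and routed into the coder by the trainer).
gen_backward <- function(g, cache, dy) {
  p <- g$params
  gr <- list()
  dstyle <- vector("list", 9L)

  d_o1 <- tanh_bw(cache$yo$cache, dy)
  bo <- conv_bw(p$out, cache$o1$cache, d_o1)
  gr$out <- list(w = bo$dw, b = bo$db)
  d_f2 <- lrelu_bw(cache$f2$cache, bo$dx)
  ab9 <- adain_bw(cache$a9$cache, d_f2)
  dstyle[[9]] <- list(dsigma = ab9$dsigma, dmu = ab9$dmu)
  bf <- conv_bw(p$fuse, cache$f1$cache, ab9$dx)
  gr$fuse <- list(w = bf$dw, b = bf$db)

  d_u4 <- lrelu_bw(cache$u4$cache, bf$dx)
  ab8 <- adain_bw(cache$a8$cache, d_u4)
  dstyle[[8]] <- list(dsigma = ab8$dsigma, dmu = ab8$dmu)
  b4 <- tconv_bw(p$dec4, cache$t4$cache, ab8$dx)
  gr$dec4 <- list(w = b4$dw, b = b4$db)
  s3 <- split_channels(b4$dx, g$config$base_channels)
  d_u3 <- lrelu_bw(cache$u3$cache, s3$first)
  d_r1_skip <- s3$rest

  ab7 <- adain_bw(cache$a7$cache, d_u3)
  dstyle[[7]] <- list(dsigma = ab7$dsigma, dmu = ab7$dmu)
  b3 <- tconv_bw(p$dec3, cache$t3$cache, ab7$dx)
  gr$dec3 <- list(w = b3$dw, b = b3$db)
  s2 <- split_channels(b3$dx, 2L * g$config$base_channels)
  d_u2 <- lrelu_bw(cache$u2$cache, s2$first)
  d_r2_skip <- s2$rest

  ab6 <- adain_bw(cache$a6$cache, d_u2)
  dstyle[[6]] <- list(dsigma = ab6$dsigma, dmu = ab6$dmu)
  b2 <- tconv_bw(p$dec2, cache$t2$cache, ab6$dx)
  gr$dec2 <- list(w = b2$dw, b = b2$db)
  s1 <- split_channels(b2$dx, 4L * g$config$base_channels)
  d_u1 <- lrelu_bw(cache$u1$cache, s1$first)
  d_r3_skip <- s1$rest

  ab5 <- adain_bw(cache$a5$cache, d_u1)
  dstyle[[5]] <- list(dsigma = ab5$dsigma, dmu = ab5$dmu)
  b1 <- tconv_bw(p$dec1, cache$t1$cache, ab5$dx)
  gr$dec1 <- list(w = b1$dw, b = b1$db)

  d_r4 <- lrelu_bw(cache$r4$cache, b1$dx)
  ab4 <- adain_bw(cache$a4$cache, d_r4)
  dstyle[[4]] <- list(dsigma = ab4$dsigma, dmu = ab4$dmu)
  e4 <- conv_bw(p$enc4, cache$c4$cache, ab4$dx)
  gr$enc4 <- list(w = e4$dw, b = e4$db)

  d_r3 <- lrelu_bw(cache$r3$cache, e4$dx + d_r3_skip)
  ab3 <- adain_bw(cache$a3$cache, d_r3)
  dstyle[[3]] <- list(dsigma = ab3$dsigma, dmu = ab3$dmu)
  e3 <- conv_bw(p$enc3, cache$c3$cache, ab3$dx)
  gr$enc3 <- list(w = e3$dw, b = e3$db)

  d_r2 <- lrelu_bw(cache$r2$cache, e3$dx + d_r2_skip)
  ab2 <- adain_bw(cache$a2$cache, d_r2)
  dstyle[[2]] <- list(dsigma = ab2$dsigma, dmu = ab2$dmu)
  e2 <- conv_bw(p$enc2, cache$c2$cache, ab2$dx)
  gr$enc2 <- list(w = e2$dw, b = e2$db)

  d_r1 <- lrelu_bw(cache$r1$cache, e2$dx + d_r1_skip)
  ab1 <- adain_bw(cache$a1$cache, d_r1)
  dstyle[[1]] <- list(dsigma = ab1$dsigma, dmu = ab1$dmu)
  e1 <- conv_bw(p$enc1, cache$c1$cache, ab1$dx)
  gr$enc1 <- list(w = e1$dw, b = e1$db)

  list(dx = e1$dx, grads = gr, dstyle = dstyle)
}

style_for <- function(g, gamma) {
  if (g$type == "switchable") style_code(gamma, g$coder)
  else identity_style(g$site_channels)
}

#' Translate an image with a generator
#'
#' Runs a forward pass. For a switchable generator, `gamma` selects the
#' target contrast: `gamma = 0` synthesizes domain B from a domain-A image
#' (`G_AB`), `gamma = 1` synthesizes domain A (`G_BA`). For a baseline
#' (plain) generator `gamma` is ignored — the direction is fixed by which
#' member of the pair is used.
#'
#' @param g A generator.
#' @param image Numeric `H x W` matrix with intensities in `[-1, 1]`; `H`
#'   and `W` must be divisible by 16 (four stride-2 stages). Out-of-range
#'   values are clamped with a warning.
#' @param gamma Domain code in `[0, 1]`.
#' @return The translated `H x W` matrix, values in `[-1, 1]`.
#' @export
generate <- function(g, image, gamma = 0) {
  stopifnot(inherits(g, "sg_generator"))
  image <- as_feature_map(image)
  d <- dim(image)
  if (d[1] %% 16L != 0L || d[2] %% 16L != 0L) {
    stop("image dimensions (", d[1], "x", d[2], ") must be divisible by 16")
  }
  if (any(image > 1 | image < -1)) {
    warning("intensities outside [-1, 1]; clamping")
    image[image > 1] <- 1
    image[image < -1] <- -1
  }
  y <- gen_forward(g, image, style_for(g, gamma), cache = FALSE)$y
  matrix(y, d[1], d[2])
}

#' @export
print.sg_generator <- function(x, ...) {
  cat("<switchgan generator>", if (x$type == "switchable")
    "switchable (AdaIN style coder attached)" else "plain (fixed identity style)",
    "\n  base channels:", x$config$base_channels,
    "\n  AdaIN sites:", length(x$site_channels),
    "(widths ", paste(x$site_channels, collapse = ", "), ")",
    "\n  trainable parameters:", format(count_parameters(x), big.mark = ","), "\n")
  invisible(x)
}
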