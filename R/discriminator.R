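# PatchGAN discriminator: five 4x4 convolutions, the first with stride 2,
# the rest stride 1; channels 1 -> 64 -> 128 -> 256 -> 512 -> 1. The first
# stage has no normalization; stages 2-4 use per-sample batch normalization
# then a leaky rectifier; the last stage is a bare convolution emitting a
# real-valued patch score map (the least-squares loss consumes raw scores).

#' Build a PatchGAN discriminator
#'
#' @param seed Integer seed for weight initialization.
#' @param base_channels Channels after the first convolution (64 at the
#'   full-scale setting; toy CPU runs use smaller).
#' @param slope Leaky-rectifier slope.
#' @return A discriminator object (class `sg_discriminator`).
#' @export
build_discriminator <- function(seed = 1L, base_channels = 64L, slope = 0.2) {
  set.seed(seed)
  c <- as.integer(base_channels)
  d <- new.env(parent = emptyenv())
  d$config <- list(base_channels = c, slope = slope)
  d$params <- list(
    conv1 = conv_init(1L, c, 4L),
    conv2 = conv_init(c, 2L * c, 4L),
    bn2 = bn_init(2L * c),
    conv3 = conv_init(2L * c, 4L * c, 4L),
    bn3 = bn_init(4L * c),
    conv4 = conv_init(4L * c, 8L * c, 4L),
    bn4 = bn_init(8L * c),
    conv5 = conv_init(8L * c, 1L, 4L)
  )
  class(d) <- "sg_discriminator"
  d
}

disc_forward <- function(d, x, cache = TRUE) {
  p <- d$params
  sl <- d$config$slope
  c1 <- conv_fw(p$conv1, x, 2L, 1L, cache)
  r1 <- lrelu_fw(c1$y, sl)
  c2 <- conv_fw(p$conv2, r1$y, 1L, 1L, cache)
  n2 <- bn_fw(p$bn2, c2$y)
  r2 <- lrelu_fw(n2$y, sl)
  c3 <- conv_fw(p$conv3, r2$y, 1L, 1L, cache)
  n3 <- bn_fw(p$bn3, c3$y)
  r3 <- lrelu_fw(n3$y, sl)
  c4 <- conv_fw(p$conv4, r3$y, 1L, 1L, cache)
  n4 <- bn_fw(p$bn4, c4$y)
  r4 <- lrelu_fw(n4$y, sl)
  c5 <- conv_fw(p$conv5, r4$y, 1L, 1L, cache)
  list(y = c5$y,
       cache = if (cache) list(c1 = c1, r1 = r1, c2 = c2, n2 = n2, r2 = r2,
                               c3 = c3, n3 = n3, r3 = r3, c4 = c4, n4 = n4,
                               r4 = r4, c5 = c5))
}

# want_params = FALSE is used when the discriminator only relays the
# adversarial gradient to the generator (its own weights must not update
# from the generator objective).
disc_backward <- function(d, cache, dy, want_params = TRUE) {
  p <- d$params
  gr <- list()
  b5 <- conv_bw(p$conv5, cache$c5$cache, dy)
  if (want_params) gr$conv5 <- list(w = b5$dw, b = b5$db)
  d4 <- lrelu_bw(cache$r4$cache, b5$dx)
  n4 <- bn_bw(p$bn4, cache$n4$cache, d4)
  if (want_params) gr$bn4 <- list(g = n4$dg, b = n4$db)
  b4 <- conv_bw(p$conv4, cache$c4$cache, n4$dx)
  if (want_params) gr$conv4 <- list(w = b4$dw, b = b4$db)
  d3 <- lrelu_bw(cache$r3$cache, b4$dx)
  n3 <- bn_bw(p$bn3, cache$n3$cache, d3)
  if (want_params) gr$bn3 <- list(g = n3$dg, b = n3$db)
  b3 <- conv_bw(p$conv3, cache$c3$cache, n3$dx)
  if (want_params) gr$conv3 <- list(w = b3$dw, b = b3$db)
  d2 <- lrelu_bw(cache$r2$cache, b3$dx)
  n2 <- bn_bw(p$bn2, cache$n2$cache, d2)
  if (want_params) gr$bn2 <- list(g = n2$dg, b = n2$db)
  b2 <- conv_bw(p$conv2, cache$c2$cache, n2$dx)
  if (want_params) gr$conv2 <- list(w = b2$dw, b = b2$db)
  d1 <- lrelu_bw(cache$r1$cache, b2$dx)
  b1 <- conv_bw(p$conv1, cache$c1$cache, d1)
  if (want_params) gr$conv1 <- list(w = b1$dw, b = b1$db)
  list(dx = b1$dx, grads = gr)
}

#' Score an image with a PatchGAN discriminator
#'
#' @param d A discriminator from [build_discriminator()].
#' @param image Numeric `H x W` matrix (or `H x W x 1` array).
#' @return A real-valued patch score matrix, spatially smaller than the
#'   input: each entry judges one overlapping receptive-field patch.
#' @export
discriminate <- function(d, image) {
  stopifnot(inherits(d, "sg_discriminator"))
  x <- as_feature_map(image)
  if (dim(x)[1] < 16L || dim(x)[2] < 16L) {
    stop("image too small for the discriminator receptive field")
  }
  y <- disc_forward(d, x, cache = FALSE)$y
  matrix(y, dim(y)[1], dim(y)[2])
}

# Patch-map spatial extent from standard convolution arithmetic:
# one stride-2 k4 p1 stage then four stride-1 k4 p1 stages.
disc_output_hw <- function(h) {
  h1 <- conv_out_hw(h, 4L, 2L, 1L)
  for (i in 1:4) h1 <- conv_out_hw(h1, 4L, 1L, 1L)
  h1
}

#' @export
print.sg_discriminator <- function(x, ...) {
  c <- x$config$base_channels
  cat("<switchgan PatchGAN discriminator>\n  channels: 1,",
      paste(c * c(1L, 2L, 4L, 8L), collapse = ", "), ", 1",
      "\n  trainable parameters:", format(count_parameters(x), big.mark = ","), "\n")
  invisible(x)
}
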