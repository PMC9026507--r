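# Minimal trainable-layer toolkit used by the generator and discriminator.
#
# Feature maps are plain R arrays with dim c(H, W, C). Convolutions are
# realised as im2col (C++) followed by one BLAS gemm; transposed convolutions
# reuse the same kernels with the roles of im2col/col2im swapped, since
# col2im is the exact adjoint of im2col. Every layer has a forward that
# returns list(y, cache) and a backward that maps the upstream gradient to
# the input gradient plus parameter gradients. No autograd: the graph is
# wired by hand in gen_forward()/disc_forward().

as_feature_map <- function(x) {
  if (is.matrix(x)) dim(x) <- c(dim(x), 1L)
  stopifnot(length(dim(x)) == 3L)
  x
}

# DCGAN-style initialization: N(0, 0.02) weights, zero bias.
conv_init <- function(c_in, c_out, k, init_sd = 0.02) {
  list(
    w = matrix(rnorm(c_out * k * k * c_in, 0, init_sd), nrow = c_out),
    b = numeric(c_out),
    k = k, c_in = c_in, c_out = c_out
  )
}

conv_out_hw <- function(h, k, stride, pad) (h + 2L * pad - k) %/% stride + 1L

conv_fw <- function(p, x, stride, pad, cache = TRUE) {
  d <- dim(x)
  if (d[3] != p$c_in) {
    stop("channel mismatch: input has ", d[3], " channels, layer expects ", p$c_in)
  }
  cols <- im2col_cpp(x, d[1], d[2], d[3], p$k, stride, pad)
  ho <- conv_out_hw(d[1], p$k, stride, pad)
  wo <- conv_out_hw(d[2], p$k, stride, pad)
  # y (P x Cout) = t(cols) %*% t(w); only the small weight is transposed
  y <- crossprod(cols, t(p$w))
  y <- y + rep(p$b, each = ho * wo)
  list(y = array(y, c(ho, wo, p$c_out)),
       cache = if (cache) list(cols = cols, xdim = d, stride = stride, pad = pad))
}

conv_bw <- function(p, cache, dy) {
  d <- dim(dy)
  m <- matrix(dy, d[1] * d[2], d[3])                 # P x Cout
  dcols <- tcrossprod(t(p$w), m)                     # K x P
  list(
    dx = col2im_cpp(dcols, cache$xdim[1], cache$xdim[2], cache$xdim[3],
                    p$k, cache$stride, cache$pad),
    dw = t(cache$cols %*% m),
    db = colSums(m)
  )
}

# Transposed convolution (kernel k, stride s, padding p): output
# H_out = (H_in - 1) * s - 2p + k. The weight is stored in the layout of the
# conv that maps output -> input, so forward is col2im(t(W) x) and backward
# on the input is a plain conv forward.
tconv_init <- function(c_in, c_out, k, init_sd = 0.02) {
  list(
    w = matrix(rnorm(c_in * k * k * c_out, 0, init_sd), nrow = c_in),
    b = numeric(c_out),
    k = k, c_in = c_in, c_out = c_out
  )
}

tconv_fw <- function(p, x, stride, pad, cache = TRUE) {
  d <- dim(x)
  if (d[3] != p$c_in) {
    stop("channel mismatch: input has ", d[3], " channels, layer expects ", p$c_in)
  }
  ho <- (d[1] - 1L) * stride - 2L * pad + p$k
  wo <- (d[2] - 1L) * stride - 2L * pad + p$k
  m <- matrix(x, d[1] * d[2], d[3])                  # P x Cin
  y <- col2im_cpp(tcrossprod(t(p$w), m), ho, wo, p$c_out, p$k, stride, pad)
  y <- y + rep(p$b, each = ho * wo)
  list(y = y, cache = if (cache) list(m = m, xdim = d, stride = stride, pad = pad))
}

tconv_bw <- function(p, cache, dy) {
  d <- dim(dy)
  dcols <- im2col_cpp(dy, d[1], d[2], d[3], p$k, cache$stride, cache$pad)
  list(
    dx = array(crossprod(dcols, t(p$w)), cache$xdim),
    dw = t(dcols %*% cache$m),
    db = colSums(matrix(dy, d[1] * d[2], d[3]))
  )
}

lrelu_fw <- function(x, slope = 0.2) {
  neg <- x < 0
  y <- x * (1 - (1 - slope) * neg)
  list(y = y, cache = list(neg = neg, slope = slope))
}

lrelu_bw <- function(cache, dy) dy * (1 - (1 - cache$slope) * cache$neg)

tanh_fw <- function(x) {
  y <- tanh(x)
  list(y = y, cache = list(y = y))
}

tanh_bw <- function(cache, dy) dy * (1 - cache$y^2)

# Per-channel normalization over the spatial dimensions of a single sample
# (the batch-size-1 regime used throughout), with learnable scale/shift.
bn_init <- function(c) list(g = rep(1, c), b = numeric(c), c = c)

bn_fw <- function(p, x, eps = 1e-5) {
  d <- dim(x)
  n <- d[1] * d[2]
  m <- matrix(x, n, d[3])
  mu <- colMeans(m)
  xc <- m - rep(mu, each = n)
  sdv <- sqrt(colMeans(xc * xc) + eps)
  xhat <- xc * rep(1 / sdv, each = n)
  y <- xhat * rep(p$g, each = n) + rep(p$b, each = n)
  list(y = array(y, d), cache = list(xhat = xhat, sdv = sdv, d = d))
}

bn_bw <- function(p, cache, dy) {
  d <- cache$d
  n <- d[1] * d[2]
  dym <- matrix(dy, n, d[3])
  dg <- colSums(dym * cache$xhat)
  db <- colSums(dym)
  dxhat <- dym * rep(p$g, each = n)
  t1 <- dxhat - rep(colMeans(dxhat), each = n)
  t2 <- cache$xhat * rep(colMeans(dxhat * cache$xhat), each = n)
  dx <- (t1 - t2) * rep(1 / cache$sdv, each = n)
  list(dx = array(dx, d), dg = dg, db = db)
}

linear_init <- function(n_in, n_out, init_sd = 0.02) {
  list(w = matrix(rnorm(n_out * n_in, 0, init_sd), n_out), b = numeric(n_out))
}

linear_fw <- function(p, x) list(y = drop(p$w %*% x + p$b), cache = list(x = x))

linear_bw <- function(p, cache, dy) {
  list(dx = drop(crossprod(p$w, dy)), dw = tcrossprod(dy, cache$x), db = dy)
}

#' Count trainable parameters of a network
#'
#' Sums the number of trainable scalars of a generator, a discriminator, a
#' style coder, or a two-generator baseline pair. For a switchable generator
#' the attached style coder is included, since its embedding and MLP weights
#' train jointly with the backbone.
#'
#' @param network A generator (from [build_switchable_generator()]), a
#'   discriminator (from [build_discriminator()]), a style coder, or a
#'   generator pair (from [build_cyclegan_pair()]).
#' @return Integer-valued count of trainable scalars.
#' @export
count_parameters <- function(network) {
  if (inherits(network, "sg_generator_pair")) {
    return(count_parameters(network[[1]]) + count_parameters(network[[2]]))
  }
  n <- sum(vapply(network$params, function(p) {
    sum(lengths(p[intersect(names(p), TRAINABLE_FIELDS)]))
  }, numeric(1)))
  if (!is.null(network$coder)) n <- n + count_parameters(network$coder)
  n
}

TRAINABLE_FIELDS <- c("w", "b", "g")

# Grad structures mirror params: list(layer = list(w = ..., b = ...)).
add_grads <- function(g1, g2) {
  if (is.null(g1)) return(g2)
  for (nm in names(g2)) {
    for (f in names(g2[[nm]])) {
      g1[[nm]][[f]] <- (g1[[nm]][[f]] %||% 0) + g2[[nm]][[f]]
    }
  }
  g1
}

`%||%` <- function(a, b) if (is.null(a)) b else a
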