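# Adaptive instance normalization (AdaIN) and the switchable style coder.
#
# AdaIN replaces the per-channel spatial mean/std of a feature map with
# externally supplied target moments. In the switchable generator the target
# moments do not come from a reference image: they come from a domain code
# gamma through the style coder F(gamma) = (1 - gamma) * (1, 0) +
# gamma * (sigma_B, mu_B), so gamma = 0 reduces every AdaIN site to plain
# instance normalization (domain A style) and gamma = 1 applies the learned
# domain-B moments.

#' Per-channel spatial moments of a feature map
#'
#' Computes the mean and standard deviation of each channel across the
#' spatial dimensions, the statistics AdaIN aligns. The standard deviation
#' uses the population (biased) convention of instance normalization, with a
#' small stabilizer `eps` added under the square root so constant channels
#' (common in early training) stay differentiable.
#'
#' @param x A feature map: an `H x W` matrix or an `H x W x C` array.
#' @param eps Non-negative stabilizer added to the per-channel variance.
#' @return A list with numeric vectors `mean` and `sd`, one entry per channel.
#' @examples
#' m <- instance_moments(matrix(c(2, 4, 6, 8), 2))
#' m$mean  # 5
#' @export
instance_moments <- function(x, eps = 1e-5) {
  x <- as_feature_map(x)
  if (!all(is.finite(x))) stop("feature map contains non-finite values")
  d <- dim(x)
  m <- matrix(x, d[1] * d[2], d[3])
  mu <- colMeans(m)
  v <- colMeans(sweep(m, 2L, mu)^2)
  list(mean = mu, sd = sqrt(v + eps))
}

#' Apply the AdaIN moment-matching transform
#'
#' Normalizes each channel of `x` to zero mean and unit variance (instance
#' normalization) and then applies the style moments:
#' `z_n = sigma_style_n * (x_n - mu(x_n)) / sigma(x_n) + mu_style_n`.
#'
#' @inheritParams instance_moments
#' @param sigma,mu Numeric style vectors, one entry per channel of `x`;
#'   all `sigma` components must be non-negative.
#' @return A feature map of the same shape as `x` whose per-channel moments
#'   match `(mu, sigma)` (up to the `eps` stabilizer).
#' @examples
#' z <- adain_transform(matrix(c(2, 4, 6, 8), 2), sigma = 2, mu = 1)
#' instance_moments(z)$mean  # 1
#' @export
adain_transform <- function(x, sigma, mu, eps = 1e-5) {
  x <- as_feature_map(x)
  d <- dim(x)
  if (length(sigma) != d[3] || length(mu) != d[3]) {
    stop("style vectors have length ", length(sigma), "/", length(mu),
         " but the feature map has ", d[3], " channels")
  }
  if (any(sigma < 0)) stop("negative sigma component in style")
  adain_fw(x, sigma, mu, eps)$y
}

# Forward with cache, used inside the networks.
adain_fw <- function(x, sigma, mu, eps = 1e-5, cache = TRUE) {
  d <- dim(x)
  n <- d[1] * d[2]
  m <- matrix(x, n, d[3])
  mux <- colMeans(m)
  xc <- m - rep(mux, each = n)
  sdx <- sqrt(colMeans(xc * xc) + eps)
  xhat <- xc * rep(1 / sdx, each = n)
  y <- xhat * rep(sigma, each = n) + rep(mu, each = n)
  list(y = array(y, d),
       cache = if (cache) list(xhat = xhat, sdx = sdx, sigma = sigma, d = d))
}

# Backward: gradients w.r.t. the input and the style vectors. The input
# gradient is the instance-norm backward scaled by sigma_style.
adain_bw <- function(cache, dy) {
  d <- cache$d
  n <- d[1] * d[2]
  dym <- matrix(dy, n, d[3])
  dsigma <- colSums(dym * cache$xhat)
  dmu <- colSums(dym)
  dxhat <- dym * rep(cache$sigma, each = n)
  t1 <- dxhat - rep(colMeans(dxhat), each = n)
  t2 <- cache$xhat * rep(colMeans(dxhat * cache$xhat), each = n)
  dx <- (t1 - t2) * rep(1 / cache$sdx, each = n)
  list(dx = array(dx, d), dsigma = dsigma, dmu = dmu)
}

#' Build the switchable style coder F(gamma)
#'
#' The coder owns a learnable 128-length embedding pushed through a two-layer
#' MLP (fully connected, leaky rectifier, fully connected) whose output is
#' split into one `(sigma_B, mu_B)` pair per AdaIN site; the sigma components
#' pass a non-negativity rectifier. [style_code()] then interpolates between
#' the fixed domain-A style `(1, 0)` and these learned domain-B moments.
#'
#' @param site_channels Integer vector of channel widths, one per AdaIN site
#'   (length 9 for the default generator).
#' @param seed Integer seed for weight initialization.
#' @param embed_dim Length of the learnable input embedding.
#' @return A style coder object (class `sg_style_coder`).
#' @export
build_style_coder <- function(site_channels, seed = 1L, embed_dim = 128L) {
  stopifnot(length(site_channels) >= 1L, all(site_channels >= 1L))
  set.seed(seed)
  total <- 2L * sum(site_channels)
  coder <- new.env(parent = emptyenv())
  coder$site_channels <- as.integer(site_channels)
  fc2 <- linear_init(embed_dim, total)
  # start the sigma head at 1 so the learned domain-B style begins near the
  # identity transform, symmetric with the fixed domain-A style (1, 0)
  ends <- cumsum(2L * coder$site_channels)
  starts <- c(1L, head(ends, -1L) + 1L)
  for (i in seq_along(coder$site_channels)) {
    fc2$b[starts[i] + seq_len(coder$site_channels[i]) - 1L] <- 1
  }
  coder$params <- list(
    emb = list(w = rnorm(embed_dim, 0, 0.02)),
    fc1 = linear_init(embed_dim, embed_dim),
    fc2 = fc2
  )
  class(coder) <- "sg_style_coder"
  coder
}

# Runs the coder MLP and returns the raw per-site (sigma_B, mu_B) with cache.
coder_fw <- function(coder, cache = TRUE) {
  p <- coder$params
  h0 <- linear_fw(p$fc1, p$emb$w)
  h1 <- lrelu_fw(h0$y)
  o <- linear_fw(p$fc2, h1$y)
  sc <- coder$site_channels
  ends <- cumsum(2L * sc)
  starts <- c(1L, head(ends, -1L) + 1L)
  sites <- vector("list", length(sc))
  relu_mask <- logical(length(o$y))
  for (i in seq_along(sc)) {
    idx <- starts[i]:ends[i]
    raw <- o$y[idx]
    sig_raw <- raw[seq_len(sc[i])]
    mu_b <- raw[sc[i] + seq_len(sc[i])]
    relu_mask[idx[seq_len(sc[i])]] <- sig_raw > 0
    sites[[i]] <- list(sigma = pmax(sig_raw, 0), mu = mu_b)
  }
  list(sites = sites,
       cache = if (cache) list(h0 = h0, h1 = h1, o = o, relu_mask = relu_mask,
                               starts = starts, ends = ends))
}

# dsites: per-site list(dsigma, dmu) already scaled by gamma by the caller.
coder_bw <- function(coder, cache, dsites) {
  p <- coder$params
  sc <- coder$site_channels
  do <- numeric(length(cache$relu_mask))
  for (i in seq_along(sc)) {
    idx <- cache$starts[i]:cache$ends[i]
    sig_idx <- idx[seq_len(sc[i])]
    do[sig_idx] <- dsites[[i]]$dsigma * cache$relu_mask[sig_idx]
    do[idx[sc[i] + seq_len(sc[i])]] <- dsites[[i]]$dmu
  }
  b2 <- linear_bw(p$fc2, cache$o$cache, do)
  dh1 <- lrelu_bw(cache$h1$cache, b2$dx)
  b1 <- linear_bw(p$fc1, cache$h0$cache, dh1)
  list(
    emb = list(w = b1$dx),
    fc1 = list(w = b1$dw, b = b1$db),
    fc2 = list(w = b2$dw, b = b2$db)
  )
}

#' Produce per-site AdaIN styles for a domain code
#'
#' Evaluates `F(gamma) = (1 - gamma) * (1, 0) + gamma * (sigma_B, mu_B)`:
#' at `gamma = 0` every site is exactly `(sigma = 1, mu = 0)` (plain instance
#' normalization, the domain-A style) regardless of the coder weights; at
#' `gamma = 1` the sites equal the coder's rectified learned moments.
#' Intermediate values linearly interpolate the two styles and are intended
#' for style-interpolation demonstrations only; training uses 0 and 1.
#'
#' @param gamma Domain code in `[0, 1]`.
#' @param coder A style coder from [build_style_coder()].
#' @return Object of class `sg_style`: a list with one `(sigma, mu)` pair per
#'   AdaIN site.
#' @export
style_code <- function(gamma, coder) {
  if (!is.numeric(gamma) || length(gamma) != 1L || is.na(gamma) ||
      gamma < 0 || gamma > 1) {
    stop("gamma must be a single number in [0, 1]")
  }
  fw <- coder_fw(coder, cache = FALSE)
  sites <- lapply(fw$sites, function(s) {
    list(sigma = (1 - gamma) * 1 + gamma * s$sigma,
         mu = gamma * s$mu)
  })
  structure(sites, class = "sg_style", gamma = gamma)
}

# Fixed identity style (sigma = 1, mu = 0): plain instance normalization,
# used at every site of the baseline (non-switchable) generators.
identity_style <- function(site_channels) {
  structure(
    lapply(site_channels, function(ch) list(sigma = rep(1, ch), mu = numeric(ch))),
    class = "sg_style", gamma = NA_real_
  )
}
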