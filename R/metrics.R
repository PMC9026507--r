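# Image-quality evaluation: PSNR, windowed SSIM, mean +/- sd summary tables
# over registered test pairs, and the paired Wilcoxon signed-rank comparison
# between methods.

#' Metric configuration
#'
#' @param k1,k2 SSIM stabilizer constants; `c1 = (k1 L)^2`, `c2 = (k2 L)^2`.
#' @param L Dynamic range of the intensities the metrics see. Images are
#'   rescaled from the network range `[-1, 1]` to `[0, 1]` before metric
#'   computation by [evaluate_synthesis()], so the default is 1.
#' @param psnr_max `MAX` in the PSNR formula (the maximum possible value of
#'   the reference image's scale; defaults to `L`).
#' @param window Odd side length of the Gaussian SSIM window.
#' @param sigma Standard deviation of the Gaussian window, in pixels.
#' @return A `metric_config` list.
#' @export
metric_config <- function(k1 = 0.01, k2 = 0.03, L = 1, psnr_max = L,
                          window = 11L, sigma = 1.5) {
  stopifnot(window %% 2L == 1L, window >= 3L, L > 0, psnr_max > 0)
  structure(list(k1 = k1, k2 = k2, L = L, psnr_max = psnr_max,
                 window = as.integer(window), sigma = sigma,
                 c1 = (k1 * L)^2, c2 = (k2 * L)^2),
            class = "metric_config")
}

#' Peak signal-to-noise ratio
#'
#' `PSNR = 20 log10(MAX / RMSE)` in decibels. Identical images have zero
#' RMSE and return `Inf` (the documented sentinel; summary tables exclude it
#' with a warning).
#'
#' @param x Reference image (matrix).
#' @param x_hat Synthesized image, same shape and intensity scale.
#' @param config A [metric_config()]; `psnr_max` supplies `MAX`.
#' @return PSNR in dB (possibly `Inf`).
#' @export
psnr <- function(x, x_hat, config = metric_config()) {
  check_same_shape(x, x_hat, "psnr")
  rmse <- sqrt(mean((x - x_hat)^2))
  if (rmse == 0) return(Inf)
  20 * log10(config$psnr_max / rmse)
}

gaussian_window <- function(window, sigma) {
  r <- (window - 1) / 2
  g1 <- exp(-((-r:r)^2) / (2 * sigma^2))
  w <- outer(g1, g1)
  w / sum(w)
}

#' Structural similarity index
#'
#' Windowed SSIM: the local luminance/contrast/structure statistic
#' `((2 mu_x mu_y + c1)(2 sigma_xy + c2)) /
#'  ((mu_x^2 + mu_y^2 + c1)(sigma_x^2 + sigma_y^2 + c2))`
#' is computed under a sliding Gaussian window (11x11, sigma 1.5 by default,
#' the convention of the original SSIM reference) and averaged over all
#' valid positions.
#'
#' @inheritParams psnr
#' @return Scalar SSIM in `[-1, 1]`; 1 for identical images.
#' @export
ssim <- function(x, x_hat, config = metric_config()) {
  check_same_shape(x, x_hat, "ssim")
  d <- dim(x)
  k <- config$window
  if (k > d[1] || k > d[2]) {
    stop("SSIM window (", k, ") larger than image (", d[1], "x", d[2], ")")
  }
  w <- gaussian_window(k, config$sigma)
  wv <- as.numeric(w)
  # valid-mode windowed means via im2col + one gemm each
  local_mean <- function(img) {
    cols <- im2col_cpp(img, d[1], d[2], 1L, k, 1L, 0L)
    drop(wv %*% cols)
  }
  mx <- local_mean(x)
  my <- local_mean(x_hat)
  mxx <- local_mean(x * x)
  myy <- local_mean(x_hat * x_hat)
  mxy <- local_mean(x * x_hat)
  vx <- mxx - mx^2
  vy <- myy - my^2
  cxy <- mxy - mx * my
  c1 <- config$c1; c2 <- config$c2
  s <- ((2 * mx * my + c1) * (2 * cxy + c2)) /
    ((mx^2 + my^2 + c1) * (vx + vy + c2))
  mean(s)
}

#' Per-image metrics and mean +/- sd summary over registered pairs
#'
#' Rescales both images of every (synthesized, target) pair from `[-1, 1]`
#' to `[0, 1]` (fixed affine map, not per-image min-max, so errors stay
#' comparable), computes PSNR and SSIM per pair, and summarizes per
#' direction as mean +/- sd. Infinite PSNR values (identical pairs) are
#' excluded from the summary with a warning.
#'
#' @param records A tibble/data.frame with list-columns `synthesized` and
#'   `target` (matrices on the `[-1, 1]` scale) and a `direction` column
#'   (`"a2b"`/`"b2a"`); extra columns are carried through.
#' @param config A [metric_config()].
#' @param rescale Set `FALSE` if the images are already on the metric scale.
#' @return An `sg_metric_table`: the per-image tibble with `psnr` and `ssim`
#'   columns; the per-direction summary is attached and available via
#'   [glance()] or `summary()`.
#' @export
evaluate_synthesis <- function(records, config = metric_config(), rescale = TRUE) {
  stopifnot(nrow(records) > 0, all(c("synthesized", "target") %in% names(records)))
  if (!"direction" %in% names(records)) records$direction <- "a2b"
  to01 <- function(m) (m + 1) / 2
  res <- purrr::map2_dfr(records$synthesized, records$target, function(s, t) {
    if (rescale) { s <- to01(s); t <- to01(t) }
    tibble::tibble(psnr = psnr(t, s, config), ssim = ssim(t, s, config))
  })
  out <- dplyr::bind_cols(records, res)
  class(out) <- c("sg_metric_table", class(out))
  attr(out, "config") <- config
  out
}

#' @export
summary.sg_metric_table <- function(object, ...) {
  tab <- dplyr::as_tibble(object)
  if (any(!is.finite(tab$psnr))) {
    warning("excluding ", sum(!is.finite(tab$psnr)),
            " infinite PSNR value(s) from the summary")
  }
  dplyr::summarise(
    dplyr::group_by(tab, .data$direction),
    n = dplyr::n(),
    psnr_mean = mean(.data$psnr[is.finite(.data$psnr)]),
    psnr_sd = sd(.data$psnr[is.finite(.data$psnr)]),
    ssim_mean = mean(.data$ssim),
    ssim_sd = sd(.data$ssim),
    .groups = "drop"
  )
}

#' @export
glance.sg_metric_table <- function(x, ...) summary(x)

#' @export
tidy.sg_metric_table <- function(x, ...) {
  dplyr::select(dplyr::as_tibble(x),
                -dplyr::any_of(c("synthesized", "target", "source")))
}

#' Paired Wilcoxon signed-rank comparison of two methods
#'
#' Two-sided signed-rank test on paired per-image metric values (the model
#' comparison used for the quality tables; p < 0.05 read as significant).
#' The exact null distribution is used for n <= 25 without ties; otherwise
#' the normal approximation with continuity correction.
#'
#' @param a,b Equal-length numeric vectors of per-image metric values,
#'   paired by image.
#' @return A tibble with `statistic`, `p_value`, `n` (pairs with non-zero
#'   difference), and `method`.
#' @export
paired_signed_rank <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 5)
  d <- a - b
  if (all(d == 0)) {
    stop("all paired differences are zero; the signed-rank test is degenerate")
  }
  nz <- d[d != 0]
  exact <- length(nz) <= 25 && !any(duplicated(abs(nz)))
  ht <- suppressWarnings(
    wilcox.test(a, b, paired = TRUE, exact = exact, correct = TRUE)
  )
  tibble::tibble(statistic = unname(ht$statistic), p_value = ht$p.value,
                 n = length(nz), method = ht$method)
}
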