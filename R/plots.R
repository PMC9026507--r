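# broom-style accessors and ggplot2 visualizations for fitted objects.

#' @export
tidy.switchgan_fit <- function(x, ...) x$log

#' @export
glance.switchgan_fit <- function(x, ...) {
  last <- x$log[x$log$epoch == max(x$log$epoch), ]
  tibble::tibble(
    model = x$model, epochs = x$epoch,
    steps_per_epoch = max(x$log$step),
    total_median = stats::median(last$total),
    adv_g_median = stats::median(last$adv_g),
    cyc_median = stats::median(last$cyc),
    id_median = stats::median(last$id),
    final_lr = last$lr[nrow(last)],
    parameters = if (x$model == "switchable") count_parameters(x$generator)
                 else count_parameters(x$generators)
  )
}

#' Plot per-epoch training loss components
#'
#' Epoch medians of the adversarial, cycle, identity and total generator
#' losses.
#'
#' @param object A `switchgan_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.switchgan_fit <- function(object, ...) {
  med <- dplyr::summarise(
    dplyr::group_by(object$log, .data$epoch),
    dplyr::across(c("adv_g", "cyc", "id", "total"), stats::median),
    .groups = "drop"
  )
  long <- tidyr_pivot(med)
  ggplot2::ggplot(long, ggplot2::aes(.data$epoch, .data$value,
                                     colour = .data$component)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "epoch", y = "median loss (per epoch)",
                  colour = NULL,
                  title = paste(object$model, "model: generator losses")) +
    ggplot2::theme_minimal()
}

# small local pivot to avoid a hard tidyr dependency
tidyr_pivot <- function(med) {
  comps <- c("adv_g", "cyc", "id", "total")
  dplyr::bind_rows(lapply(comps, function(cc) {
    tibble::tibble(epoch = med$epoch, component = cc, value = med[[cc]])
  }))
}

#' Plot benchmark summary
#'
#' SSIM (mean, +/- sd ribbon) against training-set size per model and
#' direction.
#'
#' @param object An `sg_benchmark`.
#' @param metric `"ssim"` or `"psnr"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sg_benchmark <- function(object, metric = c("ssim", "psnr"), ...) {
  metric <- match.arg(metric)
  tab <- dplyr::as_tibble(object)
  mcol <- paste0(metric, "_mean")
  scol <- paste0(metric, "_sd")
  ggplot2::ggplot(tab, ggplot2::aes(factor(.data$size), .data[[mcol]],
                                    colour = .data$model,
                                    group = .data$model)) +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = .data[[mcol]] - .data[[scol]],
      ymax = .data[[mcol]] + .data[[scol]]
    ), position = ggplot2::position_dodge(width = 0.3)) +
    ggplot2::geom_line(position = ggplot2::position_dodge(width = 0.3)) +
    ggplot2::facet_wrap(~direction) +
    ggplot2::labs(x = "training slices", y = toupper(metric), colour = NULL) +
    ggplot2::theme_minimal()
}

#' Display a phantom or translated slice
#'
#' @param image `H x W` matrix in `[-1, 1]`.
#' @param title Optional plot title.
#' @return A ggplot object (raster).
#' @export
plot_slice <- function(image, title = NULL) {
  d <- dim(image)
  df <- tibble::tibble(
    x = rep(seq_len(d[2]), each = d[1]),
    y = rep(rev(seq_len(d[1])), d[2]),
    value = as.numeric(image)
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "black", high = "white",
                                 limits = c(-1, 1)) +
    ggplot2::coord_equal() +
    ggplot2::labs(title = title) +
    ggplot2::theme_void() +
    ggplot2::theme(legend.position = "none")
}
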