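# End-to-end comparison harness: trains both model variants at one or more
# training-set sizes on a shared phantom dataset, evaluates PSNR/SSIM on the
# registered test pairs, and compares the per-image records with paired
# signed-rank tests — the structure of the published quality and
# dataset-size-robustness tables, at whatever scale the caller configures.

#' Run the two-model comparison benchmark
#'
#' For every combination of model variant and training-set size: subsample
#' the training slices, train, synthesize the registered test pairs in both
#' directions, and record per-image PSNR/SSIM.
#'
#' @param manifest A materialized `phantom_manifest` with train and test
#'   splits.
#' @param sizes Integer vector of total training-slice counts (balanced
#'   across domains). `NULL` uses the full training set once.
#' @param models Character vector from `c("switchable", "cyclegan")`.
#' @param config A [train_config()] shared by all runs.
#' @param gen_config A [generator_config()].
#' @param disc_base_channels Discriminator width.
#' @param metric_config A [metric_config()].
#' @param seed Base seed; each run derives its own from it.
#' @param verbose Print progress.
#' @return An `sg_benchmark`: summary tibble (model, size, direction, n,
#'   PSNR/SSIM mean and sd) with the per-image records and fitted models in
#'   attributes; see [compare_methods()].
#' @export
run_benchmark <- function(manifest, sizes = NULL,
                          models = c("switchable", "cyclegan"),
                          config = train_config(),
                          gen_config = generator_config(),
                          disc_base_channels = 64L,
                          metric_config = switchgan::metric_config(),
                          seed = 1L, verbose = FALSE) {
  models <- match.arg(models, several.ok = TRUE)
  if (is.null(sizes)) sizes <- sum(manifest$split == "train")
  grid <- expand.grid(model = models, size = sizes, stringsAsFactors = FALSE)
  records <- vector("list", nrow(grid))
  fits <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    mdl <- grid$model[i]; sz <- grid$size[i]
    if (verbose) message("benchmark: ", mdl, " @ ", sz, " training slices")
    sub <- subsample_manifest(manifest, sz, seed = seed + i)
    cfg <- config
    cfg$seed <- as.integer(seed + 31L * i)
    fit <- train_translation(sub, model = mdl, config = cfg,
                             gen_config = gen_config,
                             disc_base_channels = disc_base_channels)
    pairs <- synthesize_test_pairs(fit, manifest, split = "test")
    ev <- evaluate_synthesis(pairs, metric_config)
    ev$model <- mdl
    ev$size <- sz
    records[[i]] <- ev
    fits[[i]] <- fit
  }
  per_image <- dplyr::bind_rows(lapply(records, tidy))
  summary_tbl <- dplyr::summarise(
    dplyr::group_by(per_image, .data$model, .data$size, .data$direction),
    n = dplyr::n(),
    psnr_mean = mean(.data$psnr[is.finite(.data$psnr)]),
    psnr_sd = sd(.data$psnr[is.finite(.data$psnr)]),
    ssim_mean = mean(.data$ssim), ssim_sd = sd(.data$ssim),
    .groups = "drop"
  )
  structure(summary_tbl, class = c("sg_benchmark", class(summary_tbl)),
            per_image = per_image, fits = fits, grid = grid)
}

#' @export
tidy.sg_benchmark <- function(x, ...) attr(x, "per_image")

#' @export
glance.sg_benchmark <- function(x, ...) dplyr::as_tibble(x)

#' Paired model comparison on benchmark records
#'
#' Two-sided Wilcoxon signed-rank tests between the two model variants on
#' the per-image metric values, paired by test image, per size and
#' direction.
#'
#' @param benchmark An `sg_benchmark` from [run_benchmark()] that includes
#'   both model variants.
#' @param metric `"ssim"` or `"psnr"`.
#' @return Tibble with size, direction, the two means, and the signed-rank
#'   p-value.
#' @export
compare_methods <- function(benchmark, metric = c("ssim", "psnr")) {
  metric <- match.arg(metric)
  pi <- attr(benchmark, "per_image")
  stopifnot(all(c("switchable", "cyclegan") %in% pi$model))
  combos <- unique(pi[, c("size", "direction")])
  purrr::pmap_dfr(combos, function(size, direction) {
    sel <- pi$size == size & pi$direction == direction
    sw <- pi[sel & pi$model == "switchable", ]
    cg <- pi[sel & pi$model == "cyclegan", ]
    key <- function(d) paste(d$subject_id, d$slice)
    cg <- cg[match(key(sw), key(cg)), ]
    ht <- paired_signed_rank(sw[[metric]], cg[[metric]])
    tibble::tibble(size = size, direction = direction, metric = metric,
                   switchable_mean = mean(sw[[metric]]),
                   cyclegan_mean = mean(cg[[metric]]),
                   statistic = ht$statistic, p_value = ht$p_value, n = nrow(sw))
  })
}
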