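# Registered two-contrast brain-like phantom simulator.
#
# Each phantom is built from one tissue label map (background, fat rim,
# white-matter-like interior, gray-matter-like blobs and cortical band,
# fluid pockets) rendered twice with contrast-specific class intensities:
# the first contrast brightens fat and darkens fluid (T1-like ordering
# fat > WM > GM > fluid), the second brightens fluid (T2-like ordering
# fluid > GM > WM, fat intermediate). A smooth multiplicative bias field
# and additive Gaussian noise are applied per contrast; both contrasts
# share the identical label map, so every pair is registered by
# construction.

#' Phantom simulator configuration
#'
#' @param size Side length of the square slice, in pixels.
#' @param intensity_a,intensity_b Named class-mean intensities on the
#'   `[0, 1]` scale for the two contrasts, names
#'   `background`, `fat`, `wm`, `gm`, `fluid`. Defaults respect the
#'   contrast orderings above.
#' @param noise_sigma Additive Gaussian noise sd on the `[0, 1]` scale.
#' @param bias_amplitude Peak relative amplitude of the smooth
#'   multiplicative bias field (sum of 2-3 low-frequency cosines).
#' @return A `phantom_config` list.
#' @export
phantom_config <- function(size = 128L,
                           intensity_a = c(background = 0.02, fat = 0.95,
                                           wm = 0.75, gm = 0.55, fluid = 0.15),
                           intensity_b = c(background = 0.02, fat = 0.50,
                                           wm = 0.40, gm = 0.60, fluid = 0.95),
                           noise_sigma = 0.02, bias_amplitude = 0.05) {
  stopifnot(size >= 32, noise_sigma >= 0)
  cls <- c("background", "fat", "wm", "gm", "fluid")
  stopifnot(all(cls %in% names(intensity_a)), all(cls %in% names(intensity_b)))
  with(as.list(intensity_a), stopifnot(fat > wm, wm > gm, gm > fluid))
  with(as.list(intensity_b), stopifnot(fluid > gm, gm > wm))
  structure(list(size = as.integer(size), intensity_a = intensity_a,
                 intensity_b = intensity_b, noise_sigma = noise_sigma,
                 bias_amplitude = bias_amplitude),
            class = "phantom_config")
}

inside_ellipse <- function(xg, yg, cx, cy, rx, ry, theta = 0) {
  xr <- (xg - cx) * cos(theta) + (yg - cy) * sin(theta)
  yr <- -(xg - cx) * sin(theta) + (yg - cy) * cos(theta)
  (xr / rx)^2 + (yr / ry)^2 <= 1
}

# Label codes: 0 background, 1 fat, 2 wm, 3 gm, 4 fluid.
make_label_map <- function(size) {
  co <- (seq_len(size) - 0.5) / size
  xg <- matrix(co, size, size)
  yg <- t(xg)
  cx <- 0.5 + runif(1, -0.03, 0.03)
  cy <- 0.5 + runif(1, -0.03, 0.03)
  rx <- runif(1, 0.36, 0.43)
  ry <- runif(1, 0.40, 0.46)
  head <- inside_ellipse(xg, yg, cx, cy, rx, ry)
  inner <- inside_ellipse(xg, yg, cx, cy, 0.88 * rx, 0.88 * ry)
  cortex <- inside_ellipse(xg, yg, cx, cy, 0.80 * rx, 0.80 * ry)

  lab <- matrix(0L, size, size)
  lab[head] <- 1L                       # fat rim
  lab[inner] <- 3L                      # cortical gray band
  lab[cortex] <- 2L                     # white-matter interior
  # gray-matter blobs
  for (i in seq_len(sample(4:7, 1))) {
    bx <- cx + runif(1, -0.5, 0.5) * rx
    by <- cy + runif(1, -0.5, 0.5) * ry
    blob <- inside_ellipse(xg, yg, bx, by, runif(1, 0.04, 0.10),
                           runif(1, 0.04, 0.10), runif(1, 0, pi))
    lab[blob & cortex] <- 3L
  }
  # fluid pockets (ventricle-like, near the center)
  for (sgn in c(-1, 1)) {
    vx <- cx + sgn * runif(1, 0.05, 0.10) * rx
    vy <- cy + runif(1, -0.08, 0.08) * ry
    vent <- inside_ellipse(xg, yg, vx, vy, runif(1, 0.035, 0.06),
                           runif(1, 0.10, 0.16), runif(1, -0.3, 0.3))
    lab[vent & cortex] <- 4L
  }
  lab
}

bias_field <- function(size, amplitude) {
  if (amplitude == 0) return(matrix(1, size, size))
  co <- (seq_len(size) - 0.5) / size
  xg <- matrix(co, size, size)
  yg <- t(xg)
  b <- matrix(0, size, size)
  for (i in seq_len(sample(2:3, 1))) {
    fx <- runif(1, 0.3, 1.2); fy <- runif(1, 0.3, 1.2)
    ph <- runif(2, 0, 2 * pi)
    b <- b + cos(2 * pi * fx * xg + ph[1]) * cos(2 * pi * fy * yg + ph[2])
  }
  1 + amplitude * b / max(abs(b))
}

render_contrast <- function(lab, means, config) {
  img <- matrix(means[c("background", "fat", "wm", "gm", "fluid")][lab + 1L],
                nrow(lab), ncol(lab))
  img <- img * bias_field(nrow(lab), config$bias_amplitude)
  if (config$noise_sigma > 0) {
    img <- img + matrix(rnorm(length(img), 0, config$noise_sigma),
                        nrow(lab), ncol(lab))
  }
  img <- pmin(pmax(img, 0), 1)
  2 * img - 1
}

#' Generate one registered two-contrast phantom
#'
#' @param config A [phantom_config()].
#' @param subject_seed Integer seed; the same seed reproduces the phantom
#'   bit for bit.
#' @return A list with `labels` (integer matrix: 0 background, 1 fat,
#'   2 white-matter-like, 3 gray-matter-like, 4 fluid), `contrast_a` and
#'   `contrast_b` (matrices in `[-1, 1]` sharing that label map), and
#'   `seed`.
#' @export
generate_phantom <- function(config = phantom_config(), subject_seed = 1L) {
  set.seed(subject_seed)
  lab <- NULL
  for (try in 1:5) {
    cand <- make_label_map(config$size)
    # degenerate geometry guard: need all five classes present
    if (all(0:4 %in% cand)) { lab <- cand; break }
  }
  if (is.null(lab)) stop("could not generate a non-degenerate phantom geometry")
  list(labels = lab,
       contrast_a = render_contrast(lab, config$intensity_a, config),
       contrast_b = render_contrast(lab, config$intensity_b, config),
       seed = as.integer(subject_seed))
}

#' Deterministic 70/10/20 subject split
#'
#' Shuffles the ids with `master_seed`, assigns `floor(0.1 n)` to
#' validation, `floor(0.2 n)` to test, and the remainder to training (for
#' n = 1517 this gives 1063/151/303).
#'
#' @param subject_ids Vector of unique subject identifiers (n >= 10).
#' @param master_seed Integer seed.
#' @return A list with `train`, `val`, `test` id vectors (disjoint,
#'   exhaustive).
#' @export
split_subjects <- function(subject_ids, master_seed = 1L) {
  n <- length(subject_ids)
  if (n < 10) stop("need at least 10 subjects to split, got ", n)
  set.seed(master_seed)
  ids <- sample(subject_ids)
  n_val <- floor(0.1 * n)
  n_test <- floor(0.2 * n)
  list(train = ids[seq_len(n - n_val - n_test)],
       val = ids[n - n_val - n_test + seq_len(n_val)],
       test = tail(ids, n_test))
}

#' Generate a registered two-contrast phantom dataset
#'
#' Each subject contributes `slices_per_subject` independent 2D phantoms;
#' each phantom yields one slice per contrast, so the total slice count is
#' `n_subjects * slices_per_subject * 2`. Subjects are split 70/10/20 when
#' there are at least 10 of them (all assigned to training otherwise).
#' Per-slice seeds are derived deterministically from `master_seed`, so the
#' manifest regenerates byte-identically.
#'
#' @param n_subjects Number of synthetic subjects.
#' @param slices_per_subject Slices per contrast per subject.
#' @param config A [phantom_config()].
#' @param master_seed Integer master seed.
#' @param materialize If `FALSE`, build the manifest bookkeeping (ids,
#'   seeds, splits, counts) without rendering pixel data — the image column
#'   is `NULL`s. Useful for large bookkeeping checks.
#' @return A `phantom_manifest` tibble with one row per slice:
#'   `subject_id`, `slice`, `domain` (`"A"`/`"B"`), `split`, `seed`, and the
#'   list-column `image`.
#' @export
generate_dataset <- function(n_subjects, slices_per_subject = 10L,
                             config = phantom_config(), master_seed = 1L,
                             materialize = TRUE) {
  stopifnot(n_subjects >= 1, slices_per_subject >= 1)
  subject_ids <- sprintf("S%05d", seq_len(n_subjects))
  split <- rep("train", n_subjects)
  names(split) <- subject_ids
  if (n_subjects >= 10) {
    sp <- split_subjects(subject_ids, master_seed)
    split[sp$val] <- "val"
    split[sp$test] <- "test"
  }
  grid <- expand.grid(slice = seq_len(slices_per_subject),
                      subject = seq_len(n_subjects))
  # seeds below 2^31, unique per (subject, slice)
  slice_seed <- (as.integer(master_seed) %% 100000L) * 20011L +
    (grid$subject - 1L) * as.integer(slices_per_subject) + grid$slice

  render_one <- function(i) {
    ph <- generate_phantom(config, subject_seed = slice_seed[i])
    list(A = ph$contrast_a, B = ph$contrast_b)
  }
  images <- if (materialize) lapply(seq_len(nrow(grid)), render_one)

  manifest <- tibble::tibble(
    subject_id = rep(subject_ids[grid$subject], each = 2L),
    slice = rep(grid$slice, each = 2L),
    domain = rep(c("A", "B"), nrow(grid)),
    split = rep(unname(split[subject_ids[grid$subject]]), each = 2L),
    seed = rep(slice_seed, each = 2L),
    image = if (materialize) {
      purrr::flatten(lapply(images, function(p) list(p$A, p$B)))
    } else {
      vector("list", 2L * nrow(grid))
    }
  )
  class(manifest) <- c("phantom_manifest", class(manifest))
  attr(manifest, "config") <- config
  attr(manifest, "master_seed") <- as.integer(master_seed)
  manifest
}

#' Subsample the training slices of a manifest
#'
#' Uniformly samples `n_slices` training slices, balanced across the two
#' domains (`n_slices / 2` from each); validation and test rows are left
#' untouched. Supports the robustness-to-dataset-size experiment.
#'
#' @param manifest A `phantom_manifest`.
#' @param n_slices Total number of training slices to keep (even number).
#' @param seed Integer seed for the subsample.
#' @return The reduced manifest.
#' @export
subsample_manifest <- function(manifest, n_slices, seed = 1L) {
  train_idx <- which(manifest$split == "train")
  if (n_slices > length(train_idx)) {
    stop("requested ", n_slices, " training slices but only ",
         length(train_idx), " are available")
  }
  per_dom <- n_slices %/% 2L
  set.seed(seed)
  keep <- unlist(lapply(c("A", "B"), function(dm) {
    idx <- train_idx[manifest$domain[train_idx] == dm]
    sort(sample(idx, per_dom))
  }))
  out <- manifest[sort(c(keep, which(manifest$split != "train"))), ]
  class(out) <- class(manifest)
  attr(out, "config") <- attr(manifest, "config")
  out
}

#' Assemble registered test pairs for evaluation
#'
#' Joins the A and B rows of the requested split by (subject, slice) and
#' translates the source side with the fitted model in both directions.
#'
#' @param fit A `switchgan_fit`.
#' @param manifest A `phantom_manifest` with materialized images.
#' @param split Which split to evaluate (default `"test"`).
#' @return A tibble of per-image records with columns `subject_id`, `slice`,
#'   `direction`, `synthesized`, `target`, `source`, ready for
#'   [evaluate_synthesis()].
#' @export
synthesize_test_pairs <- function(fit, manifest, split = "test") {
  rows <- manifest[manifest$split == split, ]
  if (nrow(rows) == 0) stop("no rows in split '", split, "'")
  a <- rows[rows$domain == "A", ]
  b <- rows[rows$domain == "B", ]
  key_a <- paste(a$subject_id, a$slice)
  key_b <- paste(b$subject_id, b$slice)
  common <- intersect(key_a, key_b)
  a <- a[match(common, key_a), ]
  b <- b[match(common, key_b), ]
  fake_b <- synthesize(fit, a$image, "a2b")
  fake_a <- synthesize(fit, b$image, "b2a")
  dplyr::bind_rows(
    tibble::tibble(subject_id = a$subject_id, slice = a$slice,
                   direction = "a2b", synthesized = fake_b,
                   target = b$image, source = a$image),
    tibble::tibble(subject_id = b$subject_id, slice = b$slice,
                   direction = "b2a", synthesized = fake_a,
                   target = a$image, source = b$image)
  )
}
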