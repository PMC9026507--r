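# File I/O: NIfTI volumes (via RNifti), PNG slice previews, intensity
# normalization, axial slice extraction, run configuration round-trip, and
# checkpoint archives.

#' Read a NIfTI volume
#'
#' @param path Path to a `.nii` / `.nii.gz` file.
#' @return A 3D numeric array with the NIfTI header attached (voxels and
#'   affine round-trip losslessly through [write_volume()]).
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("volume not found: ", path)
  RNifti::readNifti(path)
}

#' Write a NIfTI volume
#'
#' @param vol 3D numeric array, optionally carrying NIfTI metadata (e.g.
#'   from [read_volume()]); plain arrays get a default header. Set voxel
#'   spacing with `RNifti::pixdim(vol) <- c(...)` before writing.
#' @param path Destination `.nii` or `.nii.gz` path.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  RNifti::writeNifti(vol, path)
  invisible(path)
}

#' Min-max normalize intensities to `[-1, 1]`
#'
#' The range the generator consumes and produces. Constant input maps to
#' all zeros. Idempotent.
#'
#' @param x Numeric matrix or array with finite values.
#' @return Same shape, values in `[-1, 1]`.
#' @export
normalize_intensity <- function(x) {
  if (!all(is.finite(x))) stop("non-finite intensities")
  r <- range(x)
  if (r[1] == r[2]) return(x * 0)
  2 * (x - r[1]) / (r[2] - r[1]) - 1
}

#' Extract equally spaced axial slices from the middle third of a volume
#'
#' Mirrors the common practice of evaluating a fixed number of central
#' slices per subject. The `n` slice indices are equally spaced across the
#' middle third of the slice axis, centered on the volume's mid-slice.
#'
#' @param vol 3D array (`H x W x D`).
#' @param n Number of slices (`n <= D`); `n = 1` returns the middle slice,
#'   `n = D` all slices.
#' @return List of `n` matrices, slice indices attached as names.
#' @export
extract_axial_slices <- function(vol, n) {
  d <- dim(vol)
  stopifnot(length(d) == 3)
  if (n > d[3]) stop("requested ", n, " slices from a depth-", d[3], " volume")
  if (n == d[3]) {
    idx <- seq_len(d[3])
  } else if (n == 1L) {
    idx <- ceiling(d[3] / 2)
  } else {
    lo <- max(1, ceiling(d[3] / 3))
    hi <- min(d[3], ceiling(2 * d[3] / 3))
    idx <- unique(round(seq(lo, hi, length.out = n)))
    # pad outward if rounding collapsed indices
    while (length(idx) < n) {
      idx <- unique(c(max(1, min(idx) - 1), idx, min(d[3], max(idx) + 1)))
    }
    idx <- sort(idx)[seq_len(n)]
  }
  out <- lapply(idx, function(i) vol[, , i])
  names(out) <- as.character(idx)
  out
}

#' Write / read a grayscale slice as PNG
#'
#' 8-bit preview export: intensities in `[-1, 1]` are mapped to `[0, 1]`.
#' For lossless interchange use NIfTI ([write_volume()]).
#'
#' @param image `H x W` matrix in `[-1, 1]`.
#' @param path Destination `.png`.
#' @return `path` invisibly; [read_slice_png()] returns the matrix back on
#'   the `[-1, 1]` scale (8-bit quantized).
#' @export
write_slice_png <- function(image, path) {
  png::writePNG(pmin(pmax((image + 1) / 2, 0), 1), path)
  invisible(path)
}

#' @rdname write_slice_png
#' @export
read_slice_png <- function(path) {
  if (!file.exists(path)) stop("slice not found: ", path)
  m <- png::readPNG(path)
  if (length(dim(m)) == 3L) m <- m[, , 1]
  2 * m - 1
}

#' Export a phantom manifest to disk
#'
#' Writes per-subject directories `contrast_a/`, `contrast_b/` with one
#' NIfTI slice file each plus PNG previews, and a `manifest.json` with ids,
#' paths, splits, and seeds.
#'
#' @param manifest A materialized `phantom_manifest`.
#' @param dir Output directory (created if needed).
#' @param png Also write 8-bit PNG previews.
#' @return The manifest with a `path` column, invisibly.
#' @export
export_dataset <- function(manifest, dir, png = FALSE) {
  stopifnot(!any(vapply(manifest$image, is.null, logical(1))))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(nrow(manifest))   # stored relative to `dir`
  for (i in seq_len(nrow(manifest))) {
    rel <- file.path(manifest$subject_id[i],
                     ifelse(manifest$domain[i] == "A", "contrast_a", "contrast_b"))
    dir.create(file.path(dir, rel), recursive = TRUE, showWarnings = FALSE)
    base <- sprintf("slice_%03d", manifest$slice[i])
    img <- manifest$image[[i]]
    vol <- array(img, c(dim(img), 1L))
    write_volume(vol, file.path(dir, rel, paste0(base, ".nii.gz")))
    if (png) write_slice_png(img, file.path(dir, rel, paste0(base, ".png")))
    paths[i] <- file.path(rel, paste0(base, ".nii.gz"))
  }
  meta <- manifest
  meta$image <- NULL
  meta$path <- paths
  jsonlite::write_json(
    list(master_seed = attr(manifest, "master_seed"),
         records = meta),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA
  )
  manifest$path <- file.path(dir, paths)
  invisible(manifest)
}

#' Load an exported phantom dataset
#'
#' @param dir Directory written by [export_dataset()].
#' @return A materialized `phantom_manifest`.
#' @export
import_dataset <- function(dir) {
  mf <- file.path(dir, "manifest.json")
  if (!file.exists(mf)) stop("no manifest.json in ", dir)
  j <- jsonlite::read_json(mf, simplifyVector = TRUE)
  rec <- tibble::as_tibble(j$records)
  rec$image <- lapply(rec$path, function(p) {
    v <- read_volume(file.path(dir, p))
    matrix(as.numeric(v), dim(v)[1], dim(v)[2])  # trailing singleton may drop
  })
  rec$path <- NULL
  class(rec) <- c("phantom_manifest", class(rec))
  attr(rec, "master_seed") <- j$master_seed
  rec
}

#' Run-configuration round trip
#'
#' Nested list of phantom / generator / training / metric settings,
#' serialized to YAML (or JSON by extension) and read back losslessly.
#'
#' @param config A named list.
#' @param path `.yaml`/`.yml` or `.json` destination.
#' @return `read_run_config()` returns the list.
#' @export
write_run_config <- function(config, path) {
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(config, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(config, path)
  }
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config not found: ", path)
  if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
}

# ---- Checkpoints -----------------------------------------------------------

strip_net <- function(net) {
  if (is.null(net)) return(NULL)
  list(params = net$params, config = net$config, type = net$type %||% NA,
       site_channels = net$site_channels,
       coder = if (!is.null(net$coder))
         list(params = net$coder$params, site_channels = net$coder$site_channels))
}

revive_generator <- function(st, cls) {
  g <- new.env(parent = emptyenv())
  g$params <- st$params; g$config <- st$config; g$type <- st$type
  g$site_channels <- st$site_channels
  if (!is.null(st$coder)) {
    cd <- new.env(parent = emptyenv())
    cd$params <- st$coder$params
    cd$site_channels <- st$coder$site_channels
    class(cd) <- "sg_style_coder"
    g$coder <- cd
  } else g$coder <- NULL
  class(g) <- "sg_generator"
  g
}

revive_discriminator <- function(st) {
  d <- new.env(parent = emptyenv())
  d$params <- st$params; d$config <- st$config
  class(d) <- "sg_discriminator"
  d
}

#' Save / load a training checkpoint
#'
#' A single archive holding the generator(s), style coder, both
#' discriminators, configuration, loss log and epoch counter. Forward
#' outputs after a load are identical to before the save.
#'
#' @param fit A `switchgan_fit`.
#' @param path Destination `.rds`.
#' @return [load_checkpoint()] returns the revived `switchgan_fit`.
#' @export
save_checkpoint <- function(fit, path) {
  stopifnot(inherits(fit, "switchgan_fit"))
  saveRDS(list(
    format = 1L, model = fit$model,
    generator = strip_net(fit$generator),
    generators = if (!is.null(fit$generators))
      lapply(fit$generators, strip_net),
    d_a = strip_net(fit$d_a), d_b = strip_net(fit$d_b),
    config = fit$config, weights = fit$weights, gen_config = fit$gen_config,
    log = fit$log, epoch = fit$epoch
  ), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  if (!file.exists(path)) stop("checkpoint not found: ", path)
  st <- readRDS(path)
  if (!identical(st$format, 1L)) stop("unknown checkpoint format: ", st$format)
  gens <- if (!is.null(st$generators)) {
    structure(lapply(st$generators, revive_generator), class = "sg_generator_pair")
  }
  make_fit(st$model,
           if (!is.null(st$generator)) revive_generator(st$generator),
           gens,
           revive_discriminator(st$d_a), revive_discriminator(st$d_b),
           st$config, st$weights, st$gen_config, st$log, st$epoch)
}
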