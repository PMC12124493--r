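#' Read a micrograph from TIFF or PNG
#'
#' Returns raw float intensities (not yet normalized). 8/16-bit integer
#' files are scaled by their bit depth into `[0, 1]` by the underlying
#' readers; float TIFFs are returned as stored. In single-channel mode an
#' RGB/multi-channel file is an error naming the mode.
#'
#' @param path File path (`.tif`, `.tiff`, or `.png`).
#' @param channels Expected channel count (1 or 2).
#' @return Numeric matrix (or `H x W x 2` array).
#' @export
read_image <- function(path, channels = 1L) {
  if (!file.exists(path)) stop("no such file: ", path)
  img <- read_any(path, as_is = FALSE)
  nc <- if (length(dim(img)) == 3L) dim(img)[3] else 1L
  if (channels == 1L && nc != 1L)
    stop(path, " has ", nc, " channels but single-channel mode is in effect")
  if (channels == 2L) {
    if (nc < 2L) stop(path, " has ", nc, " channel(s); two-channel mode needs 2")
    img <- img[, , 1:2, drop = FALSE]
  }
  if (length(dim(img)) == 3L && dim(img)[3] == 1L) img <- img[, , 1]
  storage.mode(img) <- "double"
  img
}

#' Read an instance label map from TIFF or PNG
#'
#' Integer values are preserved exactly (16-bit TIFF label maps round-trip
#' losslessly).
#'
#' @param path File path.
#' @return Integer matrix, 0 = background.
#' @export
read_labels <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lab <- read_any(path, as_is = TRUE)
  if (length(dim(lab)) == 3L) {
    if (dim(lab)[3] != 1L) stop("label image ", path, " must be single-channel")
    lab <- lab[, , 1]
  }
  if (max(abs(lab - round(lab))) > 0)
    stop("label image ", path, " contains non-integer values")
  storage.mode(lab) <- "integer"
  lab
}

read_any <- function(path, as_is) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    tiff::readTIFF(path, as.is = as_is)
  } else if (ext == "png") {
    img <- png::readPNG(path)
    # readPNG rescales to [0, 1]; recover 16-bit integer codes for labels.
    # TIFF is the preferred label format (readTIFF reads codes directly).
    if (as_is) round(img * 65535) else img
  } else stop("unsupported image format: .", ext, " (", path, ")")
}

#' Write a float micrograph / an integer label map as TIFF
#'
#' Micrographs are written as 32-bit float TIFF (bit-exact round trip);
#' label maps as 16-bit unsigned TIFF.
#'
#' @param image Numeric matrix (or `H x W x C` array) in `[0, 1]`.
#' @param labels Integer matrix with values in 0..65535.
#' @param path Output file path.
#' @export
write_image <- function(image, path) {
  tiff::writeTIFF(image, path, bits.per.sample = 32L, reduce = FALSE)
  invisible(path)
}

#' @rdname write_image
#' @export
write_labels <- function(labels, path) {
  if (max(labels) > 65535L) stop("more than 65535 labels cannot be stored in 16 bits")
  tiff::writeTIFF(labels / 65535, path, bits.per.sample = 16L, reduce = FALSE)
  invisible(path)
}

#' Dataset-profile run configuration
#'
#' Bundles the engine, model, postprocessing, and evaluation settings for a
#' run. The `"u2os"` profile is the published nucleus setting (40 px patch,
#' 10 simultaneous points, 30 iterations, 20 px minimum mask); the
#' `"neuroblastoma"` profile the whole-cell setting (120 px patch, 1 point,
#' 100 iterations, two-channel mask rule); `"toy"` is the scaled-down
#' synthetic setting used throughout the tests.
#'
#' @param profile `"toy"`, `"u2os"`, or `"neuroblastoma"`.
#' @param seed Global seed.
#' @param ... Overrides for any of the nested settings: `engine` (list of
#'   [engine_config()] arguments), `vqvae` (list of [vqvae_config()]
#'   arguments), `scene` (list of [scene_params()] arguments),
#'   `threshold_frac`, `min_pixels`, `channel_rules`, `taus`.
#' @return A list of class `cd_run_config` with fully expanded components.
#' @export
run_config <- function(profile = c("toy", "u2os", "neuroblastoma"),
                       seed = 1L, ...) {
  profile <- match.arg(profile)
  base <- switch(profile,
    toy = list(engine = list(patch_size = 32L, n_points = 10L, max_iter = 30L),
               vqvae = list(profile = "toy"),
               threshold_frac = 0.1, min_pixels = 20L, channel_rules = NULL),
    u2os = list(engine = list(patch_size = 40L, n_points = 10L, max_iter = 30L),
                vqvae = list(profile = "full", patch_size = 40L),
                threshold_frac = 0.1, min_pixels = 20L, channel_rules = NULL),
    neuroblastoma = list(
      engine = list(patch_size = 120L, n_points = 1L, max_iter = 100L),
      vqvae = list(profile = "full", patch_size = 120L),
      threshold_frac = 0.1, min_pixels = 20L,
      channel_rules = list(nucleus = 20L, cyto = 1L)))
  over <- list(...)
  for (nm in names(over)) {
    if (nm %in% c("engine", "vqvae", "scene")) {
      base[[nm]] <- utils::modifyList(base[[nm]] %||% list(), over[[nm]])
    } else base[[nm]] <- over[[nm]]
  }
  base$vqvae$seed <- base$vqvae$seed %||% seed
  eng <- do.call(engine_config, base$engine)
  vq <- do.call(vqvae_config, base$vqvae)
  sc <- do.call(scene_params, utils::modifyList(list(seed = seed),
                                                base$scene %||% list()))
  structure(list(profile = profile, seed = as.integer(seed), engine = eng,
                 vqvae = vq, scene = sc,
                 threshold_frac = base$threshold_frac,
                 min_pixels = base$min_pixels,
                 channel_rules = base$channel_rules,
                 taus = base$taus %||% c(0.5, 0.6, 0.7, 0.8, 0.9)),
            class = "cd_run_config")
}

#' Run the full segmentation pipeline over a set of images
#'
#' For each image: normalize, pad, multipass decomposition, binarize,
#' size-filter, resolve overlaps into a label map. When ground truth is
#' supplied, average precision over the set is evaluated as well. A
#' manifest (configuration, seed, per-image object counts and losses) makes
#' the run reproducible.
#'
#' @param images List of raw intensity matrices (or a list of `cd_scene`
#'   objects, whose images and — with `predictor = "oracle"` — labels are
#'   used).
#' @param predictor A `cd_predictor`, or the string `"oracle"` to build a
#'   ground-truth oracle per scene (requires `images` to be scenes).
#' @param config A [run_config()].
#' @param truths Optional list of ground-truth label maps (defaults to the
#'   scenes' labels when scenes are given).
#' @param normalize Whether to percentile-normalize the images first.
#' @param verbose Per-image progress messages.
#' @return List with `labels` (predicted label maps), `states` (final
#'   engine states), `report` (AP table or NULL), and `manifest`.
#' @export
run_pipeline <- function(images, predictor, config, truths = NULL,
                         normalize = TRUE, verbose = FALSE) {
  stopifnot(inherits(config, "cd_run_config"))
  scenes <- NULL
  if (length(images) > 0L && inherits(images[[1]], "cd_scene")) {
    scenes <- images
    images <- lapply(scenes, `[[`, "image")
    if (is.null(truths)) truths <- lapply(scenes, `[[`, "labels")
  }
  if (length(images) == 0L) stop("no input images")
  oracle_mode <- identical(predictor, "oracle")
  if (oracle_mode && is.null(scenes))
    stop("predictor = \"oracle\" requires cd_scene inputs with ground truth")
  labels <- vector("list", length(images))
  states <- vector("list", length(images))
  counts <- integer(length(images))
  losses <- numeric(length(images))
  for (i in seq_along(images)) {
    img <- images[[i]]
    if (normalize) img <- normalize_image(img)
    pred_i <- if (oracle_mode) {
      sc <- scenes[[i]]
      sc$image <- img
      oracle_predictor(sc, config$engine$patch_size, config$engine$mirror_px)
    } else predictor
    st <- decompose_image(img, pred_i, config$engine, verbose = verbose)
    labels[[i]] <- segment_state(st, img, config$threshold_frac,
                                 config$min_pixels, config$channel_rules)
    states[[i]] <- st
    counts[i] <- length(st$objects)
    losses[i] <- st$loss
    if (verbose)
      message(sprintf("image %d: %d objects, final loss %.3g", i, counts[i],
                      losses[i]))
  }
  report <- if (!is.null(truths)) evaluate_set(labels, truths, config$taus)
  manifest <- list(profile = config$profile, seed = config$seed,
                   n_images = length(images), objects_per_image = counts,
                   final_loss = losses,
                   engine = unclass(config$engine),
                   threshold_frac = config$threshold_frac,
                   min_pixels = config$min_pixels,
                   package_version = as.character(utils::packageVersion("celldecomp")))
  list(labels = labels, states = states, report = report, manifest = manifest)
}
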