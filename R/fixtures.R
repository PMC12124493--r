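#' Parameters for a synthetic fluorescence micrograph
#'
#' Describes a scene of bright elliptical cells with radially decaying
#' intensity on a dark, optionally noisy background, emulating nucleus-stain
#' micrographs (bright blobs of varying size and brightness, occasional
#' near-touching cells).
#'
#' @param height,width Image size in pixels.
#' @param n_cells Number of cells to place.
#' @param radius_range Min/max semi-major axis in pixels.
#' @param axis_ratio_range Min/max ratio of semi-minor to semi-major axis.
#' @param intensity_range Min/max peak intensity, as a fraction of the
#'   dynamic range (images live in `[0, 1]`).
#' @param background_noise_sd Standard deviation of additive Gaussian
#'   background noise (intensity fraction); 0 gives a noiseless scene.
#' @param min_center_separation Minimum pairwise distance between cell
#'   centers in pixels. The default, `2 * max(radius_range) + 2`, guarantees
#'   non-overlapping cells; pass something smaller (e.g. via
#'   `touching = TRUE`) to allow adjacent cells.
#' @param touching If `TRUE`, lower the separation to
#'   `max(radius_range) + 1` so cells may touch (densely packed scenes).
#' @param margin Minimum distance from a cell center to the image border.
#' @param channels 1 (default) or 2. In two-channel mode channel 1 is a
#'   cytoplasm-like stain covering the whole ellipse and channel 2 a
#'   nucleus-like stain covering a concentric ellipse of half the axes.
#' @param seed Integer seed; the whole scene (placement and noise) is a
#'   deterministic function of it.
#' @return An object of class `cd_scene_params`.
#' @export
scene_params <- function(height = 128L, width = 128L, n_cells = 10L,
                         radius_range = c(4, 8),
                         axis_ratio_range = c(0.6, 1),
                         intensity_range = c(0.5, 0.9),
                         background_noise_sd = 0.02,
                         min_center_separation = NULL,
                         touching = FALSE,
                         margin = NULL,
                         channels = 1L,
                         seed = 1L) {
  if (is.null(min_center_separation)) {
    min_center_separation <- if (touching) max(radius_range) + 1
                             else 2 * max(radius_range) + 2
  }
  if (is.null(margin)) margin <- ceiling(max(radius_range)) + 1
  stopifnot(height > 0, width > 0, n_cells >= 0,
            diff(radius_range) >= 0, diff(axis_ratio_range) >= 0,
            diff(intensity_range) >= 0, min_center_separation >= 0,
            background_noise_sd >= 0, channels %in% c(1L, 2L))
  structure(list(height = as.integer(height), width = as.integer(width),
                 n_cells = as.integer(n_cells), radius_range = radius_range,
                 axis_ratio_range = axis_ratio_range,
                 intensity_range = intensity_range,
                 background_noise_sd = background_noise_sd,
                 min_center_separation = min_center_separation,
                 margin = margin, channels = as.integer(channels),
                 seed = as.integer(seed)),
            class = "cd_scene_params")
}

# Evaluate the current RNG-independent code with a local seed, restoring the
# caller's RNG state afterwards.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Paint one radially decaying ellipse into `img` and its footprint into
# `labels`. Intensity peaks at the center and falls to half the peak at the
# boundary, so downstream brightness thresholds are exercised nontrivially.
paint_cell <- function(img, labels, cy, cx, a, b, theta, peak, label,
                       overwrite_labels = FALSE) {
  h <- nrow(img); w <- ncol(img)
  r <- ceiling(max(a, b))
  ys <- max(1L, floor(cy - r)):min(h, ceiling(cy + r))
  xs <- max(1L, floor(cx - r)):min(w, ceiling(cx + r))
  dy <- outer(ys - cy, rep(1, length(xs)))
  dx <- outer(rep(1, length(ys)), xs - cx)
  u <- cos(theta) * dy + sin(theta) * dx
  v <- -sin(theta) * dy + cos(theta) * dx
  r2 <- (u / a)^2 + (v / b)^2
  inside <- r2 <= 1
  if (!any(inside)) return(list(img = img, labels = labels, n = 0L))
  val <- peak * (1 - 0.5 * sqrt(pmax(r2, 0)))
  sub_i <- img[ys, xs, drop = FALSE]
  sub_l <- labels[ys, xs, drop = FALSE]
  take <- inside & (overwrite_labels | sub_l == 0L)
  sub_i[inside] <- pmax(sub_i[inside], val[inside])
  sub_l[take] <- label
  img[ys, xs] <- sub_i
  labels[ys, xs] <- sub_l
  list(img = img, labels = labels, n = sum(take))
}

#' Generate a synthetic micrograph with ground-truth instance labels
#'
#' Cells are rotated ellipses with smoothly (radially) decaying intensity,
#' placed by rejection sampling so that centers are pairwise at least
#' `min_center_separation` apart. Gaussian background noise is added and the
#' image clipped to `[0, 1]`. The scene is a deterministic function of
#' `params$seed`.
#'
#' @param params A [scene_params()] object.
#' @param max_attempts Rejection-sampling attempts per cell before giving up
#'   (an error signals overcrowded parameters).
#' @return A list of class `cd_scene` with elements `image` (numeric matrix,
#'   or `height x width x 2` array in two-channel mode), `labels` (integer
#'   matrix, 0 = background, 1..n_cells each present), and `params`.
#' @export
generate_scene <- function(params, max_attempts = 2000L) {
  stopifnot(inherits(params, "cd_scene_params"))
  with_seed(params$seed, {
    h <- params$height; w <- params$width
    img <- matrix(0, h, w)
    img2 <- if (params$channels == 2L) matrix(0, h, w)
    labels <- matrix(0L, h, w)
    centers <- matrix(numeric(0), ncol = 2)
    lo_m <- params$margin + 1; hi_y <- h - params$margin; hi_x <- w - params$margin
    if (params$n_cells > 0 && (hi_y < lo_m || hi_x < lo_m))
      stop("image too small for the requested margin")
    for (i in seq_len(params$n_cells)) {
      placed <- FALSE
      for (att in seq_len(max_attempts)) {
        cy <- stats::runif(1, lo_m, hi_y)
        cx <- stats::runif(1, lo_m, hi_x)
        if (nrow(centers) == 0 ||
            all(sqrt((centers[, 1] - cy)^2 + (centers[, 2] - cx)^2) >=
                params$min_center_separation)) {
          placed <- TRUE
          break
        }
      }
      if (!placed)
        stop("could not place cell ", i, " after ", max_attempts,
             " attempts; parameters overcrowd the image")
      a <- stats::runif(1, params$radius_range[1], params$radius_range[2])
      ratio <- stats::runif(1, params$axis_ratio_range[1],
                            params$axis_ratio_range[2])
      theta <- stats::runif(1, 0, pi)
      peak <- stats::runif(1, params$intensity_range[1],
                           params$intensity_range[2])
      pc <- paint_cell(img, labels, cy, cx, a, a * ratio, theta, peak, i)
      if (pc$n == 0L)
        stop("cell ", i, " received no pixels; radius too small")
      img <- pc$img; labels <- pc$labels
      if (params$channels == 2L) {
        pc2 <- paint_cell(img2, matrix(0L, h, w), cy, cx, a / 2,
                          a * ratio / 2, theta, peak, i,
                          overwrite_labels = TRUE)
        img2 <- pc2$img
      }
      centers <- rbind(centers, c(cy, cx))
    }
    if (params$background_noise_sd > 0) {
      img <- img + matrix(stats::rnorm(h * w, sd = params$background_noise_sd), h, w)
      if (params$channels == 2L)
        img2 <- img2 + matrix(stats::rnorm(h * w, sd = params$background_noise_sd), h, w)
    }
    img <- pmin(pmax(img, 0), 1)
    image <- if (params$channels == 2L) {
      img2 <- pmin(pmax(img2, 0), 1)
      array(c(img, img2), dim = c(h, w, 2L))
    } else img
    structure(list(image = image, labels = labels, params = params),
              class = "cd_scene")
  })
}

#' Ground-truth oracle predictor
#'
#' A test double for the trained generative model: at a query point it
#' returns the current image patch masked by the ground-truth instance
#' occupying the patch's central pixel, or an all-zero patch when the center
#' is background. This is exactly the training target of the single-central-
#' cell reconstruction task, so it isolates the decomposition engine from
#' model quality.
#'
#' @param scene A `cd_scene`.
#' @param patch_size Even patch side in pixels.
#' @param mirror_px Mirror band width used when padding (see
#'   [pad_for_inference()]); the label map is padded identically so mirrored
#'   cells keep their identity.
#' @return A predictor object usable with [predict_object()].
#' @export
oracle_predictor <- function(scene, patch_size, mirror_px = 8L) {
  stopifnot(inherits(scene, "cd_scene"))
  labels_p <- pad_for_inference(scene$labels, patch_size, mirror_px)
  structure(list(labels = labels_p, patch_size = as.integer(patch_size)),
            class = c("cd_oracle", "cd_predictor"))
}

#' Predict a single-object intensity patch at a point
#'
#' Generic shared by the trained VQ-VAE ([vqvae_predictor()]) and the
#' ground-truth oracle ([oracle_predictor()]): given a point in padded image
#' coordinates and the (padded) image the engine is currently explaining,
#' return the predicted single-cell patch anchored there.
#'
#' @param predictor A predictor object.
#' @param point `c(row, col)`, 1-based, in padded image coordinates; the
#'   patch's central pixel (index `patch_size/2 + 1`) lands on it.
#' @param image Padded image the prediction is made from.
#' @return List with `patch` (patch_size x patch_size, non-negative) and
#'   `anchor` (the point).
#' @export
predict_object <- function(predictor, point, image) {
  UseMethod("predict_object")
}

#' @export
predict_object.cd_oracle <- function(predictor, point, image) {
  p <- predictor$patch_size
  idx <- patch_index(point, p, dim(image))
  lab <- predictor$labels[point[1], point[2]]
  patch <- image[idx$rows, idx$cols]
  if (lab == 0L) {
    patch <- matrix(0, p, p)
  } else {
    patch <- patch * (predictor$labels[idx$rows, idx$cols] == lab)
  }
  list(patch = pmax(patch, 0), anchor = point)
}

# Row/col ranges of the patch_size window whose central pixel
# (1-based offset patch_size/2 + 1) sits on `point`.
patch_index <- function(point, patch_size, imdim) {
  half <- patch_size %/% 2L
  rows <- (point[1] - half):(point[1] + half - 1L)
  cols <- (point[2] - half):(point[2] + half - 1L)
  if (rows[1] < 1L || cols[1] < 1L || rows[patch_size] > imdim[1] ||
      cols[patch_size] > imdim[2])
    stop("patch window centered at (", point[1], ",", point[2],
         ") falls outside the padded image")
  list(rows = rows, cols = cols)
}
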