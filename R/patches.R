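#' Normalize a raw intensity image to the unit interval
#'
#' Percentile-clip normalization: values are clipped to the
#' `[p_low, p_high]` percentile range and linearly rescaled to `[0, 1]`.
#' The slightly-inset default percentiles make the mapping robust to hot
#' pixels, common in fluorescence data. A constant image (degenerate
#' percentile range) maps to all zeros.
#'
#' @param raw Numeric matrix (or `H x W x C` array) of non-negative,
#'   finite intensities.
#' @param p_low,p_high Clip percentiles, in percent.
#' @return Image of the same shape with values in `[0, 1]`.
#' @export
normalize_image <- function(raw, p_low = 0.1, p_high = 99.9) {
  if (!all(is.finite(raw))) stop("non-finite pixel values in input image")
  stopifnot(p_low < p_high)
  q <- stats::quantile(raw, probs = c(p_low, p_high) / 100, names = FALSE)
  if (q[2] <= q[1]) {
    raw[] <- 0
    return(raw)
  }
  out <- (pmin(pmax(raw, q[1]), q[2]) - q[1]) / (q[2] - q[1])
  out
}

#' Pad an image for border prediction
#'
#' Pads each side by `patch_size / 2` pixels so a patch can be centered on
#' any original pixel: the innermost `mirror_px` pixels of the pad reflect
#' the image content (symmetric reflection, edge pixel included) and the
#' remaining `patch_size / 2 - mirror_px` pixels are zero. With the paper
#' profiles this gives 20 px per side for a 40 px patch and 60 px per side
#' for a 120 px patch, 8 of them mirrored.
#'
#' Also used on integer label maps so mirrored cells keep their identity.
#'
#' @param image Numeric or integer matrix.
#' @param patch_size Even patch side in pixels.
#' @param mirror_px Width of the mirror band, `<= patch_size / 2`.
#' @return Matrix of side lengths `dim(image) + patch_size`.
#' @export
pad_for_inference <- function(image, patch_size, mirror_px = 8L) {
  if (patch_size %% 2L != 0L)
    stop("patch_size must be even so half-size padding is integral")
  half <- patch_size %/% 2L
  if (mirror_px > half) stop("mirror_px must be <= patch_size / 2")
  if (mirror_px > min(dim(image)))
    stop("mirror_px exceeds the image extent")
  h <- nrow(image); w <- ncol(image)
  ridx <- c(if (mirror_px > 0) mirror_px:1, 1:h,
            if (mirror_px > 0) h:(h - mirror_px + 1L))
  cidx <- c(if (mirror_px > 0) mirror_px:1, 1:w,
            if (mirror_px > 0) w:(w - mirror_px + 1L))
  mir <- image[ridx, cidx, drop = FALSE]
  z <- half - mirror_px
  out <- matrix(if (is.integer(image)) 0L else 0, h + patch_size, w + patch_size)
  out[(z + 1L):(z + nrow(mir)), (z + 1L):(z + ncol(mir))] <- mir
  out
}

#' Crop a padded image back to its original extent
#'
#' Inverse of [pad_for_inference()]: drops `patch_size / 2` pixels per side.
#' @inheritParams pad_for_inference
#' @export
unpad <- function(image, patch_size) {
  half <- patch_size %/% 2L
  image[(half + 1L):(nrow(image) - half), (half + 1L):(ncol(image) - half),
        drop = FALSE]
}

#' Sample one (input patch, single-central-cell target) training pair
#'
#' With probability `p_center` the patch center lands uniformly on a
#' foreground pixel of some instance, otherwise uniformly on background.
#' The target is the input patch multiplied by the mask of the instance
#' occupying the central pixel ("touching" is read literally as
#' `labels[center] != 0`), or an all-zero image for background centers —
#' the empty-target cases teach the model not to hallucinate cells.
#'
#' Uses the current RNG state; seed with `set.seed()` for reproducibility.
#'
#' @param scene A `cd_scene` (single-channel).
#' @param patch_size Even patch side in pixels.
#' @param p_center Probability that the central pixel belongs to a cell.
#' @param mirror_px Mirror band used to pad the scene for border patches.
#' @return List with `input`, `target` (patch_size x patch_size matrices),
#'   `has_center_cell`, and `center` (unpadded image coordinates).
#' @export
sample_training_pair <- function(scene, patch_size, p_center = 0.8,
                                 mirror_px = 8L) {
  sampler <- scene_sampler(scene, patch_size, mirror_px)
  sampler(p_center)
}

# Precompute the padded image/labels and the foreground/background index
# pools of a scene; returns a closure drawing one pair per call. Used by the
# training loop to avoid re-padding at every draw.
scene_sampler <- function(scene, patch_size, mirror_px = 8L) {
  stopifnot(inherits(scene, "cd_scene"), is.matrix(scene$image))
  img_p <- pad_for_inference(scene$image, patch_size, mirror_px)
  lab_p <- pad_for_inference(scene$labels, patch_size, mirror_px)
  half <- patch_size %/% 2L
  fg <- which(scene$labels != 0L)
  bg <- which(scene$labels == 0L)
  h <- nrow(scene$labels)
  function(p_center) {
    want_fg <- stats::runif(1) < p_center
    pool <- if (want_fg) fg else bg
    if (length(pool) == 0L)
      stop("scene has no ", if (want_fg) "foreground" else "background",
           " pixels to sample a patch center from")
    lin <- pool[sample.int(length(pool), 1L)]
    r <- ((lin - 1L) %% h) + 1L
    cc <- ((lin - 1L) %/% h) + 1L
    point <- c(r + half, cc + half)
    idx <- patch_index(point, patch_size, dim(img_p))
    input <- img_p[idx$rows, idx$cols]
    lab <- lab_p[point[1], point[2]]
    target <- if (lab == 0L) matrix(0, patch_size, patch_size)
              else input * (lab_p[idx$rows, idx$cols] == lab)
    list(input = input, target = target, has_center_cell = lab != 0L,
         center = c(r, cc))
  }
}
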