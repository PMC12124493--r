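#' Convert accepted object predictions to binary masks
#'
#' Each predicted intensity patch is thresholded at
#' `threshold_frac * mean(image)` — ten percent of the input-image average
#' by default — and translated from padded to unpadded image coordinates;
#' pixels falling outside the image are dropped. The threshold comparison is
#' `>= t`.
#'
#' In two-channel mode (`image` an `H x W x 2` array and predictions
#' carrying `H x W x 2` patches) each channel is thresholded at
#' `threshold_frac` times its own mean; the mask is the union and the
#' per-channel pixel counts are stored for [filter_masks()].
#'
#' @param objects List of accepted predictions (e.g. `state$objects` from
#'   [decompose_image()]).
#' @param image The unpadded, normalized input image the objects explain.
#' @param threshold_frac Fraction of the image mean used as the brightness
#'   threshold; default 0.1.
#' @param patch_size Patch side (taken from the first object if omitted).
#' @return An object of class `cd_masks`: a list with `dim` (image size) and
#'   `objects`, each holding `rows`/`cols` (index ranges within the image),
#'   a logical `mask`, the predicted `intensity` over the same window, a
#'   pixel `count`, and per-channel counts when applicable.
#' @export
binarize_objects <- function(objects, image, threshold_frac = 0.1,
                             patch_size = NULL) {
  two_ch <- length(dim(image)) == 3L
  imdim <- dim(image)[1:2]
  if (length(objects) == 0L)
    return(structure(list(dim = imdim, objects = list()), class = "cd_masks"))
  stopifnot(threshold_frac > 0)
  p <- patch_size %||% nrow(objects[[1]]$patch)
  half <- p %/% 2L
  thr <- if (two_ch) threshold_frac * c(mean(image[, , 1]), mean(image[, , 2]))
         else threshold_frac * mean(image)
  out <- list()
  for (ob in objects) {
    # patch window rows in padded coords are (anchor - half):(anchor + half - 1);
    # subtracting the half-size pad maps them to (anchor - p):(anchor - 1) unpadded
    r0 <- ob$anchor[1] - p - 1L
    c0 <- ob$anchor[2] - p - 1L
    pr <- seq_len(p) + r0
    pc <- seq_len(p) + c0
    keep_r <- which(pr >= 1L & pr <= imdim[1])
    keep_c <- which(pc >= 1L & pc <= imdim[2])
    if (length(keep_r) == 0L || length(keep_c) == 0L) next
    if (two_ch) {
      pat <- ob$patch[keep_r, keep_c, , drop = FALSE]
      m1 <- pat[, , 1] >= thr[1]
      m2 <- pat[, , 2] >= thr[2]
      mask <- m1 | m2
      intensity <- pmax(pat[, , 1], pat[, , 2])
      counts <- c(cyto = sum(m1), nucleus = sum(m2))
    } else {
      pat <- ob$patch[keep_r, keep_c, drop = FALSE]
      mask <- pat >= thr
      intensity <- pat
      counts <- NULL
    }
    if (!any(mask)) next
    out[[length(out) + 1L]] <- list(rows = pr[keep_r], cols = pc[keep_c],
                                    mask = mask, intensity = intensity,
                                    count = sum(mask),
                                    channel_counts = counts,
                                    source_pass = ob$source_pass %||% NA_integer_)
  }
  structure(list(dim = imdim, objects = out), class = "cd_masks")
}

#' Filter masks by minimum pixel counts
#'
#' Single-channel: masks with fewer than `min_pixels` pixels are removed
#' (strictly fewer — a 20-pixel mask survives the default). Two-channel:
#' a mask is removed when its nucleus-channel count is below
#' `channel_rules$nucleus` (default 20) or its cytoplasm-channel count is
#' below `channel_rules$cyto` (default 1), counts taken over the
#' thresholded per-channel intensities.
#'
#' @param masks A `cd_masks`.
#' @param min_pixels Minimum mask size in pixels; default 20.
#' @param channel_rules Optional list with per-channel minima (`nucleus`,
#'   `cyto`) enabling the two-channel rule.
#' @return Filtered `cd_masks`.
#' @export
filter_masks <- function(masks, min_pixels = 20L, channel_rules = NULL) {
  stopifnot(inherits(masks, "cd_masks"), min_pixels >= 0)
  keep <- vapply(masks$objects, function(ob) {
    if (!is.null(channel_rules)) {
      if (is.null(ob$channel_counts))
        stop("channel_rules given but masks carry no per-channel counts")
      ob$channel_counts[["nucleus"]] >= (channel_rules$nucleus %||% 20L) &&
        ob$channel_counts[["cyto"]] >= (channel_rules$cyto %||% 1L)
    } else {
      ob$count >= min_pixels
    }
  }, logical(1))
  masks$objects <- masks$objects[keep]
  masks
}

#' Resolve overlapping masks into an instance label map
#'
#' Every pixel claimed by at least one mask receives the label of the mask
#' with the highest predicted intensity there (ties go to the
#' earlier-accepted mask); unclaimed pixels are background (0). Masks left
#' with no pixels are dropped with a warning.
#'
#' @param masks A filtered `cd_masks`.
#' @return Integer label map of the image size; labels are consecutive
#'   1..n over surviving masks.
#' @export
assign_instances <- function(masks) {
  stopifnot(inherits(masks, "cd_masks"))
  labels <- matrix(0L, masks$dim[1], masks$dim[2])
  best <- matrix(-Inf, masks$dim[1], masks$dim[2])
  for (i in seq_along(masks$objects)) {
    ob <- masks$objects[[i]]
    sub_b <- best[ob$rows, ob$cols, drop = FALSE]
    win <- ob$mask & (ob$intensity > sub_b)   # strict: earlier index wins ties
    if (any(win)) {
      sub_l <- labels[ob$rows, ob$cols, drop = FALSE]
      sub_l[win] <- i
      sub_b[win] <- ob$intensity[win]
      labels[ob$rows, ob$cols] <- sub_l
      best[ob$rows, ob$cols] <- sub_b
    }
  }
  survived <- sort(unique(labels[labels > 0L]))
  lost <- setdiff(seq_along(masks$objects), survived)
  if (length(lost) > 0L)
    warning(length(lost), " mask(s) lost every pixel to overlaps and were dropped")
  relabel <- integer(length(masks$objects))
  relabel[survived] <- seq_along(survived)
  labels[labels > 0L] <- relabel[labels[labels > 0L]]
  labels
}

#' End-to-end conversion of engine output to a label map
#'
#' Binarize, size-filter, and resolve overlaps in one call.
#' @param state A `cd_state` from [decompose_image()].
#' @param image The unpadded normalized input image.
#' @param threshold_frac Brightness threshold fraction; default 0.1.
#' @param min_pixels Minimum mask size; default 20.
#' @param channel_rules Optional two-channel minima (see [filter_masks()]).
#' @return Integer instance label map.
#' @export
segment_state <- function(state, image, threshold_frac = 0.1,
                          min_pixels = 20L, channel_rules = NULL) {
  masks <- binarize_objects(state$objects, image, threshold_frac)
  masks <- filter_masks(masks, min_pixels, channel_rules)
  assign_instances(masks)
}
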