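#' Decomposition engine configuration
#'
#' Controls the iterative accept-if-loss-decreases inference loop. The
#' published profiles are `n_points = 10`, `max_iter = 30` for the nucleus
#' (U2OS-like, 40 px patch) setting and `n_points = 1`, `max_iter = 100`
#' for the whole-cell (neuroblastoma-like, 120 px patch) setting.
#'
#' @param patch_size Even predictor patch side in pixels.
#' @param n_points Number of simultaneous proposal points per iteration (N).
#' @param max_iter Cap on the propose/predict/accept iterations per pass.
#' @param proposal_kernel Side of the (odd) box kernel of ones convolved
#'   with the error image to score proposal locations; default 7.
#' @param suppression_window Side of the square zeroed around each chosen
#'   point in the working score map before picking the next; default 32.
#'   For even sides the window extends `floor((s-1)/2)` pixels before and
#'   `s - 1 - floor((s-1)/2)` after the point in each axis.
#' @param min_improvement Minimum loss decrease required to accept a
#'   prediction; acceptance requires `delta_loss < -min_improvement`, so the
#'   default 0 rejects exactly-neutral guesses (e.g. all-zero patches).
#' @param max_passes Cap on multipass rounds over the residual error.
#' @param merge_rule `"max"` (default, idempotent) or `"add"`: how accepted
#'   patches combine into the internal image.
#' @param mirror_px Mirror band width for [pad_for_inference()].
#' @return An object of class `cd_engine_config`.
#' @export
engine_config <- function(patch_size = 32L, n_points = 10L, max_iter = 30L,
                          proposal_kernel = 7L, suppression_window = 32L,
                          min_improvement = 0, max_passes = 10L,
                          merge_rule = c("max", "add"), mirror_px = 8L) {
  merge_rule <- match.arg(merge_rule)
  stopifnot(n_points >= 1L, max_iter >= 1L, proposal_kernel %% 2L == 1L,
            suppression_window >= 1L, min_improvement >= 0, max_passes >= 1L)
  structure(list(patch_size = as.integer(patch_size),
                 n_points = as.integer(n_points),
                 max_iter = as.integer(max_iter),
                 proposal_kernel = as.integer(proposal_kernel),
                 suppression_window = as.integer(suppression_window),
                 min_improvement = min_improvement,
                 max_passes = as.integer(max_passes),
                 merge_rule = merge_rule, mirror_px = as.integer(mirror_px)),
            class = "cd_engine_config")
}

# Sum of the k x k window centered at each pixel (k odd), zero outside the
# image; computed with an integral image so it is exact and O(HW).
box_sum_same <- function(mat, k) {
  h <- nrow(mat); w <- ncol(mat); r <- (k - 1L) %/% 2L
  padded <- matrix(0, h + k - 1L, w + k - 1L)
  padded[(r + 1L):(r + h), (r + 1L):(r + w)] <- mat
  cs <- apply(padded, 2, cumsum)
  cs <- t(apply(cs, 1, cumsum))
  cs <- rbind(0, cbind(0, cs))
  i1 <- 1:h; j1 <- 1:w
  cs[i1 + k, j1 + k, drop = FALSE] - cs[i1, j1 + k, drop = FALSE] -
    cs[i1 + k, j1, drop = FALSE] + cs[i1, j1, drop = FALSE]
}

#' Propose prediction points from an error image
#'
#' Convolves the error image with a `kernel x kernel` box of ones (stride
#' one, zero-padded borders) and picks up to `n_points` locations greedily:
#' the global maximum of the working score map is taken (ties broken by the
#' smallest row-major index), a `suppression x suppression` region around it
#' is zeroed in the working map, and the process repeats. Locations whose
#' kernel sum is not strictly positive are never proposed, so an all-zero
#' (or all-negative) error yields no points.
#'
#' @param error Numeric matrix, typically `input - internal`.
#' @param n_points Maximum number of points to return.
#' @param kernel Odd box-kernel side; default 7.
#' @param suppression Suppression window side; default 32.
#' @param margin Exclude centers within `margin` pixels of the border
#'   (default 0). The engine uses `patch_size / 2` so every proposed point
#'   admits a full patch window inside the padded image.
#' @return `m x 2` integer matrix of (row, col) points, `0 <= m <= n_points`,
#'   in selection order.
#' @export
propose_points <- function(error, n_points, kernel = 7L, suppression = 32L,
                           margin = 0L) {
  stopifnot(all(is.finite(error)), n_points >= 1L)
  work <- box_sum_same(error, kernel)
  h <- nrow(work); w <- ncol(work)
  if (margin > 0L) {
    if (2L * margin >= h || 2L * margin >= w) return(matrix(0L, 0L, 2L))
    keep <- matrix(0, h, w)
    keep[(margin + 1L):(h - margin), (margin + 1L):(w - margin)] <- 1
    work <- work * keep
  }
  before <- (suppression - 1L) %/% 2L
  after <- suppression - 1L - before
  pts <- matrix(0L, 0L, 2L)
  for (i in seq_len(n_points)) {
    m <- max(work)
    if (m <= 0) break
    hits <- which(work == m)
    if (length(hits) > 1L) {
      rr <- ((hits - 1L) %% h) + 1L
      cc <- ((hits - 1L) %/% h) + 1L
      o <- order(rr, cc)[1L]   # smallest row-major index
      r <- rr[o]; cl <- cc[o]
    } else {
      r <- ((hits - 1L) %% h) + 1L
      cl <- ((hits - 1L) %/% h) + 1L
    }
    pts <- rbind(pts, c(r, cl))
    work[max(1L, r - before):min(h, r + after),
         max(1L, cl - before):min(w, cl + after)] <- 0
  }
  pts
}

#' Initialize the engine's internal state
#'
#' The state holds the padded input image I, the internal predicted image P
#' (initially zero), the error image E = I - P, the accepted objects, and
#' the global loss. Padding exists only so a patch window centered on any
#' content pixel fits; the loss (and the error that drives proposals) is
#' the mean absolute error over the content region — the actual image —
#' not over the pad bands.
#'
#' @param input Padded input image (numeric matrix).
#' @param patch_size Patch side used for the padding (`patch_size / 2`
#'   pixels per side); 0 treats the whole image as content.
#' @return An object of class `cd_state`.
#' @export
init_state <- function(input, patch_size = 0L) {
  half <- patch_size %/% 2L
  rows <- (half + 1L):(nrow(input) - half)
  cols <- (half + 1L):(ncol(input) - half)
  npix <- length(rows) * length(cols)
  structure(list(input = input, internal = matrix(0, nrow(input), ncol(input)),
                 error = input, objects = list(),
                 content_rows = rows, content_cols = cols,
                 loss = sum(abs(input[rows, cols])) / npix, npix = npix),
            class = "cd_state")
}

#' Merge an object prediction into an internal image
#'
#' Under the default `"max"` rule the internal image becomes the pointwise
#' maximum of itself and the patch over the patch footprint (idempotent, so
#' re-predicting an explained cell never helps); under `"add"` the patch is
#' added.
#'
#' @param internal Internal image P (padded coordinates).
#' @param prediction List with `patch` and `anchor` as returned by
#'   [predict_object()].
#' @param rule `"max"` or `"add"`.
#' @return Updated internal image.
#' @export
merge_prediction <- function(internal, prediction, rule = "max") {
  idx <- patch_index(prediction$anchor, nrow(prediction$patch), dim(internal))
  sub <- internal[idx$rows, idx$cols]
  internal[idx$rows, idx$cols] <-
    if (rule == "max") pmax(sub, prediction$patch) else sub + prediction$patch
  internal
}

#' Accept a prediction only if it reduces the global loss
#'
#' Computes the candidate internal image on the prediction's footprint and
#' the resulting change in the global (content-region) mean absolute error
#' — exactly, since pixels outside the footprint are untouched. The
#' prediction is accepted iff `delta_loss < -min_improvement`; otherwise
#' the state is returned unchanged.
#'
#' @param state A `cd_state`.
#' @param prediction List with `patch` and `anchor`.
#' @param config An [engine_config()].
#' @param source_pass Pass index recorded on accepted objects.
#' @return List with `state` (possibly updated), `accepted`, `delta_loss`.
#' @export
try_accept <- function(state, prediction, config, source_pass = 1L) {
  idx <- patch_index(prediction$anchor, nrow(prediction$patch),
                     dim(state$input))
  i_f <- state$input[idx$rows, idx$cols]
  p_f <- state$internal[idx$rows, idx$cols]
  cand <- if (config$merge_rule == "max") pmax(p_f, prediction$patch)
          else p_f + prediction$patch
  # loss only counts the content region; restrict the footprint to it
  rin <- idx$rows %in% state$content_rows
  cin <- idx$cols %in% state$content_cols
  delta <- (sum(abs((i_f - cand)[rin, cin])) -
            sum(abs((i_f - p_f)[rin, cin]))) / state$npix
  if (delta < -config$min_improvement) {
    state$internal[idx$rows, idx$cols] <- cand
    state$error[idx$rows, idx$cols] <- i_f - cand
    state$loss <- state$loss + delta
    prediction$source_pass <- source_pass
    prediction$accepted <- TRUE
    prediction$delta_loss <- delta
    state$objects[[length(state$objects) + 1L]] <- prediction
    list(state = state, accepted = TRUE, delta_loss = delta)
  } else {
    list(state = state, accepted = FALSE, delta_loss = delta)
  }
}

#' One decomposition pass
#'
#' Repeats {propose up to N points on the current error image; predict at
#' each point from `predict_from`; accept each prediction sequentially iff
#' it lowers the global loss} until an iteration accepts nothing or
#' `max_iter` is reached. Later candidates within an iteration see earlier
#' acceptances.
#'
#' @param state A `cd_state` (global across passes).
#' @param predictor A `cd_predictor`.
#' @param config An [engine_config()].
#' @param predict_from Padded image handed to the predictor (defaults to the
#'   state's input; multipass passes hand the clamped residual instead).
#' @param source_pass Pass index recorded on accepted objects.
#' @param verbose Emit one message per iteration.
#' @return Updated `cd_state`.
#' @export
decompose_pass <- function(state, predictor, config,
                           predict_from = state$input, source_pass = 1L,
                           verbose = FALSE) {
  stopifnot(inherits(state, "cd_state"), inherits(config, "cd_engine_config"))
  half <- config$patch_size %/% 2L
  for (it in seq_len(config$max_iter)) {
    # proposals are driven by the content-region error; shifting the points
    # back by the pad width puts them in padded coordinates, where every
    # window fits by construction
    e_content <- state$error[state$content_rows, state$content_cols,
                             drop = FALSE]
    pts <- propose_points(e_content, config$n_points,
                          config$proposal_kernel, config$suppression_window)
    if (nrow(pts) == 0L) break
    pts[, 1] <- pts[, 1] + state$content_rows[1] - 1L
    pts[, 2] <- pts[, 2] + state$content_cols[1] - 1L
    n_accepted <- 0L
    for (i in seq_len(nrow(pts))) {
      pred <- tryCatch(
        predict_object(predictor, pts[i, ], predict_from),
        error = function(e) stop("predictor failed at point (", pts[i, 1],
                                 ",", pts[i, 2], "): ", conditionMessage(e)))
      res <- try_accept(state, pred, config, source_pass)
      state <- res$state
      n_accepted <- n_accepted + res$accepted
    }
    if (verbose)
      message(sprintf("pass %d iter %d: %d points, %d accepted, loss %.6f",
                      source_pass, it, nrow(pts), n_accepted, state$loss))
    if (n_accepted == 0L) break
  }
  state
}

#' Full multipass decomposition of a micrograph
#'
#' Pass 1 explains the padded input image. Each further pass hands the
#' predictor the current residual error clamped to be non-negative — cells
#' missed earlier stand out there free of already-explained neighbours —
#' while proposals and acceptance always run against the single global
#' internal image and the original input, so the global loss is
#' non-increasing across all passes. Stops when a pass accepts nothing or
#' after `max_passes` passes.
#'
#' @param image Unpadded, normalized micrograph (numeric matrix).
#' @param predictor A `cd_predictor` ([oracle_predictor()] or a trained
#'   [vqvae_predictor()]).
#' @param config An [engine_config()].
#' @param verbose Emit per-iteration progress messages.
#' @return A `cd_state` whose `objects` hold every accepted prediction with
#'   `source_pass` set; `loss` is the final global mean absolute error over
#'   the padded domain.
#' @export
decompose_image <- function(image, predictor, config, verbose = FALSE) {
  stopifnot(is.matrix(image), inherits(config, "cd_engine_config"))
  padded <- pad_for_inference(image, config$patch_size, config$mirror_px)
  state <- init_state(padded, config$patch_size)
  for (pass in seq_len(config$max_passes)) {
    predict_from <- if (pass == 1L) state$input else pmax(state$error, 0)
    n_before <- length(state$objects)
    state <- decompose_pass(state, predictor, config,
                            predict_from = predict_from, source_pass = pass,
                            verbose = verbose)
    if (length(state$objects) == n_before) break
  }
  state
}
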