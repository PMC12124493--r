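# Shared helpers: small scenes and independent brute-force oracles used to
# cross-check the fast implementations.

tiny_scene <- function(seed = 1L, n_cells = 5L, noise = 0, size = 128L,
                       ...) {
  generate_scene(scene_params(height = size, width = size, n_cells = n_cells,
                              background_noise_sd = noise, seed = seed, ...))
}

# Naive proposal oracle: kernel sums by explicit window loops, then greedy
# selection with sequential suppression on the sum map. Independent of the
# integral-image implementation.
brute_propose <- function(error, n_points, kernel = 7L, suppression = 32L) {
  h <- nrow(error); w <- ncol(error); r <- (kernel - 1L) %/% 2L
  sums <- matrix(0, h, w)
  for (i in seq_len(h)) {
    for (j in seq_len(w)) {
      rs <- max(1L, i - r):min(h, i + r)
      cs <- max(1L, j - r):min(w, j + r)
      sums[i, j] <- sum(error[rs, cs])
    }
  }
  before <- (suppression - 1L) %/% 2L
  after <- suppression - 1L - before
  pts <- matrix(0L, 0L, 2L)
  for (k in seq_len(n_points)) {
    m <- max(sums)
    if (m <= 0) break
    hit <- which(sums == m, arr.ind = TRUE)
    hit <- hit[order(hit[, 1], hit[, 2]), , drop = FALSE][1, ]
    pts <- rbind(pts, as.integer(hit))
    sums[max(1L, hit[1] - before):min(h, hit[1] + after),
         max(1L, hit[2] - before):min(w, hit[2] + after)] <- 0
  }
  pts
}

# Exhaustive nearest-neighbour quantization oracle.
brute_quantize <- function(latents, embeddings) {
  apply(latents, 2, function(z) {
    which.min(colSums((embeddings - z)^2))
  })
}

# Optimal one-to-one matching by exhaustive search over assignments of
# predictions to truth instances among pairs with IoU > tau; returns the
# maximum number of matches.
brute_match_count <- function(pred, truth, tau) {
  pl <- sort(unique(pred[pred > 0L]))
  tl <- sort(unique(truth[truth > 0L]))
  ok <- matrix(FALSE, length(pl), length(tl))
  for (i in seq_along(pl)) {
    for (j in seq_along(tl)) {
      ok[i, j] <- iou(pred == pl[i], truth == tl[j]) > tau
    }
  }
  best <- 0L
  recurse <- function(i, used_t, count) {
    if (count + (length(pl) - i + 1L) <= best) return()
    if (i > length(pl)) {
      best <<- max(best, count)
      return()
    }
    recurse(i + 1L, used_t, count)  # leave prediction i unmatched
    for (j in seq_along(tl)) {
      if (!used_t[j] && ok[i, j]) {
        used_t[j] <- TRUE
        recurse(i + 1L, used_t, count + 1L)
        used_t[j] <- FALSE
      }
    }
  }
  if (length(pl) > 0L && length(tl) > 0L) recurse(1L, logical(length(tl)), 0L)
  best
}

# Random label map with n blobby instances for matching tests.
random_label_map <- function(n, size = 32L) {
  lab <- matrix(0L, size, size)
  for (i in seq_len(n)) {
    cy <- sample(4:(size - 4), 1); cx <- sample(4:(size - 4), 1)
    r <- sample(2:4, 1)
    ys <- max(1, cy - r):min(size, cy + r)
    xs <- max(1, cx - r):min(size, cx + r)
    d <- outer((ys - cy)^2, (xs - cx)^2, "+")
    blk <- lab[ys, xs]
    blk[d <= r^2] <- i
    lab[ys, xs] <- blk
  }
  lab
}

toy_engine_config <- function(...) engine_config(patch_size = 32L, ...)
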