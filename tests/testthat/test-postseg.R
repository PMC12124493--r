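make_object <- function(patch, anchor, pass = 1L) {
  list(patch = patch, anchor = anchor, source_pass = pass)
}

test_that("binarization thresholds at the stated fraction of the image mean", {
  img <- matrix(0.2, 64, 64)  # mean 0.2 -> t = 0.02
  half <- 16L
  patch <- matrix(0.01, 32, 32)
  patch[10, 10] <- 0.03
  ob <- make_object(patch, c(40L, 40L))
  masks <- binarize_objects(list(ob), img, threshold_frac = 0.1)
  expect_identical(length(masks$objects), 1L)
  expect_identical(masks$objects[[1]]$count, 1L)
  expect_true(masks$objects[[1]]$mask[10, 10])

  # all below threshold -> no mask at all
  m0 <- binarize_objects(list(make_object(matrix(0.001, 32, 32), c(40L, 40L))),
                         img)
  expect_identical(length(m0$objects), 0L)

  # constant 2t patch -> full footprint
  m2 <- binarize_objects(list(make_object(matrix(0.04, 32, 32), c(40L, 40L))),
                         img)
  expect_identical(m2$objects[[1]]$count, 32L * 32L)
})

test_that("binarized masks land on the correct unpadded pixels", {
  s <- tiny_scene(seed = 81, n_cells = 3, noise = 0)
  cfg <- toy_engine_config()
  st <- decompose_image(s$image, oracle_predictor(s, 32L), cfg)
  masks <- binarize_objects(st$objects, s$image, threshold_frac = 0.1)
  lab <- assign_instances(filter_masks(masks, 20L))
  # noiseless oracle masks must reproduce the ground-truth footprints
  expect_identical(lab > 0L, s$labels > 0L)
})

test_that("masks near the border are clipped to the image", {
  img <- matrix(0.2, 64, 64)
  patch <- matrix(0.5, 32, 32)
  ob <- make_object(patch, c(17L, 17L))  # top-left corner of padded domain
  masks <- binarize_objects(list(ob), img)
  expect_lt(masks$objects[[1]]$count, 32L * 32L)
  expect_gte(min(masks$objects[[1]]$rows), 1L)
})

test_that("the size filter removes strictly-smaller masks only", {
  img <- matrix(0.2, 64, 64)
  mk <- function(n) {
    patch <- matrix(0, 32, 32)
    patch[seq_len(n)] <- 0.5
    make_object(patch, c(40L, 40L))
  }
  masks <- binarize_objects(list(mk(19L), mk(20L), mk(21L)), img)
  kept <- filter_masks(masks, min_pixels = 20L)
  expect_identical(vapply(kept$objects, `[[`, integer(1), "count"),
                   c(20L, 21L))
})

test_that("the two-channel rule needs 20 nucleus and 1 cytoplasm pixels", {
  img <- array(0.2, dim = c(64, 64, 2))
  mk2 <- function(n_cyto, n_nuc) {
    patch <- array(0, dim = c(32, 32, 2))
    if (n_cyto > 0) patch[1:n_cyto, 1, 1] <- 0.5
    if (n_nuc > 0) patch[1:n_nuc, 2, 2] <- 0.5
    make_object(patch, c(40L, 40L))
  }
  masks <- binarize_objects(list(mk2(25L, 0L),   # no nucleus -> dropped
                                 mk2(0L, 25L),   # no cytoplasm -> dropped
                                 mk2(1L, 20L),   # boundary: kept
                                 mk2(5L, 19L)),  # nucleus too small -> dropped
                            img)
  rules <- list(nucleus = 20L, cyto = 1L)
  kept <- filter_masks(masks, channel_rules = rules)
  expect_identical(length(kept$objects), 1L)
  expect_identical(kept$objects[[1]]$channel_counts,
                   c(cyto = 1L, nucleus = 20L))
})

test_that("overlaps resolve to the brightest prediction, ties to first", {
  img <- matrix(0.2, 64, 64)
  p1 <- matrix(0, 32, 32); p1[10:15, 10:15] <- 0.5
  p2 <- matrix(0, 32, 32); p2[10:15, 10:15] <- 0.9
  # same anchor: both masks claim the same pixels; 0.9 wins
  masks <- binarize_objects(list(make_object(p1, c(40L, 40L)),
                                 make_object(p2, c(40L, 40L))), img)
  expect_warning(assign_instances(masks), "dropped")
  lab <- suppressWarnings(assign_instances(masks))
  expect_identical(sort(unique(lab[lab > 0L])), 1L)

  # disjoint masks keep distinct labels
  p3 <- matrix(0, 32, 32); p3[1:4, 1:4] <- 0.5
  masks2 <- binarize_objects(list(make_object(p1, c(40L, 40L)),
                                  make_object(p3, c(40L, 40L))), img)
  lab2 <- assign_instances(masks2)
  expect_identical(sort(unique(lab2[lab2 > 0L])), c(1L, 2L))

  # identical intensities: the earlier mask wins the tie
  masks3 <- binarize_objects(list(make_object(p1, c(40L, 40L)),
                                  make_object(p1, c(40L, 40L))), img)
  lab3 <- suppressWarnings(assign_instances(masks3))
  expect_identical(sort(unique(lab3[lab3 > 0L])), 1L)
})

test_that("raising the threshold never grows a mask", {
  s <- tiny_scene(seed = 91, n_cells = 5, noise = 0.05)
  img <- normalize_image(s$image)
  st <- decompose_image(img, oracle_predictor(s, 32L), toy_engine_config())
  counts <- sapply(c(0.05, 0.1, 0.2, 0.4), function(f) {
    m <- binarize_objects(st$objects, img, threshold_frac = f)
    sum(vapply(m$objects, `[[`, integer(1), "count"))
  })
  expect_true(all(diff(counts) <= 0))
})
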