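test_that("proposal selection matches the brute-force oracle", {
  set.seed(17)
  for (trial in 1:12) {
    err <- matrix(stats::rnorm(64 * 64), 64, 64)
    for (n in c(1L, 3L, 8L)) {
      expect_identical(propose_points(err, n),
                       brute_propose(err, n))
    }
  }
})

test_that("proposals handle degenerate error images per contract", {
  expect_identical(nrow(propose_points(matrix(0, 50, 50), 5L)), 0L)
  expect_identical(nrow(propose_points(matrix(-1, 50, 50), 5L)), 0L)

  # single positive pixel: exactly one point whose 7x7 window covers it
  err <- matrix(0, 50, 50)
  err[20, 33] <- 1
  pts <- propose_points(err, 5L)
  expect_identical(nrow(pts), 1L)
  expect_lte(max(abs(pts[1, ] - c(20L, 33L))), 3L)

  # two equal isolated blobs far apart: both found, near their blobs
  err2 <- matrix(0, 120, 120)
  err2[10, 10] <- 1; err2[110, 110] <- 1
  pts2 <- propose_points(err2, 2L)
  expect_identical(nrow(pts2), 2L)
  d1 <- abs(sweep(pts2, 2, c(10L, 10L)))
  d2 <- abs(sweep(pts2, 2, c(110L, 110L)))
  expect_true(any(rowSums(d1 <= 3L) == 2L))
  expect_true(any(rowSums(d2 <= 3L) == 2L))

  # equal-maximum ties break to the smallest row-major index
  err3 <- matrix(0, 60, 60)
  err3[30, 40] <- 1; err3[30, 20] <- 1; err3[45, 20] <- 1
  pts3 <- propose_points(err3, 1L, suppression = 60L)
  expect_identical(pts3[1, ], brute_propose(err3, 1L, suppression = 60L)[1, ])
})

test_that("merge follows the max rule on overlaps and is idempotent", {
  P <- matrix(0, 20, 20)
  pred1 <- list(patch = matrix(stats::runif(16), 4, 4), anchor = c(8L, 8L))
  P1 <- merge_prediction(P, pred1)
  expect_equal(P1[6:9, 6:9], pred1$patch)
  expect_equal(merge_prediction(P1, pred1), P1)  # idempotent
  pred2 <- list(patch = matrix(stats::runif(16), 4, 4), anchor = c(9L, 9L))
  P2 <- merge_prediction(P1, pred2)
  expect_equal(P2[7:10, 7:10], pmax(P1[7:10, 7:10], pred2$patch))
  # additive rule
  P3 <- merge_prediction(P1, pred1, rule = "add")
  expect_equal(P3[6:9, 6:9], 2 * pred1$patch)
})

test_that("acceptance requires a strict loss decrease", {
  cfg <- engine_config(patch_size = 4L, n_points = 1L, mirror_px = 2L)
  input <- matrix(0, 12, 12)
  input[5:7, 5:7] <- 0.8
  state <- init_state(input, 4L)

  # a prediction equal to the residual is accepted and zeroes its footprint
  good <- list(patch = input[4:7, 4:7], anchor = c(6L, 6L))
  res <- try_accept(state, good, cfg)
  expect_true(res$accepted)
  expect_equal(res$state$error[4:7, 4:7], matrix(0, 4, 4))
  expect_lt(res$state$loss, state$loss)

  # the all-zero prediction is exactly neutral -> rejected
  res0 <- try_accept(state, list(patch = matrix(0, 4, 4), anchor = c(6L, 6L)),
                     cfg)
  expect_false(res0$accepted)
  expect_equal(res0$delta_loss, 0)
  expect_identical(res0$state$internal, state$internal)

  # over-predicting an already-explained region increases the loss
  st2 <- res$state
  too_bright <- list(patch = matrix(1, 4, 4), anchor = c(6L, 6L))
  res2 <- try_accept(st2, too_bright, cfg)
  expect_false(res2$accepted)
  expect_gt(res2$delta_loss, 0)
})

test_that("footprint-local delta loss equals full recomputation", {
  set.seed(23)
  s <- tiny_scene(seed = 23, n_cells = 8, noise = 0.05)
  img <- normalize_image(s$image)
  cfg <- toy_engine_config()
  st <- decompose_image(img, oracle_predictor(s, 32L), cfg)
  full <- mean(abs((st$input - st$internal)[st$content_rows, st$content_cols]))
  expect_equal(st$loss, full, tolerance = 1e-6)
  # recomputed error field agrees everywhere
  expect_equal(st$error, st$input - st$internal, tolerance = 1e-12)
  # every recorded acceptance strictly decreased the loss
  deltas <- vapply(st$objects, `[[`, numeric(1), "delta_loss")
  expect_true(all(deltas < 0))
})

test_that("a blank image terminates immediately with no objects", {
  cfg <- toy_engine_config()
  st <- decompose_image(matrix(0, 96, 96), oracle_predictor(
    generate_scene(scene_params(n_cells = 0, height = 96, width = 96,
                                background_noise_sd = 0, seed = 1)), 32L), cfg)
  expect_identical(length(st$objects), 0L)
  expect_equal(st$loss, 0)
})

test_that("iteration caps bound the number of accepted objects", {
  s <- tiny_scene(seed = 31, n_cells = 10, noise = 0)
  cfg <- engine_config(patch_size = 32L, n_points = 1L, max_iter = 1L,
                       max_passes = 1L)
  st <- decompose_image(s$image, oracle_predictor(s, 32L), cfg)
  expect_lte(length(st$objects), 1L)
})

test_that("oracle-driven decomposition recovers every cell exactly", {
  for (seed in c(41, 42, 43)) {
    n <- 5L + seed %% 9L
    s <- tiny_scene(seed = seed, n_cells = n, noise = 0)
    st <- decompose_image(s$image, oracle_predictor(s, 32L),
                          toy_engine_config())
    expect_identical(length(st$objects), as.integer(n))
    expect_lt(st$loss, 1e-6)
  }
})

test_that("a cell missed in pass 1 is recovered from the error image", {
  s <- tiny_scene(seed = 51, n_cells = 6, noise = 0)
  cfg <- toy_engine_config()
  padded <- pad_for_inference(s$image, 32L)

  # pass 1 uses an oracle blinded to cell 3 (its label erased, so the
  # blinded oracle treats its pixels as background and predicts nothing)
  blind <- s
  blind$labels[blind$labels == 3L] <- 0L
  state <- init_state(padded, 32L)
  state <- decompose_pass(state, oracle_predictor(blind, 32L), cfg,
                          source_pass = 1L)
  expect_identical(length(state$objects), 5L)
  expect_gt(state$loss, 0)

  # pass 2: full oracle on the clamped residual recovers the missing cell
  state2 <- decompose_pass(state, oracle_predictor(s, 32L), cfg,
                           predict_from = pmax(state$error, 0),
                           source_pass = 2L)
  expect_identical(length(state2$objects), 6L)
  expect_lt(state2$loss, 1e-6)
  expect_identical(state2$objects[[6]]$source_pass, 2L)
})

test_that("multipass stops after a pass that accepts nothing", {
  s <- tiny_scene(seed = 61, n_cells = 7, noise = 0)
  st <- decompose_image(s$image, oracle_predictor(s, 32L),
                        toy_engine_config())
  passes <- vapply(st$objects, `[[`, integer(1), "source_pass")
  expect_true(all(passes == 1L))  # fully explained in pass 1
})

test_that("global loss is non-increasing across acceptances and passes", {
  for (seed in 71:74) {
    s <- tiny_scene(seed = seed, n_cells = 9, noise = 0.05)
    img <- normalize_image(s$image)
    st <- decompose_image(img, oracle_predictor(s, 32L), toy_engine_config())
    deltas <- vapply(st$objects, `[[`, numeric(1), "delta_loss")
    expect_true(all(deltas < 0))
    init_loss <- mean(abs(pad_for_inference(img, 32L)[st$content_rows,
                                                      st$content_cols]))
    expect_equal(st$loss, init_loss + sum(deltas), tolerance = 1e-9)
  }
})
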