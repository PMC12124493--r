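# The conv framework and the VQ-VAE built on it.

nn <- function(f) utils::getFromNamespace(f, "celldecomp")

test_that("conv/tconv gradients agree with finite differences", {
  set.seed(1)
  net <- nn("nn_seq")(
    nn("nn_conv")(1L, 3L, 4L, 2L, c(1L, 1L), name = "c1"), nn("nn_relu")(),
    nn("nn_conv")(3L, 3L, 4L, 1L, c(1L, 2L), name = "c2"),
    nn("nn_res")(nn("nn_seq")(
      nn("nn_relu")(), nn("nn_conv")(3L, 3L, 3L, 1L, c(1L, 1L), name = "r1"),
      nn("nn_relu")(), nn("nn_conv")(3L, 3L, 1L, 1L, c(0L, 0L), name = "r2"))),
    nn("nn_tconv")(3L, 2L, 4L, 2L, 1L, name = "t1"), nn("nn_relu")(),
    nn("nn_tconv")(2L, 1L, 3L, 1L, 1L, name = "t2"))
  net <- nn("nn_init")(net)
  x <- array(stats::rnorm(8 * 8 * 2), dim = c(1, 8, 8, 2))
  tgt <- array(stats::rnorm(8 * 8 * 2), dim = c(1, 8, 8, 2))
  lossfn <- function(n, xx) sum((nn("nn_forward")(n, xx)$out - tgt)^2) / 2
  fw <- nn("nn_forward")(net, x)
  bw <- nn("nn_backward")(net, fw$cache, fw$out - tgt)
  pars <- nn("nn_params")(net)
  eps <- 1e-5
  for (nm in names(pars)) {
    for (trial in 1:3) {
      i <- sample(length(pars[[nm]]), 1)
      pp <- pars
      pp[[nm]][i] <- pars[[nm]][i] + eps
      lp <- lossfn(nn("nn_set_params")(net, pp), x)
      pp[[nm]][i] <- pars[[nm]][i] - eps
      lm <- lossfn(nn("nn_set_params")(net, pp), x)
      num <- (lp - lm) / (2 * eps)
      expect_equal(bw$grads[[nm]][i], num, tolerance = 1e-4)
    }
  }
  i <- sample(length(x), 1)
  x2 <- x; x2[i] <- x[i] + eps
  x3 <- x; x3[i] <- x[i] - eps
  expect_equal(bw$dx[i], (lossfn(net, x2) - lossfn(net, x3)) / (2 * eps),
               tolerance = 1e-4)
})

test_that("encode/decode preserve spatial shape across patch sizes", {
  for (ps in c(32L, 40L, 120L)) {
    cfg <- vqvae_config("toy", patch_size = ps,
                        enc_units = c(4L, 4L, 8L, 8L, 8L),
                        dec_units = c(4L, 4L, 4L), seed = 2)
    m <- vqvae_init(cfg)
    x <- matrix(stats::runif(ps * ps), ps, ps)
    z <- vqvae_encode(m, x)
    expect_identical(dim(z)[2:3], rep(ps %/% 8L, 2L))  # three stride-2 halvings
    r <- vqvae_decode(m, z)
    expect_identical(dim(r)[1:2], c(ps, ps))
  }
})

test_that("encoder is deterministic and zero weights give zero latents", {
  cfg <- vqvae_config("toy", seed = 4)
  m <- vqvae_init(cfg)
  x <- matrix(stats::runif(32 * 32), 32, 32)
  expect_identical(vqvae_encode(m, x), vqvae_encode(m, x))
  zero <- lapply(nn("nn_params")(m$encoder), function(p) p * 0)
  m$encoder <- nn("nn_set_params")(m$encoder, zero)
  expect_true(all(vqvae_encode(m, x) == 0))
})

test_that("quantization matches the exhaustive nearest-neighbour oracle", {
  set.seed(10)
  for (K in c(1L, 8L, 64L)) {
    emb <- matrix(stats::rnorm(2 * K), 2, K)
    z <- matrix(stats::rnorm(2 * 200), 2, 200)
    q <- vq_quantize(z, emb)
    expect_identical(q$indices, as.integer(brute_quantize(z, emb)))
    expect_equal(q$quantized, emb[, q$indices, drop = FALSE])
    # exact hit maps to its own index
    q2 <- vq_quantize(emb[, K, drop = FALSE], emb)
    expect_identical(q2$indices, K)
  }
})

test_that("EMA update moves the assigned code toward the batch mean", {
  set.seed(3)
  emb <- matrix(c(-5, -5, 0, 0, 5, 5), 2, 3)  # three well-separated codes
  cb <- list(embeddings = emb, ema_cluster_size = rep(1, 3),
             ema_embed_sum = emb, initialized = TRUE)
  z <- matrix(stats::rnorm(2 * 50, mean = 5.5, sd = 0.05), 2, 50)  # all near code 3
  idx <- vq_quantize(z, emb)$indices
  expect_true(all(idx == 3L))
  cb2 <- nn("ema_update")(cb, z, idx, decay = 0.9)
  d_before <- sum((emb[, 3] - rowMeans(z))^2)
  d_after <- sum((cb2$embeddings[, 3] - rowMeans(z))^2)
  expect_lt(d_after, d_before)
  # unassigned codes: EMA sums only decay, embeddings essentially unchanged
  expect_equal(cb2$ema_embed_sum[, 1:2], 0.9 * cb$ema_embed_sum[, 1:2])
  expect_equal(cb2$embeddings[, 1:2], emb[, 1:2], tolerance = 1e-3)
})

test_that("dead codes are reseeded from batch vectors", {
  set.seed(5)
  emb <- matrix(c(0, 0, 100, 100), 2, 2)
  cb <- list(embeddings = emb, ema_cluster_size = c(1, 1e-4),
             ema_embed_sum = emb, initialized = TRUE)
  z <- matrix(stats::rnorm(2 * 20), 2, 20)
  idx <- vq_quantize(z, emb)$indices
  cb2 <- nn("ema_update")(cb, z, idx, decay = 0.99)
  # the dead code was replaced by one of the batch vectors
  expect_true(any(apply(z, 2, function(v) all(abs(v - cb2$embeddings[, 2]) < 1e-12))))
  expect_equal(cb2$ema_cluster_size[2], 1)
})

test_that("short training runs are seed-deterministic and learn empty targets", {
  scenes <- list(tiny_scene(seed = 31, n_cells = 6))
  cfg <- vqvae_config("toy", enc_units = c(4L, 4L, 8L, 8L, 8L),
                      dec_units = c(4L, 4L, 4L), train_steps = 25L,
                      batch_size = 8L, seed = 7)
  stream <- make_pair_stream(scenes, cfg)
  m1 <- vqvae_train(cfg, stream, log_every = 5L)
  m2 <- vqvae_train(cfg, stream, log_every = 5L)
  expect_identical(m1$loss_history, m2$loss_history)

  # training on empty-center pairs drives predictions toward empty images
  cfg0 <- vqvae_config("toy", enc_units = c(4L, 4L, 8L, 8L, 8L),
                       dec_units = c(4L, 4L, 4L), train_steps = 120L,
                       batch_size = 8L, p_center = 0, seed = 8)
  stream0 <- make_pair_stream(scenes, cfg0)
  m0 <- vqvae_train(cfg0, stream0, log_every = 40L)
  expect_lt(m0$loss_history[3], m0$loss_history[1])
})

test_that("predictions are anchored, clamped, and reproducible", {
  cfg <- vqvae_config("toy", seed = 9)
  m <- vqvae_init(cfg)
  img <- pad_for_inference(matrix(stats::runif(64 * 64), 64, 64), 32L)
  point <- c(40L, 45L)
  p1 <- predict_object(m, point, img)
  p2 <- predict_object(m, point, img)
  expect_identical(p1, p2)
  expect_identical(p1$anchor, point)
  expect_true(all(p1$patch >= 0))
  expect_identical(dim(p1$patch), c(32L, 32L))
  expect_error(predict_object(m, c(5L, 5L), img), "outside")
})

test_that("checkpoints round-trip through disk", {
  cfg <- vqvae_config("toy", enc_units = c(4L, 4L, 8L, 8L, 8L),
                      dec_units = c(4L, 4L, 4L), seed = 12)
  m <- vqvae_init(cfg)
  path <- tempfile(fileext = ".rds")
  save_checkpoint(m, path)
  m2 <- load_checkpoint(path)
  expect_identical(m2$config, m$config)
  x <- matrix(stats::runif(32 * 32), 32, 32)
  expect_identical(vqvae_encode(m, x), vqvae_encode(m2, x))
  saveRDS(list(a = 1), path)
  expect_error(load_checkpoint(path), "checkpoint")
})
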