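#' VQ-VAE configuration
#'
#' Hyperparameters of the single-central-cell VQ-VAE. The `"full"` profile
#' is the published configuration (40 px patches, 128 embeddings of
#' dimension 2, Adam at 1e-4, batch 32, 500,000 steps); the `"toy"` profile
#' is a scaled-down configuration (32 px patches, 32 embeddings, narrower
#' layers, 3,000 steps at 1e-3) sized so that training on synthetic scenes
#' completes in minutes on one CPU while exercising the identical code path.
#'
#' @param profile `"toy"` or `"full"`; sets defaults, each overridable.
#' @param patch_size Even input/output side in pixels.
#' @param codebook_size Number of codebook embeddings K.
#' @param embedding_dim Dimension D of each embedding.
#' @param commitment_cost Weight of the commitment term pulling encoder
#'   outputs toward their assigned codebook vector.
#' @param ema_decay Decay of the exponential-moving-average codebook update.
#' @param charbonnier_eps Smoothing width of the reconstruction loss: the
#'   optimized objective is the Charbonnier (smoothed-L1) penalty
#'   `sqrt(err^2 + eps^2) - eps`, whose gradient equals the L1 sign
#'   gradient for errors well above `eps` and decays linearly to zero
#'   below it. The smoothing removes the sign-gradient chatter of the 95%
#'   exactly-zero background pixels, which otherwise buries the learning
#'   signal and can drive ReLU layers dead. 0.01 is 1% of the intensity
#'   range, far below any structure the model must reproduce.
#' @param enc_units Output channels of the five encoder conv layers.
#' @param dec_units Output channels of the three stride-2 transposed convs.
#' @param learning_rate,batch_size,train_steps Adam optimisation settings.
#' @param warmup_steps Steps trained with the quantization bottleneck
#'   bypassed before the codebook is initialized by k-means on encoder
#'   latents and quantization switched on. Bootstrapping the codebook from
#'   a warmed-up encoder prevents the joint encoder/codebook collapse that
#'   otherwise dominates short runs; 0 disables the warm-up (the codebook
#'   is then seeded from the first batch).
#' @param p_center Probability a training patch has a cell at its center
#'   (the remaining patches train the model to emit an empty image).
#' @param mirror_px Mirror band used when padding scenes.
#' @param seed Integer seed controlling initialization and the data stream.
#' @return An object of class `cd_vqvae_config`.
#' @export
vqvae_config <- function(profile = c("toy", "full"),
                         patch_size = NULL, codebook_size = NULL,
                         embedding_dim = 2L, commitment_cost = 0.25,
                         ema_decay = 0.99, charbonnier_eps = 0.01,
                         enc_units = NULL, dec_units = NULL,
                         learning_rate = NULL, batch_size = 32L,
                         train_steps = NULL, warmup_steps = 500L,
                         p_center = 0.8, mirror_px = 8L,
                         seed = 1L) {
  profile <- match.arg(profile)
  def <- if (profile == "full") {
    list(patch_size = 40L, codebook_size = 128L,
         enc_units = c(64L, 64L, 128L, 128L, 128L),
         dec_units = c(64L, 64L, 64L),
         learning_rate = 1e-4, train_steps = 500000L)
  } else {
    list(patch_size = 32L, codebook_size = 32L,
         enc_units = c(16L, 16L, 32L, 32L, 32L),
         dec_units = c(16L, 16L, 16L),
         learning_rate = 1e-3, train_steps = 3000L)
  }
  cfg <- list(profile = profile,
              patch_size = as.integer(patch_size %||% def$patch_size),
              codebook_size = as.integer(codebook_size %||% def$codebook_size),
              embedding_dim = as.integer(embedding_dim),
              commitment_cost = commitment_cost, ema_decay = ema_decay,
              charbonnier_eps = charbonnier_eps,
              enc_units = as.integer(enc_units %||% def$enc_units),
              dec_units = as.integer(dec_units %||% def$dec_units),
              learning_rate = learning_rate %||% def$learning_rate,
              batch_size = as.integer(batch_size),
              train_steps = as.integer(train_steps %||% def$train_steps),
              warmup_steps = as.integer(warmup_steps),
              p_center = p_center, mirror_px = as.integer(mirror_px),
              seed = as.integer(seed))
  stopifnot(cfg$codebook_size >= 1L, cfg$embedding_dim >= 1L,
            cfg$warmup_steps >= 0L, cfg$charbonnier_eps >= 0,
            cfg$ema_decay > 0, cfg$ema_decay < 1, cfg$commitment_cost >= 0,
            cfg$patch_size %% 8L == 0L, length(cfg$enc_units) == 5L,
            length(cfg$dec_units) == 3L)
  structure(cfg, class = "cd_vqvae_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Encoder: 3 stride-2 4x4 convs, a stride-1 4x4 conv, a stride-1 3x3 conv,
# two residual blocks, then a 1x1 projection to the embedding dimension.
# The stride-1 4x4 layer uses asymmetric padding (1, 2) so it preserves the
# spatial size; the stride-2 layers halve it exactly for even inputs.
build_encoder <- function(cfg) {
  u <- cfg$enc_units
  nn_seq(
    nn_conv(1L, u[1], 4L, 2L, c(1L, 1L), name = "enc1"), nn_relu(),
    nn_conv(u[1], u[2], 4L, 2L, c(1L, 1L), name = "enc2"), nn_relu(),
    nn_conv(u[2], u[3], 4L, 2L, c(1L, 1L), name = "enc3"), nn_relu(),
    nn_conv(u[3], u[4], 4L, 1L, c(1L, 2L), name = "enc4"), nn_relu(),
    nn_conv(u[4], u[5], 3L, 1L, c(1L, 1L), name = "enc5"),
    nn_res(nn_seq(nn_relu(), nn_conv(u[5], u[5], 3L, 1L, c(1L, 1L), name = "encres1a"),
                  nn_relu(), nn_conv(u[5], u[5], 1L, 1L, c(0L, 0L), name = "encres1b"))),
    nn_res(nn_seq(nn_relu(), nn_conv(u[5], u[5], 3L, 1L, c(1L, 1L), name = "encres2a"),
                  nn_relu(), nn_conv(u[5], u[5], 1L, 1L, c(0L, 0L), name = "encres2b"))),
    nn_relu(),
    nn_conv(u[5], cfg$embedding_dim, 1L, 1L, c(0L, 0L), name = "enc_proj"),
    name = "encoder")
}

# Decoder: 1x1 expansion from the embedding dimension, a stride-1 4x4 conv
# (asymmetric padding, shape preserving), two residual blocks, three
# stride-2 4x4 transposed convs (padding 1, each exactly doubling the side),
# and a final stride-1 3x3 transposed conv emitting one channel (linear
# output; negatives are clamped at predict time).
build_decoder <- function(cfg) {
  u5 <- cfg$enc_units[5]; d <- cfg$dec_units
  nn_seq(
    nn_conv(cfg$embedding_dim, u5, 1L, 1L, c(0L, 0L), name = "dec_proj"),
    nn_conv(u5, u5, 4L, 1L, c(1L, 2L), name = "dec1"),
    nn_res(nn_seq(nn_relu(), nn_conv(u5, u5, 3L, 1L, c(1L, 1L), name = "decres1a"),
                  nn_relu(), nn_conv(u5, u5, 1L, 1L, c(0L, 0L), name = "decres1b"))),
    nn_res(nn_seq(nn_relu(), nn_conv(u5, u5, 3L, 1L, c(1L, 1L), name = "decres2a"),
                  nn_relu(), nn_conv(u5, u5, 1L, 1L, c(0L, 0L), name = "decres2b"))),
    nn_relu(),
    nn_tconv(u5, d[1], 4L, 2L, 1L, name = "dec_up1"), nn_relu(),
    nn_tconv(d[1], d[2], 4L, 2L, 1L, name = "dec_up2"), nn_relu(),
    nn_tconv(d[2], d[3], 4L, 2L, 1L, name = "dec_up3"), nn_relu(),
    nn_tconv(d[3], 1L, 3L, 1L, 1L, name = "dec_out"),
    name = "decoder")
}

#' Initialize an untrained VQ-VAE
#'
#' @param cfg A [vqvae_config()].
#' @return A model object of class `cd_vqvae` (also a `cd_predictor`).
#' @export
vqvae_init <- function(cfg) {
  stopifnot(inherits(cfg, "cd_vqvae_config"))
  with_seed(cfg$seed, {
    enc <- nn_init(build_encoder(cfg))
    dec <- nn_init(build_decoder(cfg))
    codebook <- list(
      embeddings = matrix(stats::rnorm(cfg$embedding_dim * cfg$codebook_size,
                                       sd = 0.1), nrow = cfg$embedding_dim),
      ema_cluster_size = rep(1, cfg$codebook_size),
      ema_embed_sum = NULL, initialized = FALSE)
    codebook$ema_embed_sum <- codebook$embeddings
    structure(list(config = cfg, encoder = enc, decoder = dec,
                   codebook = codebook, step = 0L, loss_history = numeric(0)),
              class = c("cd_vqvae", "cd_predictor"))
  })
}

#' Nearest-neighbour vector quantization
#'
#' Snaps each latent vector to its nearest codebook embedding in Euclidean
#' distance (ties to the lowest index).
#'
#' @param latents `D x n` matrix of latent vectors (columns).
#' @param embeddings `D x K` matrix of codebook vectors.
#' @return List with `indices` (length n, in 1..K) and `quantized`
#'   (`D x n`).
#' @export
vq_quantize <- function(latents, embeddings) {
  stopifnot(nrow(latents) == nrow(embeddings), ncol(embeddings) >= 1L)
  # squared distance = |z|^2 - 2 z.e + |e|^2; |z|^2 is constant per column
  sc <- crossprod(embeddings, latents)            # K x n
  d2 <- -2 * sc + colSums(embeddings^2)           # recycles |e|^2 down columns
  idx <- max.col(-t(d2), ties.method = "first")
  list(indices = idx, quantized = embeddings[, idx, drop = FALSE])
}

#' Run the encoder on a batch of patches
#'
#' @param model A `cd_vqvae`.
#' @param patches `patch_size x patch_size x B` array (or a single matrix).
#' @return Latent array `D x h x w x B` of pre-quantization vectors.
#' @export
vqvae_encode <- function(model, patches) {
  x <- as_batch(patches, model$config$patch_size)
  nn_forward(model$encoder, x)$out
}

#' Run the decoder on a (quantized) latent grid
#'
#' @param model A `cd_vqvae`.
#' @param latents `D x h x w x B` array.
#' @return `patch_size x patch_size x B` array of reconstructions (linear
#'   output, not clamped).
#' @export
vqvae_decode <- function(model, latents) {
  out <- nn_forward(model$decoder, latents)$out
  d <- dim(out)
  stopifnot(d[1] == 1L)
  array(out, dim = c(d[2], d[3], d[4]))
}

as_batch <- function(patches, patch_size) {
  if (is.matrix(patches)) patches <- array(patches, dim = c(dim(patches), 1L))
  d <- dim(patches)
  stopifnot(d[1] == patch_size, d[2] == patch_size)
  array(patches, dim = c(1L, d[1], d[2], d[3]))
}

# EMA codebook update on one batch of latent vectors (D x n) and their
# assignments. Cluster sizes and embedding sums are exponential moving
# averages; Laplace smoothing keeps the division stable and codes whose EMA
# cluster size collapses below `dead_threshold` are reseeded from random
# batch vectors so the codebook cannot die at toy scale.
ema_update <- function(codebook, z, idx, decay, eps = 1e-5,
                       dead_threshold = 1e-3) {
  K <- ncol(codebook$embeddings)
  n_k <- tabulate(idx, nbins = K)
  sums <- matrix(0, nrow(z), K)
  agg <- rowsum(t(z), group = idx)          # one row per occupied code
  sums[, as.integer(rownames(agg))] <- t(agg)
  codebook$ema_cluster_size <- decay * codebook$ema_cluster_size +
    (1 - decay) * n_k
  codebook$ema_embed_sum <- decay * codebook$ema_embed_sum + (1 - decay) * sums
  total <- sum(codebook$ema_cluster_size)
  smoothed <- (codebook$ema_cluster_size + eps) / (total + K * eps) * total
  codebook$embeddings <- sweep(codebook$ema_embed_sum, 2, smoothed, "/")
  dead <- which(codebook$ema_cluster_size < dead_threshold)
  if (length(dead) > 0 && ncol(z) > 0) {
    take <- sample.int(ncol(z), length(dead), replace = ncol(z) < length(dead))
    codebook$embeddings[, dead] <- z[, take, drop = FALSE]
    codebook$ema_embed_sum[, dead] <- z[, take, drop = FALSE]
    codebook$ema_cluster_size[dead] <- 1
  }
  codebook
}

# Initialize the codebook by k-means over a set of latent vectors (D x n),
# falling back to sampled vectors with jitter when k-means cannot find K
# distinct centers. EMA accumulators start at the cluster occupancies.
codebook_from_latents <- function(codebook, zmat) {
  K <- ncol(codebook$embeddings)
  n <- ncol(zmat)
  centers <- tryCatch({
    km <- suppressWarnings(stats::kmeans(t(zmat), centers = K, nstart = 3L,
                                         iter.max = 50L))
    list(emb = t(km$centers), size = pmax(km$size, 1))
  }, error = function(e) {
    take <- sample.int(n, K, replace = n < K)
    emb <- zmat[, take, drop = FALSE] +
      matrix(stats::rnorm(length(codebook$embeddings), sd = 1e-3), nrow(zmat))
    list(emb = emb, size = rep(n / K, K))
  })
  codebook$embeddings <- centers$emb
  codebook$ema_cluster_size <- centers$size
  codebook$ema_embed_sum <- sweep(centers$emb, 2, centers$size, "*")
  codebook$initialized <- TRUE
  codebook
}

# One optimisation step on a batch. inputs/targets: (p, p, B) arrays.
# During warm-up (use_vq = FALSE) the latents feed the decoder directly and
# the codebook is untouched; afterwards the quantized latents are decoded,
# gradients pass straight through the quantization, and the codebook is
# updated by EMA.
vqvae_train_step <- function(model, params, opt, inputs, targets,
                             use_vq = TRUE) {
  cfg <- model$config
  x <- array(inputs, dim = c(1L, dim(inputs)))
  fw_e <- nn_forward(model$encoder, x)
  ze <- fw_e$out
  dz <- dim(ze)
  n_lat <- prod(dz[2:4])
  zmat <- ze; dim(zmat) <- c(dz[1], n_lat)
  if (use_vq && !model$codebook$initialized)
    model$codebook <- codebook_from_latents(model$codebook, zmat)
  if (use_vq) {
    vq <- vq_quantize(zmat, model$codebook$embeddings)
    zq <- vq$quantized
    dim(zq) <- dz
    commit <- mean((zmat - vq$quantized)^2)
  } else {
    zq <- ze
    commit <- 0
  }
  fw_d <- nn_forward(model$decoder, zq)
  recon <- fw_d$out
  diff <- recon - array(targets, dim = dim(recon))
  recon_loss <- mean(abs(diff))
  # Charbonnier-smoothed L1 gradient; straight-through estimator through
  # the quantization (recorded loss stays plain L1 for interpretability)
  drecon <- array(diff / sqrt(diff^2 + cfg$charbonnier_eps^2) / length(diff),
                  dim = dim(diff))
  bw_d <- nn_backward(model$decoder, fw_d$cache, drecon)
  dze <- bw_d$dx
  if (use_vq) {
    dim(dze) <- c(dz[1], n_lat)
    dze <- dze + cfg$commitment_cost * 2 * (zmat - vq$quantized) /
      length(zmat)
    dim(dze) <- dz
  }
  bw_e <- nn_backward(model$encoder, fw_e$cache, dze)
  grads <- c(bw_d$grads, bw_e$grads)
  st <- adam_step(params, grads, opt, cfg$learning_rate)
  if (use_vq)
    model$codebook <- ema_update(model$codebook, zmat, vq$indices,
                                 cfg$ema_decay)
  list(model = model, params = st$params, opt = st$state,
       loss = recon_loss + cfg$commitment_cost * commit,
       recon_loss = recon_loss, commit = commit)
}

#' Train the VQ-VAE on single-central-cell pairs
#'
#' Minimizes the mean absolute error between the reconstruction and the
#' single-central-cell target plus the commitment term
#' `commitment_cost * |z_e - sg(z_q)|^2`; the codebook is updated by
#' exponential moving averages (never by gradient) and gradients pass
#' straight through the quantization. Training aborts with a diagnostic if
#' the loss becomes non-finite.
#'
#' @param cfg A [vqvae_config()].
#' @param pair_fn Function of a batch size `b` returning
#'   `list(inputs, targets)`, two `patch_size x patch_size x b` arrays; see
#'   [make_pair_stream()]. Called under the seeded training RNG.
#' @param steps Number of optimisation steps (default `cfg$train_steps`).
#' @param log_every Record/report the running loss every this many steps;
#'   0 silences reporting.
#' @param model Optionally, a model to continue training.
#' @return A trained `cd_vqvae` with `loss_history` (one entry per
#'   `log_every` steps, mean batch loss over the window).
#' @export
vqvae_train <- function(cfg, pair_fn, steps = NULL, log_every = 100L,
                        model = NULL) {
  stopifnot(inherits(cfg, "cd_vqvae_config"))
  if (is.null(model)) model <- vqvae_init(cfg)
  steps <- steps %||% cfg$train_steps
  params <- c(nn_params(model$encoder), nn_params(model$decoder))
  opt <- adam_init(params)
  window <- numeric(0)
  with_seed(cfg$seed + 1L, {
    for (s in seq_len(steps)) {
      batch <- pair_fn(cfg$batch_size)
      model$encoder <- nn_set_params(model$encoder, params)
      model$decoder <- nn_set_params(model$decoder, params)
      use_vq <- model$codebook$initialized ||
        (model$step + s) > cfg$warmup_steps
      st <- vqvae_train_step(model, params, opt, batch$inputs, batch$targets,
                             use_vq = use_vq)
      model <- st$model
      params <- st$params
      opt <- st$opt
      if (!is.finite(st$loss))
        stop("non-finite loss at step ", s,
             " (recon = ", st$recon_loss, ", commit = ", st$commit, ")")
      window <- c(window, st$loss)
      if (log_every > 0 && s %% log_every == 0L) {
        model$loss_history <- c(model$loss_history, mean(window))
        window <- numeric(0)
      }
    }
    if (!model$codebook$initialized) {
      # run ended inside the warm-up; bootstrap the codebook so the model
      # quantizes from here on
      model$encoder <- nn_set_params(model$encoder, params)
      batch <- pair_fn(cfg$batch_size)
      ze <- nn_forward(model$encoder,
                       array(batch$inputs, dim = c(1L, dim(batch$inputs))))$out
      dz <- dim(ze)
      dim(ze) <- c(dz[1], prod(dz[2:4]))
      model$codebook <- codebook_from_latents(model$codebook, ze)
    }
  })
  model$encoder <- nn_set_params(model$encoder, params)
  model$decoder <- nn_set_params(model$decoder, params)
  model$step <- model$step + steps
  model
}

#' Build a training-pair stream from synthetic scenes
#'
#' Returns a function of a batch size that samples patches across `scenes`,
#' centering them on foreground with probability `cfg$p_center`, exactly as
#' [sample_training_pair()] does per draw.
#'
#' @param scenes List of `cd_scene` objects.
#' @param cfg A [vqvae_config()].
#' @param normalize Percentile-normalize each scene image first (default
#'   `TRUE`), matching what [run_pipeline()] feeds the model at inference.
#' @return Function `f(b)` giving `list(inputs, targets)` arrays.
#' @export
make_pair_stream <- function(scenes, cfg, normalize = TRUE) {
  if (normalize)
    scenes <- lapply(scenes, function(s) {
      s$image <- normalize_image(s$image)
      s
    })
  samplers <- lapply(scenes, scene_sampler, patch_size = cfg$patch_size,
                     mirror_px = cfg$mirror_px)
  p <- cfg$patch_size
  function(b) {
    inputs <- array(0, dim = c(p, p, b))
    targets <- array(0, dim = c(p, p, b))
    for (i in seq_len(b)) {
      s <- samplers[[sample.int(length(samplers), 1L)]]
      pair <- s(cfg$p_center)
      inputs[, , i] <- pair$input
      targets[, , i] <- pair$target
    }
    list(inputs = inputs, targets = targets)
  }
}

#' Use a trained VQ-VAE as an object predictor
#'
#' Wraps the model for the [predict_object()] interface: at a query point
#' the patch-sized window is extracted from the padded image, run through
#' encode, quantize and decode, clamped to be non-negative, and returned
#' anchored at the point.
#'
#' @param model A trained `cd_vqvae`.
#' @return The model itself (it already implements the interface).
#' @export
vqvae_predictor <- function(model) {
  stopifnot(inherits(model, "cd_vqvae"))
  model
}

#' @export
predict_object.cd_vqvae <- function(predictor, point, image) {
  p <- predictor$config$patch_size
  idx <- patch_index(point, p, dim(image))
  patch <- image[idx$rows, idx$cols]
  ze <- vqvae_encode(predictor, patch)
  dz <- dim(ze)
  zmat <- ze; dim(zmat) <- c(dz[1], prod(dz[2:4]))
  vq <- vq_quantize(zmat, predictor$codebook$embeddings)
  zq <- vq$quantized; dim(zq) <- dz
  recon <- vqvae_decode(predictor, zq)
  list(patch = pmax(matrix(recon, p, p), 0), anchor = point)
}

#' Save / load a model checkpoint
#'
#' The checkpoint carries the full configuration (including the seed) so a
#' run can be reproduced from it.
#' @param model A `cd_vqvae`.
#' @param path File path (`.rds`).
#' @export
save_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "cd_vqvae"))
  saveRDS(list(format = "celldecomp_vqvae", version = 1L, model = model), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  if (!identical(ck$format, "celldecomp_vqvae"))
    stop("not a celldecomp VQ-VAE checkpoint: ", path)
  ck$model
}

#' Mean absolute error of the constant-zero predictor
#'
#' Baseline for training-signal checks: the L1 loss a predictor that always
#' outputs an empty image would incur, i.e. the mean absolute target value.
#' @param targets Array of target patches.
#' @export
zero_predictor_baseline <- function(targets) mean(abs(targets))
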