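# Minimal convolutional network layer framework backing the VQ-VAE.
# Activations are 4-D arrays dim (C, H, W, B), column-major.  Each layer is a
# plain list; forward passes return list(out, cache) and backward passes
# return list(dx, grads) with grads named like the layer's parameters.

nn_conv <- function(in_ch, out_ch, k, stride = 1L, pad = c(0L, 0L),
                    name = "conv") {
  # pad = c(top/left, bottom/right); asymmetric padding lets even kernels
  # preserve spatial size at stride 1 (e.g. k = 4, pad = c(1, 2)).
  list(type = "conv", in_ch = in_ch, out_ch = out_ch, k = as.integer(k),
       stride = as.integer(stride), pad = as.integer(pad), name = name,
       W = NULL, b = NULL)
}

nn_tconv <- function(in_ch, out_ch, k, stride = 1L, pad = 0L, name = "tconv") {
  # Transposed convolution, the adjoint of nn_conv with symmetric padding.
  # Output side = (in - 1) * stride - 2 * pad + k.
  list(type = "tconv", in_ch = in_ch, out_ch = out_ch, k = as.integer(k),
       stride = as.integer(stride), pad = as.integer(pad), name = name,
       W = NULL, b = NULL)
}

nn_relu <- function(name = "relu") list(type = "relu", name = name)

nn_seq <- function(..., name = "seq") {
  list(type = "seq", layers = list(...), name = name)
}

# Residual block: x + inner(x).  Inner shape must match x.
nn_res <- function(inner, name = "res") {
  list(type = "res", inner = inner, name = name)
}

conv_out_side <- function(n, k, stride, pad_lo, pad_hi) {
  (n + pad_lo + pad_hi - k) %/% stride + 1L
}

# Weights ~ U(-1/sqrt(fan), 1/sqrt(fan)) with small uniform biases. The
# conservative scale matters: larger (He-style) initializations start the
# decoder with wild outputs whose correction under the L1 sign gradient
# drives whole ReLU layers dead before any structure is learned.
init_wb <- function(nrow_, ncol_) {
  bnd <- 1 / sqrt(ncol_)
  list(W = matrix(stats::runif(nrow_ * ncol_, -bnd, bnd), nrow_),
       b = stats::runif(nrow_, -0.01, 0.01))
}

nn_init <- function(layer) {
  switch(layer$type,
    conv = {
      wb <- init_wb(layer$out_ch, layer$in_ch * layer$k^2)
      layer$W <- wb$W
      layer$b <- wb$b
      layer
    },
    tconv = {
      # weight stored in conv geometry (in_ch, out_ch * k * k): the forward
      # pass is the adjoint of a conv mapping out-image -> in-image
      wb <- init_wb(layer$in_ch, layer$out_ch * layer$k^2)
      layer$W <- wb$W
      layer$b <- stats::runif(layer$out_ch, -0.01, 0.01)  # per output channel
      layer
    },
    relu = layer,
    seq = { layer$layers <- lapply(layer$layers, nn_init); layer },
    res = { layer$inner <- nn_init(layer$inner); layer },
    stop("unknown layer type: ", layer$type)
  )
}

nn_forward <- function(layer, x) {
  d <- dim(x)
  switch(layer$type,
    conv = {
      stopifnot(d[1] == layer$in_ch)
      OH <- conv_out_side(d[2], layer$k, layer$stride, layer$pad[1], layer$pad[2])
      OW <- conv_out_side(d[3], layer$k, layer$stride, layer$pad[1], layer$pad[2])
      col <- cd_im2col(x, d[1], d[2], d[3], d[4], layer$k, layer$k,
                       layer$stride, layer$pad[1], layer$pad[1], OH, OW)
      out <- layer$W %*% col + layer$b
      dim(out) <- c(layer$out_ch, OH, OW, d[4])
      list(out = out, cache = list(col = col, xdim = d, OH = OH, OW = OW))
    },
    tconv = {
      stopifnot(d[1] == layer$in_ch)
      OH <- (d[2] - 1L) * layer$stride - 2L * layer$pad + layer$k
      OW <- (d[3] - 1L) * layer$stride - 2L * layer$pad + layer$k
      xmat <- x; dim(xmat) <- c(d[1], prod(d[2:4]))
      tmp <- crossprod(layer$W, xmat)  # (out_ch*k*k, IH*IW*B)
      out <- cd_col2im(tmp, layer$out_ch, OH, OW, d[4], layer$k, layer$k,
                       layer$stride, layer$pad, layer$pad, d[2], d[3])
      dim(out) <- c(layer$out_ch, OH, OW, d[4])
      out <- out + layer$b  # recycles over channel (fastest) dimension
      list(out = out, cache = list(xmat = xmat, xdim = d, OH = OH, OW = OW))
    },
    relu = {
      mask <- x > 0
      list(out = x * mask, cache = list(mask = mask))
    },
    seq = {
      caches <- vector("list", length(layer$layers))
      for (i in seq_along(layer$layers)) {
        fw <- nn_forward(layer$layers[[i]], x)
        x <- fw$out
        caches[[i]] <- fw$cache
      }
      list(out = x, cache = caches)
    },
    res = {
      fw <- nn_forward(layer$inner, x)
      list(out = x + fw$out, cache = fw$cache)
    }
  )
}

nn_backward <- function(layer, cache, dout) {
  switch(layer$type,
    conv = {
      n <- prod(dim(dout)[2:4])
      dm <- dout; dim(dm) <- c(layer$out_ch, n)
      dW <- tcrossprod(dm, cache$col)
      db <- rowSums(dm)
      dcol <- crossprod(layer$W, dm)
      dx <- cd_col2im(dcol, cache$xdim[1], cache$xdim[2], cache$xdim[3],
                      cache$xdim[4], layer$k, layer$k, layer$stride,
                      layer$pad[1], layer$pad[1], cache$OH, cache$OW)
      dim(dx) <- cache$xdim
      list(dx = dx, grads = stats::setNames(list(dW, db),
                                            paste0(layer$name, c(".W", ".b"))))
    },
    tconv = {
      db <- rowSums(dout, dims = 1L)
      dcol <- cd_im2col(dout, layer$out_ch, cache$OH, cache$OW, cache$xdim[4],
                        layer$k, layer$k, layer$stride, layer$pad, layer$pad,
                        cache$xdim[2], cache$xdim[3])
      dx <- layer$W %*% dcol
      dim(dx) <- cache$xdim
      dW <- tcrossprod(cache$xmat, dcol)
      list(dx = dx, grads = stats::setNames(list(dW, db),
                                            paste0(layer$name, c(".W", ".b"))))
    },
    relu = list(dx = dout * cache$mask, grads = list()),
    seq = {
      grads <- list()
      for (i in rev(seq_along(layer$layers))) {
        bw <- nn_backward(layer$layers[[i]], cache[[i]], dout)
        dout <- bw$dx
        grads <- c(grads, bw$grads)
      }
      list(dx = dout, grads = grads)
    },
    res = {
      bw <- nn_backward(layer$inner, cache, dout)
      list(dx = dout + bw$dx, grads = bw$grads)
    }
  )
}

nn_params <- function(layer) {
  switch(layer$type,
    conv = ,
    tconv = stats::setNames(list(layer$W, layer$b),
                            paste0(layer$name, c(".W", ".b"))),
    relu = list(),
    seq = do.call(c, c(lapply(layer$layers, nn_params), list(list()))),
    res = nn_params(layer$inner)
  )
}

nn_set_params <- function(layer, params) {
  switch(layer$type,
    conv = ,
    tconv = {
      layer$W <- params[[paste0(layer$name, ".W")]]
      layer$b <- params[[paste0(layer$name, ".b")]]
      layer
    },
    relu = layer,
    seq = { layer$layers <- lapply(layer$layers, nn_set_params, params); layer },
    res = { layer$inner <- nn_set_params(layer$inner, params); layer }
  )
}

# Adam optimizer over a named list of parameter arrays.
adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}
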