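# Minimal dense/convolutional network engine with reverse-mode gradients.
#
# Layers are plain lists; a model is an ordered list of layers. Image batches
# are 4-D arrays (H, W, C, N); feature batches are N x F matrices. The global
# average pooling layer is the boundary between the two shapes. Convolution
# is im2col + BLAS matrix multiplication, with the gather indices cached per
# (shape, kernel, batch) signature.

.im2col_cache <- new.env(parent = emptyenv())

im2col_idx <- function(H, W, C, kh, kw, stride, pad) {
  key <- paste(H, W, C, kh, kw, stride, pad, sep = "_")
  hit <- .im2col_cache[[key]]
  if (!is.null(hit)) return(hit)
  Hout <- (H + 2 * pad - kh) %/% stride + 1
  Wout <- (W + 2 * pad - kw) %/% stride + 1
  P <- Hout * Wout
  K <- kh * kw * C
  g <- expand.grid(oh = seq_len(Hout), ow = seq_len(Wout))      # p = oh fastest
  off <- expand.grid(ih = seq_len(kh), iw = seq_len(kw), c = seq_len(C))
  idx <- matrix(NA_integer_, P, K)
  for (k in seq_len(K)) {
    ih <- (g$oh - 1L) * stride + off$ih[k] - pad
    iw <- (g$ow - 1L) * stride + off$iw[k] - pad
    ok <- ih >= 1L & ih <= H & iw >= 1L & iw <= W
    lin <- ih + (iw - 1L) * H + (off$c[k] - 1L) * H * W
    lin[!ok] <- NA_integer_
    idx[, k] <- lin
  }
  out <- list(idx = idx, Hout = Hout, Wout = Wout, P = P, K = K)
  .im2col_cache[[key]] <- out
  out
}

batch_idx <- function(info, L, N) {
  key <- paste("b", L, N, nrow(info$idx), ncol(info$idx),
               info$idx[1, 1], info$idx[info$P, info$K], sep = "_")
  hit <- .im2col_cache[[key]]
  if (!is.null(hit) && identical(dim(hit), c(info$P * N, info$K))) return(hit)
  big <- info$idx[rep(seq_len(info$P), N), , drop = FALSE] +
    rep((seq_len(N) - 1L) * L, each = info$P)
  .im2col_cache[[key]] <- big
  big
}

# ---- layer constructors ----------------------------------------------------

nn_conv <- function(in_ch, out_ch, kernel = 3, stride = 1, pad = 1) {
  list(type = "conv", in_ch = in_ch, out_ch = out_ch, kernel = kernel,
       stride = stride, pad = pad,
       params = list(W = matrix(0, kernel * kernel * in_ch, out_ch),
                     b = numeric(out_ch)))
}
nn_dense <- function(n_in, n_out) {
  list(type = "dense", n_in = n_in, n_out = n_out,
       params = list(W = matrix(0, n_in, n_out), b = numeric(n_out)))
}
nn_batchnorm <- function(n_feat, momentum = 0.9, eps = 1e-5) {
  list(type = "batchnorm", n_feat = n_feat, momentum = momentum, eps = eps,
       params = list(gamma = rep(1, n_feat), beta = numeric(n_feat)),
       state = list(running_mean = numeric(n_feat), running_var = rep(1, n_feat)))
}
nn_relu <- function() list(type = "relu", params = list())
nn_selu <- function() list(type = "selu", params = list())
nn_dropout <- function(p) list(type = "dropout", p = p, params = list())
nn_maxpool <- function() list(type = "maxpool", params = list())
nn_gap <- function() list(type = "gap", params = list())

SELU_LAMBDA <- 1.0507009873554805
SELU_ALPHA <- 1.6732632423543772

init_layer <- function(layer) {
  if (layer$type == "conv") {
    fan_in <- nrow(layer$params$W)
    layer$params$W[] <- stats::rnorm(length(layer$params$W), 0, sqrt(2 / fan_in))
  } else if (layer$type == "dense") {
    fan_in <- layer$n_in
    layer$params$W[] <- stats::rnorm(length(layer$params$W), 0, sqrt(1 / fan_in))
  }
  layer
}

# ---- forward ---------------------------------------------------------------

layer_forward <- function(layer, x, training) {
  switch(layer$type,
    conv = {
      d <- dim(x); H <- d[1]; W <- d[2]; C <- d[3]; N <- d[4]
      info <- im2col_idx(H, W, C, layer$kernel, layer$kernel, layer$stride, layer$pad)
      big <- batch_idx(info, H * W * C, N)
      cols <- as.vector(x)[big]
      if (layer$pad > 0) cols[is.na(cols)] <- 0
      dim(cols) <- dim(big)
      out_mat <- cols %*% layer$params$W +
        matrix(layer$params$b, nrow(cols), layer$out_ch, byrow = TRUE)
      out <- array(out_mat, c(info$Hout, info$Wout, N, layer$out_ch))
      out <- aperm(out, c(1, 2, 4, 3))
      list(out = out, cache = list(cols = cols, big = big, info = info,
                                   in_dim = d))
    },
    dense = {
      out <- x %*% layer$params$W +
        matrix(layer$params$b, nrow(x), layer$n_out, byrow = TRUE)
      list(out = out, cache = list(x = x))
    },
    batchnorm = {
      if (training) {
        n <- nrow(x)
        mu <- colMeans(x)
        v <- colMeans(x^2) - mu^2
        invstd <- 1 / sqrt(v + layer$eps)
        xhat <- sweep(sweep(x, 2, mu), 2, invstd, `*`)
        out <- sweep(sweep(xhat, 2, layer$params$gamma, `*`), 2,
                     layer$params$beta, `+`)
        new_state <- list(
          running_mean = layer$momentum * layer$state$running_mean + (1 - layer$momentum) * mu,
          running_var = layer$momentum * layer$state$running_var + (1 - layer$momentum) * v)
        list(out = out, cache = list(xhat = xhat, invstd = invstd, train = TRUE),
             state = new_state)
      } else {
        invstd <- 1 / sqrt(layer$state$running_var + layer$eps)
        xhat <- sweep(sweep(x, 2, layer$state$running_mean), 2, invstd, `*`)
        out <- sweep(sweep(xhat, 2, layer$params$gamma, `*`), 2,
                     layer$params$beta, `+`)
        list(out = out, cache = list(xhat = xhat, invstd = invstd, train = FALSE))
      }
    },
    relu = list(out = pmax(x, 0), cache = list(mask = x > 0)),
    selu = {
      pos <- x > 0
      out <- SELU_LAMBDA * ifelse(pos, x, SELU_ALPHA * expm1(x))
      list(out = out, cache = list(x = x, pos = pos))
    },
    dropout = {
      if (training && layer$p > 0) {
        keep <- 1 - layer$p
        mask <- (array(stats::runif(length(x)), dim = dim(x) %||% length(x)) < keep) / keep
        list(out = x * mask, cache = list(mask = mask))
      } else list(out = x, cache = list(mask = NULL))
    },
    maxpool = {
      d <- dim(x)
      oi <- seq(1, d[1], 2); ei <- seq(2, d[1], 2)
      oj <- seq(1, d[2], 2); ej <- seq(2, d[2], 2)
      x11 <- x[oi, oj, , , drop = FALSE]; x21 <- x[ei, oj, , , drop = FALSE]
      x12 <- x[oi, ej, , , drop = FALSE]; x22 <- x[ei, ej, , , drop = FALSE]
      m <- pmax(x11, x21, x12, x22)
      list(out = m, cache = list(x11 = x11, x21 = x21, x12 = x12, x22 = x22,
                                 m = m, in_dim = d))
    },
    gap = {
      d <- dim(x)
      out <- t(apply(x, c(3, 4), mean))        # N x C
      if (d[4] == 1) out <- matrix(out, 1, d[3])
      list(out = out, cache = list(in_dim = d))
    },
    stop("unknown layer type ", layer$type)
  )
}

# ---- backward --------------------------------------------------------------

layer_backward <- function(layer, cache, dout) {
  switch(layer$type,
    conv = {
      d <- dim(dout)
      P <- d[1] * d[2]; N <- d[4]
      dmat <- aperm(dout, c(1, 2, 4, 3))
      dim(dmat) <- c(P * N, layer$out_ch)
      dW <- crossprod(cache$cols, dmat)
      db <- colSums(dmat)
      dcols <- dmat %*% t(layer$params$W)
      L <- prod(cache$in_dim)
      dxv <- numeric(L)
      for (k in seq_len(ncol(cache$big))) {
        v <- cache$big[, k]
        ok <- which(!is.na(v))
        if (length(ok)) dxv[v[ok]] <- dxv[v[ok]] + dcols[ok, k]
      }
      list(dx = array(dxv, cache$in_dim), grads = list(W = dW, b = db))
    },
    dense = list(dx = dout %*% t(layer$params$W),
                 grads = list(W = crossprod(cache$x, dout), b = colSums(dout))),
    batchnorm = {
      if (cache$train) {
        n <- nrow(dout)
        dgamma <- colSums(dout * cache$xhat)
        dbeta <- colSums(dout)
        dxhat <- sweep(dout, 2, layer$params$gamma, `*`)
        t1 <- sweep(dxhat * n, 2, colSums(dxhat))
        t2 <- cache$xhat * matrix(colSums(dxhat * cache$xhat), n,
                                  ncol(dout), byrow = TRUE)
        dx <- sweep(t1 - t2, 2, cache$invstd / n, `*`)
        list(dx = dx, grads = list(gamma = dgamma, beta = dbeta))
      } else {
        # eval mode: running statistics are constants
        dx <- sweep(dout, 2, layer$params$gamma * cache$invstd, `*`)
        list(dx = dx, grads = list(gamma = colSums(dout * cache$xhat),
                                   beta = colSums(dout)))
      }
    },
    relu = list(dx = dout * cache$mask, grads = list()),
    selu = {
      g <- SELU_LAMBDA * ifelse(cache$pos, 1, SELU_ALPHA * exp(cache$x))
      list(dx = dout * g, grads = list())
    },
    dropout = {
      if (is.null(cache$mask)) list(dx = dout, grads = list())
      else list(dx = dout * cache$mask, grads = list())
    },
    maxpool = {
      m1 <- cache$x11 == cache$m
      m2 <- (cache$x21 == cache$m) & !m1
      m3 <- (cache$x12 == cache$m) & !(m1 | m2)
      m4 <- !(m1 | m2 | m3)
      d <- cache$in_dim
      dx <- array(0, d)
      oi <- seq(1, d[1], 2); ei <- seq(2, d[1], 2)
      oj <- seq(1, d[2], 2); ej <- seq(2, d[2], 2)
      dx[oi, oj, , ] <- dout * m1
      dx[ei, oj, , ] <- dout * m2
      dx[oi, ej, , ] <- dout * m3
      dx[ei, ej, , ] <- dout * m4
      list(dx = dx, grads = list())
    },
    gap = {
      d <- cache$in_dim
      per <- 1 / (d[1] * d[2])
      dx <- array(0, d)
      for (n in seq_len(d[4]))
        dx[, , , n] <- array(rep(dout[n, ] * per, each = d[1] * d[2]),
                             d[1:3])
      list(dx = dx, grads = list())
    },
    stop("unknown layer type ", layer$type)
  )
}

# Forward pass over all layers; returns final output, caches, and (for
# batch-norm in training mode) updated running statistics written back into
# the returned model.
net_forward <- function(model, x, training = FALSE, keep_outputs = FALSE) {
  caches <- vector("list", length(model$layers))
  outputs <- if (keep_outputs) vector("list", length(model$layers))
  for (i in seq_along(model$layers)) {
    fw <- layer_forward(model$layers[[i]], x, training)
    x <- fw$out
    caches[[i]] <- fw$cache
    if (keep_outputs) outputs[[i]] <- x
    if (!is.null(fw$state)) model$layers[[i]]$state <- fw$state
  }
  list(out = x, caches = caches, model = model, outputs = outputs)
}

# Backward pass; returns per-layer gradient lists and the gradient flowing
# into each layer's input (dx recorded so Grad-CAM can tap any boundary).
net_backward <- function(model, caches, dout, stop_after = 0) {
  grads <- vector("list", length(model$layers))
  dxs <- vector("list", length(model$layers))
  for (i in rev(seq_along(model$layers))) {
    bw <- layer_backward(model$layers[[i]], caches[[i]], dout)
    grads[[i]] <- bw$grads
    dxs[[i]] <- bw$dx
    dout <- bw$dx
    if (i <= stop_after + 1 && stop_after > 0) break
  }
  list(grads = grads, dx_in = dxs)
}

# ---- parameter bookkeeping -------------------------------------------------

net_param_count <- function(model) {
  sum(vapply(model$layers, function(l) {
    n <- sum(vapply(l$params, length, numeric(1)))
    if (!is.null(l$state)) n <- n + sum(vapply(l$state, length, numeric(1)))
    n
  }, numeric(1)))
}

# squared L2 norm over weight matrices (conv + dense W), the quantity
# penalized by the DeepSurv regularizer
net_weight_sq_norm <- function(model) {
  sum(vapply(model$layers, function(l) {
    if (l$type %in% c("conv", "dense")) sum(l$params$W^2) else 0
  }, numeric(1)))
}

weight_decay_grads <- function(model, grads, lambda) {
  if (lambda == 0) return(grads)
  for (i in seq_along(model$layers)) {
    if (model$layers[[i]]$type %in% c("conv", "dense"))
      grads[[i]]$W <- grads[[i]]$W + 2 * lambda * model$layers[[i]]$params$W
  }
  grads
}

grad_global_norm <- function(grads) {
  sqrt(sum(vapply(grads, function(g) sum(vapply(g, function(a) sum(a^2), numeric(1))),
                  numeric(1))))
}

clip_grads <- function(grads, max_norm) {
  if (is.null(max_norm) || !is.finite(max_norm)) return(grads)
  gn <- grad_global_norm(grads)
  if (gn <= max_norm || gn == 0) return(grads)
  sc <- max_norm / gn
  lapply(grads, function(g) lapply(g, function(a) a * sc))
}

# ---- optimizers ------------------------------------------------------------

optimizer_init <- function(model) {
  lapply(model$layers, function(l)
    lapply(l$params, function(p) list(m = p * 0, v = p * 0)))
}

# Nadam update (Dozat 2016): Nesterov-accelerated adaptive moments.
# `momentum` plays the role of beta1; beta2 fixed at 0.999.
optimizer_step <- function(model, grads, opt_state, config, t) {
  lr <- config$learning_rate
  b1 <- config$momentum
  b2 <- 0.999
  eps <- 1e-8
  for (i in seq_along(model$layers)) {
    ps <- model$layers[[i]]$params
    if (length(ps) == 0) next
    for (nm in names(ps)) {
      g <- grads[[i]][[nm]]
      if (is.null(g)) next
      if (identical(config$optimizer, "sgd_nesterov")) {
        st <- opt_state[[i]][[nm]]
        v_new <- b1 * st$m - lr * g
        model$layers[[i]]$params[[nm]] <- ps[[nm]] + b1 * v_new - lr * g
        opt_state[[i]][[nm]]$m <- v_new
      } else {
        st <- opt_state[[i]][[nm]]
        m <- b1 * st$m + (1 - b1) * g
        v <- b2 * st$v + (1 - b2) * g^2
        mhat <- m / (1 - b1^(t + 1))
        ghat <- g / (1 - b1^t)
        vhat <- v / (1 - b2^t)
        upd <- lr * (b1 * mhat + (1 - b1) * ghat) / (sqrt(vhat) + eps)
        model$layers[[i]]$params[[nm]] <- ps[[nm]] - upd
        opt_state[[i]][[nm]]$m <- m
        opt_state[[i]][[nm]]$v <- v
      }
    }
  }
  list(model = model, opt_state = opt_state)
}
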