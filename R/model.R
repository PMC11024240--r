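#' Survival head specification
#'
#' The DeepSurv head mapping pooled backbone features to a single log-hazard
#' output: two hidden layers of 8 nodes with scaled-exponential-linear-unit
#' activation, batch normalization, and dropout 0.5, followed by one linear
#' output node. Defaults are the tuned values the model was developed with.
#'
#' @param hidden_layers number of hidden layers.
#' @param nodes_per_layer nodes per hidden layer.
#' @param activation `"selu"` or `"relu"`.
#' @param dropout dropout rate inside the head.
#' @param batch_norm logical, batch normalization after each hidden linear
#'   layer.
#' @export
survival_head_spec <- function(hidden_layers = 2, nodes_per_layer = 8,
                               activation = c("selu", "relu"), dropout = 0.5,
                               batch_norm = TRUE) {
  structure(list(hidden_layers = hidden_layers,
                 nodes_per_layer = nodes_per_layer,
                 activation = match.arg(activation),
                 dropout = dropout, batch_norm = batch_norm),
            class = "survival_head_spec")
}

#' Training configuration
#'
#' Optimization hyperparameters. The defaults are the tuned values: learning
#' rate 0.154, weight decay 0.00567 (the `lambda` of the regularized loss),
#' momentum 0.887, Nadam, batch size 16, dropout 0.2 on the pooled backbone
#' features. The learning rate is unusually large for Nadam; it is the tuned
#' default but freely configurable, and a step decay schedule is available.
#'
#' @param learning_rate initial learning rate.
#' @param weight_decay L2 penalty `lambda` applied to conv/dense weights.
#' @param momentum first-moment coefficient (Nadam beta1 / Nesterov momentum).
#' @param optimizer `"nadam"` or `"sgd_nesterov"`.
#' @param batch_size minibatch size; Cox risk sets are formed within each
#'   batch.
#' @param epochs training epochs.
#' @param gradient_clip global-norm gradient clip (`Inf` disables).
#' @param lr_decay multiplicative decay applied every `lr_decay_every` epochs.
#' @param lr_decay_every epochs between decays.
#' @param seed integer seed; recorded in every artifact.
#' @param aggregation patient-level aggregation of per-image scores,
#'   `"mean"` or `"max"`.
#' @param dropout_transfer dropout applied to the pooled backbone features.
#' @export
train_config <- function(learning_rate = 0.154, weight_decay = 0.00567,
                         momentum = 0.887, optimizer = c("nadam", "sgd_nesterov"),
                         batch_size = 16, epochs = 300, gradient_clip = 5,
                         lr_decay = 1, lr_decay_every = 50, seed = 1,
                         aggregation = c("mean", "max"),
                         dropout_transfer = 0.2) {
  stopifnot(learning_rate > 0, weight_decay >= 0, momentum >= 0, momentum < 1,
            batch_size >= 2, epochs >= 1)
  structure(list(learning_rate = learning_rate, weight_decay = weight_decay,
                 momentum = momentum, optimizer = match.arg(optimizer),
                 batch_size = batch_size, epochs = epochs,
                 gradient_clip = gradient_clip, lr_decay = lr_decay,
                 lr_decay_every = lr_decay_every, seed = as.integer(seed),
                 aggregation = match.arg(aggregation),
                 dropout_transfer = dropout_transfer),
            class = "train_config")
}

#' Build a DeepSurv model
#'
#' Assembles backbone convolutional layers, global average pooling, transfer
#' dropout, and the survival head into one trainable network ending in a
#' single log-hazard node. Only the `tiny_test` backbone allocates weights;
#' the ImageNet backbones are shape specs for complexity accounting, and
#' requesting a trainable build of one is an error.
#'
#' @param backbone a [backbone_spec()].
#' @param head a [survival_head_spec()].
#' @param seed seed for weight initialization (two builds with the same seed
#'   have identical initial weights).
#' @param dropout_transfer dropout rate on the pooled features.
#' @return object of class `deepsurv_model`.
#' @export
build_model <- function(backbone, head = survival_head_spec(), seed = 1,
                        dropout_transfer = 0.2) {
  stopifnot(inherits(backbone, "backbone_spec"))
  if (backbone$name != "tiny_test")
    hs_error("untrainable-backbone",
             paste0("backbone '", backbone$name, "' is an architecture spec; ",
                    "only tiny_test builds a trainable network"))
  layers <- list()
  in_ch <- 3
  for (ch in backbone$tiny_channels) {
    layers <- c(layers, list(nn_conv(in_ch, ch, 3, 1, 1), nn_relu(), nn_maxpool()))
    in_ch <- ch
  }
  layers <- c(layers, list(nn_gap()))
  n_backbone_layers <- length(layers)
  if (dropout_transfer > 0) layers <- c(layers, list(nn_dropout(dropout_transfer)))
  act <- function() if (head$activation == "selu") nn_selu() else nn_relu()
  n_in <- backbone$feature_dim
  for (i in seq_len(head$hidden_layers)) {
    layers <- c(layers, list(nn_dense(n_in, head$nodes_per_layer)))
    if (head$batch_norm) layers <- c(layers, list(nn_batchnorm(head$nodes_per_layer)))
    layers <- c(layers, list(act()))
    if (head$dropout > 0) layers <- c(layers, list(nn_dropout(head$dropout)))
    n_in <- head$nodes_per_layer
  }
  layers <- c(layers, list(nn_dense(n_in, 1)))
  model <- structure(list(layers = layers, backbone = backbone, head = head,
                          n_backbone_layers = n_backbone_layers,
                          seed = as.integer(seed),
                          baseline = NULL),
                     class = "deepsurv_model")
  model$layers <- with_local_seed(seed, lapply(model$layers, init_layer))
  model
}

#' Build a DeepSurv model over tabular covariates
#'
#' A head-only network whose input is a covariate vector rather than pooled
#' image features. With `hidden_layers = 0` the network is a single linear
#' node, which trained to convergence must reproduce the linear Cox model's
#' risk ranking — the package's analytic cross-check.
#'
#' @param n_covariates input dimension.
#' @param head a [survival_head_spec()]; use
#'   `survival_head_spec(hidden_layers = 0, dropout = 0, batch_norm = FALSE)`
#'   for the linear configuration.
#' @param seed init seed.
#' @export
build_tabular_model <- function(n_covariates, head = survival_head_spec(),
                                seed = 1) {
  layers <- list()
  act <- function() if (head$activation == "selu") nn_selu() else nn_relu()
  n_in <- n_covariates
  for (i in seq_len(head$hidden_layers)) {
    layers <- c(layers, list(nn_dense(n_in, head$nodes_per_layer)))
    if (head$batch_norm) layers <- c(layers, list(nn_batchnorm(head$nodes_per_layer)))
    layers <- c(layers, list(act()))
    if (head$dropout > 0) layers <- c(layers, list(nn_dropout(head$dropout)))
    n_in <- head$nodes_per_layer
  }
  layers <- c(layers, list(nn_dense(n_in, 1)))
  model <- structure(list(layers = layers, backbone = NULL, head = head,
                          n_backbone_layers = 0, seed = as.integer(seed),
                          baseline = NULL),
                     class = "deepsurv_model")
  model$layers <- with_local_seed(seed, lapply(model$layers, init_layer))
  model
}

#' Preprocess an image for a backbone
#'
#' Checks the minimum resolution, converts to RGB if needed (with a warning),
#' bilinearly resizes to the backbone's input size, and applies the
#' backbone's input scaling (`x * 2 - 1` for the Inception family and the
#' tiny backbone, channel-mean centering for VGG/ResNet). Deterministic:
#' the same file always yields the same tensor.
#'
#' @param image numeric array `H x W x 3` (or `H x W`) with values in
#'   `[0, 1]`, as returned by [png::readPNG()].
#' @param backbone a [backbone_spec()].
#' @return array `input_size x input_size x 3`.
#' @export
preprocess_image <- function(image, backbone) {
  stopifnot(inherits(backbone, "backbone_spec"))
  d <- dim(image)
  if (length(d) == 2) {
    warning("grayscale image converted to RGB")
    image <- array(rep(image, 3), c(d, 3))
    d <- dim(image)
  }
  if (d[3] == 4) image <- image[, , 1:3]      # drop alpha
  if (d[1] < backbone$min_resolution || d[2] < backbone$min_resolution)
    hs_error("below-min-resolution",
             paste0("image is ", d[1], "x", d[2], "; both sides must be >= ",
                    backbone$min_resolution))
  s <- backbone$input_size
  out <- array(0, c(s, s, 3))
  for (ch in 1:3) out[, , ch] <- bilinear_resize(image[, , ch], s, s)
  if (backbone$name %in% c("vgg19", "resnet50")) {
    means <- c(0.485, 0.456, 0.406)
    for (ch in 1:3) out[, , ch] <- out[, , ch] - means[ch]
  } else {
    out <- out * 2 - 1
  }
  out
}

# deterministic bilinear interpolation with half-pixel centers
bilinear_resize <- function(mat, out_h, out_w) {
  in_h <- nrow(mat); in_w <- ncol(mat)
  if (in_h == out_h && in_w == out_w) return(mat)
  ry <- (seq_len(out_h) - 0.5) * in_h / out_h - 0.5
  rx <- (seq_len(out_w) - 0.5) * in_w / out_w - 0.5
  y0 <- pmin(pmax(floor(ry), 0), in_h - 1); y1 <- pmin(y0 + 1, in_h - 1)
  x0 <- pmin(pmax(floor(rx), 0), in_w - 1); x1 <- pmin(x0 + 1, in_w - 1)
  wy <- pmin(pmax(ry - y0, 0), 1); wx <- pmin(pmax(rx - x0, 0), 1)
  a <- mat[y0 + 1, x0 + 1, drop = FALSE] * outer(1 - wy, 1 - wx)
  b <- mat[y1 + 1, x0 + 1, drop = FALSE] * outer(wy, 1 - wx)
  cc <- mat[y0 + 1, x1 + 1, drop = FALSE] * outer(1 - wy, wx)
  dd <- mat[y1 + 1, x1 + 1, drop = FALSE] * outer(wy, wx)
  a + b + cc + dd
}

# forward a stack of preprocessed images (list of H x W x 3 arrays) and
# return one log-hazard per image
model_scores <- function(model, images, training = FALSE) {
  x <- array(0, c(dim(images[[1]]), length(images)))
  for (i in seq_along(images)) x[, , , i] <- images[[i]]
  drop(net_forward(model, x, training = training)$out)
}

#' Train a DeepSurv model with the minibatch Cox partial-likelihood loss
#'
#' Each epoch shuffles samples into minibatches; the Cox risk set is formed
#' within each batch (a batch at least as large as the data reproduces the
#' full-cohort loss exactly). Batches without any event are skipped and
#' counted. Training aborts with diagnostics if the loss becomes non-finite.
#' Fully reproducible from the config seed.
#'
#' @param model a `deepsurv_model`.
#' @param x for image models, a list of preprocessed image arrays; for
#'   tabular models, a numeric matrix.
#' @param times,events per-sample follow-up outcome (images inherit their
#'   patient's outcome).
#' @param config a [train_config()].
#' @param validation optional list with `x`, `times`, `events` evaluated at
#'   the end of each epoch.
#' @return the trained model, with a `history` attribute: data frame of
#'   per-epoch training (and validation) loss and the skipped-batch counter.
#' @export
train_deepsurv <- function(model, x, times, events, config = train_config(),
                           validation = NULL) {
  is_image <- is.list(x)
  n <- if (is_image) length(x) else nrow(x)
  if (sum(events) < 2) hs_error("no-events", "need at least 2 events to train")
  if (length(times) != n || length(events) != n)
    hs_error("length-mismatch", "x, times, events must agree")
  opt_state <- optimizer_init(model)
  history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        val_loss = numeric(0), lr = numeric(0),
                        skipped_batches = integer(0))
  lr0 <- config$learning_rate
  step <- 0
  with_local_seed(config$seed, {
    for (epoch in seq_len(config$epochs)) {
      cfg <- config
      cfg$learning_rate <- lr0 * config$lr_decay^((epoch - 1) %/% config$lr_decay_every)
      perm <- sample.int(n)
      skipped <- 0L
      epoch_losses <- numeric(0)
      starts <- seq(1, n, by = config$batch_size)
      for (s0 in starts) {
        idx <- perm[s0:min(s0 + config$batch_size - 1, n)]
        if (sum(events[idx]) == 0) { skipped <- skipped + 1L; next }
        if (length(idx) < 2) { skipped <- skipped + 1L; next }
        xb <- if (is_image) {
          b <- array(0, c(dim(x[[1]]), length(idx)))
          for (j in seq_along(idx)) b[, , , j] <- x[[idx[j]]]
          b
        } else x[idx, , drop = FALSE]
        fw <- net_forward(model, xb, training = TRUE)
        model <- fw$model
        scores <- drop(fw$out)
        lg <- cox_loss_grad(scores, times[idx], events[idx])
        loss <- lg$loss + config$weight_decay * net_weight_sq_norm(model)
        if (!is.finite(loss))
          hs_error("non-finite-loss",
                   paste0("loss became non-finite at epoch ", epoch,
                          ", step ", step, "; last finite losses: ",
                          paste(signif(utils::tail(epoch_losses, 3), 6),
                                collapse = ", ")))
        dout <- matrix(lg$grad, ncol = 1)
        bw <- net_backward(model, fw$caches, dout)
        grads <- weight_decay_grads(model, bw$grads, config$weight_decay)
        grads <- clip_grads(grads, config$gradient_clip)
        step <- step + 1
        upd <- optimizer_step(model, grads, opt_state, cfg, step)
        model <- upd$model
        opt_state <- upd$opt_state
        epoch_losses <- c(epoch_losses, loss)
      }
      val_loss <- NA_real_
      if (!is.null(validation)) {
        vs <- if (is_image) model_scores(model, validation$x)
              else drop(net_forward(model, validation$x)$out)
        val_loss <- deepsurv_loss(vs, validation$times, validation$events,
                                  net_weight_sq_norm(model), config$weight_decay)
      }
      history[nrow(history) + 1, ] <-
        list(epoch, mean(epoch_losses), val_loss, cfg$learning_rate, skipped)
    }
  })
  attr(model, "history") <- history
  model$train_config <- config
  model
}

#' Predict one patient's log-hazard score
#'
#' Scores every image of the patient and aggregates (default: mean) into a
#' single patient-level log hazard.
#'
#' @param model a trained `deepsurv_model`.
#' @param images list of preprocessed image arrays for one patient.
#' @param aggregation `"mean"` or `"max"`.
#' @return a list (`risk_score`): `log_hazard`, `n_images`, `aggregation`.
#' @export
predict_patient <- function(model, images, aggregation = c("mean", "max")) {
  aggregation <- match.arg(aggregation)
  if (length(images) == 0) hs_error("no-images", "patient has no images")
  s <- model_scores(model, images)
  lh <- if (aggregation == "mean") mean(s) else max(s)
  structure(list(log_hazard = lh, n_images = length(images),
                 aggregation = aggregation, per_image = s),
            class = "risk_score")
}

#' Measure average inference time
#'
#' Wall-clock mean seconds per image over repeated forward passes after one
#' warm-up pass. Reported for complexity accounting only; never asserted on.
#'
#' @param model a `deepsurv_model`.
#' @param n_images batch size per repeat.
#' @param repeats number of timed repeats.
#' @export
measure_inference_time <- function(model, n_images = 1, repeats = 5) {
  s <- model$backbone$input_size %||% 48
  imgs <- replicate(n_images, array(0.5, c(s, s, 3)), simplify = FALSE)
  model_scores(model, imgs)                       # warm-up
  t0 <- vapply(seq_len(repeats), function(r) {
    tt <- system.time(model_scores(model, imgs))[["elapsed"]]
    tt / n_images
  }, numeric(1))
  mean(t0)
}

#' Complexity report for a backbone
#'
#' Parameters, FLOPs (with the counting convention recorded) and, for the
#' trainable tiny backbone, measured average inference time.
#'
#' @param x a `backbone_spec` or backbone name.
#' @param input_size evaluation input size (default: the spec's).
#' @param measure_time measure inference time (tiny_test only).
#' @return object of class `complexity_report`.
#' @export
complexity_report <- function(x, input_size = NULL, measure_time = FALSE) {
  if (is.character(x)) x <- backbone_spec(x)
  fl <- count_flops(x, input_size)
  avg <- NA_real_
  if (measure_time && x$name == "tiny_test")
    avg <- measure_inference_time(build_model(x, seed = 1))
  structure(list(model_id = x$name,
                 param_count = count_parameters(x),
                 flops = fl$flops,
                 avg_inference_seconds = avg,
                 flop_convention = fl$convention,
                 input_size = input_size %||% x$input_size),
            class = "complexity_report")
}

#' Save / load a model checkpoint
#'
#' Weights are serialized alongside a JSON sidecar recording the backbone
#' name, head spec, training config, seed, and the Breslow baseline hazard
#' curve, so a checkpoint is a self-contained predictor.
#'
#' @param model a `deepsurv_model`.
#' @param path file path for the checkpoint (`.rds`); the sidecar is written
#'   to `paste0(path, ".json")`.
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(model, path)
  sidecar <- list(
    schema_version = 1L,
    backbone = model$backbone$name %||% "tabular",
    head = unclass(model$head),
    train_config = if (!is.null(model$train_config)) unclass(model$train_config),
    seed = model$seed,
    baseline_hazard = if (!is.null(model$baseline))
      list(times = model$baseline$times,
           cumulative_hazard = model$baseline$cumulative_hazard))
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) readRDS(path)
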