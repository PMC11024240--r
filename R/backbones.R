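# Backbone architecture accounting.
#
# The four ImageNet backbones are represented as layer-by-layer shape
# specifications (channels, kernels, strides, padding, batch-norm flavour),
# built by propagating the input shape through the graph. That is enough to
# reproduce exact parameter counts and to report forward-pass FLOPs under a
# stated convention, without instantiating tens of millions of weights.
# Only the `tiny_test` backbone is built as an actual trainable network.
#
# Batch-norm conventions mirror the reference implementations these
# architectures are defined by: the Inception family uses un-scaled batch
# norm (beta + moving mean + moving variance, 3 per channel); ResNet uses
# full batch norm (4 per channel). Parameter counts include non-trainable
# moving statistics.

arch_new <- function(input_size, channels = 3) {
  list(h = input_size, w = input_size, c = channels, rows = list())
}

out_dim <- function(n, k, stride, pad) {
  if (pad == "same") ceiling(n / stride) else floor((n - k) / stride) + 1
}

arch_conv <- function(st, out_ch, kh, kw = kh, stride = 1, pad = "same",
                      bias = TRUE, bn = "none", name = "conv") {
  ho <- out_dim(st$h, kh, stride, pad)
  wo <- out_dim(st$w, kw, stride, pad)
  params <- kh * kw * st$c * out_ch + if (bias) out_ch else 0
  macs <- as.numeric(kh) * kw * st$c * out_ch * ho * wo
  st$rows[[length(st$rows) + 1]] <-
    data.frame(name = name, type = "conv", in_ch = st$c, out_ch = out_ch,
               kh = kh, kw = kw, stride = stride, h_out = ho, w_out = wo,
               params = params, macs = macs)
  if (bn != "none") {
    per <- if (bn == "noscale") 3 else 4
    st$rows[[length(st$rows) + 1]] <-
      data.frame(name = paste0(name, "_bn"), type = "batchnorm",
                 in_ch = out_ch, out_ch = out_ch, kh = 0, kw = 0, stride = 1,
                 h_out = ho, w_out = wo, params = per * out_ch, macs = 0)
  }
  st$h <- ho; st$w <- wo; st$c <- out_ch
  st
}

arch_pool <- function(st, k, stride, pad = "valid", what = "max") {
  ho <- out_dim(st$h, k, stride, pad)
  wo <- out_dim(st$w, k, stride, pad)
  st$rows[[length(st$rows) + 1]] <-
    data.frame(name = paste0(what, "pool"), type = "pool", in_ch = st$c,
               out_ch = st$c, kh = k, kw = k, stride = stride,
               h_out = ho, w_out = wo, params = 0, macs = 0)
  st$h <- ho; st$w <- wo
  st
}

arch_zeropad <- function(st, p) {
  st$h <- st$h + 2 * p
  st$w <- st$w + 2 * p
  st
}

# run each branch function from the current state and concatenate channels
arch_branches <- function(st, ...) {
  fns <- list(...)
  outs <- lapply(fns, function(f) f(st))
  hs <- vapply(outs, `[[`, numeric(1), "h")
  if (length(unique(hs)) != 1)
    stop("branch spatial dims disagree: ", paste(hs, collapse = ","))
  st$rows <- c(st$rows, unlist(lapply(outs, `[[`, "rows"), recursive = FALSE))
  st$h <- outs[[1]]$h
  st$w <- outs[[1]]$w
  st$c <- sum(vapply(outs, `[[`, numeric(1), "c"))
  st
}

# residual add: branch output channels must equal input channels
arch_residual <- function(st, f) {
  out <- f(st)
  st$rows <- c(st$rows, out$rows)
  st
}

arch_table <- function(st) do.call(rbind, st$rows)

# ---- the four ImageNet backbones ------------------------------------------

build_vgg19 <- function(input_size = 336) {
  st <- arch_new(input_size)
  blocks <- list(c(64, 2), c(128, 2), c(256, 4), c(512, 4), c(512, 4))
  for (b in blocks) {
    for (i in seq_len(b[2]))
      st <- arch_conv(st, b[1], 3, bias = TRUE, bn = "none")
    st <- arch_pool(st, 2, 2)
  }
  st
}

build_resnet50 <- function(input_size = 336) {
  cb <- function(st, ch, k = 1, stride = 1, pad = "valid")
    arch_conv(st, ch, k, stride = stride, pad = pad, bias = TRUE, bn = "full")
  bottleneck <- function(st, f1, f3, fo, stride = 1, project = FALSE) {
    main <- function(s) {
      s$rows <- list()
      s <- cb(s, f1, 1, stride = stride)
      s <- cb(s, f3, 3, pad = "same")
      cb(s, fo, 1)
    }
    short <- function(s) {
      s$rows <- list()
      if (project) cb(s, fo, 1, stride = stride) else s
    }
    m <- main(st); sh <- short(st)
    st$rows <- c(st$rows, m$rows, sh$rows)
    st$h <- m$h; st$w <- m$w; st$c <- fo
    st
  }
  st <- arch_new(input_size)
  st <- arch_zeropad(st, 3)
  st <- arch_conv(st, 64, 7, stride = 2, pad = "valid", bias = TRUE, bn = "full")
  st <- arch_zeropad(st, 1)
  st <- arch_pool(st, 3, 2)
  stages <- list(list(64, 256, 3, 1), list(128, 512, 4, 2),
                 list(256, 1024, 6, 2), list(512, 2048, 3, 2))
  for (sg in stages) {
    st <- bottleneck(st, sg[[1]], sg[[1]], sg[[2]], stride = sg[[4]], project = TRUE)
    for (i in seq_len(sg[[3]] - 1))
      st <- bottleneck(st, sg[[1]], sg[[1]], sg[[2]])
  }
  st
}

build_inception_v3 <- function(input_size = 336) {
  cb <- function(st, ch, kh, kw = kh, stride = 1, pad = "same")
    arch_conv(st, ch, kh, kw, stride = stride, pad = pad, bias = FALSE,
              bn = "noscale")
  st <- arch_new(input_size)
  st <- cb(st, 32, 3, stride = 2, pad = "valid")
  st <- cb(st, 32, 3, pad = "valid")
  st <- cb(st, 64, 3)
  st <- arch_pool(st, 3, 2)
  st <- cb(st, 80, 1, pad = "valid")
  st <- cb(st, 192, 3, pad = "valid")
  st <- arch_pool(st, 3, 2)
  mixed_a <- function(st, pool_ch) {
    arch_branches(st,
      function(s) { s$rows <- list(); cb(s, 64, 1) },
      function(s) { s$rows <- list(); s <- cb(s, 48, 1); cb(s, 64, 5) },
      function(s) { s$rows <- list(); s <- cb(s, 64, 1); s <- cb(s, 96, 3); cb(s, 96, 3) },
      function(s) { s$rows <- list(); s <- arch_pool(s, 3, 1, pad = "same", what = "avg"); cb(s, pool_ch, 1) })
  }
  st <- mixed_a(st, 32); st <- mixed_a(st, 64); st <- mixed_a(st, 64)
  # mixed3: grid reduction
  st <- arch_branches(st,
    function(s) { s$rows <- list(); cb(s, 384, 3, stride = 2, pad = "valid") },
    function(s) { s$rows <- list(); s <- cb(s, 64, 1); s <- cb(s, 96, 3); cb(s, 96, 3, stride = 2, pad = "valid") },
    function(s) { s$rows <- list(); arch_pool(s, 3, 2) })
  mixed_b <- function(st, ch) {
    arch_branches(st,
      function(s) { s$rows <- list(); cb(s, 192, 1) },
      function(s) { s$rows <- list(); s <- cb(s, ch, 1); s <- cb(s, ch, 1, 7); cb(s, 192, 7, 1) },
      function(s) { s$rows <- list(); s <- cb(s, ch, 1); s <- cb(s, ch, 7, 1)
                    s <- cb(s, ch, 1, 7); s <- cb(s, ch, 7, 1); cb(s, 192, 1, 7) },
      function(s) { s$rows <- list(); s <- arch_pool(s, 3, 1, pad = "same", what = "avg"); cb(s, 192, 1) })
  }
  st <- mixed_b(st, 128); st <- mixed_b(st, 160); st <- mixed_b(st, 160)
  st <- mixed_b(st, 192)
  # mixed8: grid reduction
  st <- arch_branches(st,
    function(s) { s$rows <- list(); s <- cb(s, 192, 1); cb(s, 320, 3, stride = 2, pad = "valid") },
    function(s) { s$rows <- list(); s <- cb(s, 192, 1); s <- cb(s, 192, 1, 7)
                  s <- cb(s, 192, 7, 1); cb(s, 192, 3, stride = 2, pad = "valid") },
    function(s) { s$rows <- list(); arch_pool(s, 3, 2) })
  mixed_c <- function(st) {
    arch_branches(st,
      function(s) { s$rows <- list(); cb(s, 320, 1) },
      function(s) { s$rows <- list(); s <- cb(s, 384, 1)
                    arch_branches(s,
                      function(q) { q$rows <- list(); cb(q, 384, 1, 3) },
                      function(q) { q$rows <- list(); cb(q, 384, 3, 1) }) },
      function(s) { s$rows <- list(); s <- cb(s, 448, 1); s <- cb(s, 384, 3)
                    arch_branches(s,
                      function(q) { q$rows <- list(); cb(q, 384, 1, 3) },
                      function(q) { q$rows <- list(); cb(q, 384, 3, 1) }) },
      function(s) { s$rows <- list(); s <- arch_pool(s, 3, 1, pad = "same", what = "avg"); cb(s, 192, 1) })
  }
  st <- mixed_c(st); st <- mixed_c(st)
  st
}

build_inception_resnet_v2 <- function(input_size = 336) {
  cb <- function(st, ch, kh, kw = kh, stride = 1, pad = "same")
    arch_conv(st, ch, kh, kw, stride = stride, pad = pad, bias = FALSE,
              bn = "noscale")
  up <- function(st, ch)  # residual-scaling projection: bias, no batch norm
    arch_conv(st, ch, 1, bias = TRUE, bn = "none", name = "up")
  st <- arch_new(input_size)
  st <- cb(st, 32, 3, stride = 2, pad = "valid")
  st <- cb(st, 32, 3, pad = "valid")
  st <- cb(st, 64, 3)
  st <- arch_pool(st, 3, 2)
  st <- cb(st, 80, 1, pad = "valid")
  st <- cb(st, 192, 3, pad = "valid")
  st <- arch_pool(st, 3, 2)
  # mixed_5b
  st <- arch_branches(st,
    function(s) { s$rows <- list(); cb(s, 96, 1) },
    function(s) { s$rows <- list(); s <- cb(s, 48, 1); cb(s, 64, 5) },
    function(s) { s$rows <- list(); s <- cb(s, 64, 1); s <- cb(s, 96, 3); cb(s, 96, 3) },
    function(s) { s$rows <- list(); s <- arch_pool(s, 3, 1, pad = "same", what = "avg"); cb(s, 64, 1) })
  block35 <- function(st) {
    arch_residual(st, function(s) {
      s$rows <- list()
      s <- arch_branches(s,
        function(q) { q$rows <- list(); cb(q, 32, 1) },
        function(q) { q$rows <- list(); q <- cb(q, 32, 1); cb(q, 32, 3) },
        function(q) { q$rows <- list(); q <- cb(q, 32, 1); q <- cb(q, 48, 3); cb(q, 64, 3) })
      up(s, 320)
    })
  }
  for (i in 1:10) st <- block35(st)
  # mixed_6a
  st <- arch_branches(st,
    function(s) { s$rows <- list(); cb(s, 384, 3, stride = 2, pad = "valid") },
    function(s) { s$rows <- list(); s <- cb(s, 256, 1); s <- cb(s, 256, 3); cb(s, 384, 3, stride = 2, pad = "valid") },
    function(s) { s$rows <- list(); arch_pool(s, 3, 2) })
  block17 <- function(st) {
    arch_residual(st, function(s) {
      s$rows <- list()
      s <- arch_branches(s,
        function(q) { q$rows <- list(); cb(q, 192, 1) },
        function(q) { q$rows <- list(); q <- cb(q, 128, 1); q <- cb(q, 160, 1, 7); cb(q, 192, 7, 1) })
      up(s, 1088)
    })
  }
  for (i in 1:20) st <- block17(st)
  # mixed_7a
  st <- arch_branches(st,
    function(s) { s$rows <- list(); s <- cb(s, 256, 1); cb(s, 384, 3, stride = 2, pad = "valid") },
    function(s) { s$rows <- list(); s <- cb(s, 256, 1); cb(s, 288, 3, stride = 2, pad = "valid") },
    function(s) { s$rows <- list(); s <- cb(s, 256, 1); s <- cb(s, 288, 3); cb(s, 320, 3, stride = 2, pad = "valid") },
    function(s) { s$rows <- list(); arch_pool(s, 3, 2) })
  block8 <- function(st) {
    arch_residual(st, function(s) {
      s$rows <- list()
      s <- arch_branches(s,
        function(q) { q$rows <- list(); cb(q, 192, 1) },
        function(q) { q$rows <- list(); q <- cb(q, 192, 1); q <- cb(q, 224, 1, 3); cb(q, 256, 3, 1) })
      up(s, 2080)
    })
  }
  for (i in 1:10) st <- block8(st)
  st <- cb(st, 1536, 1)
  st
}

BACKBONE_BUILDERS <- list(
  vgg19 = build_vgg19,
  resnet50 = build_resnet50,
  inception_v3 = build_inception_v3,
  inception_resnet_v2 = build_inception_resnet_v2
)

BACKBONE_FEATURE_DIM <- c(vgg19 = 512, resnet50 = 2048, inception_v3 = 2048,
                          inception_resnet_v2 = 1536)

#' Backbone specification
#'
#' Describes the convolutional feature extractor: one of the four ImageNet
#' architectures used for transfer learning, or `tiny_test`, a small
#' configurable CNN for desk-scale experiments and tests. The ImageNet
#' backbones are represented as exact architecture shape specs (sufficient
#' for complexity accounting); `tiny_test` is fully trainable.
#'
#' @param name one of `"inception_v3"`, `"resnet50"`, `"inception_resnet_v2"`,
#'   `"vgg19"`, `"tiny_test"`.
#' @param input_size input side in pixels (default 336; `tiny_test` defaults
#'   to 48).
#' @param pretrained logical; kept as metadata (no weights are downloaded).
#' @param tiny_channels integer vector of conv channel widths for
#'   `tiny_test`; each conv is 3x3/same followed by ReLU and 2x2 max-pooling.
#' @return object of class `backbone_spec`.
#' @export
backbone_spec <- function(name, input_size = NULL, pretrained = FALSE,
                          tiny_channels = c(8, 16)) {
  name <- match.arg(name, c("inception_v3", "resnet50", "inception_resnet_v2",
                            "vgg19", "tiny_test"))
  if (is.null(input_size)) input_size <- if (name == "tiny_test") 48 else 336
  feature_dim <- if (name == "tiny_test") tiny_channels[length(tiny_channels)]
                 else unname(BACKBONE_FEATURE_DIM[name])
  min_resolution <- if (name == "tiny_test") 16 else 300
  structure(list(name = name, input_size = input_size,
                 feature_dim = feature_dim, pretrained = pretrained,
                 tiny_channels = tiny_channels,
                 min_resolution = min_resolution),
            class = "backbone_spec")
}

backbone_arch_table <- function(spec) {
  if (spec$name == "tiny_test") {
    st <- arch_new(spec$input_size)
    for (ch in spec$tiny_channels) {
      st <- arch_conv(st, ch, 3, bias = TRUE, bn = "none")
      st <- arch_pool(st, 2, 2)
    }
    return(arch_table(st))
  }
  arch_table(BACKBONE_BUILDERS[[spec$name]](spec$input_size))
}

#' Count model parameters
#'
#' Total weight count, trainable plus non-trainable (batch-norm moving
#' statistics included), of a backbone architecture or a built model.
#'
#' @param x a `backbone_spec`, a `deepsurv_model`, or a backbone name string.
#' @param ... unused.
#' @return integer-valued numeric.
#' @export
count_parameters <- function(x, ...) UseMethod("count_parameters")

#' @export
count_parameters.character <- function(x, ...)
  count_parameters(backbone_spec(x), ...)

#' @export
count_parameters.backbone_spec <- function(x, ...)
  sum(backbone_arch_table(x)$params)

#' @export
count_parameters.deepsurv_model <- function(x, ...) net_param_count(x)

#' Count forward-pass FLOPs
#'
#' Forward-pass floating-point operations at the given input size, under the
#' convention that one multiply-accumulate is 2 FLOPs and only convolution
#' and dense layers are counted (batch norm, pooling and activations are
#' excluded). The convention string travels with every complexity report.
#'
#' @param x a `backbone_spec` or backbone name.
#' @param input_size input side in pixels; defaults to the spec's.
#' @return list with `flops` and `convention`.
#' @export
count_flops <- function(x, input_size = NULL) {
  if (is.character(x)) x <- backbone_spec(x)
  stopifnot(inherits(x, "backbone_spec"))
  if (!is.null(input_size)) x$input_size <- input_size
  tab <- backbone_arch_table(x)
  list(flops = 2 * sum(tab$macs),
       convention = "2 FLOPs per multiply-accumulate; conv and dense layers only")
}
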