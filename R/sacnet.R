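# The segmentation network: an encoder-decoder in the DeepLabV3+ style with
# a MobileNetV2 backbone whose bottleneck depthwise convolutions are replaced
# by split-attention convolutions (SAC), a densely connected atrous pyramid
# with strip pooling (DenseASPP+SP) on the deep features, and a CBAM-refined
# decoder. Ablation toggles reproduce the A / A+B / A+B+C / A+B+C+D variants.

#' Split-attention convolution settings
#'
#' @param radix number of parallel 3x3 depthwise splits whose outputs are
#'   re-weighted by softmax attention (default 2).
#' @param cardinality number of independent attention groups (default 1).
#' @param reduction channel reduction of the attention bottleneck MLP
#'   (default 4).
#' @return an object of class `sac_spec`.
#' @export
sac_spec <- function(radix = 2L, cardinality = 1L, reduction = 4L) {
  stopifnot(radix >= 1, reduction >= 1, cardinality >= 1)
  structure(list(radix = as.integer(radix), cardinality = as.integer(cardinality),
                 reduction = as.integer(reduction)), class = "sac_spec")
}

#' Dense atrous pyramid + strip pooling settings
#'
#' @param dilations strictly increasing dilation rates of the cascaded
#'   branches (default 3, 6, 12, 18, 24).
#' @param growth output channels contributed by each dense branch (default 64).
#' @param reduce_channels 1x1 bottleneck width inside each branch (default 128).
#' @param strip_pooling add horizontal + vertical strip-pooling branches.
#' @param out_channels channels after the final 1x1 fusion (default 256).
#' @param pre_channels 1x1 projection of the backbone output before the
#'   pyramid, bounding dense channel growth (default 256).
#' @return an object of class `dense_aspp_spec`.
#' @export
dense_aspp_spec <- function(dilations = c(3L, 6L, 12L, 18L, 24L), growth = 64L,
                            reduce_channels = 128L, strip_pooling = TRUE,
                            out_channels = 256L, pre_channels = 256L) {
  stopifnot(all(diff(dilations) > 0), growth > 0, out_channels > 0)
  structure(list(dilations = as.integer(dilations), growth = as.integer(growth),
                 reduce_channels = as.integer(reduce_channels),
                 strip_pooling = isTRUE(strip_pooling),
                 out_channels = as.integer(out_channels),
                 pre_channels = as.integer(pre_channels)),
            class = "dense_aspp_spec")
}

#' Convolutional block attention settings
#'
#' @param reduction channel-attention MLP reduction ratio (default 16).
#' @param spatial_kernel odd kernel size of the spatial-attention convolution
#'   (default 7).
#' @return an object of class `cbam_spec`.
#' @export
cbam_spec <- function(reduction = 16L, spatial_kernel = 7L) {
  stopifnot(reduction >= 1, spatial_kernel %% 2 == 1)
  structure(list(reduction = as.integer(reduction),
                 spatial_kernel = as.integer(spatial_kernel)),
            class = "cbam_spec")
}

#' Backbone stage table
#'
#' The inverted-residual stage layout (expansion factor t, output channels c,
#' repeats n, stride s) of the MobileNetV2-style encoder. Stride-2 stages past
#' output stride 16 are executed with stride 1 and dilation so the deep branch
#' stays at output stride 16 (the usual DeepLab re-wiring).
#'
#' @param width_mult channel width multiplier (default 1).
#' @return an object of class `backbone_spec`.
#' @export
backbone_spec <- function(width_mult = 1.0) {
  stages <- data.frame(
    t = c(1L, 6L, 6L, 6L, 6L, 6L, 6L),
    c = c(16L, 24L, 32L, 64L, 96L, 160L, 320L),
    n = c(1L, 2L, 3L, 4L, 3L, 3L, 1L),
    s = c(1L, 2L, 2L, 2L, 1L, 2L, 1L)
  )
  structure(list(stages = stages, stem_channels = 32L, last_channels = 1280L,
                 width_mult = width_mult, output_stride = 16L),
            class = "backbone_spec")
}

#' Network configuration with ablation toggles
#'
#' `variant` selects the ablation rung: `"A"` = lightweight backbone with a
#' plain atrous pyramid, `"A+B"` adds split-attention bottlenecks, `"A+B+C"`
#' swaps the pyramid for DenseASPP+SP, `"A+B+C+D"` (default) adds the CBAM
#' decoder. Individual toggles can still be overridden.
#'
#' @param num_classes output classes (default 2: crop row / background).
#' @param variant ablation rung, see above.
#' @param width_mult backbone width multiplier.
#' @param sac `sac_spec()` or NULL to disable split attention.
#' @param head `dense_aspp_spec()`; used when the dense head is enabled.
#' @param cbam `cbam_spec()` or NULL to disable decoder attention.
#' @param use_sac,use_dense_aspp,use_cbam explicit toggles overriding `variant`.
#' @param decoder_channels decoder feature width (default 256).
#' @param shallow_channels 1x1-projected low-level feature width (default 48).
#' @return an object of class `net_config`.
#' @export
net_config <- function(num_classes = 2L, variant = c("A+B+C+D", "A+B+C", "A+B", "A"),
                       width_mult = 1.0, sac = sac_spec(),
                       head = dense_aspp_spec(), cbam = cbam_spec(),
                       use_sac = NULL, use_dense_aspp = NULL, use_cbam = NULL,
                       decoder_channels = 256L, shallow_channels = 48L) {
  variant <- match.arg(variant)
  on_b <- variant %in% c("A+B", "A+B+C", "A+B+C+D")
  on_c <- variant %in% c("A+B+C", "A+B+C+D")
  on_d <- variant == "A+B+C+D"
  if (!is.null(use_sac)) on_b <- isTRUE(use_sac)
  if (!is.null(use_dense_aspp)) on_c <- isTRUE(use_dense_aspp)
  if (!is.null(use_cbam)) on_d <- isTRUE(use_cbam)
  structure(list(num_classes = as.integer(num_classes),
                 backbone = backbone_spec(width_mult),
                 sac = if (on_b) sac else NULL,
                 head = head, use_dense_aspp = on_c,
                 cbam = if (on_d) cbam else NULL,
                 decoder_channels = as.integer(decoder_channels),
                 shallow_channels = as.integer(shallow_channels)),
            class = "net_config")
}

# ---- blocks -----------------------------------------------------------------

# Split-attention convolution over C channels: `radix` parallel depthwise 3x3
# convolutions; their sum is globally pooled, passed through a bottleneck MLP,
# and a per-channel softmax across the radix axis re-weights each split.
cn_sac <- function(C, stride = 1L, dil = 1L, spec = sac_spec()) {
  m <- cn_module("sac")
  r <- spec$radix
  d <- max(C %/% spec$reduction, 8L)
  for (k in seq_len(r)) {
    m$children[[paste0("split", k)]] <-
      cn_conv(C, C, k = 3L, stride = stride, dil = dil, groups = C, bias = FALSE)
  }
  # attention-logit path: bare convs (no BN / activation on the logits)
  m$children$fc1 <- cn_conv(C, d, k = 1L, bias = TRUE)
  m$children$fc2 <- cn_conv(d, C * r, k = 1L, bias = TRUE)
  m$spec <- spec
  m$C <- C
  m$forward <- function(x, training = FALSE) {
    splits <- lapply(seq_len(r), function(k)
      m$children[[paste0("split", k)]]$forward(x, training))
    if (r == 1L) {
      s <- splits[[1]]
    } else {
      s <- splits[[1]]
      for (k in 2:r) s <- ag_add(s, splits[[k]])
    }
    pooled <- ag_gap(s)
    z <- ag_relu(m$children$fc1$forward(pooled, training))
    logits <- m$children$fc2$forward(z, training)
    att <- ag_radix_softmax(logits, r)          # (1,1,C*r,N)
    out <- NULL
    for (k in seq_len(r)) {
      av <- ag_op(ag_value(att)[, , ((k - 1) * C + 1):(k * C), , drop = FALSE],
                  list(att), local({
                    kk <- k
                    function(gy) {
                      g <- array(0, dim = dim(ag_value(att)))
                      g[, , ((kk - 1) * C + 1):(kk * C), ] <- gy
                      list(g)
                    }
                  }))
      term <- ag_scale_channel(splits[[k]], av)
      out <- if (is.null(out)) term else ag_add(out, term)
    }
    out
  }
  m
}

# Inverted residual: 1x1 expand -> (SAC | depthwise 3x3) -> 1x1 project,
# with a skip connection at matching dims.
cn_inverted_residual <- function(cin, cout, t, stride = 1L, dil = 1L,
                                 sac = NULL) {
  m <- cn_module("invres")
  hid <- cin * t
  if (t != 1L) m$children$expand <- cn_cba(cin, hid, k = 1L)
  if (!is.null(sac)) {
    m$children$mid <- cn_sac(hid, stride = stride, dil = dil, spec = sac)
  } else {
    m$children$mid <- cn_conv(hid, hid, k = 3L, stride = stride, dil = dil,
                              groups = hid, bias = FALSE)
  }
  m$children$mid_bn <- cn_bn(hid)
  m$children$project <- cn_cba(hid, cout, k = 1L, act = "none")
  m$skip <- (stride == 1L && cin == cout)
  m$forward <- function(x, training = FALSE) {
    y <- x
    if (!is.null(m$children$expand)) y <- m$children$expand$forward(y, training)
    y <- m$children$mid$forward(y, training)
    y <- ag_relu6(m$children$mid_bn$forward(y, training))
    y <- m$children$project$forward(y, training)
    if (m$skip) y <- ag_add(y, x) else y
  }
  m
}

cn_backbone <- function(spec, sac = NULL) {
  m <- cn_module("backbone")
  wm <- spec$width_mult
  ch <- function(c) make_divisible(c * wm)
  stem_c <- ch(spec$stem_channels)
  m$children$stem <- cn_cba(3L, stem_c, k = 3L, stride = 2L)
  cin <- stem_c
  os <- 2L; dil <- 1L
  blocks <- list(); binfo <- list()
  si <- 0L
  shallow_after <- 2L   # tap after the second bottleneck stage (output stride 4)
  for (i in seq_len(nrow(spec$stages))) {
    st <- spec$stages[i, ]
    cout <- ch(st$c)
    for (j in seq_len(st$n)) {
      s <- if (j == 1L) st$s else 1L
      d <- dil
      if (s == 2L && os >= spec$output_stride) { # convert stride to dilation
        dil <- dil * 2L
        d <- dil
        s <- 1L
      } else if (s == 2L) {
        os <- os * 2L
      }
      si <- si + 1L
      blocks[[si]] <- cn_inverted_residual(cin, cout, st$t, stride = s,
                                           dil = d, sac = sac)
      cin <- cout
    }
    binfo[[i]] <- list(stage = i, out_channels = cin, n_blocks = si)
  }
  m$children$blocks <- cn_sequential(blocks)
  last_c <- ch(spec$last_channels)
  m$children$last <- cn_cba(cin, last_c, k = 1L)
  m$shallow_block <- binfo[[shallow_after]]$n_blocks
  m$shallow_channels <- binfo[[shallow_after]]$out_channels
  m$deep_channels <- last_c
  m$forward <- function(x, training = FALSE) {
    y <- m$children$stem$forward(x, training)
    shallow <- NULL
    bl <- m$children$blocks$children
    for (k in seq_along(bl)) {
      y <- bl[[k]]$forward(y, training)
      if (k == m$shallow_block) shallow <- y
    }
    deep <- m$children$last$forward(y, training)
    list(shallow = shallow, deep = deep)
  }
  m
}

# DenseASPP + strip pooling head. Branch l consumes the concatenation of the
# projected input and all previous branch outputs; horizontal and vertical
# strip-pooled features join the final 1x1 fusion.
cn_dense_aspp_sp <- function(cin, spec = dense_aspp_spec()) {
  m <- cn_module("dense_aspp_sp")
  m$spec <- spec
  m$children$pre <- cn_cba(cin, spec$pre_channels, k = 1L)
  nb <- length(spec$dilations)
  for (l in seq_len(nb)) {
    in_l <- spec$pre_channels + (l - 1L) * spec$growth
    m$children[[paste0("reduce", l)]] <- cn_cba(in_l, spec$reduce_channels, k = 1L)
    m$children[[paste0("dconv", l)]] <-
      cn_cba(spec$reduce_channels, spec$growth, k = 3L, dil = spec$dilations[l])
  }
  fuse_in <- nb * spec$growth
  if (spec$strip_pooling) {
    m$children$strip_h <- cn_cba(spec$pre_channels, spec$growth, k = 1L)
    m$children$strip_v <- cn_cba(spec$pre_channels, spec$growth, k = 1L)
    fuse_in <- fuse_in + 2L * spec$growth
  }
  m$children$fuse <- cn_cba(fuse_in, spec$out_channels, k = 1L)
  m$out_channels <- spec$out_channels
  m$forward <- function(x, training = FALSE) {
    x0 <- m$children$pre$forward(x, training)
    feats <- list(x0)
    outs <- list()
    for (l in seq_along(m$spec$dilations)) {
      inp <- if (length(feats) == 1L) feats[[1]] else ag_concat_c(feats)
      y <- m$children[[paste0("reduce", l)]]$forward(inp, training)
      y <- m$children[[paste0("dconv", l)]]$forward(y, training)
      outs[[l]] <- y
      feats[[length(feats) + 1L]] <- y
    }
    if (m$spec$strip_pooling) {
      W <- dim(ag_value(x0))[2]; H <- dim(ag_value(x0))[1]
      sh <- ag_broadcast_w(
        m$children$strip_h$forward(ag_strip_pool_h(x0), training), W)
      sv <- ag_broadcast_h(
        m$children$strip_v$forward(ag_strip_pool_v(x0), training), H)
      outs <- c(outs, list(sh, sv))
    }
    m$children$fuse$forward(ag_concat_c(outs), training)
  }
  m
}

# Plain atrous pyramid fallback (the "C off" rung): parallel 1x1, three
# dilated 3x3 branches and an image-pooling branch on the projected input.
cn_aspp <- function(cin, out_channels = 256L, branch_channels = 64L,
                    dilations = c(6L, 12L, 18L), pre_channels = 256L) {
  m <- cn_module("aspp")
  m$children$pre <- cn_cba(cin, pre_channels, k = 1L)
  m$children$b0 <- cn_cba(pre_channels, branch_channels, k = 1L)
  for (i in seq_along(dilations)) {
    m$children[[paste0("b", i)]] <-
      cn_cba(pre_channels, branch_channels, k = 3L, dil = dilations[i])
  }
  m$children$pool <- cn_cba(pre_channels, branch_channels, k = 1L)
  fuse_in <- (2L + length(dilations)) * branch_channels
  m$children$fuse <- cn_cba(fuse_in, out_channels, k = 1L)
  m$dilations <- dilations
  m$out_channels <- out_channels
  m$forward <- function(x, training = FALSE) {
    x0 <- m$children$pre$forward(x, training)
    d <- dim(ag_value(x0))
    outs <- list(m$children$b0$forward(x0, training))
    for (i in seq_along(m$dilations)) {
      outs[[i + 1L]] <- m$children[[paste0("b", i)]]$forward(x0, training)
    }
    pooled <- m$children$pool$forward(ag_gap(x0), training)
    outs[[length(outs) + 1L]] <- ag_broadcast_w(ag_broadcast_h(pooled, d[1]), d[2])
    m$children$fuse$forward(ag_concat_c(outs), training)
  }
  m
}

# CBAM: channel attention (shared MLP over average- and max-pooled
# descriptors, sigmoid), then spatial attention (7x7 conv over the
# channel-wise mean/max maps, sigmoid), both multiplicative.
cn_cbam <- function(C, spec = cbam_spec()) {
  m <- cn_module("cbam")
  d <- max(C %/% spec$reduction, 8L)
  m$children$mlp1 <- cn_conv(C, d, k = 1L, bias = TRUE)
  m$children$mlp2 <- cn_conv(d, C, k = 1L, bias = TRUE)
  m$children$spatial <- cn_conv(2L, 1L, k = spec$spatial_kernel, bias = TRUE)
  m$forward <- function(x, training = FALSE) {
    mlp <- function(v) m$children$mlp2$forward(
      ag_relu(m$children$mlp1$forward(v, training)), training)
    mc <- ag_sigmoid(ag_add(mlp(ag_gap(x)), mlp(ag_gmp(x))))
    y <- ag_scale_channel(x, mc)
    sm <- ag_concat_c(list(ag_channel_mean(y), ag_channel_max(y)))
    ms <- ag_sigmoid(m$children$spatial$forward(sm, training))
    ag_scale_spatial(y, ms)
  }
  m
}

# ---- full model -------------------------------------------------------------

#' Build the segmentation model
#'
#' Assembles encoder (backbone with shallow tap at output stride 4 and deep
#' tap at output stride 16), head (DenseASPP+SP or plain pyramid), and decoder
#' (projected shallow features + 4x-upsampled head output, optional CBAM, two
#' 3x3 convolutions, classifier, 4x upsampling to input size). Weight
#' initialization draws from the current RNG state; seed it for reproducible
#' models.
#'
#' @param config a [net_config()].
#' @return a model object (class `cn_model`).
#' @export
build_model <- function(config = net_config()) {
  stopifnot(inherits(config, "net_config"))
  m <- cn_module("model")
  m$config <- config
  m$children$backbone <- cn_backbone(config$backbone, sac = config$sac)
  deep_c <- m$children$backbone$deep_channels
  m$children$head <- if (config$use_dense_aspp) {
    cn_dense_aspp_sp(deep_c, config$head)
  } else {
    cn_aspp(deep_c)
  }
  head_c <- m$children$head$out_channels
  m$children$shallow_proj <- cn_cba(m$children$backbone$shallow_channels,
                                    config$shallow_channels, k = 1L)
  cat_c <- head_c + config$shallow_channels
  if (!is.null(config$cbam)) m$children$cbam <- cn_cbam(cat_c, config$cbam)
  m$children$dec1 <- cn_cba(cat_c, config$decoder_channels, k = 3L)
  m$children$dec2 <- cn_cba(config$decoder_channels, config$decoder_channels, k = 3L)
  m$children$classifier <- cn_conv(config$decoder_channels, config$num_classes,
                                   k = 1L, bias = TRUE)
  m$forward <- function(x, training = FALSE) {
    d <- dim(ag_value(x))
    taps <- m$children$backbone$forward(x, training)
    head <- m$children$head$forward(taps$deep, training)
    sh <- m$children$shallow_proj$forward(taps$shallow, training)
    dsh <- dim(ag_value(sh))
    up <- ag_resize_bilinear(head, dsh[1], dsh[2])
    y <- ag_concat_c(list(sh, up))
    if (!is.null(m$children$cbam)) y <- m$children$cbam$forward(y, training)
    y <- m$children$dec1$forward(y, training)
    y <- m$children$dec2$forward(y, training)
    y <- m$children$classifier$forward(y, training)
    ag_resize_bilinear(y, d[1], d[2])
  }
  m
}

#' Forward pass of the segmentation model
#'
#' @param model a model from [build_model()].
#' @param x input tensor, dim (H, W, 3, N), standardized (see [preprocess()]);
#'   H and W must be divisible by 16.
#' @param training logical; training mode uses batch statistics in batch norm
#'   and records gradients if a tape is active.
#' @return logits array, dim (H, W, num_classes, N).
#' @export
model_forward <- function(model, x, training = FALSE) {
  d <- dim(x)
  if (is.null(d) || length(d) == 3L) {
    dim(x) <- c(d[1], d[2], d[3], 1L)
    d <- dim(x)
  }
  if (d[1] %% 16L != 0L || d[2] %% 16L != 0L) {
    stop(sprintf(paste0("input spatial size %dx%d invalid: height and width ",
                        "must be divisible by 16 (output stride constraint)"),
                 d[1], d[2]), call. = FALSE)
  }
  if (d[3] != 3L) stop("input must have 3 channels", call. = FALSE)
  ag_value(model$forward(x, training))
}

#' Apply a split-attention convolution block to a feature tensor
#'
#' Functional wrapper: builds a freshly initialized block (seeded by the
#' current RNG state) and applies it. Channel count must be divisible by
#' radix * cardinality.
#'
#' @param features tensor (H, W, C, N).
#' @param spec a [sac_spec()].
#' @param stride,dilation convolution stride/dilation.
#' @return tensor of the same spatial size and channel count.
#' @export
sac_block <- function(features, spec = sac_spec(), stride = 1L, dilation = 1L) {
  d <- dim(features)
  C <- d[3]
  if (C %% (spec$radix * spec$cardinality) != 0L) {
    stop("channel count must be divisible by radix * cardinality", call. = FALSE)
  }
  blk <- cn_sac(C, stride = stride, dil = dilation, spec = spec)
  ag_value(blk$forward(features, training = FALSE))
}

#' Apply a DenseASPP + strip-pooling head to deep features
#'
#' Functional wrapper around a freshly initialized head module.
#'
#' @param deep_features tensor (H, W, C, N) at output stride 16.
#' @param spec a [dense_aspp_spec()].
#' @return fused tensor with `spec$out_channels` channels.
#' @export
dense_aspp_sp <- function(deep_features, spec = dense_aspp_spec()) {
  mod <- cn_dense_aspp_sp(dim(deep_features)[3], spec)
  ag_value(mod$forward(deep_features, training = FALSE))
}

#' Apply a CBAM attention block
#'
#' Channel attention first, spatial attention second, both multiplicative.
#'
#' @param features tensor (H, W, C, N).
#' @param spec a [cbam_spec()].
#' @return re-weighted tensor of identical shape.
#' @export
cbam <- function(features, spec = cbam_spec()) {
  mod <- cn_cbam(dim(features)[3], spec)
  ag_value(mod$forward(features, training = FALSE))
}
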