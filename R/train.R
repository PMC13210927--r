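# Desk-scale training loop wiring the network to the combined focal + dice
# loss: Adam (beta1 = 0.9) with decoupled weight decay, cosine-annealed
# learning rate, seeded end to end, with per-epoch train/val loss logging and
# best-by-validation checkpointing.

#' Training configuration
#'
#' @param lr initial learning rate (default 1e-3).
#' @param lr_min cosine-annealing floor (default 1e-5).
#' @param beta1 first-moment decay coefficient (the "momentum factor" of the
#'   adaptive-moment optimizer, default 0.9).
#' @param beta2 second-moment decay coefficient (default 0.999).
#' @param weight_decay decoupled weight-decay coefficient (default 5e-4).
#' @param batch_size mini-batch size (default 8).
#' @param epochs training epochs (default 50).
#' @param scale_lr_by_batch if TRUE, scale `lr` linearly by batch_size / 8
#'   (off by default).
#' @param loss a [loss_config()].
#' @param seed integer seed fixing shuffling and weight initialization.
#' @return object of class `train_config`.
#' @export
train_config <- function(lr = 1e-3, lr_min = 1e-5, beta1 = 0.9, beta2 = 0.999,
                         weight_decay = 5e-4, batch_size = 8L, epochs = 50L,
                         scale_lr_by_batch = FALSE, loss = loss_config(),
                         seed = 1L) {
  stopifnot(lr > 0, batch_size >= 1, epochs >= 0)
  structure(list(lr = lr, lr_min = lr_min, beta1 = beta1, beta2 = beta2,
                 weight_decay = weight_decay,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 scale_lr_by_batch = isTRUE(scale_lr_by_batch),
                 loss = loss, seed = as.integer(seed)),
            class = "train_config")
}

#' Desk-scale network configuration
#'
#' A narrow variant of the full architecture (width multiplier 0.35, slim
#' head and decoder) keeping every structural element — split-attention
#' bottlenecks, dense atrous pyramid with strip pooling, CBAM decoder —
#' while staying trainable on a single CPU at small input sizes. Used for
#' learnability experiments, not accuracy benchmarks.
#'
#' @return a [net_config()].
#' @export
desk_net_config <- function() {
  net_config(width_mult = 0.35, decoder_channels = 64L, shallow_channels = 24L,
             head = dense_aspp_spec(growth = 32L, reduce_channels = 64L,
                                    out_channels = 128L, pre_channels = 128L))
}

adam_state <- function(params) {
  lapply(params, function(p) list(m = array(0, dim = dim(p$value) %||% length(p$value)),
                                  v = array(0, dim = dim(p$value) %||% length(p$value))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

adam_step <- function(params, state, t, lr, beta1, beta2, wd, eps = 1e-8) {
  for (i in seq_along(params)) {
    p <- params[[i]]
    g <- p$grad
    if (is.null(g)) next
    st <- state[[i]]
    st$m <- beta1 * st$m + (1 - beta1) * g
    st$v <- beta2 * st$v + (1 - beta2) * g^2
    mhat <- st$m / (1 - beta1^t)
    vhat <- st$v / (1 - beta2^t)
    p$value <- p$value - lr * (mhat / (sqrt(vhat) + eps) + wd * p$value)
    state[[i]] <- st
  }
  state
}

cosine_lr <- function(epoch, epochs, lr, lr_min) {
  if (epochs <= 1) return(lr)
  lr_min + 0.5 * (lr - lr_min) * (1 + cos(pi * (epoch - 1) / (epochs - 1)))
}

# Stack a list of pairs into batch tensors (H, W, 3, B) / (H, W, B).
stack_pairs <- function(pairs) {
  H <- dim(pairs[[1]]$image)[1]; W <- dim(pairs[[1]]$image)[2]
  B <- length(pairs)
  x <- array(0, dim = c(H, W, 3, B))
  t <- array(0, dim = c(H, W, B))
  for (i in seq_len(B)) {
    x[, , , i] <- pairs[[i]]$image
    t[, , i] <- pairs[[i]]$mask
  }
  list(x = x, t = t)
}

# Loss of a model on stacked pairs (no gradients; eval-mode batch norm).
eval_loss <- function(model, pairs, loss_cfg) {
  b <- stack_pairs(pairs)
  logits <- ag_value(model$forward(b$x, training = FALSE))
  p <- softmax_fg(logits)
  total_loss(p, b$t, loss_cfg)
}

softmax_fg <- function(logits) {
  d <- dim(logits)
  e1 <- exp(logits[, , 1, , drop = FALSE] - pmax(logits[, , 1, , drop = FALSE],
                                                 logits[, , 2, , drop = FALSE]))
  e2 <- exp(logits[, , 2, , drop = FALSE] - pmax(logits[, , 1, , drop = FALSE],
                                                 logits[, , 2, , drop = FALSE]))
  p <- e2 / (e1 + e2)
  array(p, dim = c(d[1], d[2], d[4]))
}

#' Train the segmentation model
#'
#' Seeded loop minimizing the combined focal + dice loss with Adam (decoupled
#' weight decay) and cosine learning-rate annealing. Preprocessed image/mask
#' pairs are expected (`list(image = HxWx3 standardized, mask = HxW binary)`);
#' spatial sizes must be divisible by 16.
#'
#' @param train_set,val_set lists of pairs; `train_set` non-empty.
#' @param net_cfg a [net_config()].
#' @param cfg a [train_config()].
#' @param model optionally, a prebuilt/pretrained model to continue training
#'   (the weight-loading hook).
#' @param verbose print per-epoch losses.
#' @return list with `model` (final weights), `best_model` (deep copy at the
#'   best validation loss), and `manifest` (config snapshot, seed, per-epoch
#'   train/val loss, learning rates).
#' @export
train_model <- function(train_set, val_set = list(), net_cfg = net_config(),
                        cfg = train_config(), model = NULL, verbose = FALSE) {
  if (length(train_set) == 0) stop("train_set must be non-empty", call. = FALSE)
  if (is.null(model)) {
    model <- with_seed(cfg$seed, build_model(net_cfg))
  }
  params <- module_params(model)
  state <- adam_state(params)
  lr0 <- cfg$lr * if (cfg$scale_lr_by_batch) cfg$batch_size / 8 else 1
  hist <- data.frame(epoch = integer(0), train_loss = numeric(0),
                     val_loss = numeric(0), lr = numeric(0))
  best <- list(val = Inf, params = NULL)
  t_global <- 0L
  for (epoch in seq_len(cfg$epochs)) {
    lr <- cosine_lr(epoch, cfg$epochs, lr0, cfg$lr_min)
    ord <- with_seed(cfg$seed + 1000L + epoch, sample.int(length(train_set)))
    batches <- split(ord, ceiling(seq_along(ord) / cfg$batch_size))
    ep_loss <- 0
    for (bi in batches) {
      b <- stack_pairs(train_set[bi])
      ag_tape_begin()
      logits <- model$forward(b$x, training = TRUE)
      probs <- ag_softmax_c(logits)
      lf <- ag_focal_loss_node(probs, b$t, cfg$loss$gamma, cfg$loss$alpha)
      ld <- ag_dice_loss_node(probs, b$t, cfg$loss$eps)
      lt <- ag_add_scalar(lf, ld)
      lval <- ag_value(lt)
      if (!is.finite(lval)) {
        ag_tape_end()
        stop(sprintf("non-finite loss at epoch %d (focal=%g, dice=%g)",
                     epoch, ag_value(lf), ag_value(ld)), call. = FALSE)
      }
      for (p in params) p$grad <- NULL
      ag_backward(lt)
      ag_tape_end()
      t_global <- t_global + 1L
      state <- adam_step(params, state, t_global, lr, cfg$beta1, cfg$beta2,
                         cfg$weight_decay)
      ep_loss <- ep_loss + lval * length(bi)
    }
    ep_loss <- ep_loss / length(train_set)
    vl <- if (length(val_set) > 0) eval_loss(model, val_set, cfg$loss) else NA_real_
    hist <- rbind(hist, data.frame(epoch = epoch, train_loss = ep_loss,
                                   val_loss = vl, lr = lr))
    if (verbose) {
      message(sprintf("epoch %3d  lr %.2e  train %.4f  val %s", epoch, lr,
                      ep_loss, ifelse(is.na(vl), "-", sprintf("%.4f", vl))))
    }
    if (!is.na(vl) && vl < best$val) {
      best$val <- vl
      best$params <- lapply(params, function(p) p$value)
    }
  }
  best_model <- NULL
  if (!is.null(best$params)) {
    best_model <- with_seed(cfg$seed, build_model(net_cfg))
    bp <- module_params(best_model)
    for (i in seq_along(bp)) bp[[i]]$value <- best$params[[i]]
    copy_running_stats(model, best_model)
  }
  list(model = model,
       best_model = best_model %||% model,
       manifest = list(net_config = net_cfg, train_config = cfg,
                       seed = cfg$seed, history = hist,
                       best_val_loss = best$val))
}

copy_running_stats <- function(from, to) {
  walk2 <- function(a, b) {
    if (!is.null(a$running)) {
      b$running$mean <- a$running$mean
      b$running$var <- a$running$var
    }
    for (nm in names(a$children)) walk2(a$children[[nm]], b$children[[nm]])
  }
  walk2(from, to)
  invisible(NULL)
}

#' Predict a binary crop-row mask
#'
#' Eval-mode forward pass followed by per-pixel argmax.
#'
#' @param model a trained model.
#' @param image preprocessed H x W x 3 array (see [preprocess()]).
#' @return binary H x W matrix (1 = crop row).
#' @export
predict_mask <- function(model, image) {
  d <- dim(image)
  logits <- model_forward(model, array(image, dim = c(d[1], d[2], 3, 1)))
  matrix(as.integer(logits[, , 2, 1] > logits[, , 1, 1]), d[1], d[2])
}

#' Save / load a model checkpoint
#'
#' The checkpoint stores the network configuration, all parameter values and
#' batch-norm running statistics.
#'
#' @param model a model.
#' @param path file path.
#' @return `load_checkpoint` returns the rebuilt model.
#' @export
save_checkpoint <- function(model, path) {
  params <- module_params(model)
  stats <- list()
  walk <- function(m, prefix = "") {
    if (!is.null(m$running)) {
      stats[[prefix]] <<- list(mean = m$running$mean, var = m$running$var)
    }
    for (nm in names(m$children)) walk(m$children[[nm]], paste0(prefix, nm, "."))
  }
  walk(model)
  saveRDS(list(config = model$config, values = lapply(params, `[[`, "value"),
               running = stats), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  model <- build_model(ck$config)
  params <- module_params(model)
  stopifnot(length(params) == length(ck$values))
  for (i in seq_along(params)) params[[i]]$value <- ck$values[[i]]
  walk <- function(m, prefix = "") {
    if (!is.null(m$running) && !is.null(ck$running[[prefix]])) {
      m$running$mean <- ck$running[[prefix]]$mean
      m$running$var <- ck$running[[prefix]]$var
    }
    for (nm in names(m$children)) walk(m$children[[nm]], paste0(prefix, nm, "."))
  }
  walk(model)
  model
}

#' Mean forward-pass time per frame
#'
#' Warm-up frames are run first and excluded; the mean of `n_timed`
#' consecutive single-frame forward passes is reported. Hardware-dependent
#' diagnostic only.
#'
#' @param model a model.
#' @param input_size (H, W) of the timed input.
#' @param n_warmup,n_timed warm-up and timed frame counts.
#' @return list(mean_ms, times_ms) with `length(times_ms) == n_timed`.
#' @export
measure_inference_time <- function(model, input_size = c(128L, 128L),
                                   n_warmup = 10L, n_timed = 100L) {
  if (n_timed <= 0) stop("n_timed must be positive (nothing to average)",
                         call. = FALSE)
  x <- array(rnorm(prod(input_size) * 3), dim = c(input_size[1], input_size[2], 3, 1))
  for (i in seq_len(n_warmup)) invisible(model$forward(x, training = FALSE))
  times <- numeric(n_timed)
  for (i in seq_len(n_timed)) {
    t0 <- proc.time()[["elapsed"]]
    invisible(model$forward(x, training = FALSE))
    times[i] <- (proc.time()[["elapsed"]] - t0) * 1000
  }
  list(mean_ms = mean(times), times_ms = times)
}
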