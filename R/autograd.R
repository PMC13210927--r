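# Minimal reverse-mode autodiff over 4-D tensors (H, W, C, N).
#
# A "node" is an environment holding a value, an accumulated gradient, its
# parent nodes and a backward closure. Operations record themselves on the
# active tape in creation order, which is already a topological order for a
# define-by-run graph, so the backward pass is a single reverse sweep.
# When no tape is active the ops compute values only (inference mode).

ag_tape_begin <- function() {
  .cropnav$tape <- new.env(parent = emptyenv())
  .cropnav$tape$nodes <- vector("list", 256L)
  .cropnav$tape$n <- 0L
  invisible(.cropnav$tape)
}

ag_tape_end <- function() {
  .cropnav$tape <- NULL
  invisible(NULL)
}

ag_tape_active <- function() !is.null(.cropnav$tape)

ag_record <- function(node) {
  tape <- .cropnav$tape
  if (is.null(tape)) return(node)
  n <- tape$n + 1L
  if (n > length(tape$nodes)) tape$nodes <- c(tape$nodes, vector("list", length(tape$nodes)))
  tape$nodes[[n]] <- node
  tape$n <- n
  node
}

# Leaf parameter: shared, persistent across steps; optimizer reads $grad.
ag_param <- function(value, name = "") {
  e <- new.env(parent = emptyenv())
  e$value <- value
  e$grad <- NULL
  e$track <- TRUE
  e$name <- name
  class(e) <- "ag_node"
  e
}

ag_is_node <- function(x) inherits(x, "ag_node")

ag_value <- function(x) if (ag_is_node(x)) x$value else x

# Internal op node constructor.
ag_op <- function(value, parents, backfn) {
  if (!ag_tape_active()) return(value)
  e <- new.env(parent = emptyenv())
  e$value <- value
  e$grad <- NULL
  e$track <- TRUE
  e$parents <- parents
  e$backfn <- backfn
  class(e) <- "ag_node"
  ag_record(e)
  e
}

ag_accumulate <- function(node, g) {
  if (!ag_is_node(node) || !isTRUE(node$track)) return(invisible(NULL))
  node$grad <- if (is.null(node$grad)) g else node$grad + g
  invisible(NULL)
}

# Reverse sweep from a scalar loss node.
ag_backward <- function(loss_node) {
  tape <- .cropnav$tape
  if (is.null(tape)) stop("no active tape", call. = FALSE)
  loss_node$grad <- 1
  for (i in rev(seq_len(tape$n))) {
    nd <- tape$nodes[[i]]
    if (is.null(nd$grad) || is.null(nd$backfn)) next
    gs <- nd$backfn(nd$grad)
    for (j in seq_along(nd$parents)) {
      if (!is.null(gs[[j]])) ag_accumulate(nd$parents[[j]], gs[[j]])
    }
    nd$grad <- NULL  # free
  }
  invisible(NULL)
}

# ---- tensor ops -------------------------------------------------------------

ag_conv2d <- function(x, w, b, stride = 1L, pad = 0L, dil = 1L, groups = 1L) {
  xv <- ag_value(x); wv <- ag_value(w)
  bv <- if (is.null(b)) numeric(0) else ag_value(b)
  y <- cpp_conv2d_forward(xv, wv, bv, dim(xv), dim(wv),
                          as.integer(stride), as.integer(pad),
                          as.integer(dil), as.integer(groups))
  parents <- list(x, w, b)
  ag_op(y, parents, function(gy) {
    gr <- cpp_conv2d_backward(xv, wv, gy, dim(xv), dim(wv),
                              as.integer(stride), as.integer(pad),
                              as.integer(dil), as.integer(groups),
                              length(bv) > 0)
    list(gr$gx, gr$gw, if (length(bv) > 0) gr$gb else NULL)
  })
}

ag_resize_bilinear <- function(x, Ho, Wo) {
  xv <- ag_value(x)
  d <- dim(xv)
  y <- cpp_resize_bilinear(xv, d, as.integer(Ho), as.integer(Wo))
  ag_op(y, list(x), function(gy) {
    list(cpp_resize_bilinear_backward(gy, dim(y), d[1], d[2]))
  })
}

ag_relu6 <- function(x) {
  xv <- ag_value(x)
  y <- pmin(pmax(xv, 0), 6); dim(y) <- dim(xv)
  ag_op(y, list(x), function(gy) list(gy * (xv > 0 & xv < 6)))
}

ag_relu <- function(x) {
  xv <- ag_value(x)
  y <- pmax(xv, 0); dim(y) <- dim(xv)
  ag_op(y, list(x), function(gy) list(gy * (xv > 0)))
}

ag_sigmoid <- function(x) {
  xv <- ag_value(x)
  y <- 1 / (1 + exp(-xv)); dim(y) <- dim(xv)
  ag_op(y, list(x), function(gy) list(gy * y * (1 - y)))
}

ag_add <- function(a, b) {
  av <- ag_value(a); bv <- ag_value(b)
  ag_op(av + bv, list(a, b), function(gy) list(gy, gy))
}

# Batch norm over (H, W, N) per channel. `par` holds gamma/beta param nodes and
# running-stat buffers; in training mode batch statistics are used and running
# stats updated in place.
ag_batchnorm <- function(x, gamma, beta, running, training,
                         momentum = 0.1, eps = 1e-5) {
  xv <- ag_value(x)
  d <- dim(xv); H <- d[1]; W <- d[2]; C <- d[3]; N <- d[4]
  m <- H * W * N
  M <- matrix(xv, nrow = H * W)            # (H*W) x (C*N)
  if (training) {
    cm <- colMeans(M)                       # length C*N
    mu <- rowMeans(matrix(cm, nrow = C))    # per channel
    cm2 <- colMeans(M * M)
    ex2 <- rowMeans(matrix(cm2, nrow = C))
    varb <- ex2 - mu^2                      # biased
    running$mean <- (1 - momentum) * running$mean + momentum * mu
    unb <- if (m > 1) varb * m / (m - 1) else varb
    running$var <- (1 - momentum) * running$var + momentum * unb
  } else {
    mu <- running$mean
    varb <- running$var
  }
  gv <- ag_value(gamma); bv <- ag_value(beta)
  inv <- 1 / sqrt(varb + eps)
  mu_full <- rep(rep(mu, each = H * W), times = N)
  inv_full <- rep(rep(inv, each = H * W), times = N)
  xhat <- (as.vector(xv) - mu_full) * inv_full
  yv <- xhat * rep(rep(gv, each = H * W), times = N) +
    rep(rep(bv, each = H * W), times = N)
  dim(yv) <- d
  ag_op(yv, list(x, gamma, beta), function(gy) {
    gyv <- as.vector(gy)
    Mg <- matrix(gyv, nrow = H * W)
    dbeta <- rowSums(matrix(colSums(Mg), nrow = C))
    Mgx <- matrix(gyv * xhat, nrow = H * W)
    dgamma <- rowSums(matrix(colSums(Mgx), nrow = C))
    if (training) {
      g_full <- rep(rep(gv, each = H * W), times = N)
      mean_gy <- rep(rep(dbeta / m, each = H * W), times = N)
      mean_gyx <- rep(rep(dgamma / m, each = H * W), times = N)
      dx <- g_full * inv_full * (gyv - mean_gy - xhat * mean_gyx)
    } else {
      dx <- rep(rep(gv * inv, each = H * W), times = N) * gyv
    }
    dim(dx) <- d
    list(dx, dgamma, dbeta)
  })
}

ag_concat_c <- function(xs) {
  vals <- lapply(xs, ag_value)
  d1 <- dim(vals[[1]])
  Cs <- vapply(vals, function(v) dim(v)[3], numeric(1))
  H <- d1[1]; W <- d1[2]; N <- d1[4]
  Ctot <- sum(Cs)
  y <- array(0, dim = c(H, W, Ctot, N))
  off <- 0L
  for (i in seq_along(vals)) {
    y[, , (off + 1L):(off + Cs[i]), ] <- vals[[i]]
    off <- off + Cs[i]
  }
  ag_op(y, xs, function(gy) {
    out <- vector("list", length(xs))
    off <- 0L
    for (i in seq_along(xs)) {
      g <- gy[, , (off + 1L):(off + Cs[i]), , drop = FALSE]
      dim(g) <- c(H, W, Cs[i], N)
      out[[i]] <- g
      off <- off + Cs[i]
    }
    out
  })
}

# Global average pool over H, W -> (1, 1, C, N)
ag_gap <- function(x) {
  xv <- ag_value(x)
  d <- dim(xv); H <- d[1]; W <- d[2]; C <- d[3]; N <- d[4]
  y <- array(colMeans(matrix(xv, nrow = H * W)), dim = c(1, 1, C, N))
  ag_op(y, list(x), function(gy) {
    g <- rep(as.vector(gy) / (H * W), each = H * W)
    dim(g) <- d
    list(g)
  })
}

# Global max pool over H, W -> (1, 1, C, N); subgradient to first argmax.
ag_gmp <- function(x) {
  xv <- ag_value(x)
  d <- dim(xv); H <- d[1]; W <- d[2]; C <- d[3]; N <- d[4]
  M <- matrix(xv, nrow = H * W)
  idx <- max.col(t(M), ties.method = "first")   # argmax per column
  y <- array(M[cbind(idx, seq_len(C * N))], dim = c(1, 1, C, N))
  ag_op(y, list(x), function(gy) {
    g <- array(0, dim = d)
    gm <- matrix(g, nrow = H * W)
    gm[cbind(idx, seq_len(C * N))] <- as.vector(gy)
    dim(gm) <- d
    list(gm)
  })
}

# Multiply x (H,W,C,N) by channel weights s (1,1,C,N)
ag_scale_channel <- function(x, s) {
  xv <- ag_value(x); sv <- ag_value(s)
  d <- dim(xv); H <- d[1]; W <- d[2]; C <- d[3]; N <- d[4]
  sfull <- rep(as.vector(sv), each = H * W)
  y <- xv * sfull; dim(y) <- d
  ag_op(y, list(x, s), function(gy) {
    dx <- gy * sfull; dim(dx) <- d
    ds <- array(colSums(matrix(gy * as.vector(xv), nrow = H * W)),
                dim = c(1, 1, C, N))
    list(dx, ds)
  })
}

# Multiply x (H,W,C,N) by spatial map s (H,W,1,N)
ag_scale_spatial <- function(x, s) {
  xv <- ag_value(x); sv <- ag_value(s)
  d <- dim(xv); H <- d[1]; W <- d[2]; C <- d[3]; N <- d[4]
  sidx <- rep(seq_len(H * W), times = C) +
    rep((seq_len(N) - 1L) * H * W, each = H * W * C)
  sfull <- as.vector(sv)[sidx]
  y <- xv * sfull; dim(y) <- d
  ag_op(y, list(x, s), function(gy) {
    dx <- gy * sfull; dim(dx) <- d
    prod <- as.vector(gy) * as.vector(xv)
    dim(prod) <- c(H * W, C, N)
    ds <- apply(prod, c(1, 3), sum)
    dim(ds) <- c(H, W, 1, N)
    list(dx, ds)
  })
}

# Mean over channels -> (H,W,1,N) and max over channels
ag_channel_mean <- function(x) {
  xv <- ag_value(x)
  d <- dim(xv); H <- d[1]; W <- d[2]; C <- d[3]; N <- d[4]
  xm <- xv; dim(xm) <- c(H * W, C, N)
  y <- apply(xm, c(1, 3), mean)
  dim(y) <- c(H, W, 1, N)
  ag_op(y, list(x), function(gy) {
    sidx <- rep(seq_len(H * W), times = C) +
      rep((seq_len(N) - 1L) * H * W, each = H * W * C)
    g <- as.vector(gy)[sidx] / C
    dim(g) <- d
    list(g)
  })
}

ag_channel_max <- function(x) {
  xv <- ag_value(x)
  d <- dim(xv); H <- d[1]; W <- d[2]; C <- d[3]; N <- d[4]
  xm <- xv; dim(xm) <- c(H * W, C, N)
  amax <- apply(xm, c(1, 3), which.max)
  y <- apply(xm, c(1, 3), max)
  dim(y) <- c(H, W, 1, N)
  ag_op(y, list(x), function(gy) {
    g <- array(0, dim = c(H * W, C, N))
    for (n in seq_len(N)) {
      g[cbind(seq_len(H * W), amax[, n], n)] <- as.vector(gy[, , 1, n])
    }
    dim(g) <- d
    list(g)
  })
}

# Strip pooling: mean over width -> (H,1,C,N); mean over height -> (1,W,C,N)
ag_strip_pool_h <- function(x) {
  xv <- ag_value(x)
  d <- dim(xv); H <- d[1]; W <- d[2]; C <- d[3]; N <- d[4]
  xm <- xv; dim(xm) <- c(H, W, C * N)
  y <- apply(xm, c(1, 3), mean)
  dim(y) <- c(H, 1, C, N)
  ag_op(y, list(x), function(gy) {
    g <- array(rep(as.vector(gy) / W, times = 1), dim = c(H, C * N))
    gfull <- array(0, dim = c(H, W, C * N))
    for (w in seq_len(W)) gfull[, w, ] <- g
    dim(gfull) <- d
    list(gfull)
  })
}

ag_strip_pool_v <- function(x) {
  xv <- ag_value(x)
  d <- dim(xv); H <- d[1]; W <- d[2]; C <- d[3]; N <- d[4]
  y <- colMeans(xv)                       # dims (W, C, N)
  dim(y) <- c(1, W, C, N)
  ag_op(y, list(x), function(gy) {
    g <- rep(as.vector(gy) / H, each = H)
    dim(g) <- d
    list(g)
  })
}

# Broadcast (H,1,C,N) across width W, or (1,W,C,N) across height H
ag_broadcast_w <- function(x, W) {
  xv <- ag_value(x)
  d <- dim(xv); H <- d[1]; C <- d[3]; N <- d[4]
  y <- array(0, dim = c(H, W, C, N))
  for (w in seq_len(W)) y[, w, , ] <- xv[, 1, , ]
  ag_op(y, list(x), function(gy) {
    gm <- gy; dim(gm) <- c(H, W, C * N)
    g <- apply(gm, c(1, 3), sum)
    dim(g) <- d
    list(g)
  })
}

ag_broadcast_h <- function(x, H) {
  xv <- ag_value(x)
  d <- dim(xv); W <- d[2]; C <- d[3]; N <- d[4]
  y <- rep(as.vector(xv), each = H)
  dim(y) <- c(H, W, C, N)
  ag_op(y, list(x), function(gy) {
    g <- colSums(gy)
    dim(g) <- d
    list(g)
  })
}

# Softmax across radix groups: x has C*radix channels ordered
# [split1 chans, split2 chans, ...]; softmax over the radix axis per channel.
ag_radix_softmax <- function(x, radix) {
  xv <- ag_value(x)
  d <- dim(xv); C <- d[3] / radix; N <- d[4]
  stopifnot(d[1] == 1, d[2] == 1)
  av <- array(xv, dim = c(C, radix, N))
  mx <- apply(av, c(1, 3), max)
  for (k in seq_len(radix)) av[, k, ] <- av[, k, ] - mx
  e <- exp(av)
  s <- apply(e, c(1, 3), sum)
  y <- e
  for (k in seq_len(radix)) y[, k, ] <- e[, k, ] / s
  yv <- y; dim(yv) <- d
  ag_op(yv, list(x), function(gy) {
    gya <- array(gy, dim = c(C, radix, N))
    dot <- apply(gya * y, c(1, 3), sum)
    g <- y
    for (k in seq_len(radix)) g[, k, ] <- y[, k, ] * (gya[, k, ] - dot)
    dim(g) <- d
    list(g)
  })
}

# Channel softmax over the class axis (for 2-class logits -> probabilities)
ag_softmax_c <- function(x) {
  xv <- ag_value(x)
  d <- dim(xv); H <- d[1]; W <- d[2]; C <- d[3]; N <- d[4]
  a <- xv; dim(a) <- c(H * W, C, N)
  mx <- apply(a, c(1, 3), max)
  for (k in seq_len(C)) a[, k, ] <- a[, k, ] - mx
  e <- exp(a)
  s <- apply(e, c(1, 3), sum)
  p <- e
  for (k in seq_len(C)) p[, k, ] <- e[, k, ] / s
  pv <- p; dim(pv) <- d
  ag_op(pv, list(x), function(gy) {
    gya <- gy; dim(gya) <- c(H * W, C, N)
    dot <- apply(gya * p, c(1, 3), sum)
    g <- p
    for (k in seq_len(C)) g[, k, ] <- p[, k, ] * (gya[, k, ] - dot)
    dim(g) <- d
    list(g)
  })
}

# ---- loss nodes -------------------------------------------------------------
# probs: (H,W,2,N) class probabilities (channel 1 = background, 2 = foreground)
# target: (H,W,N) or (H,W,1,N) binary foreground mask.

ag_focal_loss_node <- function(probs, target, gamma, alpha) {
  pv <- ag_value(probs)
  d <- dim(pv); H <- d[1]; W <- d[2]; N <- d[4]
  tv <- array(as.vector(ag_value(target)), dim = c(H, W, N))
  pt <- ifelse(tv == 1, pv[, , 2, , drop = TRUE], pv[, , 1, , drop = TRUE])
  dim(pt) <- c(H, W, N)
  at <- ifelse(tv == 1, alpha, 1 - alpha)
  ptc <- clamp(pt, 1e-7, 1 - 1e-7)
  npix <- H * W * N
  loss <- sum(-at * (1 - ptc)^gamma * log(ptc)) / npix
  ag_op(loss, list(probs), function(gy) {
    # d/dp_t of -a(1-p)^g log p  =  a*g*(1-p)^(g-1)*log p - a*(1-p)^g / p
    if (gamma == 0) {
      dpt <- -at / ptc
    } else {
      dpt <- at * gamma * (1 - ptc)^(gamma - 1) * log(ptc) - at * (1 - ptc)^gamma / ptc
    }
    dpt <- dpt / npix * gy
    g <- array(0, dim = d)
    fg <- tv == 1
    gb <- ifelse(fg, 0, dpt); dim(gb) <- c(H, W, N)
    gf <- ifelse(fg, dpt, 0); dim(gf) <- c(H, W, N)
    g[, , 1, ] <- gb
    g[, , 2, ] <- gf
    list(g)
  })
}

ag_dice_loss_node <- function(probs, target, eps = 1e-6) {
  pv <- ag_value(probs)
  d <- dim(pv); H <- d[1]; W <- d[2]; N <- d[4]
  tv <- array(as.vector(ag_value(target)), dim = c(H, W, N))
  pf <- pv[, , 2, , drop = TRUE]; dim(pf) <- c(H, W, N)
  inter <- sum(pf * tv)
  denom <- sum(pf) + sum(tv)
  loss <- 1 - (2 * inter + eps) / (denom + eps)
  ag_op(loss, list(probs), function(gy) {
    # dL/dp_i = -(2 t_i (denom+eps) - (2 inter + eps)) / (denom+eps)^2
    dpf <- -(2 * tv * (denom + eps) - (2 * inter + eps)) / (denom + eps)^2
    g <- array(0, dim = d)
    g[, , 2, ] <- dpf * gy
    list(g)
  })
}

ag_add_scalar <- function(a, b) {
  ag_op(ag_value(a) + ag_value(b), list(a, b), function(gy) list(gy, gy))
}
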