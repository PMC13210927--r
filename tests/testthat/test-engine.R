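# The tensor/autodiff engine: C++ kernels against independent oracles and
# finite-difference gradient checks of every differentiable op the network
# uses.

cpp_fwd <- cropnav:::cpp_conv2d_forward
cpp_bwd <- cropnav:::cpp_conv2d_backward

test_that("convolution kernel matches a direct-summation oracle", {
  set.seed(11)
  cases <- list(
    list(H = 7, W = 6, C = 4, N = 2, k = 3, Cout = 6, stride = 2, pad = 1,
         dil = 1, groups = 2),
    list(H = 9, W = 9, C = 3, N = 1, k = 3, Cout = 5, stride = 1, pad = 2,
         dil = 2, groups = 1),
    list(H = 8, W = 8, C = 6, N = 2, k = 3, Cout = 6, stride = 1, pad = 1,
         dil = 1, groups = 6),   # depthwise fast path
    list(H = 5, W = 7, C = 4, N = 1, k = 1, Cout = 8, stride = 1, pad = 0,
         dil = 1, groups = 1)
  )
  for (cs in cases) {
    x <- array(rnorm(cs$H * cs$W * cs$C * cs$N), c(cs$H, cs$W, cs$C, cs$N))
    w <- array(rnorm(cs$k^2 * (cs$C / cs$groups) * cs$Cout),
               c(cs$k, cs$k, cs$C / cs$groups, cs$Cout))
    b <- rnorm(cs$Cout)
    got <- cpp_fwd(x, w, b, dim(x), dim(w), cs$stride, cs$pad, cs$dil, cs$groups)
    want <- naive_conv2d(x, w, b, cs$stride, cs$pad, cs$dil, cs$groups)
    expect_equal(as.vector(got), as.vector(want), tolerance = 1e-12)
  }
})

test_that("convolution backward agrees with finite differences", {
  set.seed(12)
  for (groups in c(1L, 2L, 4L)) {   # 4 = depthwise here
    x <- array(rnorm(6 * 5 * 4 * 2), c(6, 5, 4, 2))
    w <- array(rnorm(9 * (4 / groups) * 4), c(3, 3, 4 / groups, 4))
    b <- rnorm(4)
    y <- cpp_fwd(x, w, b, dim(x), dim(w), 1L, 1L, 1L, groups)
    gy <- array(rnorm(length(y)), dim(y))
    gr <- cpp_bwd(x, w, gy, dim(x), dim(w), 1L, 1L, 1L, groups, TRUE)
    eps <- 1e-6
    for (i in sample(length(x), 10)) {
      xp <- x; xp[i] <- xp[i] + eps
      xm <- x; xm[i] <- xm[i] - eps
      fd <- (sum(cpp_fwd(xp, w, b, dim(x), dim(w), 1L, 1L, 1L, groups) * gy) -
             sum(cpp_fwd(xm, w, b, dim(x), dim(w), 1L, 1L, 1L, groups) * gy)) /
        (2 * eps)
      expect_equal(gr$gx[i], fd, tolerance = 1e-5)
    }
    for (i in sample(length(w), 10)) {
      wp <- w; wp[i] <- wp[i] + eps
      wm <- w; wm[i] <- wm[i] - eps
      fd <- (sum(cpp_fwd(x, wp, b, dim(x), dim(w), 1L, 1L, 1L, groups) * gy) -
             sum(cpp_fwd(x, wm, b, dim(x), dim(w), 1L, 1L, 1L, groups) * gy)) /
        (2 * eps)
      expect_equal(gr$gw[i], fd, tolerance = 1e-5)
    }
    expect_equal(gr$gb, colSums(matrix(aperm(gy, c(1, 2, 4, 3)),
                                       ncol = dim(y)[3])),
                 tolerance = 1e-10)
  }
})

test_that("bilinear resize matches a hand-computed oracle and is adjoint-consistent", {
  # 2x2 checkerboard upscaled to 4x4: half-pixel centers place the interior
  # samples 1/4 of the way between source pixels
  x <- array(c(0, 255, 255, 0), c(2, 2, 1, 1))
  y <- cropnav:::cpp_resize_bilinear(x, dim(x), 4L, 4L)
  # independent oracle: src = (i + 0.5)/2 - 0.5 for i = 0..3 -> -0.25,.25,.75,1.25
  src <- pmin(pmax((0:3 + 0.5) / 2 - 0.5, 0), 1)
  want <- outer(src, src, function(sy, sx) {
    (1 - sy) * ((1 - sx) * 0 + sx * 255) + sy * ((1 - sx) * 255 + sx * 0)
  })
  expect_equal(y[, , 1, 1], want, tolerance = 1e-12)

  set.seed(13)
  a <- array(rnorm(8 * 6 * 2), c(8, 6, 2, 1))
  g <- array(rnorm(12 * 10 * 2), c(12, 10, 2, 1))
  lhs <- sum(cropnav:::cpp_resize_bilinear(a, dim(a), 12L, 10L) * g)
  rhs <- sum(a * cropnav:::cpp_resize_bilinear_backward(g, dim(g), 8L, 6L))
  expect_equal(lhs, rhs, tolerance = 1e-10)
})

fd_check_unary <- function(op, x, tol = 1e-5, npick = 8) {
  ag_tape_begin <- cropnav:::ag_tape_begin
  ag_tape_begin()
  xn <- cropnav:::ag_param(x)
  y <- op(xn)
  gy <- array(rnorm(length(cropnav:::ag_value(y))), dim(cropnav:::ag_value(y)))
  L <- cropnav:::ag_op(sum(cropnav:::ag_value(y) * gy), list(y),
                       function(g) list(g * gy))
  cropnav:::ag_backward(L)
  cropnav:::ag_tape_end()
  eps <- 1e-6
  for (i in sample(length(x), min(npick, length(x)))) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    fd <- (sum(cropnav:::ag_value(op(xp)) * gy) -
           sum(cropnav:::ag_value(op(xm)) * gy)) / (2 * eps)
    expect_equal(xn$grad[i], fd, tolerance = tol)
  }
}

test_that("autodiff ops pass finite-difference checks", {
  set.seed(14)
  x <- array(rnorm(5 * 4 * 6 * 2), c(5, 4, 6, 2))
  fd_check_unary(cropnav:::ag_sigmoid, x)
  fd_check_unary(cropnav:::ag_relu6, x + 3)       # away from the kinks
  fd_check_unary(cropnav:::ag_gap, x)
  fd_check_unary(cropnav:::ag_gmp, x)
  fd_check_unary(cropnav:::ag_channel_mean, x)
  fd_check_unary(cropnav:::ag_channel_max, x)
  fd_check_unary(cropnav:::ag_strip_pool_h, x)
  fd_check_unary(cropnav:::ag_strip_pool_v, x)
  fd_check_unary(function(v) cropnav:::ag_softmax_c(v), x)
  xr <- array(rnorm(1 * 1 * 8 * 2), c(1, 1, 8, 2))
  fd_check_unary(function(v) cropnav:::ag_radix_softmax(v, 2L), xr)
})

test_that("radix softmax weights sum to one across splits", {
  set.seed(15)
  x <- array(rnorm(1 * 1 * 12 * 3), c(1, 1, 12, 3))
  y <- cropnav:::ag_radix_softmax(x, 2L)
  s <- y[, , 1:6, , drop = FALSE] + y[, , 7:12, , drop = FALSE]
  expect_equal(as.vector(s), rep(1, 18), tolerance = 1e-12)
})

test_that("batch norm training mode normalizes and matches finite differences", {
  set.seed(16)
  x <- array(rnorm(6 * 5 * 3 * 4, mean = 2, sd = 3), c(6, 5, 3, 4))
  run <- new.env(); run$mean <- numeric(3); run$var <- rep(1, 3)
  g <- cropnav:::ag_param(rep(1, 3)); b <- cropnav:::ag_param(numeric(3))
  y <- cropnav:::ag_batchnorm(x, g, b, run, training = TRUE)
  yv <- cropnav:::ag_value(y)
  for (c in 1:3) {
    expect_equal(mean(yv[, , c, ]), 0, tolerance = 1e-10)
    expect_equal(sd(as.vector(yv[, , c, ])) * sqrt(119 / 120), 1,
                 tolerance = 1e-4)
  }
  run2 <- new.env(); run2$mean <- numeric(3); run2$var <- rep(1, 3)
  fd_check_unary(function(v) {
    r <- new.env(); r$mean <- numeric(3); r$var <- rep(1, 3)
    cropnav:::ag_batchnorm(v, g, b, r, training = TRUE)
  }, x, tol = 1e-4)
})
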