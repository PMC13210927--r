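# Architecture contracts: shapes, ablation toggles, attention algebra,
# parameter bookkeeping.

test_that("forward preserves spatial size and enforces the stride constraint", {
  set.seed(20)
  m <- build_model(net_config(width_mult = 0.35))
  x <- array(rnorm(64 * 64 * 3 * 1), c(64, 64, 3, 1))
  y <- model_forward(m, x)
  expect_equal(dim(y), c(64L, 64L, 2L, 1L))
  expect_true(all(is.finite(y)))
  expect_error(model_forward(m, array(0, c(50, 50, 3, 1))), "divisible by 16")
})

test_that("eval-mode forward is deterministic and batch-consistent", {
  set.seed(21)
  m <- build_model(net_config(width_mult = 0.35))
  x1 <- array(rnorm(32 * 32 * 3), c(32, 32, 3, 1))
  xb <- array(c(x1, x1), c(32, 32, 3, 2))
  y <- model_forward(m, xb)
  expect_identical(y[, , , 1], y[, , , 2])
  expect_identical(model_forward(m, xb), y)
})

test_that("split attention with radix 1 degenerates to its single conv path", {
  set.seed(22)
  blk <- cropnav:::cn_sac(8L, spec = sac_spec(radix = 1L))
  x <- array(rnorm(10 * 10 * 8), c(10, 10, 8, 1))
  y <- cropnav:::ag_value(blk$forward(x))
  direct <- cropnav:::ag_value(blk$children$split1$forward(x))
  expect_equal(y, direct, tolerance = 1e-12)
})

test_that("zero input makes the split-attention output zero with attention from biases", {
  set.seed(23)
  blk <- cropnav:::cn_sac(4L, spec = sac_spec(radix = 2L))
  x <- array(0, c(6, 6, 4, 1))
  y <- cropnav:::ag_value(blk$forward(x))
  expect_equal(max(abs(y)), 0)
  # hand-stepped attention: splits are 0 (no conv bias), pooled descriptor 0,
  # logits = W2 %*% relu(b1) + b2, softmax per channel across the two splits
  b1 <- blk$children$fc1$params$b$value
  z <- pmax(b1, 0)
  W2 <- blk$children$fc2$params$w$value   # (1,1,d,8)
  b2 <- blk$children$fc2$params$b$value
  logits <- sapply(1:8, function(co) sum(W2[1, 1, , co] * z) + b2[co])
  att_manual <- sapply(1:4, function(c) {
    e <- exp(c(logits[c], logits[c + 4]) - max(logits[c], logits[c + 4]))
    e / sum(e)
  })
  att_pkg <- cropnav:::ag_value(cropnav:::ag_radix_softmax(
    array(logits, c(1, 1, 8, 1)), 2L))
  expect_equal(as.vector(att_pkg), as.vector(t(att_manual)), tolerance = 1e-12)
})

test_that("dense pyramid branch wiring and strip pooling identities hold", {
  spec <- dense_aspp_spec(growth = 16L, reduce_channels = 32L,
                          out_channels = 48L, pre_channels = 40L)
  set.seed(24)
  mod <- cropnav:::cn_dense_aspp_sp(20L, spec)
  # branch l consumes pre_channels + (l-1) * growth channels
  for (l in seq_along(spec$dilations)) {
    expect_equal(dim(mod$children[[paste0("reduce", l)]]$children$conv$params$w$value)[3],
                 40L + (l - 1L) * 16L)
  }
  x <- array(rnorm(16 * 16 * 20), c(16, 16, 20, 1))
  y <- mod$forward(x)
  expect_equal(dim(cropnav:::ag_value(y)), c(16L, 16L, 48L, 1L))

  # horizontal strip pooling of a row-constant map reproduces the map
  rc <- array(rep(rnorm(8), times = 8), c(8, 8, 1, 1))  # constant along rows
  pooled <- cropnav:::ag_value(cropnav:::ag_strip_pool_h(rc))
  back <- cropnav:::ag_value(cropnav:::ag_broadcast_w(pooled, 8L))
  expect_equal(back, rc, tolerance = 1e-12)
})

test_that("CBAM preserves shape, halves twice at zero logits, and pools degenerately", {
  set.seed(25)
  mod <- cropnav:::cn_cbam(6L, cbam_spec(reduction = 2L))
  x <- array(rnorm(12 * 12 * 6), c(12, 12, 6, 1))
  y <- cropnav:::ag_value(mod$forward(x))
  expect_equal(dim(y), dim(x))

  # zero all attention weights -> both gates are sigmoid(0) = 0.5
  for (nm in c("mlp1", "mlp2", "spatial")) {
    mod$children[[nm]]$params$w$value[] <- 0
    mod$children[[nm]]$params$b$value[] <- 0
  }
  y0 <- cropnav:::ag_value(mod$forward(x))
  expect_equal(y0, 0.25 * x, tolerance = 1e-12)

  # spatially constant input: AvgPool(F) = MaxPool(F), so the channel gate is
  # Sigmoid(2 * MLP(v)); verified against an independent dense-layer trace
  set.seed(26)
  mod2 <- cropnav:::cn_cbam(4L, cbam_spec(reduction = 2L))
  v <- rnorm(4)
  xc <- array(rep(v, each = 25), c(5, 5, 4, 1))
  W1 <- mod2$children$mlp1$params$w$value; b1 <- mod2$children$mlp1$params$b$value
  W2 <- mod2$children$mlp2$params$w$value; b2 <- mod2$children$mlp2$params$b$value
  mlp_v <- sapply(seq_along(b2), function(co)
    sum(W2[1, 1, , co] * pmax(sapply(seq_along(b1), function(d)
      sum(W1[1, 1, , d] * v) + b1[d]), 0)) + b2[co])
  mc_manual <- 1 / (1 + exp(-2 * mlp_v))
  yc <- cropnav:::ag_value(mod2$forward(xc))
  # recover the channel gate from the output at the spatial-attention level:
  # output = ms * mc * v; ms is constant over space here, so ratio to v gives
  # ms * mc; divide out the (shared) spatial gate via a second channel
  ratio <- yc[1, 1, , 1] / v
  expect_equal(ratio / ratio[1], mc_manual / mc_manual[1], tolerance = 1e-10)
})

test_that("parameter counts follow closed forms and monotone ablation ordering", {
  conv <- cropnav:::cn_conv(3L, 8L, k = 1L, bias = TRUE)
  expect_equal(count_parameters(conv), 3 * 8 + 8)

  set.seed(27)
  counts <- sapply(c("A", "A+B", "A+B+C", "A+B+C+D"), function(v)
    count_parameters(build_model(net_config(variant = v))))
  expect_true(all(diff(counts) > 0))

  # toggling CBAM off removes exactly the CBAM block's own parameters
  full <- build_model(net_config())
  no_d <- build_model(net_config(variant = "A+B+C"))
  cbam_params <- count_parameters(full$children$cbam)
  expect_equal(count_parameters(full) - count_parameters(no_d), cbam_params)

  # width multiplier monotonicity
  set.seed(28)
  expect_lt(count_parameters(build_model(net_config(width_mult = 0.5))),
            count_parameters(build_model(net_config(width_mult = 1.0))))
})

test_that("functional block wrappers keep their shape contracts", {
  set.seed(29)
  x <- array(rnorm(8 * 8 * 8), c(8, 8, 8, 1))
  expect_equal(dim(sac_block(x)), dim(x))
  expect_error(sac_block(array(0, c(4, 4, 3, 1))), "divisible")
  y <- dense_aspp_sp(x, dense_aspp_spec(growth = 8L, reduce_channels = 16L,
                                        out_channels = 24L, pre_channels = 16L))
  expect_equal(dim(y), c(8L, 8L, 24L, 1L))
  expect_equal(dim(cbam(x, cbam_spec(reduction = 2L))), dim(x))
})
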