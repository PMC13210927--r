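# Focal + dice loss and the confusion-matrix metric suite.

test_that("focal loss matches hand arithmetic and its limits", {
  # single pixel, p_t = 0.6, gamma = 2, alpha_t = 0.25
  p <- array(0.6, c(1, 1)); t <- array(1, c(1, 1))
  expect_equal(focal_loss(p, t, loss_config(gamma = 2, alpha = 0.25)),
               0.25 * 0.16 * -log(0.6), tolerance = 1e-12)
  # gamma = 0, alpha = 0.5 -> half the mean cross-entropy
  set.seed(1)
  p <- matrix(runif(64, 0.05, 0.95), 8, 8)
  t <- matrix(rbinom(64, 1, 0.5), 8, 8)
  ce <- mean(-(t * log(p) + (1 - t) * log(1 - p)))
  expect_equal(focal_loss(p, t, loss_config(gamma = 0, alpha = 0.5)),
               0.5 * ce, tolerance = 1e-12)
  # perfect prediction -> 0
  expect_equal(focal_loss(t, t), 0, tolerance = 1e-9)
  expect_error(focal_loss(p * 3, t), "probabilities")
})

test_that("per-pixel focal term is non-increasing in p_t", {
  cfg <- loss_config()
  pt <- seq(0.01, 0.99, by = 0.01)
  term <- sapply(pt, function(q) focal_loss(array(q, c(1, 1)), array(1, c(1, 1)), cfg))
  expect_true(all(diff(term) <= 1e-12))
})

test_that("dice loss closed forms hold", {
  t <- matrix(c(1, 1, 0, 0), 2, 2)
  expect_equal(dice_loss(t, t), 0, tolerance = 1e-6)
  disjoint <- 1 - t
  expect_equal(dice_loss(disjoint, t), 1, tolerance = 1e-5)
  p <- matrix(0.5, 4, 4)
  th <- matrix(rep(c(1, 0), 8), 4, 4)   # half the pixels foreground
  expect_equal(dice_loss(p, th), 0.5, tolerance = 1e-6)
})

test_that("total loss is the sum of its parts and its gradient passes FD", {
  set.seed(2)
  p <- matrix(runif(16, 0.1, 0.9), 4, 4)
  t <- matrix(rbinom(16, 1, 0.4), 4, 4)
  cfg <- loss_config()
  expect_equal(total_loss(p, t, cfg),
               focal_loss(p, t, cfg) + dice_loss(p, t, cfg), tolerance = 1e-14)
  expect_equal(total_loss(t, t, cfg), 0, tolerance = 1e-5)

  g_total <- loss_gradient(p, t, cfg)
  g_sum <- loss_gradient(p, t, cfg, "focal") + loss_gradient(p, t, cfg, "dice")
  expect_equal(g_total, g_sum, tolerance = 1e-14)
  eps <- 1e-6
  for (i in seq_len(16)) {
    pp <- p; pp[i] <- pp[i] + eps
    pm <- p; pm[i] <- pm[i] - eps
    fd <- (total_loss(pp, t, cfg) - total_loss(pm, t, cfg)) / (2 * eps)
    expect_equal(g_total[i], fd, tolerance = 1e-4)
  }
})

test_that("confusion counts match an exhaustive per-pixel loop", {
  set.seed(3)
  pred <- matrix(rbinom(256, 1, 0.5), 16, 16)
  true <- matrix(rbinom(256, 1, 0.3), 16, 16)
  cm <- confusion(pred, true)
  tp <- fp <- fn <- tn <- 0
  for (i in 1:16) for (j in 1:16) {
    if (pred[i, j] == 1 && true[i, j] == 1) tp <- tp + 1
    if (pred[i, j] == 1 && true[i, j] == 0) fp <- fp + 1
    if (pred[i, j] == 0 && true[i, j] == 1) fn <- fn + 1
    if (pred[i, j] == 0 && true[i, j] == 0) tn <- tn + 1
  }
  expect_equal(unclass(cm)[c("TP", "FP", "FN", "TN")],
               list(TP = tp, FP = fp, FN = fn, TN = tn))
  expect_equal(cm$TP + cm$FP + cm$FN + cm$TN, 256)

  expect_equal(confusion(true, true)$FP, 0)
  expect_equal(confusion(true, true)$FN, 0)
  ones <- matrix(1, 16, 16)
  cm1 <- confusion(ones, true)
  expect_equal(cm1$TP, sum(true)); expect_equal(cm1$FP, 256 - sum(true))
  expect_equal(cm1$FN, 0); expect_equal(cm1$TN, 0)
  expect_error(confusion(pred, true[1:8, ]), "shape")
})

test_that("metric formulas match their definitions", {
  # constructed 4x4 masks with TP=6, FP=2, FN=1
  true <- matrix(0, 4, 4); true[1, 1:4] <- 1; true[2, 1:3] <- 1
  pred <- matrix(0, 4, 4); pred[1, 1:4] <- 1; pred[2, 1:2] <- 1; pred[3, 1:2] <- 1
  cm <- confusion(pred, true)
  expect_equal(unclass(cm)[c("TP", "FP", "FN")], list(TP = 6, FP = 2, FN = 1))
  m <- metrics_from_confusion(cm)
  expect_equal(m$iou[["foreground"]], 6 / 9, tolerance = 1e-12)
  expect_equal(m$precision, 0.75, tolerance = 1e-12)
  expect_equal(m$recall, 6 / 7, tolerance = 1e-12)
  expect_equal(m$f1, 0.8, tolerance = 1e-12)

  perfect <- metrics_from_confusion(confusion(true, true))
  for (f in c("miou", "precision", "recall", "mpa", "f1", "dice", "accuracy")) {
    expect_equal(perfect[[f]], 1)
  }
})

test_that("metric identities hold over random confusion matrices", {
  set.seed(4)
  for (k in 1:100) {
    pred <- matrix(rbinom(64, 1, runif(1, 0.1, 0.9)), 8, 8)
    true <- matrix(rbinom(64, 1, runif(1, 0.1, 0.9)), 8, 8)
    m <- metrics_from_confusion(confusion(pred, true))
    P <- m$precision; R <- m$recall
    if (P + R > 0) expect_equal(m$f1, 2 * P * R / (P + R), tolerance = 1e-12)
    expect_gte(m$f1, m$iou[["foreground"]])
    expect_equal(m$dice, m$f1)
    expect_true(all(unlist(m[c("miou", "precision", "recall", "mpa", "f1")]) >= 0))
    expect_true(all(unlist(m[c("miou", "precision", "recall", "mpa", "f1")]) <= 1))
  }
})
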