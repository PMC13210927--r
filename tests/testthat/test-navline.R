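# Row-instance clustering, anchor extraction/repair, RANSAC, consistency
# filtering, and the full mask -> navigation-lines pipeline.

test_that("a solid vertical bar yields one instance holding all foreground", {
  m <- matrix(0L, 100, 60)
  m[, 28:31] <- 1L
  inst <- cluster_rows(m)
  expect_length(inst, 1)
  expect_equal(nrow(inst[[1]]$pixels), sum(m))
  expect_length(cluster_rows(matrix(0L, 50, 50)), 0)
})

test_that("bars merge below eps and separate above it", {
  m <- matrix(0L, 100, 200)
  m[, 40:43] <- 1L; m[, 63:66] <- 1L           # 20 px apart govern centroids 23 px
  expect_length(cluster_rows(m), 1)
  m2 <- matrix(0L, 100, 200)
  m2[, 40:43] <- 1L; m2[, 160:163] <- 1L       # 120 px apart
  expect_length(cluster_rows(m2), 2)
})

test_that("instances partition a 3-row synthetic scene by generating row", {
  cfg <- scene_config(n_rows = 3L, gap_probability = 0, weed_density = 0,
                      seed = 61L)
  sc <- generate_scene(cfg)
  inst <- cluster_rows(sc$mask)
  expect_length(inst, 3)
  expect_equal(sum(sapply(inst, function(i) nrow(i$pixels))), sum(sc$mask))
  for (i in inst) {
    d <- sapply(sc$rows, function(r) {
      cl <- r$centerline
      mean(abs(cl[1] * i$pixels[, "x"] + cl[2] * i$pixels[, "y"] + cl[3]))
    })
    gen <- which.min(d)
    # every pixel of the instance belongs to that row's blob union
    cl <- sc$rows[[gen]]$centerline
    dist <- abs(cl[1] * i$pixels[, "x"] + cl[2] * i$pixels[, "y"] + cl[3])
    expect_lt(max(dist), cfg$row_spacing / 2)
  }
  # pairwise disjoint pixel sets
  keys <- lapply(inst, function(i) paste(i$pixels[, 1], i$pixels[, 2]))
  expect_equal(length(unique(unlist(keys))), length(unlist(keys)))
})

test_that("anchors are slice centroids, with empty slices skipped", {
  m <- matrix(0L, 100, 60)
  m[, 28:31] <- 1L                              # centered at x = 28.5 (0-based)
  inst <- cluster_rows(m)[[1]]
  cfg <- cluster_config(n_anchor_rows = 5L)
  a <- extract_anchors(inst, cfg)
  expect_equal(nrow(a), 5)
  expect_equal(a$x, rep(28.5, 5), tolerance = 1e-12)

  # gap band -> no detected anchor at that height
  m2 <- m; m2[41:60, ] <- 0L
  inst2 <- cluster_rows(m2, cluster_config(closing_height = 3L))[[1]]
  a2 <- extract_anchors(inst2, cfg)
  expect_equal(nrow(a2), 4)
  expect_false(3L %in% a2$height_index)

  # asymmetric L-shaped slice: centroid equals the exhaustive pixel mean
  m3 <- matrix(0L, 20, 40)
  m3[1:20, 10:12] <- 1L
  m3[9:12, 13:30] <- 1L
  inst3 <- cluster_rows(m3, cluster_config(min_samples = 1L, n_bands = 5L,
                                           closing_height = 1L))[[1]]
  a3 <- extract_anchors(inst3, cluster_config(n_anchor_rows = 2L))
  band <- inst3$repaired_mask[1:10, , drop = FALSE]
  idx <- which(band == 1, arr.ind = TRUE)
  expect_equal(a3$x[1], mean(idx[, 2] - 1), tolerance = 1e-12)
})

test_that("repair copies the nearest detected anchor with the smaller-y tie rule", {
  m <- matrix(0L, 100, 60); m[, 28:31] <- 1L
  inst <- cluster_rows(m)[[1]]
  cfg <- cluster_config(n_anchor_rows = 5L)
  a <- extract_anchors(inst, cfg)
  expect_identical(repair_anchors(a, inst, cfg)[, c("x", "y")], a[, c("x", "y")])

  # missing bottom height copies the second-to-bottom anchor
  a2 <- a[a$height_index != 5L, ]
  r2 <- repair_anchors(a2, inst, cfg)
  expect_equal(nrow(r2), 5)
  expect_equal(r2$source[r2$height_index == 5L], "repaired")
  expect_equal(r2$x[r2$height_index == 5L], a$x[a$height_index == 4L])

  # equidistant tie between different x values resolves toward smaller y
  a3 <- a
  a3$x <- c(10, 10, 10, 50, 50)
  a3 <- a3[a3$height_index != 3L, ]
  r3 <- repair_anchors(a3, inst, cfg)
  expect_equal(r3$x[r3$height_index == 3L], 10)

  empty <- a[0, ]
  expect_warning(out <- repair_anchors(empty, inst, cfg), "no detected")
  expect_null(out)
})

test_that("RANSAC honors the minimum-inlier gate and recovers exact lines", {
  a12 <- collinear_anchors(12, slope = 0, x0 = 40)
  fit <- ransac_fit(a12, ransac_config(), seed = 1)
  expect_s3_class(fit, "line_model")
  expect_equal(fit$n_inliers, 12)
  expect_equal(abs(fit$coefficients[1]), 1, tolerance = 1e-12)
  expect_equal(fit$coefficients[2], 0, tolerance = 1e-12)
  expect_equal(-fit$coefficients[3] / fit$coefficients[1], 40, tolerance = 1e-9)

  expect_null(ransac_fit(collinear_anchors(9), ransac_config(), seed = 1))
  expect_error(ransac_fit(collinear_anchors(1), ransac_config()), "2 anchors")
})

test_that("RANSAC excludes gross outliers and refits to machine precision", {
  set.seed(62)
  xs <- seq(5, 100, length.out = 20)
  true_pts <- data.frame(x = xs, y = 2 * xs + 5)
  off <- runif(8, 10, 40) * sample(c(-1, 1), 8, TRUE)
  outl <- data.frame(x = runif(8, 5, 100), y = 0)
  outl$y <- 2 * outl$x + 5 + off
  anchors <- rbind(true_pts, outl)
  fit <- ransac_fit(anchors, ransac_config(), seed = 3)
  expect_equal(sort(fit$inliers), 1:20)
  slope <- fit$coefficients[1] / -fit$coefficients[2]
  expect_equal(slope, 2, tolerance = 1e-6)
  # all inliers within the threshold of the refit line
  d <- abs(fit$coefficients[1] * anchors$x[fit$inliers] +
             fit$coefficients[2] * anchors$y[fit$inliers] + fit$coefficients[3])
  expect_lte(max(d), 5)
})

test_that("RANSAC is deterministic per seed and monotone in collinear support", {
  a <- collinear_anchors(15, slope = 0.1)
  f1 <- ransac_fit(a, ransac_config(), seed = 9)
  f2 <- ransac_fit(a, ransac_config(), seed = 9)
  expect_identical(f1$coefficients, f2$coefficients)
  more <- rbind(a, collinear_anchors(5, slope = 0.1, y_step = 17))
  f3 <- ransac_fit(more, ransac_config(), seed = 9)
  expect_gte(f3$n_inliers, f1$n_inliers)
})

test_that("consistency filter drops isolated inliers and refits", {
  a <- collinear_anchors(10, slope = 0, x0 = 30, y_step = 10)  # y 0..90
  fit <- ransac_fit(a, ransac_config(), seed = 1)
  expect_identical(consistency_filter(fit)$inliers, fit$inliers)

  iso <- rbind(collinear_anchors(11, slope = 0, x0 = 30, y_step = 10),
               data.frame(x = 30, y = 1100))     # 10x the median gap away
  fit2 <- ransac_fit(iso, ransac_config(), seed = 1)
  expect_equal(fit2$n_inliers, 12)
  filt <- consistency_filter(fit2)
  expect_equal(filt$n_inliers, 11)
  expect_false(12L %in% filt$inliers)

  two <- structure(list(coefficients = c(1, 0, -5), inliers = 1:2,
                        n_inliers = 2L,
                        anchors = data.frame(x = c(5, 5), y = c(0, 50))),
                   class = "line_model")
  expect_identical(consistency_filter(two)$inliers, 1:2)
})

test_that("full pipeline labels the middle rows and matches ground truth", {
  sc <- generate_scene(scene_config(n_rows = 5L, gap_probability = 0,
                                    weed_density = 0, seed = 70L))
  expect_length(extract_navigation_lines(matrix(0L, 64, 64)), 0)
  lines <- extract_navigation_lines(sc$mask, seed = 4)
  expect_length(lines, 3)
  expect_equal(sapply(lines, `[[`, "position"), c("left", "middle", "right"))
  mx <- sapply(lines, `[[`, "mean_x")
  expect_true(all(diff(mx) > 0))
  H <- nrow(sc$mask)
  true_x <- sapply(sc$rows, function(r)
    -(r$centerline[2] * H / 2 + r$centerline[3]) / r$centerline[1])
  for (ln in lines) {
    xl <- -(ln$coefficients[2] * H / 2 + ln$coefficients[3]) / ln$coefficients[1]
    truth <- sc$rows[[which.min(abs(true_x - xl))]]$centerline
    expect_lt(angle_deviation(ln, truth), 0.5)
  }
})

test_that("lines survive 40% plant omission", {
  cfg <- scene_config(n_rows = 3L, gap_probability = 0.4, weed_density = 0,
                      seed = 71L)
  sc <- generate_scene(cfg)
  lines <- extract_navigation_lines(sc$mask, seed = 5)
  expect_gte(length(lines), 1)
  H <- nrow(sc$mask)
  true_x <- sapply(sc$rows, function(r)
    -(r$centerline[2] * H / 2 + r$centerline[3]) / r$centerline[1])
  for (ln in lines) {
    xl <- -(ln$coefficients[2] * H / 2 + ln$coefficients[3]) / ln$coefficients[1]
    truth <- sc$rows[[which.min(abs(true_x - xl))]]$centerline
    expect_lt(angle_deviation(ln, truth), 1)
  }
})
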