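# Training-loop plumbing, checkpoints, pipeline, timing protocol. The full
# 30-epoch learnability run lives in the acceptance tests; here only cheap
# contracts are exercised.

tiny_pairs <- function(n, seed = 80L) {
  cfg <- scene_config(image_height = 32L, image_width = 32L, n_rows = 1L,
                      row_spacing = 16, plant_spacing = 8,
                      plant_radius_range = c(2, 3), gap_probability = 0,
                      weed_density = 0, seed = seed)
  lapply(generate_batch(n, cfg), scene_to_pair)
}

tiny_net <- function() {
  net_config(width_mult = 0.35, decoder_channels = 16L, shallow_channels = 8L,
             head = dense_aspp_spec(growth = 8L, reduce_channels = 16L,
                                    out_channels = 16L, pre_channels = 16L))
}

test_that("zero-epoch training returns empty history and initial weights", {
  pairs <- tiny_pairs(2)
  fit <- train_model(pairs, net_cfg = tiny_net(),
                     cfg = train_config(epochs = 0L, seed = 5L))
  expect_equal(nrow(fit$manifest$history), 0)
  ref <- with_seed(5L, build_model(tiny_net()))
  expect_equal(module_params(fit$model)[[1]]$value,
               module_params(ref)[[1]]$value)
  expect_error(train_model(list(), net_cfg = tiny_net()), "non-empty")
})

test_that("same seed and config reproduce identical loss histories", {
  pairs <- tiny_pairs(4)
  cfg <- train_config(epochs = 2L, batch_size = 2L, seed = 11L)
  f1 <- train_model(pairs, pairs[1], tiny_net(), cfg)
  f2 <- train_model(pairs, pairs[1], tiny_net(), cfg)
  expect_identical(f1$manifest$history$train_loss, f2$manifest$history$train_loss)
  expect_identical(f1$manifest$history$val_loss, f2$manifest$history$val_loss)
  expect_true(all(is.finite(f1$manifest$history$train_loss)))
  # cosine annealing starts at lr and ends at lr_min
  expect_equal(f1$manifest$history$lr[1], cfg$lr)
  expect_equal(f1$manifest$history$lr[2], cfg$lr_min)
})

test_that("checkpoints round-trip weights and running statistics", {
  pairs <- tiny_pairs(2)
  fit <- train_model(pairs, net_cfg = tiny_net(),
                     cfg = train_config(epochs = 1L, batch_size = 2L, seed = 3L))
  path <- tempfile(fileext = ".rds")
  save_checkpoint(fit$model, path)
  m2 <- load_checkpoint(path)
  x <- pairs[[1]]$image
  expect_identical(predict_mask(fit$model, x), predict_mask(m2, x))
  unlink(path)
})

test_that("the pipeline runs with an untrained model and with oracle masks", {
  scenes <- generate_batch(2, small_scene_config(seed = 90L))
  m <- with_seed(1, build_model(tiny_net()))
  spec <- normalization_spec(resize_to = c(128L, 128L), scale = 1)
  out <- run_pipeline(lapply(scenes, `[[`, "image"), m, spec,
                      true_masks = lapply(scenes, `[[`, "mask"), seed = 2)
  expect_length(out$results, 2)
  expect_equal(out$summary$n_failed, 0)
  for (r in out$results) {
    expect_true(all(r$mask %in% c(0L, 1L)))
    expect_true(is.list(r$lines))
    expect_true(is.numeric(r$metrics$miou))
  }
  # empty input -> empty report, success
  empty <- run_pipeline(list(), m, spec)
  expect_length(empty$results, 0)
  expect_true(empty$summary$exit_ok)

  # ground-truth masks bypassing the network recover the true lines
  sc <- generate_scene(scene_config(n_rows = 3L, gap_probability = 0,
                                    weed_density = 0, seed = 91L))
  lines <- extract_navigation_lines(sc$mask, seed = 3)
  H <- nrow(sc$mask)
  for (ln in lines) {
    true_x <- sapply(sc$rows, function(r)
      -(r$centerline[2] * H / 2 + r$centerline[3]) / r$centerline[1])
    xl <- -(ln$coefficients[2] * H / 2 + ln$coefficients[3]) / ln$coefficients[1]
    truth <- sc$rows[[which.min(abs(true_x - xl))]]$centerline
    expect_lt(angle_deviation(ln, truth), 0.5)
  }
})

test_that("timing protocol excludes warm-up and averages the timed frames", {
  m <- with_seed(1, build_model(tiny_net()))
  tm <- measure_inference_time(m, input_size = c(32L, 32L), n_warmup = 2L,
                               n_timed = 5L)
  expect_length(tm$times_ms, 5)
  expect_equal(tm$mean_ms, mean(tm$times_ms))
  expect_error(measure_inference_time(m, n_timed = 0L), "positive")
})
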