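# Preprocessing (bilinear resize to a fixed size, [0,1] scaling, ImageNet
# channel standardization), the leakage-free 8:1:1 split, and the seeded
# augmentation loop that expands only the training split.

#' Normalization specification
#'
#' @param resize_to target (height, width) in px (default 512 x 512).
#' @param scale divisor mapping the source range to \[0, 1\] (default 255).
#' @param channel_mean,channel_std per-channel statistics (defaults: the
#'   ImageNet statistics).
#' @return object of class `normalization_spec`.
#' @export
normalization_spec <- function(resize_to = c(512L, 512L), scale = 255,
                               channel_mean = c(0.485, 0.456, 0.406),
                               channel_std = c(0.229, 0.224, 0.225)) {
  stopifnot(all(channel_std > 0), all(resize_to > 0))
  structure(list(resize_to = as.integer(resize_to), scale = scale,
                 channel_mean = channel_mean, channel_std = channel_std),
            class = "normalization_spec")
}

#' Preprocess an RGB image for the network
#'
#' Bilinear resize to `spec$resize_to`, scaling to \[0, 1\], then per-channel
#' standardization `((v / scale) - mean) / std`.
#'
#' @param image H x W x 3 array (any spatial size), values in \[0, scale\].
#' @param spec a [normalization_spec()].
#' @return standardized array of dim (H', W', 3).
#' @export
preprocess <- function(image, spec = normalization_spec()) {
  d <- dim(image)
  if (is.null(d) || length(d) != 3 || d[3] != 3) {
    stop("image must be an H x W x 3 array", call. = FALSE)
  }
  x <- array(image, dim = c(d[1], d[2], 3, 1))
  y <- cpp_resize_bilinear(x, dim(x), spec$resize_to[1], spec$resize_to[2])
  y <- array(y, dim = c(spec$resize_to[1], spec$resize_to[2], 3))
  for (ch in 1:3) {
    y[, , ch] <- (y[, , ch] / spec$scale - spec$channel_mean[ch]) /
      spec$channel_std[ch]
  }
  y
}

#' Split samples into train / val / test without leakage
#'
#' Seeded shuffle, then sizes floor(r * n) for val and test with the
#' remainder assigned to train; the three parts are disjoint and cover all
#' samples.
#'
#' @param samples list (or vector) of samples.
#' @param ratios length-3 positive vector summing to 1 (train, val, test).
#' @param seed integer seed.
#' @return list with elements `train`, `val`, `test`.
#' @export
split_dataset <- function(samples, ratios = c(0.8, 0.1, 0.1), seed = 1L) {
  n <- length(samples)
  if (n == 0) stop("samples must be non-empty", call. = FALSE)
  if (length(ratios) != 3 || any(ratios <= 0) ||
      abs(sum(ratios) - 1) > 1e-8) {
    stop("ratios must be 3 positive numbers summing to 1", call. = FALSE)
  }
  perm <- with_seed(seed, sample.int(n))
  n_val <- floor(ratios[2] * n)
  n_test <- floor(ratios[3] * n)
  n_train <- n - n_val - n_test
  idx <- list(train = perm[seq_len(n_train)],
              val = perm[n_train + seq_len(n_val)],
              test = perm[n_train + n_val + seq_len(n_test)])
  lapply(idx, function(i) samples[i])
}

#' Augmentation configuration
#'
#' @param target_total N, the target total dataset size the training split is
#'   grown towards (default 5000; the augmentation loop runs until
#'   `|train| >= N * split_ratios[1]`).
#' @param split_ratios train/val/test ratios (default 0.8, 0.1, 0.1).
#' @param alpha_range brightness/contrast factor interval (default 0.8-1.2).
#' @param flip_probability probability of each flip transform (default 0.5).
#' @param rotation_range rotation angle interval in degrees (default +-15).
#' @param blur_kernel odd Gaussian kernel size in px (default 3).
#' @param noise_variance Gaussian noise variance on the \[0,1\] intensity
#'   scale (default 0.01).
#' @param gate_probability probability each non-flip transform fires
#'   (draws are repeated until at least one transform fires).
#' @param seed integer seed.
#' @return object of class `augment_config`.
#' @export
augment_config <- function(target_total = 5000L,
                           split_ratios = c(0.8, 0.1, 0.1),
                           alpha_range = c(0.8, 1.2), flip_probability = 0.5,
                           rotation_range = c(-15, 15), blur_kernel = 3L,
                           noise_variance = 0.01, gate_probability = 0.5,
                           seed = 1L) {
  stopifnot(target_total > 0, all(split_ratios > 0),
            abs(sum(split_ratios) - 1) < 1e-8, blur_kernel %% 2 == 1)
  structure(list(target_total = as.integer(target_total),
                 split_ratios = split_ratios, alpha_range = alpha_range,
                 flip_probability = flip_probability,
                 rotation_range = rotation_range,
                 blur_kernel = as.integer(blur_kernel),
                 noise_variance = noise_variance,
                 gate_probability = gate_probability,
                 seed = as.integer(seed)),
            class = "augment_config")
}

# Rotate about the image center by `theta` degrees (inverse mapping);
# `bilinear` for images, nearest for masks; exposed borders filled with 0
# (background by the label semantics).
rotate_image <- function(img, theta, bilinear = TRUE) {
  d <- dim(img)
  H <- d[1]; W <- d[2]
  nch <- if (length(d) == 3) d[3] else 1L
  rad <- theta * pi / 180
  cy <- (H + 1) / 2; cx <- (W + 1) / 2
  yy <- matrix(seq_len(H), H, W) - cy
  xx <- matrix(seq_len(W), H, W, byrow = TRUE) - cx
  # inverse rotation of output coords into the source frame
  sx <- cos(rad) * xx + sin(rad) * yy + cx
  sy <- -sin(rad) * xx + cos(rad) * yy + cy
  sample_plane <- function(m) {
    if (bilinear) {
      x0 <- floor(sx); y0 <- floor(sy)
      fx <- sx - x0; fy <- sy - y0
      gv <- function(yi, xi) {
        ok <- yi >= 1 & yi <= H & xi >= 1 & xi <= W
        v <- matrix(0, H, W)
        v[ok] <- m[cbind(yi[ok], xi[ok])]
        v
      }
      v00 <- gv(y0, x0); v01 <- gv(y0, x0 + 1)
      v10 <- gv(y0 + 1, x0); v11 <- gv(y0 + 1, x0 + 1)
      (1 - fy) * ((1 - fx) * v00 + fx * v01) + fy * ((1 - fx) * v10 + fx * v11)
    } else {
      xi <- round(sx); yi <- round(sy)
      ok <- yi >= 1 & yi <= H & xi >= 1 & xi <= W
      v <- matrix(0, H, W)
      v[ok] <- m[cbind(yi[ok], xi[ok])]
      v
    }
  }
  if (length(d) == 3) {
    out <- array(0, dim = d)
    for (ch in seq_len(nch)) out[, , ch] <- sample_plane(img[, , ch])
    out
  } else {
    sample_plane(img)
  }
}

gaussian_kernel_1d <- function(k) {
  # binomial approximation of a Gaussian (k = 3 gives 1-2-1 / 4)
  v <- choose(k - 1, 0:(k - 1))
  v / sum(v)
}

blur_image <- function(img, k = 3L) {
  kern <- gaussian_kernel_1d(k)
  r <- (k - 1L) %/% 2L
  conv1 <- function(m, along) {
    out <- m * kern[r + 1]
    H <- nrow(m); W <- ncol(m)
    for (s in seq_len(r)) {
      if (along == 1) {
        up <- rbind(m[-seq_len(s), , drop = FALSE], matrix(m[H, ], s, W, byrow = TRUE))
        dn <- rbind(matrix(m[1, ], s, W, byrow = TRUE), m[seq_len(H - s), , drop = FALSE])
      } else {
        up <- cbind(m[, -seq_len(s), drop = FALSE], matrix(m[, W], H, s))
        dn <- cbind(matrix(m[, 1], H, s), m[, seq_len(W - s), drop = FALSE])
      }
      out <- out + kern[r + 1 + s] * up + kern[r + 1 - s] * dn
    }
    out
  }
  d <- dim(img)
  if (length(d) == 3) {
    for (ch in seq_len(d[3])) img[, , ch] <- conv1(conv1(img[, , ch], 1), 2)
    img
  } else {
    conv1(conv1(img, 1), 2)
  }
}

#' Apply one stochastic augmentation to an image/mask pair
#'
#' Independent Bernoulli gates select one or more transforms (re-drawn until
#' at least one fires). Geometric transforms (flips, rotation) act
#' identically on image and mask (nearest-neighbor for the mask); photometric
#' transforms (brightness/contrast, blur, noise) touch the image only. The
#' output mask is always binary.
#'
#' @param image H x W x 3 array in \[0, 1\].
#' @param mask binary H x W matrix.
#' @param config an [augment_config()].
#' @param seed optional integer; if given, the draw is made reproducible.
#' @return list(image, mask, applied = character vector of transform names).
#' @export
augment_pair <- function(image, mask, config = augment_config(), seed = NULL) {
  if (!identical(dim(image)[1:2], dim(mask)[1:2])) {
    stop("image and mask must share spatial dimensions", call. = FALSE)
  }
  run <- function() {
    repeat {
      gates <- c(
        brightness_contrast = runif(1) < config$gate_probability,
        hflip = runif(1) < config$flip_probability,
        vflip = runif(1) < config$flip_probability,
        rotation = runif(1) < config$gate_probability,
        blur = runif(1) < config$gate_probability,
        noise = runif(1) < config$gate_probability
      )
      if (any(gates)) break
    }
    img <- image; m <- mask
    if (gates["brightness_contrast"]) {
      a <- runif(1, config$alpha_range[1], config$alpha_range[2])
      b <- runif(1, -0.1, 0.1)
      img <- clamp(a * img + b, 0, 1)
    }
    if (gates["hflip"]) {
      img <- img[, rev(seq_len(ncol(m))), , drop = FALSE]
      m <- m[, rev(seq_len(ncol(m))), drop = FALSE]
    }
    if (gates["vflip"]) {
      img <- img[rev(seq_len(nrow(m))), , , drop = FALSE]
      m <- m[rev(seq_len(nrow(m))), , drop = FALSE]
    }
    if (gates["rotation"]) {
      theta <- runif(1, config$rotation_range[1], config$rotation_range[2])
      img <- rotate_image(img, theta, bilinear = TRUE)
      m <- rotate_image(m, theta, bilinear = FALSE)
    }
    if (gates["blur"]) img <- blur_image(img, config$blur_kernel)
    if (gates["noise"]) {
      img <- clamp(img + array(rnorm(length(img), 0,
                                     sqrt(config$noise_variance)), dim(img)),
                   0, 1)
    }
    m <- matrix(as.integer(m > 0.5), nrow(m), ncol(m))
    list(image = img, mask = m, applied = names(gates)[gates])
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

#' Grow the training split by seeded augmentation
#'
#' Repeatedly samples a source pair from `train_raw`, augments it and appends
#' it until `length(train) >= target_total * split_ratios[1]`. Validation and
#' test samples are never read. Each augmented pair records the index of its
#' source (`source_index`), so provenance can be audited.
#'
#' @param train_raw non-empty list of pairs (each `list(image, mask, ...)`).
#' @param config an [augment_config()].
#' @return list of pairs: the originals followed by augmented pairs.
#' @export
build_augmented_training_set <- function(train_raw, config = augment_config()) {
  if (length(train_raw) == 0) stop("train_raw must be non-empty", call. = FALSE)
  target <- ceiling(config$target_total * config$split_ratios[1])
  out <- train_raw
  k <- 0L
  while (length(out) < target) {
    k <- k + 1L
    src <- with_seed(config$seed + 2L * k, sample.int(length(train_raw), 1))
    pair <- train_raw[[src]]
    aug <- augment_pair(pair$image, pair$mask, config,
                        seed = config$seed + 2L * k + 1L)
    aug$source_index <- src
    out[[length(out) + 1L]] <- aug
  }
  out
}

#' Crop-type composition of a dataset manifest
#'
#' Fraction (in percent) of images per category from a manifest with a
#' `category` column; used to audit dataset composition.
#'
#' @param manifest data.frame with a `category` column (one row per image).
#' @return named numeric vector of percentages, decreasing.
#' @export
class_composition <- function(manifest) {
  stopifnot("category" %in% names(manifest))
  tab <- table(manifest$category)
  p <- 100 * as.vector(tab) / sum(tab)
  names(p) <- names(tab)
  sort(p, decreasing = TRUE)
}
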