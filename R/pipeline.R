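# End-to-end inference pipeline and PNG mask/image I/O.

#' Read / write binary masks as PNG (0/255)
#'
#' @param mask binary H x W matrix.
#' @param path file path.
#' @return `read_mask_png` returns a binary H x W matrix.
#' @export
write_mask_png <- function(mask, path) {
  png::writePNG(mask * 1.0, path)
  invisible(path)
}

#' @rdname write_mask_png
#' @export
read_mask_png <- function(path) {
  m <- png::readPNG(path)
  if (length(dim(m)) == 3) m <- m[, , 1]
  matrix(as.integer(m > 0.5), nrow(m), ncol(m))
}

#' Read / write an RGB image as PNG
#'
#' @param image H x W x 3 array in \[0, 1\].
#' @param path file path.
#' @return `read_image_png` returns an H x W x 3 array in \[0, 1\].
#' @export
write_image_png <- function(image, path) {
  png::writePNG(image, path)
  invisible(path)
}

#' @rdname write_image_png
#' @export
read_image_png <- function(path) {
  m <- png::readPNG(path)
  if (length(dim(m)) == 2) m <- array(rep(m, 3), dim = c(dim(m), 3))
  if (dim(m)[3] == 4) m <- m[, , 1:3]
  m
}

line_to_list <- function(lm) {
  list(a = lm$coefficients[1], b = lm$coefficients[2], c = lm$coefficients[3],
       n_inliers = lm$n_inliers, position = lm$position %||% NA,
       anchors = lapply(seq_len(nrow(lm$anchors)), function(i)
         list(x = lm$anchors$x[i], y = lm$anchors$y[i],
              source = lm$anchors$source[i])))
}

#' Run the full perception pipeline over images
#'
#' Per image: preprocess, forward pass, argmax mask, navigation-line
#' extraction; optionally evaluate against ground-truth masks. Unreadable
#' images are skipped with a warning and counted in the summary.
#'
#' @param images list of H x W x 3 arrays, or a character vector of PNG paths.
#' @param model a trained model (or a checkpoint path).
#' @param norm_spec a [normalization_spec()] (its `resize_to` must be
#'   divisible by 16).
#' @param cluster_cfg,ransac_cfg navigation-line settings.
#' @param true_masks optional list of ground-truth masks (at `resize_to`
#'   scale) for per-image segmentation metrics.
#' @param seed integer seed for the RANSAC stage.
#' @return list with `results` (per image: mask, lines, metrics) and
#'   `summary` (n_images, n_failed).
#' @export
run_pipeline <- function(images, model, norm_spec = normalization_spec(),
                         cluster_cfg = cluster_config(),
                         ransac_cfg = ransac_config(), true_masks = NULL,
                         seed = 1L) {
  if (is.character(model)) model <- load_checkpoint(model)
  results <- list()
  n_failed <- 0L
  for (i in seq_along(images)) {
    img <- tryCatch({
      if (is.character(images)) read_image_png(images[i]) * 255 else images[[i]]
    }, error = function(e) {
      warning(sprintf("skipping unreadable image %d: %s", i, conditionMessage(e)))
      NULL
    })
    if (is.null(img)) {
      n_failed <- n_failed + 1L
      next
    }
    x <- preprocess(img, norm_spec)
    mask <- predict_mask(model, x)
    lines <- extract_navigation_lines(mask, cluster_cfg, ransac_cfg,
                                      seed = seed + i)
    res <- list(index = i, mask = mask,
                lines = lapply(lines, line_to_list))
    if (!is.null(true_masks)) {
      res$metrics <- unclass(evaluate_mask(mask, true_masks[[i]]))
    }
    results[[length(results) + 1L]] <- res
  }
  list(results = results,
       summary = list(n_images = length(images), n_failed = n_failed,
                      exit_ok = TRUE))
}
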