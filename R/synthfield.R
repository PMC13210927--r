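# Seeded synthetic field scenes: quasi-parallel crop rows rendered as chains
# of lobed, perturbed-ellipse plant canopies on a textured soil background,
# with missing seedlings, weed clutter (image only, never mask foreground)
# and an illumination gradient. Ground-truth centerlines and plant centers
# are recorded, so clustering, anchor extraction and line fitting can all be
# scored exactly.

#' Scene configuration
#'
#' Defaults emulate a nadir-ish view of maize seedling rows: 60 cm row
#' spacing and 28 cm plant spacing mapped to 120 px and 56 px at a 512-px
#' image width (the generator owns the px scale; the agronomic spacing fixes
#' only the ratio).
#'
#' @param image_height,image_width scene size in pixels.
#' @param n_rows number of crop rows (>= 0).
#' @param row_spacing center-to-center spacing in px.
#' @param row_curvature quadratic coefficient of x(y); 0 = straight rows.
#' @param row_slope common lateral slope of the rows (quasi-parallel); small
#'   per-row jitter is added on top.
#' @param plant_spacing along-row spacing in px.
#' @param plant_radius_range min/max plant blob radius in px.
#' @param gap_probability probability a plant is omitted (missing seedling).
#' @param weed_density expected weed blobs per image (Poisson).
#' @param illumination_gradient multiplicative illumination range across the
#'   image width, length 2.
#' @param seed integer seed; the scene is a deterministic function of it.
#' @return object of class `scene_config`.
#' @export
scene_config <- function(image_height = 512L, image_width = 512L, n_rows = 5L,
                         row_spacing = 120, row_curvature = 0,
                         row_slope = 0, plant_spacing = 56,
                         plant_radius_range = c(10, 16),
                         gap_probability = 0.05, weed_density = 8,
                         illumination_gradient = c(0.85, 1.15), seed = 1L) {
  if (image_height <= 0 || image_width <= 0) {
    stop("image dimensions must be positive", call. = FALSE)
  }
  if (n_rows < 0) stop("n_rows must be >= 0", call. = FALSE)
  if (gap_probability < 0 || gap_probability > 1) {
    stop("gap_probability must be in [0, 1]", call. = FALSE)
  }
  if (row_spacing <= 0 || plant_spacing <= 0) {
    stop("spacings must be positive", call. = FALSE)
  }
  structure(list(image_height = as.integer(image_height),
                 image_width = as.integer(image_width),
                 n_rows = as.integer(n_rows), row_spacing = row_spacing,
                 row_curvature = row_curvature, row_slope = row_slope,
                 plant_spacing = plant_spacing,
                 plant_radius_range = plant_radius_range,
                 gap_probability = gap_probability,
                 weed_density = weed_density,
                 illumination_gradient = illumination_gradient,
                 seed = as.integer(seed)),
            class = "scene_config")
}

# Rasterize one lobed blob into logical matrix `canvas` (TRUE = covered).
# The blob is an ellipse (axes ax, by) whose radius is modulated by
# 1 + amp*cos(lobes*phi + phase), mimicking a leaf canopy.
rasterize_blob <- function(H, W, cx, cy, ax, by, lobes, amp, phase) {
  rmax <- max(ax, by) * (1 + amp) + 1
  x0 <- max(1L, floor(cx - rmax)); x1 <- min(W, ceiling(cx + rmax))
  y0 <- max(1L, floor(cy - rmax)); y1 <- min(H, ceiling(cy + rmax))
  if (x0 > x1 || y0 > y1) return(NULL)
  xs <- x0:x1; ys <- y0:y1
  dx <- outer(ys * 0, xs - cx, FUN = function(a, b) b) # rows = y, cols = x
  dy <- outer(ys - cy, xs * 0, FUN = function(a, b) a)
  rho <- sqrt((dx / ax)^2 + (dy / by)^2)
  phi <- atan2(dy, dx)
  inside <- rho <= 1 + amp * cos(lobes * phi + phase)
  list(ys = ys, xs = xs, inside = inside)
}

row_center_x <- function(y, x0, slope, curv, H) {
  x0 + slope * (y - H / 2) + curv * (y - H / 2)^2
}

#' Generate one synthetic field scene
#'
#' Deterministic for a fixed `config$seed`: the same config yields
#' bit-identical image, mask and ground truth.
#'
#' @param config a [scene_config()].
#' @return object of class `field_scene`: list with `image` (H x W x 3 in
#'   \[0,1\]), `mask` (H x W binary, 1 = crop row), `rows` (list of per-row
#'   ground truth: `row_index`, `centerline` c(a, b, c) with a^2+b^2=1 for
#'   straight rows, `polyline` for curved rows, `plant_centers`,
#'   `gap_positions`), and `config`.
#' @export
generate_scene <- function(config = scene_config()) {
  stopifnot(inherits(config, "scene_config"))
  with_seed(config$seed, {
    H <- config$image_height; W <- config$image_width
    mask <- matrix(0L, H, W)
    # soil background with mild texture
    soil <- c(0.45, 0.36, 0.26)
    img <- array(0, dim = c(H, W, 3))
    tex <- matrix(rnorm(H * W, 0, 0.025), H, W)
    for (ch in 1:3) img[, , ch] <- clamp(soil[ch] + tex, 0, 1)

    rows <- list()
    if (config$n_rows > 0) {
      slope <- config$row_slope + runif(1, -0.03, 0.03)
      xs0 <- W / 2 + (seq_len(config$n_rows) - (config$n_rows + 1) / 2) *
        config$row_spacing
      for (i in seq_len(config$n_rows)) {
        s_i <- slope + runif(1, -0.008, 0.008)
        x0 <- xs0[i] + runif(1, -3, 3)
        ys <- seq(config$plant_spacing / 2, H - config$plant_spacing / 2,
                  by = config$plant_spacing)
        keep <- runif(length(ys)) >= config$gap_probability
        centers <- NULL; gaps <- NULL
        green0 <- c(0.20, 0.55, 0.25)
        for (k in seq_along(ys)) {
          yk <- ys[k]
          xk <- row_center_x(yk, x0, s_i, config$row_curvature, H) +
            runif(1, -1.5, 1.5)
          if (!keep[k]) {
            gaps <- rbind(gaps, c(xk, yk))
            next
          }
          centers <- rbind(centers, c(xk, yk))
          r0 <- runif(1, config$plant_radius_range[1], config$plant_radius_range[2])
          b <- rasterize_blob(H, W, xk, yk, ax = r0, by = r0 * runif(1, 0.75, 1.25),
                              lobes = sample(3:6, 1), amp = runif(1, 0.12, 0.25),
                              phase = runif(1, 0, 2 * pi))
          if (is.null(b)) next
          sub <- mask[b$ys, b$xs, drop = FALSE]
          sub[b$inside] <- 1L
          mask[b$ys, b$xs] <- sub
          gcol <- clamp(green0 + rnorm(3, 0, 0.04), 0, 1)
          for (ch in 1:3) {
            subi <- img[, , ch][b$ys, b$xs, drop = FALSE]
            subi[b$inside] <- clamp(gcol[ch] + rnorm(sum(b$inside), 0, 0.03), 0, 1)
            img[, , ch][b$ys, b$xs] <- subi
          }
        }
        cl <- NULL; poly <- NULL
        if (config$row_curvature == 0) {
          # line through (x(y), y): x - s_i*(y - H/2) - x0 = 0,
          # normalized to a^2 + b^2 = 1
          nrm <- sqrt(1 + s_i^2)
          cl <- c(1, -s_i, s_i * H / 2 - x0) / nrm
        } else {
          yy <- seq(0, H - 1, by = 4)
          poly <- cbind(x = row_center_x(yy, x0, s_i, config$row_curvature, H),
                        y = yy)
        }
        rows[[i]] <- list(row_index = i, centerline = cl, polyline = poly,
                          plant_centers = centers, gap_positions = gaps)
      }
    }
    # weeds: image clutter only, never mask foreground
    n_weed <- rpois(1, config$weed_density)
    if (n_weed > 0) {
      for (k in seq_len(n_weed)) {
        wx <- runif(1, 1, W); wy <- runif(1, 1, H)
        r0 <- runif(1, 2.5, 6)
        b <- rasterize_blob(H, W, wx, wy, ax = r0, by = r0 * runif(1, 0.7, 1.3),
                            lobes = sample(3:5, 1), amp = runif(1, 0.1, 0.3),
                            phase = runif(1, 0, 2 * pi))
        if (is.null(b)) next
        wcol <- clamp(c(0.30, 0.50, 0.22) + rnorm(3, 0, 0.05), 0, 1)
        for (ch in 1:3) {
          subi <- img[, , ch][b$ys, b$xs, drop = FALSE]
          subi[b$inside] <- wcol[ch]
          img[, , ch][b$ys, b$xs] <- subi
        }
      }
    }
    # multiplicative illumination ramp across the width
    g <- config$illumination_gradient
    ramp <- matrix(seq(g[1], g[2], length.out = W), H, W, byrow = TRUE)
    for (ch in 1:3) img[, , ch] <- clamp(img[, , ch] * ramp, 0, 1)

    structure(list(image = img, mask = mask, rows = rows, config = config),
              class = "field_scene")
  })
}

#' Generate a batch of scenes
#'
#' Scene i uses seed `config$seed + i - 1`, so every element is individually
#' reproducible.
#'
#' @param n number of scenes (>= 0).
#' @param config a [scene_config()] used as the template.
#' @return list of `field_scene` objects.
#' @export
generate_batch <- function(n, config = scene_config()) {
  stopifnot(n >= 0)
  lapply(seq_len(n), function(i) {
    cfg <- config
    cfg$seed <- config$seed + i - 1L
    generate_scene(cfg)
  })
}

#' Ground-truth centerline of a row as a normalized line
#'
#' For straight rows returns the stored coefficients; for curved rows fits a
#' total-least-squares line through the sampled polyline (the straight-line
#' reference the navigation pipeline is scored against).
#'
#' @param row one element of `field_scene$rows`.
#' @return numeric c(a, b, c) with a^2 + b^2 = 1.
#' @export
row_centerline <- function(row) {
  if (!is.null(row$centerline)) return(normalize_line(row$centerline))
  fit_line_tls(row$polyline[, 1], row$polyline[, 2])
}
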