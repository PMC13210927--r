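# Binary crop-row mask -> per-row navigation lines:
# horizontal-band connected components -> 1-D DBSCAN over representative
# x-coordinates -> per-instance vertical closing -> moment-based anchor
# extraction at equidistant heights -> up/down gap repair -> seeded RANSAC
# line fitting with total-least-squares refit -> spatial consistency filter.
#
# Coordinates: 0-based pixel indices, x rightward, y downward; anchor heights
# are band centers. All geometry stays in image coordinates.

#' Row-instance clustering configuration
#'
#' @param eps DBSCAN neighborhood radius in px over representative
#'   x-coordinates (default 30).
#' @param min_samples DBSCAN core-point minimum neighbor count, the point
#'   itself included (default 5).
#' @param n_bands horizontal bands used to reduce the mask to per-band
#'   connected-component representatives (default 20).
#' @param closing_height height in px of the 1-wide vertical morphological
#'   closing kernel applied per instance (default 15).
#' @param n_anchor_rows number of vertical equidistant anchor sampling
#'   heights (default 10).
#' @param max_rows_kept number of central rows returned by the full pipeline
#'   (default 3, the middle rows).
#' @return object of class `cluster_config`.
#' @export
cluster_config <- function(eps = 30, min_samples = 5L, n_bands = 20L,
                           closing_height = 15L, n_anchor_rows = 10L,
                           max_rows_kept = 3L) {
  stopifnot(eps > 0, min_samples >= 1, n_anchor_rows >= 2, n_bands >= 1)
  structure(list(eps = eps, min_samples = as.integer(min_samples),
                 n_bands = as.integer(n_bands),
                 closing_height = as.integer(closing_height),
                 n_anchor_rows = as.integer(n_anchor_rows),
                 max_rows_kept = as.integer(max_rows_kept)),
            class = "cluster_config")
}

#' RANSAC configuration
#'
#' @param max_iter maximum iterations K (default 100).
#' @param threshold inlier perpendicular-distance threshold T in px
#'   (default 5).
#' @param min_inliers minimum inlier count for a model to be accepted
#'   (default 10).
#' @return object of class `ransac_config`.
#' @export
ransac_config <- function(max_iter = 100L, threshold = 5, min_inliers = 10L) {
  stopifnot(max_iter >= 1, threshold > 0, min_inliers >= 2)
  structure(list(max_iter = as.integer(max_iter), threshold = threshold,
                 min_inliers = as.integer(min_inliers)),
            class = "ransac_config")
}

# 1-D DBSCAN over x values. Returns integer labels (0 = noise).
dbscan_1d <- function(x, eps, min_pts) {
  n <- length(x)
  if (n == 0) return(integer(0))
  ord <- order(x)
  xs <- x[ord]
  # neighbor counts within eps via two-pointer sweep (self included)
  lo <- findInterval(xs - eps, xs) + 1L          # first index with xs >= xs-eps
  lo <- pmin(lo, seq_len(n))
  hi <- findInterval(xs + eps, xs)               # last index with xs <= xs+eps
  ncount <- hi - lo + 1L
  core <- ncount >= min_pts
  labels <- integer(n)
  cl <- 0L
  for (i in seq_len(n)) {
    if (labels[i] != 0L || !core[i]) next
    cl <- cl + 1L
    queue <- i
    labels[i] <- cl
    while (length(queue) > 0) {
      j <- queue[[1]]; queue <- queue[-1]
      nb <- lo[j]:hi[j]
      for (k in nb) {
        if (labels[k] == 0L) {
          labels[k] <- cl
          if (core[k]) queue <- c(queue, k)
        }
      }
    }
  }
  # border points reachable from a core point but themselves labeled 0 remain
  # noise only if not within eps of any core point; sweep above already
  # assigns them. Map back to input order.
  out <- integer(n)
  out[ord] <- labels
  out
}

# Vertical morphological closing (dilate then erode with a 1 x h kernel).
# Operates on the foreground bounding box only (instances are narrow).
close_vertical <- function(m, h) {
  if (h <= 1 || sum(m) == 0) return(m)
  r <- h %/% 2L
  rows <- range(which(rowSums(m) > 0))
  cols <- range(which(colSums(m) > 0))
  r0 <- max(1L, rows[1] - r); r1 <- min(nrow(m), rows[2] + r)
  sub <- close_vertical_full(m[r0:r1, cols[1]:cols[2], drop = FALSE], h)
  out <- m
  out[r0:r1, cols[1]:cols[2]] <- sub
  out
}

close_vertical_full <- function(m, h) {
  r <- h %/% 2L
  shift_stack <- function(mm, combine) {
    out <- mm
    H <- nrow(mm)
    for (s in seq_len(r)) {
      up <- rbind(mm[-seq_len(s), , drop = FALSE],
                  matrix(0L, s, ncol(mm)))
      dn <- rbind(matrix(0L, s, ncol(mm)),
                  mm[seq_len(H - s), , drop = FALSE])
      out <- combine(out, up, dn)
    }
    out
  }
  dil <- shift_stack(m, function(a, b, c) pmax(a, b, c))
  ero <- shift_stack(dil, function(a, b, c) pmin(a, b, c))
  ero
}

#' Cluster a binary mask into crop-row instances
#'
#' Per horizontal band, connected components of the foreground are reduced to
#' representative points (component centroid x); the pooled representatives
#' are clustered by 1-D DBSCAN on x. Noise representatives are discarded;
#' each surviving cluster becomes one row instance, whose mask is closed
#' vertically to bridge plant gaps.
#'
#' @param mask binary H x W matrix (1 = crop row).
#' @param config a [cluster_config()].
#' @return list of `row_instance` objects: `id`, `pixels` (2-column x, y
#'   matrix, 0-based), `mask` (binary H x W), `repaired_mask` (after vertical
#'   closing), `mean_x`.
#' @export
cluster_rows <- function(mask, config = cluster_config()) {
  stopifnot_binary(mask, "mask")
  H <- nrow(mask); W <- ncol(mask)
  if (sum(mask) == 0) return(list())
  bands <- band_bounds(H, config$n_bands)
  reps <- list()
  for (b in seq_len(nrow(bands))) {
    sub <- mask[bands[b, 1]:bands[b, 2], , drop = FALSE]
    if (sum(sub) == 0) next
    lab <- EBImage::bwlabel(sub)
    for (cc in seq_len(max(lab))) {
      idx <- which(lab == cc, arr.ind = TRUE)
      # x = column - 1, y = absolute row - 1 (0-based image coords)
      xs <- idx[, 2] - 1
      ys <- idx[, 1] + bands[b, 1] - 2
      reps[[length(reps) + 1L]] <- list(cx = mean(xs), px = xs, py = ys)
    }
  }
  if (length(reps) == 0) return(list())
  cx <- vapply(reps, `[[`, numeric(1), "cx")
  labels <- dbscan_1d(cx, config$eps, config$min_samples)
  instances <- list()
  for (cl in sort(unique(labels[labels > 0]))) {
    sel <- which(labels == cl)
    px <- unlist(lapply(reps[sel], `[[`, "px"))
    py <- unlist(lapply(reps[sel], `[[`, "py"))
    inst_mask <- matrix(0L, H, W)
    inst_mask[cbind(py + 1, px + 1)] <- 1L
    rep_mask <- close_vertical(inst_mask, config$closing_height)
    instances[[length(instances) + 1L]] <- structure(
      list(id = length(instances) + 1L,
           pixels = cbind(x = px, y = py),
           mask = inst_mask, repaired_mask = rep_mask,
           mean_x = mean(px)),
      class = "row_instance")
  }
  instances[order(vapply(instances, `[[`, numeric(1), "mean_x"))]
}

band_bounds <- function(H, n_bands) {
  edges <- round(seq(0, H, length.out = n_bands + 1))
  cbind(start = pmax(1, edges[-length(edges)] + 1), end = edges[-1])
}

#' Extract anchor points of a row instance
#'
#' At each of `n_anchor_rows` equidistant heights (band centers), the zeroth
#' and first moments of the instance's repaired-mask slice give the centroid
#' x; empty slices yield no detected anchor. Canny edges of the instance mask
#' are attached as a boundary diagnostic (not used for centroids).
#'
#' @param instance a `row_instance` from [cluster_rows()].
#' @param config a [cluster_config()].
#' @param edges logical, also compute the edge diagnostic (default FALSE).
#' @return data.frame with columns x, y, row_id, source ("detected"); empty
#'   heights are absent. Attribute `"edges"` holds the edge map if requested.
#' @export
extract_anchors <- function(instance, config = cluster_config(), edges = FALSE) {
  m <- instance$repaired_mask
  H <- nrow(m)
  bands <- band_bounds(H, config$n_anchor_rows)
  out <- NULL
  for (k in seq_len(nrow(bands))) {
    sub <- m[bands[k, 1]:bands[k, 2], , drop = FALSE]
    m00 <- sum(sub)
    if (m00 == 0) next
    # first moment in x over the slice (0-based x = col - 1)
    m10 <- sum(colSums(sub) * (seq_len(ncol(sub)) - 1))
    yc <- (bands[k, 1] - 1 + bands[k, 2] - 1) / 2
    out <- rbind(out, data.frame(x = m10 / m00, y = yc,
                                 row_id = instance$id, source = "detected",
                                 height_index = k))
  }
  if (is.null(out)) {
    out <- data.frame(x = numeric(0), y = numeric(0), row_id = integer(0),
                      source = character(0), height_index = integer(0))
  }
  if (edges) attr(out, "edges") <- canny_edges(instance$repaired_mask * 255)
  out
}

# Compact Canny detector (Sobel gradients, non-maximum suppression along the
# quantized gradient direction, double-threshold hysteresis). Diagnostic only.
canny_edges <- function(img, low = 50, high = 150) {
  H <- nrow(img); W <- ncol(img)
  pad <- function(m) {
    m2 <- matrix(0, H + 2, W + 2)
    m2[2:(H + 1), 2:(W + 1)] <- m
    m2
  }
  p <- pad(img)
  sh <- function(dy, dx) p[(2 + dy):(H + 1 + dy), (2 + dx):(W + 1 + dx)]
  gx <- -sh(-1, -1) - 2 * sh(0, -1) - sh(1, -1) +
    sh(-1, 1) + 2 * sh(0, 1) + sh(1, 1)
  gy <- -sh(-1, -1) - 2 * sh(-1, 0) - sh(-1, 1) +
    sh(1, -1) + 2 * sh(1, 0) + sh(1, 1)
  mag <- sqrt(gx^2 + gy^2)
  ang <- atan2(gy, gx) * 180 / pi
  ang[ang < 0] <- ang[ang < 0] + 180
  dir <- findInterval(ang, c(22.5, 67.5, 112.5, 157.5)) %% 4  # 0:h 1:d1 2:v 3:d2
  pm <- pad(mag)
  shm <- function(dy, dx) pm[(2 + dy):(H + 1 + dy), (2 + dx):(W + 1 + dx)]
  n1 <- mag; n2 <- mag
  n1[dir == 0] <- shm(0, -1)[dir == 0]; n2[dir == 0] <- shm(0, 1)[dir == 0]
  n1[dir == 1] <- shm(-1, 1)[dir == 1]; n2[dir == 1] <- shm(1, -1)[dir == 1]
  n1[dir == 2] <- shm(-1, 0)[dir == 2]; n2[dir == 2] <- shm(1, 0)[dir == 2]
  n1[dir == 3] <- shm(-1, -1)[dir == 3]; n2[dir == 3] <- shm(1, 1)[dir == 3]
  keep <- mag >= n1 & mag >= n2
  strong <- keep & mag >= high
  weak <- keep & mag >= low & mag < high
  # hysteresis: weak pixels survive if 8-connected to a strong pixel
  ps <- pad(strong * 1)
  nbr <- matrix(0, H, W)
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0 && dx == 0) next
    nbr <- nbr + ps[(2 + dy):(H + 1 + dy), (2 + dx):(W + 1 + dx)]
  }
  edges <- strong | (weak & nbr > 0)
  matrix(as.integer(edges), H, W)
}

#' Repair missing anchors by up-down search
#'
#' Each missing height receives an anchor whose x is copied from the nearest
#' (in |dy|) detected anchor, ties broken toward smaller y; the result always
#' has exactly `n_anchor_rows` anchors.
#'
#' @param anchors data.frame from [extract_anchors()].
#' @param instance the owning `row_instance` (for its id and mask height).
#' @param config a [cluster_config()].
#' @return completed anchor data.frame ordered by y, sources marked
#'   "detected"/"repaired"; NULL (with a warning) if no anchor was detected.
#' @export
repair_anchors <- function(anchors, instance, config = cluster_config()) {
  H <- nrow(instance$repaired_mask)
  bands <- band_bounds(H, config$n_anchor_rows)
  if (nrow(anchors) == 0) {
    warning("instance ", instance$id, " has no detected anchors; dropped")
    return(NULL)
  }
  out <- anchors
  for (k in seq_len(nrow(bands))) {
    if (k %in% anchors$height_index) next
    yc <- (bands[k, 1] - 1 + bands[k, 2] - 1) / 2
    dy <- abs(anchors$y - yc)
    best <- which(dy == min(dy))
    if (length(best) > 1) best <- best[which.min(anchors$y[best])]
    out <- rbind(out, data.frame(x = anchors$x[best], y = yc,
                                 row_id = instance$id, source = "repaired",
                                 height_index = k))
  }
  out[order(out$y), ]
}

# Normalize (a, b, c) to a^2 + b^2 = 1 with a >= 0 (b > 0 if a == 0).
normalize_line <- function(abc) {
  n <- sqrt(abc[1]^2 + abc[2]^2)
  if (n == 0) stop("degenerate line coefficients", call. = FALSE)
  v <- abc / n
  if (v[1] < 0 || (v[1] == 0 && v[2] < 0)) v <- -v
  v
}

# Total least squares (orthogonal regression) line through points.
fit_line_tls <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  X <- cbind(x - mx, y - my)
  S <- crossprod(X) / length(x)
  ev <- eigen(S, symmetric = TRUE)
  nvec <- ev$vectors[, 2]   # eigenvector of the smallest eigenvalue = normal
  normalize_line(c(nvec[1], nvec[2], -(nvec[1] * mx + nvec[2] * my)))
}

line_distance <- function(line, x, y) abs(line[1] * x + line[2] * y + line[3])

#' RANSAC line fit over anchor points
#'
#' K seeded iterations of 2-point sampling (duplicate coordinate pairs are
#' resampled), perpendicular-distance inlier counting at threshold T, and
#' best-model tracking subject to the minimum inlier count; the best inlier
#' set is refit by total least squares (minimizing the sum of squared
#' perpendicular distances) and renormalized.
#'
#' @param anchors data.frame with columns x, y (>= 2 rows).
#' @param config a [ransac_config()].
#' @param seed integer seed for the sampling.
#' @return a `line_model` (list: `coefficients` c(a,b,c) with a^2+b^2=1,
#'   `inliers` row indices into `anchors`, `n_inliers`, `anchors`) or NULL if
#'   no iteration reaches `min_inliers`.
#' @export
ransac_fit <- function(anchors, config = ransac_config(), seed = 1L) {
  if (nrow(anchors) < 2) stop("need at least 2 anchors", call. = FALSE)
  x <- anchors$x; y <- anchors$y
  n <- nrow(anchors)
  with_seed(seed, {
    best <- NULL; best_count <- 0L
    for (k in seq_len(config$max_iter)) {
      for (try in 1:50) {
        ij <- sample.int(n, 2L)
        if (x[ij[1]] != x[ij[2]] || y[ij[1]] != y[ij[2]]) break
        ij <- NULL
      }
      if (is.null(ij)) next
      dx <- x[ij[2]] - x[ij[1]]; dy <- y[ij[2]] - y[ij[1]]
      line <- normalize_line(c(dy, -dx, dx * y[ij[1]] - dy * x[ij[1]]))
      d <- line_distance(line, x, y)
      S <- which(d < config$threshold)
      if (length(S) > best_count && length(S) >= config$min_inliers) {
        best_count <- length(S)
        best <- list(line = line, inliers = S)
      }
    }
    if (is.null(best)) return(NULL)
    refit <- fit_line_tls(x[best$inliers], y[best$inliers])
    d <- line_distance(refit, x, y)
    inl <- which(d <= config$threshold)
    structure(list(coefficients = refit, inliers = inl,
                   n_inliers = length(inl),
                   anchors = anchors),
              class = "line_model")
  })
}

#' Spatial consistency filter on a fitted line
#'
#' Inliers are ordered by their projection along the line; runs separated by
#' gaps larger than 3x the median inter-anchor gap are split and only the
#' longest run (the dominant straight segment) is retained. If any anchor is
#' removed, the line is refit by total least squares.
#'
#' @param line a `line_model` from [ransac_fit()].
#' @return a `line_model`, refit if the filter removed points.
#' @export
consistency_filter <- function(line) {
  stopifnot(inherits(line, "line_model"))
  idx <- line$inliers
  if (length(idx) <= 2) return(line)
  a <- line$coefficients[1]; b <- line$coefficients[2]
  x <- line$anchors$x[idx]; y <- line$anchors$y[idx]
  t <- -b * x + a * y                      # projection along direction (-b, a)
  ord <- order(t)
  gaps <- diff(t[ord])
  med <- median(gaps)
  if (med <= 0 || all(gaps <= 3 * med)) return(line)
  cut <- which(gaps > 3 * med)
  starts <- c(1, cut + 1)
  ends <- c(cut, length(ord))
  runs <- cbind(starts, ends)
  lens <- ends - starts + 1
  keep_run <- which.max(lens)
  keep <- idx[ord[runs[keep_run, 1]:runs[keep_run, 2]]]
  if (length(keep) == length(idx)) return(line)
  refit <- fit_line_tls(line$anchors$x[keep], line$anchors$y[keep])
  structure(list(coefficients = refit, inliers = keep,
                 n_inliers = length(keep), anchors = line$anchors),
            class = "line_model")
}

#' Full navigation-line extraction pipeline
#'
#' Cluster -> per-instance anchors -> gap repair -> RANSAC -> consistency
#' filter; instances are ranked by mean x and the central `max_rows_kept`
#' are returned with positional labels.
#'
#' @param mask binary H x W matrix.
#' @param cluster_cfg a [cluster_config()].
#' @param ransac_cfg a [ransac_config()].
#' @param seed integer seed (per-instance RANSAC uses seed + instance id).
#' @return list of `line_model` objects with `$position` labels
#'   ("left"/"middle"/"right" for 3 rows, else "row_i"); empty list for an
#'   empty mask or when no instance yields a line.
#' @export
extract_navigation_lines <- function(mask, cluster_cfg = cluster_config(),
                                     ransac_cfg = ransac_config(), seed = 1L) {
  instances <- cluster_rows(mask, cluster_cfg)
  if (length(instances) == 0) return(list())
  lines <- list()
  for (inst in instances) {
    anchors <- extract_anchors(inst, cluster_cfg)
    anchors <- repair_anchors(anchors, inst, cluster_cfg)
    if (is.null(anchors) || nrow(anchors) < 2) next
    lm <- ransac_fit(anchors, ransac_cfg, seed = seed + inst$id)
    if (is.null(lm)) next
    lm <- consistency_filter(lm)
    lm$mean_x <- inst$mean_x
    lm$instance_id <- inst$id
    lines[[length(lines) + 1L]] <- lm
  }
  if (length(lines) == 0) return(list())
  mx <- vapply(lines, `[[`, numeric(1), "mean_x")
  ord <- order(mx)
  k <- min(cluster_config_rows_kept(cluster_cfg), length(lines))
  start <- (length(lines) - k) %/% 2 + 1
  sel <- ord[start:(start + k - 1)]
  out <- lines[sel]
  labels <- if (k == 3) c("left", "middle", "right") else paste0("row_", seq_len(k))
  for (i in seq_len(k)) out[[i]]$position <- labels[i]
  out
}

cluster_config_rows_kept <- function(cfg) cfg$max_rows_kept
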