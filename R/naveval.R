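# Navigation-line quality measures: angular deviation, horizontal distance
# deviation at sampled heights, anchor fitting accuracy, and per-position
# summaries (mean / sample SD).

#' Acute angle between two lines, in degrees
#'
#' `acos(|d1 . d2|)` over the unit direction vectors d = (-b, a); symmetric
#' in its arguments and invariant to coefficient sign flips.
#'
#' @param pred,truth lines as `line_model` objects or numeric c(a, b, c).
#' @return angle in degrees, in \[0, 90\].
#' @export
angle_deviation <- function(pred, truth) {
  p <- line_coeffs(pred); t <- line_coeffs(truth)
  d1 <- c(-p[2], p[1]); d2 <- c(-t[2], t[1])
  acos(clamp(abs(sum(d1 * d2)), 0, 1)) * 180 / pi
}

line_coeffs <- function(x) {
  if (inherits(x, "line_model")) return(normalize_line(x$coefficients))
  normalize_line(as.numeric(x))
}

#' Mean horizontal offset between two lines at sampled heights
#'
#' `mean over heights of |x_pred(y) - x_truth(y)|` with `x(y) = -(b y + c)/a`.
#' Horizontal lines (a = 0) have no x(y) and raise an error.
#'
#' @inheritParams angle_deviation
#' @param heights numeric vector of y positions (px).
#' @return mean absolute offset in px.
#' @export
horizontal_deviation <- function(pred, truth, heights) {
  p <- line_coeffs(pred); t <- line_coeffs(truth)
  if (abs(p[1]) < 1e-12 || abs(t[1]) < 1e-12) {
    stop("horizontal line (a = 0) has no x(y); deviation undefined",
         call. = FALSE)
  }
  xp <- -(p[2] * heights + p[3]) / p[1]
  xt <- -(t[2] * heights + t[3]) / t[1]
  mean(abs(xp - xt))
}

#' Fraction of anchors within a tolerance of a line
#'
#' @param anchors data.frame with columns x, y (non-empty).
#' @param line a `line_model` or c(a, b, c).
#' @param tol perpendicular-distance tolerance in px (default 5, the RANSAC
#'   inlier threshold).
#' @return fraction in \[0, 1\].
#' @export
anchor_fit_accuracy <- function(anchors, line, tol = 5) {
  if (is.null(anchors) || nrow(anchors) == 0) {
    stop("anchors must be non-empty", call. = FALSE)
  }
  l <- line_coeffs(line)
  mean(line_distance(l, anchors$x, anchors$y) <= tol)
}

#' Compare a fitted line against ground truth
#'
#' @param pred a `line_model` (its anchors are scored for fitting accuracy).
#' @param truth ground-truth line c(a, b, c) or `line_model`.
#' @param heights heights for the horizontal deviation (default: the pred
#'   anchors' y values).
#' @param tol anchor tolerance in px.
#' @return data.frame row: position, angle_dev, horiz_dev, anchor_acc.
#' @export
compare_line <- function(pred, truth, heights = NULL, tol = 5) {
  if (is.null(heights)) heights <- pred$anchors$y
  data.frame(position = if (!is.null(pred$position)) pred$position else NA,
             angle_dev = angle_deviation(pred, truth),
             horiz_dev = horizontal_deviation(pred, truth, heights),
             anchor_acc = anchor_fit_accuracy(pred$anchors, pred, tol))
}

#' Summarize line comparisons per row position
#'
#' Sample mean and sample standard deviation (n - 1 denominator) of each
#' measure per position; positions with fewer than 2 entries report SD 0 and
#' are flagged.
#'
#' @param comparisons data.frame with columns position, angle_dev, horiz_dev,
#'   anchor_acc (rows from [compare_line()]).
#' @return data.frame: position, measure, mean, sd, n, flagged.
#' @export
summarize_line_comparisons <- function(comparisons) {
  stopifnot(nrow(comparisons) > 0)
  out <- NULL
  for (pos in unique(comparisons$position)) {
    sub <- comparisons[comparisons$position == pos, ]
    for (meas in c("angle_dev", "horiz_dev", "anchor_acc")) {
      v <- sub[[meas]]
      s <- if (length(v) >= 2) sd(v) else 0
      out <- rbind(out, data.frame(position = pos, measure = meas,
                                   mean = mean(v), sd = s, n = length(v),
                                   flagged = length(v) < 2))
    }
  }
  out
}
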