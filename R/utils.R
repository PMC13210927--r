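#' @keywords internal
"_PACKAGE"

#' @useDynLib cropnav, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif rbinom median sd quantile
NULL

.cropnav <- new.env(parent = emptyenv())

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores the global RNG state so seeded components (scene
#' generation, augmentation, weight init, RANSAC) never perturb the caller's
#' random stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  set.seed(as.integer(seed))
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  force(expr)
}

# Round channel counts to a hardware-friendly multiple, never dropping below
# 90% of the requested width (MobileNet convention).
make_divisible <- function(v, divisor = 8L) {
  new_v <- max(divisor, as.integer(v + divisor / 2) %/% divisor * divisor)
  if (new_v < 0.9 * v) new_v <- new_v + divisor
  as.integer(new_v)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# 4-D tensor helper: dims c(H, W, C, N)
tensor4 <- function(x, H, W, C, N) array(x, dim = c(H, W, C, N))

stopifnot_binary <- function(m, what = "mask") {
  u <- unique(as.vector(m))
  if (!all(u %in% c(0, 1))) {
    stop(sprintf("%s must be binary (0/1); found other values", what), call. = FALSE)
  }
  invisible(TRUE)
}
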