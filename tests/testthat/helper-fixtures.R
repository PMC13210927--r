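# Shared fixtures: small seeded scene configurations and a naive direct
# convolution used as the independent oracle for the C++ kernels.

# 128-px scenes with geometry scaled 1/4 from the 512-px defaults
small_scene_config <- function(seed = 1L, ...) {
  scene_config(image_height = 128L, image_width = 128L, n_rows = 3L,
               row_spacing = 30, plant_spacing = 14,
               plant_radius_range = c(2.5, 4), gap_probability = 0.05,
               weed_density = 3, seed = seed, ...)
}

scene_to_pair <- function(scene) {
  spec <- normalization_spec(resize_to = c(nrow(scene$mask), ncol(scene$mask)),
                             scale = 1)
  list(image = preprocess(scene$image, spec), mask = scene$mask)
}

# Direct-summation convolution oracle (independent of the im2col path).
naive_conv2d <- function(x, w, b, stride = 1, pad = 0, dil = 1, groups = 1) {
  H <- dim(x)[1]; W <- dim(x)[2]; C <- dim(x)[3]; N <- dim(x)[4]
  kh <- dim(w)[1]; kw <- dim(w)[2]; Cg <- dim(w)[3]; Cout <- dim(w)[4]
  Cog <- Cout / groups
  Ho <- (H + 2 * pad - (dil * (kh - 1) + 1)) %/% stride + 1
  Wo <- (W + 2 * pad - (dil * (kw - 1) + 1)) %/% stride + 1
  out <- array(0, c(Ho, Wo, Cout, N))
  for (n in 1:N) for (co in 1:Cout) {
    g <- (co - 1) %/% Cog
    for (ho in 1:Ho) for (wo in 1:Wo) {
      acc <- if (length(b)) b[co] else 0
      for (ci in 1:Cg) for (i in 1:kh) for (j in 1:kw) {
        hi <- (ho - 1) * stride - pad + (i - 1) * dil + 1
        wi <- (wo - 1) * stride - pad + (j - 1) * dil + 1
        if (hi >= 1 && hi <= H && wi >= 1 && wi <= W) {
          acc <- acc + x[hi, wi, g * Cg + ci, n] * w[i, j, ci, co]
        }
      }
      out[ho, wo, co, n] <- acc
    }
  }
  out
}

# Collinear anchors on x = m*y + x0 at the given heights.
collinear_anchors <- function(n, slope = 0, x0 = 40, y_step = 20) {
  y <- seq(0, by = y_step, length.out = n)
  data.frame(x = x0 + slope * y, y = y)
}
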