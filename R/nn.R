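# Small module system on top of the autodiff ops: each module is an
# environment with named parameter nodes, child modules and a forward
# closure. Parameters are collected recursively for the optimizer and for
# parameter counting.

cn_module <- function(type) {
  m <- new.env(parent = emptyenv())
  m$type <- type
  m$params <- list()
  m$children <- list()
  class(m) <- c(paste0("cn_", type), "cn_module")
  m
}

#' Collect all trainable parameters of a model
#' @param m a model/module built by [build_model()] or an internal constructor.
#' @return named list of parameter nodes (each with `$value`, `$grad`).
#' @keywords internal
module_params <- function(m, prefix = "") {
  out <- list()
  for (nm in names(m$params)) {
    out[[paste0(prefix, nm)]] <- m$params[[nm]]
  }
  for (nm in names(m$children)) {
    out <- c(out, module_params(m$children[[nm]], paste0(prefix, nm, ".")))
  }
  out
}

#' Count trainable parameters
#'
#' Sums the element counts of every trainable parameter tensor (convolution
#' weights/biases, batch-norm scale/shift; running statistics are buffers and
#' excluded).
#'
#' @param model a built model or any module.
#' @return integer-valued numeric count.
#' @export
count_parameters <- function(model) {
  ps <- module_params(model)
  sum(vapply(ps, function(p) length(p$value), numeric(1)))
}

kaiming_init <- function(kh, kw, cin_g, cout) {
  fan_in <- kh * kw * cin_g
  array(rnorm(kh * kw * cin_g * cout, sd = sqrt(2 / fan_in)),
        dim = c(kh, kw, cin_g, cout))
}

cn_conv <- function(cin, cout, k = 3L, stride = 1L, pad = NULL, dil = 1L,
                    groups = 1L, bias = TRUE) {
  m <- cn_module("conv")
  if (is.null(pad)) pad <- (dil * (k - 1L)) %/% 2L
  m$cfg <- list(cin = cin, cout = cout, k = as.integer(k),
                stride = as.integer(stride), pad = as.integer(pad),
                dil = as.integer(dil), groups = as.integer(groups))
  m$params$w <- ag_param(kaiming_init(k, k, cin %/% groups, cout))
  if (bias) m$params$b <- ag_param(numeric(cout))
  m$forward <- function(x, training = FALSE) {
    ag_conv2d(x, m$params$w, m$params$b, m$cfg$stride, m$cfg$pad,
              m$cfg$dil, m$cfg$groups)
  }
  m
}

cn_bn <- function(C) {
  m <- cn_module("bn")
  m$params$gamma <- ag_param(rep(1, C))
  m$params$beta <- ag_param(numeric(C))
  m$running <- new.env(parent = emptyenv())
  m$running$mean <- numeric(C)
  m$running$var <- rep(1, C)
  m$forward <- function(x, training = FALSE) {
    ag_batchnorm(x, m$params$gamma, m$params$beta, m$running, training)
  }
  m
}

# conv -> batch norm -> activation; the workhorse block. Attention-logit
# layers use bare convs instead (no BN, no activation).
cn_cba <- function(cin, cout, k = 3L, stride = 1L, pad = NULL, dil = 1L,
                   groups = 1L, act = "relu6") {
  m <- cn_module("cba")
  m$children$conv <- cn_conv(cin, cout, k, stride, pad, dil, groups, bias = FALSE)
  m$children$bn <- cn_bn(cout)
  m$act <- act
  m$forward <- function(x, training = FALSE) {
    y <- m$children$conv$forward(x, training)
    y <- m$children$bn$forward(y, training)
    switch(m$act, relu6 = ag_relu6(y), relu = ag_relu(y), none = y)
  }
  m
}

cn_sequential <- function(mods) {
  m <- cn_module("sequential")
  if (is.null(names(mods))) names(mods) <- paste0("m", seq_along(mods))
  m$children <- mods
  m$forward <- function(x, training = FALSE) {
    for (ch in m$children) x <- ch$forward(x, training)
    x
  }
  m
}
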