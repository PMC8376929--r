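## Minimal layer framework backing the detector and grading networks.
##
## Tensors are plain R arrays with dim = c(H, W, C, N); vector features are
## matrices with dim = c(d, N). Layers are environments holding `params`,
## `grads` and closures `fwd(x, train)` / `bwd(gy)`; `bwd` accumulates
## parameter gradients and returns the input gradient, so layer objects have
## reference semantics and can be shared between passes only via batching.

new_layer <- function(type) {
  l <- new.env(parent = emptyenv())
  l$type <- type
  l$params <- list()
  l$grads <- list()
  l
}

#' @keywords internal
nn_conv2d <- function(in_ch, out_ch, kernel, stride = 1L, pad = 0L,
                      groups = 1L, init_gain = 2) {
  stopifnot(in_ch %% groups == 0, out_ch %% groups == 0)
  l <- new_layer("conv2d")
  l$stride <- as.integer(stride); l$pad <- as.integer(pad)
  l$groups <- as.integer(groups)
  cg <- in_ch %/% groups
  fan_in <- kernel * kernel * cg
  l$params <- list(
    W = array(stats::rnorm(kernel * kernel * cg * out_ch,
                           sd = sqrt(init_gain / fan_in)),
              dim = c(kernel, kernel, cg, out_ch)),
    b = numeric(out_ch))
  l$grads <- list(W = array(0, dim(l$params$W)), b = numeric(out_ch))
  l$fwd <- function(x, train = FALSE) {
    l$x <- x
    conv2d_fwd_cpp(x, l$params$W, l$params$b, l$stride, l$pad, l$groups)
  }
  l$bwd <- function(gy) {
    r <- conv2d_bwd_cpp(l$x, l$params$W, gy, l$stride, l$pad, l$groups)
    l$grads$W <- l$grads$W + r$gw
    l$grads$b <- l$grads$b + r$gb
    r$gx
  }
  l
}

#' @keywords internal
nn_linear <- function(in_dim, out_dim, bias = TRUE, init_gain = 2) {
  l <- new_layer("linear")
  l$params <- list(W = matrix(stats::rnorm(out_dim * in_dim,
                                           sd = sqrt(init_gain / in_dim)),
                              out_dim, in_dim))
  l$grads <- list(W = matrix(0, out_dim, in_dim))
  if (bias) {
    l$params$b <- numeric(out_dim)
    l$grads$b <- numeric(out_dim)
  }
  l$fwd <- function(x, train = FALSE) {
    l$x <- x
    y <- l$params$W %*% x
    if (!is.null(l$params$b)) y <- y + l$params$b
    y
  }
  l$bwd <- function(gy) {
    l$grads$W <- l$grads$W + gy %*% t(l$x)
    if (!is.null(l$params$b)) l$grads$b <- l$grads$b + rowSums(gy)
    t(l$params$W) %*% gy
  }
  l
}

#' @keywords internal
nn_relu <- function() {
  l <- new_layer("relu")
  l$fwd <- function(x, train = FALSE) {
    l$mask <- x > 0
    x * l$mask
  }
  l$bwd <- function(gy) gy * l$mask
  l
}

#' @keywords internal
nn_maxpool2 <- function() {
  l <- new_layer("maxpool2")
  l$fwd <- function(x, train = FALSE) {
    l$xdim <- dim(x)
    r <- maxpool2_fwd_cpp(x)
    l$argmax <- r$argmax
    r$out
  }
  l$bwd <- function(gy) maxpool2_bwd_cpp(l$argmax, gy, as.integer(l$xdim))
  l
}

#' @keywords internal
nn_flatten <- function() {
  l <- new_layer("flatten")
  l$fwd <- function(x, train = FALSE) {
    l$xdim <- dim(x)
    dim(x) <- c(prod(l$xdim[1:3]), l$xdim[4])
    x
  }
  l$bwd <- function(gy) {
    dim(gy) <- l$xdim
    gy
  }
  l
}

#' @keywords internal
nn_gap <- function() {
  # global average pooling (H,W,C,N) -> (C,N)
  l <- new_layer("gap")
  l$fwd <- function(x, train = FALSE) {
    d <- dim(x); l$xdim <- d
    m <- matrix(x, d[1] * d[2], d[3] * d[4])
    matrix(colMeans(m), d[3], d[4])
  }
  l$bwd <- function(gy) {
    d <- l$xdim
    array(rep(as.numeric(gy), each = d[1] * d[2]) / (d[1] * d[2]), dim = d)
  }
  l
}

#' @keywords internal
nn_dropout <- function(p = 0.5) {
  l <- new_layer("dropout")
  l$p <- p
  l$fwd <- function(x, train = FALSE) {
    if (!train || l$p <= 0) {
      l$mask <- NULL
      return(x)
    }
    l$mask <- (stats::runif(length(x)) >= l$p) / (1 - l$p)
    dim(l$mask) <- dim(x)
    x * l$mask
  }
  l$bwd <- function(gy) if (is.null(l$mask)) gy else gy * l$mask
  l
}

sigmoid <- function(x) 1 / (1 + exp(-x))

softmax_cols <- function(z) {
  z <- exp(sweep(z, 2, apply(z, 2, max)))
  sweep(z, 2, colSums(z), "/")
}

seq_fwd <- function(layers, x, train = FALSE) {
  for (l in layers) x <- l$fwd(x, train)
  x
}

seq_bwd <- function(layers, gy) {
  for (l in rev(layers)) gy <- l$bwd(gy)
  gy
}

## ---- parameter bookkeeping -------------------------------------------------

param_layers <- function(x) {
  # flatten any nesting of layers / modules (lists with a `layers` field)
  if (is.environment(x)) {
    if (!is.null(x$layers)) return(param_layers(x$layers))
    if (length(x$params)) return(list(x))
    return(list())
  }
  if (is.list(x)) return(do.call(c, lapply(x, param_layers)))
  list()
}

zero_grads <- function(layers) {
  for (l in param_layers(layers))
    for (nm in names(l$grads))
      l$grads[[nm]] <- l$grads[[nm]] * 0
  invisible(NULL)
}

get_params <- function(layers) {
  lapply(param_layers(layers), function(l) l$params)
}

set_params <- function(layers, values) {
  pl <- param_layers(layers)
  stopifnot(length(pl) == length(values))
  for (i in seq_along(pl)) pl[[i]]$params <- values[[i]]
  invisible(NULL)
}

## ---- Adam ------------------------------------------------------------------

#' @keywords internal
adam_new <- function(layers, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  opt <- new.env(parent = emptyenv())
  opt$layers <- param_layers(layers)
  opt$beta1 <- beta1; opt$beta2 <- beta2; opt$eps <- eps
  opt$t <- 0L
  opt$m <- lapply(opt$layers, function(l) lapply(l$params, function(p) p * 0))
  opt$v <- opt$m
  opt
}

#' @keywords internal
adam_step <- function(opt, lr, weight_decay = 0) {
  opt$t <- opt$t + 1L
  b1 <- opt$beta1; b2 <- opt$beta2
  c1 <- 1 - b1^opt$t; c2 <- 1 - b2^opt$t
  for (i in seq_along(opt$layers)) {
    l <- opt$layers[[i]]
    for (nm in names(l$params)) {
      g <- l$grads[[nm]]
      if (weight_decay > 0) g <- g + weight_decay * l$params[[nm]]
      opt$m[[i]][[nm]] <- b1 * opt$m[[i]][[nm]] + (1 - b1) * g
      opt$v[[i]][[nm]] <- b2 * opt$v[[i]][[nm]] + (1 - b2) * g * g
      mhat <- opt$m[[i]][[nm]] / c1
      vhat <- opt$v[[i]][[nm]] / c2
      l$params[[nm]] <- l$params[[nm]] - lr * mhat / (sqrt(vhat) + opt$eps)
    }
  }
  invisible(NULL)
}

## ---- serialization helpers -------------------------------------------------

# Models are rebuilt from their config and parameter values; environments are
# not serialized directly.
model_state <- function(model) {
  list(config = model$config, params = get_params(model$layers))
}
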