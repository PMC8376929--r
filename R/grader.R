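## SE-ResNext grading networks: a Siamese two-patch model with adaptive
## gated feature fusion and a single-branch whole-knee variant, both with
## eight task heads (KL 0-4, six OARSI features 0-3, OA binary).

task_sizes <- function() {
  c(kl = 5L, fl = 4L, fm = 4L, tl = 4L, tm = 4L, jsn_l = 4L, jsn_m = 4L,
    oa = 2L)
}

#' Squeeze-and-excitation module
#'
#' Channel recalibration: per-channel global average pooling (squeeze),
#' a two-layer bottleneck `w = sigmoid(W2 relu(W1 z))` with reduction ratio
#' `r` (excitation), and channel-wise rescaling of the feature map by `w`.
#'
#' @param channels number of feature-map channels `C`.
#' @param reduction reduction ratio `r`; `C` must be divisible by `r`.
#' @return a module usable inside [resnext_block()]; call via `$fwd(x)` /
#'   `$bwd(gy)` on `(H, W, C, N)` arrays.
#' @export
se_block <- function(channels, reduction = 16L) {
  if (channels %% reduction != 0)
    stop("se_block: channels must be divisible by the reduction ratio")
  m <- new.env(parent = emptyenv())
  m$l1 <- nn_linear(channels, channels %/% reduction, bias = FALSE)
  m$l2 <- nn_linear(channels %/% reduction, channels, bias = FALSE)
  m$layers <- list(m$l1, m$l2)
  m$fwd <- function(x, train = FALSE) {
    d <- dim(x); m$xdim <- d
    hw <- d[1] * d[2]
    z <- matrix(colMeans(matrix(x, hw, d[3] * d[4])), d[3], d[4])
    s <- m$l1$fwd(z, train)
    m$smask <- s > 0
    wgt <- sigmoid(m$l2$fwd(s * m$smask, train))
    m$x <- x; m$wgt <- wgt
    x * array(rep(wgt, each = hw), dim = d)
  }
  m$bwd <- function(gy) {
    d <- m$xdim; hw <- d[1] * d[2]
    wb <- array(rep(m$wgt, each = hw), dim = d)
    gx_direct <- gy * wb
    gw <- matrix(colSums(matrix(gy * m$x, hw, d[3] * d[4])), d[3], d[4])
    ga <- gw * m$wgt * (1 - m$wgt)          # through the sigmoid
    gs <- m$l2$bwd(ga) * m$smask            # through ReLU
    gz <- m$l1$bwd(gs)
    gx_direct + array(rep(gz / hw, each = hw), dim = d)
  }
  m
}

#' Aggregated-transform residual block with squeeze-and-excitation
#'
#' `y = relu(x + SE(expand(gconv(reduce(x)))))` where `reduce` is a 1x1
#' convolution to `cardinality * bottleneck_width` channels, `gconv` a 3x3
#' grouped convolution with `cardinality` groups (the grouped form of the
#' sum of `cardinality` parallel bottleneck transforms), and `expand` a 1x1
#' convolution back to `out_channels`. A 1x1 projection shortcut is inserted
#' when input and output widths differ.
#'
#' @param in_channels,out_channels block widths.
#' @param cardinality number of aggregated transforms (groups).
#' @param bottleneck_width channels per transform.
#' @param reduction SE reduction ratio.
#' @return a module; call via `$fwd(x, train)` / `$bwd(gy)`.
#' @export
resnext_block <- function(in_channels, out_channels, cardinality = 32L,
                          bottleneck_width = 4L, reduction = 16L) {
  stopifnot(cardinality >= 1)
  b <- cardinality * bottleneck_width
  m <- new.env(parent = emptyenv())
  m$reduce <- nn_conv2d(in_channels, b, 1)
  m$r1 <- nn_relu()
  m$gconv <- nn_conv2d(b, b, 3, pad = 1, groups = cardinality)
  m$r2 <- nn_relu()
  m$expand <- nn_conv2d(b, out_channels, 1)
  m$se <- se_block(out_channels, reduction)
  m$proj <- if (in_channels != out_channels)
    nn_conv2d(in_channels, out_channels, 1) else NULL
  m$rout <- nn_relu()
  m$layers <- c(list(m$reduce, m$gconv, m$expand, m$se),
                if (!is.null(m$proj)) list(m$proj))
  m$fwd <- function(x, train = FALSE) {
    idt <- if (is.null(m$proj)) x else m$proj$fwd(x, train)
    h <- m$r2$fwd(m$gconv$fwd(m$r1$fwd(m$reduce$fwd(x, train), train),
                              train), train)
    h <- m$se$fwd(m$expand$fwd(h, train), train)
    m$rout$fwd(h + idt, train)
  }
  m$bwd <- function(gy) {
    g <- m$rout$bwd(gy)
    gb <- m$reduce$bwd(m$r1$bwd(m$gconv$bwd(m$r2$bwd(
      m$expand$bwd(m$se$bwd(g))))))
    gidt <- if (is.null(m$proj)) g else m$proj$bwd(g)
    gb + gidt
  }
  m
}

#' Backbone configuration
#'
#' Two profiles: `"tiny"` (stem of width 16, two SE-ResNext stages of widths
#' 32 and 64 with cardinality 8 and bottleneck width 2, feature dimension
#' 64) for CPU-scale training, and `"full"`, the 50-layer plan (stem 64,
#' stages of 3/4/6/3 blocks with widths 256/512/1024/2048, cardinality 32,
#' bottleneck width 4, reduction 16, feature dimension 2048).
#'
#' @param profile `"tiny"` or `"full"`.
#' @param input_size expected square patch side (tiny 48, full 128).
#' @return a `backbone_config` list.
#' @export
backbone_config <- function(profile = c("tiny", "full"), input_size = NULL) {
  profile <- match.arg(profile)
  if (profile == "tiny") {
    list(profile = "tiny",
         input_size = if (is.null(input_size)) 48L else as.integer(input_size),
         stem = 16L, widths = c(32L, 64L), blocks = c(1L, 1L),
         cardinality = 8L, bottleneck_width = 2L, reduction = 8L,
         feature_dim = 64L)
  } else {
    list(profile = "full",
         input_size = if (is.null(input_size)) 128L else as.integer(input_size),
         stem = 64L, widths = c(256L, 512L, 1024L, 2048L),
         blocks = c(3L, 4L, 6L, 3L), cardinality = 32L,
         bottleneck_width = 4L, reduction = 16L, feature_dim = 2048L)
  }
}

build_backbone <- function(cfg) {
  m <- new.env(parent = emptyenv())
  m$cfg <- cfg
  chain <- if (cfg$profile == "full")
    list(nn_conv2d(1, cfg$stem, 7, stride = 2, pad = 3), nn_relu(),
         nn_maxpool2())
  else # tiny: stride-2 stem keeps CPU cost down
    list(nn_conv2d(1, cfg$stem, 3, stride = 2, pad = 1), nn_relu(),
         nn_maxpool2())
  in_ch <- cfg$stem
  for (s in seq_along(cfg$widths)) {
    width <- cfg$widths[s]
    card <- cfg$cardinality
    bw <- if (cfg$profile == "full")
      cfg$bottleneck_width * 2^(s - 1) else cfg$bottleneck_width
    for (k in seq_len(cfg$blocks[s])) {
      chain[[length(chain) + 1L]] <-
        resnext_block(in_ch, width, cardinality = card,
                      bottleneck_width = bw, reduction = cfg$reduction)
      in_ch <- width
    }
    chain[[length(chain) + 1L]] <- nn_maxpool2()
  }
  chain[[length(chain) + 1L]] <- nn_gap()
  m$chain <- chain
  m$layers <- chain
  m
}

#' Run the shared backbone on a batch of patches
#'
#' @param model a grader model (see [build_siamese_grader()]).
#' @param patches array `(H, W, 1, N)` of normalized intensities.
#' @param train enable training mode (dropout etc.).
#' @return feature matrix `(d, N)`.
#' @export
backbone_forward <- function(model, patches, train = FALSE) {
  cfg <- model$backbone$cfg
  if (dim(patches)[1] != cfg$input_size || dim(patches)[2] != cfg$input_size)
    stop("backbone_forward: patch size does not match the configured input")
  seq_fwd(model$backbone$chain, patches, train)
}

#' Adaptive gated feature fusion
#'
#' `g = sigmoid(W_g (f_left (+) f_right))` elementwise, and
#' `f = g * f_left + (1 - g) * f_right`: a learned convex combination of the
#' two patch features, computed per feature dimension.
#'
#' @param f_left,f_right feature matrices `(d, N)`.
#' @param W_g gate parameter matrix `(d, 2d)`.
#' @return list with the fused features `f` and the gate `g` (both
#'   `(d, N)`).
#' @export
gated_fuse <- function(f_left, f_right, W_g) {
  if (!all(dim(f_left) == dim(f_right)))
    stop("gated_fuse: feature length mismatch")
  d <- nrow(f_left)
  if (ncol(W_g) != 2 * d || nrow(W_g) != d)
    stop("gated_fuse: W_g must map 2d -> d")
  g <- sigmoid(W_g %*% rbind(f_left, f_right))
  list(f = g * f_left + (1 - g) * f_right, g = g)
}

# fusion as a trainable module
fusion_module <- function(d) {
  m <- new.env(parent = emptyenv())
  m$lin <- nn_linear(2L * d, d, bias = FALSE, init_gain = 0.1)
  m$d <- d
  m$layers <- list(m$lin)
  m$fwd <- function(f_left, f_right, train = FALSE) {
    m$fl <- f_left; m$fr <- f_right
    m$g <- sigmoid(m$lin$fwd(rbind(f_left, f_right), train))
    m$g * f_left + (1 - m$g) * f_right
  }
  m$bwd <- function(gf) {
    ga <- gf * (m$fl - m$fr) * m$g * (1 - m$g)
    gu <- m$lin$bwd(ga)
    d <- m$d
    list(gfl = gf * m$g + gu[seq_len(d), , drop = FALSE],
         gfr = gf * (1 - m$g) + gu[d + seq_len(d), , drop = FALSE])
  }
  m
}

# eight task heads with a shared dropout before the linear layers
heads_module <- function(d, dropout = 0.5) {
  m <- new.env(parent = emptyenv())
  ts <- task_sizes()
  m$drop <- nn_dropout(dropout)
  m$heads <- lapply(ts, function(k) nn_linear(d, k, init_gain = 0.05))
  m$layers <- m$heads
  m$fwd <- function(f, train = FALSE) {
    fd <- m$drop$fwd(f, train)
    lapply(m$heads, function(hl) hl$fwd(fd, train))
  }
  m$bwd <- function(glogits) {
    gf <- 0
    for (nm in names(m$heads)) gf <- gf + m$heads[[nm]]$bwd(glogits[[nm]])
    m$drop$bwd(gf)
  }
  m
}

#' Build the Siamese grading model
#'
#' Two weight-shared SE-ResNext branches (realized by batching both patches
#' through one backbone), adaptive gated fusion of the pooled features, and
#' eight softmax task heads with dropout 0.5 before each fully connected
#' layer.
#'
#' @param cfg a [backbone_config].
#' @param dropout dropout rate before the heads.
#' @return a grader model (environment), `mode = "siamese"`.
#' @export
build_siamese_grader <- function(cfg = backbone_config("tiny"),
                                 dropout = 0.5) {
  m <- new.env(parent = emptyenv())
  m$config <- cfg
  m$mode <- "siamese"
  m$backbone <- build_backbone(cfg)
  m$fusion <- fusion_module(cfg$feature_dim)
  m$heads <- heads_module(cfg$feature_dim, dropout)
  m$layers <- list(m$backbone, m$fusion, m$heads)
  m$fc_layers <- list(m$fusion, m$heads)
  m$backbone_layers <- list(m$backbone)
  class(m) <- "knee_grader"
  m
}

#' Build the whole-knee (global) grading model
#'
#' A single SE-ResNext branch over the whole knee region with the same eight
#' task heads; the global member of the global+local ensemble.
#'
#' @inheritParams build_siamese_grader
#' @return a grader model, `mode = "global"`.
#' @export
build_global_grader <- function(cfg = backbone_config("tiny"),
                                dropout = 0.5) {
  m <- build_siamese_grader(cfg, dropout)
  m$mode <- "global"
  m$layers <- list(m$backbone, m$heads)
  m$fc_layers <- list(m$heads)
  m
}

# forward pass: left/right are (H,W,1,N) arrays (for global mode only left
# is used). Returns logits (list) and caches for backward.
grader_forward <- function(model, left, right = NULL, train = FALSE) {
  n <- dim(left)[4]
  if (model$mode == "siamese") {
    if (is.null(right))
      stop("siamese model needs both left and right patches")
    both <- array(c(left, right), dim = c(dim(left)[1:3], 2L * n))
    feats <- backbone_forward(model, both, train)
    fl <- feats[, seq_len(n), drop = FALSE]
    fr <- feats[, n + seq_len(n), drop = FALSE]
    f <- model$fusion$fwd(fl, fr, train)
  } else {
    f <- backbone_forward(model, left, train)
  }
  model$heads$fwd(f, train)
}

grader_backward <- function(model, glogits, backbone = TRUE) {
  gf <- model$heads$bwd(glogits)
  if (model$mode == "siamese") {
    gb <- model$fusion$bwd(gf)
    if (backbone)
      seq_bwd(model$backbone$chain, cbind(gb$gfl, gb$gfr))
  } else if (backbone) {
    seq_bwd(model$backbone$chain, gf)
  }
  invisible(NULL)
}

#' Predict grades for prepared patches
#'
#' @param model a trained grader model.
#' @param left,right arrays `(H, W, 1, N)` of normalized patches (`right`
#'   ignored in global mode).
#' @return a `grade_prediction` list: `probs` (per-task `K x N` probability
#'   matrices, columns summing to 1) and `grades` (per-task argmax grades,
#'   0-based).
#' @export
predict_grades <- function(model, left, right = NULL) {
  logits <- grader_forward(model, left, right, train = FALSE)
  probs <- lapply(logits, softmax_cols)
  grades <- lapply(probs, function(p) max.col(t(p), ties.method = "first") - 1L)
  structure(list(probs = probs, grades = grades), class = "grade_prediction")
}

#' Ensemble of the global and Siamese graders
#'
#' Per-task probabilities are the arithmetic mean of the two models'
#' probability vectors; grades are the argmax of the mean.
#'
#' @param global_model,siamese_model trained graders with compatible task
#'   spaces.
#' @param roi whole-knee array `(H, W, 1, N)` for the global model.
#' @param left,right patch arrays for the Siamese model.
#' @return a `grade_prediction`.
#' @export
ensemble_predict <- function(global_model, siamese_model, roi, left, right) {
  pg <- predict_grades(global_model, roi)
  ps <- predict_grades(siamese_model, left, right)
  if (!identical(lapply(pg$probs, nrow), lapply(ps$probs, nrow)))
    stop("ensemble_predict: task spaces do not match")
  probs <- Map(function(a, b) (a + b) / 2, pg$probs, ps$probs)
  grades <- lapply(probs, function(p) max.col(t(p), ties.method = "first") - 1L)
  structure(list(probs = probs, grades = grades), class = "grade_prediction")
}
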