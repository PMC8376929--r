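## Two-stage cascaded multi-task knee-joint detector.
##
## Stage 1 is a fully convolutional proposal network scanned over an image
## pyramid; stage 2 re-scores fixed-size crops and regresses the bounding box
## and six key points. Boxes are c(x_min, y_min, x_max, y_max), 0-based,
## half-open, origin top-left, y down.

#' Cascade detector configuration
#'
#' @param stage1_input_size proposal-network window (default 48).
#' @param stage2_input_size refinement-network input (default 96).
#' @param pyramid_scale_factor geometric pyramid factor in (0,1)
#'   (default 0.709).
#' @param min_knee_size smallest detectable knee in pixels (default 80); the
#'   first pyramid scale is `stage1_input_size / min_knee_size`.
#' @param stage1_score_threshold,stage2_score_threshold proposal / refinement
#'   score cut-offs (defaults 0.6, 0.7).
#' @param nms_iou_stage1,nms_iou_stage2 NMS overlap thresholds (0.7, 0.5).
#' @param alpha_stage1,alpha_stage2 per-stage loss weights
#'   `c(det, box, kp)`; defaults `c(1, 0.5, 0)` and `c(0.8, 0.6, 1.5)`.
#' @param stage1_channels,stage2_channels convolution widths.
#' @param stage2_fc hidden width of the stage-2 fully connected layer.
#' @return a `cascade_config` list.
#' @export
cascade_config <- function(stage1_input_size = 48L, stage2_input_size = 96L,
                           pyramid_scale_factor = 0.709, min_knee_size = 80L,
                           stage1_score_threshold = 0.6,
                           stage2_score_threshold = 0.7,
                           nms_iou_stage1 = 0.7, nms_iou_stage2 = 0.5,
                           alpha_stage1 = c(det = 1, box = 0.5, kp = 0),
                           alpha_stage2 = c(det = 0.8, box = 0.6, kp = 1.5),
                           stage1_channels = c(16L, 32L, 64L),
                           stage2_channels = c(32L, 64L, 64L, 128L),
                           stage2_fc = 256L) {
  stopifnot(pyramid_scale_factor > 0, pyramid_scale_factor < 1,
            stage1_score_threshold > 0, stage1_score_threshold < 1,
            stage2_score_threshold > 0, stage2_score_threshold < 1)
  if (any(c(alpha_stage1, alpha_stage2) < 0))
    stop("cascade_config: loss weights alpha must be >= 0")
  structure(as.list(environment()), class = "cascade_config")
}

#' Build the stage-1 proposal network
#'
#' Fully convolutional: three 3x3 convolution + 2x2 max-pool stages followed
#' by three further convolutions (3x3, 2x2 and the 1x1 heads). Applied to a
#' `stage1_input_size` window the output grid is 1x1; on larger inputs the
#' network slides with stride 8 and window `stage1_input_size`. Per location
#' it emits a knee/non-knee score (logit) and 4 box offsets normalized by the
#' window side.
#'
#' @param config a [cascade_config].
#' @return network object (environment) used by [stage1_forward()].
#' @export
build_stage1 <- function(config = cascade_config()) {
  ch <- config$stage1_channels
  net <- new.env(parent = emptyenv())
  net$config <- config
  net$trunk <- list(
    nn_conv2d(1, ch[1], 3), nn_relu(), nn_maxpool2(),
    nn_conv2d(ch[1], ch[2], 3), nn_relu(), nn_maxpool2(),
    nn_conv2d(ch[2], ch[3], 3), nn_relu(), nn_maxpool2(),
    nn_conv2d(ch[3], ch[3], 3), nn_relu(),
    nn_conv2d(ch[3], 2 * ch[3], 2), nn_relu())
  net$head_score <- nn_conv2d(2 * ch[3], 1, 1, init_gain = 1)
  net$head_box <- nn_conv2d(2 * ch[3], 4, 1, init_gain = 1)
  net$layers <- c(net$trunk, list(net$head_score, net$head_box))
  net$stride <- 8L
  class(net) <- "knee_stage1"
  net
}

stage1_forward <- function(net, x, train = FALSE) {
  h <- seq_fwd(net$trunk, x, train)
  list(score = net$head_score$fwd(h, train),
       box = net$head_box$fwd(h, train))
}

stage1_backward <- function(net, gscore, gbox) {
  gh <- net$head_score$bwd(gscore) + net$head_box$bwd(gbox)
  seq_bwd(net$trunk, gh)
}

#' Build the stage-2 refinement network
#'
#' Three 3x3 convolution + 2x2 max-pool stages, one further convolution, and
#' two fully connected layers ending in a 17-dimensional output: 1 knee
#' score (logit), 4 box offsets and 12 key-point coordinates normalized to
#' the candidate window.
#'
#' @param config a [cascade_config].
#' @return network object used by [stage2_forward()].
#' @export
build_stage2 <- function(config = cascade_config()) {
  ch <- config$stage2_channels
  s <- config$stage2_input_size
  # spatial size after the conv/pool stack (valid convs, floor pooling)
  sz <- s
  for (i in 1:3) sz <- (sz - 2) %/% 2
  sz <- sz - 2
  if (sz < 1) stop("stage2_input_size too small for the network")
  net <- new.env(parent = emptyenv())
  net$config <- config
  net$feat_dim <- sz * sz * ch[4]
  net$trunk <- list(
    nn_conv2d(1, ch[1], 3), nn_relu(), nn_maxpool2(),
    nn_conv2d(ch[1], ch[2], 3), nn_relu(), nn_maxpool2(),
    nn_conv2d(ch[2], ch[3], 3), nn_relu(), nn_maxpool2(),
    nn_conv2d(ch[3], ch[4], 3), nn_relu(),
    nn_flatten(),
    nn_linear(net$feat_dim, config$stage2_fc), nn_relu())
  net$head <- nn_linear(config$stage2_fc, 17L, init_gain = 1)
  net$layers <- c(net$trunk, list(net$head))
  class(net) <- "knee_stage2"
  net
}

stage2_forward <- function(net, x, train = FALSE) {
  s <- net$config$stage2_input_size
  if (dim(x)[1] != s || dim(x)[2] != s)
    stop("stage2 input must be resized to stage2_input_size")
  out <- net$head$fwd(seq_fwd(net$trunk, x, train), train)
  list(score = out[1, , drop = FALSE], box = out[2:5, , drop = FALSE],
       kp = out[6:17, , drop = FALSE])
}

stage2_backward <- function(net, gscore, gbox, gkp) {
  gout <- rbind(gscore, gbox, gkp)
  seq_bwd(net$trunk, net$head$bwd(gout))
}

#' Multi-task detector loss
#'
#' Batch-averaged weighted sum
#' `alpha_det * CE + alpha_box * L2(box) + alpha_kp * L2(keypoints)`:
#' binary cross-entropy on the knee/non-knee score (positives and negatives
#' only; part samples excluded), and Euclidean (mean-squared, per
#' coordinate) losses on the box offsets (positives and parts) and key
#' points (positives). Returns the scalar loss with the logit gradients as
#' attributes, so one call serves both evaluation and the backward pass.
#'
#' @param pred list with `score` (logits, 1 x N), `box` (4 x N) and
#'   optionally `kp` (12 x N).
#' @param target list with `cls` (1 knee / 0 non-knee / NA part, length N),
#'   `box` (4 x N, NA where unsupervised), `kp` (12 x N or NULL).
#' @param alpha named weights `c(det, box, kp)`, all `>= 0`.
#' @return scalar loss; attributes `gscore`, `gbox`, `gkp` hold gradients.
#' @export
multitask_loss <- function(pred, target, alpha) {
  if (any(alpha < 0)) stop("multitask_loss: alpha must be >= 0")
  n <- length(target$cls)
  s <- as.numeric(pred$score)
  p <- sigmoid(s)
  cls_mask <- !is.na(target$cls)
  y <- ifelse(cls_mask, target$cls, 0)
  eps <- 1e-12
  ce <- -(y * log(p + eps) + (1 - y) * log(1 - p + eps)) * cls_mask
  gscore <- matrix((p - y) * cls_mask, 1, n) * alpha[["det"]] / n

  box_mask <- !is.na(target$box[1, ])
  db <- (pred$box - ifelse(is.na(target$box), 0, target$box))
  db <- sweep(db, 2, as.numeric(box_mask), "*")
  l_box <- colMeans(db^2)
  gbox <- 2 * db / nrow(pred$box) * alpha[["box"]] / n

  l_kp <- numeric(n); gkp <- NULL
  if (!is.null(pred$kp)) {
    kp_mask <- !is.na(target$kp[1, ])
    dk <- (pred$kp - ifelse(is.na(target$kp), 0, target$kp))
    dk <- sweep(dk, 2, as.numeric(kp_mask), "*")
    l_kp <- colMeans(dk^2)
    gkp <- 2 * dk / nrow(pred$kp) * alpha[["kp"]] / n
  }
  loss <- mean(alpha[["det"]] * ce + alpha[["box"]] * l_box +
                 alpha[["kp"]] * l_kp)
  attr(loss, "gscore") <- gscore
  attr(loss, "gbox") <- gbox
  attr(loss, "gkp") <- gkp
  loss
}

#' Image pyramid scales
#'
#' Scales `s_k = (stage1_input_size / min_knee_size) * factor^k`, kept while
#' the scaled smaller image side is at least `stage1_input_size`.
#'
#' @param img a [knee_image] (or intensity matrix).
#' @param config a [cascade_config].
#' @return numeric vector of strictly decreasing scales.
#' @export
build_pyramid_scales <- function(img, config = cascade_config()) {
  pix <- if (inherits(img, "knee_image")) img$pixels else img
  m <- min(dim(pix))
  if (m < config$min_knee_size)
    stop("empty pyramid: image smaller than min_knee_size")
  s <- config$stage1_input_size / config$min_knee_size
  scales <- numeric(0)
  while (m * s >= config$stage1_input_size) {
    scales <- c(scales, s)
    s <- s * config$pyramid_scale_factor
  }
  scales
}

#' Intersection over union of two boxes
#'
#' Boxes are `c(x_min, y_min, x_max, y_max)` under the half-open convention.
#'
#' @param a,b boxes.
#' @return IoU in `[0, 1]`.
#' @export
iou <- function(a, b) {
  iw <- min(a[3], b[3]) - max(a[1], b[1])
  ih <- min(a[4], b[4]) - max(a[2], b[2])
  if (iw <= 0 || ih <= 0) return(0)
  inter <- iw * ih
  inter / ((a[3] - a[1]) * (a[4] - a[2]) + (b[3] - b[1]) * (b[4] - b[2]) -
             inter)
}

#' Greedy non-maximum suppression
#'
#' Keeps the highest-scoring detection, removes all detections whose IoU
#' with a kept box exceeds the threshold, and repeats. Ties are broken by
#' the earlier index. Output is sorted by score, descending.
#'
#' @param boxes n x 4 matrix.
#' @param scores length-n vector in `[0, 1]`.
#' @param iou_threshold overlap threshold.
#' @return integer indices (into the input) of the retained detections.
#' @export
nms <- function(boxes, scores, iou_threshold) {
  n <- length(scores)
  if (n == 0) return(integer(0))
  ord <- order(-scores, seq_len(n))
  keep <- integer(0)
  alive <- rep(TRUE, n)
  for (i in ord) {
    if (!alive[i]) next
    keep <- c(keep, i)
    for (j in ord) {
      if (alive[j] && j != i &&
          iou(boxes[i, ], boxes[j, ]) > iou_threshold)
        alive[j] <- FALSE
    }
    alive[i] <- FALSE
  }
  keep
}

# Crop a window (possibly beyond the border: zero padded) and resize to
# side x side; returns intensities normalized to roughly [-0.5, 0.5].
crop_resize_norm <- function(pix, win, side) {
  x1 <- floor(win[1]); y1 <- floor(win[2])
  x2 <- ceiling(win[3]); y2 <- ceiling(win[4])
  h <- y2 - y1; w <- x2 - x1
  out <- matrix(0, h, w)
  if (y1 + 1 <= nrow(pix) && y2 >= 1 && x1 + 1 <= ncol(pix) && x2 >= 1) {
    sy <- max(1, y1 + 1):min(nrow(pix), y2)
    sx <- max(1, x1 + 1):min(ncol(pix), x2)
    out[sy - y1, sx - x1] <- pix[sy, sx]
  }
  resize_matrix(out, side, side) / 255 - 0.5
}

#' Detect the knee joint in a single-knee image
#'
#' Runs the full cascade: image pyramid, stage-1 sliding-window scoring with
#' box refinement and NMS, stage-2 re-scoring with box and key-point
#' regression, final NMS, and returns the single highest-scoring detection
#' with key points mapped back to image coordinates. Returns `NULL` when no
#' candidate survives the thresholds.
#'
#' @param img a standardized single-knee [knee_image] (or matrix).
#' @param stage1,stage2 trained networks from [build_stage1()] /
#'   [build_stage2()].
#' @param config a [cascade_config].
#' @return a detection `list(box, score, keypoints)` or `NULL`.
#' @export
detect_knee <- function(img, stage1, stage2, config = cascade_config()) {
  pix <- if (inherits(img, "knee_image")) img$pixels else img
  scales <- build_pyramid_scales(pix, config)
  s1 <- config$stage1_input_size
  cand <- list()
  for (sc in scales) {
    h <- max(s1, round(nrow(pix) * sc)); w <- max(s1, round(ncol(pix) * sc))
    small <- resize_matrix(pix, h, w) / 255 - 0.5
    x <- array(small, dim = c(h, w, 1, 1))
    out <- stage1_forward(stage1, x)
    sc_map <- sigmoid(out$score[, , 1, 1])
    if (is.null(dim(sc_map))) sc_map <- matrix(sc_map, dim(out$score)[1],
                                               dim(out$score)[2])
    hits <- which(sc_map >= config$stage1_score_threshold, arr.ind = TRUE)
    if (nrow(hits) == 0) next
    for (r in seq_len(nrow(hits))) {
      i <- hits[r, 1]; j <- hits[r, 2]
      win <- c((j - 1) * stage1$stride, (i - 1) * stage1$stride,
               (j - 1) * stage1$stride + s1, (i - 1) * stage1$stride + s1) / sc
      off <- out$box[i, j, , 1]
      side <- s1 / sc
      box <- win + off * side
      cand[[length(cand) + 1L]] <- list(box = box, score = sc_map[i, j])
    }
  }
  if (length(cand) == 0) return(NULL)
  boxes <- do.call(rbind, lapply(cand, `[[`, "box"))
  scores <- vapply(cand, `[[`, numeric(1), "score")
  keep <- nms(boxes, scores, config$nms_iou_stage1)
  boxes <- boxes[keep, , drop = FALSE]

  # stage 2: square crops around the refined candidates
  s2 <- config$stage2_input_size
  dets <- list()
  wins <- list()
  crops <- array(0, dim = c(s2, s2, 1, nrow(boxes)))
  for (k in seq_len(nrow(boxes))) {
    b <- boxes[k, ]
    side <- max(b[3] - b[1], b[4] - b[2]) * 1.05
    cx <- (b[1] + b[3]) / 2; cy <- (b[2] + b[4]) / 2
    win <- c(cx - side / 2, cy - side / 2, cx + side / 2, cy + side / 2)
    wins[[k]] <- win
    crops[, , 1, k] <- crop_resize_norm(pix, win, s2)
  }
  out2 <- stage2_forward(stage2, crops)
  p2 <- sigmoid(as.numeric(out2$score))
  ok <- which(p2 >= config$stage2_score_threshold)
  if (length(ok) == 0) return(NULL)
  fboxes <- matrix(0, length(ok), 4)
  fkps <- vector("list", length(ok))
  for (t in seq_along(ok)) {
    k <- ok[t]
    win <- wins[[k]]
    side <- win[3] - win[1]
    fboxes[t, ] <- win + out2$box[, k] * side
    fkps[[t]] <- cbind(win[1] + out2$kp[seq(1, 11, 2), k] * side,
                       win[2] + out2$kp[seq(2, 12, 2), k] * side)
  }
  keep2 <- nms(fboxes, p2[ok], config$nms_iou_stage2)
  best <- keep2[1]
  b <- fboxes[best, ]
  b <- c(max(0, b[1]), max(0, b[2]), min(ncol(pix), b[3]),
         min(nrow(pix), b[4]))
  list(box = b, score = p2[ok][best], keypoints = fkps[[best]])
}

#' Detection accuracy over paired detections and ground truths
#'
#' A knee counts as detected when a detection exists and its IoU with the
#' ground-truth box reaches `iou_min`.
#'
#' @param detections list of detections (or `NULL`s) from [detect_knee()].
#' @param truths list of ground-truth boxes.
#' @param iou_min IoU criterion (default 0.5).
#' @return fraction in `[0, 1]`.
#' @export
detection_accuracy <- function(detections, truths, iou_min = 0.5) {
  if (length(detections) != length(truths))
    stop("detection_accuracy: length mismatch")
  hit <- vapply(seq_along(truths), function(i) {
    d <- detections[[i]]
    !is.null(d) && iou(d$box, truths[[i]]) >= iou_min
  }, logical(1))
  mean(hit)
}
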