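## Training protocol for the grading model, the multi-task grading
## objective, data augmentation, and the detector training loop.

#' Grading-model training configuration
#'
#' Defaults follow the published protocol: 20 epochs of Adam with weight
#' decay 1e-4 and dropout 0.5; epochs 1-2 train only the fully connected
#' layers (fusion gate and task heads) at learning rate 0.01, epoch 3 trains
#' the whole network at 0.001, and epochs >= 4 at 0.0001.
#'
#' @param epochs number of epochs (default 20).
#' @param batch_size minibatch size (default 16 for the tiny profile,
#'   32 for full).
#' @param weight_decay L2 penalty coupled into Adam (default 1e-4).
#' @param dropout dropout before the fully connected layers (default 0.5).
#' @param task_weights named weights for the eight task losses (default
#'   all 1).
#' @param schedule `"pretrain"` (default) applies the full published
#'   protocol above, which assumes a pretrained backbone; `"scratch"` keeps
#'   the two FC-only warm-up epochs at 0.01 but then trains the whole
#'   network at a constant 0.001, the appropriate regime when the backbone
#'   starts from random initialization (pretraining is not bundled).
#' @param augment enable data augmentation.
#' @param aug_contrast,aug_gamma,aug_rotate_deg,aug_translate augmentation
#'   magnitudes: contrast scale range, gamma range, |rotation| in degrees,
#'   |translation| as a fraction of the patch side.
#' @param seed RNG seed used by [train_grader()].
#' @return a `train_config` list.
#' @export
train_config <- function(epochs = 20L, batch_size = 16L,
                         weight_decay = 1e-4, dropout = 0.5,
                         task_weights = NULL,
                         schedule = c("pretrain", "scratch"),
                         augment = TRUE,
                         aug_contrast = c(0.8, 1.2),
                         aug_gamma = c(0.7, 1.3), aug_rotate_deg = 10,
                         aug_translate = 0.05, seed = 1L) {
  schedule <- match.arg(schedule)
  stopifnot(epochs >= 1, batch_size >= 1, weight_decay >= 0)
  if (is.null(task_weights))
    task_weights <- stats::setNames(rep(1, 8), names(task_sizes()))
  structure(as.list(environment()), class = "train_config")
}

#' Learning-rate schedule for the grading model
#'
#' @param epoch epoch number, 1-based.
#' @param cfg a [train_config] (bounds checking only).
#' @return list with `lr` and `scope` (`"fc_only"` or `"all"`).
#' @export
lr_schedule <- function(epoch, cfg = train_config()) {
  if (epoch < 1 || epoch > cfg$epochs)
    stop("lr_schedule: epoch out of range")
  if (epoch <= 2) return(list(lr = 0.01, scope = "fc_only"))
  if (identical(cfg$schedule, "scratch"))
    return(list(lr = 0.001, scope = "all"))
  if (epoch == 3) list(lr = 0.001, scope = "all")
  else list(lr = 1e-4, scope = "all")
}

#' Multi-task grading loss
#'
#' Weighted sum of per-task softmax cross-entropies, averaged over the
#' batch; tasks with missing (NA) labels are masked out of both the loss and
#' the gradient. Gradients with respect to the logits are attached as the
#' `"glogits"` attribute.
#'
#' @param logits named list of `K x N` logit matrices (tasks of
#'   [task_sizes()]).
#' @param labels named list (or data.frame) of integer grade vectors,
#'   0-based, NA = missing.
#' @param task_weights named task weights (default all 1).
#' @return scalar loss with attribute `glogits`.
#' @export
grading_loss <- function(logits, labels,
                         task_weights = stats::setNames(rep(1, 8),
                                                        names(task_sizes()))) {
  n <- ncol(logits[[1]])
  total <- 0
  glogits <- list()
  any_task <- FALSE
  for (nm in names(logits)) {
    w <- task_weights[[nm]]
    y <- labels[[nm]]
    mask <- !is.na(y)
    p <- softmax_cols(logits[[nm]])
    g <- p
    li <- numeric(n)
    if (any(mask)) {
      if (w > 0) any_task <- TRUE
      idx <- cbind(y[mask] + 1L, which(mask))
      li[mask] <- -log(pmax(p[idx], 1e-12))
      onehot <- matrix(0, nrow(p), n)
      onehot[idx] <- 1
      g <- (p - onehot)
    }
    g <- sweep(g, 2, as.numeric(mask), "*") * w / n
    glogits[[nm]] <- g
    total <- total + w * mean(li)
  }
  if (!any_task) stop("grading_loss: all tasks masked")
  structure(total, glogits = glogits)
}

#' Randomly augment an 8-bit patch
#'
#' Composes contrast scaling about the image mean, gamma correction,
#' rotation and translation, with magnitudes drawn uniformly from the ranges
#' in the config. Deterministic given the RNG state.
#'
#' @param img intensity matrix (0-255).
#' @param cfg a [train_config].
#' @param params transform parameters from [draw_augment_params()]; drawn
#'   from `cfg` when `NULL`. Passing the same params to several patches
#'   (e.g. the two halves of one knee) applies one consistent transform.
#' @return augmented matrix, clipped to 0-255.
#' @export
augment <- function(img, cfg = train_config(), params = NULL) {
  if (!cfg$augment) return(img)
  if (is.null(params)) params <- draw_augment_params(cfg)
  con <- params$contrast; gam <- params$gamma; ang <- params$angle
  tx <- params$tx * ncol(img)
  ty <- params$ty * nrow(img)
  m <- mean(img)
  out <- (img - m) * con + m
  out[out < 0] <- 0; out[out > 255] <- 255
  out <- 255 * (out / 255)^gam
  if (abs(ang) > 1e-8) {
    r <- EBImage::rotate(out, ang, output.dim = dim(out), bg.col = 0)
    out <- matrix(as.numeric(r), nrow(img), ncol(img))
  }
  if (abs(tx) > 1e-8 || abs(ty) > 1e-8) {
    r <- EBImage::translate(out, c(round(ty), round(tx)), bg.col = 0)
    out <- matrix(as.numeric(r), nrow(img), ncol(img))
  }
  out <- round(out)
  out[out < 0] <- 0; out[out > 255] <- 255
  out
}

#' Draw a set of augmentation parameters
#'
#' @param cfg a [train_config].
#' @return list with `contrast`, `gamma`, `angle` (degrees), `tx`, `ty`
#'   (fractions of the patch side).
#' @export
draw_augment_params <- function(cfg = train_config()) {
  list(contrast = stats::runif(1, cfg$aug_contrast[1], cfg$aug_contrast[2]),
       gamma = stats::runif(1, cfg$aug_gamma[1], cfg$aug_gamma[2]),
       angle = stats::runif(1, -cfg$aug_rotate_deg, cfg$aug_rotate_deg),
       tx = stats::runif(1, -1, 1) * cfg$aug_translate,
       ty = stats::runif(1, -1, 1) * cfg$aug_translate)
}

# stack a list of patch matrices into a normalized (H,W,1,N) array
stack_patches <- function(patches) {
  h <- nrow(patches[[1]]); w <- ncol(patches[[1]])
  array(unlist(patches, use.names = FALSE),
        dim = c(h, w, 1, length(patches))) / 255 - 0.5
}

labels_at <- function(labels, idx) {
  lapply(labels, function(v) v[idx])
}

#' Train a grading model
#'
#' Minibatch Adam training under the schedule of [lr_schedule()]: epochs 1-2
#' update only the fully connected parameters (the backbone is untouched),
#' later epochs update everything. Augmentation is applied per sample and
#' epoch. Returns the model (updated in place) and a per-epoch log of the
#' training loss and, when a validation set is given, validation loss; the
#' parameters of the best validation epoch are restored at the end.
#'
#' @param model a grader from [build_siamese_grader()] /
#'   [build_global_grader()].
#' @param data list with `left`, `right` (lists of patch matrices; `right`
#'   ignored in global mode) and `labels` (named list of 0-based grades).
#' @param cfg a [train_config].
#' @param val optional validation list of the same shape.
#' @param verbose print per-epoch losses.
#' @return list with `model` and `log` (data.frame epoch/lr/scope/loss).
#' @export
train_grader <- function(model, data, cfg = train_config(), val = NULL,
                         verbose = FALSE) {
  n <- length(data$left)
  if (n == 0) stop("train_grader: empty dataset")
  set.seed(cfg$seed)
  opt_fc <- adam_new(model$fc_layers)
  opt_all <- adam_new(model$layers)
  log <- data.frame()
  best <- list(loss = Inf, params = NULL)
  for (epoch in seq_len(cfg$epochs)) {
    sch <- lr_schedule(epoch, cfg)
    opt <- if (sch$scope == "fc_only") opt_fc else opt_all
    ord <- sample(n)
    ep_loss <- 0; nb <- 0
    for (start in seq(1, n, by = cfg$batch_size)) {
      idx <- ord[start:min(start + cfg$batch_size - 1, n)]
      aug <- if (cfg$augment) lapply(idx, function(i)
        draw_augment_params(cfg)) else NULL
      lp <- lapply(seq_along(idx), function(k)
        augment(data$left[[idx[k]]], cfg, aug[[k]]))
      left <- stack_patches(lp)
      right <- NULL
      if (model$mode == "siamese") {
        # the two halves of one knee share one transform
        rp <- lapply(seq_along(idx), function(k)
          augment(data$right[[idx[k]]], cfg, aug[[k]]))
        right <- stack_patches(rp)
      }
      logits <- grader_forward(model, left, right, train = TRUE)
      loss <- grading_loss(logits, labels_at(data$labels, idx),
                           cfg$task_weights)
      zero_grads(model$layers)
      grader_backward(model, attr(loss, "glogits"),
                      backbone = sch$scope != "fc_only")
      adam_step(opt, sch$lr, cfg$weight_decay)
      ep_loss <- ep_loss + as.numeric(loss); nb <- nb + 1
    }
    row <- data.frame(epoch = epoch, lr = sch$lr, scope = sch$scope,
                      train_loss = ep_loss / nb, val_loss = NA_real_)
    if (!is.null(val)) {
      row$val_loss <- grader_eval_loss(model, val, cfg)
      if (row$val_loss < best$loss)
        best <- list(loss = row$val_loss, params = get_params(model$layers))
    }
    log <- rbind(log, row)
    if (verbose)
      message(sprintf("epoch %d (%s, lr %g): train %.4f val %.4f", epoch,
                      sch$scope, sch$lr, row$train_loss, row$val_loss))
  }
  if (!is.null(best$params)) set_params(model$layers, best$params)
  list(model = model, log = log)
}

grader_eval_loss <- function(model, data, cfg) {
  left <- stack_patches(data$left)
  right <- if (model$mode == "siamese") stack_patches(data$right) else NULL
  logits <- grader_forward(model, left, right, train = FALSE)
  as.numeric(grading_loss(logits, data$labels, cfg$task_weights))
}

#' Train the cascaded detector on labeled windows
#'
#' Trains stage 1 on 48x48 windows (knee score + box offsets) and stage 2 on
#' stage-2-sized windows (score + box offsets + key points) with the
#' multi-task loss and the published loss weights per stage. Part samples
#' contribute only to box regression.
#'
#' @param windows list of records from [sample_detector_windows()] together
#'   with their source images: each element
#'   `list(crop48, crop_s2, label, offsets, keypoints_norm)`.
#' @param config a [cascade_config].
#' @param epochs,lr_stage1,lr_stage2,batch_size optimization settings
#'   (CPU-scale defaults).
#' @param seed RNG seed.
#' @param verbose print per-epoch losses.
#' @return list with `stage1`, `stage2` and a training `log`.
#' @export
train_detector <- function(windows, config = cascade_config(), epochs = 40L,
                           lr_stage1 = 1e-3, lr_stage2 = 1e-3,
                           batch_size = 100L, seed = 1L, verbose = FALSE) {
  set.seed(seed)
  stage1 <- build_stage1(config)
  stage2 <- build_stage2(config)
  n <- length(windows)
  labels <- vapply(windows, `[[`, character(1), "label")
  cls <- ifelse(labels == "pos", 1, ifelse(labels == "neg", 0, NA))
  off <- vapply(windows, function(w)
    if (is.null(w$offsets)) rep(NA_real_, 4) else w$offsets, numeric(4))
  kp <- vapply(windows, function(w)
    if (is.null(w$keypoints_norm)) rep(NA_real_, 12)
    else as.numeric(t(w$keypoints_norm)), numeric(12))

  # window crops are stored already normalized to about [-0.5, 0.5]
  s1 <- config$stage1_input_size
  s2 <- config$stage2_input_size
  x48 <- array(unlist(lapply(windows, `[[`, "crop48")), c(s1, s1, 1, n))
  xs2 <- array(unlist(lapply(windows, `[[`, "crop_s2")), c(s2, s2, 1, n))

  opt1 <- adam_new(stage1$layers)
  opt2 <- adam_new(stage2$layers)
  log <- data.frame()
  for (epoch in seq_len(epochs)) {
    ord <- sample(n)
    l1t <- 0; l2t <- 0; nb <- 0
    for (start in seq(1, n, by = batch_size)) {
      idx <- ord[start:min(start + batch_size - 1, n)]
      m <- length(idx)
      tgt <- list(cls = cls[idx], box = off[, idx, drop = FALSE],
                  kp = kp[, idx, drop = FALSE])
      # stage 1 (no key-point branch)
      out1 <- stage1_forward(stage1, x48[, , , idx, drop = FALSE],
                             train = TRUE)
      pred1 <- list(score = matrix(out1$score, 1, m),
                    box = matrix(aperm(out1$box, c(3, 1, 2, 4)), 4, m))
      loss1 <- multitask_loss(pred1, tgt, config$alpha_stage1)
      zero_grads(stage1$layers)
      stage1_backward(stage1,
                      array(attr(loss1, "gscore"), c(1, 1, 1, m)),
                      array(attr(loss1, "gbox"), c(1, 1, 4, m)))
      adam_step(opt1, lr_stage1)
      # stage 2
      out2 <- stage2_forward(stage2, xs2[, , , idx, drop = FALSE],
                             train = TRUE)
      loss2 <- multitask_loss(out2, tgt, config$alpha_stage2)
      zero_grads(stage2$layers)
      stage2_backward(stage2, attr(loss2, "gscore"), attr(loss2, "gbox"),
                      attr(loss2, "gkp"))
      adam_step(opt2, lr_stage2)
      l1t <- l1t + loss1; l2t <- l2t + loss2; nb <- nb + 1
    }
    log <- rbind(log, data.frame(epoch = epoch, loss_stage1 = l1t / nb,
                                 loss_stage2 = l2t / nb))
    if (verbose)
      message(sprintf("epoch %d: stage1 %.4f stage2 %.4f", epoch, l1t / nb,
                      l2t / nb))
  }
  list(stage1 = stage1, stage2 = stage2, log = log, config = config)
}

#' Build detector training windows from phantom samples
#'
#' Samples labeled windows from each phantom and crops/normalizes them at
#' both cascade input sizes.
#'
#' @param samples list of single-knee `phantom_sample`s.
#' @param config a [cascade_config].
#' @param n_pos,n_part,n_neg windows per phantom.
#' @return list of window records consumable by [train_detector()].
#' @export
make_detector_windows <- function(samples, config = cascade_config(),
                                  n_pos = 3L, n_part = 2L, n_neg = 3L) {
  out <- list()
  for (s in samples) {
    wins <- sample_detector_windows(s, n_pos, n_part, n_neg)
    pix <- s$image$pixels
    for (w in wins) {
      w$crop48 <- crop_resize_norm(pix, w$window, config$stage1_input_size)
      w$crop_s2 <- crop_resize_norm(pix, w$window, config$stage2_input_size)
      if (!is.null(w$offsets)) w$offsets <- as.numeric(w$offsets)
      out[[length(out) + 1L]] <- w
    }
  }
  out
}
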