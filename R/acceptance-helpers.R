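## Desk-scale study configurations shared by the acceptance tests and the
## acceptance script: the data volumes, model profiles and training budgets
## of the package's synthetic-phantom benchmark.

#' Desk-scale cascade configuration
#'
#' The CPU-sized detector used for the synthetic-phantom benchmark: published
#' stage-1 geometry (48-pixel window, stride-8 sliding), a 48-pixel stage-2
#' input and reduced channel widths.
#'
#' @return a [cascade_config].
#' @export
desk_cascade_config <- function() {
  cascade_config(stage2_input_size = 48L,
                 stage1_channels = c(12L, 24L, 32L),
                 stage2_channels = c(16L, 32L, 32L, 64L),
                 stage2_fc = 128L)
}

#' Train and evaluate the desk-scale detector benchmark
#'
#' Renders `n_train` phantoms, preprocesses them, mines ~`8 * n_train`
#' labeled windows, trains the two-stage cascade, and measures detection
#' accuracy (IoU >= `iou_min`) on `n_test` freshly rendered held-out
#' phantoms.
#'
#' @param n_train,n_test phantom counts (defaults 100 and 200).
#' @param seed RNG seed for data and training.
#' @param epochs training epochs.
#' @param iou_min detection criterion.
#' @return list with `accuracy`, `detector`, `mean_iou`, `elapsed_train`.
#' @export
run_detector_benchmark <- function(n_train = 100L, n_test = 200L, seed = 1L,
                                   epochs = 14L, iou_min = 0.5) {
  cfg <- desk_cascade_config()
  prep <- function(s) {
    s$image <- standardize_intensity(normalize_polarity(s$image))
    s
  }
  train <- lapply(generate_dataset(n_train, seed = seed,
                                   type = "single")$samples, prep)
  set.seed(seed)
  wins <- make_detector_windows(train, cfg)
  t0 <- Sys.time()
  det <- train_detector(wins, cfg, epochs = epochs, seed = seed)
  elapsed <- as.numeric(Sys.time() - t0, units = "secs")
  test <- lapply(generate_dataset(n_test, seed = seed + 10000L,
                                  type = "single")$samples, prep)
  dets <- lapply(test, function(s)
    detect_knee(s$image, det$stage1, det$stage2, cfg))
  truths <- lapply(test, `[[`, "box")
  ious <- vapply(seq_along(dets), function(i)
    if (is.null(dets[[i]])) 0 else iou(dets[[i]]$box, truths[[i]]),
    numeric(1))
  list(accuracy = detection_accuracy(dets, truths, iou_min),
       mean_iou = mean(ious), detector = det, elapsed_train = elapsed,
       n_windows = length(wins))
}

#' Train and evaluate the desk-scale Siamese grader benchmark
#'
#' Renders `n_train + n_test` phantoms, derives symmetric patch pairs from
#' the ground-truth regions, trains the tiny Siamese SE-ResNext grader under
#' the scratch schedule (FC-only warm-up epochs 1-2, then constant 1e-3) and
#' evaluates all eight tasks on the held-out phantoms.
#'
#' The desk-scale training protocol: batch 8, dropout 0.25, no
#' augmentation (train and test phantoms share one distribution, and the
#' small corner osteophyte cue does not survive heavy train-time jitter),
#' 60 epochs.
#'
#' @param n_train,n_test phantom counts (defaults 1000 and 300).
#' @param seed RNG seed.
#' @param epochs training epochs (default 60).
#' @param patch_size grader input patch side.
#' @return list with `report` ([evaluate_grades()] result), `model`,
#'   `elapsed_train`.
#' @export
run_grader_benchmark <- function(n_train = 1000L, n_test = 300L, seed = 1L,
                                 epochs = 60L, patch_size = 48L) {
  gen <- generate_dataset(n_train + n_test, seed = seed, type = "single")
  dat <- grader_data_from_samples(gen$samples, patch_size = patch_size)
  tr_idx <- seq_len(n_train)
  te_idx <- n_train + seq_len(n_test)
  tr <- list(left = dat$left[tr_idx], right = dat$right[tr_idx],
             labels = lapply(dat$labels, `[`, tr_idx))
  te <- list(left = dat$left[te_idx], right = dat$right[te_idx],
             labels = lapply(dat$labels, `[`, te_idx))
  set.seed(seed)
  model <- build_siamese_grader(backbone_config("tiny",
                                                input_size = patch_size),
                                dropout = 0.25)
  cfg <- train_config(epochs = epochs, batch_size = 8L, seed = seed,
                      schedule = "scratch", augment = FALSE)
  t0 <- Sys.time()
  train_grader(model, tr, cfg)
  elapsed <- as.numeric(Sys.time() - t0, units = "secs")
  pred <- predict_grades(model, stack_patches(te$left),
                         stack_patches(te$right))
  list(report = evaluate_grades(pred$grades, te$labels), model = model,
       elapsed_train = elapsed)
}
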