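## End-to-end pipeline over file artifacts: simulate -> preprocess ->
## detect -> crop -> predict -> evaluate. Every interchange file uses
## 0-based pixel coordinates, origin top-left, y down, half-open boxes.

#' Save / load kneepipe models
#'
#' Models are serialized as their configuration plus parameter values and
#' rebuilt on load.
#'
#' @param model a detector (list with `stage1`, `stage2`) or grader model.
#' @param path `.rds` path.
#' @export
save_model <- function(model, path) {
  obj <- if (inherits(model, "knee_grader")) {
    list(kind = "grader", mode = model$mode, config = model$config,
         params = get_params(model$layers))
  } else if (!is.null(model$stage1)) {
    list(kind = "detector", config = model$config,
         params1 = get_params(model$stage1$layers),
         params2 = get_params(model$stage2$layers))
  } else stop("save_model: unrecognized model")
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname save_model
#' @return `load_model` returns the reconstructed model.
#' @export
load_model <- function(path) {
  obj <- readRDS(path)
  if (obj$kind == "detector") {
    stage1 <- build_stage1(obj$config)
    stage2 <- build_stage2(obj$config)
    set_params(stage1$layers, obj$params1)
    set_params(stage2$layers, obj$params2)
    list(stage1 = stage1, stage2 = stage2, config = obj$config)
  } else {
    model <- if (obj$mode == "siamese") build_siamese_grader(obj$config)
             else build_global_grader(obj$config)
    set_params(model$layers, obj$params)
    model
  }
}

#' Prepare grader training data from phantom samples
#'
#' Uses the ground-truth box and key points of each sample to refine the
#' region of interest, split it into symmetric patches, and collect the
#' eight-task labels.
#'
#' @param samples list of single-knee `phantom_sample`s.
#' @param margin_factor,patch_size ROI parameters (see [refine_roi()],
#'   [split_patches()]).
#' @param equalize preprocess each phantom with [standardize_intensity()]
#'   first (matches what the pipeline feeds the grader).
#' @return list with `left`, `right`, `roi` (patch matrices) and `labels`.
#' @export
grader_data_from_samples <- function(samples, margin_factor = 0.2,
                                     patch_size = 48L, equalize = TRUE) {
  n <- length(samples)
  left <- vector("list", n); right <- vector("list", n)
  roi <- vector("list", n)
  labs <- lapply(names(task_sizes()), function(nm)
    vapply(samples, function(s) s$labels[[nm]], numeric(1)))
  names(labs) <- names(task_sizes())
  for (i in seq_len(n)) {
    s <- samples[[i]]
    img <- s$image
    if (equalize) img <- standardize_intensity(normalize_polarity(img))
    det <- list(box = s$box, keypoints = s$keypoints)
    box <- refine_roi(det, dim(img$pixels), margin_factor)
    pp <- split_patches(img, box, patch_size)
    left[[i]] <- pp$left_patch
    right[[i]] <- pp$right_patch_flipped
    roi[[i]] <- resize_matrix(img$pixels[(floor(box[2]) + 1):ceiling(box[4]),
                                         (floor(box[1]) + 1):ceiling(box[3]),
                                         drop = FALSE],
                              patch_size, patch_size)
  }
  list(left = left, right = right, roi = roi, labels = labs)
}

#' Run pipeline stages over a working directory
#'
#' Executes the requested stages in order. Artifacts live under `workdir`:
#' `images/` (simulated double-knee phantoms + `labels.csv` +
#' `keypoints.json`), `singles/` (preprocessed single knees),
#' `detections.csv`, `patches/` + `crop_manifest.csv`, `preds.csv`,
#' `report.json`. Stages `detect` and `predict` require
#' `detector$model_path` / `grader$model_path` in the config. All
#' randomness flows from `config$seed`; two runs with the same config and
#' inputs produce identical artifacts.
#'
#' @param config configuration from [load_config()].
#' @param stages character vector, subset of `c("simulate", "preprocess",
#'   "detect", "crop", "predict", "evaluate")`.
#' @param workdir artifact directory.
#' @param verbose print stage progress.
#' @return invisibly, a named list of the artifacts each stage produced.
#' @export
run_pipeline <- function(config, stages, workdir, verbose = FALSE) {
  dir.create(workdir, showWarnings = FALSE, recursive = TRUE)
  known <- c("simulate", "preprocess", "detect", "crop", "predict",
             "evaluate")
  stages <- match.arg(stages, known, several.ok = TRUE)
  out <- list()
  hash <- config_hash(config)
  note <- function(stage, msg) {
    if (verbose)
      message(sprintf("[%s] seed=%d cfg=%s %s", stage, config$seed, hash,
                      msg))
  }
  img_dir <- file.path(workdir, "images")
  singles_dir <- file.path(workdir, "singles")
  patch_dir <- file.path(workdir, "patches")
  det_csv <- file.path(workdir, "detections.csv")
  crop_csv <- file.path(workdir, "crop_manifest.csv")
  preds_csv <- file.path(workdir, "preds.csv")

  need <- function(path, stage) {
    if (!file.exists(path))
      stop(sprintf("%s: missing upstream artifact '%s'", stage, path))
  }

  for (stage in stages) {
    t0 <- Sys.time()
    if (stage == "simulate") {
      gen <- generate_dataset(config$synth$n, seed = config$seed,
                              type = config$synth$type,
                              spec_args = list(base_gap = config$synth$base_gap,
                                               noise_sd = config$synth$noise_sd),
                              polarity_mix = config$synth$polarity_mix,
                              out_dir = img_dir)
      out$simulate <- img_dir
    } else if (stage == "preprocess") {
      need(img_dir, stage)
      files <- preprocess_images(img_dir, singles_dir,
                                 clahe = config$preprocess$clahe)
      out$preprocess <- singles_dir
    } else if (stage == "detect") {
      need(singles_dir, stage)
      if (is.null(config$detector$model_path))
        stop("detect: missing upstream artifact 'detector$model_path'")
      det_model <- load_model(config$detector$model_path)
      dcfg <- det_model$config
      files <- sort(list.files(singles_dir, pattern = "\\.png$",
                               full.names = TRUE))
      rows <- list()
      for (f in files) {
        img <- read_knee_image(f, side = "left",
                               polarity = "dark_background")
        d <- detect_knee(img, det_model$stage1, det_model$stage2, dcfg)
        if (is.null(d)) next
        rows[[length(rows) + 1L]] <- data.frame(
          knee_id = img$source_id, score = d$score,
          x1 = d$box[1], y1 = d$box[2], x2 = d$box[3], y2 = d$box[4],
          matrix(as.numeric(t(d$keypoints)), 1,
                 dimnames = list(NULL, paste0(rep(c("kx", "ky"), 6),
                                              rep(1:6, each = 2)))))
      }
      det_df <- if (length(rows)) do.call(rbind, rows) else
        stats::setNames(data.frame(matrix(nrow = 0, ncol = 18)),
                        c("knee_id", "score", "x1", "y1", "x2", "y2",
                          paste0(rep(c("kx", "ky"), 6), rep(1:6, each = 2))))
      utils::write.csv(det_df, det_csv, row.names = FALSE)
      out$detect <- det_csv
    } else if (stage == "crop") {
      need(det_csv, stage)
      dets <- utils::read.csv(det_csv)
      dir.create(patch_dir, showWarnings = FALSE)
      man <- list()
      for (i in seq_len(nrow(dets))) {
        r <- dets[i, ]
        img <- read_knee_image(file.path(singles_dir,
                                         paste0(r$knee_id, ".png")),
                               side = "left", polarity = "dark_background")
        kps <- matrix(as.numeric(r[paste0(rep(c("kx", "ky"), 6),
                                          rep(1:6, each = 2))]),
                      6, 2, byrow = TRUE)
        det <- list(box = c(r$x1, r$y1, r$x2, r$y2), keypoints = kps)
        pp <- tryCatch({
          box <- refine_roi(det, dim(img$pixels), config$roi$margin_factor)
          split_patches(img, box, config$roi$patch_size)
        }, error = function(e) {
          warning(sprintf("crop: skipping %s (%s)", r$knee_id,
                          conditionMessage(e)))
          NULL
        })
        if (is.null(pp)) next
        lp <- file.path(patch_dir, paste0(r$knee_id, "_left.png"))
        rp <- file.path(patch_dir, paste0(r$knee_id, "_right.png"))
        write_knee_image(knee_image(round(pp$left_patch),
                                    polarity = "dark_background",
                                    side = "left", source_id = r$knee_id),
                         lp)
        write_knee_image(knee_image(round(pp$right_patch_flipped),
                                    polarity = "dark_background",
                                    side = "right", source_id = r$knee_id),
                         rp)
        man[[i]] <- data.frame(knee_id = r$knee_id, left = basename(lp),
                               right = basename(rp),
                               x1 = pp$origin_box[1], y1 = pp$origin_box[2],
                               x2 = pp$origin_box[3], y2 = pp$origin_box[4])
      }
      utils::write.csv(do.call(rbind, man), crop_csv, row.names = FALSE)
      out$crop <- crop_csv
    } else if (stage == "predict") {
      need(crop_csv, stage)
      if (is.null(config$grader$model_path))
        stop("predict: missing upstream artifact 'grader$model_path'")
      model <- load_model(config$grader$model_path)
      man <- utils::read.csv(crop_csv)
      left <- lapply(file.path(patch_dir, man$left), function(p)
        read_knee_image(p)$pixels)
      right <- lapply(file.path(patch_dir, man$right), function(p)
        read_knee_image(p)$pixels)
      pred <- predict_grades(model, stack_patches(left),
                             stack_patches(right))
      df <- data.frame(knee_id = man$knee_id)
      for (nm in names(pred$grades)) {
        df[[nm]] <- pred$grades[[nm]]
        df[[paste0(nm, "_prob")]] <-
          apply(pred$probs[[nm]], 2, max)
      }
      utils::write.csv(df, preds_csv, row.names = FALSE)
      out$predict <- preds_csv
    } else if (stage == "evaluate") {
      need(preds_csv, stage)
      need(file.path(img_dir, "labels.csv"), stage)
      preds <- utils::read.csv(preds_csv)
      labels <- utils::read.csv(file.path(img_dir, "labels.csv"))
      m <- merge(preds, labels, by = "knee_id", suffixes = c("_pred", ""))
      rep <- evaluate_grades(
        stats::setNames(lapply(names(task_sizes()), function(nm)
          m[[paste0(nm, "_pred")]]), names(task_sizes())),
        stats::setNames(lapply(names(task_sizes()), function(nm) m[[nm]]),
                        names(task_sizes())))
      json <- list(n_samples = rep$n_samples, config_hash = hash,
                   metrics = rep$metrics)
      jsonlite::write_json(json, file.path(workdir, "report.json"),
                           auto_unbox = TRUE, digits = NA, dataframe = "rows")
      for (nm in names(rep$confusion))
        utils::write.csv(rep$confusion[[nm]],
                         file.path(workdir, paste0("confusion_", nm, ".csv")))
      out$evaluate <- file.path(workdir, "report.json")
    }
    note(stage, sprintf("done in %.1fs", as.numeric(Sys.time() - t0,
                                                    units = "secs")))
  }
  invisible(out)
}
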