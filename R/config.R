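## YAML pipeline configuration: nested sections with validated ranges.

default_pipeline_config <- function() {
  list(
    seed = 1L,
    preprocess = list(clahe = FALSE),
    detector = list(stage1_input_size = 48L, stage2_input_size = 96L,
                    pyramid_scale_factor = 0.709, min_knee_size = 80L,
                    stage1_score_threshold = 0.6,
                    stage2_score_threshold = 0.7,
                    nms_iou_stage1 = 0.7, nms_iou_stage2 = 0.5,
                    epochs = 40L, batch_size = 100L,
                    lr_stage1 = 1e-3, lr_stage2 = 1e-3,
                    model_path = NULL),
    roi = list(margin_factor = 0.2, patch_size = 48L),
    grader = list(arch = "tiny", mode = "siamese", model_path = NULL),
    trainer = list(epochs = 20L, batch_size = 16L, weight_decay = 1e-4,
                   dropout = 0.5, augment = TRUE),
    metrics = list(kappa_weighting = "quadratic", iou_min = 0.5),
    synth = list(n = 50L, type = "double", polarity_mix = 0.3,
                 base_gap = 24, noise_sd = 8)
  )
}

config_checks <- function() {
  list(
    "roi.margin_factor" = function(v) is.numeric(v) && v >= 0,
    "roi.patch_size" = function(v) is.numeric(v) && v >= 8,
    "metrics.iou_min" = function(v) is.numeric(v) && v > 0 && v <= 1,
    "metrics.kappa_weighting" = function(v)
      v %in% c("none", "linear", "quadratic"),
    "detector.pyramid_scale_factor" = function(v)
      is.numeric(v) && v > 0 && v < 1,
    "detector.stage1_score_threshold" = function(v)
      is.numeric(v) && v > 0 && v < 1,
    "detector.stage2_score_threshold" = function(v)
      is.numeric(v) && v > 0 && v < 1,
    "grader.arch" = function(v) v %in% c("tiny", "full"),
    "grader.mode" = function(v) v %in% c("siamese", "global"),
    "trainer.epochs" = function(v) is.numeric(v) && v >= 1,
    "trainer.weight_decay" = function(v) is.numeric(v) && v >= 0,
    "synth.n" = function(v) is.numeric(v) && v >= 1,
    "synth.type" = function(v) v %in% c("single", "double"),
    "synth.polarity_mix" = function(v) is.numeric(v) && v >= 0 && v <= 1
  )
}

#' Load and validate a pipeline configuration
#'
#' Reads a YAML file, fills unset keys with defaults, rejects unknown keys,
#' and validates value ranges with errors that name the offending key
#' (e.g. `roi.margin_factor`). An empty or missing file yields the full
#' default configuration.
#'
#' @param path YAML file, or `NULL` for pure defaults.
#' @return a validated nested configuration list.
#' @export
load_config <- function(path = NULL) {
  cfg <- default_pipeline_config()
  user <- if (!is.null(path) && file.exists(path) &&
                file.info(path)$size > 0)
    yaml::read_yaml(path) else list()
  if (is.null(user)) user <- list()
  for (section in names(user)) {
    if (!section %in% names(cfg))
      stop(sprintf("config: unknown key '%s'", section))
    if (is.list(cfg[[section]])) {
      for (key in names(user[[section]])) {
        if (!key %in% names(cfg[[section]]))
          stop(sprintf("config: unknown key '%s.%s'", section, key))
        cfg[[section]][[key]] <- user[[section]][[key]]
      }
    } else {
      cfg[[section]] <- user[[section]]
    }
  }
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  for (key in names(config_checks())) {
    parts <- strsplit(key, ".", fixed = TRUE)[[1]]
    v <- cfg[[parts[1]]][[parts[2]]]
    if (!is.null(v) && !config_checks()[[key]](v))
      stop(sprintf("config: invalid value for %s", key))
  }
  invisible(cfg)
}

#' Save a configuration to YAML
#'
#' @param cfg configuration list.
#' @param path output path.
#' @export
save_config <- function(cfg, path) {
  yaml::write_yaml(cfg, path)
  invisible(path)
}

config_hash <- function(cfg) {
  # small stable hash of the serialized config for artifact provenance
  s <- yaml::as.yaml(cfg)
  sprintf("%08x", sum(utf8ToInt(s) * (seq_len(nchar(s)) %% 97 + 1)) %%
            .Machine$integer.max)
}
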