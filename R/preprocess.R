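## Radiograph preprocessing: polarity normalization, double-knee splitting,
## 8-bit conversion and histogram equalization.

#' Classify image polarity
#'
#' Radiographs come in two polarities: dark background with bright bone, or
#' the inverse. The knee is centered in the frame, so polarity is classified
#' by comparing the mean intensity of a thin border frame (5% of each
#' dimension, at least 1 pixel) against the mean of the central 50% region:
#' a border brighter than the center indicates a bright background.
#'
#' @param img a [knee_image].
#' @return `"dark_background"` or `"bright_background"`.
#' @export
classify_polarity <- function(img) {
  assert_knee_image(img)
  p <- img$pixels
  h <- nrow(p); w <- ncol(p)
  bh <- max(1L, floor(0.05 * h)); bw <- max(1L, floor(0.05 * w))
  border_mask <- matrix(FALSE, h, w)
  border_mask[c(seq_len(bh), h - seq_len(bh) + 1L), ] <- TRUE
  border_mask[, c(seq_len(bw), w - seq_len(bw) + 1L)] <- TRUE
  r0 <- max(1L, floor(h / 4) + 1L); r1 <- min(h, ceiling(3 * h / 4))
  c0 <- max(1L, floor(w / 4) + 1L); c1 <- min(w, ceiling(3 * w / 4))
  center <- p[r0:r1, c0:c1]
  if (mean(p[border_mask]) > mean(center)) "bright_background"
  else "dark_background"
}

#' Normalize image polarity to dark background
#'
#' Bright-background images are pixel-inverted (`p -> max_representable - p`)
#' so all downstream stages see dark background and bright bone. Images whose
#' polarity is `"unknown"` are first classified with [classify_polarity()].
#'
#' @param img a [knee_image].
#' @param force if `TRUE`, invert unconditionally (useful for testing the
#'   involution property).
#' @return a [knee_image] with `polarity = "dark_background"`.
#' @export
normalize_polarity <- function(img, force = FALSE) {
  assert_knee_image(img)
  pol <- img$polarity
  if (pol == "unknown") pol <- classify_polarity(img)
  if (force || pol == "bright_background") {
    img$pixels <- max_representable(img) - img$pixels
  }
  img$polarity <- "dark_background"
  img
}

#' Split a double-knee image at the vertical midline
#'
#' The left half keeps columns `1:floor(w/2)`; for odd widths the right half
#' receives the extra column. Together the halves partition the original
#' columns exactly.
#'
#' @param img a [knee_image] with `side = "double"` and width >= 2.
#' @return list with elements `left` and `right`, each a [knee_image] with
#'   `side` set and `source_id` suffixed `_L` / `_R`.
#' @export
split_double_knee <- function(img) {
  assert_knee_image(img)
  if (img$side != "double")
    stop("split_double_knee: image side must be 'double'")
  w <- ncol(img$pixels)
  if (w < 2L) stop("split_double_knee: width must be >= 2")
  half <- w %/% 2L
  mk <- function(cols, side, suffix) {
    knee_image(img$pixels[, cols, drop = FALSE], bit_depth = img$bit_depth,
               polarity = img$polarity, side = side,
               source_id = paste0(img$source_id, suffix))
  }
  list(left = mk(seq_len(half), "left", "_L"),
       right = mk((half + 1L):w, "right", "_R"))
}

#' Convert to 8-bit and apply global histogram equalization
#'
#' 16-bit images are first linearly min-max rescaled to `[0, 255]` per image.
#' Global histogram equalization over 256 bins is then applied with the
#' standard cumulative-distribution mapping
#' `v -> round(255 * (cdf(v) - cdf(v_min)) / (1 - cdf(v_min)))`, which is
#' monotone non-decreasing; a constant image is returned unchanged. Optional
#' tile-based contrast-limited equalization (CLAHE) via EBImage is available
#' behind a flag but is off by default.
#'
#' @param img a [knee_image] with `polarity = "dark_background"`.
#' @param clahe if `TRUE`, use EBImage's adaptive equalization instead of the
#'   global mapping.
#' @return an 8-bit equalized [knee_image].
#' @export
standardize_intensity <- function(img, clahe = FALSE) {
  assert_knee_image(img)
  if (img$polarity != "dark_background")
    stop("standardize_intensity: polarity must be dark_background; ",
         "run normalize_polarity first")
  p <- img$pixels
  if (img$bit_depth == 16L) {
    rng <- range(p)
    p <- if (rng[2] > rng[1]) round((p - rng[1]) / (rng[2] - rng[1]) * 255)
         else round(p * 0)
  }
  p[p < 0] <- 0; p[p > 255] <- 255
  if (clahe) {
    eq <- EBImage::clahe(t(p) / 255, nx = 8, ny = 8)
    out <- round(t(matrix(as.numeric(eq), ncol(p), nrow(p))) * 255)
    out[out < 0] <- 0; out[out > 255] <- 255
  } else {
    out <- equalize_global(p)
  }
  knee_image(out, bit_depth = 8L, polarity = "dark_background",
             side = img$side, source_id = img$source_id)
}

# Global 256-bin histogram equalization of an integer 8-bit matrix.
equalize_global <- function(p) {
  counts <- tabulate(as.integer(p) + 1L, nbins = 256L)
  if (sum(counts > 0) <= 1L) return(p) # single gray level: identity
  cdf <- cumsum(counts) / length(p)
  cdf_min <- cdf[which(counts > 0)[1]]
  lut <- round(255 * (cdf - cdf_min) / (1 - cdf_min))
  lut[lut < 0] <- 0
  out <- matrix(lut[as.integer(p) + 1L], nrow(p), ncol(p))
  out
}

#' Preprocess a directory or list of radiographs
#'
#' Runs [normalize_polarity()], [split_double_knee()] (for double-knee
#' images) and [standardize_intensity()] and writes one 8-bit PNG per single
#' knee named `<source_id>_<L|R>.png`.
#'
#' @param images list of [knee_image] objects, or a directory of PNG/TIFF
#'   files.
#' @param out_dir output directory.
#' @param clahe passed to [standardize_intensity()].
#' @return invisibly, the list of written file paths.
#' @export
preprocess_images <- function(images, out_dir, clahe = FALSE) {
  if (is.character(images)) {
    files <- list.files(images, pattern = "\\.(png|tif|tiff)$",
                        ignore.case = TRUE, full.names = TRUE)
    images <- lapply(files, read_knee_image)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  for (img in images) {
    img <- normalize_polarity(img)
    singles <- if (img$side == "double") split_double_knee(img) else list(img)
    for (s in singles) {
      s <- standardize_intensity(s, clahe = clahe)
      path <- file.path(out_dir, paste0(s$source_id, ".png"))
      write_knee_image(s, path)
      written <- c(written, path)
    }
  }
  invisible(written)
}
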