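## Key-point-driven refinement of detected knee joints and symmetric patch
## splitting.

#' Knee joint width from the six key points
#'
#' Defined as the difference between the maximum and minimum x coordinates
#' (abscissas) of the six key points.
#'
#' @param keypoints 6 x 2 matrix of (x, y).
#' @return width in pixels (> 0).
#' @export
knee_width <- function(keypoints) {
  stopifnot(is.matrix(keypoints), nrow(keypoints) == 6, ncol(keypoints) == 2)
  if (!all(is.finite(keypoints))) stop("knee_width: non-finite key points")
  w <- max(keypoints[, 1]) - min(keypoints[, 1])
  if (w <= 0) stop("knee_width: degenerate key points (zero width)")
  w
}

#' Refine a detection into the main knee-joint region
#'
#' The vertical extent is the key points' y range expanded by
#' `margin_factor` times the knee width above and below; the horizontal
#' extent is the detected box's x range, unchanged. The result is clipped to
#' the image.
#'
#' @param detection `list(box, keypoints, ...)` as returned by
#'   [detect_knee()].
#' @param image_size `c(height, width)` for clipping, or `NULL` to skip.
#' @param margin_factor vertical margin as a fraction of knee width
#'   (default 0.2).
#' @return refined box `c(x_min, y_min, x_max, y_max)`.
#' @export
refine_roi <- function(detection, image_size = NULL, margin_factor = 0.2) {
  kps <- detection$keypoints
  if (is.null(kps)) stop("refine_roi: detection has no key points")
  w <- knee_width(kps)
  box <- c(detection$box[1], min(kps[, 2]) - margin_factor * w,
           detection$box[3], max(kps[, 2]) + margin_factor * w)
  if (!is.null(image_size)) {
    box[1] <- max(0, box[1]); box[2] <- max(0, box[2])
    box[3] <- min(image_size[2], box[3]); box[4] <- min(image_size[1], box[4])
  }
  if (box[3] <= box[1] || box[4] <= box[2])
    stop("refine_roi: refined box is empty after clipping")
  box
}

#' Split a knee region into symmetric left/right patches
#'
#' Crops the box, splits it at the vertical midline (for odd crop widths the
#' right half receives the extra column), horizontally flips the right half
#' so both patches share the same anatomical orientation, and resizes each
#' patch to `patch_size x patch_size`.
#'
#' @param img a [knee_image] or intensity matrix.
#' @param box region to crop, within the image.
#' @param patch_size output side length (default 128); `NA` to skip the
#'   resize.
#' @return list with `left_patch`, `right_patch_flipped` (matrices) and
#'   `origin_box`.
#' @export
split_patches <- function(img, box, patch_size = 128L) {
  pix <- if (inherits(img, "knee_image")) img$pixels else img
  x1 <- floor(box[1]); y1 <- floor(box[2])
  x2 <- ceiling(box[3]); y2 <- ceiling(box[4])
  if (x1 < 0 || y1 < 0 || x2 > ncol(pix) || y2 > nrow(pix))
    stop("split_patches: box outside image")
  crop <- pix[(y1 + 1):y2, (x1 + 1):x2, drop = FALSE]
  w <- ncol(crop)
  half <- w %/% 2L
  left <- crop[, seq_len(half), drop = FALSE]
  right <- crop[, (half + 1L):w, drop = FALSE]
  right_flipped <- right[, rev(seq_len(ncol(right))), drop = FALSE]
  if (!is.na(patch_size)) {
    left <- resize_matrix(left, patch_size, patch_size)
    right_flipped <- resize_matrix(right_flipped, patch_size, patch_size)
  }
  list(left_patch = left, right_patch_flipped = right_flipped,
       origin_box = c(x1, y1, x2, y2))
}
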