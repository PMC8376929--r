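#' Knee image container
#'
#' A light container for a grayscale radiograph: an integer-valued intensity
#' matrix indexed `[row, col]` (origin top-left, y increases downward) plus
#' polarity and provenance metadata. Intensities run from 0 to
#' `2^bit_depth - 1`.
#'
#' @param pixels numeric matrix of intensities, rows = image y.
#' @param bit_depth 8 or 16.
#' @param polarity one of `"dark_background"`, `"bright_background"`,
#'   `"unknown"`. Radiographs are standardized to dark background / bright
#'   bone.
#' @param side one of `"left"`, `"right"`, `"double"`.
#' @param source_id identifier carried through the pipeline.
#' @return an object of class `knee_image`.
#' @export
knee_image <- function(pixels, bit_depth = 8L,
                       polarity = c("unknown", "dark_background",
                                    "bright_background"),
                       side = c("double", "left", "right"),
                       source_id = "") {
  polarity <- match.arg(polarity)
  side <- match.arg(side)
  if (!is.matrix(pixels) || length(pixels) == 0L)
    stop("invalid image: pixels must be a non-empty 2-D matrix")
  if (!bit_depth %in% c(8L, 16L)) stop("bit_depth must be 8 or 16")
  structure(list(pixels = pixels, bit_depth = as.integer(bit_depth),
                 polarity = polarity, side = side,
                 source_id = as.character(source_id)),
            class = "knee_image")
}

#' @export
print.knee_image <- function(x, ...) {
  cat(sprintf("<knee_image %s: %dx%d, %d-bit, %s, side=%s>\n",
              x$source_id, nrow(x$pixels), ncol(x$pixels), x$bit_depth,
              x$polarity, x$side))
  invisible(x)
}

max_representable <- function(img) 2^img$bit_depth - 1

assert_knee_image <- function(img) {
  if (!inherits(img, "knee_image"))
    stop("invalid image: expected a knee_image")
  if (!is.matrix(img$pixels) || length(img$pixels) == 0L)
    stop("invalid image: pixels must be a non-empty 2-D matrix")
  invisible(img)
}

#' Read a grayscale image as a knee_image
#'
#' Supports PNG and TIFF (8- or 16-bit grayscale); color input is converted to
#' luminance. DICOM is not supported.
#'
#' @param path file path.
#' @param bit_depth stored bit depth of the file (values are rescaled to this
#'   range); default 8.
#' @param side,polarity,source_id metadata; `source_id` defaults to the file
#'   name without extension.
#' @return a [knee_image].
#' @export
read_knee_image <- function(path, bit_depth = 8L, side = "double",
                            polarity = "unknown", source_id = NULL) {
  im <- EBImage::readImage(path)
  a <- EBImage::imageData(im)
  if (length(dim(a)) == 3L) a <- apply(a, c(1, 2), mean) # luminance
  pix <- round(t(a) * (2^bit_depth - 1)) # EBImage stores (x, y)
  if (is.null(source_id))
    source_id <- sub("\\.[^.]+$", "", basename(path))
  knee_image(pix, bit_depth = bit_depth, polarity = polarity, side = side,
             source_id = source_id)
}

#' Write a knee_image as an 8-bit PNG
#'
#' @param img a [knee_image] (8-bit).
#' @param path output path ending in `.png`.
#' @export
write_knee_image <- function(img, path) {
  assert_knee_image(img)
  if (img$bit_depth != 8L) stop("only 8-bit images are written")
  EBImage::writeImage(t(img$pixels / 255), path)
  invisible(path)
}

# Bilinear resize of an intensity matrix to out_h x out_w.
resize_matrix <- function(pix, out_h, out_w) {
  # EBImage's first spatial dimension maps to our rows
  r <- EBImage::resize(pix, w = out_h, h = out_w)
  matrix(as.numeric(r), out_h, out_w)
}
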