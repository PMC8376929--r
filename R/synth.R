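## Deterministic synthetic knee phantoms.
##
## A phantom emulates the structure the pipeline consumes from a real
## radiograph: two bright bone masses (femur above, tibia below) on a dark
## background, a two-compartment joint space whose per-compartment gap
## narrows with the joint-space-narrowing (JSN) grade, semicircular
## osteophyte protrusions at the four joint-margin corners whose radius grows
## with the osteophyte grade, two tibial spines in the intercondylar notch,
## and six anatomical key points. Left/right knees are mirror images.

#' Phantom specification
#'
#' @param image_size `c(height, width)` of the single-knee canvas
#'   (default 256 x 256).
#' @param base_gap joint-space height in pixels at JSN grade 0 (default 24);
#'   the gap of a compartment with grade g is `base_gap * (1 - 0.25 * g)`.
#' @param jsn_l,jsn_m joint-space-narrowing grades 0-3 (lateral, medial).
#' @param fl,fm,tl,tm osteophyte grades 0-3 (femoral/tibial x
#'   lateral/medial); the osteophyte bump radius is `2 * grade + 1` pixels.
#' @param knee_width width of the bone masses in pixels (default 140).
#' @param bone_intensity,background_intensity 8-bit gray levels.
#' @param noise_sd Gaussian pixel noise standard deviation.
#' @param blur_sigma Gaussian blur sigma in pixels.
#' @param polarity `"dark"` (default) or `"bright"` (inverted output).
#' @param jitter_px maximum |translation| of the knee center in pixels.
#' @param jitter_deg maximum |rotation| of the knee in degrees.
#' @param jitter_width maximum |knee-width perturbation| in pixels.
#' @param mirror if `TRUE` the medial compartment is drawn on the left
#'   (a right knee in image orientation).
#' @return a `phantom_spec` list.
#' @export
phantom_spec <- function(image_size = c(256L, 256L), base_gap = 24,
                         jsn_l = 0L, jsn_m = 0L, fl = 0L, fm = 0L,
                         tl = 0L, tm = 0L, knee_width = 140,
                         bone_intensity = 200, background_intensity = 30,
                         noise_sd = 8, blur_sigma = 1, polarity = "dark",
                         jitter_px = 0, jitter_deg = 0, jitter_width = 0,
                         mirror = FALSE) {
  grades <- c(jsn_l = jsn_l, jsn_m = jsn_m, fl = fl, fm = fm, tl = tl,
              tm = tm)
  if (any(grades < 0 | grades > 3))
    stop("phantom_spec: grades must be in 0..3")
  if (base_gap * (1 - 0.25 * 3) < 2)
    stop("phantom_spec: base_gap too small to render grade-3 narrowing")
  if (!polarity %in% c("dark", "bright")) stop("polarity must be dark/bright")
  structure(list(image_size = as.integer(image_size), base_gap = base_gap,
                 jsn_l = jsn_l, jsn_m = jsn_m, fl = fl, fm = fm, tl = tl,
                 tm = tm, knee_width = knee_width,
                 bone_intensity = bone_intensity,
                 background_intensity = background_intensity,
                 noise_sd = noise_sd, blur_sigma = blur_sigma,
                 polarity = polarity, jitter_px = jitter_px,
                 jitter_deg = jitter_deg, jitter_width = jitter_width,
                 mirror = mirror),
            class = "phantom_spec")
}

# Composite severity label for synthetic data: definite osteophytes and
# narrowing jointly raise the Kellgren-Lawrence grade.
kl_from_grades <- function(fl, fm, tl, tm, jsn_l, jsn_m) {
  pmin(4L, pmax(fl, fm, tl, tm) + pmax(jsn_l, jsn_m))
}

#' Assemble the eight-task label vector
#'
#' The composite KL grade of a phantom is defined as
#' `min(4, max(osteophyte grades) + max(JSN grades))` and the binary OA label
#' as `KL >= 2`.
#'
#' @param fl,fm,tl,tm,jsn_l,jsn_m integer grades 0-3.
#' @return named list with `kl`, the six feature grades, and `oa`.
#' @export
grade_labels <- function(fl, fm, tl, tm, jsn_l, jsn_m) {
  kl <- kl_from_grades(fl, fm, tl, tm, jsn_l, jsn_m)
  list(kl = kl, fl = fl, fm = fm, tl = tl, tm = tm, jsn_l = jsn_l,
       jsn_m = jsn_m, oa = as.integer(kl >= 2))
}

#' Render a single-knee phantom
#'
#' Renders the phantom deterministically from the spec and the current RNG
#' state (jitter and noise are the only random elements; with all jitter and
#' noise at zero the render is a pure function of the spec). Ground truth
#' (bounding box, six key points, labels) is returned in image coordinates
#' after the jitter transform; coordinates are 0-based, origin top-left,
#' y down, boxes half-open.
#'
#' Key-point order: lateral femoral margin, medial femoral margin, lateral
#' tibial margin, medial tibial margin, lateral tibial spine, medial tibial
#' spine.
#'
#' @param spec a [phantom_spec].
#' @return a `phantom_sample` list with `image` ([knee_image]), `box`
#'   (`c(x_min, y_min, x_max, y_max)`), `keypoints` (6 x 2 matrix of (x, y)),
#'   and `labels` (see [grade_labels()]).
#' @export
render_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  h <- spec$image_size[1]; w <- spec$image_size[2]
  kw <- spec$knee_width +
    if (spec$jitter_width > 0) stats::runif(1, -1, 1) * spec$jitter_width else 0
  cx <- w / 2 + if (spec$jitter_px > 0) stats::runif(1, -1, 1) * spec$jitter_px else 0
  cy <- h / 2 + if (spec$jitter_px > 0) stats::runif(1, -1, 1) * spec$jitter_px else 0
  th <- if (spec$jitter_deg > 0)
    stats::runif(1, -1, 1) * spec$jitter_deg * pi / 180 else 0

  g_lat <- spec$base_gap * (1 - 0.25 * spec$jsn_l)
  g_med <- spec$base_gap * (1 - 0.25 * spec$jsn_m)
  bh <- 52           # bone-mass height on each side of the joint
  corner_r <- 10     # rounding of the outer bone corners
  notch_hw <- 22     # intercondylar notch half-width
  notch_depth <- 12
  spine_u <- 14      # tibial-spine offset from the joint center
  spine_h <- 9
  spine_hw <- 6
  sgn <- if (spec$mirror) -1 else 1 # mirror swaps lateral/medial sides

  # pixel-center coordinates relative to the knee center, rotated into the
  # knee frame (u across the joint, v down)
  x <- matrix(rep(seq_len(w) - 0.5, each = h), h, w) - cx
  y <- matrix(rep(seq_len(h) - 0.5, times = w), h, w) - cy
  u <- sgn * (x * cos(th) + y * sin(th))
  v <- -x * sin(th) + y * cos(th)

  half <- kw / 2
  # femur bottom edge (negative v is up): lateral compartment at u < 0
  fem_bot <- ifelse(abs(u) < notch_hw, -(spec$base_gap / 2 + notch_depth),
                    ifelse(u < 0, -g_lat / 2, -g_med / 2))
  tib_top <- ifelse(u < 0, g_lat / 2, g_med / 2)

  in_rect <- abs(u) <= half
  # round the four outer corners of the bone block
  cor_u <- half - corner_r
  cor_vf <- -bh + corner_r
  cor_vt <- bh - corner_r
  rounded_f <- !(abs(u) > cor_u & v < cor_vf &
                   (abs(u) - cor_u)^2 + (v - cor_vf)^2 > corner_r^2)
  rounded_t <- !(abs(u) > cor_u & v > cor_vt &
                   (abs(u) - cor_u)^2 + (v - cor_vt)^2 > corner_r^2)
  femur <- in_rect & v >= -bh & v <= fem_bot & rounded_f
  tibia <- in_rect & v >= tib_top & v <= bh & rounded_t

  # tibial spines: triangles rising from the plateau into the notch
  for (s in c(-1, 1)) {
    us <- s * spine_u
    tt <- if (us < 0) g_lat / 2 else g_med / 2
    tip_v <- tt - spine_h
    tri <- abs(u - us) <= spine_hw * (1 - (tt - v) / spine_h) &
      v <= tt & v >= tip_v
    tibia <- tibia | tri
  }

  # osteophytes: semicircular bumps at the four joint-margin corners
  bump <- function(mask, uc, vc, grade) {
    r <- 2 * grade + 1
    mask | ((u - uc)^2 + (v - vc)^2 <= r^2)
  }
  femur <- bump(femur, -half, -g_lat / 2, spec$fl)
  femur <- bump(femur, +half, -g_med / 2, spec$fm)
  tibia <- bump(tibia, -half, +g_lat / 2, spec$tl)
  tibia <- bump(tibia, +half, +g_med / 2, spec$tm)

  bone <- femur | tibia
  img <- matrix(spec$background_intensity, h, w)
  img[bone] <- spec$bone_intensity
  if (spec$blur_sigma > 0) {
    b <- EBImage::gblur(img, sigma = spec$blur_sigma)
    img <- matrix(as.numeric(b), h, w)
  }
  if (spec$noise_sd > 0)
    img <- img + matrix(stats::rnorm(h * w, sd = spec$noise_sd), h, w)
  img <- round(img)
  img[img < 0] <- 0; img[img > 255] <- 255
  pol <- "dark_background"
  if (spec$polarity == "bright") {
    img <- 255 - img
    pol <- "bright_background"
  }

  # ground truth in knee-frame coordinates, then mapped to image coordinates
  kp_knee <- rbind(
    c(-half, -g_lat / 2),                       # lateral femoral margin
    c(+half, -g_med / 2),                       # medial femoral margin
    c(-half, +g_lat / 2),                       # lateral tibial margin
    c(+half, +g_med / 2),                       # medial tibial margin
    c(-spine_u, g_lat / 2 - spine_h),           # lateral tibial spine
    c(+spine_u, g_med / 2 - spine_h))           # medial tibial spine
  to_image <- function(uv) {
    uu <- sgn * uv[, 1]; vv <- uv[, 2]
    cbind(cx + uu * cos(th) - vv * sin(th),
          cy + uu * sin(th) + vv * cos(th))
  }
  kps <- to_image(kp_knee)
  pad <- 10
  corners <- to_image(rbind(c(-half - pad, -bh - pad), c(half + pad, -bh - pad),
                            c(-half - pad, bh + pad), c(half + pad, bh + pad)))
  box <- c(max(0, min(corners[, 1])), max(0, min(corners[, 2])),
           min(w, max(corners[, 1])), min(h, max(corners[, 2])))

  labels <- grade_labels(spec$fl, spec$fm, spec$tl, spec$tm, spec$jsn_l,
                         spec$jsn_m)
  structure(list(
    image = knee_image(img, bit_depth = 8L, polarity = pol,
                       side = if (spec$mirror) "right" else "left",
                       source_id = "phantom"),
    box = box, keypoints = kps, labels = labels, spec = spec),
    class = "phantom_sample")
}

#' Render a double-knee phantom
#'
#' Places two independently graded single-knee phantoms side by side on one
#' canvas; the right knee is mirrored (anatomical left/right symmetry).
#' Ground truth is reported per knee in double-image coordinates together
#' with the column offset of each half.
#'
#' @param spec_left,spec_right [phantom_spec]s for the two knees (sizes must
#'   match; `mirror` is set automatically).
#' @return list with `image` (a double [knee_image]) and `knees`, a list of
#'   two `phantom_sample`-like records with an extra `x_offset` field.
#' @export
render_double_phantom <- function(spec_left, spec_right) {
  spec_left$mirror <- FALSE
  spec_right$mirror <- TRUE
  a <- render_phantom(spec_left)
  b <- render_phantom(spec_right)
  pol <- a$image$polarity
  if (b$image$polarity != pol)
    stop("both knees of a double image must share polarity")
  w_l <- ncol(a$image$pixels)
  pix <- cbind(a$image$pixels, b$image$pixels)
  img <- knee_image(pix, bit_depth = 8L, polarity = pol, side = "double",
                    source_id = "phantom")
  b$box <- b$box + c(w_l, 0, w_l, 0)
  b$keypoints[, 1] <- b$keypoints[, 1] + w_l
  a$x_offset <- 0; b$x_offset <- w_l
  list(image = img, knees = list(left = a, right = b))
}

#' Sample per-task grade labels from the generator's marginals
#'
#' Each of the six OARSI features is drawn independently from the marginal
#' distribution over grades 0-3; the KL and OA labels are then derived with
#' the composite rule of [grade_labels()].
#'
#' @param n number of knees.
#' @param marginals probability vector over grades 0-3 (default
#'   `c(0.45, 0.25, 0.15, 0.15)`).
#' @return data.frame with columns fl, fm, tl, tm, jsn_l, jsn_m, kl, oa.
#' @export
sample_grade_labels <- function(n, marginals = c(0.45, 0.25, 0.15, 0.15)) {
  if (abs(sum(marginals) - 1) > 1e-8)
    stop("grade distribution must sum to 1")
  draw <- function() sample(0:3, n, replace = TRUE, prob = marginals)
  d <- data.frame(fl = draw(), fm = draw(), tl = draw(), tm = draw(),
                  jsn_l = draw(), jsn_m = draw())
  d$kl <- kl_from_grades(d$fl, d$fm, d$tl, d$tm, d$jsn_l, d$jsn_m)
  d$oa <- as.integer(d$kl >= 2)
  d
}

#' Generate a labeled phantom dataset
#'
#' Draws grades from the marginal distribution, renders one phantom per knee
#' and assigns a stratified 5:1:3 train/validation/test split by KL grade.
#' With `out_dir` set, writes PNG images, a labels CSV
#' (`knee_id, kl, fl, fm, tl, tm, jsn_l, jsn_m, oa, split`) and a key-point
#' JSON; otherwise samples are kept in memory.
#'
#' @param n number of knees (single) or knee pairs (double).
#' @param seed integer seed; the manifest is reproducible given `(n, seed)`.
#' @param type `"single"` or `"double"`.
#' @param marginals per-task grade marginals, see [sample_grade_labels()].
#' @param spec_args named list of overrides passed to [phantom_spec()]
#'   (e.g. jitter or noise levels).
#' @param polarity_mix fraction of images rendered with bright background.
#' @param out_dir optional output directory.
#' @return list with `samples` (list of `phantom_sample`s; for doubles, each
#'   element is a `render_double_phantom()` result) and `manifest`
#'   (data.frame of labels and split).
#' @export
generate_dataset <- function(n, seed = 1L, type = c("single", "double"),
                             marginals = c(0.45, 0.25, 0.15, 0.15),
                             spec_args = list(), polarity_mix = 0,
                             out_dir = NULL) {
  type <- match.arg(type)
  stopifnot(n >= 1)
  set.seed(seed)
  n_knees <- if (type == "double") 2L * n else n
  lab <- sample_grade_labels(n_knees, marginals)
  bright <- stats::runif(if (type == "double") n else n_knees) < polarity_mix

  default_jitter <- list(jitter_px = 14, jitter_deg = 4, jitter_width = 14)
  mk_spec <- function(i, pol) {
    args <- c(list(jsn_l = lab$jsn_l[i], jsn_m = lab$jsn_m[i],
                   fl = lab$fl[i], fm = lab$fm[i], tl = lab$tl[i],
                   tm = lab$tm[i], polarity = pol),
              spec_args)
    for (nm in names(default_jitter))
      if (is.null(args[[nm]])) args[[nm]] <- default_jitter[[nm]]
    do.call(phantom_spec, args)
  }

  samples <- vector("list", n)
  if (type == "single") {
    for (i in seq_len(n)) {
      pol <- if (bright[i]) "bright" else "dark"
      samples[[i]] <- render_phantom(mk_spec(i, pol))
      samples[[i]]$image$source_id <- sprintf("ph%05d", i)
    }
    ids <- sprintf("ph%05d", seq_len(n))
  } else {
    for (i in seq_len(n)) {
      pol <- if (bright[i]) "bright" else "dark"
      samples[[i]] <- render_double_phantom(mk_spec(2 * i - 1, pol),
                                            mk_spec(2 * i, pol))
      samples[[i]]$image$source_id <- sprintf("ph%05d", i)
    }
    ids <- as.vector(rbind(sprintf("ph%05d_L", seq_len(n)),
                           sprintf("ph%05d_R", seq_len(n))))
  }

  manifest <- cbind(data.frame(knee_id = ids), lab)
  manifest$split <- stratified_split(manifest$kl)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    kp_records <- list()
    for (i in seq_len(n)) {
      s <- samples[[i]]
      write_knee_image(s$image, file.path(out_dir,
                                          paste0(s$image$source_id, ".png")))
      recs <- if (type == "double") s$knees else list(s)
      rid <- if (type == "double")
        paste0(s$image$source_id, c("_L", "_R")) else s$image$source_id
      for (k in seq_along(recs))
        kp_records[[length(kp_records) + 1L]] <- list(
          image = paste0(s$image$source_id, ".png"), knee_id = rid[k],
          box = unname(recs[[k]]$box),
          keypoints = unname(apply(recs[[k]]$keypoints, 1, c,
                                   simplify = FALSE)))
    }
    utils::write.csv(manifest, file.path(out_dir, "labels.csv"),
                     row.names = FALSE)
    jsonlite::write_json(kp_records, file.path(out_dir, "keypoints.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(samples = samples, manifest = manifest)
}

# 5:1:3 split stratified by a grouping label.
stratified_split <- function(strata) {
  split <- character(length(strata))
  for (g in unique(strata)) {
    idx <- sample(which(strata == g))
    k <- length(idx)
    n_tr <- round(k * 5 / 9); n_va <- round(k * 1 / 9)
    split[idx[seq_len(n_tr)]] <- "train"
    split[idx[n_tr + seq_len(min(n_va, k - n_tr))]] <- "val"
    split[idx[split[idx] == ""]] <- "test"
  }
  split
}

#' Sample labeled detector training windows from a phantom
#'
#' Draws square windows around (and away from) the ground-truth box and
#' labels them by intersection-over-union with the truth: positives at
#' IoU >= 0.65, negatives below 0.3, and part samples in between (used for
#' box regression only). Positives and parts carry box offsets normalized by
#' the window side; positives also carry key points normalized to the window.
#'
#' @param sample a `phantom_sample` (single knee).
#' @param n_pos,n_part,n_neg window counts per class.
#' @param max_tries sampling attempts before giving up.
#' @return list of windows, each `list(window, iou, label, offsets,
#'   keypoints_norm)` with `label` in `c("pos", "part", "neg")`.
#' @export
sample_detector_windows <- function(sample, n_pos = 4L, n_part = 2L,
                                    n_neg = 4L, max_tries = 4000L) {
  img <- sample$image$pixels
  h <- nrow(img); w <- ncol(img)
  tb <- sample$box
  bw <- tb[3] - tb[1]; bh <- tb[4] - tb[2]
  side0 <- max(bw, bh)
  out <- list()
  want <- c(pos = n_pos, part = n_part, neg = n_neg)
  have <- c(pos = 0L, part = 0L, neg = 0L)
  tries <- 0L
  while (any(have < want) && tries < max_tries) {
    tries <- tries + 1L
    near <- stats::runif(1) < 0.75
    if (near) {
      side <- side0 * stats::runif(1, 0.8, 1.35)
      cxw <- (tb[1] + tb[3]) / 2 + stats::runif(1, -0.18, 0.18) * side0
      cyw <- (tb[2] + tb[4]) / 2 + stats::runif(1, -0.18, 0.18) * side0
    } else {
      side <- stats::runif(1, 0.3, 1) * min(h, w)
      cxw <- stats::runif(1, side / 2, w - side / 2)
      cyw <- stats::runif(1, side / 2, h - side / 2)
    }
    win <- c(cxw - side / 2, cyw - side / 2, cxw + side / 2, cyw + side / 2)
    if (win[1] < 0 || win[2] < 0 || win[3] > w || win[4] > h) next
    ov <- iou(win, tb)
    label <- if (ov >= 0.65) "pos" else if (ov < 0.3) "neg" else "part"
    if (have[label] >= want[label]) next
    have[label] <- have[label] + 1L
    rec <- list(window = win, iou = ov, label = label)
    if (label != "neg")
      rec$offsets <- (tb - win) / side
    if (label == "pos")
      rec$keypoints_norm <- cbind((sample$keypoints[, 1] - win[1]) / side,
                                  (sample$keypoints[, 2] - win[2]) / side)
    out[[length(out) + 1L]] <- rec
  }
  if (any(have < want))
    stop("sample_detector_windows: could not find requested windows")
  out
}
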