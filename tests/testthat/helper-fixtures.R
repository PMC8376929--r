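# Shared fixtures: tiny trained models are expensive, so they are built once
# per test run and memoized here.

.fixtures <- new.env()

# a small, fast cascade used by unit tests (not the acceptance-scale one)
tiny_cascade_config <- function() {
  cascade_config(stage2_input_size = 48L,
                 stage1_channels = c(8L, 16L, 24L),
                 stage2_channels = c(12L, 24L, 24L, 48L),
                 stage2_fc = 64L)
}

random_boxes <- function(n, size = 100) {
  t(replicate(n, {
    x1 <- runif(1, 0, size * 0.8); y1 <- runif(1, 0, size * 0.8)
    c(x1, y1, x1 + runif(1, 2, size * 0.4), y1 + runif(1, 2, size * 0.4))
  }))
}

# O(n^2) reference NMS: iteratively pick the best-scoring live box and kill
# overlapping ones, using pairwise IoU computed from scratch.
nms_oracle <- function(boxes, scores, thr) {
  pair_iou <- function(a, b) {
    iw <- min(a[3], b[3]) - max(a[1], b[1])
    ih <- min(a[4], b[4]) - max(a[2], b[2])
    if (iw <= 0 || ih <= 0) return(0)
    ia <- iw * ih
    ia / ((a[3] - a[1]) * (a[4] - a[2]) + (b[3] - b[1]) * (b[4] - b[2]) - ia)
  }
  alive <- rep(TRUE, length(scores))
  keep <- integer(0)
  while (any(alive)) {
    cand <- which(alive)
    best <- cand[which.max(scores[cand])]
    keep <- c(keep, best)
    alive[best] <- FALSE
    for (j in which(alive))
      if (pair_iou(boxes[best, ], boxes[j, ]) > thr) alive[j] <- FALSE
  }
  keep
}

# central-difference gradient check of a scalar-valued function of one
# parameter array inside a layer environment
fd_grad <- function(fun, get, set, idx, eps = 1e-6) {
  v0 <- get()
  vp <- v0; vp[idx] <- v0[idx] + eps; set(vp); fp <- fun()
  vm <- v0; vm[idx] <- v0[idx] - eps; set(vm); fm <- fun()
  set(v0)
  (fp - fm) / (2 * eps)
}

quick_phantom_samples <- function(n, seed, equalize = TRUE, ...) {
  gen <- generate_dataset(n, seed = seed, type = "single", ...)
  lapply(gen$samples, function(s) {
    if (equalize)
      s$image <- standardize_intensity(normalize_polarity(s$image))
    s
  })
}
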