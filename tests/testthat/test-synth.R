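test_that("rendering is deterministic given the RNG seed", {
  spec <- phantom_spec(jsn_l = 1, fl = 2, jitter_px = 10, jitter_deg = 3)
  set.seed(31); a <- render_phantom(spec)
  set.seed(31); b <- render_phantom(spec)
  expect_identical(a$image$pixels, b$image$pixels)
  expect_identical(a$keypoints, b$keypoints)
  expect_identical(a$box, b$box)
})

test_that("joint-space gap narrows with the JSN grade as specified", {
  # noiseless, unjittered render: measure the gap column-wise from the mask
  measure_gap <- function(jsn_l, jsn_m) {
    s <- render_phantom(phantom_spec(jsn_l = jsn_l, jsn_m = jsn_m,
                                     noise_sd = 0, blur_sigma = 0))
    p <- s$image$pixels
    h <- nrow(p)
    mid <- (h %/% 2 - 40):(h %/% 2 + 40)
    lat_col <- round(ncol(p) / 2 - 35) # lateral compartment, avoids spines
    med_col <- round(ncol(p) / 2 + 35)
    c(lat = sum(p[mid, lat_col] < 100), med = sum(p[mid, med_col] < 100))
  }
  g <- measure_gap(0, 3)
  expect_equal(unname(g["lat"]), 24)          # base_gap at grade 0
  expect_equal(unname(g["med"]), 24 * 0.25)   # base_gap * (1 - 0.25 * 3)
  # monotone narrowing across grades
  gaps <- vapply(0:3, function(j) measure_gap(j, 0)["lat"], numeric(1))
  expect_equal(unname(gaps), 24 * (1 - 0.25 * (0:3)))
  expect_true(all(diff(gaps) < 0))
})

test_that("all-zero grades give a mirror-symmetric phantom with equal gaps", {
  s <- render_phantom(phantom_spec(noise_sd = 0, blur_sigma = 0))
  p <- s$image$pixels
  expect_equal(p, p[, rev(seq_len(ncol(p)))]) # symmetric about the midline
  expect_equal(s$labels$kl, 0)
  expect_equal(s$labels$oa, 0)
})

test_that("osteophyte footprint grows strictly with grade", {
  areas <- vapply(0:3, function(g) {
    s <- render_phantom(phantom_spec(fl = g, noise_sd = 0, blur_sigma = 0))
    sum(s$image$pixels > 100)
  }, numeric(1))
  expect_true(all(diff(areas) > 0))
})

test_that("key points lie inside the ground-truth box", {
  set.seed(32)
  for (trial in 1:10) {
    s <- render_phantom(phantom_spec(jsn_l = sample(0:3, 1),
                                     fl = sample(0:3, 1),
                                     jitter_px = 12, jitter_deg = 4,
                                     jitter_width = 12))
    k <- s$keypoints
    expect_true(all(k[, 1] >= s$box[1] & k[, 1] <= s$box[3] &
                      k[, 2] >= s$box[2] & k[, 2] <= s$box[4]))
  }
})

test_that("bright-polarity phantoms are the pixel inversion of dark ones", {
  sp <- phantom_spec(noise_sd = 0, blur_sigma = 0)
  dark <- render_phantom(sp)
  sp$polarity <- "bright"
  bright <- render_phantom(sp)
  expect_equal(bright$image$pixels, 255 - dark$image$pixels)
  expect_equal(bright$image$polarity, "bright_background")
})

test_that("sampled grade labels respect the marginals and the KL rule", {
  set.seed(33)
  lab <- sample_grade_labels(5000)
  marg <- c(0.45, 0.25, 0.15, 0.15)
  for (nm in c("fl", "fm", "tl", "tm", "jsn_l", "jsn_m")) {
    freq <- tabulate(lab[[nm]] + 1L, 4) / 5000
    se <- sqrt(marg * (1 - marg) / 5000)
    expect_true(all(abs(freq - marg) < 3 * se + 1e-9),
                info = paste("marginal of", nm))
  }
  expect_equal(lab$kl, pmin(4, pmax(lab$fl, lab$fm, lab$tl, lab$tm) +
                              pmax(lab$jsn_l, lab$jsn_m)))
  expect_equal(lab$oa, as.integer(lab$kl >= 2))
  expect_error(sample_grade_labels(10, c(0.5, 0.5, 0.5, 0.5)), "sum")
})

test_that("generate_dataset is reproducible and writes a consistent manifest", {
  out1 <- file.path(tempdir(), "synth_a")
  out2 <- file.path(tempdir(), "synth_b")
  g1 <- generate_dataset(8, seed = 5, type = "double", out_dir = out1)
  g2 <- generate_dataset(8, seed = 5, type = "double", out_dir = out2)
  expect_identical(g1$manifest, g2$manifest)
  expect_identical(g1$samples[[3]]$image$pixels,
                   g2$samples[[3]]$image$pixels)
  m <- read.csv(file.path(out1, "labels.csv"))
  expect_equal(nrow(m), 16) # two knees per double image
  expect_equal(m$kl, pmin(4, pmax(m$fl, m$fm, m$tl, m$tm) +
                            pmax(m$jsn_l, m$jsn_m)))
  expect_true(all(m$split %in% c("train", "val", "test")))
  expect_true(file.exists(file.path(out1, "keypoints.json")))
  kp <- jsonlite::read_json(file.path(out1, "keypoints.json"))
  expect_length(kp, 16)
  expect_length(kp[[1]]$keypoints, 6)
})

test_that("the split is 5:1:3 stratified by KL", {
  set.seed(34)
  lab <- sample_grade_labels(900)
  split <- kneepipe:::stratified_split(lab$kl)
  expect_equal(sum(split == "train") / 900, 5 / 9, tolerance = 0.02)
  expect_equal(sum(split == "val") / 900, 1 / 9, tolerance = 0.02)
  expect_equal(sum(split == "test") / 900, 3 / 9, tolerance = 0.02)
})

test_that("detector windows honor the IoU mining rules", {
  set.seed(35)
  s <- render_phantom(phantom_spec(jitter_px = 10))
  wins <- sample_detector_windows(s, n_pos = 5, n_part = 3, n_neg = 5)
  labels <- vapply(wins, `[[`, character(1), "label")
  expect_equal(sum(labels == "pos"), 5)
  expect_equal(sum(labels == "neg"), 5)
  for (w in wins) {
    ov <- iou(w$window, s$box) # cross-module audit with the standalone op
    if (w$label == "pos") expect_gte(ov, 0.65)
    if (w$label == "neg") expect_lt(ov, 0.3)
    if (w$label == "part") expect_true(ov >= 0.3 && ov < 0.65)
    if (!is.null(w$offsets)) {
      side <- w$window[3] - w$window[1]
      expect_equal(w$window + w$offsets * side, s$box, tolerance = 1e-9)
    }
  }
  # a window equal to the truth box is a positive with zero offsets
  exact <- list(window = s$box)
  expect_equal(iou(s$box, s$box), 1)
})
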