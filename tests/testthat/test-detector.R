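test_that("iou handles identical, disjoint and partially overlapping boxes", {
  a <- c(0, 0, 2, 2)
  expect_equal(iou(a, a), 1)
  expect_equal(iou(a, c(5, 5, 7, 7)), 0)
  # [0,0,2,2] vs [1,0,3,2]: intersection 1x2 = 2, union 4 + 4 - 2 = 6
  expect_equal(iou(a, c(1, 0, 3, 2)), 2 / 6)
  # boxes touching along an edge do not intersect (half-open convention)
  expect_equal(iou(a, c(2, 0, 4, 2)), 0)
})

test_that("nms equals the exhaustive oracle on random instances", {
  set.seed(101)
  for (trial in 1:1000) {
    n <- sample(1:25, 1)
    boxes <- random_boxes(n)
    scores <- runif(n)
    thr <- runif(1, 0.2, 0.8)
    expect_identical(nms(boxes, scores, thr), nms_oracle(boxes, scores, thr))
  }
})

test_that("nms keeps the higher-scoring of two identical boxes", {
  b <- rbind(c(0, 0, 10, 10), c(0, 0, 10, 10))
  expect_identical(nms(b, c(0.8, 0.9), 0.5), 2L)
  expect_identical(nms(b[1, , drop = FALSE], 0.7, 0.5), 1L)
})

test_that("pyramid scales follow the geometric schedule and stop correctly", {
  cfg <- cascade_config()
  img <- matrix(0, 480, 480)
  sc <- build_pyramid_scales(img, cfg)
  expect_equal(sc[1], 48 / 80)
  expect_true(all(diff(sc) < 0))
  expect_equal(sc, 0.6 * cfg$pyramid_scale_factor^(seq_along(sc) - 1))
  # every kept scale leaves the smaller side >= the stage-1 window
  expect_true(all(480 * sc >= 48))
  expect_lt(480 * min(sc) * cfg$pyramid_scale_factor, 48)

  # boundary: image side exactly stage1_input_size / first_scale
  expect_length(build_pyramid_scales(matrix(0, 80, 80), cfg), 1)
  expect_error(build_pyramid_scales(matrix(0, 60, 60), cfg), "pyramid")

  half <- cascade_config(pyramid_scale_factor = 0.5, min_knee_size = 48L)
  sh <- build_pyramid_scales(matrix(0, 400, 400), half)
  expect_equal(sh, 1 * 0.5^(seq_along(sh) - 1))
})

test_that("multitask loss matches an independent scalar computation", {
  # two samples: one positive with known residuals, one negative
  pred <- list(score = matrix(c(2, -1), 1),
               box = matrix(c(0.1, 0.2, -0.1, 0, 0.3, 0, 0, 0), 4),
               kp = matrix(c(rep(0.05, 12), rep(0, 12)), 12))
  target <- list(cls = c(1, 0),
                 box = matrix(c(0, 0.1, 0, 0.1, rep(NA, 4)), 4),
                 kp = matrix(c(rep(0, 12), rep(NA, 12)), 12))
  alpha <- c(det = 0.8, box = 0.6, kp = 1.5)
  loss <- multitask_loss(pred, target, alpha)
  # hand computation: CE terms -log(sigmoid(2)) and -log(1 - sigmoid(-1));
  # box MSE over 4 coords for sample 1; kp MSE over 12 coords
  ce <- -log(1 / (1 + exp(-2))) - log(1 - 1 / (1 + exp(1)))
  box1 <- mean(c(0.1 - 0, 0.2 - 0.1, -0.1 - 0, 0 - 0.1)^2)
  kp1 <- mean(rep(0.05, 12)^2)
  expect_equal(as.numeric(loss),
               (0.8 * ce + 0.6 * box1 + 1.5 * kp1) / 2, tolerance = 1e-10)

  # perfect predictions: residual terms vanish, CE = -log(p_correct)
  perfect <- list(score = matrix(c(20, -20), 1), box = target$box,
                  kp = target$kp)
  perfect$box[is.na(perfect$box)] <- 0
  perfect$kp[is.na(perfect$kp)] <- 0
  l2 <- multitask_loss(perfect, target, alpha)
  expect_lt(as.numeric(l2), 1e-6)

  expect_error(multitask_loss(pred, target, c(det = -1, box = 0, kp = 0)),
               "alpha")
})

test_that("alpha_kp = 0 removes the key-point gradient exactly", {
  set.seed(44)
  pred <- list(score = matrix(rnorm(3), 1), box = matrix(rnorm(12), 4),
               kp = matrix(rnorm(36), 12))
  target <- list(cls = c(1, 0, 1), box = matrix(rnorm(12), 4),
                 kp = matrix(rnorm(36), 12))
  loss <- multitask_loss(pred, target, c(det = 1, box = 0.5, kp = 0))
  expect_true(all(attr(loss, "gkp") == 0))
  expect_gte(as.numeric(loss), 0)
})

test_that("stage-1 is fully convolutional with stride 8 and window 48", {
  set.seed(45)
  cfg <- tiny_cascade_config()
  net <- build_stage1(cfg)
  x48 <- array(rnorm(48 * 48), c(48, 48, 1, 1))
  o <- kneepipe:::stage1_forward(net, x48)
  expect_equal(dim(o$score), c(1, 1, 1, 1))
  expect_equal(dim(o$box), c(1, 1, 4, 1))

  x96 <- array(rnorm(96 * 96), c(96, 96, 1, 1))
  o96 <- kneepipe:::stage1_forward(net, x96)
  expect_equal(dim(o96$score)[1:2], c(7, 7))

  # sliding-window equivalence: grid cell (i, j) equals the per-crop score
  # of the 48x48 window at stride-8 offsets
  for (ij in list(c(1, 1), c(3, 2), c(7, 7))) {
    i <- ij[1]; j <- ij[2]
    crop <- x96[(i - 1) * 8 + 1:48, (j - 1) * 8 + 1:48, , , drop = FALSE]
    oc <- kneepipe:::stage1_forward(net, crop)
    expect_equal(o96$score[i, j, 1, 1], oc$score[1, 1, 1, 1],
                 tolerance = 1e-10)
    expect_equal(o96$box[i, j, , 1], oc$box[1, 1, , 1], tolerance = 1e-10)
  }
})

test_that("stage-2 emits a 17-dimensional multi-task output deterministically", {
  set.seed(46)
  cfg <- tiny_cascade_config()
  net <- build_stage2(cfg)
  x <- array(rnorm(48 * 48 * 2), c(48, 48, 1, 2))
  o <- kneepipe:::stage2_forward(net, x)
  expect_equal(dim(o$score), c(1, 2))
  expect_equal(dim(o$box), c(4, 2))
  expect_equal(dim(o$kp), c(12, 2))
  # identical crops give identical outputs; sigmoid score in (0, 1)
  x2 <- array(rep(x[, , , 1], 2), c(48, 48, 1, 2))
  o2 <- kneepipe:::stage2_forward(net, x2)
  expect_equal(o2$score[, 1], o2$score[, 2])
  p <- kneepipe:::sigmoid(o$score)
  expect_true(all(p > 0 & p < 1))
  expect_error(kneepipe:::stage2_forward(net, array(0, c(40, 40, 1, 1))),
               "resized")
})

test_that("detection accuracy counts IoU hits against ground truth", {
  truths <- list(c(0, 0, 10, 10), c(5, 5, 20, 20), c(0, 0, 8, 8),
                 c(2, 2, 12, 12))
  dets <- list(list(box = c(0, 0, 10, 10)),     # IoU 1
               list(box = c(6, 6, 21, 21)),     # high IoU
               NULL,                            # miss
               list(box = c(50, 50, 60, 60)))   # IoU 0
  expect_equal(detection_accuracy(dets, truths), 0.5)
  expect_equal(detection_accuracy(dets[1:2], truths[1:2]), 1)
  expect_equal(detection_accuracy(list(NULL), truths[1]), 0)
  expect_error(detection_accuracy(dets[1:2], truths), "mismatch")
})
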