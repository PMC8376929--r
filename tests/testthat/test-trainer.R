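test_that("the learning-rate schedule follows the published protocol", {
  cfg <- train_config(epochs = 20)
  expect_equal(lr_schedule(1, cfg), list(lr = 0.01, scope = "fc_only"))
  expect_equal(lr_schedule(2, cfg), list(lr = 0.01, scope = "fc_only"))
  expect_equal(lr_schedule(3, cfg), list(lr = 0.001, scope = "all"))
  expect_equal(lr_schedule(4, cfg), list(lr = 1e-4, scope = "all"))
  expect_equal(lr_schedule(20, cfg), list(lr = 1e-4, scope = "all"))
  expect_error(lr_schedule(0, cfg), "range")
  expect_error(lr_schedule(21, cfg), "range")
})

test_that("grading loss has the closed-form value for uniform predictions", {
  n <- 3
  ts <- kneepipe:::task_sizes()
  logits <- lapply(ts, function(k) matrix(0, k, n)) # equal logits = uniform
  labels <- lapply(ts, function(k) sample(0:(k - 1), n, replace = TRUE))
  loss <- grading_loss(logits, labels)
  # sum of log task cardinalities: one 5-class, six 4-class, one binary
  expect_equal(as.numeric(loss), log(5) + 6 * log(4) + log(2),
               tolerance = 1e-10)

  # perfect one-hot predictions give zero loss
  sharp <- lapply(names(ts), function(nm) {
    m <- matrix(-1000, ts[[nm]], n)
    m[cbind(labels[[nm]] + 1L, seq_len(n))] <- 1000
    m
  })
  names(sharp) <- names(ts)
  expect_equal(as.numeric(grading_loss(sharp, labels)), 0, tolerance = 1e-8)
})

test_that("masked labels and zero task weights contribute no gradient", {
  n <- 4
  ts <- kneepipe:::task_sizes()
  logits <- lapply(ts, function(k) matrix(rnorm(k * n), k, n))
  labels <- lapply(ts, function(k) sample(0:(k - 1), n, replace = TRUE))
  labels$fl[2] <- NA
  w <- stats::setNames(rep(1, 8), names(ts)); w["tm"] <- 0
  loss <- grading_loss(logits, labels, w)
  g <- attr(loss, "glogits")
  expect_true(all(g$fl[, 2] == 0))  # masked sample
  expect_true(all(g$tm == 0))       # zero-weight task
  expect_true(any(g$kl != 0))
  all_na <- lapply(labels, function(v) rep(NA_integer_, n))
  expect_error(grading_loss(logits, all_na), "masked")
})

test_that("augmentation is seed-deterministic and identity at pinned parameters", {
  set.seed(301)
  img <- matrix(sample(0:255, 48 * 48, replace = TRUE), 48, 48)
  cfg <- train_config()
  set.seed(77); a <- augment(img, cfg)
  set.seed(77); b <- augment(img, cfg)
  expect_identical(a, b)

  off <- train_config(augment = FALSE)
  expect_identical(augment(img, off), img)

  pinned <- list(contrast = 1, gamma = 1, angle = 0, tx = 0, ty = 0)
  expect_equal(augment(img, cfg, pinned), img)
})

test_that("fc-only training leaves the backbone bit-identical", {
  set.seed(302)
  model <- build_siamese_grader(backbone_config("tiny"))
  before <- kneepipe:::get_params(model$backbone_layers)
  samples <- quick_phantom_samples(10, seed = 302)
  dat <- grader_data_from_samples(samples, patch_size = 48)
  dat$labels <- lapply(dat$labels, as.integer)
  tr <- list(left = dat$left, right = dat$right, labels = dat$labels)
  cfg <- train_config(epochs = 2, batch_size = 5, seed = 302,
                      augment = FALSE)
  fc_before <- kneepipe:::get_params(model$fc_layers)
  train_grader(model, tr, cfg)
  expect_identical(kneepipe:::get_params(model$backbone_layers), before)
  expect_false(identical(kneepipe:::get_params(model$fc_layers), fc_before))
})

test_that("loss decreases over repeated fc-only steps on a fixed batch", {
  set.seed(303)
  model <- build_siamese_grader(backbone_config("tiny"))
  samples <- quick_phantom_samples(10, seed = 303)
  dat <- grader_data_from_samples(samples, patch_size = 48)
  left <- kneepipe:::stack_patches(dat$left)
  right <- kneepipe:::stack_patches(dat$right)
  opt <- kneepipe:::adam_new(model$fc_layers)
  losses <- numeric(20)
  for (i in 1:20) {
    logits <- kneepipe:::grader_forward(model, left, right, train = FALSE)
    loss <- grading_loss(logits, dat$labels)
    kneepipe:::zero_grads(model$layers)
    kneepipe:::grader_backward(model, attr(loss, "glogits"))
    kneepipe:::adam_step(opt, 0.01)
    losses[i] <- loss
  }
  expect_lt(losses[20], losses[1])
  expect_true(all(diff(losses) < 0.05)) # essentially monotone descent
})

test_that("grader training is reproducible under a fixed seed", {
  samples <- quick_phantom_samples(8, seed = 304)
  dat <- grader_data_from_samples(samples, patch_size = 48)
  tr <- list(left = dat$left, right = dat$right, labels = dat$labels)
  cfg <- train_config(epochs = 1, batch_size = 4, seed = 9)
  run <- function() {
    set.seed(99)
    m <- build_siamese_grader(backbone_config("tiny"))
    train_grader(m, tr, cfg)$log$train_loss
  }
  expect_identical(run(), run())
})
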