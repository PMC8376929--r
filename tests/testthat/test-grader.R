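# The squeeze-and-excitation block, the aggregated-transform residual block
# and the gated fusion are checked against independent scalar computations
# of their defining formulas.

se_oracle <- function(P, W1, W2) {
  # element-wise reference: squeeze, two-layer excitation, rescale
  d <- dim(P)
  out <- array(0, d)
  for (n in seq_len(d[4])) {
    z <- vapply(seq_len(d[3]), function(c) mean(P[, , c, n]), numeric(1))
    s <- pmax(W1 %*% z, 0)
    w <- 1 / (1 + exp(-(W2 %*% s)))
    for (c in seq_len(d[3])) out[, , c, n] <- w[c] * P[, , c, n]
  }
  out
}

test_that("SE block matches the element-wise oracle on random feature maps", {
  set.seed(71)
  for (trial in 1:5) {
    m <- se_block(4, reduction = 2)
    P <- array(rnorm(3 * 3 * 4 * 2), c(3, 3, 4, 2))
    expect_equal(m$fwd(P), se_oracle(P, m$l1$params$W, m$l2$params$W),
                 tolerance = 1e-6)
  }
  expect_error(se_block(6, reduction = 4), "divisible")
})

test_that("constant channels squeeze to the constant and zero weights gate at 0.5", {
  m <- se_block(4, reduction = 2)
  P <- array(0, c(3, 3, 4, 1))
  for (c in 1:4) P[, , c, 1] <- c * 1.5
  d <- dim(P)
  z <- matrix(colMeans(matrix(P, 9, 4)), 4, 1)
  expect_equal(as.numeric(z), (1:4) * 1.5) # squeeze of constant = constant

  m$l1$params$W[] <- 0
  m$l2$params$W[] <- 0
  out <- m$fwd(P)
  expect_equal(out, 0.5 * P) # sigmoid(0) = 0.5 per channel
})

test_that("SE reweighting preserves the sign pattern of every channel", {
  set.seed(72)
  m <- se_block(8, reduction = 4)
  P <- array(rnorm(5 * 5 * 8 * 2), c(5, 5, 8, 2))
  out <- m$fwd(P)
  expect_true(all(sign(out) == sign(P)))
})

test_that("grouped-convolution block equals the explicit 32-branch sum", {
  set.seed(73)
  blk <- resnext_block(64, 64, cardinality = 32, bottleneck_width = 4,
                       reduction = 16)
  x <- array(rnorm(5 * 5 * 64), c(5, 5, 64, 1))
  y <- blk$fwd(x)
  expect_equal(dim(y), dim(x))

  # reference: run each of the 32 bottleneck branches separately with plain
  # convolutions and sum the aggregated transforms
  b <- 32 * 4
  h1 <- kneepipe:::conv2d_fwd_cpp(x, blk$reduce$params$W,
                                  blk$reduce$params$b, 1L, 0L, 1L)
  h1 <- pmax(h1, 0)
  agg <- array(0, c(5, 5, b, 1))
  for (g in 1:32) {
    chans <- (g - 1) * 4 + 1:4
    xin <- h1[, , chans, , drop = FALSE]
    wg <- blk$gconv$params$W[, , , chans, drop = FALSE]
    agg[, , chans, ] <- kneepipe:::conv2d_fwd_cpp(
      xin, wg, blk$gconv$params$b[chans], 1L, 1L, 1L)
  }
  agg <- pmax(agg, 0)
  h2 <- kneepipe:::conv2d_fwd_cpp(agg, blk$expand$params$W,
                                  blk$expand$params$b, 1L, 0L, 1L)
  h2 <- blk$se$fwd(h2)
  ref <- pmax(h2 + x, 0)
  expect_equal(y, ref, tolerance = 1e-5)
})

test_that("a zero-weight residual block is the identity after ReLU", {
  blk <- resnext_block(8, 8, cardinality = 4, bottleneck_width = 2,
                       reduction = 4)
  for (l in list(blk$reduce, blk$gconv, blk$expand)) {
    l$params$W[] <- 0
    l$params$b[] <- 0
  }
  x <- array(abs(rnorm(4 * 4 * 8)), c(4, 4, 8, 1)) # non-negative input
  expect_equal(blk$fwd(x), x)
})

test_that("gated fusion matches scalar evaluation and its invariants", {
  set.seed(74)
  for (trial in 1:100) {
    d <- sample(2:8, 1)
    fl <- matrix(rnorm(d), d, 1)
    fr <- matrix(rnorm(d), d, 1)
    Wg <- matrix(rnorm(d * 2 * d, sd = 0.5), d, 2 * d)
    r <- gated_fuse(fl, fr, Wg)
    # scalar oracle, element by element
    for (i in seq_len(d)) {
      gi <- 1 / (1 + exp(-sum(Wg[i, ] * c(fl, fr))))
      expect_equal(r$g[i, 1], gi, tolerance = 1e-9)
      expect_equal(r$f[i, 1], gi * fl[i, 1] + (1 - gi) * fr[i, 1],
                   tolerance = 1e-9)
    }
    # fused output lies between the elementwise min and max
    expect_true(all(r$f >= pmin(fl, fr) - 1e-12 &
                      r$f <= pmax(fl, fr) + 1e-12))
  }
})

test_that("fusion degenerate cases: zero gate weights and equal inputs", {
  d <- 6
  fl <- matrix(rnorm(d), d, 1); fr <- matrix(rnorm(d), d, 1)
  r0 <- gated_fuse(fl, fr, matrix(0, d, 2 * d))
  expect_equal(r0$g, matrix(0.5, d, 1))
  expect_equal(r0$f, (fl + fr) / 2)
  Wg <- matrix(rnorm(d * 2 * d), d, 2 * d)
  req <- gated_fuse(fl, fl, Wg)
  expect_equal(req$f, fl) # convex combination of equal points
  expect_error(gated_fuse(fl, matrix(0, d + 1, 1), Wg), "mismatch")
})

test_that("swapping inputs and gate blocks flips the gate and keeps the fusion", {
  set.seed(75)
  d <- 5
  fl <- matrix(rnorm(d), d, 1); fr <- matrix(rnorm(d), d, 1)
  A <- matrix(rnorm(d * d), d, d); B <- matrix(rnorm(d * d), d, d)
  Wg <- cbind(A, B)
  Wg_swapped <- cbind(B, A)
  r1 <- gated_fuse(fl, fr, Wg)
  r2 <- gated_fuse(fr, fl, -Wg_swapped)
  expect_equal(r2$g, 1 - r1$g, tolerance = 1e-12)
  expect_equal(r2$f, r1$f, tolerance = 1e-12)
})

test_that("task heads emit normalized probabilities and dropout is eval-silent", {
  set.seed(76)
  model <- build_siamese_grader(backbone_config("tiny"))
  n <- 2
  left <- array(rnorm(48 * 48 * n), c(48, 48, 1, n))
  right <- array(rnorm(48 * 48 * n), c(48, 48, 1, n))
  pred <- predict_grades(model, left, right)
  sizes <- kneepipe:::task_sizes()
  expect_named(pred$probs, names(sizes))
  for (nm in names(sizes)) {
    expect_equal(nrow(pred$probs[[nm]]), unname(sizes[[nm]]))
    expect_equal(colSums(pred$probs[[nm]]), rep(1, n), tolerance = 1e-6)
    expect_true(all(pred$probs[[nm]] >= 0))
  }
  # eval mode is deterministic (dropout off)
  pred2 <- predict_grades(model, left, right)
  expect_identical(pred$probs, pred2$probs)
  # Siamese weight sharing: identical patches give identical features, so
  # fused = branch feature and prediction equals itself under swap
  predsw <- predict_grades(model, left, left)
  expect_equal(predsw$probs, predict_grades(model, left, left)$probs)
})

test_that("ensemble averages per-task probabilities", {
  set.seed(77)
  cfgb <- backbone_config("tiny")
  gm <- build_global_grader(cfgb)
  sm <- build_siamese_grader(cfgb)
  n <- 3
  roi <- array(rnorm(48 * 48 * n), c(48, 48, 1, n))
  l <- array(rnorm(48 * 48 * n), c(48, 48, 1, n))
  r <- array(rnorm(48 * 48 * n), c(48, 48, 1, n))
  pe <- ensemble_predict(gm, sm, roi, l, r)
  pg <- predict_grades(gm, roi)
  ps <- predict_grades(sm, l, r)
  for (nm in names(pe$probs)) {
    expect_equal(pe$probs[[nm]], (pg$probs[[nm]] + ps$probs[[nm]]) / 2)
    expect_equal(colSums(pe$probs[[nm]]), rep(1, n), tolerance = 1e-6)
  }
  # a serialized round trip of one member leaves the ensemble unchanged
  sm_path <- file.path(tempdir(), "sm.rds")
  save_model(sm, sm_path)
  sm2 <- load_model(sm_path)
  pe2 <- ensemble_predict(gm, sm2, roi, l, r)
  expect_equal(pe2$probs, pe$probs, tolerance = 1e-12)
})

test_that("backbone forward is finite on degenerate input and respects sizes", {
  model <- build_siamese_grader(backbone_config("tiny"))
  zero <- array(0, c(48, 48, 1, 1))
  f <- backbone_forward(model, zero)
  expect_true(all(is.finite(f)))
  expect_equal(nrow(f), 64)
  expect_error(backbone_forward(model, array(0, c(32, 32, 1, 1))), "size")
})

test_that("the full 50-layer profile builds and runs a forward pass", {
  set.seed(78)
  cfg <- backbone_config("full", input_size = 64)
  model <- build_siamese_grader(cfg)
  x <- array(rnorm(64 * 64), c(64, 64, 1, 1))
  f <- backbone_forward(model, x)
  expect_equal(nrow(f), 2048)
  expect_true(all(is.finite(f)))
})
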