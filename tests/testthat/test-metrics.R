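test_that("top1 and top_pm1 reproduce worked examples", {
  expect_equal(top1(c(0, 2, 2, 0), c(0, 1, 2, 3)), 0.5)
  expect_equal(top1(c(1, 2), c(1, 2)), 1)
  expect_equal(top1(3, 1), 0)
  # labels (0, 4), preds (1, 2): |1-0| = 1 ok, |2-4| = 2 not
  expect_equal(top1(c(1, 2), c(0, 4)), 0)
  expect_equal(top_pm1(c(1, 2), c(0, 4)), 0.5)
  expect_equal(top_pm1(c(0, 4), c(0, 4)), 1)
  expect_error(top1(integer(0), integer(0)), "empty")
  expect_error(top_pm1(1:3, 1:2), "mismatch")
})

test_that("top_pm1 equals a per-pair oracle and dominates top1", {
  set.seed(201)
  for (trial in 1:20) {
    n <- 500
    preds <- sample(0:4, n, replace = TRUE)
    labels <- sample(0:4, n, replace = TRUE)
    oracle <- sum(vapply(seq_len(n), function(i)
      abs(preds[i] - labels[i]) <= 1, logical(1))) / n
    expect_equal(top_pm1(preds, labels), oracle)
    expect_gte(top_pm1(preds, labels), top1(preds, labels))
  }
  # binary task: |diff| <= 1 always, so top_pm1 is identically 1
  expect_equal(top_pm1(sample(0:1, 100, TRUE), sample(0:1, 100, TRUE)), 1)
})

test_that("kappa reproduces a hand-computed 3x3 contingency table", {
  # observed table (rows true, cols pred):
  #   22  7  1
  #    5 37  8
  #    0  6 14
  labels <- rep(c(0, 0, 0, 1, 1, 1, 2, 2, 2), c(22, 7, 1, 5, 37, 8, 0, 6, 14))
  preds <- rep(c(0, 1, 2, 0, 1, 2, 0, 1, 2), c(22, 7, 1, 5, 37, 8, 0, 6, 14))
  n <- 100
  O <- matrix(c(22, 5, 0, 7, 37, 6, 1, 8, 14), 3) # column-major
  E <- outer(rowSums(O), colSums(O)) / n
  for (wt in c("none", "linear", "quadratic")) {
    W <- switch(wt, none = 1 - diag(3),
                linear = abs(outer(0:2, 0:2, "-")),
                quadratic = outer(0:2, 0:2, "-")^2)
    expect_equal(kappa(preds, labels, wt), 1 - sum(W * O) / sum(W * E),
                 tolerance = 1e-12)
  }
  expect_equal(kappa(labels, labels, "none"), 1)
})

test_that("unweighted kappa agrees with e1071 and independence gives ~0", {
  skip_if_not_installed("e1071")
  set.seed(202)
  labels <- sample(0:3, 300, replace = TRUE)
  preds <- pmin(3, pmax(0, labels + sample(-1:1, 300, replace = TRUE)))
  tab <- table(factor(labels, 0:3), factor(preds, 0:3))
  expect_equal(kappa(preds, labels, "none"),
               e1071::classAgreement(tab)$kappa, tolerance = 1e-10)

  # independent raters: kappa ~ 0 at n = 10000
  labs <- sample(0:4, 10000, replace = TRUE)
  prds <- sample(0:4, 10000, replace = TRUE)
  expect_lt(abs(kappa(prds, labs, "quadratic")), 0.03)
  expect_lt(abs(kappa(prds, labs, "none")), 0.03)
})

test_that("degenerate single-class agreement is flagged, not fabricated", {
  k <- kappa(rep(2, 10), rep(2, 10), "none", n_classes = 4)
  expect_true(is.na(k))
  expect_true(attr(k, "degenerate"))
})

test_that("quadratic kappa is invariant to order-preserving relabeling", {
  set.seed(203)
  labels <- sample(0:4, 400, replace = TRUE)
  preds <- pmin(4, pmax(0, labels + sample(-2:2, 400, replace = TRUE)))
  k1 <- kappa(preds, labels, "quadratic")
  # affine order-preserving map g -> 2g + 1 applied to both raters
  k2 <- kappa(2 * preds + 1, 2 * labels + 1, "quadratic", n_classes = 10)
  expect_equal(k1, k2, tolerance = 1e-10)
})

test_that("mse matches arithmetic and confusion matches a counting oracle", {
  expect_equal(mse(c(1, 0), c(0, 2)), 2.5)
  expect_equal(mse(1:4, 1:4), 0)
  set.seed(204)
  preds <- sample(0:3, 200, replace = TRUE)
  labels <- sample(0:3, 200, replace = TRUE)
  cm <- confusion(preds, labels, 4)
  expect_equal(sum(cm), 200)
  for (i in 0:3) for (j in 0:3)
    expect_equal(cm[i + 1, j + 1], sum(labels == i & preds == j))
  expect_true(all(diag(confusion(labels, labels, 4)) == rowSums(cm) * 0 +
                    table(factor(labels, 0:3))))
  expect_error(confusion(c(0, 4), c(0, 1), 4), "range")
})

test_that("evaluation report assembles per-task metrics and suppresses OA top_pm1", {
  set.seed(205)
  lab <- sample_grade_labels(200)
  noisy <- lapply(lab, function(v)
    pmax(0, v + sample(c(-1, 0, 0, 1), 200, replace = TRUE)))
  noisy$kl <- pmin(4, noisy$kl)
  for (nm in c("fl", "fm", "tl", "tm", "jsn_l", "jsn_m"))
    noisy[[nm]] <- pmin(3, noisy[[nm]])
  noisy$oa <- pmin(1, noisy$oa)
  rep <- evaluate_grades(noisy, lab)
  expect_s3_class(rep, "eval_report")
  expect_equal(nrow(rep$metrics), 8)
  expect_true(is.na(rep$metrics$top_pm1[rep$metrics$task == "oa"]))
  ord <- rep$metrics$task != "oa"
  expect_true(all(rep$metrics$top_pm1[ord] >= rep$metrics$top1[ord]))
  for (nm in rep$metrics$task)
    expect_equal(sum(rep$confusion[[nm]]), 200)
})
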