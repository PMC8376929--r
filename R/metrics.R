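## Ordinal evaluation metrics: top1, top+/-1 accuracy, Cohen's kappa
## (unweighted / linear / quadratic), mean squared error, confusion
## matrices, and report assembly.

#' Top-1 accuracy
#'
#' @param preds,labels integer grade vectors of equal length >= 1.
#' @return fraction of exact matches.
#' @export
top1 <- function(preds, labels) {
  if (length(preds) != length(labels)) stop("top1: length mismatch")
  if (length(preds) == 0) stop("top1: empty input")
  mean(preds == labels)
}

#' Top +/-1 accuracy for ordinal grades
#'
#' A prediction counts as correct when its grade differs from the true grade
#' by at most one: a grade-1 knee predicted as 0, 1 or 2 is accepted. The
#' endpoints are handled by the same absolute-distance rule (grade 0 accepts
#' 0 and 1).
#'
#' @param preds,labels integer grade vectors of equal length >= 1.
#' @return fraction with `|pred - label| <= 1`.
#' @export
top_pm1 <- function(preds, labels) {
  if (length(preds) != length(labels)) stop("top_pm1: length mismatch")
  if (length(preds) == 0) stop("top_pm1: empty input")
  mean(abs(preds - labels) <= 1)
}

#' Cohen's kappa with optional ordinal weighting
#'
#' `kappa = 1 - sum(W * O) / sum(W * E)` with disagreement weights
#' `W[i,j] = (i != j)` (none), `|i - j|` (linear) or `(i - j)^2` (quadratic),
#' observed contingency table `O`, and chance-expected table `E` from the
#' marginal products. Quadratic weighting is the default, the convention for
#' ordinal radiographic grading. When both raters use a single identical
#' category the statistic is undefined and `NA` is returned with attribute
#' `degenerate = TRUE`.
#'
#' @param preds,labels integer grade vectors (length >= 2).
#' @param weighting `"quadratic"` (default), `"linear"` or `"none"`.
#' @param n_classes number of categories; defaults to the observed range.
#' @return kappa in `[-1, 1]`, or flagged `NA` when undefined.
#' @export
kappa <- function(preds, labels,
                  weighting = c("quadratic", "linear", "none"),
                  n_classes = NULL) {
  weighting <- match.arg(weighting)
  if (length(preds) != length(labels)) stop("kappa: length mismatch")
  if (length(preds) < 2) stop("kappa: need at least 2 samples")
  if (is.null(n_classes)) n_classes <- max(preds, labels) + 1L
  k <- n_classes
  O <- confusion(preds, labels, k)
  n <- sum(O)
  E <- outer(rowSums(O), colSums(O)) / n
  i <- matrix(0:(k - 1), k, k)
  W <- switch(weighting,
              none = (i != t(i)) * 1,
              linear = abs(i - t(i)),
              quadratic = (i - t(i))^2)
  denom <- sum(W * E)
  if (denom == 0)
    return(structure(NA_real_, degenerate = TRUE))
  1 - sum(W * O) / denom
}

#' Mean squared error of integer grades
#'
#' @param preds,labels integer grade vectors of equal length >= 1.
#' @return mean of squared grade differences.
#' @export
mse <- function(preds, labels) {
  if (length(preds) != length(labels)) stop("mse: length mismatch")
  if (length(preds) == 0) stop("mse: empty input")
  mean((preds - labels)^2)
}

#' Confusion matrix
#'
#' Entry `(i, j)` counts samples with true grade `i - 1` predicted as grade
#' `j - 1`; row sums give per-class support.
#'
#' @param preds,labels integer grade vectors.
#' @param n_classes number of grades.
#' @return `n_classes x n_classes` integer matrix.
#' @export
confusion <- function(preds, labels, n_classes) {
  if (any(preds < 0 | preds >= n_classes | labels < 0 |
            labels >= n_classes))
    stop("confusion: grade out of range")
  m <- matrix(0L, n_classes, n_classes,
              dimnames = list(true = 0:(n_classes - 1),
                              pred = 0:(n_classes - 1)))
  for (i in seq_along(preds))
    m[labels[i] + 1L, preds[i] + 1L] <- m[labels[i] + 1L, preds[i] + 1L] + 1L
  m
}

#' Assemble the per-task evaluation report
#'
#' Computes top1, top+/-1, kappa (all three weightings), MSE and the
#' confusion matrix for each of the eight tasks. Top +/-1 is suppressed
#' (NA) for the binary OA task, where it is trivially 1.
#'
#' @param preds,labels named lists (or data.frames) of integer grade vectors
#'   for the tasks of [task_sizes()] (subsets allowed).
#' @return an `eval_report` list: `metrics` (data.frame) and `confusion`
#'   (named list of matrices), plus `n_samples`.
#' @export
evaluate_grades <- function(preds, labels) {
  tasks <- intersect(names(task_sizes()), names(preds))
  ts <- task_sizes()
  rows <- list(); conf <- list()
  for (nm in tasks) {
    p <- preds[[nm]]; y <- labels[[nm]]
    keep <- !is.na(y)
    p <- p[keep]; y <- y[keep]
    rows[[nm]] <- data.frame(
      task = nm,
      top1 = top1(p, y),
      top_pm1 = if (nm == "oa") NA_real_ else top_pm1(p, y),
      kappa_quadratic = as.numeric(kappa(p, y, "quadratic", ts[[nm]])),
      kappa_linear = as.numeric(kappa(p, y, "linear", ts[[nm]])),
      kappa_none = as.numeric(kappa(p, y, "none", ts[[nm]])),
      mse = mse(p, y))
    conf[[nm]] <- confusion(p, y, ts[[nm]])
  }
  structure(list(metrics = do.call(rbind, rows), confusion = conf,
                 n_samples = length(preds[[tasks[1]]])),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report: %d samples>\n", x$n_samples))
  print(x$metrics, row.names = FALSE, digits = 3)
  invisible(x)
}
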