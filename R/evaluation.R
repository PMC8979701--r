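#' Confusion matrix and classification metrics
#'
#' Builds the exact integer confusion matrix and computes accuracy,
#' sensitivity and specificity. Sensitivity is recall on the designated
#' positive (abnormal) class, specificity is recall on the rest (for binary
#' problems, the normal class); for multi-class inputs both are computed
#' one-vs-rest against `positive_class`. When a class is absent from the
#' truth the corresponding rate is reported as `NA`, never as 0.
#'
#' @param predicted integer vector of predicted 0-based labels.
#' @param truth integer vector of true 0-based labels.
#' @param n_classes number of classes; inferred from the labels if `NULL`.
#' @param positive_class 0-based index of the positive/abnormal class
#'   (default 1).
#' @return An object of class `eval_report` with fields `confusion`
#'   (N_c x N_c integer matrix, rows = truth, columns = prediction), `acc`,
#'   `sen`, `spe`, `auc` (`NA` until scores are supplied), `roc_points`,
#'   `n`, and `positive_class`.
#' @examples
#' confusion_and_metrics(c(0, 1, 1, 0), c(0, 1, 0, 0))
#' @export
confusion_and_metrics <- function(predicted, truth, n_classes = NULL,
                                  positive_class = 1) {
  predicted <- as.integer(predicted)
  truth <- as.integer(truth)
  if (length(predicted) != length(truth))
    stop(sprintf("length mismatch: %d predictions vs %d truths",
                 length(predicted), length(truth)), call. = FALSE)
  nc <- as.integer(n_classes %||% (max(predicted, truth) + 1L))
  if (any(predicted < 0 | predicted >= nc) || any(truth < 0 | truth >= nc))
    stop("labels out of range [0, N_c)", call. = FALSE)
  conf <- matrix(0L, nc, nc,
                 dimnames = list(truth = 0:(nc - 1), predicted = 0:(nc - 1)))
  for (i in seq_along(truth))
    conf[truth[i] + 1L, predicted[i] + 1L] <- conf[truth[i] + 1L, predicted[i] + 1L] + 1L
  n <- length(truth)
  acc <- sum(diag(conf)) / n
  pos <- positive_class + 1L
  n_pos <- sum(conf[pos, ])
  n_neg <- n - n_pos
  sen <- if (n_pos > 0) conf[pos, pos] / n_pos else NA_real_
  # one-vs-rest: a true negative is any non-positive sample not predicted positive
  spe <- if (n_neg > 0) (n_neg - (sum(conf[, pos]) - conf[pos, pos])) / n_neg else NA_real_
  structure(list(confusion = conf, acc = acc, sen = sen, spe = spe,
                 auc = NA_real_, roc_points = NULL, n = n,
                 positive_class = as.integer(positive_class)),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report: n=%d  ACC=%.3f  SEN=%s  SPE=%s  AUC=%s>\n",
              x$n, x$acc,
              ifelse(is.na(x$sen), "NA", sprintf("%.3f", x$sen)),
              ifelse(is.na(x$spe), "NA", sprintf("%.3f", x$spe)),
              ifelse(is.na(x$auc), "NA", sprintf("%.3f", x$auc))))
  print(x$confusion)
  invisible(x)
}

#' Area under the ROC curve (rank / midrank form)
#'
#' Computed with the midrank tie convention, so the value equals the
#' Mann-Whitney U statistic divided by `n_pos * n_neg`: the probability
#' that a randomly chosen positive scores above a randomly chosen negative
#' (ties counting one half). Invariant under any strictly monotone
#' transformation of the scores.
#'
#' @param scores numeric scores for the positive class.
#' @param labels binary vector (0 = negative, 1 = positive); both classes
#'   must be present.
#' @return AUC in [0, 1].
#' @export
auc_score <- function(scores, labels) {
  labels <- as.integer(labels)
  if (length(scores) != length(labels))
    stop("scores and labels must have equal length", call. = FALSE)
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == 0)
  if (n_pos == 0 || n_neg == 0)
    stop("AUC requires both classes to be present", call. = FALSE)
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' ROC curve points
#'
#' Sweeps every distinct score as a threshold (predict positive when
#' `score >= threshold`) and returns the (FPR, TPR) staircase from (0,0) to
#' (1,1); tied scores move together, matching the midrank AUC.
#'
#' @inheritParams auc_score
#' @return A tibble with columns `threshold`, `fpr`, `tpr`, ordered with
#'   both rates non-decreasing.
#' @export
roc_curve <- function(scores, labels) {
  labels <- as.integer(labels)
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == 0)
  if (n_pos == 0 || n_neg == 0)
    stop("ROC requires both classes to be present", call. = FALSE)
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; y <- labels[o]
  tp <- cumsum(y == 1)
  fp <- cumsum(y == 0)
  last <- !duplicated(s, fromLast = TRUE)   # collapse tied thresholds
  tibble::tibble(threshold = c(Inf, s[last]),
                 fpr = c(0, fp[last] / n_neg),
                 tpr = c(0, tp[last] / n_pos))
}

#' Evaluate a trained network on labeled data
#'
#' Predicts every image, builds the confusion matrix and metrics, and (for
#' binary problems) adds the ROC curve and midrank AUC computed from the
#' positive-class softmax probability.
#'
#' @param net an [accn_network()].
#' @param x image batch (H, W, C, N).
#' @param y integer true 0-based labels.
#' @param positive_class 0-based positive class (default 1).
#' @return An `eval_report` (see [confusion_and_metrics()]).
#' @export
evaluate_model <- function(net, x, y, positive_class = 1) {
  x <- as_image_batch(x)
  probs <- predict_in_chunks(net, x, what = "prob")
  pred <- max.col(probs, ties.method = "first") - 1L
  rep_ <- confusion_and_metrics(pred, y, n_classes = ncol(probs),
                                positive_class = positive_class)
  if (ncol(probs) == 2 && length(unique(y)) == 2) {
    sc <- probs[, positive_class + 1L]
    bin <- as.integer(y == positive_class)
    rep_$auc <- auc_score(sc, bin)
    rep_$roc_points <- roc_curve(sc, bin)
  }
  rep_
}
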