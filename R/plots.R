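#' Plot training loss curves
#'
#' Draws the per-step loss terms (labeled cross-entropy, augmentation
#' consistency, centroid consistency, pseudo-label cross-entropy) and the
#' combined objective, optionally smoothed by a moving average to make the
#' downward trend visible through the batch-to-batch ups and downs caused
#' by pseudo-label regeneration.
#'
#' @param object an `accn_fit`.
#' @param smooth moving-average window in steps (1 = raw values).
#' @param ... ignored.
#' @return A ggplot object.
#' @export
autoplot.accn_fit <- function(object, smooth = 10, ...) {
  h <- object$history
  h$global_step <- seq_len(nrow(h))
  long <- do.call(rbind, lapply(c("l_lce", "l_ac", "l_gc", "l_pce", "total"),
    function(nm) {
      val <- moving_average(h[[nm]], smooth)
      tibble::tibble(global_step = h$global_step, term = nm, value = val)
    }))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$global_step, y = .data$value,
                                     colour = .data$term)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "training step", y = "loss",
                  colour = NULL,
                  title = "Training loss",
                  subtitle = if (smooth > 1)
                    sprintf("%d-step moving average", smooth) else NULL) +
    ggplot2::theme_minimal()
}

#' Plot an ROC curve
#'
#' @param object an `eval_report` containing ROC points (binary problems
#'   evaluated via [evaluate_model()]).
#' @param ... ignored.
#' @return A ggplot object.
#' @export
autoplot.eval_report <- function(object, ...) {
  if (is.null(object$roc_points))
    stop("this eval_report has no ROC points (non-binary evaluation?)",
         call. = FALSE)
  ggplot2::ggplot(object$roc_points, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_step() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "false positive rate", y = "true positive rate",
                  title = sprintf("ROC curve (AUC = %.3f)", object$auc)) +
    ggplot2::theme_minimal()
}

moving_average <- function(x, w) {
  if (w <= 1) return(x)
  n <- length(x)
  out <- numeric(n)
  cs <- cumsum(x)
  for (i in seq_len(n)) {
    j <- max(1L, i - w + 1L)
    out[i] <- (cs[i] - if (j > 1) cs[j - 1] else 0) / (i - j + 1)
  }
  out
}
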