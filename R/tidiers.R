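#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a fitted training run
#'
#' `tidy()` returns the per-step loss history in long format (one row per
#' step and loss term); `glance()` returns a one-row summary with the final
#' loss, final and best held-out accuracy, and the final pseudo-label
#' accuracy when it was monitored.
#'
#' @param x an `accn_fit`.
#' @param ... ignored.
#' @return A tibble.
#' @export
tidy.accn_fit <- function(x, ...) {
  h <- x$history
  h$global_step <- seq_len(nrow(h))
  do.call(rbind, lapply(c("l_lce", "l_ac", "l_gc", "l_pce", "total"),
    function(nm) {
      val <- h[[nm]]
      tibble::tibble(epoch = h$epoch, step = h$step,
                     global_step = h$global_step, term = nm, value = val)
    }))
}

#' @rdname tidy.accn_fit
#' @export
glance.accn_fit <- function(x, ...) {
  em <- x$epoch_metrics
  last <- em[nrow(em), ]
  tibble::tibble(
    epochs = max(x$history$epoch),
    steps = nrow(x$history),
    final_total_loss = x$history$total[nrow(x$history)],
    final_acc = last$acc,
    best_acc = if (any(!is.na(em$acc))) max(em$acc, na.rm = TRUE) else NA_real_,
    best_epoch = x$best_epoch,
    final_pseudo_acc = last$pseudo_acc)
}

#' Tidy an evaluation report
#'
#' `tidy()` returns one row per metric; `glance()` returns the metrics as a
#' one-row tibble.
#'
#' @param x an `eval_report`.
#' @param ... ignored.
#' @return A tibble.
#' @export
tidy.eval_report <- function(x, ...) {
  tibble::tibble(metric = c("acc", "sen", "spe", "auc"),
                 value = c(x$acc, x$sen, x$spe, x$auc))
}

#' @rdname tidy.eval_report
#' @export
glance.eval_report <- function(x, ...) {
  tibble::tibble(n = x$n, acc = x$acc, sen = x$sen, spe = x$spe, auc = x$auc)
}
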