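#' Centroid state for the weight clustering unit
#'
#' Holds the dynamic global centroid memory `M_k` (one row per class), the
#' per-class occurrence counters `t_k` (how many samples were pseudo-labelled
#' `k` in the previous batch), and bookkeeping flags. The memory is updated
#' each batch by the damped convex combination
#' `M_k <- (1 - eta) M_k + eta c_k` with rate `eta = exp(-t_k)`, so
#' well-populated classes move slowly while rarely seen classes snap to
#' fresh evidence.
#'
#' @param n_classes number of classes.
#' @param d_f feature dimension.
#' @return An object of class `centroid_state`.
#' @export
centroid_state <- function(n_classes, d_f) {
  stopifnot(n_classes >= 2, d_f >= 1)
  structure(list(memory = matrix(0, n_classes, d_f),
                 counts = integer(n_classes),
                 seen = logical(n_classes),
                 n_classes = as.integer(n_classes),
                 d_f = as.integer(d_f)),
            class = "centroid_state")
}

#' @export
print.centroid_state <- function(x, ...) {
  cat(sprintf("<centroid_state: %d classes, d_f=%d, counts=[%s]>\n",
              x$n_classes, x$d_f, paste(x$counts, collapse = ",")))
  invisible(x)
}

#' Soft-weighted class centroids
#'
#' Estimates a centroid per class as the softmax-weighted mean of the
#' feature vectors: `c_k = sum_i delta_k(P_i) f_i / sum_i delta_k(P_i)`,
#' where `delta_k(P_i)` is sample i's predicted probability of class k.
#' With one-hot probabilities this degenerates to per-class arithmetic
#' means; with uniform probabilities every centroid equals the global
#' feature mean.
#'
#' A class whose total weight falls below `eps` in the batch has no usable
#' local centroid; its row is backfilled from `memory` (when supplied) and
#' flagged invalid so downstream losses/updates can skip it.
#'
#' @param features n x d_f feature matrix.
#' @param probs n x N_c matrix of probability rows.
#' @param memory optional N_c x d_f matrix used to backfill empty classes.
#' @param eps empty-class detection threshold on the total class weight.
#' @return A list: `centroids` (N_c x d_f) and `valid` (logical N_c).
#' @export
soft_weighted_centroids <- function(features, probs, memory = NULL, eps = 1e-6) {
  features <- as.matrix(features)
  probs <- as.matrix(probs)
  if (nrow(features) == 0) stop("cannot form centroids from an empty batch", call. = FALSE)
  if (nrow(features) != nrow(probs))
    stop(sprintf("features (%d rows) and probs (%d rows) disagree",
                 nrow(features), nrow(probs)), call. = FALSE)
  w_tot <- colSums(probs)
  cent <- crossprod(probs, features)          # N_c x d_f
  valid <- w_tot >= eps
  cent[valid, ] <- cent[valid, , drop = FALSE] / w_tot[valid]
  if (any(!valid)) {
    if (!is.null(memory)) cent[!valid, ] <- memory[!valid, , drop = FALSE]
    else cent[!valid, ] <- 0
  }
  list(centroids = cent, valid = valid)
}

#' Nearest-centroid pseudo-labels
#'
#' Assigns each feature vector the 0-based label of the nearest centroid in
#' Euclidean distance; ties break toward the smallest class index.
#' Distances are accumulated in double precision so the tie-break is
#' reproducible.
#'
#' @param features n x d_f matrix.
#' @param centroids N_c x d_f matrix; must be finite.
#' @return Integer vector of n pseudo-labels in `0:(N_c-1)`.
#' @export
assign_pseudolabels <- function(features, centroids) {
  features <- as.matrix(features)
  centroids <- as.matrix(centroids)
  if (!all(is.finite(centroids)))
    stop("centroids contain non-finite values", call. = FALSE)
  if (ncol(features) != ncol(centroids))
    stop("feature dimension does not match centroid dimension", call. = FALSE)
  d2 <- outer(rowSums(features^2), rowSums(centroids^2), "+") -
    2 * tcrossprod(features, centroids)
  max.col(-d2, ties.method = "first") - 1L
}

#' Update the global centroid memory
#'
#' Applies the damped update `M_k <- (1 - eta_k) M_k + eta_k c_k` with
#' `eta_k = exp(-t_k)`, where `t_k` is the stored count of class-k
#' pseudo-labels from the previous batch. At `t_k = 0` the memory is fully
#' replaced by the local centroid; `M_k = c_k` is a fixed point for any
#' `t_k`. Classes flagged invalid (empty in this batch) are skipped. The
#' stored counts are then replaced by `batch_class_counts`.
#'
#' @param state a [centroid_state()].
#' @param local_centroids N_c x d_f matrix of batch-local centroids.
#' @param batch_class_counts integer N_c vector: pseudo-label counts of the
#'   current batch (becomes the next update's `t_k`).
#' @param valid logical N_c; `FALSE` rows are left untouched.
#' @return The updated `centroid_state`.
#' @export
update_memory <- function(state, local_centroids, batch_class_counts,
                          valid = rep(TRUE, state$n_classes)) {
  stopifnot(inherits(state, "centroid_state"))
  local_centroids <- as.matrix(local_centroids)
  if (any(batch_class_counts < 0))
    stop("negative class counts", call. = FALSE)
  if (!identical(dim(local_centroids), dim(state$memory)))
    stop("local centroids and memory have different shapes", call. = FALSE)
  eta <- exp(-as.numeric(state$counts))
  upd <- valid & is.finite(rowSums(local_centroids))
  state$memory[upd, ] <- (1 - eta[upd]) * state$memory[upd, , drop = FALSE] +
    eta[upd] * local_centroids[upd, , drop = FALSE]
  if (any(!is.finite(state$memory)))
    stop("centroid memory became non-finite", call. = FALSE)
  state$seen <- state$seen | upd
  state$counts <- as.integer(batch_class_counts)
  state
}

#' Confidence-thresholded pseudo-labels (clustering-free baseline)
#'
#' The ablation baseline that replaces the weight clustering unit: each
#' sample is pseudo-labelled by its softmax argmax, and only samples whose
#' top probability reaches `threshold` are kept.
#'
#' @param probs n x N_c matrix of probability rows.
#' @param threshold confidence threshold in (0, 1).
#' @return A list: `labels` (integer, 0-based) and `keep` (logical mask).
#' @export
confidence_pseudolabels <- function(probs, threshold = 0.95) {
  if (threshold <= 0 || threshold >= 1)
    .stop_field("threshold", "must lie strictly inside (0, 1)")
  probs <- as.matrix(probs)
  top <- apply(probs, 1, max)
  list(labels = max.col(probs, ties.method = "first") - 1L,
       keep = top >= threshold)
}
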