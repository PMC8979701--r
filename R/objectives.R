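#' The four training losses and their balanced combination
#'
#' Training minimises `L = L_lce + gamma1 * L_ac + gamma2 * L_gc +
#' gamma3 * L_pce` over the network parameters:
#' \describe{
#'   \item{`lce_loss`}{labeled cross-entropy over the labeled images and
#'     their weak augmentations.}
#'   \item{`ac_loss`}{augmentation consistency: the mean (squared-Euclidean
#'     by default) distance between the probability vector of each raw
#'     unlabeled image and those of its strong augmentations.}
#'   \item{`gc_loss`}{global consistency: mean squared distance between the
#'     batch-local centroids and the global memory centroids.}
#'   \item{`pce_loss`}{pseudo-label cross-entropy over the unlabeled images
#'     and their strong augmentations, against nearest-centroid
#'     pseudo-labels treated as constants.}
#' }
#' All set-valued sums are implemented as means over samples, so the
#' default balance weights `(0.6, 0.3, 0.8)` keep their meaning across
#' batch sizes. Cross-entropies are computed from log-softmax outputs.
#'
#' @param log_probs n x N_c matrix of row-wise log-probabilities.
#' @param labels integer vector of 0-based class labels.
#' @return A single non-negative number.
#' @name objectives
NULL

ce_mean <- function(log_probs, labels, what) {
  log_probs <- as.matrix(log_probs)
  labels <- as.integer(labels)
  if (length(labels) != nrow(log_probs))
    stop(what, ": one label per row required", call. = FALSE)
  if (length(labels) == 0) return(0)
  if (any(labels < 0 | labels >= ncol(log_probs)))
    stop(what, ": label out of range [0, N_c)", call. = FALSE)
  -mean(log_probs[cbind(seq_along(labels), labels + 1L)])
}

#' @rdname objectives
#' @export
lce_loss <- function(log_probs, labels) ce_mean(log_probs, labels, "lce_loss")

#' @rdname objectives
#' @param probs_raw m x N_c probability rows of the raw (anchor) images.
#' @param probs_aug (m*K) x N_c probability rows of the augmented views.
#' @param pairing integer vector, one entry per augmented row, giving the
#'   index of its source row in `probs_raw`.
#' @param norm `"sql2"` (squared Euclidean, default) or `"l1"`.
#' @export
ac_loss <- function(probs_raw, probs_aug, pairing, norm = c("sql2", "l1")) {
  norm <- match.arg(norm)
  probs_raw <- as.matrix(probs_raw)
  probs_aug <- as.matrix(probs_aug)
  pairing <- as.integer(pairing)
  if (length(pairing) != nrow(probs_aug))
    stop("ac_loss: every augmented row needs a pairing to its raw row", call. = FALSE)
  if (nrow(probs_aug) == 0) return(0)
  if (any(pairing < 1 | pairing > nrow(probs_raw)))
    stop("ac_loss: pairing index out of range", call. = FALSE)
  diff <- probs_aug - probs_raw[pairing, , drop = FALSE]
  if (norm == "sql2") mean(rowSums(diff^2)) else mean(rowSums(abs(diff)))
}

#' @rdname objectives
#' @param memory,local_centroids N_c x d_f matrices.
#' @param valid logical N_c mask; invalid (empty) classes are excluded from
#'   the mean.
#' @export
gc_loss <- function(memory, local_centroids, valid = rep(TRUE, nrow(memory))) {
  memory <- as.matrix(memory)
  local_centroids <- as.matrix(local_centroids)
  if (!identical(dim(memory), dim(local_centroids)))
    stop("gc_loss: memory and local centroids have different shapes", call. = FALSE)
  if (!any(valid)) {
    warning("gc_loss: all classes masked; returning 0")
    return(0)
  }
  mean(rowSums((memory[valid, , drop = FALSE] -
                local_centroids[valid, , drop = FALSE])^2))
}

#' @rdname objectives
#' @param pseudolabels integer vector of 0-based pseudo-labels (constant
#'   targets; no gradient flows through them).
#' @export
pce_loss <- function(log_probs, pseudolabels) ce_mean(log_probs, pseudolabels, "pce_loss")

#' @rdname objectives
#' @param l_lce,l_ac,l_gc,l_pce the four loss values.
#' @param gammas numeric length 3, the balance weights `(gamma1, gamma2,
#'   gamma3)` for the ac/gc/pce terms; defaults `c(0.6, 0.3, 0.8)`.
#' @return `total_loss()` returns a `loss_bundle`: the four terms, the
#'   weights, and `total = l_lce + gamma1*l_ac + gamma2*l_gc + gamma3*l_pce`.
#' @export
total_loss <- function(l_lce, l_ac = 0, l_gc = 0, l_pce = 0,
                       gammas = c(0.6, 0.3, 0.8)) {
  if (length(gammas) != 3 || any(gammas < 0))
    .stop_field("gammas", "need three non-negative balance weights")
  structure(list(l_lce = l_lce, l_ac = l_ac, l_gc = l_gc, l_pce = l_pce,
                 gammas = as.numeric(gammas),
                 total = l_lce + gammas[1] * l_ac + gammas[2] * l_gc +
                   gammas[3] * l_pce),
            class = "loss_bundle")
}

#' @export
print.loss_bundle <- function(x, ...) {
  cat(sprintf("<loss_bundle: total=%.5f (lce=%.5f, ac=%.5f, gc=%.5f, pce=%.5f; gammas=%s)>\n",
              x$total, x$l_lce, x$l_ac, x$l_gc, x$l_pce,
              paste(x$gammas, collapse = "/")))
  invisible(x)
}

# ---- analytic gradients (w.r.t. logits / features), used by the trainer ----

# d(mean CE)/d(logits): (softmax - onehot) / n, rows without labels get 0.
grad_ce_logits <- function(logits, labels, denom = length(labels)) {
  p <- softmax_rows(logits)
  if (length(labels)) {
    idx <- cbind(seq_along(labels), as.integer(labels) + 1L)
    p[idx] <- p[idx] - 1
  }
  p / max(denom, 1)
}

# d(mean ||P_aug - P_raw||^2)/d(logits_aug), anchors constant.
grad_ac_logits_aug <- function(probs_raw, probs_aug, logits_aug, pairing) {
  n <- nrow(probs_aug)
  gP <- 2 * (probs_aug - probs_raw[pairing, , drop = FALSE]) / n
  # softmax Jacobian: dz = p * (g - sum(g * p))
  probs_aug * (gP - rowSums(gP * probs_aug))
}

# d(gc)/d(features): weights delta_k treated as constants, memory constant.
grad_gc_features <- function(features, probs, centroids, memory, valid) {
  n_valid <- sum(valid)
  if (n_valid == 0) return(matrix(0, nrow(features), ncol(features)))
  g <- matrix(0, nrow(features), ncol(features))
  w_tot <- colSums(probs)
  for (k in which(valid)) {
    dck <- 2 * (centroids[k, ] - memory[k, ]) / n_valid
    g <- g + (probs[, k] / w_tot[k]) %o% dck
  }
  g
}
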