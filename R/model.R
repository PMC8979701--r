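#' Compact convolutional classifier: feature extractor G + linear head F
#'
#' The model is the composition of a convolutional feature extractor `G`
#' (3x3 conv blocks, each conv -> batch norm -> ReLU -> 2x2 average
#' pooling, ending in global average pooling) and a single linear
#' classifier `F`, so the class prediction for an image `x` is
#' `P(x) = softmax(F(G(x)))`. Inputs are centred (0.5 is subtracted from
#' the [0,1] intensities) on the way in. The interface is
#' backbone-agnostic: the training loop only ever calls the
#' forward/backward contract, so any channel configuration runs unchanged.
#' Two presets are provided: `"tiny"` (3 blocks, feature dimension 64, for
#' 32x32 test images) and `"wide"` (4 blocks, feature dimension 256, for
#' larger inputs).
#'
#' Backprop is exact: convolutions use a compiled im2col + GEMM kernel and
#' its adjoint; batch-norm gradients use the full batch-statistics
#' Jacobian. Batch statistics are used in training mode only — inference
#' uses running averages, so inference is deterministic and duplicated
#' inputs always map to identical features.
#'
#' @param n_classes number of classes `N_c` (>= 2).
#' @param input_size image side in pixels; must be divisible by
#'   `2^length(channels)`.
#' @param in_channels number of image channels.
#' @param backbone `"tiny"`, `"wide"`, or an integer vector of per-block
#'   channel counts (the last entry is the feature dimension `d_f`).
#' @param normalize_features L2-normalise `G(x)` before the classifier and
#'   the clustering unit (off by default; centroids are formed on raw
#'   features).
#' @param seed integer seed for weight initialisation.
#' @return An object of class `accn_network`.
#' @examples
#' net <- accn_network(n_classes = 2, input_size = 32, seed = 1)
#' x <- array(runif(32 * 32 * 1 * 4), dim = c(32, 32, 1, 4))
#' p <- predict_probs(x, net)
#' rowSums(p)  # all 1
#' @export
accn_network <- function(n_classes, input_size = 32, in_channels = 1,
                         backbone = "tiny", normalize_features = FALSE,
                         seed = 1) {
  if (!is.numeric(n_classes) || n_classes < 2)
    .stop_field("n_classes", "need at least 2 classes")
  channels <- if (is.character(backbone)) {
    switch(match.arg(backbone, c("tiny", "wide")),
           tiny = c(4L, 8L, 64L),
           wide = c(32L, 64L, 128L, 256L))
  } else as.integer(backbone)
  if (any(channels < 1)) .stop_field("backbone", "channel counts must be positive")
  nb <- length(channels)
  if (input_size %% (2^nb) != 0)
    .stop_field("input_size", sprintf("must be divisible by 2^%d for %d conv blocks", nb, nb))

  stream <- rng_stream(fork_seed(seed, "init"))
  params <- list()
  bn_stats <- vector("list", nb)
  cin <- in_channels
  for (i in seq_len(nb)) {
    fan_in <- 9 * cin
    params[[paste0("conv", i, "_W")]] <-
      matrix(r_norm(stream, fan_in * channels[i], sd = sqrt(2 / fan_in)),
             nrow = fan_in, ncol = channels[i])
    params[[paste0("bn", i, "_gamma")]] <- rep(1, channels[i])
    params[[paste0("bn", i, "_beta")]] <- numeric(channels[i])
    bn_stats[[i]] <- list(mean = numeric(channels[i]), var = rep(1, channels[i]))
    cin <- channels[i]
  }
  d_f <- channels[nb]
  params$fc_W <- matrix(r_norm(stream, d_f * n_classes, sd = sqrt(1 / d_f)),
                        nrow = d_f, ncol = n_classes)
  params$fc_b <- numeric(n_classes)

  structure(list(
    params = params,
    bn_stats = bn_stats,
    config = list(n_classes = as.integer(n_classes),
                  input_size = as.integer(input_size),
                  in_channels = as.integer(in_channels),
                  channels = channels, d_f = d_f,
                  normalize_features = isTRUE(normalize_features),
                  backbone = if (is.character(backbone)) backbone else "custom",
                  seed = as.integer(seed))
  ), class = "accn_network")
}

#' @export
print.accn_network <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("<accn_network '%s': %dx%dx%d -> d_f=%d -> %d classes; %d conv blocks>\n",
              cfg$backbone, cfg$input_size, cfg$input_size, cfg$in_channels,
              cfg$d_f, cfg$n_classes, length(cfg$channels)))
  invisible(x)
}

check_input_dims <- function(net, x) {
  d <- dim(x)
  cfg <- net$config
  want <- c(cfg$input_size, cfg$input_size, cfg$in_channels)
  if (!identical(as.integer(d[1:3]), as.integer(want)))
    stop(sprintf("input dimensions %s do not match network's expected %s",
                 paste(d[1:3], collapse = "x"), paste(want, collapse = "x")),
         call. = FALSE)
  invisible(NULL)
}

# Full forward pass. `train = TRUE` uses batch statistics in the norm
# layers (and returns updated running stats); inference mode uses running
# averages. Returns features (N x d_f), logits (N x N_c) and, when
# keep_cache, everything backward() needs.
network_forward <- function(net, x, keep_cache = FALSE, train = FALSE) {
  x <- as_image_batch(x)
  check_input_dims(net, x)
  p <- net$params
  nb <- length(net$config$channels)
  N <- dim(x)[4]
  H <- dim(x)[1]; W <- dim(x)[2]
  h <- to_pixel_major(x) - 0.5
  caches <- if (keep_cache) vector("list", nb) else NULL
  bn_stats <- net$bn_stats
  for (i in seq_len(nb)) {
    co <- net$config$channels[i]
    cv <- conv_pm_forward(h, H, W, N, p[[paste0("conv", i, "_W")]], numeric(co))
    bn <- bn_forward(cv$pre, p[[paste0("bn", i, "_gamma")]],
                     p[[paste0("bn", i, "_beta")]], bn_stats[[i]], train)
    bn_stats[[i]] <- bn$stats
    mask <- bn$out > 0
    act <- bn$out * mask
    pl <- avgpool_pm_forward(act, H, W, N)
    if (keep_cache)
      caches[[i]] <- list(conv = cv, bn = bn[c("xhat", "inv")], mask = mask,
                          pool = pl[c("H", "W", "N")])
    h <- pl$out
    H <- H %/% 2L; W <- W %/% 2L
  }
  gp <- gap_forward_pm(h, N)
  feats <- gp$out
  norms <- NULL
  if (net$config$normalize_features) {
    norms <- sqrt(rowSums(feats^2)) + 1e-12
    feats <- feats / norms
  }
  lin <- linear_forward(feats, p$fc_W, p$fc_b)
  list(features = feats, logits = lin$out, bn_stats = bn_stats,
       cache = if (keep_cache) list(blocks = caches, gap = gp[c("hw", "N")],
                                    lin = lin, norms = norms) else NULL)
}

# Backward pass: dlogits (N x N_c) and/or an extra gradient on the features
# (N x d_f, e.g. from the centroid-consistency loss). Returns a grads list
# aligned with net$params.
network_backward <- function(net, cache, dlogits = NULL, dfeatures = NULL) {
  p <- net$params
  grads <- list()
  n <- nrow(cache$lin$f)
  dfeat <- if (is.null(dfeatures)) matrix(0, n, net$config$d_f) else dfeatures
  if (!is.null(dlogits)) {
    lb <- linear_backward(dlogits, cache$lin, p$fc_W)
    grads$fc_W <- lb$dW
    grads$fc_b <- lb$db
    dfeat <- dfeat + lb$df
  } else {
    grads$fc_W <- matrix(0, nrow(p$fc_W), ncol(p$fc_W))
    grads$fc_b <- numeric(length(p$fc_b))
  }
  if (net$config$normalize_features) {
    # f = g / ||g||: d/dg = (I - f f^T) / ||g||, applied row-wise
    f <- cache$lin$f
    dot <- rowSums(dfeat * f)
    dfeat <- (dfeat - f * dot) / cache$norms
  }
  dh <- gap_backward_pm(dfeat, cache$gap)
  nb <- length(net$config$channels)
  for (i in rev(seq_len(nb))) {
    blk <- cache$blocks[[i]]
    dact <- avgpool_pm_backward(dh, blk$pool)
    dbn_out <- dact * blk$mask
    bb <- bn_backward(dbn_out, blk$bn, p[[paste0("bn", i, "_gamma")]])
    grads[[paste0("bn", i, "_gamma")]] <- bb$dgamma
    grads[[paste0("bn", i, "_beta")]] <- bb$dbeta
    cb <- conv_pm_backward(bb$dx, blk$conv, p[[paste0("conv", i, "_W")]])
    grads[[paste0("conv", i, "_W")]] <- cb$dW
    dh <- cb$dx
  }
  grads
}

#' Extract feature vectors G(x) for a batch of images
#'
#' Runs in inference mode (running batch-norm statistics), so outputs are
#' deterministic.
#'
#' @param images an (H, W, C, N) array, a single image, or a list of images.
#' @param net an [accn_network()].
#' @return An N x d_f numeric matrix, one row per image.
#' @export
extract_features <- function(images, net) {
  network_forward(net, images)$features
}

#' Class-probability predictions P(x) = softmax(F(G(x)))
#'
#' @inheritParams extract_features
#' @return An N x N_c matrix; each row is a probability vector.
#' @export
predict_probs <- function(images, net) {
  softmax_rows(network_forward(net, images)$logits)
}

#' @export
predict.accn_network <- function(object, images,
                                 type = c("prob", "class", "feature"), ...) {
  type <- match.arg(type)
  fw <- network_forward(object, images)
  switch(type,
         prob = softmax_rows(fw$logits),
         class = max.col(fw$logits, ties.method = "first") - 1L,
         feature = fw$features)
}

#' Save / load a training checkpoint
#'
#' A checkpoint bundles the network weights, normalisation statistics and
#' configuration, the centroid memory state, the optimiser state, the
#' random-stream states, the epoch counter and the training history, so a
#' run can resume exactly where it stopped.
#'
#' @param fit an `accn_fit` object (from [accn_train()]) or a list with at
#'   least `network`.
#' @param path file path.
#' @return `load_checkpoint()` returns the restored object.
#' @export
save_checkpoint <- function(fit, path) {
  saveRDS(fit, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  readRDS(path)
}
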