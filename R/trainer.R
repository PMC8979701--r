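#' Training configuration
#'
#' Collects every knob of the semi-supervised training loop. Defaults follow
#' the reference recipe: batch size 8 for both the labeled and unlabeled
#' sub-batch, learning rate 0.001, Adam, balance weights
#' `gammas = (0.6, 0.3, 0.8)` for the consistency / centroid / pseudo-label
#' terms, one supervised warm-up epoch before the clustering unit switches
#' on, and nearest-centroid assignment against the memory-smoothed
#' centroids.
#'
#' @param epochs training epochs (an epoch is one pass over the unlabeled
#'   pool, or over the labeled set when no unlabeled data are given).
#' @param batch_size per-stream batch size (>= 2).
#' @param learning_rate optimiser step size (> 0).
#' @param optimizer `"adam"` or `"sgd"` (with momentum).
#' @param momentum SGD momentum (ignored by Adam).
#' @param gammas numeric length 3: weights of the ac/gc/pce losses.
#' @param policy an [augmentation_policy()].
#' @param backbone passed to [accn_network()].
#' @param warmup_epochs supervised epochs before the pseudo-label (pce) and
#'   centroid-consistency (gc) losses activate.
#' @param assign_to `"memory"` (default): pseudo-labels are assigned against
#'   the memory-smoothed centroids after the batch update; `"local"`: against
#'   the raw batch centroids.
#' @param ac_norm `"sql2"` or `"l1"` distance for the consistency loss.
#' @param ac_stopgrad treat anchor predictions as constants in the
#'   consistency loss (default TRUE).
#' @param weak_unlabeled also weakly augment the unlabeled anchor view
#'   (default FALSE: the raw image is the anchor).
#' @param epoch_refresh refresh pseudo-labels over the full unlabeled pool
#'   at each epoch end (default TRUE).
#' @param disable_acl ablation: drop strong augmentation and the ac loss;
#'   pseudo-label training uses raw images only.
#' @param disable_wcu ablation: replace the clustering unit by
#'   confidence-thresholded argmax pseudo-labels and drop the gc loss.
#' @param confidence_threshold threshold for the `disable_wcu` baseline.
#' @param n_classes number of classes; `NULL` infers from the labels.
#' @param seed root seed; fans out to initialisation, batching and
#'   augmentation streams.
#' @return An object of class `train_config`.
#' @export
train_config <- function(epochs = 30, batch_size = 8, learning_rate = 0.001,
                         optimizer = c("adam", "sgd"), momentum = 0.9,
                         gammas = c(0.6, 0.3, 0.8),
                         policy = augmentation_policy(),
                         backbone = "tiny", warmup_epochs = 1,
                         assign_to = c("memory", "local"),
                         ac_norm = c("sql2", "l1"), ac_stopgrad = TRUE,
                         weak_unlabeled = FALSE, epoch_refresh = TRUE,
                         disable_acl = FALSE, disable_wcu = FALSE,
                         confidence_threshold = 0.95,
                         n_classes = NULL, seed = 1) {
  if (batch_size < 2) .stop_field("batch_size", "must be >= 2")
  if (learning_rate <= 0) .stop_field("learning_rate", "must be > 0")
  if (epochs < 1) .stop_field("epochs", "must be >= 1")
  if (length(gammas) != 3 || any(gammas < 0))
    .stop_field("gammas", "need three non-negative weights")
  stopifnot(inherits(policy, "augmentation_policy"))
  structure(list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 optimizer = match.arg(optimizer), momentum = momentum,
                 gammas = as.numeric(gammas), policy = policy,
                 backbone = backbone, warmup_epochs = as.integer(warmup_epochs),
                 assign_to = match.arg(assign_to),
                 ac_norm = match.arg(ac_norm), ac_stopgrad = isTRUE(ac_stopgrad),
                 weak_unlabeled = isTRUE(weak_unlabeled),
                 epoch_refresh = isTRUE(epoch_refresh),
                 disable_acl = isTRUE(disable_acl),
                 disable_wcu = isTRUE(disable_wcu),
                 confidence_threshold = confidence_threshold,
                 n_classes = n_classes, seed = as.integer(seed)),
            class = "train_config")
}

# ---- optimiser -------------------------------------------------------------

optim_init <- function(params, config) {
  zeros <- lapply(params, function(p) p * 0)
  list(m = zeros, v = zeros, t = 0L, config = config)
}

optim_step <- function(params, grads, opt) {
  lr <- opt$config$learning_rate
  if (opt$config$optimizer == "adam") {
    b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
    opt$t <- opt$t + 1L
    for (nm in names(params)) {
      opt$m[[nm]] <- b1 * opt$m[[nm]] + (1 - b1) * grads[[nm]]
      opt$v[[nm]] <- b2 * opt$v[[nm]] + (1 - b2) * grads[[nm]]^2
      mhat <- opt$m[[nm]] / (1 - b1^opt$t)
      vhat <- opt$v[[nm]] / (1 - b2^opt$t)
      params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
    }
  } else {
    for (nm in names(params)) {
      opt$m[[nm]] <- opt$config$momentum * opt$m[[nm]] + grads[[nm]]
      params[[nm]] <- params[[nm]] - lr * opt$m[[nm]]
    }
  }
  list(params = params, opt = opt)
}

add_grads <- function(a, b) {
  for (nm in names(b)) a[[nm]] <- if (is.null(a[[nm]])) b[[nm]] else a[[nm]] + b[[nm]]
  a
}

# ---- batch cycling ---------------------------------------------------------

new_cycler <- function(n) {
  e <- new.env(parent = emptyenv())
  e$n <- n; e$order <- integer(0); e$pos <- 0L
  e
}

next_batch <- function(cyc, b, stream) {
  out <- integer(0)
  while (length(out) < b) {
    if (cyc$pos >= length(cyc$order)) {
      cyc$order <- r_sample(stream, seq_len(cyc$n))
      cyc$pos <- 0L
    }
    take <- min(b - length(out), length(cyc$order) - cyc$pos)
    out <- c(out, cyc$order[cyc$pos + seq_len(take)])
    cyc$pos <- cyc$pos + take
  }
  out
}

# probs -> dlogits through the row-wise softmax Jacobian
softmax_vjp <- function(probs, gP) probs * (gP - rowSums(gP * probs))

augment_batch_weak <- function(x, idx, policy, stream) {
  views <- lapply(idx, function(i) weak_augment(x[, , , i, drop = TRUE], policy, stream))
  as_image_batch(views)
}

history_tibble <- function(rows, old = NULL) {
  m <- do.call(rbind, rows)
  tb <- tibble::tibble(epoch = as.integer(m[, 1]), step = as.integer(m[, 2]),
                       l_lce = m[, 3], l_ac = m[, 4], l_gc = m[, 5],
                       l_pce = m[, 6], total = m[, 7])
  if (is.null(old)) tb else rbind(old, tb)
}

#' Train an augmentation-consistent clustering network
#'
#' Runs the full semi-supervised loop: each step draws a labeled and an
#' unlabeled sub-batch, forms weak views of the labeled images and K strong
#' views of each unlabeled image, computes the labeled cross-entropy and
#' augmentation-consistency losses, runs the weight clustering unit
#' (soft-weighted batch centroids, damped global-memory update,
#' nearest-centroid pseudo-labels), adds the centroid-consistency and
#' pseudo-label cross-entropy terms, and takes one optimiser step on the
#' combined objective. With an empty unlabeled set the loop degenerates
#' exactly to supervised cross-entropy training.
#'
#' @param labeled list with `x` (an (H,W,C,N) array, intensities in [0,1])
#'   and `y` (integer 0-based labels); every class must appear at least
#'   once.
#' @param unlabeled optional list with `x`; may be `NULL` or empty.
#' @param config a [train_config()].
#' @param eval_data optional list with `x` and `y`: evaluated at every epoch
#'   end (accuracy, sensitivity, specificity, AUC for binary problems).
#' @param truth optional integer vector of hidden true labels for the
#'   unlabeled pool, used only to monitor pseudo-label accuracy.
#' @param resume an `accn_fit` from a previous call: continues training
#'   from its exact internal state for `config$epochs` additional epochs.
#' @return An object of class `accn_fit`: the trained `network`, the
#'   centroid `state`, per-step `history` and per-epoch `epoch_metrics`
#'   tibbles, final pool `pseudo_labels`, and the resolved `config`.
#' @seealso [supervised_baseline()], [run_ablation()], [evaluate_model()]
#' @export
accn_train <- function(labeled, unlabeled = NULL, config = train_config(),
                       eval_data = NULL, truth = NULL, resume = NULL) {
  stopifnot(inherits(config, "train_config"))
  if (is.null(labeled) || length(labeled$y) == 0)
    stop("training requires at least one labeled sample", call. = FALSE)
  x_l <- as_image_batch(labeled$x)
  y_l <- as.integer(labeled$y)
  nc <- config$n_classes %||% (max(y_l) + 1L)
  if (!all((seq_len(nc) - 1L) %in% y_l))
    stop("every class must have at least one labeled sample", call. = FALSE)
  has_unl <- !is.null(unlabeled) && !is.null(unlabeled$x) &&
    batch_size_of(as_image_batch(unlabeled$x)) > 0
  x_u <- if (has_unl) as_image_batch(unlabeled$x) else NULL
  n_l <- batch_size_of(x_l)
  n_u <- if (has_unl) batch_size_of(x_u) else 0L
  B <- config$batch_size
  pol <- config$policy
  g <- config$gammas

  if (is.null(resume)) {
    net <- accn_network(nc, input_size = dim(x_l)[1], in_channels = dim(x_l)[3],
                        backbone = config$backbone, seed = config$seed)
    state <- centroid_state(nc, net$config$d_f)
    opt <- optim_init(net$params, config)
    batch_stream <- rng_stream(fork_seed(config$seed, "batch"))
    aug_stream <- rng_stream(fork_seed(config$seed, "augment"))
    lab_cyc <- new_cycler(n_l)
    unl_cyc <- if (has_unl) new_cycler(n_u) else NULL
    history <- list()
    old_history <- NULL
    epoch_metrics <- list()
    epoch0 <- 0L
    memory_ready <- FALSE
  } else {
    stopifnot(inherits(resume, "accn_fit"))
    net <- resume$network
    state <- resume$state
    it <- resume$internal
    opt <- it$opt; batch_stream <- it$batch_stream; aug_stream <- it$aug_stream
    lab_cyc <- it$lab_cyc; unl_cyc <- it$unl_cyc
    history <- list()
    old_history <- resume$history
    epoch_metrics <- list(resume$epoch_metrics)
    epoch0 <- it$epoch
    memory_ready <- it$memory_ready
  }

  steps <- if (has_unl) ceiling(n_u / B) else ceiling(n_l / B)
  clustering_on <- function(ep) has_unl && ep > config$warmup_epochs
  plab_pool <- NULL

  for (ep in (epoch0 + 1L):(epoch0 + config$epochs)) {
    if (clustering_on(ep) && !config$disable_wcu && !memory_ready) {
      # seed the memory with per-class means of labeled features: the
      # supervised warm-up model plays the role of the pretrained baseline
      f_l <- extract_features(x_l, net)
      for (k in seq_len(nc))
        state$memory[k, ] <- colMeans(f_l[y_l == (k - 1L), , drop = FALSE])
      state$counts <- integer(nc)
      state$seen <- rep(TRUE, nc)
      memory_ready <- TRUE
    }
    for (st in seq_len(steps)) {
      lab_idx <- next_batch(lab_cyc, B, batch_stream)
      if (has_unl) unl_idx <- next_batch(unl_cyc, B, batch_stream)

      # --- labeled stream: raw + weak views, cross-entropy ---
      weak_l <- augment_batch_weak(x_l, lab_idx, pol, aug_stream)
      xb_l <- array(c(batch_subset(x_l, lab_idx), weak_l),
                    dim = c(dim(weak_l)[1:3], 2L * B))
      yb_l <- rep(y_l[lab_idx], 2L)
      fw_l <- network_forward(net, xb_l, keep_cache = TRUE, train = TRUE)
      net$bn_stats <- fw_l$bn_stats
      l_lce <- lce_loss(log_softmax_rows(fw_l$logits), yb_l)
      dlog_l <- grad_ce_logits(fw_l$logits, yb_l)

      l_ac <- 0; l_gc <- 0; l_pce <- 0
      grads <- network_backward(net, fw_l$cache, dlogits = dlog_l)

      if (has_unl) {
        xb_u <- batch_subset(x_u, unl_idx)
        if (config$weak_unlabeled)
          xb_u <- augment_batch_weak(x_u, unl_idx, pol, aug_stream)
        strong <- NULL; pairing <- integer(0)
        if (!config$disable_acl) {
          views <- lapply(seq_len(B), function(i)
            strong_augment(xb_u[, , , i, drop = TRUE], pol, aug_stream))
          strong <- as_image_batch(unlist(views, recursive = FALSE))
          pairing <- rep(seq_len(B), each = pol$K)
        }
        fw_u <- network_forward(net, xb_u, keep_cache = TRUE, train = TRUE)
        net$bn_stats <- fw_u$bn_stats
        # anchor predictions and clustering decisions use inference-mode
        # statistics so pseudo-labels are not polluted by batch-stat noise;
        # gradients flow through the training-mode pass above
        inf_u <- network_forward(net, xb_u)
        probs_u <- softmax_rows(inf_u$logits)
        fw_s <- NULL; probs_s <- NULL
        dlog_u <- matrix(0, B, nc)
        dlog_s <- NULL

        if (!is.null(strong)) {
          fw_s <- network_forward(net, strong, keep_cache = TRUE, train = TRUE)
          net$bn_stats <- fw_s$bn_stats
          probs_s <- softmax_rows(fw_s$logits)
          l_ac <- ac_loss(probs_u, probs_s, pairing, norm = config$ac_norm)
          np <- nrow(probs_s)
          diff <- probs_s - probs_u[pairing, , drop = FALSE]
          gP_s <- if (config$ac_norm == "sql2") 2 * diff / np else sign(diff) / np
          dlog_s <- g[1] * softmax_vjp(probs_s, gP_s)
          if (!config$ac_stopgrad) {
            gP_u <- -rowsum(gP_s, pairing)
            probs_u_tr <- softmax_rows(fw_u$logits)
            dlog_u <- dlog_u + g[1] * softmax_vjp(probs_u_tr, as.matrix(gP_u))
          }
        }

        dfeat_u <- NULL
        if (clustering_on(ep)) {
          if (!config$disable_wcu) {
            sw <- soft_weighted_centroids(fw_u$features, probs_u,
                                          memory = state$memory)
            l_gc <- gc_loss(state$memory, sw$centroids, sw$valid)
            dfeat_u <- g[2] * grad_gc_features(fw_u$features, probs_u,
                                               sw$centroids, state$memory, sw$valid)
            state <- update_memory(state, sw$centroids, integer(nc), sw$valid)
            ref <- if (config$assign_to == "memory") state$memory else sw$centroids
            plab <- assign_pseudolabels(inf_u$features, ref)
            state$counts <- tabulate(plab + 1L, nbins = nc)
            keep <- rep(TRUE, B)
          } else {
            cp <- confidence_pseudolabels(probs_u, config$confidence_threshold)
            plab <- cp$labels
            keep <- cp$keep
          }
          rows_u <- which(keep)
          rows_s <- if (length(pairing)) which(keep[pairing]) else integer(0)
          n_pce <- length(rows_u) + length(rows_s)
          if (n_pce > 0) {
            log_u <- log_softmax_rows(fw_u$logits)
            lp_terms <- -log_u[cbind(rows_u, plab[rows_u] + 1L)]
            d_u <- grad_ce_logits(fw_u$logits[rows_u, , drop = FALSE],
                                  plab[rows_u], denom = n_pce)
            dlog_u[rows_u, ] <- dlog_u[rows_u, ] + g[3] * d_u
            if (length(rows_s)) {
              log_s <- log_softmax_rows(fw_s$logits)
              lp_terms <- c(lp_terms, -log_s[cbind(rows_s, plab[pairing[rows_s]] + 1L)])
              d_s <- grad_ce_logits(fw_s$logits[rows_s, , drop = FALSE],
                                    plab[pairing[rows_s]], denom = n_pce)
              dlog_s[rows_s, ] <- dlog_s[rows_s, ] + g[3] * d_s
            }
            l_pce <- sum(lp_terms) / n_pce
          }
        }

        grads <- add_grads(grads, network_backward(net, fw_u$cache,
                                                   dlogits = dlog_u,
                                                   dfeatures = dfeat_u))
        if (!is.null(fw_s))
          grads <- add_grads(grads, network_backward(net, fw_s$cache,
                                                     dlogits = dlog_s))
      }

      bundle <- total_loss(l_lce, l_ac, l_gc, l_pce, gammas = g)
      if (!is.finite(bundle$total))
        stop(sprintf("non-finite loss at epoch %d step %d (lce=%g ac=%g gc=%g pce=%g)",
                     ep, st, l_lce, l_ac, l_gc, l_pce), call. = FALSE)
      res <- optim_step(net$params, grads, opt)
      net$params <- res$params
      opt <- res$opt
      history[[length(history) + 1L]] <-
        c(ep, st, l_lce, l_ac, l_gc, l_pce, bundle$total)
    }

    # --- epoch end: pool-level pseudo-label refresh + held-out metrics ---
    pseudo_acc <- NA_real_
    if (clustering_on(ep) && !config$disable_wcu && config$epoch_refresh) {
      f_pool <- predict_in_chunks(net, x_u, what = "feature")
      plab_pool <- assign_pseudolabels(f_pool, state$memory)
      if (!is.null(truth)) pseudo_acc <- mean(plab_pool == truth)
    }
    em <- tibble::tibble(epoch = ep, acc = NA_real_, sen = NA_real_,
                         spe = NA_real_, auc = NA_real_, pseudo_acc = pseudo_acc)
    if (!is.null(eval_data)) {
      ev <- evaluate_model(net, eval_data$x, eval_data$y)
      em$acc <- ev$acc; em$sen <- ev$sen; em$spe <- ev$spe; em$auc <- ev$auc
    }
    epoch_metrics[[length(epoch_metrics) + 1L]] <- em
  }

  history <- history_tibble(history, old_history)
  epoch_metrics <- do.call(rbind, epoch_metrics)
  best_epoch <- if (any(!is.na(epoch_metrics$acc)))
    epoch_metrics$epoch[which.max(epoch_metrics$acc)] else NA_integer_

  structure(list(network = net, state = state, history = history,
                 epoch_metrics = epoch_metrics,
                 pseudo_labels = plab_pool,
                 best_epoch = best_epoch, n_classes = nc, config = config,
                 internal = list(opt = opt, batch_stream = batch_stream,
                                 aug_stream = aug_stream, lab_cyc = lab_cyc,
                                 unl_cyc = unl_cyc, epoch = epoch0 + config$epochs,
                                 memory_ready = memory_ready)),
            class = "accn_fit")
}

#' @export
print.accn_fit <- function(x, ...) {
  last <- x$history[nrow(x$history), ]
  cat(sprintf("<accn_fit: %d classes, %d epochs, final total loss %.4f>\n",
              x$n_classes, max(x$history$epoch), last$total))
  if (any(!is.na(x$epoch_metrics$acc)))
    cat(sprintf("  final held-out accuracy %.3f (best epoch %d)\n",
                x$epoch_metrics$acc[nrow(x$epoch_metrics)], x$best_epoch))
  invisible(x)
}

predict_in_chunks <- function(net, x, what = c("prob", "feature"), chunk = 128L) {
  what <- match.arg(what)
  n <- batch_size_of(x)
  out <- vector("list", ceiling(n / chunk))
  for (i in seq_along(out)) {
    idx <- ((i - 1L) * chunk + 1L):min(i * chunk, n)
    fw <- network_forward(net, batch_subset(x, idx))
    out[[i]] <- if (what == "prob") softmax_rows(fw$logits) else fw$features
  }
  do.call(rbind, out)
}

#' Plain supervised cross-entropy baseline
#'
#' Trains the same backbone on the labeled set only (raw images plus their
#' weak views) with plain cross-entropy, using the identical seed fan-out,
#' batch cycling and optimiser as [accn_train()]. With an empty unlabeled
#' set and zero balance weights the two produce bit-identical trajectories,
#' and this is the paired baseline for measuring the semi-supervised gain.
#'
#' @inheritParams accn_train
#' @return An `accn_fit` (with all unsupervised loss terms absent).
#' @export
supervised_baseline <- function(labeled, config = train_config(),
                                eval_data = NULL) {
  stopifnot(inherits(config, "train_config"))
  x_l <- as_image_batch(labeled$x)
  y_l <- as.integer(labeled$y)
  nc <- config$n_classes %||% (max(y_l) + 1L)
  n_l <- batch_size_of(x_l)
  B <- config$batch_size
  pol <- config$policy

  net <- accn_network(nc, input_size = dim(x_l)[1], in_channels = dim(x_l)[3],
                      backbone = config$backbone, seed = config$seed)
  opt <- optim_init(net$params, config)
  batch_stream <- rng_stream(fork_seed(config$seed, "batch"))
  aug_stream <- rng_stream(fork_seed(config$seed, "augment"))
  cyc <- new_cycler(n_l)
  history <- list()
  epoch_metrics <- list()
  steps <- ceiling(n_l / B)

  for (ep in seq_len(config$epochs)) {
    for (st in seq_len(steps)) {
      idx <- next_batch(cyc, B, batch_stream)
      weak <- augment_batch_weak(x_l, idx, pol, aug_stream)
      xb <- array(c(batch_subset(x_l, idx), weak), dim = c(dim(weak)[1:3], 2L * B))
      yb <- rep(y_l[idx], 2L)
      fw <- network_forward(net, xb, keep_cache = TRUE, train = TRUE)
      net$bn_stats <- fw$bn_stats
      l <- lce_loss(log_softmax_rows(fw$logits), yb)
      grads <- network_backward(net, fw$cache,
                                dlogits = grad_ce_logits(fw$logits, yb))
      res <- optim_step(net$params, grads, opt)
      net$params <- res$params
      opt <- res$opt
      history[[length(history) + 1L]] <- c(ep, st, l, 0, 0, 0, l)
    }
    em <- tibble::tibble(epoch = ep, acc = NA_real_, sen = NA_real_,
                         spe = NA_real_, auc = NA_real_, pseudo_acc = NA_real_)
    if (!is.null(eval_data)) {
      ev <- evaluate_model(net, eval_data$x, eval_data$y)
      em$acc <- ev$acc; em$sen <- ev$sen; em$spe <- ev$spe; em$auc <- ev$auc
    }
    epoch_metrics[[length(epoch_metrics) + 1L]] <- em
  }

  history <- history_tibble(history)
  epoch_metrics <- do.call(rbind, epoch_metrics)
  structure(list(network = net, state = NULL, history = history,
                 epoch_metrics = epoch_metrics, pseudo_labels = NULL,
                 best_epoch = if (any(!is.na(epoch_metrics$acc)))
                   epoch_metrics$epoch[which.max(epoch_metrics$acc)] else NA_integer_,
                 n_classes = nc, config = config,
                 internal = list(opt = opt, batch_stream = batch_stream,
                                 aug_stream = aug_stream, lab_cyc = cyc,
                                 unl_cyc = NULL, epoch = config$epochs,
                                 memory_ready = FALSE)),
            class = "accn_fit")
}

#' Ablation and sweep harness
#'
#' Re-runs training under controlled variations and tabulates held-out
#' metrics:
#' \describe{
#'   \item{`"full"`}{the complete method.}
#'   \item{`"no_acl"`}{augmentation-consistent learning removed: raw images
#'     only, no consistency loss; the clustering unit still runs.}
#'   \item{`"no_wcu"`}{weight clustering removed: confidence-thresholded
#'     argmax pseudo-labels, no centroid-consistency loss.}
#'   \item{`"supervised"`}{labeled data only.}
#'   \item{`"label_budget"`}{sweep over the total number of labeled images.}
#'   \item{`"positive_fraction"`}{sweep over the fraction of positive cases
#'     in the unlabeled pool (binary problems).}
#' }
#' Each sweep point regenerates synthetic data from `spec` (sharing the
#' spec's seed), trains, and evaluates on a freshly generated held-out set.
#'
#' @param which character vector of variant names (see above).
#' @param spec a [synthetic_spec()] describing the base dataset.
#' @param config a [train_config()].
#' @param budgets total labeled-image counts for the `label_budget` sweep
#'   (split evenly across classes).
#' @param fractions positive fractions for the `positive_fraction` sweep.
#' @param n_eval_per_class held-out test images per class.
#' @param out_csv optional path; the metrics table is also written as CSV.
#' @return A tibble with columns `variant`, `sweep` (budget or fraction,
#'   `NA` otherwise), `acc`, `sen`, `spe`, `auc`.
#' @export
run_ablation <- function(which, spec = synthetic_spec(),
                         config = train_config(),
                         budgets = c(50, 100, 200, 400),
                         fractions = c(0.2, 0.35, 0.5, 0.65, 0.8),
                         n_eval_per_class = 100, out_csv = NULL) {
  known <- c("full", "no_acl", "no_wcu", "supervised", "label_budget",
             "positive_fraction")
  bad <- setdiff(which, known)
  if (length(bad))
    stop("unknown ablation variant(s): ", paste(bad, collapse = ", "),
         call. = FALSE)

  eval_set_for <- function(sp) {
    es <- synthetic_spec(n_classes = sp$n_classes,
                         n_labeled_per_class = n_eval_per_class,
                         n_unlabeled_per_class = 0,
                         image_size = sp$image_size, separation = sp$separation,
                         noise_sd = sp$noise_sd, seed = fork_seed(sp$seed, "eval"))
    ds <- generate_dataset(es)
    list(x = ds$labeled$x, y = ds$labeled$y)
  }

  one_run <- function(variant, sp, cfg) {
    ds <- generate_dataset(sp)
    ev <- eval_set_for(sp)
    fit <- if (variant == "supervised")
      supervised_baseline(ds$labeled, cfg, eval_data = ev)
    else accn_train(ds$labeled, ds$unlabeled, cfg, eval_data = ev,
                    truth = ds$unlabeled$y_true)
    m <- fit$epoch_metrics[nrow(fit$epoch_metrics), ]
    tibble::tibble(acc = m$acc, sen = m$sen, spe = m$spe, auc = m$auc)
  }

  rows <- list()
  for (v in which) {
    if (v %in% c("full", "no_acl", "no_wcu", "supervised")) {
      cfg <- config
      if (v == "no_acl") cfg$disable_acl <- TRUE
      if (v == "no_wcu") cfg$disable_wcu <- TRUE
      m <- one_run(v, spec, cfg)
      rows[[length(rows) + 1L]] <- tibble::tibble(variant = v, sweep = NA_real_, m)
    } else if (v == "label_budget") {
      for (b in budgets) {
        sp <- spec
        sp$n_labeled_per_class <- as.integer(round(b / spec$n_classes))
        m <- one_run(v, sp, config)
        rows[[length(rows) + 1L]] <- tibble::tibble(variant = v, sweep = b, m)
      }
    } else if (v == "positive_fraction") {
      if (spec$n_classes != 2)
        stop("positive_fraction sweep requires a binary problem", call. = FALSE)
      for (p in fractions) {
        sp <- spec
        sp$positive_fraction_unlabeled <- p
        m <- one_run(v, sp, config)
        rows[[length(rows) + 1L]] <- tibble::tibble(variant = v, sweep = p, m)
      }
    }
  }
  out <- do.call(rbind, rows)
  if (!is.null(out_csv)) utils::write.csv(out, out_csv, row.names = FALSE)
  out
}
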