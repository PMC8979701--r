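#' Specification for a class-conditional synthetic image dataset
#'
#' Describes a small semi-supervised benchmark emulating the data regime of
#' fundus-screening studies: a small labeled set, a larger unlabeled pool,
#' and (optionally, in the binary case) a controllable fraction of positive
#' cases among the unlabeled images. Each class has a deterministic base
#' pattern — a concentric ring texture whose radial frequency is
#' class-specific, under a central Gaussian envelope — and images are the
#' class pattern plus i.i.d. Gaussian pixel noise. Frequency is chosen as
#' the class cue because it is invariant under the augmentation group
#' (flips, small rotations/shears, crops) while remaining detectable by a
#' small convolutional network. Patterns are scaled so that the peak
#' pixelwise contrast between any two class-conditional mean images equals
#' `separation * noise_sd` — `separation` measures how far the class
#' appearances sit apart in units of the within-class noise standard
#' deviation (a local texture signal-to-noise, analogous to lesion
#' contrast), and `separation = 0` makes all class means identical.
#'
#' Defaults mirror the package's reference benchmark: 2 classes, 32x32
#' grayscale images, 10 labeled and 200 unlabeled images per class,
#' separation 6.
#'
#' @param n_classes number of classes (>= 2).
#' @param n_labeled_per_class labeled images per class (>= 0).
#' @param n_unlabeled_per_class unlabeled images per class (>= 0).
#' @param image_size pixels per side (>= 8).
#' @param separation peak contrast between class mean images in noise-sd
#'   units (>= 0).
#' @param noise_sd pixel-noise standard deviation on the [0,1] intensity
#'   scale (> 0).
#' @param positive_fraction_unlabeled for binary problems only: fraction of
#'   the unlabeled pool drawn from class 1 (the positive class). `NULL`
#'   (default) keeps the pool balanced at the per-class counts.
#' @param seed integer; generation is bit-identical given the same spec.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_classes = 2, n_labeled_per_class = 10,
                           n_unlabeled_per_class = 200, image_size = 32,
                           separation = 6, noise_sd = 0.08,
                           positive_fraction_unlabeled = NULL, seed = 1) {
  if (!is.numeric(n_classes) || length(n_classes) != 1 || n_classes < 2)
    .stop_field("n_classes", "must be a single integer >= 2")
  if (!is.numeric(n_labeled_per_class) || n_labeled_per_class < 0)
    .stop_field("n_labeled_per_class", "must be >= 0")
  if (!is.numeric(n_unlabeled_per_class) || n_unlabeled_per_class < 0)
    .stop_field("n_unlabeled_per_class", "must be >= 0")
  if (!is.numeric(image_size) || image_size < 8)
    .stop_field("image_size", "must be >= 8")
  if (!is.numeric(separation) || separation < 0)
    .stop_field("separation", "must be >= 0")
  if (!is.numeric(noise_sd) || noise_sd <= 0)
    .stop_field("noise_sd", "must be > 0")
  if (!is.null(positive_fraction_unlabeled)) {
    if (n_classes != 2)
      .stop_field("positive_fraction_unlabeled", "only meaningful for binary problems (n_classes = 2)")
    if (!is.numeric(positive_fraction_unlabeled) ||
        positive_fraction_unlabeled < 0 || positive_fraction_unlabeled > 1)
      .stop_field("positive_fraction_unlabeled", "must lie in [0, 1]")
  }
  structure(list(n_classes = as.integer(n_classes),
                 n_labeled_per_class = as.integer(n_labeled_per_class),
                 n_unlabeled_per_class = as.integer(n_unlabeled_per_class),
                 image_size = as.integer(image_size),
                 separation = as.numeric(separation),
                 noise_sd = as.numeric(noise_sd),
                 positive_fraction_unlabeled = positive_fraction_unlabeled,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' @export
print.synthetic_spec <- function(x, ...) {
  cat(sprintf("<synthetic_spec: %d classes, %dx%d px, %d labeled + %d unlabeled per class, separation %.3g sd, seed %d>\n",
              x$n_classes, x$image_size, x$image_size, x$n_labeled_per_class,
              x$n_unlabeled_per_class, x$separation, x$seed))
  invisible(x)
}

# Deterministic per-class mean images (S, S, 1, N_c), pairwise-mean distance
# scaled to separation * noise_sd. Classes differ by the radial frequency of
# a concentric ring texture under a central Gaussian envelope: frequency is
# invariant to flips/rotations and barely moved by the crops, shears and
# photometric ops of the augmentation policies, so the class identity is a
# texture statistic (as lesion texture is in fundus images), not a pixel
# position that augmentation would scramble.
class_mean_images <- function(spec) {
  S <- spec$image_size
  nc <- spec$n_classes
  gx <- matrix(seq_len(S) - 0.5, S, S)
  gy <- t(gx)
  r <- sqrt((gx - S / 2)^2 + (gy - S / 2)^2)
  env <- exp(-r^2 / (2 * (0.22 * S)^2))
  freqs <- 4 * (10 / 4)^((seq_len(nc) - 1) / (nc - 1))
  pats <- array(0, dim = c(S, S, nc))
  for (k in seq_len(nc)) pats[, , k] <- env * cos(2 * pi * freqs[k] * r / S)
  mu <- apply(pats, c(1, 2), mean)
  for (k in seq_len(nc)) pats[, , k] <- pats[, , k] - mu
  # Scale so the maximum pixelwise distance between any two class means is
  # separation * noise_sd: `separation` is the peak contrast between class
  # appearances, in units of the pixel-noise standard deviation (the local
  # signal-to-noise of the class-defining texture, analogous to lesion
  # contrast). separation = 0 collapses all class means onto one image.
  peak <- 0
  for (a in seq_len(nc - 1)) for (b in (a + 1):nc)
    peak <- max(peak, max(abs(pats[, , a] - pats[, , b])))
  alpha <- if (spec$separation == 0 || peak == 0) 0 else
    spec$separation * spec$noise_sd / peak
  means <- array(0, dim = c(S, S, 1, nc))
  for (k in seq_len(nc)) means[, , 1, k] <- 0.5 + alpha * pats[, , k]
  means
}

#' Generate a synthetic semi-supervised image dataset
#'
#' Draws the labeled and unlabeled sets described by a [synthetic_spec()].
#' Pixel intensities are quantised to 8-bit levels (multiples of 1/255) on
#' the [0,1] scale, so a dataset round-trips exactly through PNG files. The
#' true labels of unlabeled images are retained in a side channel
#' (`unlabeled$y_true`) for evaluation only; they are never visible to the
#' trainer.
#'
#' @param spec a [synthetic_spec()].
#' @return An object of class `accn_dataset`: a list with `labeled`
#'   (`x`: (S,S,1,n) array, `y`: integer 0-based labels), `unlabeled`
#'   (`x`, `y_true`), `class_means`, and `spec`.
#' @examples
#' ds <- generate_dataset(synthetic_spec(n_labeled_per_class = 5,
#'                                       n_unlabeled_per_class = 10))
#' dim(ds$labeled$x)   # 32 32 1 10
#' table(ds$labeled$y)
#' @export
generate_dataset <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  S <- spec$image_size
  means <- class_mean_images(spec)
  stream <- rng_stream(fork_seed(spec$seed, "synthetic"))

  # Per-image illumination nuisance (class-independent): a global intensity
  # offset and a multiplicative contrast gain, emulating the acquisition
  # variability of real fundus photography. Fixed at offset sd 0.04 and
  # gain sd 0.10 around 1.
  draw <- function(k, n) {
    if (n == 0) return(array(0, dim = c(S, S, 1, 0)))
    signal <- array(rep(means[, , , k + 1L] - 0.5, n), dim = c(S, S, 1, n))
    noise <- array(r_norm(stream, S * S * n, sd = spec$noise_sd),
                   dim = c(S, S, 1, n))
    offset <- rep(r_norm(stream, n, sd = 0.04), each = S * S)
    gain <- rep(pmax(0.5, r_norm(stream, n, mean = 1, sd = 0.10)), each = S * S)
    x <- 0.5 + offset + gain * (signal + noise)
    round(clamp01(x) * 255) / 255
  }

  nl <- spec$n_labeled_per_class
  lab_x <- vector("list", spec$n_classes)
  for (k in seq_len(spec$n_classes) - 1L) lab_x[[k + 1L]] <- draw(k, nl)
  labeled <- list(
    x = array(unlist(lab_x), dim = c(S, S, 1, nl * spec$n_classes)),
    y = rep(seq_len(spec$n_classes) - 1L, each = nl))

  if (spec$n_classes == 2 && !is.null(spec$positive_fraction_unlabeled)) {
    total <- 2L * spec$n_unlabeled_per_class
    n1 <- as.integer(round(spec$positive_fraction_unlabeled * total))
    counts <- c(total - n1, n1)
  } else {
    counts <- rep(spec$n_unlabeled_per_class, spec$n_classes)
  }
  unl_x <- vector("list", spec$n_classes)
  for (k in seq_len(spec$n_classes) - 1L) unl_x[[k + 1L]] <- draw(k, counts[k + 1L])
  unlabeled <- list(
    x = array(unlist(unl_x), dim = c(S, S, 1, sum(counts))),
    y_true = rep(seq_len(spec$n_classes) - 1L, times = counts))

  structure(list(labeled = labeled, unlabeled = unlabeled,
                 class_means = means, spec = spec),
            class = "accn_dataset")
}

#' @export
print.accn_dataset <- function(x, ...) {
  cat(sprintf("<accn_dataset: %d labeled, %d unlabeled, %d classes, %dx%d px>\n",
              length(x$labeled$y), length(x$unlabeled$y_true),
              x$spec$n_classes, x$spec$image_size, x$spec$image_size))
  invisible(x)
}

#' Nearest-class-mean accuracy on the unlabeled pool
#'
#' A deliberately simple reference classifier used to validate the
#' generator: class means are estimated from the labeled images and each
#' unlabeled image is assigned to the nearest mean (Euclidean distance),
#' scored against the hidden true labels. At `separation = 0` this is at
#' chance; accuracy grows monotonically with separation.
#'
#' @param dataset an `accn_dataset` with non-empty labeled and unlabeled
#'   parts.
#' @return accuracy in [0, 1].
#' @export
nearest_mean_accuracy <- function(dataset) {
  stopifnot(inherits(dataset, "accn_dataset"))
  y <- dataset$labeled$y
  nc <- dataset$spec$n_classes
  S <- dataset$spec$image_size
  lx <- matrix(dataset$labeled$x, nrow = S * S, ncol = length(y))
  mu <- sapply(seq_len(nc) - 1L, function(k) rowMeans(lx[, y == k, drop = FALSE]))
  ux <- matrix(dataset$unlabeled$x, nrow = S * S, ncol = length(dataset$unlabeled$y_true))
  d2 <- outer(colSums(ux^2), colSums(mu^2), "+") - 2 * crossprod(ux, mu)
  pred <- max.col(-d2, ties.method = "first") - 1L
  mean(pred == dataset$unlabeled$y_true)
}

#' Write a dataset to disk as PNG images plus CSV manifests
#'
#' Images are written as 8-bit grayscale PNGs. The training manifest
#' (`manifest.csv`, columns `filename,label`) carries the integer class
#' index for labeled rows and `-1` for unlabeled rows. The hidden true
#' labels of the unlabeled images go to a separate side file
#' (`truth.csv`, columns `filename,true_label`) which the training reader
#' never touches.
#'
#' @param dataset an `accn_dataset`.
#' @param out_dir output directory (created if missing).
#' @return (invisibly) the manifest as a tibble.
#' @export
write_manifest <- function(dataset, out_dir) {
  stopifnot(inherits(dataset, "accn_dataset"))
  ok <- dir.exists(out_dir) || dir.create(out_dir, recursive = TRUE)
  if (!ok) stop("cannot create output directory: ", out_dir, call. = FALSE)

  write_one <- function(x4, i, name) {
    img <- x4[, , , i]
    if (is.null(dim(img))) img <- matrix(img, dim(x4)[1], dim(x4)[2])
    path <- file.path(out_dir, name)
    tryCatch(png::writePNG(img, target = path),
             error = function(e) stop("failed to write image at ", path, ": ",
                                      conditionMessage(e), call. = FALSE))
    name
  }

  nl <- length(dataset$labeled$y)
  nu <- length(dataset$unlabeled$y_true)
  lab_names <- if (nl) sprintf("lab_%05d.png", seq_len(nl)) else character(0)
  unl_names <- if (nu) sprintf("unl_%05d.png", seq_len(nu)) else character(0)
  for (i in seq_len(nl)) write_one(dataset$labeled$x, i, lab_names[i])
  for (i in seq_len(nu)) write_one(dataset$unlabeled$x, i, unl_names[i])

  manifest <- tibble::tibble(
    filename = c(lab_names, unl_names),
    label = c(dataset$labeled$y, rep(-1L, nu)))
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"), row.names = FALSE)
  truth <- tibble::tibble(filename = unl_names,
                          true_label = dataset$unlabeled$y_true)
  utils::write.csv(truth, file.path(out_dir, "truth.csv"), row.names = FALSE)
  invisible(manifest)
}
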