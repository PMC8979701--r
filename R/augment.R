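#' Weak and strong augmentation policies
#'
#' The weak policy is a random crop (area fraction drawn from `crop_range`,
#' resized back to the input size) followed by a random horizontal flip —
#' the mild transformation whose prediction serves as the anchor. The
#' strong policy is an ordered collection of `K` pipelines, each a
#' RandAugment draw (`n_ops` operators sampled from the standard 14-op
#' geometric + photometric pool at magnitude `magnitude` on the 0–30 scale)
#' followed by a fixed sequence (by default Cutout: a random square erase
#' with side `cutout_frac` of the image side). Geometric operators fill
#' exposed borders by edge reflection so no black-corner shortcut is
#' introduced.
#'
#' Every operator maps an H x W x C image to an image of identical shape,
#' and all randomness is drawn from the caller-supplied [rng_stream()].
#'
#' @param crop_range length-2 numeric in (0,1]: min/max crop area fraction.
#' @param flip_prob horizontal flip probability in [0,1].
#' @param n_ops RandAugment operators per strong view.
#' @param magnitude RandAugment magnitude in [0, 30]; 0 makes every operator
#'   collapse to (near-)identity.
#' @param K number of strong views per image (>= 1).
#' @param fixed_ops character vector of post-RandAugment fixed operators;
#'   currently `"cutout"` or empty (`character(0)`).
#' @param cutout_frac cutout square side as a fraction of the image side.
#' @return An object of class `augmentation_policy`.
#' @export
augmentation_policy <- function(crop_range = c(0.8, 1), flip_prob = 0.5,
                                n_ops = 2, magnitude = 10, K = 2,
                                fixed_ops = "cutout", cutout_frac = 0.25) {
  if (length(crop_range) != 2 || any(crop_range <= 0) || any(crop_range > 1) ||
      crop_range[1] > crop_range[2])
    .stop_field("crop_range", "must be increasing and within (0, 1]")
  if (flip_prob < 0 || flip_prob > 1)
    .stop_field("flip_prob", "must lie in [0, 1]")
  if (!is.numeric(K) || K < 1)
    .stop_field("K", "need at least one strong view")
  if (magnitude < 0 || magnitude > 30)
    .stop_field("magnitude", "must lie in [0, 30]")
  if (n_ops < 0) .stop_field("n_ops", "must be >= 0")
  if (length(fixed_ops) && !all(fixed_ops %in% "cutout"))
    .stop_field("fixed_ops", "unknown fixed operator")
  structure(list(crop_range = as.numeric(crop_range),
                 flip_prob = as.numeric(flip_prob),
                 n_ops = as.integer(n_ops), magnitude = as.numeric(magnitude),
                 K = as.integer(K), fixed_ops = fixed_ops,
                 cutout_frac = as.numeric(cutout_frac)),
            class = "augmentation_policy")
}

#' @export
print.augmentation_policy <- function(x, ...) {
  cat(sprintf("<augmentation_policy: weak crop %.0f-%.0f%% + flip p=%.2f; strong K=%d RandAugment(n=%d, m=%g) + [%s]>\n",
              100 * x$crop_range[1], 100 * x$crop_range[2], x$flip_prob, x$K,
              x$n_ops, x$magnitude, paste(x$fixed_ops, collapse = ",")))
  invisible(x)
}

# ---- sampling machinery ----------------------------------------------------

# reflect a real coordinate into [1, n] (mirror boundary, period 2(n-1))
reflect_coord <- function(x, n) {
  if (n == 1) return(rep(1, length(x)))
  p <- 2 * (n - 1)
  abs((x - 1) %% p - (n - 1)) + 1
}

# Bilinear sampling of img (H x W x C) at real source coords (sr, sc),
# H x W matrices; out-of-range coords are reflected at the borders.
bilinear_sample <- function(img, sr, sc) {
  d <- dim(img)
  H <- d[1]; W <- d[2]; C <- d[3]
  r0 <- floor(sr); fr <- sr - r0
  c0 <- floor(sc); fc <- sc - c0
  ra <- reflect_coord(r0, H); rb <- reflect_coord(r0 + 1, H)
  ca <- reflect_coord(c0, W); cb <- reflect_coord(c0 + 1, W)
  out <- array(0, dim = c(dim(sr), C))
  iaa <- (ca - 1) * H + ra; iab <- (cb - 1) * H + ra
  iba <- (ca - 1) * H + rb; ibb <- (cb - 1) * H + rb
  for (ch in seq_len(C)) {
    m <- img[, , ch]
    out[, , ch] <- (1 - fr) * ((1 - fc) * m[iaa] + fc * m[iab]) +
                   fr * ((1 - fc) * m[iba] + fc * m[ibb])
  }
  out
}

# inverse-affine warp: source = A %*% (target - ctr) + ctr + shift
affine_warp <- function(img, A, shift = c(0, 0)) {
  d <- dim(img)
  ctr <- (d[1:2] + 1) / 2
  r <- matrix(seq_len(d[1]), d[1], d[2]) - ctr[1]
  c <- matrix(seq_len(d[2]), d[1], d[2], byrow = TRUE) - ctr[2]
  sr <- A[1, 1] * r + A[1, 2] * c + ctr[1] + shift[1]
  sc <- A[2, 1] * r + A[2, 2] * c + ctr[2] + shift[2]
  bilinear_sample(img, sr, sc)
}

crop_resize <- function(img, r0, c0, ch, cw) {
  d <- dim(img)
  sr <- if (d[1] == 1) matrix(r0, d[1], d[2]) else
    matrix(r0 + (seq_len(d[1]) - 1) * (ch - 1) / (d[1] - 1), d[1], d[2])
  sc <- if (d[2] == 1) matrix(c0, d[1], d[2]) else
    matrix(c0 + (seq_len(d[2]) - 1) * (cw - 1) / (d[2] - 1), d[1], d[2], byrow = TRUE)
  bilinear_sample(img, sr, sc)
}

# ---- photometric operators -------------------------------------------------

op_autocontrast <- function(img) {
  for (ch in seq_len(dim(img)[3])) {
    m <- img[, , ch]
    rng <- range(m)
    if (rng[2] > rng[1]) img[, , ch] <- (m - rng[1]) / (rng[2] - rng[1])
  }
  img
}

op_equalize <- function(img) {
  for (ch in seq_len(dim(img)[3])) {
    m <- img[, , ch]
    q <- pmin(pmax(round(m * 255), 0), 255)
    h <- tabulate(q + 1, nbins = 256)
    cdf <- cumsum(h)
    nz <- cdf[h > 0]
    if (length(nz) <= 1) next
    cdf_min <- nz[1]
    lut <- (cdf - cdf_min) / (cdf[256] - cdf_min)
    img[, , ch] <- matrix(lut[q + 1], nrow(m), ncol(m))
  }
  clamp01(img)
}

op_solarize <- function(img, threshold) {
  ifelse(img >= threshold, 1 - img, img)
}

op_posterize <- function(img, bits) {
  levels <- 2^bits
  pmin(floor(img * levels), levels - 1) / (levels - 1)
}

op_brightness <- function(img, factor) clamp01(img * factor)

op_contrast <- function(img, factor) clamp01(mean(img) + factor * (img - mean(img)))

op_color <- function(img, factor) {
  if (dim(img)[3] == 1) return(img)  # saturation is a no-op in grayscale
  gray <- array(rep(apply(img, c(1, 2), mean), dim(img)[3]), dim = dim(img))
  clamp01(gray + factor * (img - gray))
}

blur3 <- function(img) {
  d <- dim(img)
  out <- img
  k <- c(1, 1, 1, 1, 4, 1, 1, 1, 1) / 12
  offs <- expand.grid(dr = -1:1, dc = -1:1)
  for (ch in seq_len(d[3])) {
    m <- img[, , ch]
    acc <- matrix(0, d[1], d[2])
    rows <- seq_len(d[1]); cols <- seq_len(d[2])
    for (o in seq_len(9)) {
      rr <- pmin(pmax(rows + offs$dr[o], 1), d[1])
      cc <- pmin(pmax(cols + offs$dc[o], 1), d[2])
      acc <- acc + k[o] * m[rr, cc]
    }
    out[, , ch] <- acc
  }
  out
}

op_sharpness <- function(img, factor) {
  b <- blur3(img)
  clamp01(b + factor * (img - b))
}

op_cutout <- function(img, stream, frac) {
  d <- dim(img)
  side <- max(1L, round(frac * min(d[1:2])))
  cr <- floor(r_unif(stream, 1, 1, d[1] + 1))
  cc <- floor(r_unif(stream, 1, 1, d[2] + 1))
  r1 <- max(1, cr - side %/% 2); r2 <- min(d[1], r1 + side - 1)
  c1 <- max(1, cc - side %/% 2); c2 <- min(d[2], c1 + side - 1)
  img[r1:r2, c1:c2, ] <- 0.5
  img
}

# ---- RandAugment -----------------------------------------------------------

randaugment_ops <- c("identity", "autocontrast", "equalize", "rotate",
                     "solarize", "color", "posterize", "contrast",
                     "brightness", "sharpness", "shear_x", "shear_y",
                     "translate_x", "translate_y")

apply_randaugment_op <- function(img, op, f, stream) {
  sgn <- if (r_unif(stream, 1) < 0.5) -1 else 1
  switch(op,
    identity = img,
    # magnitude-free ops are blended with the identity by f so magnitude 0
    # degrades gracefully to a no-op
    autocontrast = clamp01((1 - f) * img + f * op_autocontrast(img)),
    equalize = clamp01((1 - f) * img + f * op_equalize(img)),
    rotate = {
      a <- sgn * f * 30 * pi / 180
      affine_warp(img, matrix(c(cos(a), -sin(a), sin(a), cos(a)), 2, 2))
    },
    solarize = if (f == 0) img else op_solarize(img, 1 - f),
    color = op_color(img, 1 + sgn * f * 0.9),
    posterize = op_posterize(img, 8L - as.integer(round(f * 4))),
    contrast = op_contrast(img, 1 + sgn * f * 0.9),
    brightness = op_brightness(img, 1 + sgn * f * 0.9),
    sharpness = op_sharpness(img, 1 + sgn * f * 0.9),
    shear_x = affine_warp(img, matrix(c(1, 0, sgn * f * 0.3, 1), 2, 2)),
    shear_y = affine_warp(img, matrix(c(1, sgn * f * 0.3, 0, 1), 2, 2)),
    translate_x = affine_warp(img, diag(2), shift = c(0, sgn * f * 0.33 * dim(img)[2])),
    translate_y = affine_warp(img, diag(2), shift = c(sgn * f * 0.33 * dim(img)[1], 0)),
    stop("unknown RandAugment op: ", op))
}

randaugment <- function(img, n_ops, magnitude, stream) {
  f <- magnitude / 30
  if (n_ops == 0) return(img)
  ops <- randaugment_ops[ceiling(r_unif(stream, n_ops, 0, length(randaugment_ops)))]
  for (op in ops) img <- apply_randaugment_op(img, op, f, stream)
  img
}

# ---- public API ------------------------------------------------------------

#' Weakly augment an image (random crop + random horizontal flip)
#'
#' @param image an H x W x C array (or H x W matrix) with intensities in
#'   [0, 1].
#' @param policy an [augmentation_policy()].
#' @param stream an [rng_stream()] supplying all randomness.
#' @return An array with the same dimensions as the input.
#' @export
weak_augment <- function(image, policy, stream) {
  image <- as_image_array(image)
  d <- dim(image)
  if (any(d[1:2] == 0)) stop("cannot augment a zero-sized image", call. = FALSE)
  a <- r_unif(stream, 1, policy$crop_range[1], policy$crop_range[2])
  side <- sqrt(a)
  ch <- max(1L, round(side * d[1]))
  cw <- max(1L, round(side * d[2]))
  r0 <- floor(r_unif(stream, 1, 1, d[1] - ch + 1 + 1e-9))
  c0 <- floor(r_unif(stream, 1, 1, d[2] - cw + 1 + 1e-9))
  out <- if (ch == d[1] && cw == d[2]) image else crop_resize(image, r0, c0, ch, cw)
  if (policy$flip_prob > 0 && r_unif(stream, 1) < policy$flip_prob)
    out <- out[, rev(seq_len(d[2])), , drop = FALSE]
  out
}

#' Strongly augment an image into K views (RandAugment + fixed sequence)
#'
#' @inheritParams weak_augment
#' @return A list of `policy$K` arrays, each the same shape as the input.
#' @export
strong_augment <- function(image, policy, stream) {
  image <- as_image_array(image)
  if (any(dim(image)[1:2] == 0)) stop("cannot augment a zero-sized image", call. = FALSE)
  if (policy$K < 1) .stop_field("K", "need at least one strong view")
  lapply(seq_len(policy$K), function(k) {
    out <- randaugment(image, policy$n_ops, policy$magnitude, stream)
    for (fx in policy$fixed_ops)
      out <- switch(fx, cutout = op_cutout(out, stream, policy$cutout_frac))
    out
  })
}
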