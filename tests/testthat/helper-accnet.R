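# Shared fixture builders. Everything is generated in code; no files ship
# with the tests.

# a small random image batch in [0, 1]
random_images <- function(n, S = 16, C = 1, seed = 1) {
  s <- rng_stream(seed)
  array(r_unif(s, S * S * C * n), dim = c(S, S, C, n))
}

# a small labeled set with an easy two-class structure (bright top vs
# bright bottom half), for quick trainer smoke tests
tiny_labeled_set <- function(n_per = 6, S = 16, seed = 1, amp = 0.25) {
  s <- rng_stream(seed)
  x <- array(0, dim = c(S, S, 1, 2 * n_per))
  half <- S %/% 2
  for (i in seq_len(n_per)) {
    b0 <- matrix(0.5, S, S); b0[1:half, ] <- 0.5 + amp
    b1 <- matrix(0.5, S, S); b1[(half + 1):S, ] <- 0.5 + amp
    x[, , 1, i] <- b0 + matrix(r_norm(s, S * S, sd = 0.05), S, S)
    x[, , 1, n_per + i] <- b1 + matrix(r_norm(s, S * S, sd = 0.05), S, S)
  }
  x <- round(clamp01(x) * 255) / 255
  list(x = x, y = rep(0:1, each = n_per))
}

clamp01 <- function(x) pmin(pmax(x, 0), 1)

# small custom backbone that accepts 16x16 inputs
tiny16_config <- function(...) {
  train_config(backbone = c(4L, 8L, 16L), ...)
}

# loop-based soft-weighted centroid oracle (independent of the package's
# vectorised path)
centroid_oracle <- function(features, probs) {
  nc <- ncol(probs)
  d <- ncol(features)
  out <- matrix(NA_real_, nc, d)
  for (k in seq_len(nc)) {
    num <- numeric(d)
    den <- 0
    for (i in seq_len(nrow(features))) {
      num <- num + probs[i, k] * features[i, ]
      den <- den + probs[i, k]
    }
    if (den > 0) out[k, ] <- num / den
  }
  out
}

# exhaustive nearest-centroid oracle
assign_oracle <- function(features, centroids) {
  n <- nrow(features)
  lab <- integer(n)
  for (j in seq_len(n)) {
    best <- Inf; arg <- NA_integer_
    for (k in seq_len(nrow(centroids))) {
      d <- sqrt(sum((features[j, ] - centroids[k, ])^2))
      if (d < best - 1e-15) { best <- d; arg <- k }
    }
    lab[j] <- arg - 1L
  }
  lab
}

# scalar-loop cross-entropy oracle
ce_oracle <- function(log_probs, labels) {
  tot <- 0
  for (i in seq_along(labels)) tot <- tot - log_probs[i, labels[i] + 1]
  tot / length(labels)
}
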