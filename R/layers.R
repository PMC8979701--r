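# Differentiable layer primitives for the compact CNN backbone.
#
# Activations are carried in pixel-major matrix form: a (P x C) matrix
# whose row index runs p = h + H*w + H*W*n over pixels and batch members.
# Convolutions (im2col + GEMM and the exact adjoint) live in compiled
# code; batch norm, ReLU, 2x2 average pooling and global average pooling
# are vectorised matrix ops here. Backward functions return exact
# gradients w.r.t. inputs and parameters.

# image batch (H, W, C, N) -> pixel-major matrix (H*W*N x C)
to_pixel_major <- function(x) {
  d <- dim(x)
  if (d[3] == 1L) return(matrix(x, ncol = 1L))
  matrix(aperm(x, c(1, 2, 4, 3)), ncol = d[3])
}

conv_pm_forward <- function(xmat, H, W, N, Wmat, bias) {
  res <- conv_pm_forward_cpp(xmat, as.integer(c(H, W, N)), Wmat, bias)
  list(pre = res$pre, cols = res$cols, hwn = c(H, W, N), cin = ncol(xmat))
}

conv_pm_backward <- function(dmat, cache, Wmat) {
  conv_pm_backward_cpp(dmat, as.integer(cache$hwn), cache$cin, cache$cols, Wmat)
}

# Batch normalisation over the (pixel x batch) axis, one statistic per
# channel. Running statistics serve inference mode; they average
# cumulatively over the first updates (so short runs get calibrated
# statistics immediately) and then decay exponentially.
bn_forward <- function(pre, gamma, beta, stats, train, eps = 1e-5) {
  res <- bn_fwd_cpp(pre, gamma, beta, stats$mean, stats$var, train, eps)
  if (train) {
    n <- (stats$n %||% 0) + 1
    mom <- max(0.05, 1 / n)
    stats$mean <- if (n == 1) res$mu else (1 - mom) * stats$mean + mom * res$mu
    stats$var <- if (n == 1) res$v else (1 - mom) * stats$var + mom * res$v
    stats$n <- n
  }
  list(out = res$out, xhat = res$xhat, inv = res$inv, stats = stats)
}

bn_backward <- function(dout, cache, gamma) {
  res <- bn_bwd_cpp(dout, cache$xhat, cache$inv, gamma)
  list(dx = res$dx, dgamma = res$dgamma, dbeta = res$dbeta)
}

# 2x2/stride-2 average pooling on pixel-major matrices (compiled kernels)
avgpool_pm_forward <- function(act, H, W, N) {
  list(out = pool2_fwd_cpp(act, as.integer(c(H, W, N))), H = H, W = W, N = N)
}

avgpool_pm_backward <- function(dout, cache) {
  pool2_bwd_cpp(dout, as.integer(c(cache$H, cache$W, cache$N)))
}

# global average pooling (HW*N x C) -> features (N x C)
gap_forward_pm <- function(act, N) {
  hw <- nrow(act) %/% N
  f <- rowsum(act, group = rep(seq_len(N), each = hw), reorder = FALSE) / hw
  dimnames(f) <- NULL
  list(out = f, hw = hw, N = N)
}

gap_backward_pm <- function(dfeat, cache) {
  dfeat[rep(seq_len(cache$N), each = cache$hw), , drop = FALSE] / cache$hw
}

# dense head: features (N x d_in) -> logits (N x d_out)
linear_forward <- function(f, Wmat, bias) {
  out <- f %*% Wmat
  out <- sweep(out, 2, bias, "+")
  list(out = out, f = f)
}

linear_backward <- function(dout, cache, Wmat) {
  list(df = dout %*% t(Wmat),
       dW = t(cache$f) %*% dout,
       db = colSums(dout))
}

row_max <- function(z) {
  m <- z[, 1]
  for (j in seq_len(ncol(z))[-1]) m <- pmax(m, z[, j])
  m
}

# row-wise numerically stable softmax / log-softmax on a logits matrix
softmax_rows <- function(z) {
  z <- z - row_max(z)
  e <- exp(z)
  e / rowSums(e)
}

log_softmax_rows <- function(z) {
  z <- z - row_max(z)
  z - log(rowSums(exp(z)))
}
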