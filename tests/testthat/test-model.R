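test_that("feature extraction obeys the shape contract and configured d_f", {
  net <- accn_network(n_classes = 3, input_size = 16, backbone = c(4L, 8L, 16L),
                      seed = 1)
  x <- random_images(5, S = 16)
  f <- extract_features(x, net)
  expect_equal(dim(f), c(5, 16))
  net64 <- accn_network(n_classes = 2, input_size = 32, backbone = "tiny")
  expect_equal(net64$config$d_f, 64)
  expect_equal(ncol(extract_features(random_images(2, S = 32), net64)), 64)
})

test_that("backbone presets swap behind the same interface", {
  # the 4-block wide preset accepts 16x16 inputs (16 = 2^4) and exposes
  # the same forward contract as the tiny preset
  net <- accn_network(n_classes = 2, input_size = 16, backbone = "wide",
                      seed = 11)
  expect_equal(net$config$d_f, 256)
  p <- predict_probs(random_images(2, S = 16), net)
  expect_equal(dim(p), c(2, 2))
  expect_equal(rowSums(p), c(1, 1), tolerance = 1e-6)
  expect_error(accn_network(n_classes = 2, input_size = 20, backbone = "wide"),
               "divisible")
})

test_that("duplicated images map to identical features and predictions", {
  net <- accn_network(n_classes = 2, input_size = 16, backbone = c(4L, 8L),
                      seed = 2)
  img <- random_images(1, S = 16)
  batch <- array(c(img, img, random_images(1, S = 16, seed = 9)),
                 dim = c(16, 16, 1, 3))
  f <- extract_features(batch, net)
  expect_equal(f[1, ], f[2, ])
  p <- predict_probs(batch, net)
  expect_equal(p[1, ], p[2, ])
})

test_that("predictions live on the probability simplex", {
  net <- accn_network(n_classes = 4, input_size = 16, backbone = c(4L, 8L),
                      seed = 3)
  p <- predict_probs(random_images(7, S = 16), net)
  expect_equal(dim(p), c(7, 4))
  expect_true(all(p > 0 & p < 1))
  expect_equal(rowSums(p), rep(1, 7), tolerance = 1e-6)
})

test_that("an all-zero classifier head predicts the uniform distribution", {
  net <- accn_network(n_classes = 3, input_size = 16, backbone = c(4L, 8L),
                      seed = 4)
  net$params$fc_W[] <- 0
  net$params$fc_b[] <- 0
  p <- predict_probs(random_images(4, S = 16), net)
  expect_equal(p, matrix(1 / 3, 4, 3), tolerance = 1e-12)
})

test_that("a hand-set head with logits (ln 3, 0) predicts (0.75, 0.25)", {
  net <- accn_network(n_classes = 2, input_size = 16, backbone = c(4L, 8L),
                      seed = 5)
  net$params$fc_W[] <- 0
  net$params$fc_b <- c(log(3), 0)
  p <- predict_probs(random_images(3, S = 16), net)
  for (i in 1:3) expect_equal(p[i, ], c(0.75, 0.25), tolerance = 1e-12)
})

test_that("dimension mismatches are rejected with the expected size named", {
  net <- accn_network(n_classes = 2, input_size = 16, backbone = c(4L, 8L))
  expect_error(extract_features(random_images(2, S = 32), net), "16x16x1")
})

test_that("network gradients match finite differences", {
  net <- accn_network(n_classes = 3, input_size = 8, in_channels = 2,
                      backbone = c(3L, 5L), seed = 6)
  s <- rng_stream(10)
  x <- array(r_unif(s, 8 * 8 * 2 * 4), dim = c(8, 8, 2, 4))
  y <- c(0L, 2L, 1L, 1L)
  loss_of <- function(params) {
    net$params <- params
    fw <- accnet:::network_forward(net, x, train = TRUE)
    accnet:::ce_mean(accnet:::log_softmax_rows(fw$logits), y, "t") +
      0.5 * sum(fw$features^2) / nrow(fw$features)
  }
  fw <- accnet:::network_forward(net, x, keep_cache = TRUE, train = TRUE)
  gr <- accnet:::network_backward(
    net, fw$cache,
    dlogits = accnet:::grad_ce_logits(fw$logits, y),
    dfeatures = fw$features / nrow(fw$features))
  eps <- 1e-6
  for (nm in names(net$params)) {
    idx <- r_sample(s, seq_along(net$params[[nm]]),
                    min(4, length(net$params[[nm]])))
    for (i in idx) {
      pp <- net$params
      pp[[nm]][i] <- pp[[nm]][i] + eps
      up <- loss_of(pp)
      pp[[nm]][i] <- pp[[nm]][i] - 2 * eps
      dn <- loss_of(pp)
      fd <- (up - dn) / (2 * eps)
      expect_equal(gr[[nm]][i], fd, tolerance = 1e-4,
                   label = sprintf("grad of %s[%d]", nm, i))
    }
  }
})

test_that("the compiled convolution satisfies the adjoint identity", {
  # <conv(x), y> == <x, conv^T(y)> for random x, y — checks im2col/col2im
  s <- rng_stream(20)
  H <- 6L; W <- 5L; C <- 3L; N <- 2L; Co <- 4L
  xm <- matrix(r_norm(s, C * H * W * N), ncol = C)
  Wm <- matrix(r_norm(s, 9 * C * Co), 9 * C)
  fw <- accnet:::conv_pm_forward(xm, H, W, N, Wm, numeric(Co))
  ym <- matrix(r_norm(s, Co * H * W * N), ncol = Co)
  bw <- accnet:::conv_pm_backward(ym, fw, Wm)
  expect_equal(sum(fw$pre * ym), sum(xm * bw$dx) + 0, tolerance = 1e-10)
})

test_that("checkpoints round-trip the full model state", {
  net <- accn_network(n_classes = 2, input_size = 16, backbone = c(4L, 8L),
                      seed = 7)
  x <- random_images(3, S = 16)
  path <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(list(network = net), path)
  back <- load_checkpoint(path)
  expect_equal(predict_probs(x, back$network), predict_probs(x, net))
})
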