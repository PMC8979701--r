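test_that("soft-weighted centroids match a loop-based oracle on random instances", {
  s <- rng_stream(1)
  for (rep in 1:100) {
    n <- 2 + (rep %% 49)
    d <- 1 + (rep %% 16)
    nc <- 2 + (rep %% 4)
    f <- matrix(r_norm(s, n * d), n, d)
    pr <- matrix(r_unif(s, n * nc), n, nc)
    pr <- pr / rowSums(pr)
    got <- soft_weighted_centroids(f, pr)
    expect_true(all(got$valid))
    expect_equal(got$centroids, centroid_oracle(f, pr), tolerance = 1e-6)
  }
})

test_that("centroid special cases: one-hot means, uniform collapse, worked example", {
  f <- matrix(c(1, 0, 0, 1), 2, 2, byrow = TRUE)
  # worked example: class-0 weights (0.9, 0.1) -> c_0 = (0.9, 0.1)
  pr <- matrix(c(0.9, 0.1, 0.1, 0.9), 2, 2)
  expect_equal(soft_weighted_centroids(f, pr)$centroids[1, ], c(0.9, 0.1))
  # one-hot probabilities degenerate to class means
  f2 <- matrix(r_norm(rng_stream(2), 12), 6, 2)
  y <- c(0, 0, 1, 1, 1, 0)
  onehot <- matrix(0, 6, 2)
  onehot[cbind(1:6, y + 1)] <- 1
  cent <- soft_weighted_centroids(f2, onehot)$centroids
  expect_equal(cent[1, ], colMeans(f2[y == 0, ]))
  expect_equal(cent[2, ], colMeans(f2[y == 1, ]))
  # uniform probabilities make every centroid the global mean
  unif <- matrix(1 / 3, 6, 3)
  cu <- soft_weighted_centroids(f2, unif)$centroids
  for (k in 1:3) expect_equal(cu[k, ], colMeans(f2))
})

test_that("empty classes are flagged and backfilled from memory", {
  f <- matrix(1:4, 2, 2)
  pr <- matrix(c(1, 1, 0, 0), 2, 2)   # class 2 has zero weight
  mem <- matrix(9, 2, 2)
  got <- soft_weighted_centroids(f, pr, memory = mem)
  expect_equal(got$valid, c(TRUE, FALSE))
  expect_equal(got$centroids[2, ], c(9, 9))
  expect_error(soft_weighted_centroids(f[0, , drop = FALSE], pr[0, , drop = FALSE]),
               "empty")
})

test_that("pseudo-label assignment matches the brute-force oracle and documented tie-breaks", {
  s <- rng_stream(3)
  for (rep in 1:100) {
    n <- 1 + (rep %% 50)
    d <- 1 + (rep %% 8)
    nc <- 2 + (rep %% 3)
    f <- matrix(r_norm(s, n * d), n, d)
    cent <- matrix(r_norm(s, nc * d), nc, d)
    expect_equal(assign_pseudolabels(f, cent), assign_oracle(f, cent))
  }
  cent <- matrix(c(0, 0, 2, 0), 2, 2, byrow = TRUE)
  # a feature exactly on a centroid takes its label
  expect_equal(assign_pseudolabels(matrix(c(2, 0), 1), cent), 1L)
  # equidistant features break ties toward the smaller class index
  expect_equal(assign_pseudolabels(matrix(c(1, 5), 1), cent), 0L)
  expect_error(assign_pseudolabels(matrix(1, 1, 2),
                                   matrix(c(NA, 1, 1, 1), 2, 2)), "finite")
})

test_that("assignment is permutation-equivariant in sample order", {
  s <- rng_stream(4)
  f <- matrix(r_norm(s, 40), 20, 2)
  cent <- matrix(r_norm(s, 6), 3, 2)
  lab <- assign_pseudolabels(f, cent)
  perm <- r_sample(s, 20)
  expect_equal(assign_pseudolabels(f[perm, ], cent), lab[perm])
})

test_that("memory updates follow the damped rule eta = exp(-t_k) exactly", {
  st <- centroid_state(2, 2)
  # t_k = 0: full replacement by the local centroid
  st$memory <- matrix(5, 2, 2)
  st$counts <- c(0L, 0L)
  loc <- matrix(c(1, 1, 2, 2), 2, 2, byrow = TRUE)
  st1 <- update_memory(st, loc, c(3L, 4L))
  expect_equal(st1$memory, loc)
  expect_equal(st1$counts, c(3L, 4L))
  # t_k = 1: M' = (1 - e^-1) M + e^-1 c
  st$counts <- c(1L, 1L)
  st$memory <- matrix(0, 2, 2)
  st2 <- update_memory(st, matrix(1, 2, 2), c(0L, 0L))
  expect_equal(st2$memory, matrix(exp(-1), 2, 2), tolerance = 1e-12)
  # t_k = 5
  st$counts <- c(5L, 5L)
  st$memory <- matrix(2, 2, 2)
  st3 <- update_memory(st, matrix(4, 2, 2), c(0L, 0L))
  expect_equal(st3$memory, matrix((1 - exp(-5)) * 2 + exp(-5) * 4, 2, 2),
               tolerance = 1e-12)
  # fixed point: c_k = M_k leaves the memory unchanged for any t_k
  st$counts <- c(2L, 7L)
  st$memory <- matrix(c(1, 2, 3, 4), 2, 2)
  st4 <- update_memory(st, st$memory, c(1L, 1L))
  expect_equal(st4$memory, st$memory)
  expect_error(update_memory(st, st$memory, c(-1L, 0L)), "negative")
})

test_that("the memory update is a contraction toward the local centroid", {
  s <- rng_stream(5)
  for (rep in 1:25) {
    st <- centroid_state(3, 4)
    st$memory <- matrix(r_norm(s, 12), 3, 4)
    st$counts <- as.integer(floor(r_unif(s, 3, 0, 10)))
    loc <- matrix(r_norm(s, 12), 3, 4)
    st2 <- update_memory(st, loc, c(1L, 1L, 1L))
    for (k in 1:3) {
      expect_lte(sqrt(sum((st2$memory[k, ] - loc[k, ])^2)),
                 sqrt(sum((st$memory[k, ] - loc[k, ])^2)) + 1e-12)
      # the new memory lies on the segment between old memory and centroid
      seg <- st2$memory[k, ] - st$memory[k, ]
      dir <- loc[k, ] - st$memory[k, ]
      expect_equal(seg, exp(-st$counts[k]) * dir, tolerance = 1e-10)
    }
  }
  # eta decreases strictly in t_k
  etas <- exp(-(0:10))
  expect_true(all(diff(etas) < 0))
})

test_that("confidence pseudo-labels threshold the softmax argmax", {
  pr <- rbind(c(0.96, 0.04), c(0.6, 0.4), c(0.5, 0.5))
  got <- confidence_pseudolabels(pr, 0.95)
  expect_equal(got$labels, c(0L, 0L, 0L))
  expect_equal(got$keep, c(TRUE, FALSE, FALSE))
  expect_error(confidence_pseudolabels(pr, 1), "threshold")
  expect_error(confidence_pseudolabels(pr, 0), "threshold")
})

test_that("one clustering round denoises a weak classifier on separated clusters", {
  # 3 Gaussian clusters 6 sd apart; input labels only 70% accurate
  d <- 8
  for (seed in 1:5) {
    s <- rng_stream(seed)
    mu <- matrix(0, 3, d)
    mu[2, 1] <- 6
    mu[3, 2] <- 6
    y <- rep(0:2, each = 100)
    f <- mu[y + 1, ] + matrix(r_norm(s, 300 * d), 300, d)
    noisy <- y
    flip <- r_sample(s, 300, 90)
    noisy[flip] <- (y[flip] + ifelse(r_unif(s, 90) < 0.5, 1, 2)) %% 3
    input_acc <- mean(noisy == y)
    probs <- matrix(0.1, 300, 3)
    probs[cbind(1:300, noisy + 1)] <- 0.8
    cent <- soft_weighted_centroids(f, probs)$centroids
    out <- assign_pseudolabels(f, cent)
    expect_gt(mean(out == y), input_acc)
  }
})
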