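test_that("perfect predictions give unit metrics and exact confusion counts", {
  r <- confusion_and_metrics(c(0, 1, 1, 0), c(0, 1, 1, 0))
  expect_equal(r$acc, 1)
  expect_equal(r$sen, 1)
  expect_equal(r$spe, 1)
  expect_equal(sum(r$confusion), 4)
})

test_that("a 600-sample instance with 279 + 261 correct computes 90.0% accuracy", {
  truth <- rep(c(1L, 0L), each = 300)
  pred <- truth
  pred[1:21] <- 0L            # 21 missed abnormals
  pred[301:339] <- 1L         # 39 false alarms
  r <- confusion_and_metrics(pred, truth, positive_class = 1)
  expect_equal(r$confusion[2, 2], 279L)
  expect_equal(r$confusion[1, 1], 261L)
  expect_equal(r$acc, 540 / 600)
  expect_equal(r$sen, 279 / 300)
  expect_equal(r$spe, 261 / 300)
  # binary identity ACC = (SEN n_pos + SPE n_neg) / n
  expect_equal(r$acc, (r$sen * 300 + r$spe * 300) / 600)
})

test_that("metrics match a pair-counting oracle on random instances", {
  s <- rng_stream(1)
  for (rep in 1:100) {
    nc <- 2 + (rep %% 3)
    truth <- as.integer(floor(r_unif(s, 100, 0, nc)))
    pred <- as.integer(floor(r_unif(s, 100, 0, nc)))
    pos <- rep %% nc
    r <- confusion_and_metrics(pred, truth, n_classes = nc, positive_class = pos)
    expect_equal(r$acc, mean(pred == truth))
    if (any(truth == pos))
      expect_equal(r$sen, mean(pred[truth == pos] == pos))
    if (any(truth != pos))
      expect_equal(r$spe, mean(pred[truth != pos] != pos))
    for (a in 0:(nc - 1)) for (b in 0:(nc - 1))
      expect_equal(r$confusion[a + 1, b + 1], sum(truth == a & pred == b))
  }
})

test_that("degenerate metric cases are NA or errors, never silent zeros", {
  expect_error(confusion_and_metrics(c(0, 1), c(0, 1, 1)), "mismatch")
  r <- confusion_and_metrics(c(0L, 0L), c(0L, 0L), n_classes = 2)
  expect_true(is.na(r$sen))   # no positives present
  expect_equal(r$spe, 1)
})

test_that("the confusion matrix is permutation-equivariant under relabeling", {
  s <- rng_stream(2)
  truth <- as.integer(floor(r_unif(s, 80, 0, 3)))
  pred <- as.integer(floor(r_unif(s, 80, 0, 3)))
  r1 <- confusion_and_metrics(pred, truth, n_classes = 3)
  perm <- c(2L, 0L, 1L)
  r2 <- confusion_and_metrics(perm[pred + 1], perm[truth + 1], n_classes = 3)
  expect_equal(unname(r2$confusion[perm + 1, perm + 1]), unname(r1$confusion))
})

test_that("AUC equals the Mann-Whitney statistic and honours its invariances", {
  s <- rng_stream(3)
  for (rep in 1:100) {
    n <- 20 + (rep %% 30)
    y <- as.integer(r_unif(s, n) < 0.4)
    if (sum(y) == 0 || sum(y) == n) next
    sc <- round(r_norm(s, n), 2)  # rounding induces ties
    a <- auc_score(sc, y)
    w <- suppressWarnings(stats::wilcox.test(sc[y == 1], sc[y == 0]))
    expect_equal(a, unname(w$statistic) / (sum(y) * sum(1 - y)),
                 tolerance = 1e-12)
    # invariance under strictly monotone transforms
    expect_equal(auc_score(exp(2 * sc), y), a)
  }
  # perfectly separating scores
  expect_equal(auc_score(c(1, 2, 3, 10, 11), c(0, 0, 0, 1, 1)), 1)
  expect_error(auc_score(1:3, c(1, 1, 1)), "both classes")
})

test_that("AUC on independent scores concentrates near one half", {
  s <- rng_stream(4)
  y <- as.integer(r_unif(s, 2000) < 0.5)
  sc <- r_norm(s, 2000)
  expect_lt(abs(auc_score(sc, y) - 0.5), 0.03)
})

test_that("our ROC/AUC agree with pROC as an independent reference", {
  s <- rng_stream(5)
  y <- as.integer(r_unif(s, 300) < 0.5)
  sc <- r_norm(s, 300) + y
  ours <- auc_score(sc, y)
  theirs <- as.numeric(pROC::auc(pROC::roc(y, sc, quiet = TRUE,
                                           direction = "<")))
  expect_equal(ours, theirs, tolerance = 1e-12)
})

test_that("ROC points form a monotone staircase from (0,0) to (1,1)", {
  s <- rng_stream(6)
  y <- as.integer(r_unif(s, 150) < 0.3)
  sc <- round(r_norm(s, 150) + 0.8 * y, 1)
  roc <- roc_curve(sc, y)
  expect_equal(roc$fpr[1], 0)
  expect_equal(roc$tpr[1], 0)
  expect_equal(roc$fpr[nrow(roc)], 1)
  expect_equal(roc$tpr[nrow(roc)], 1)
  expect_true(all(diff(roc$fpr) >= 0))
  expect_true(all(diff(roc$tpr) >= 0))
  # trapezoid under the staircase equals the midrank AUC
  area <- sum(diff(roc$fpr) * (head(roc$tpr, -1) + tail(roc$tpr, -1)) / 2)
  expect_equal(area, auc_score(sc, y), tolerance = 1e-12)
})

test_that("evaluate_model produces a full binary report from a network", {
  net <- accn_network(n_classes = 2, input_size = 16, backbone = c(4L, 8L),
                      seed = 8)
  ts <- tiny_labeled_set(n_per = 10)
  r <- evaluate_model(net, ts$x, ts$y)
  expect_s3_class(r, "eval_report")
  expect_equal(sum(r$confusion), 20)
  expect_true(r$auc >= 0 && r$auc <= 1)
  expect_false(is.null(r$roc_points))
  g <- glance(r)
  expect_equal(g$n, 20)
})
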