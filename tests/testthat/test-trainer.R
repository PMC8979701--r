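test_that("with no unlabeled data and zero gammas the trainer equals the supervised loop exactly", {
  ts <- tiny_labeled_set(n_per = 6, seed = 3)
  cfg <- tiny16_config(epochs = 2, batch_size = 4, gammas = c(0, 0, 0), seed = 21)
  fit_a <- accn_train(ts, NULL, cfg)
  fit_b <- supervised_baseline(ts, cfg)
  expect_equal(fit_a$history, fit_b$history)
  expect_equal(fit_a$network$params, fit_b$network$params)
  expect_equal(fit_a$network$bn_stats, fit_b$network$bn_stats)
})

test_that("training history is bit-reproducible under a fixed seed", {
  ts <- tiny_labeled_set(n_per = 5, seed = 4)
  un <- list(x = tiny_labeled_set(n_per = 8, seed = 5)$x)
  cfg <- tiny16_config(epochs = 2, batch_size = 4, warmup_epochs = 1, seed = 33)
  f1 <- accn_train(ts, un, cfg)
  f2 <- accn_train(ts, un, cfg)
  expect_identical(f1$history, f2$history)
  expect_equal(f1$network$params, f2$network$params)
  # a different seed gives a different trajectory
  cfg2 <- tiny16_config(epochs = 2, batch_size = 4, warmup_epochs = 1, seed = 34)
  f3 <- accn_train(ts, un, cfg2)
  expect_false(isTRUE(all.equal(f1$history$total, f3$history$total)))
})

test_that("checkpoint save/reload/continue reproduces an uninterrupted run", {
  ts <- tiny_labeled_set(n_per = 5, seed = 6)
  un <- list(x = tiny_labeled_set(n_per = 8, seed = 7)$x)
  cfg2 <- tiny16_config(epochs = 2, batch_size = 4, warmup_epochs = 1, seed = 55)
  cfg4 <- tiny16_config(epochs = 4, batch_size = 4, warmup_epochs = 1, seed = 55)
  full <- accn_train(ts, un, cfg4)
  half <- accn_train(ts, un, cfg2)
  path <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(half, path)
  resumed <- accn_train(ts, un, cfg2, resume = load_checkpoint(path))
  expect_equal(resumed$history, full$history, tolerance = 1e-12)
  expect_equal(resumed$network$params, full$network$params, tolerance = 1e-12)
})

test_that("the full objective is assembled from all four terms after warm-up", {
  ts <- tiny_labeled_set(n_per = 5, seed = 8)
  un <- list(x = tiny_labeled_set(n_per = 10, seed = 9)$x)
  cfg <- tiny16_config(epochs = 3, batch_size = 4, warmup_epochs = 1, seed = 66)
  fit <- accn_train(ts, un, cfg)
  h <- fit$history
  warm <- h[h$epoch == 1, ]
  late <- h[h$epoch > 1, ]
  expect_true(all(warm$l_pce == 0) && all(warm$l_gc == 0))
  expect_true(any(late$l_pce > 0))
  expect_true(all(h$l_ac > 0))
  g <- cfg$gammas
  expect_equal(h$total, h$l_lce + g[1] * h$l_ac + g[2] * h$l_gc + g[3] * h$l_pce)
  expect_true(all(h[, c("l_lce", "l_ac", "l_gc", "l_pce")] >= 0))
})

test_that("ablation flags change the loss structure as documented", {
  ts <- tiny_labeled_set(n_per = 5, seed = 10)
  un <- list(x = tiny_labeled_set(n_per = 8, seed = 11)$x)
  no_acl <- accn_train(ts, un, tiny16_config(epochs = 2, batch_size = 4,
                                             warmup_epochs = 1, seed = 77,
                                             disable_acl = TRUE))
  expect_true(all(no_acl$history$l_ac == 0))
  no_wcu <- accn_train(ts, un, tiny16_config(epochs = 2, batch_size = 4,
                                             warmup_epochs = 1, seed = 77,
                                             disable_wcu = TRUE))
  expect_true(all(no_wcu$history$l_gc == 0))
})

test_that("run_ablation sweeps produce one metrics row per point and reject unknown variants", {
  spec <- synthetic_spec(n_labeled_per_class = 4, n_unlabeled_per_class = 6,
                         image_size = 16, seed = 12)
  cfg <- tiny16_config(epochs = 1, batch_size = 4, warmup_epochs = 0, seed = 88)
  tab <- run_ablation("label_budget", spec = spec, config = cfg,
                      budgets = c(4, 8), n_eval_per_class = 5)
  expect_equal(nrow(tab), 2)
  expect_equal(tab$sweep, c(4, 8))
  expect_true(all(c("variant", "acc", "sen", "spe", "auc") %in% names(tab)))
  expect_true(all(tab$acc >= 0 & tab$acc <= 1))
  expect_error(run_ablation("no_such_thing", spec = spec, config = cfg),
               "unknown ablation variant")
  tabp <- run_ablation("positive_fraction", spec = spec, config = cfg,
                       fractions = 0.25, n_eval_per_class = 5)
  expect_equal(tabp$sweep, 0.25)
})

test_that("trainer rejects empty or incomplete labeled sets", {
  expect_error(accn_train(NULL, NULL, tiny16_config()), "labeled")
  one_class <- list(x = random_images(4, S = 16), y = rep(0L, 4))
  expect_error(accn_train(one_class, NULL, tiny16_config(n_classes = 2)),
               "every class")
})

test_that("broom tidiers and autoplot summarise a fit", {
  ts <- tiny_labeled_set(n_per = 5, seed = 13)
  cfg <- tiny16_config(epochs = 2, batch_size = 4, seed = 99)
  fit <- supervised_baseline(ts, cfg, eval_data = ts)
  td <- tidy(fit)
  expect_true(all(c("epoch", "step", "term", "value") %in% names(td)))
  expect_equal(nrow(td), 5 * nrow(fit$history))
  gl <- glance(fit)
  expect_equal(nrow(gl), 1)
  expect_true(is.finite(gl$final_total_loss))
  p <- autoplot(fit)
  expect_s3_class(p, "ggplot")
})
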