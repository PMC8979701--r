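test_that("generation returns exactly the requested counts per class", {
  ds <- generate_dataset(synthetic_spec(n_classes = 2, n_labeled_per_class = 10,
                                        n_unlabeled_per_class = 50, seed = 3))
  expect_equal(length(ds$labeled$y), 20)
  expect_equal(length(ds$unlabeled$y_true), 100)
  expect_equal(unname(table(ds$labeled$y)), c(10L, 10L), ignore_attr = TRUE)
  expect_equal(unname(table(ds$unlabeled$y_true)), c(50L, 50L), ignore_attr = TRUE)
  expect_equal(dim(ds$labeled$x), c(32, 32, 1, 20))

  ds3 <- generate_dataset(synthetic_spec(n_classes = 3, n_labeled_per_class = 4,
                                         n_unlabeled_per_class = 7, seed = 3))
  expect_equal(length(ds3$labeled$y), 12)
  expect_equal(length(ds3$unlabeled$y_true), 21)
})

test_that("generation is bit-identical under the same spec", {
  spec <- synthetic_spec(n_labeled_per_class = 5, n_unlabeled_per_class = 8,
                         seed = 42)
  a <- generate_dataset(spec)
  b <- generate_dataset(spec)
  expect_identical(a$labeled$x, b$labeled$x)
  expect_identical(a$unlabeled$x, b$unlabeled$x)
  # a different seed produces different pixels
  c <- generate_dataset(synthetic_spec(n_labeled_per_class = 5,
                                       n_unlabeled_per_class = 8, seed = 43))
  expect_false(identical(a$labeled$x, c$labeled$x))
})

test_that("pixel intensities are 8-bit quantised values in [0,1]", {
  ds <- generate_dataset(synthetic_spec(n_labeled_per_class = 3,
                                        n_unlabeled_per_class = 3, seed = 1))
  expect_true(all(ds$labeled$x >= 0 & ds$labeled$x <= 1))
  expect_equal(ds$labeled$x, round(ds$labeled$x * 255) / 255)
})

test_that("nearest-class-mean accuracy is at chance at separation 0 and grows with separation", {
  accs <- vapply(c(0, 2, 6), function(sep) {
    nearest_mean_accuracy(generate_dataset(
      synthetic_spec(separation = sep, n_labeled_per_class = 10,
                     n_unlabeled_per_class = 100, seed = 7)))
  }, numeric(1))
  expect_lt(abs(accs[1] - 0.5), 0.12)        # chance for 2 classes
  expect_true(all(diff(accs) >= -0.02))       # monotone up to sampling noise
  expect_gt(accs[3], accs[1] + 0.2)           # clearly separable at 6 sd
})

test_that("positive fraction controls the unlabeled class balance in binary mode", {
  ds <- generate_dataset(synthetic_spec(n_unlabeled_per_class = 100,
                                        positive_fraction_unlabeled = 0.25,
                                        seed = 2))
  expect_equal(length(ds$unlabeled$y_true), 200)
  expect_equal(sum(ds$unlabeled$y_true == 1), 50)
})

test_that("invalid specs fail naming the offending field", {
  expect_error(synthetic_spec(n_classes = 1), "n_classes")
  expect_error(synthetic_spec(image_size = 4), "image_size")
  expect_error(synthetic_spec(noise_sd = 0), "noise_sd")
  expect_error(synthetic_spec(n_labeled_per_class = -1), "n_labeled_per_class")
  expect_error(synthetic_spec(separation = -2), "separation")
  expect_error(synthetic_spec(positive_fraction_unlabeled = 1.5),
               "positive_fraction_unlabeled")
  expect_error(synthetic_spec(n_classes = 3, positive_fraction_unlabeled = 0.5),
               "positive_fraction_unlabeled")
})

test_that("write_manifest writes PNGs, a -1-coded manifest and a separate truth file", {
  dir <- withr::local_tempdir()
  ds <- generate_dataset(synthetic_spec(n_labeled_per_class = 10,
                                        n_unlabeled_per_class = 50, seed = 5))
  man <- write_manifest(ds, dir)
  expect_equal(nrow(man), 120)
  expect_equal(sum(man$label == -1), 100)
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  truth <- utils::read.csv(file.path(dir, "truth.csv"))
  expect_equal(nrow(truth), 100)
  # hidden truths never leak into the training manifest
  expect_false("true_label" %in% names(man))
})

test_that("a written dataset round-trips exactly through the reader", {
  dir <- withr::local_tempdir()
  ds <- generate_dataset(synthetic_spec(n_labeled_per_class = 4,
                                        n_unlabeled_per_class = 6, seed = 9))
  write_manifest(ds, dir)
  back <- load_dataset(file.path(dir, "manifest.csv"))
  expect_equal(back$labeled$y, ds$labeled$y)
  expect_equal(back$labeled$x, ds$labeled$x)
  expect_equal(back$unlabeled$x, ds$unlabeled$x)
})

test_that("an empty dataset yields a header-only manifest", {
  dir <- withr::local_tempdir()
  ds <- generate_dataset(synthetic_spec(n_labeled_per_class = 0,
                                        n_unlabeled_per_class = 0, seed = 1))
  man <- write_manifest(ds, dir)
  expect_equal(nrow(man), 0)
  lines <- readLines(file.path(dir, "manifest.csv"))
  expect_equal(length(lines), 1)
})
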