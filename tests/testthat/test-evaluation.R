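test_that("confusion counts follow the positive = fractured convention", {
  c1 <- confusion(c(1, 1, 0), c(1, 1, 0))
  expect_identical(unname(unlist(c1)), c(2L, 0L, 0L, 1L))
  c2 <- confusion(c(1, 1), c(1, 0))
  expect_identical(c2$tp, 1L)
  expect_identical(c2$fp, 1L)
  expect_error(confusion(c(1, 0), c(1)), "equal length")
  expect_error(confusion(c(1, 2), c(1, 0)), "0/1")
})

test_that("confusion matches a brute-force cell enumeration on random pairs", {
  set.seed(7)
  for (rep in 1:5) {
    pred <- rbinom(50, 1, 0.6)
    truth <- rbinom(50, 1, 0.5)
    got <- confusion(pred, truth)
    oracle <- brute_force_confusion(pred, truth)
    expect_identical(
      c(tp = got$tp, fp = got$fp, fn = got$fn, tn = got$tn), oracle
    )
  }
})

test_that("the four metrics reproduce their defining formulas", {
  perfect <- classification_metrics(tibble::tibble(tp = 97, fp = 0, fn = 0, tn = 48))
  expect_identical(perfect$accuracy, 1)
  expect_identical(perfect$f1, 1)

  m <- classification_metrics(tibble::tibble(tp = 3, fp = 1, fn = 1, tn = 5))
  expect_equal(m$accuracy, 0.8)
  expect_equal(m$precision, 0.75)
  expect_equal(m$recall, 0.75)
  expect_equal(m$f1, 0.75)

  none_pos <- classification_metrics(tibble::tibble(tp = 0, fp = 0, fn = 3, tn = 5))
  expect_true(is.na(none_pos$precision))
  expect_identical(none_pos$recall, 0)
  expect_true(is.na(none_pos$f1))

  expect_error(classification_metrics(tibble::tibble(tp = 0, fp = 0, fn = 0, tn = 0)),
               "positive total")
})

test_that("metrics agree with an independent implementation on random tables", {
  set.seed(123)
  for (i in 1:1000) {
    cells <- as.integer(rmultinom(1, sample(1:200, 1), prob = runif(4, 0.05, 1)))
    got <- classification_metrics(
      tibble::tibble(tp = cells[1], fp = cells[2], fn = cells[3], tn = cells[4])
    )
    want <- independent_metrics(cells[1], cells[2], cells[3], cells[4])
    expect_equal(got$accuracy, unname(want["accuracy"]))
    expect_equal(got$precision, unname(want["precision"]))
    expect_equal(got$recall, unname(want["recall"]))
    expect_equal(got$f1, unname(want["f1"]))
    # harmonic mean never exceeds the arithmetic mean
    if (!is.na(got$f1)) {
      expect_lte(got$f1, (got$precision + got$recall) / 2 + 1e-12)
    }
  }
})

test_that("leave-one-out visits every record exactly once as the test case", {
  d <- tiny_dataset(2L, 2L, seed = 8L)
  r <- loocv(d, quick_spec("nnn", epochs = 3L))
  expect_identical(r$n_folds, 4L)
  expect_identical(sort(r$folds$fold), 1:4)
  expect_identical(r$train_size, 3L)

  # a singleton minority class cannot be left out: that fold is skipped with
  # a warning and the effective fold count says so
  d3 <- tiny_dataset(2L, 1L, seed = 8L)
  expect_warning(r3 <- loocv(d3, quick_spec("nnn", epochs = 3L)), "single-class")
  expect_identical(r3$n_folds, 2L)
  expect_identical(r3$skipped, which(d3$fractured == 0))

  d2 <- tiny_dataset(9L, 6L, seed = 8L)
  r2 <- loocv(d2, quick_spec("two_way", epochs = 5L))
  expect_identical(sort(r2$folds$fold), 1:15)
  expect_identical(r2$folds$truth, as.integer(d2$fractured))
  expect_error(loocv(d2[1:2, ], quick_spec()), "at least 3")
})

test_that("pooled accuracy equals the mean of per-fold accuracies", {
  d <- tiny_dataset(8L, 5L, seed = 21L)
  r <- loocv(d, quick_spec("ann", epochs = 8L))
  per_fold <- as.numeric(r$folds$estimate == r$folds$truth)
  expect_equal(r$metrics$accuracy, mean(per_fold))
})

test_that("a constant positive predictor scores the majority proportion on 97/48", {
  d <- read_dataset(study_fixture_path())
  # decision threshold 0 turns any model into the constant fractured predictor
  spec <- quick_spec("nnn", epochs = 1L, decision_threshold = 0)
  r <- loocv(d, spec)
  expect_identical(r$counts$tp, 97L)
  expect_identical(r$counts$fp, 48L)
  expect_equal(r$metrics$accuracy, 97 / 145)
  expect_identical(r$metrics$recall, 1)
})

test_that("leave-one-out runs are reproducible and seed-sensitive", {
  d <- tiny_dataset(8L, 5L, seed = 13L)
  r1 <- loocv(d, quick_spec("tsfnn", epochs = 6L, seed = 5L))
  r2 <- loocv(d, quick_spec("tsfnn", epochs = 6L, seed = 5L))
  expect_identical(r1$folds, r2$folds)
  r3 <- loocv(d, quick_spec("tsfnn", epochs = 6L, seed = 6L))
  expect_false(identical(r1$folds$prob, r3$folds$prob))
})

test_that("global preprocessing scope fits artifacts once outside the loop", {
  d <- tiny_dataset(8L, 5L, seed = 17L)
  r <- loocv(d, quick_spec("tsfnn", epochs = 5L), preprocess_scope = "global")
  expect_identical(r$preprocess_scope, "global")
  expect_identical(r$n_folds, 13L)
})

test_that("comparison tables carry model rows plus improvement rows", {
  d <- tiny_dataset(10L, 6L, seed = 19L)
  specs <- list(
    quick_spec("tsfnn", epochs = 6L, use_batch_norm = FALSE),
    quick_spec("tsfnn", epochs = 6L)
  )
  cmp <- compare_models(d, specs, names = c("tsfnn", "tsfnn+bn"))
  expect_identical(nrow(cmp), 3L)
  expect_identical(cmp$row, c("model", "model", "improvement"))
  expect_equal(
    cmp$accuracy[3], cmp$accuracy[2] - cmp$accuracy[1]
  )
  expect_identical(nrow(attr(cmp, "manifest")), 2L)

  # a spec compared with itself improves by exactly zero
  same <- compare_models(d, list(specs[[2]], specs[[2]]))
  expect_identical(same$accuracy[3], 0)
  expect_identical(same$f1[3], 0)

  f <- withr::local_tempfile()
  write_comparison(cmp, f)
  expect_true(file.exists(paste0(f, ".csv")))
  expect_true(file.exists(paste0(f, ".json")))
  expect_error(compare_models(d, specs[1]), "at least two")
})

test_that("result objects tidy, glance and plot", {
  d <- tiny_dataset(8L, 5L, seed = 23L)
  r <- loocv(d, quick_spec("cnn", epochs = 5L))
  td <- tidy(r)
  expect_identical(names(td), c("fold", "truth", "estimate", "prob"))
  g <- glance(r)
  expect_identical(g$n_folds, 13L)
  expect_s3_class(autoplot(r), "gg")

  cmp <- compare_models(d, list(quick_spec("nnn", epochs = 4L),
                                quick_spec("two_way", epochs = 4L)))
  expect_s3_class(autoplot(cmp), "gg")
})
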