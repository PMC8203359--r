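test_that("dataset splitting uses largest-remainder sizes and is seeded", {
  sp <- split_dataset(104, seed = 1)
  expect_equal(lengths(sp), c(train = 71L, validation = 15L, test = 18L))

  sp10 <- split_dataset(10, seed = 2)
  expect_equal(lengths(sp10), c(train = 7L, validation = 1L, test = 2L))

  all_idx <- sort(unname(unlist(sp)))
  expect_equal(all_idx, 1:104)            # disjoint cover
  expect_identical(split_dataset(104, seed = 7), split_dataset(104, seed = 7))
  expect_false(identical(split_dataset(104, seed = 7)$test,
                         split_dataset(104, seed = 8)$test))
  expect_error(split_dataset(2), "at least 3")
})

make_separable <- function(n_t1 = 8, n_t2 = 12, seed = 1) {
  set.seed(seed)
  x <- c(lapply(seq_len(n_t1), function(i) rnorm(40, sd = 1) + c(rep(0, 20), rep(6, 20))),
         lapply(seq_len(n_t2), function(i) rnorm(40, sd = 1)))
  list(x = x, y = c(rep("T1", n_t1), rep("T2", n_t2)))
}

test_that("the threshold detector separates separable features perfectly", {
  d <- make_separable()
  sp <- split_dataset(20, seed = 3)
  det <- fit_detector(d$x[sp$train], d$y[sp$train],
                      d$x[sp$validation], d$y[sp$validation])
  expect_equal(det$val_accuracy, 1)
  expect_equal(evaluate_detector(det, d$x[sp$test], d$y[sp$test]), 1)

  expect_error(
    fit_detector(d$x[d$y == "T2"], d$y[d$y == "T2"],
                 d$x[sp$validation], d$y[sp$validation]),
    "single-class")
})

test_that("detector training and prediction are deterministic given a seed", {
  d <- make_separable(seed = 5)
  sp <- split_dataset(20, seed = 4)
  for (backend in c("threshold", "recurrent")) {
    cfg <- detector_config(backend = backend, seed = 11, input_length = 40L,
                           epochs = 15L)
    det1 <- fit_detector(d$x[sp$train], d$y[sp$train],
                         d$x[sp$validation], d$y[sp$validation], cfg)
    det2 <- fit_detector(d$x[sp$train], d$y[sp$train],
                         d$x[sp$validation], d$y[sp$validation], cfg)
    expect_identical(predict(det1, d$x[sp$test]), predict(det2, d$x[sp$test]))
  }
})

test_that("the recurrent backend learns a mean-shift sequence problem", {
  d <- make_separable(n_t1 = 12, n_t2 = 12, seed = 6)
  sp <- split_dataset(24, seed = 5)
  cfg <- detector_config(backend = "recurrent", seed = 1, input_length = 40L,
                         epochs = 40L)
  det <- fit_detector(d$x[sp$train], d$y[sp$train],
                      d$x[sp$validation], d$y[sp$validation], cfg)
  expect_gte(evaluate_detector(det, d$x[sp$test], d$y[sp$test]), 0.75)
})

test_that("evaluation is the fraction of correct labels", {
  d <- make_separable()
  sp <- split_dataset(20, seed = 3)
  det <- fit_detector(d$x[sp$train], d$y[sp$train],
                      d$x[sp$validation], d$y[sp$validation])

  # a constant-label rule on a 7 T1 / 11 T2 test set scores 11/18
  const_det <- det
  const_det$cutoff <- Inf                 # always predicts T2
  y_test <- c(rep("T1", 7), rep("T2", 11))
  x_test <- make_separable(7, 11, seed = 9)$x
  expect_equal(evaluate_detector(const_det, x_test, y_test), 11 / 18)

  # accuracy agrees with an elementwise-comparison oracle
  pred <- predict(det, x_test)
  expect_equal(evaluate_detector(det, x_test, y_test),
               1 - sum(pred != y_test) / length(y_test))
  expect_error(evaluate_detector(det, list(), character(0)), "empty test set")

  # accuracy is invariant to recording order
  perm <- sample(length(y_test))
  expect_equal(evaluate_detector(det, x_test[perm], y_test[perm]),
               evaluate_detector(det, x_test, y_test))
})

test_that("the window-size experiment is reproducible and covers all sizes", {
  d <- make_separable(n_t1 = 10, n_t2 = 14, seed = 8)
  feats <- list(features = list(`150` = d$x, `650` = d$x), labels = d$y)
  ex1 <- window_size_experiment(feats, repeats = 3, seed = 2)
  ex2 <- window_size_experiment(feats, repeats = 3, seed = 2)
  expect_identical(ex1, ex2)
  expect_equal(sort(ex1$summary$window_size), c(150L, 650L))
  expect_true(all(ex1$detail$accuracy >= 0 & ex1$detail$accuracy <= 1))
  expect_equal(nrow(ex1$detail), 6L)      # 2 sizes x 3 repeats
})

test_that("the raw-tachogram baseline is reproducible on a small dataset", {
  ds <- generate_dataset(n_t1 = 4L, n_t2 = 6L,
                         cfg = synth_config(duration_s = 120, event_time_s = 60), seed = 3,
                         event_jitter_s = 20)
  cfg <- detector_config(backend = "recurrent", seed = 2, input_length = 120L,
                         epochs = 10L)
  b1 <- raw_baseline(ds, cfg, repeats = 2, seed = 5, ratios = c(6, 2, 2))
  b2 <- raw_baseline(ds, cfg, repeats = 2, seed = 5, ratios = c(6, 2, 2))
  expect_identical(b1, b2)
  expect_true(b1$mean_accuracy >= 0 && b1$mean_accuracy <= 1)
})
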