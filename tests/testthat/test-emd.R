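test_that("local extrema match inspection, monotone inputs and a brute-force scan", {
  e <- find_local_extrema(c(0, 1, 0, -1, 0, 1, 0))
  expect_equal(e$maxima, c(2L, 6L))
  expect_equal(e$minima, 4L)

  mono <- find_local_extrema(1:20)
  expect_length(mono$maxima, 0L)
  expect_length(mono$minima, 0L)

  set.seed(5)
  walk <- cumsum(rnorm(10000))
  expect_equal(find_local_extrema(walk), brute_extrema(walk))
})

test_that("flat plateaus contribute their midpoint index once", {
  # plateau of 1s at indices 3:5 flanked by lower values -> one maximum at 4
  e <- find_local_extrema(c(0, 0.5, 1, 1, 1, 0.5, 0))
  expect_equal(e$maxima, 4L)
  # even-length plateau at 3:4 -> lower median index 3
  e2 <- find_local_extrema(c(0, 0.5, 1, 1, 0.5, 0))
  expect_equal(e2$maxima, 3L)
})

test_that("envelope mean of a symmetric tone is near zero, offsets pass through", {
  s <- tone_series(0.2, 60, fs = 8)
  m <- envelope_mean(s)
  n <- length(m$values)
  interior <- seq(floor(n * 0.1), ceiling(n * 0.9))
  expect_lt(max(abs(m$values[interior])), 0.05)

  s5 <- uniform_series(s$values + 5, fs = 8)
  m5 <- envelope_mean(s5)
  expect_lt(max(abs(m5$values[interior] - 5)), 0.05)
})

test_that("envelope mean is defined on the full grid with minimal extrema", {
  # 2 maxima and 2 minima exactly: 2.5 periods of a slow tone
  t <- seq(0, 2.5, by = 1 / 32)
  s <- uniform_series(sin(2 * pi * t), fs = 32)
  m <- envelope_mean(s)
  expect_length(m$values, length(s$values))
  expect_true(all(is.finite(m$values)))
})

test_that("a sifting pass subtracts exactly the envelope mean", {
  set.seed(9)
  h <- uniform_series(cumsum(rnorm(500)), fs = 8)
  expect_equal(sift_once(h)$values, h$values - envelope_mean(h)$values)

  # a near-symmetric oscillation is close to a fixed point
  s <- tone_series(0.25, 120, fs = 8)
  h1 <- extract_imf(s)
  n <- length(s$values)
  interior <- seq(floor(n * 0.1), ceiling(n * 0.9))
  expect_gt(cor(h1$values[interior], s$values[interior]), 0.99)
})

test_that("extracted modes satisfy the extrema/zero-crossing property on most signals", {
  set.seed(21)
  ok <- 0L; total <- 0L
  for (i in 1:20) {
    v <- 900 + 30 * sin(2 * pi * 0.25 * seq(0, 150, by = 1 / 8) + runif(1, 0, 6)) +
      40 * sin(2 * pi * 0.07 * seq(0, 150, by = 1 / 8) + runif(1, 0, 6)) +
      rnorm(1201, sd = 4)
    d <- emd_decompose(uniform_series(v, fs = 8))
    for (k in seq_len(n_imfs(d))) {
      imf <- d$imfs[, k]
      total <- total + 1L
      if (abs(count_extrema(imf) - zero_crossings(imf)) <= 1L) ok <- ok + 1L
    }
  }
  expect_gte(ok / total, 0.95)
})

test_that("decomposition handles constants, separates tones and reconstructs", {
  # constant input: no extrema, zero modes, residue = input
  const <- uniform_series(rep(3, 64), fs = 8)
  d0 <- emd_decompose(const)
  expect_equal(n_imfs(d0), 0L)
  expect_equal(d0$residue, const$values)

  t <- seq(0, 600, by = 1 / 8)
  s <- uniform_series(sin(2 * pi * 0.25 * t) + 0.5 * sin(2 * pi * 0.05 * t),
                      fs = 8)
  d <- emd_decompose(s)
  expect_gte(n_imfs(d), 2L)
  doms <- vapply(seq_len(n_imfs(d)), function(i) {
    dominant_frequency(imf_spectrum(imf_series(d, i)))
  }, numeric(1))
  expect_true(doms[1] >= 0.2 && doms[1] <= 0.3)
  expect_true(any(doms[-1] >= 0.04 & doms[-1] <= 0.06))
  expect_lte(reconstruction_error(d, s), 1e-8)

  expect_error(emd_decompose(uniform_series(rnorm(8), fs = 8)), "too short")
})

test_that("completeness and mode ordering hold across random signals", {
  set.seed(33)
  for (i in 1:8) {
    v <- 900 + 25 * sin(2 * pi * runif(1, 0.2, 0.35) * seq(0, 200, 1 / 8)) +
      35 * sin(2 * pi * runif(1, 0.05, 0.1) * seq(0, 200, 1 / 8)) +
      rnorm(1601, sd = 5)
    s <- uniform_series(v, fs = 8)
    d <- emd_decompose(s)
    expect_lte(reconstruction_error(d, s), 1e-8)
    # zero-crossing rate non-increasing from mode to mode
    zc <- vapply(seq_len(n_imfs(d)), function(k) zero_crossings(d$imfs[, k]),
                 numeric(1))
    expect_true(all(diff(zc) <= 0))
  }
})

test_that("sifting terminates within its configured bounds", {
  cfg <- sift_config(sd_threshold = 1e-12, max_sift_iterations = 5L,
                     max_imfs = 3L)
  set.seed(2)
  s <- uniform_series(rnorm(400), fs = 8)
  d <- emd_decompose(s, cfg)   # must return despite an unreachable threshold
  expect_lte(n_imfs(d), 3L)
  expect_lte(reconstruction_error(d, s), 1e-8)
})

test_that("decomposition CSV output has the documented columns", {
  dir <- withr::local_tempdir()
  t <- seq(0, 80, by = 1 / 8)
  d <- emd_decompose(uniform_series(sin(2 * pi * 0.25 * t) +
                                      0.4 * sin(2 * pi * 0.06 * t), fs = 8))
  path <- file.path(dir, "d.csv")
  write_decomposition_csv(d, path)
  df <- read.csv(path)
  expect_equal(names(df),
               c("time_s", paste0("imf", seq_len(n_imfs(d))), "residue"))
  expect_equal(nrow(df), d$source_length)
})
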