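test_that("periodogram peaks at the tone frequency and satisfies Parseval", {
  t <- (0:511) / 8
  s <- uniform_series(sin(2 * pi * 0.25 * t), fs = 8)
  sp <- imf_spectrum(s)
  expect_equal(sp$freq_hz[which.max(sp$power)], 0.25, tolerance = 8 / 512)

  set.seed(14)
  v <- rnorm(1024)
  spv <- imf_spectrum(uniform_series(v, fs = 8))
  expect_equal(sum(spv$power), mean((v - mean(v))^2), tolerance = 1e-6)

  # white noise spreads power: no bin dominates
  expect_lt(max(spv$power) / sum(spv$power), 0.2)

  expect_error(imf_spectrum(uniform_series(rnorm(16), fs = 8)), "too short")
})

test_that("dominant frequency is exact for bin-aligned tones and matches a DFT oracle", {
  # 0.078125 Hz = bin 10 of a 1024-sample record at 8 Hz
  t <- (0:1023) / 8
  s <- uniform_series(sin(2 * pi * 0.078125 * t), fs = 8)
  expect_equal(dominant_frequency(imf_spectrum(s)), 0.078125)

  two <- uniform_series(2 * sin(2 * pi * 0.1 * t) + sin(2 * pi * 0.3 * t),
                        fs = 8)
  # neither tone is bin-aligned; the louder one wins within one bin of leakage
  expect_lt(abs(dominant_frequency(imf_spectrum(two)) - 0.1), 0.02)

  set.seed(8)
  for (i in 1:5) {
    v <- as.numeric(arima.sim(list(ar = 0.9), 512))
    s <- uniform_series(v, fs = 8)
    expect_equal(dominant_frequency(imf_spectrum(s)),
                 brute_dominant_freq(v, 8))
  }

  expect_error(dominant_frequency(list(freq_hz = c(0, 1), power = c(0, 0))),
               "all-zero")
})

# hand-built decomposition with known per-mode tones
fake_decomposition <- function(freqs, fs = 8, n = 1600) {
  t <- (seq_len(n) - 1) / fs
  imfs <- vapply(freqs, function(f) sin(2 * pi * f * t), numeric(n))
  colnames(imfs) <- paste0("imf", seq_along(freqs))
  structure(list(imfs = imfs, residue = rep(0.5, n), fs = fs,
                 start_time_s = 0, source_length = n),
            class = "imf_decomposition")
}

test_that("band assignment follows the 0.15 Hz HF-inclusive boundary", {
  # 0.25, 0.05 and exactly 0.15 Hz are all bin-aligned for n = 1600 at 8 Hz
  d <- fake_decomposition(c(0.25, 0.05, 0.15))
  a <- assign_bands(d)
  expect_equal(a$band, c("HF", "LF", "HF"))
  expect_equal(a$dominant_frequency_hz, c(0.25, 0.05, 0.15), tolerance = 1e-9)
  expect_equal(a$residue_band, "LF")

  # above-HF modes stay HF by default, can be excluded
  d2 <- fake_decomposition(c(0.5, 0.05))
  expect_equal(assign_bands(d2)$band, c("HF", "LF"))
  expect_equal(assign_bands(d2, exclude_above_hf = TRUE)$band,
               c("excluded", "LF"))
})

test_that("recombination partitions the decomposition and reconstructs the source", {
  d <- fake_decomposition(c(0.05, 0.08))
  a <- assign_bands(d)
  cs <- recombine(d, a)
  src <- rowSums(d$imfs) + d$residue
  expect_equal(cs$lf$values, src)            # everything LF
  expect_true(all(cs$hf$values == 0))

  t <- seq(0, 600, by = 1 / 8)
  s <- uniform_series(900 + 20 * sin(2 * pi * 0.3 * t) +
                        35 * sin(2 * pi * 0.08 * t), fs = 8)
  dec <- emd_decompose(s)
  cs2 <- recombine(dec, assign_bands(dec))
  expect_lt(max(abs(cs2$hf$values + cs2$lf$values - s$values)) /
              max(abs(s$values)), 1e-8)

  # each tone's variance lands mostly in its own component
  hf_tone <- 20 * sin(2 * pi * 0.3 * t)
  lf_tone <- 35 * sin(2 * pi * 0.08 * t)
  expect_gt(1 - var(cs2$hf$values - hf_tone) / var(hf_tone), 0.8)
  expect_gt(1 - var(cs2$lf$values - 900 - lf_tone) / var(lf_tone), 0.8)
})

test_that("residue exclusion removes only the residue from the LF component", {
  d <- fake_decomposition(c(0.25, 0.05))
  cs_in <- recombine(d, assign_bands(d, residue_band = "LF"))
  cs_out <- recombine(d, assign_bands(d, residue_band = "excluded"))
  expect_equal(cs_in$lf$values - cs_out$lf$values, d$residue)
  expect_equal(cs_in$hf$values, cs_out$hf$values)
})

test_that("matched T1/T2 pairs share their HF component but not their LF component", {
  cfg <- synth_config(seed = 19)
  t1 <- pipeline_components(generate_recording(cfg, "T1"))
  t2 <- pipeline_components(generate_recording(cfg, "T2"))
  n <- min(length(t1$hf$values), length(t2$hf$values))
  expect_gt(cor(t1$hf$values[1:n], t2$hf$values[1:n]), 0.9)
  expect_lt(cor(t1$lf$values[1:n], t2$lf$values[1:n]), 0.9)
})

test_that("component CSV and band report have the documented shape", {
  dir <- withr::local_tempdir()
  d <- fake_decomposition(c(0.25, 0.05))
  a <- assign_bands(d)
  cs <- recombine(d, a)
  write_components_csv(cs, file.path(dir, "c.csv"))
  expect_named(read.csv(file.path(dir, "c.csv")), c("time_s", "hf", "lf"))
  write_assignment_report(a, file.path(dir, "a.txt"))
  lines <- readLines(file.path(dir, "a.txt"))
  expect_length(lines, 3L)  # 2 modes + residue line
  expect_match(lines[3], "residue\tNA\tLF")
})
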