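# Independent oracles used across test files. These deliberately avoid the
# code paths they check.

# Natural cubic spline via direct solve of the tridiagonal system for the
# knot second derivatives, evaluated piecewise.
natural_spline_eval <- function(x, y, xout) {
  n <- length(x)
  h <- diff(x)
  A <- matrix(0, n, n)
  rhs <- numeric(n)
  A[1, 1] <- 1
  A[n, n] <- 1
  for (i in 2:(n - 1)) {
    A[i, i - 1] <- h[i - 1]
    A[i, i] <- 2 * (h[i - 1] + h[i])
    A[i, i + 1] <- h[i]
    rhs[i] <- 6 * ((y[i + 1] - y[i]) / h[i] - (y[i] - y[i - 1]) / h[i - 1])
  }
  M <- solve(A, rhs)
  vapply(xout, function(t) {
    i <- max(1L, min(n - 1L, findInterval(t, x)))
    d <- x[i + 1] - x[i]
    a <- (x[i + 1] - t) / d
    b <- (t - x[i]) / d
    a * y[i] + b * y[i + 1] +
      ((a^3 - a) * M[i] + (b^3 - b) * M[i + 1]) * d^2 / 6
  }, numeric(1))
}

# Exhaustive strict-neighbour extrema scan (tie-free inputs only).
brute_extrema <- function(x) {
  n <- length(x)
  i <- 2:(n - 1)
  list(maxima = i[x[i] > x[i - 1] & x[i] > x[i + 1]],
       minima = i[x[i] < x[i - 1] & x[i] < x[i + 1]])
}

# Argmax frequency of a direct DFT magnitude (excludes DC).
brute_dominant_freq <- function(v, fs) {
  v <- v - mean(v)
  n <- length(v)
  mag <- Mod(fft(v))[2:floor(n / 2 + 1)]
  ((2:floor(n / 2 + 1)) - 1)[which.max(mag)] * fs / n
}

zero_crossings <- function(v) sum(diff(sign(v[v != 0])) != 0)

count_extrema <- function(v) {
  e <- brute_extrema(v)
  length(e$maxima) + length(e$minima)
}

tone_series <- function(freq, duration_s, fs = 8, amp = 1, phase = 0) {
  t <- seq(0, duration_s, by = 1 / fs)
  uniform_series(amp * sin(2 * pi * freq * t + phase), fs = fs)
}
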