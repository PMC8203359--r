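#' Sliding-window configuration
#'
#' @param size_samples window length in resampled points (>= 2). At the 8 Hz
#'   resampling rate, 100 points = 12.5 s.
#' @param step_samples stride between consecutive windows (default 1, dense).
#' @return A list of class \code{window_config}.
#' @export
window_config <- function(size_samples, step_samples = 1L) {
  stopifnot(size_samples >= 2L, step_samples >= 1L)
  structure(list(size_samples = as.integer(size_samples),
                 step_samples = as.integer(step_samples)),
            class = "window_config")
}

#' Endpoint-difference feature over a sliding time window
#'
#' For each full window the feature is the value at the window's right
#' endpoint minus the value at its left endpoint (orientation fixed by
#' convention; detection uses the magnitude). Only full windows are emitted —
#' no edge padding, which would fabricate endpoint values. With step 1 the
#' output has \code{length(x) - size + 1} values.
#'
#' @param lf a \code{uniform_series} (typically the LF component).
#' @param w a \code{window_config} with \code{size_samples <= length}.
#' @return An object of class \code{feature_series}: \code{values},
#'   \code{window_size}, \code{step}, \code{source_id}.
#' @export
#'
#' @examples
#' s <- uniform_series(0.5 * (0:19))          # ramp, slope 0.5 per sample
#' f <- endpoint_difference(s, window_config(5))
#' unique(round(f$values, 12))                # 0.5 * (5 - 1) = 2
endpoint_difference <- function(lf, w) {
  stopifnot(inherits(lf, "uniform_series"), inherits(w, "window_config"))
  n <- length(lf$values)
  size <- w$size_samples
  if (n < size) {
    stop(sprintf("series length %d shorter than window size %d", n, size),
         call. = FALSE)
  }
  starts <- seq.int(1L, n - size + 1L, by = w$step_samples)
  structure(
    list(values = lf$values[starts + size - 1L] - lf$values[starts],
         window_size = size, step = w$step_samples,
         source_id = attr(lf, "source_id")),
    class = "feature_series"
  )
}

#' @export
print.feature_series <- function(x, ...) {
  cat(sprintf("<feature_series> window %d, step %d, %d values, max|f| = %.4g\n",
              x$window_size, x$step, length(x$values), max(abs(x$values))))
  invisible(x)
}

#' Sweep the window size
#'
#' Extracts the endpoint-difference feature once per window size in
#' \code{seq(min_size, max_size, by = increment)} — by default 100 to 650
#' resampling points in steps of 50, i.e. 12 sizes.
#'
#' @inheritParams endpoint_difference
#' @param min_size,max_size,increment sweep bounds in resampled points.
#' @param step_samples stride passed to every window.
#' @return Named list mapping window size (as character) to
#'   \code{feature_series}.
#' @export
window_sweep <- function(lf, min_size = 100L, max_size = 650L,
                         increment = 50L, step_samples = 1L) {
  stopifnot(inherits(lf, "uniform_series"))
  sizes <- seq.int(min_size, max_size, by = increment)
  n <- length(lf$values)
  too_big <- sizes[sizes > n]
  if (length(too_big) > 0L) {
    stop(sprintf("window size %d exceeds series length %d", too_big[1L], n),
         call. = FALSE)
  }
  out <- lapply(sizes, function(sz) {
    endpoint_difference(lf, window_config(sz, step_samples))
  })
  names(out) <- as.character(sizes)
  out
}

#' Window sizes selected for the detection experiment
#'
#' The six sizes (in resampled points) at which detection accuracy is
#' evaluated: 150, 250, 350, 450, 550, 650.
#'
#' @return integer vector of length 6.
#' @export
selected_sizes <- function() {
  c(150L, 250L, 350L, 450L, 550L, 650L)
}

#' Write a feature series as CSV
#'
#' Columns \code{window_start_index, feature} (1-based start index).
#'
#' @param f a \code{feature_series}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_features_csv <- function(f, path) {
  stopifnot(inherits(f, "feature_series"))
  starts <- seq.int(1L, by = f$step, length.out = length(f$values))
  utils::write.csv(data.frame(window_start_index = starts, feature = f$values),
                   path, row.names = FALSE)
  invisible(path)
}
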