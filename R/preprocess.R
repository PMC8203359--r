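#' RR-interval sequence
#'
#' Container for a beat-to-beat RR recording: an ordered vector of interval
#' durations in milliseconds, an optional class label (\code{"T1"} = noxious
#' stimulation present, \code{"T2"} = anesthesia only) and, for simulated T1
#' recordings, the known stimulation onset time.
#'
#' @param rr_ms numeric vector of RR intervals in milliseconds, one per beat.
#' @param label optional, \code{"T1"} or \code{"T2"}.
#' @param recording_id opaque identifier.
#' @param event_time_s optional stimulation onset in seconds (simulated T1).
#'
#' @return An object of class \code{rr_intervals}.
#' @seealso [validate_rr()], [resample_uniform()]
#' @export
rr_intervals <- function(rr_ms, label = NULL, recording_id = "rr",
                         event_time_s = NA_real_) {
  rr_ms <- as.numeric(rr_ms)
  if (!is.null(label)) label <- match.arg(label, c("T1", "T2"))
  obj <- structure(
    list(rr_ms = rr_ms, label = label, recording_id = recording_id,
         event_time_s = event_time_s),
    class = "rr_intervals"
  )
  validate_rr_obj(obj)
  obj
}

validate_rr_obj <- function(x) {
  rr <- x$rr_ms
  bad <- which(!is.finite(rr) | rr <= 0)
  if (length(bad) > 0L) {
    stop(sprintf("non-positive or non-finite RR value at index %d (%.6g ms)",
                 bad[1L], rr[bad[1L]]), call. = FALSE)
  }
  if (length(rr) < 4L) {
    stop(sprintf(
      "RR sequence has %d beats; at least 4 are required for cubic-spline resampling",
      length(rr)), call. = FALSE)
  }
  invisible(x)
}

#' Validate a raw RR-interval vector
#'
#' Rejects non-positive or non-finite values (with the offending index) and
#' sequences too short to support a cubic spline. Positive values outside a
#' configurable physiological band are reported with a warning but kept: the
#' upstream method applies no artifact correction, so data are never silently
#' altered.
#'
#' @param raw numeric vector of candidate RR intervals (milliseconds).
#' @param band length-2 numeric, the plausible physiological range in ms.
#' @inheritParams rr_intervals
#'
#' @return An \code{rr_intervals} object.
#' @export
#'
#' @examples
#' validate_rr(c(1000, 990, 1010, 1000))
validate_rr <- function(raw, band = c(300, 2000), label = NULL,
                        recording_id = "rr", event_time_s = NA_real_) {
  if (length(raw) == 0L) stop("empty RR input", call. = FALSE)
  obj <- rr_intervals(raw, label = label, recording_id = recording_id,
                      event_time_s = event_time_s)
  out <- which(obj$rr_ms < band[1L] | obj$rr_ms > band[2L])
  if (length(out) > 0L) {
    warning(sprintf(
      "%d RR value(s) outside the physiological band [%g, %g] ms (first at index %d); kept unmodified",
      length(out), band[1L], band[2L], out[1L]), call. = FALSE)
  }
  obj
}

#' @export
print.rr_intervals <- function(x, ...) {
  cat(sprintf("<rr_intervals> %s: %d beats, %.1f s%s%s\n",
              x$recording_id, length(x$rr_ms), sum(x$rr_ms) / 1000,
              if (is.null(x$label)) "" else paste0(", label ", x$label),
              if (is.na(x$event_time_s)) "" else
                sprintf(", event at %.1f s", x$event_time_s)))
  invisible(x)
}

#' Beat times of an RR sequence
#'
#' Each interval is anchored at the time of its terminating beat, so
#' \code{t[i] = sum(rr_ms[1:i]) / 1000}. Times are strictly increasing because
#' all intervals are positive.
#'
#' @param rr an \code{rr_intervals} object.
#' @return numeric vector of beat times in seconds, same length as the input.
#' @export
beat_times <- function(rr) {
  stopifnot(inherits(rr, "rr_intervals"))
  cumsum(rr$rr_ms) / 1000
}

#' Uniformly sampled series
#'
#' A real-valued series on a uniform time grid: the resampled tachogram and
#' every signal derived from it (intrinsic mode functions, HF/LF components).
#'
#' @param values numeric vector, length >= 2.
#' @param fs sampling rate in Hz (> 0).
#' @param start_time_s time of the first sample, seconds.
#' @return An object of class \code{uniform_series}.
#' @export
uniform_series <- function(values, fs = 8, start_time_s = 0) {
  values <- as.numeric(values)
  stopifnot(length(values) >= 2L, is.finite(fs), fs > 0)
  structure(list(values = values, fs = fs, start_time_s = start_time_s),
            class = "uniform_series")
}

#' @export
print.uniform_series <- function(x, ...) {
  cat(sprintf("<uniform_series> %d samples at %g Hz, t in [%.3f, %.3f] s\n",
              length(x$values), x$fs, x$start_time_s,
              x$start_time_s + (length(x$values) - 1L) / x$fs))
  invisible(x)
}

#' Sample times of a uniform series
#' @param x a \code{uniform_series}.
#' @return numeric vector of sample times in seconds.
#' @export
series_times <- function(x) {
  stopifnot(inherits(x, "uniform_series"))
  x$start_time_s + (seq_along(x$values) - 1L) / x$fs
}

#' Resample an RR sequence to a uniform tachogram
#'
#' Fits a natural cubic spline through (beat time, RR value) pairs and
#' evaluates it on the uniform grid \code{t1, t1 + 1/fs, ...} clipped to the
#' observed time span; the spline is never extrapolated. 8 Hz is the
#' conventional rate for HRV resampling.
#'
#' @param rr an \code{rr_intervals} object (>= 4 beats).
#' @param fs target sampling rate in Hz.
#' @return A \code{uniform_series} of RR values in milliseconds.
#' @export
#'
#' @examples
#' rr <- rr_intervals(rep(1000, 20))
#' tach <- resample_uniform(rr, fs = 8)
#' range(tach$values)  # constant input stays constant
resample_uniform <- function(rr, fs = 8) {
  stopifnot(inherits(rr, "rr_intervals"), is.finite(fs), fs > 0)
  t_beat <- beat_times(rr)
  n_grid <- floor((t_beat[length(t_beat)] - t_beat[1L]) * fs) + 1L
  if (n_grid < 2L) stop("recording too short for the requested sampling rate",
                        call. = FALSE)
  grid <- t_beat[1L] + (seq_len(n_grid) - 1L) / fs
  f <- stats::splinefun(t_beat, rr$rr_ms, method = "natural")
  uniform_series(f(grid), fs = fs, start_time_s = t_beat[1L])
}

#' Read one RR recording from CSV
#'
#' Expects a header with an \code{rr_ms} column; other columns are ignored.
#'
#' @param path CSV file path.
#' @inheritParams validate_rr
#' @return An \code{rr_intervals} object, id taken from the file name.
#' @export
read_rr_csv <- function(path, band = c(300, 2000), label = NULL,
                        event_time_s = NA_real_) {
  df <- utils::read.csv(path)
  if (!"rr_ms" %in% names(df)) {
    stop(sprintf("'%s' has no 'rr_ms' column", path), call. = FALSE)
  }
  validate_rr(df$rr_ms, band = band, label = label,
              recording_id = tools::file_path_sans_ext(basename(path)),
              event_time_s = event_time_s)
}

#' Write a uniform series as CSV
#'
#' Columns \code{time_s,value_ms}.
#'
#' @param x a \code{uniform_series}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_tachogram_csv <- function(x, path) {
  stopifnot(inherits(x, "uniform_series"))
  utils::write.csv(data.frame(time_s = series_times(x), value_ms = x$values),
                   path, row.names = FALSE)
  invisible(path)
}
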