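#' Sifting configuration
#'
#' Parameters of the empirical-mode-decomposition sifting loop. The inner loop
#' stops when the classical standard-deviation criterion between consecutive
#' sift iterates, \eqn{\sum_t (h_{n-1}(t) - h_n(t))^2 / h_{n-1}(t)^2}, falls
#' below \code{sd_threshold} (classical default 0.2) or after
#' \code{max_sift_iterations} passes. Envelopes are natural cubic splines
#' through the local extrema after mirroring \code{boundary_mirror_extrema}
#' extrema across each end of the record, which suppresses spline divergence
#' at the boundaries.
#'
#' @param sd_threshold positive real, sifting stop threshold.
#' @param max_sift_iterations integer cap on sifting passes per mode.
#' @param max_imfs integer cap on extracted modes.
#' @param boundary_mirror_extrema extrema mirrored across each boundary.
#' @return A list of class \code{sift_config}.
#' @export
sift_config <- function(sd_threshold = 0.2, max_sift_iterations = 100L,
                        max_imfs = 12L, boundary_mirror_extrema = 2L) {
  stopifnot(sd_threshold > 0, max_sift_iterations >= 1L, max_imfs >= 1L,
            boundary_mirror_extrema >= 1L)
  structure(list(sd_threshold = sd_threshold,
                 max_sift_iterations = as.integer(max_sift_iterations),
                 max_imfs = as.integer(max_imfs),
                 boundary_mirror_extrema = as.integer(boundary_mirror_extrema)),
            class = "sift_config")
}

#' Local extrema of a sequence
#'
#' Interior strict local maxima and minima. A flat plateau flanked by lower
#' (higher) neighbours counts once, at its midpoint index (lower median for
#' even-length plateaus) — a deterministic tie-break. Endpoints are never
#' extrema.
#'
#' @param x numeric vector, length >= 3.
#' @return list with integer vectors \code{maxima} and \code{minima}.
#' @export
#'
#' @examples
#' find_local_extrema(c(0, 1, 0, -1, 0, 1, 0))
find_local_extrema <- function(x) {
  stopifnot(length(x) >= 3L)
  r <- rle(x)
  k <- length(r$lengths)
  if (k < 3L) return(list(maxima = integer(0), minima = integer(0)))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  mids <- (starts + ends) %/% 2L
  v <- r$values
  i <- 2:(k - 1L)
  is_max <- v[i] > v[i - 1L] & v[i] > v[i + 1L]
  is_min <- v[i] < v[i - 1L] & v[i] < v[i + 1L]
  list(maxima = mids[i][is_max], minima = mids[i][is_min])
}

# Mirror the k extrema nearest each record end across that end, in index
# coordinates, so the envelope spline is supported beyond [1, n].
mirror_extrema <- function(idx, val, n, k) {
  m <- length(idx)
  kl <- min(k, m)
  left_i <- 2L - idx[seq_len(kl)]            # reflect about index 1
  left_v <- val[seq_len(kl)]
  right_sel <- seq.int(m, by = -1L, length.out = kl)
  right_i <- 2L * n - idx[right_sel]         # reflect about index n
  right_v <- val[right_sel]
  ord <- order(c(left_i, idx, right_i))
  ii <- c(left_i, idx, right_i)[ord]
  vv <- c(left_v, val, right_v)[ord]
  keep <- !duplicated(ii)
  list(idx = ii[keep], val = vv[keep])
}

# Signal raised when a residue has too few extrema to support envelopes;
# decompose() consumes it as the natural stopping condition.
monotone_residue_condition <- function(n_max, n_min) {
  structure(
    class = c("monotone_residue", "condition"),
    list(message = sprintf(
      "monotone residue: %d maxima, %d minima (need >= 2 of each)",
      n_max, n_min),
      call = NULL)
  )
}

#' Mean of the upper and lower envelopes
#'
#' Upper and lower envelopes are natural cubic splines through the
#' boundary-extended local maxima and minima; the result is their pointwise
#' mean on the series' own grid. Signals a \code{monotone_residue} condition
#' when fewer than two maxima or two minima exist.
#'
#' @param x a \code{uniform_series}.
#' @param cfg a \code{sift_config}.
#' @return A \code{uniform_series} with the envelope mean.
#' @export
envelope_mean <- function(x, cfg = sift_config()) {
  stopifnot(inherits(x, "uniform_series"))
  v <- x$values
  n <- length(v)
  ext <- find_local_extrema(v)
  if (length(ext$maxima) < 2L || length(ext$minima) < 2L) {
    stop(monotone_residue_condition(length(ext$maxima), length(ext$minima)))
  }
  k <- cfg$boundary_mirror_extrema
  up <- mirror_extrema(ext$maxima, v[ext$maxima], n, k)
  lo <- mirror_extrema(ext$minima, v[ext$minima], n, k)
  grid <- seq_len(n)
  s_up <- stats::splinefun(up$idx, up$val, method = "natural")(grid)
  s_lo <- stats::splinefun(lo$idx, lo$val, method = "natural")(grid)
  uniform_series((s_up + s_lo) / 2, fs = x$fs, start_time_s = x$start_time_s)
}

#' One sifting pass
#'
#' Subtracts the envelope mean: \code{h - envelope_mean(h)}.
#'
#' @inheritParams envelope_mean
#' @param h a \code{uniform_series}.
#' @return A \code{uniform_series}.
#' @export
sift_once <- function(h, cfg = sift_config()) {
  m <- envelope_mean(h, cfg)
  uniform_series(h$values - m$values, fs = h$fs, start_time_s = h$start_time_s)
}

#' Extract one intrinsic mode function
#'
#' Iterates sifting passes on \code{s} until the standard-deviation criterion
#' between consecutive sift iterates,
#' \eqn{SD = \sum_t (h_{n-1}(t) - h_n(t))^2 / h_{n-1}(t)^2},
#' drops below \code{cfg$sd_threshold} or the iteration cap is reached;
#' returns the final candidate as the mode. Grid points where the previous
#' iterate is negligibly small are excluded from the sum to keep the
#' criterion finite.
#'
#' @inheritParams envelope_mean
#' @param s a \code{uniform_series} with at least 2 maxima and 2 minima.
#' @return A \code{uniform_series}, the extracted mode.
#' @export
extract_imf <- function(s, cfg = sift_config()) {
  h <- sift_once(s, cfg)
  prev <- s$values
  for (it in seq_len(cfg$max_sift_iterations - 1L)) {
    keep <- prev^2 > 1e-12 * mean(prev^2)
    sd_crit <- sum((prev[keep] - h$values[keep])^2 / prev[keep]^2)
    if (!is.finite(sd_crit) || sd_crit < cfg$sd_threshold) break
    prev <- h$values
    h <- tryCatch(sift_once(h, cfg),
                  monotone_residue = function(e) NULL)
    if (is.null(h)) {  # over-sifted to monotone; keep the previous candidate
      h <- uniform_series(prev, fs = s$fs, start_time_s = s$start_time_s)
      break
    }
  }
  h
}

#' Empirical mode decomposition
#'
#' Decomposes a uniform series into intrinsic mode functions (highest
#' frequency first) and a residue by repeatedly extracting a mode from the
#' running residue. Extraction stops when the residue has fewer than two
#' maxima or two minima (a steady trend or constant) or \code{cfg$max_imfs}
#' is reached. By telescoping, the modes plus residue reconstruct the input
#' exactly up to floating point; this is asserted on every call.
#'
#' @param s a \code{uniform_series}, length >= 16.
#' @param cfg a \code{sift_config}.
#' @return An object of class \code{imf_decomposition}: list with \code{imfs}
#'   (a length-n x k matrix, one mode per column), \code{residue} (numeric),
#'   \code{fs}, \code{start_time_s}, \code{source_length}.
#' @export
#'
#' @examples
#' t <- seq(0, 120, by = 1 / 8)
#' s <- uniform_series(sin(2 * pi * 0.25 * t) + 0.5 * sin(2 * pi * 0.05 * t))
#' d <- emd_decompose(s)
#' n_imfs(d)
emd_decompose <- function(s, cfg = sift_config()) {
  stopifnot(inherits(s, "uniform_series"))
  n <- length(s$values)
  if (n < 16L) stop("series too short for decomposition (need >= 16 samples)",
                    call. = FALSE)
  residue <- s
  imfs <- vector("list", cfg$max_imfs)
  k <- 0L
  while (k < cfg$max_imfs) {
    imf <- tryCatch(extract_imf(residue, cfg),
                    monotone_residue = function(e) NULL)
    if (is.null(imf)) break
    k <- k + 1L
    imfs[[k]] <- imf$values
    residue <- uniform_series(residue$values - imf$values, fs = s$fs,
                              start_time_s = s$start_time_s)
  }
  imf_mat <- if (k > 0L) {
    matrix(unlist(imfs[seq_len(k)]), nrow = n, ncol = k,
           dimnames = list(NULL, paste0("imf", seq_len(k))))
  } else {
    matrix(numeric(0), nrow = n, ncol = 0L)
  }
  d <- structure(
    list(imfs = imf_mat, residue = residue$values, fs = s$fs,
         start_time_s = s$start_time_s, source_length = n),
    class = "imf_decomposition"
  )
  err <- reconstruction_error(d, s)
  if (err > 1e-8) {
    stop(sprintf("decomposition failed completeness check (relative error %.3g)",
                 err), call. = FALSE)
  }
  d
}

#' Number of modes in a decomposition
#' @param d an \code{imf_decomposition}.
#' @return integer.
#' @export
n_imfs <- function(d) {
  stopifnot(inherits(d, "imf_decomposition"))
  ncol(d$imfs)
}

#' Extract one mode as a uniform series
#' @param d an \code{imf_decomposition}.
#' @param i mode index (1 = highest frequency), or \code{"residue"}.
#' @return A \code{uniform_series}.
#' @export
imf_series <- function(d, i) {
  stopifnot(inherits(d, "imf_decomposition"))
  v <- if (identical(i, "residue")) d$residue else d$imfs[, i]
  uniform_series(v, fs = d$fs, start_time_s = d$start_time_s)
}

#' Relative reconstruction error of a decomposition
#'
#' \code{max |s - (sum of modes + residue)| / max |s|}; exact decompositions
#' return ~1e-16.
#'
#' @param d an \code{imf_decomposition}.
#' @param s the source \code{uniform_series}.
#' @return non-negative scalar.
#' @export
reconstruction_error <- function(d, s) {
  stopifnot(inherits(d, "imf_decomposition"), inherits(s, "uniform_series"))
  recon <- d$residue + if (ncol(d$imfs) > 0L) rowSums(d$imfs) else 0
  denom <- max(abs(s$values))
  if (denom == 0) return(max(abs(s$values - recon)))
  max(abs(s$values - recon)) / denom
}

#' @export
print.imf_decomposition <- function(x, ...) {
  cat(sprintf("<imf_decomposition> %d modes + residue, %d samples at %g Hz\n",
              ncol(x$imfs), x$source_length, x$fs))
  invisible(x)
}

#' Write a decomposition as CSV
#'
#' Columns \code{time_s, imf1, ..., imfk, residue}.
#'
#' @param d an \code{imf_decomposition}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_decomposition_csv <- function(d, path) {
  stopifnot(inherits(d, "imf_decomposition"))
  tt <- d$start_time_s + (seq_len(d$source_length) - 1L) / d$fs
  df <- data.frame(time_s = tt)
  if (ncol(d$imfs) > 0L) df <- cbind(df, as.data.frame(d$imfs))
  df$residue <- d$residue
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
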