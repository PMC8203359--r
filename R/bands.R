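#' One-sided periodogram of a mode
#'
#' Raw periodogram (no taper, no padding) of the mean-removed series, with
#' frequencies in Hz on \code{(0, fs/2]} plus the zero bin. Power is
#' normalized so the bins sum to the series variance (Parseval).
#'
#' @param imf a \code{uniform_series}, length >= 32.
#' @return list with numeric vectors \code{freq_hz} and \code{power}.
#' @export
imf_spectrum <- function(imf) {
  stopifnot(inherits(imf, "uniform_series"))
  v <- imf$values
  if (length(v) < 32L) stop("series too short for spectral analysis (need >= 32 samples)",
                            call. = FALSE)
  v <- v - mean(v)
  sp <- stats::spec.pgram(stats::ts(v, frequency = imf$fs), taper = 0,
                          detrend = FALSE, demean = FALSE, fast = FALSE,
                          plot = FALSE)
  # rescale the two-sided density to per-bin power summing to the variance
  # (the unpaired Nyquist bin is not doubled); prepend the zero-power DC bin
  df <- imf$fs / length(v)
  power <- 2 * df * sp$spec
  nyq <- sp$freq == imf$fs / 2
  power[nyq] <- power[nyq] / 2
  list(freq_hz = c(0, sp$freq), power = c(0, power))
}

#' Dominant frequency of a spectrum
#'
#' Frequency of the maximum-power bin, excluding the zero-frequency bin.
#'
#' @param spectrum list with \code{freq_hz} and \code{power}, as returned by
#'   [imf_spectrum()].
#' @return positive scalar, Hz.
#' @export
dominant_frequency <- function(spectrum) {
  stopifnot(is.list(spectrum), length(spectrum$freq_hz) > 0L)
  keep <- spectrum$freq_hz > 0
  p <- spectrum$power[keep]
  if (all(p == 0)) stop("all-zero power spectrum", call. = FALSE)
  spectrum$freq_hz[keep][which.max(p)]
}

#' Assign each mode to the HF or LF band
#'
#' Each intrinsic mode function is labeled by its dominant periodogram
#' frequency: HF when it is at or above \code{hf_boundary_hz} (0.15 Hz, the
#' conventional LF/HF split; the boundary is HF-inclusive), LF otherwise. The
#' VLF band is merged into LF, so the trend-like residue joins LF by default.
#' Modes whose dominant frequency exceeds 0.4 Hz (above the physiological HF
#' band: noise modes) stay in HF unless \code{exclude_above_hf = TRUE}.
#'
#' @param d an \code{imf_decomposition} with at least one mode.
#' @param hf_boundary_hz LF/HF boundary (Hz), HF-inclusive.
#' @param residue_band \code{"LF"} (default: the residue is VLF-like) or
#'   \code{"excluded"}.
#' @param exclude_above_hf drop modes with dominant frequency > 0.4 Hz from
#'   both components.
#' @return An object of class \code{band_assignment}: \code{band} (character
#'   per mode), \code{dominant_frequency_hz}, \code{residue_band},
#'   \code{hf_boundary_hz}.
#' @export
assign_bands <- function(d, hf_boundary_hz = 0.15,
                         residue_band = c("LF", "excluded"),
                         exclude_above_hf = FALSE) {
  stopifnot(inherits(d, "imf_decomposition"), n_imfs(d) >= 1L)
  residue_band <- match.arg(residue_band)
  dom <- vapply(seq_len(n_imfs(d)), function(i) {
    dominant_frequency(imf_spectrum(imf_series(d, i)))
  }, numeric(1))
  band <- ifelse(dom >= hf_boundary_hz, "HF", "LF")
  if (exclude_above_hf) band[dom > 0.4] <- "excluded"
  structure(list(band = band, dominant_frequency_hz = dom,
                 residue_band = residue_band,
                 hf_boundary_hz = hf_boundary_hz),
            class = "band_assignment")
}

#' @export
print.band_assignment <- function(x, ...) {
  cat("<band_assignment>\n")
  for (i in seq_along(x$band)) {
    cat(sprintf("  imf%-2d  %.4f Hz  %s\n", i, x$dominant_frequency_hz[i],
                x$band[i]))
  }
  cat(sprintf("  residue -> %s\n", x$residue_band))
  invisible(x)
}

#' Recombine modes into HF and LF component signals
#'
#' The HF component is the elementwise sum of the HF-labeled modes; the LF
#' component sums the LF-labeled modes, plus the residue when
#' \code{residue_band = "LF"}. When nothing is excluded, \code{hf + lf}
#' reconstructs the source exactly (a partition of the decomposition).
#'
#' @param d an \code{imf_decomposition}.
#' @param a a \code{band_assignment} covering every mode of \code{d}.
#' @return An object of class \code{component_signals}: \code{hf} and
#'   \code{lf} (\code{uniform_series}) and \code{assignment}.
#' @export
recombine <- function(d, a = assign_bands(d)) {
  stopifnot(inherits(d, "imf_decomposition"), inherits(a, "band_assignment"))
  if (length(a$band) != n_imfs(d)) {
    stop("band assignment does not cover every mode", call. = FALSE)
  }
  n <- d$source_length
  sum_band <- function(which_band) {
    sel <- a$band == which_band
    if (any(sel)) rowSums(d$imfs[, sel, drop = FALSE]) else numeric(n)
  }
  hf <- sum_band("HF")
  lf <- sum_band("LF")
  if (a$residue_band == "LF") lf <- lf + d$residue
  structure(
    list(hf = uniform_series(hf, fs = d$fs, start_time_s = d$start_time_s),
         lf = uniform_series(lf, fs = d$fs, start_time_s = d$start_time_s),
         assignment = a),
    class = "component_signals"
  )
}

#' @export
print.component_signals <- function(x, ...) {
  cat(sprintf("<component_signals> %d samples at %g Hz (%d HF / %d LF modes, residue -> %s)\n",
              length(x$hf$values), x$hf$fs,
              sum(x$assignment$band == "HF"), sum(x$assignment$band == "LF"),
              x$assignment$residue_band))
  invisible(x)
}

#' Write component signals as CSV
#'
#' Columns \code{time_s, hf, lf}.
#'
#' @param cs a \code{component_signals}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_components_csv <- function(cs, path) {
  stopifnot(inherits(cs, "component_signals"))
  utils::write.csv(data.frame(time_s = series_times(cs$hf),
                              hf = cs$hf$values, lf = cs$lf$values),
                   path, row.names = FALSE)
  invisible(path)
}

#' Write a band-assignment summary report
#'
#' Small key-value text file: one line per mode with its dominant frequency
#' and band, plus the residue destination.
#'
#' @param a a \code{band_assignment}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_assignment_report <- function(a, path) {
  stopifnot(inherits(a, "band_assignment"))
  lines <- c(
    sprintf("imf%d\t%.6f\t%s", seq_along(a$band), a$dominant_frequency_hz,
            a$band),
    sprintf("residue\tNA\t%s", a$residue_band)
  )
  writeLines(lines, path)
  invisible(path)
}
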