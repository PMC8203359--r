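# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards.
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = env)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  code
}

#' Synthetic tachogram configuration
#'
#' Parameters of the simulated RR recordings. A recording is a baseline heart
#' period modulated by one HF oscillation (respiratory-band, 0.15-0.4 Hz), one
#' LF oscillation (< 0.15 Hz), white per-beat noise and — for T1 recordings
#' only — a smooth sigmoid rise of the baseline at the stimulation time,
#' emulating the level shift that tracheal intubation imprints on the LF
#' component while leaving the HF component unchanged.
#'
#' @param duration_s recording length, seconds.
#' @param base_rr_ms baseline heart period, ms.
#' @param hf_freq_hz,hf_amp_ms HF oscillation frequency (in [0.15, 0.4)) and
#'   amplitude.
#' @param lf_freq_hz,lf_amp_ms LF oscillation frequency (in (0, 0.15)) and
#'   amplitude.
#' @param noise_sd_ms per-beat white-noise standard deviation, ms.
#' @param event_time_s,event_rise_s,event_delta_ms stimulation onset, rise
#'   time constant and asymptotic RR shift (T1 recordings only).
#' @param phi_hf,phi_lf oscillation phases, radians.
#' @param seed integer seed for the per-beat noise.
#' @return A list of class \code{synth_config}.
#' @export
synth_config <- function(duration_s = 600, base_rr_ms = 900,
                         hf_freq_hz = 0.25, hf_amp_ms = 20,
                         lf_freq_hz = 0.08, lf_amp_ms = 35,
                         noise_sd_ms = 5,
                         event_time_s = 300, event_rise_s = 10,
                         event_delta_ms = 60,
                         phi_hf = 0, phi_lf = 0, seed = 1L) {
  stopifnot(duration_s > 0, base_rr_ms > 0, hf_amp_ms >= 0, lf_amp_ms >= 0,
            noise_sd_ms >= 0, event_rise_s > 0, event_delta_ms >= 0,
            hf_freq_hz >= 0.15, hf_freq_hz < 0.4,
            lf_freq_hz > 0, lf_freq_hz < 0.15,
            event_time_s > 0, event_time_s < duration_s)
  structure(list(duration_s = duration_s, base_rr_ms = base_rr_ms,
                 hf_freq_hz = hf_freq_hz, hf_amp_ms = hf_amp_ms,
                 lf_freq_hz = lf_freq_hz, lf_amp_ms = lf_amp_ms,
                 noise_sd_ms = noise_sd_ms, event_time_s = event_time_s,
                 event_rise_s = event_rise_s, event_delta_ms = event_delta_ms,
                 phi_hf = phi_hf, phi_lf = phi_lf, seed = as.integer(seed)),
            class = "synth_config")
}

#' Noise-free instantaneous RR value
#'
#' The deterministic part of the simulated heart period at time \code{t}:
#' baseline + HF sine + LF sine, plus (T1 only) the sigmoid event ramp
#' \code{event_delta_ms / (1 + exp(-(t - event_time_s) / event_rise_s))}.
#'
#' @param t time(s) in seconds, within \code{[0, duration_s]}.
#' @param cfg a \code{synth_config}.
#' @param label \code{"T1"} (event present) or \code{"T2"}.
#' @return numeric vector of RR values in ms, same length as \code{t}.
#' @export
instantaneous_rr <- function(t, cfg, label = c("T2", "T1")) {
  stopifnot(inherits(cfg, "synth_config"))
  label <- match.arg(label)
  if (any(t < 0 | t > cfg$duration_s)) {
    stop("time outside the recording duration", call. = FALSE)
  }
  rr <- cfg$base_rr_ms +
    cfg$hf_amp_ms * sin(2 * pi * cfg$hf_freq_hz * t + cfg$phi_hf) +
    cfg$lf_amp_ms * sin(2 * pi * cfg$lf_freq_hz * t + cfg$phi_lf)
  if (label == "T1") {
    rr <- rr + cfg$event_delta_ms /
      (1 + exp(-(t - cfg$event_time_s) / cfg$event_rise_s))
  }
  rr
}

#' Generate one synthetic RR recording
#'
#' Beat times are generated by forward stepping on the instantaneous heart
#' period: \code{t[k+1] = t[k] + (instantaneous_rr(t[k]) + noise) / 1000},
#' with independent Gaussian per-beat noise, until the duration is reached.
#' This is an approximation to an integral pulse-frequency model, adequate at
#' these modulation depths. Deterministic given \code{cfg$seed}.
#'
#' @param cfg a \code{synth_config}.
#' @param label \code{"T1"} or \code{"T2"}.
#' @param recording_id identifier for the output object.
#' @return An \code{rr_intervals} object; \code{event_time_s} is set for T1.
#' @export
generate_recording <- function(cfg, label = c("T2", "T1"),
                               recording_id = NULL) {
  stopifnot(inherits(cfg, "synth_config"))
  label <- match.arg(label)
  if (is.null(recording_id)) {
    recording_id <- sprintf("synth_%s_seed%d", label, cfg$seed)
  }
  min_rr_s <- 0.25          # hard floor: no beat faster than 240 bpm
  cap <- ceiling(cfg$duration_s / min_rr_s) + 8L
  rr <- numeric(cap)
  with_seed(cfg$seed, {
    noise <- if (cfg$noise_sd_ms > 0) {
      stats::rnorm(cap, sd = cfg$noise_sd_ms)
    } else numeric(cap)
    t <- 0
    k <- 0L
    while (t < cfg$duration_s && k < cap) {
      k <- k + 1L
      rr_k <- max(instantaneous_rr(t, cfg, label) + noise[k], min_rr_s * 1000)
      rr[k] <- rr_k
      t <- t + rr_k / 1000
    }
    rr <- rr[seq_len(k)]
  })
  rr_intervals(rr, label = label, recording_id = recording_id,
               event_time_s = if (label == "T1") cfg$event_time_s else NA_real_)
}

#' Generate a labeled dataset of synthetic recordings
#'
#' Produces \code{n_t1 + n_t2} recordings with per-recording seeds derived
#' from \code{seed}, uniformly jittered event times (+/- \code{event_jitter_s})
#' and uniformly drawn oscillation phases, so no two recordings are aligned.
#' Class sizes default to 42 T1 / 62 T2.
#'
#' @param n_t1,n_t2 number of recordings per class.
#' @param cfg template \code{synth_config}; per-recording fields (seed,
#'   phases, event time) are overridden.
#' @param seed master seed.
#' @param event_jitter_s half-width of the uniform event-time jitter.
#' @return An object of class \code{labeled_dataset}: \code{recordings} (list
#'   of \code{rr_intervals}) and \code{labels} (character vector).
#' @export
generate_dataset <- function(n_t1 = 42L, n_t2 = 62L, cfg = synth_config(),
                             seed = 1L, event_jitter_s = 60) {
  stopifnot(n_t1 >= 0L, n_t2 >= 0L, inherits(cfg, "synth_config"))
  n <- n_t1 + n_t2
  labels <- c(rep("T1", n_t1), rep("T2", n_t2))
  draws <- with_seed(seed, list(
    seeds = sample.int(.Machine$integer.max - 1L, n),
    phi_hf = stats::runif(n, 0, 2 * pi),
    phi_lf = stats::runif(n, 0, 2 * pi),
    jitter = stats::runif(n, -event_jitter_s, event_jitter_s)
  ))
  recordings <- lapply(seq_len(n), function(i) {
    cfg_i <- cfg
    cfg_i$seed <- as.integer(draws$seeds[i])
    cfg_i$phi_hf <- draws$phi_hf[i]
    cfg_i$phi_lf <- draws$phi_lf[i]
    cfg_i$event_time_s <- cfg$event_time_s + draws$jitter[i]
    cfg_i <- do.call(synth_config, unclass(cfg_i))  # re-validate invariants
    generate_recording(cfg_i, label = labels[i],
                       recording_id = sprintf("rec%03d_%s", i, labels[i]))
  })
  structure(list(recordings = recordings, labels = labels),
            class = "labeled_dataset")
}

#' @export
print.labeled_dataset <- function(x, ...) {
  cat(sprintf("<labeled_dataset> %d recordings (%d T1 / %d T2)\n",
              length(x$recordings), sum(x$labels == "T1"),
              sum(x$labels == "T2")))
  invisible(x)
}

#' Write a simulated dataset to disk
#'
#' One CSV per recording (column \code{rr_ms}) plus a manifest CSV with
#' columns \code{recording_id, label, event_time_s, seed}.
#'
#' @param ds a \code{labeled_dataset}.
#' @param dir output directory (created if missing).
#' @param seed the master seed recorded in the manifest.
#' @return Path of the manifest CSV, invisibly.
#' @export
write_dataset_csv <- function(ds, dir, seed = NA_integer_) {
  stopifnot(inherits(ds, "labeled_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (rec in ds$recordings) {
    utils::write.csv(data.frame(rr_ms = rec$rr_ms),
                     file.path(dir, paste0(rec$recording_id, ".csv")),
                     row.names = FALSE)
  }
  manifest <- data.frame(
    recording_id = vapply(ds$recordings, `[[`, "", "recording_id"),
    label = ds$labels,
    event_time_s = vapply(ds$recordings, `[[`, 0, "event_time_s"),
    seed = seed
  )
  mpath <- file.path(dir, "manifest.csv")
  utils::write.csv(manifest, mpath, row.names = FALSE)
  invisible(mpath)
}
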