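#' Pipeline configuration
#'
#' Bundles every stage's options for an end-to-end run; each field is
#' validated by its own constructor.
#'
#' @param fs resampling rate, Hz.
#' @param sift a \code{sift_config}.
#' @param hf_boundary_hz,residue_band,exclude_above_hf band options, see
#'   [assign_bands()].
#' @param sweep_min,sweep_max,sweep_increment window-sweep bounds (resampled
#'   points).
#' @param sizes window sizes used in the detection experiment.
#' @param detector a \code{detector_config}.
#' @param repeats random re-splits per window size.
#' @param seed global seed.
#' @return A list of class \code{pipeline_config}.
#' @export
pipeline_config <- function(fs = 8, sift = sift_config(),
                            hf_boundary_hz = 0.15, residue_band = "LF",
                            exclude_above_hf = FALSE,
                            sweep_min = 100L, sweep_max = 650L,
                            sweep_increment = 50L,
                            sizes = selected_sizes(),
                            detector = detector_config(), repeats = 5L,
                            seed = 1L) {
  stopifnot(fs > 0, inherits(sift, "sift_config"),
            inherits(detector, "detector_config"),
            sweep_min >= 2L, sweep_max >= sweep_min, sweep_increment >= 1L,
            repeats >= 1L)
  structure(list(fs = fs, sift = sift, hf_boundary_hz = hf_boundary_hz,
                 residue_band = residue_band,
                 exclude_above_hf = exclude_above_hf,
                 sweep_min = as.integer(sweep_min),
                 sweep_max = as.integer(sweep_max),
                 sweep_increment = as.integer(sweep_increment),
                 sizes = as.integer(sizes), detector = detector,
                 repeats = as.integer(repeats), seed = as.integer(seed)),
            class = "pipeline_config")
}

# Polynomial rolling hash over the deparsed config: a stable fingerprint for
# provenance (kept in double precision, modulus below 2^31).
config_hash <- function(x) {
  bytes <- utf8ToInt(paste(deparse(x), collapse = "\n"))
  h <- 0
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Load a dataset from a manifest CSV
#'
#' The manifest (as written by [write_dataset_csv()]) must have columns
#' \code{recording_id} and \code{label}; \code{event_time_s} is optional.
#' Each recording is read from \code{<dir>/<recording_id>.csv}.
#'
#' @param manifest_path path to the manifest CSV.
#' @return A \code{labeled_dataset}.
#' @export
read_dataset_csv <- function(manifest_path) {
  if (!file.exists(manifest_path)) {
    stop(sprintf("manifest not found: %s", manifest_path), call. = FALSE)
  }
  man <- utils::read.csv(manifest_path)
  if (!all(c("recording_id", "label") %in% names(man))) {
    stop("manifest needs 'recording_id' and 'label' columns", call. = FALSE)
  }
  dir <- dirname(manifest_path)
  recordings <- lapply(seq_len(nrow(man)), function(i) {
    path <- file.path(dir, paste0(man$recording_id[i], ".csv"))
    if (!file.exists(path)) {
      stop(sprintf("recording file missing: %s", path), call. = FALSE)
    }
    ev <- if ("event_time_s" %in% names(man)) man$event_time_s[i] else NA_real_
    read_rr_csv(path, label = man$label[i], event_time_s = ev)
  })
  structure(list(recordings = recordings, labels = as.character(man$label)),
            class = "labeled_dataset")
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE)
  })
}

#' Run the full detection pipeline
#'
#' Executes resampling, decomposition, band recombination, feature extraction
#' and the repeated-split detection experiment on a labeled dataset, writing
#' intermediate CSVs, a per-repeat and summary results table, and a
#' provenance block (config fingerprint, seed, package version) under
#' \code{out_dir}. Errors carry the name of the failing stage.
#'
#' @param ds a \code{labeled_dataset}, or a manifest CSV path.
#' @param config a \code{pipeline_config}.
#' @param out_dir output directory (created if needed); \code{NULL} skips all
#'   file output.
#' @param baseline also run the raw-tachogram recurrent baseline.
#' @param quiet suppress progress messages (stderr).
#' @return list with \code{experiment} (detail + summary), optional
#'   \code{baseline}, \code{assignments}, and \code{provenance}.
#' @export
run_pipeline <- function(ds, config = pipeline_config(), out_dir = NULL,
                         baseline = FALSE, quiet = FALSE) {
  say <- function(...) if (!quiet) message(sprintf(...))
  t0 <- Sys.time()
  if (is.character(ds)) ds <- stage("load", read_dataset_csv(ds))
  stopifnot(inherits(ds, "labeled_dataset"),
            inherits(config, "pipeline_config"))
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE,
                                    showWarnings = FALSE)
  n <- length(ds$recordings)
  say("pipeline: %d recordings, seed %d", n, config$seed)

  # windows must fit the shortest resampled recording before any heavy work
  stage("validate", {
    shortest <- min(vapply(ds$recordings, function(r) {
      floor((sum(r$rr_ms) - r$rr_ms[1L]) / 1000 * config$fs) + 1
    }, numeric(1)))
    if (max(config$sizes, config$sweep_max) > shortest) {
      stop(sprintf("window size %d exceeds the shortest recording (%d samples)",
                   max(config$sizes, config$sweep_max), shortest))
    }
  })

  assignments <- vector("list", n)
  lf <- vector("list", n)
  for (i in seq_len(n)) {
    rr <- ds$recordings[[i]]
    tach <- stage("preprocess", resample_uniform(rr, fs = config$fs))
    d <- stage("emd", emd_decompose(tach, config$sift))
    a <- stage("bands", assign_bands(
      d, hf_boundary_hz = config$hf_boundary_hz,
      residue_band = config$residue_band,
      exclude_above_hf = config$exclude_above_hf))
    cs <- stage("bands", recombine(d, a))
    assignments[[i]] <- a
    lf[[i]] <- cs$lf
    if (!is.null(out_dir)) {
      id <- rr$recording_id
      write_tachogram_csv(tach, file.path(out_dir, paste0(id, "_tachogram.csv")))
      write_decomposition_csv(d, file.path(out_dir, paste0(id, "_imfs.csv")))
      write_components_csv(cs, file.path(out_dir, paste0(id, "_components.csv")))
      write_assignment_report(a, file.path(out_dir, paste0(id, "_bands.txt")))
      for (sz in config$sizes) {
        f <- stage("features", endpoint_difference(lf[[i]], window_config(sz)))
        write_features_csv(f, file.path(out_dir,
                                        sprintf("%s_features_w%d.csv", id, sz)))
      }
    }
  }
  say("decomposition done (%.1f s)", as.numeric(Sys.time() - t0, units = "secs"))

  feats <- stage("features", list(
    features = {
      out <- lapply(config$sizes, function(sz) {
        lapply(lf, function(s) endpoint_difference(s, window_config(sz))$values)
      })
      names(out) <- as.character(config$sizes)
      out
    },
    labels = ds$labels, lf = lf))
  experiment <- stage("detect", window_size_experiment(
    feats, cfg = config$detector, repeats = config$repeats,
    seed = config$seed))
  base <- if (baseline) {
    stage("detect", raw_baseline(
      ds, cfg = detector_config(backend = "recurrent",
                                seed = config$detector$seed,
                                input_length = config$detector$input_length),
      repeats = config$repeats, seed = config$seed, fs = config$fs))
  }
  provenance <- list(config_hash = config_hash(config), seed = config$seed,
                     package_version = as.character(utils::packageVersion("stwhrv")),
                     n_recordings = n,
                     elapsed_s = round(as.numeric(Sys.time() - t0,
                                                  units = "secs"), 2))
  if (!is.null(out_dir)) {
    utils::write.csv(experiment$detail,
                     file.path(out_dir, "results_detail.csv"),
                     row.names = FALSE)
    utils::write.csv(experiment$summary,
                     file.path(out_dir, "results_summary.csv"),
                     row.names = FALSE)
    if (baseline) {
      utils::write.csv(base$detail, file.path(out_dir, "baseline_detail.csv"),
                       row.names = FALSE)
    }
    writeLines(c(sprintf("config_hash: %s", provenance$config_hash),
                 sprintf("seed: %d", provenance$seed),
                 sprintf("package_version: %s", provenance$package_version),
                 sprintf("n_recordings: %d", provenance$n_recordings),
                 sprintf("elapsed_s: %.2f", provenance$elapsed_s)),
               file.path(out_dir, "provenance.txt"))
  }
  say("experiment done (%.1f s total)",
      as.numeric(Sys.time() - t0, units = "secs"))
  list(experiment = experiment, baseline = base, assignments = assignments,
       provenance = provenance)
}
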