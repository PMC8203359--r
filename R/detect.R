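#' Random train/validation/test split
#'
#' Partitions \code{1:n} into train, validation and test index sets with sizes
#' proportional to \code{ratios} (largest-remainder rounding), deterministic
#' given \code{seed}. The default ratios reproduce the 71/15/18 split of a
#' 104-recording dataset.
#'
#' @param n number of items (>= 3).
#' @param ratios length-3 positive weights for train/validation/test.
#' @param seed integer seed.
#' @return list with integer vectors \code{train}, \code{validation},
#'   \code{test} — disjoint, jointly covering \code{1:n}.
#' @export
#'
#' @examples
#' lengths(split_dataset(104, seed = 1))  # 71 / 15 / 18
split_dataset <- function(n, ratios = c(71, 15, 18), seed = 1L) {
  if (n < 3L) stop("need at least 3 items to split", call. = FALSE)
  stopifnot(length(ratios) == 3L, all(ratios > 0))
  quota <- n * ratios / sum(ratios)
  sizes <- floor(quota)
  short <- n - sum(sizes)
  if (short > 0L) {
    extra <- order(quota - sizes, decreasing = TRUE)[seq_len(short)]
    sizes[extra] <- sizes[extra] + 1L
  }
  perm <- with_seed(seed, sample.int(n))
  list(train = sort(perm[seq_len(sizes[1L])]),
       validation = sort(perm[sizes[1L] + seq_len(sizes[2L])]),
       test = sort(perm[sizes[1L] + sizes[2L] + seq_len(sizes[3L])]))
}

#' Detector configuration
#'
#' @param backend \code{"threshold"} (default): classify by whether the
#'   maximum absolute feature value exceeds a cutoff tuned on the validation
#'   set. \code{"recurrent"}: a small single-layer recurrent (Elman) network
#'   trained on the full sequence.
#' @param seed integer seed for weight initialization.
#' @param input_length fixed sequence length for the recurrent backend;
#'   longer inputs are truncated, shorter ones zero-padded. The threshold
#'   backend is length-agnostic.
#' @param epochs,learning_rate,hidden_size recurrent training hyperparameters.
#' @return A list of class \code{detector_config}.
#' @export
detector_config <- function(backend = c("threshold", "recurrent"), seed = 1L,
                            input_length = 300L, epochs = 50L,
                            learning_rate = 0.02, hidden_size = 16L) {
  backend <- match.arg(backend)
  stopifnot(input_length > 0L, epochs >= 1L, learning_rate > 0,
            hidden_size >= 1L)
  structure(list(backend = backend, seed = as.integer(seed),
                 input_length = as.integer(input_length),
                 epochs = as.integer(epochs), learning_rate = learning_rate,
                 hidden_size = as.integer(hidden_size)),
            class = "detector_config")
}

# Per-series detection statistic of the threshold backend.
max_abs_stat <- function(x) {
  vapply(x, function(v) max(abs(as.numeric(v))), numeric(1))
}

as_value_list <- function(x) {
  lapply(x, function(v) {
    if (inherits(v, "feature_series") || inherits(v, "uniform_series")) v$values
    else as.numeric(v)
  })
}

#' Fit a binary noxious-stimulation detector
#'
#' Threshold backend: computes \code{max(abs(series))} per recording and
#' chooses, among midpoints of the pooled train+validation statistics, the
#' cutoff maximizing validation accuracy (ties go to the smallest cutoff);
#' predicts T1 when the statistic exceeds the cutoff. Recurrent backend:
#' trains a single-layer Elman network (tanh hidden units, mean-pooled state,
#' logistic output) by full-batch Adam on the training set, keeping the
#' weights with the best validation accuracy. Both are deterministic given
#' \code{cfg$seed}.
#'
#' @param train_x,val_x lists of numeric vectors (or \code{feature_series} /
#'   \code{uniform_series}).
#' @param train_y,val_y character labels, \code{"T1"} or \code{"T2"}.
#' @param cfg a \code{detector_config}.
#' @return An object of class \code{stw_detector} with a \code{predict}
#'   method.
#' @export
fit_detector <- function(train_x, train_y, val_x, val_y,
                         cfg = detector_config()) {
  stopifnot(inherits(cfg, "detector_config"),
            length(train_x) == length(train_y),
            length(val_x) == length(val_y))
  if (length(unique(train_y)) < 2L) {
    stop("single-class training set: both T1 and T2 are required",
         call. = FALSE)
  }
  train_x <- as_value_list(train_x)
  val_x <- as_value_list(val_x)
  fitted <- if (cfg$backend == "threshold") {
    fit_threshold(train_x, train_y, val_x, val_y)
  } else {
    fit_recurrent(train_x, train_y, val_x, val_y, cfg)
  }
  structure(c(fitted, list(backend = cfg$backend, cfg = cfg)),
            class = "stw_detector")
}

fit_threshold <- function(train_x, train_y, val_x, val_y) {
  s_train <- max_abs_stat(train_x)
  s_val <- max_abs_stat(val_x)
  pool <- sort(unique(c(s_train, s_val)))
  cuts <- if (length(pool) > 1L) {
    c(pool[1L] - 1, (pool[-length(pool)] + pool[-1L]) / 2)
  } else {
    pool - 1
  }
  acc_val <- vapply(cuts, function(cut) {
    mean(ifelse(s_val > cut, "T1", "T2") == val_y)
  }, numeric(1))
  best <- which(acc_val == max(acc_val))
  if (length(best) > 1L) {  # break ties by training accuracy ...
    acc_tr <- vapply(cuts[best], function(cut) {
      mean(ifelse(s_train > cut, "T1", "T2") == train_y)
    }, numeric(1))
    best <- best[acc_tr == max(acc_tr)]
  }
  # ... then take the middle of the tied run: a max-margin cutoff
  pick <- best[ceiling(length(best) / 2)]
  list(cutoff = cuts[pick], val_accuracy = acc_val[pick])
}

#' Predict labels with a fitted detector
#'
#' @param object an \code{stw_detector}.
#' @param newdata list of numeric vectors (or series objects).
#' @param ... unused.
#' @return character vector of \code{"T1"}/\code{"T2"} labels.
#' @export
predict.stw_detector <- function(object, newdata, ...) {
  newdata <- as_value_list(newdata)
  if (object$backend == "threshold") {
    ifelse(max_abs_stat(newdata) > object$cutoff, "T1", "T2")
  } else {
    p <- rnn_forward(rnn_inputs(newdata, object$input_length,
                                object$center, object$scale),
                     object$weights)$p
    ifelse(p > 0.5, "T1", "T2")
  }
}

#' @export
print.stw_detector <- function(x, ...) {
  if (x$backend == "threshold") {
    cat(sprintf("<stw_detector> threshold backend, cutoff %.4g (validation accuracy %.3f)\n",
                x$cutoff, x$val_accuracy))
  } else {
    cat(sprintf("<stw_detector> recurrent backend, hidden %d, input length %d (validation accuracy %.3f)\n",
                ncol(x$weights$U), x$input_length, x$val_accuracy))
  }
  invisible(x)
}

#' Evaluate a detector on a test set
#'
#' @param detector an \code{stw_detector}.
#' @param test_x list of numeric vectors (or series objects).
#' @param test_y character labels.
#' @return accuracy, the fraction of correct labels in [0, 1].
#' @export
evaluate_detector <- function(detector, test_x, test_y) {
  if (length(test_x) == 0L) stop("empty test set", call. = FALSE)
  stopifnot(length(test_x) == length(test_y))
  mean(predict(detector, test_x) == test_y)
}

## ---- recurrent backend: single-layer Elman network, full-batch Adam ----

# Truncate / zero-pad each series to `len`, then center and scale.
rnn_inputs <- function(x, len, center, scale) {
  X <- matrix(0, nrow = length(x), ncol = len)
  for (i in seq_along(x)) {
    v <- x[[i]]
    m <- min(length(v), len)
    X[i, seq_len(m)] <- v[seq_len(m)]
  }
  (X - center) / scale
}

rnn_init <- function(hidden, seed) {
  with_seed(seed, {
    list(Win = stats::runif(hidden, -0.5, 0.5),
         U = matrix(stats::runif(hidden * hidden, -0.3, 0.3), hidden),
         b = numeric(hidden),
         wout = stats::runif(hidden, -0.5, 0.5),
         cout = 0)
  })
}

# Forward pass over all sequences at once. X: n x T. Returns mean-pooled
# probabilities and, when keep = TRUE, the hidden trajectory for BPTT.
rnn_forward <- function(X, w, keep = FALSE) {
  n <- nrow(X); T_len <- ncol(X); H <- length(w$Win)
  h <- matrix(0, n, H)
  hbar <- matrix(0, n, H)
  hist <- if (keep) vector("list", T_len) else NULL
  for (t in seq_len(T_len)) {
    h <- tanh(outer(X[, t], w$Win) + h %*% w$U +
                matrix(w$b, n, H, byrow = TRUE))
    hbar <- hbar + h
    if (keep) hist[[t]] <- h
  }
  hbar <- hbar / T_len
  z <- drop(hbar %*% w$wout) + w$cout
  list(p = 1 / (1 + exp(-z)), hbar = hbar, hist = hist)
}

rnn_grads <- function(X, y01, w, fwd) {
  n <- nrow(X); T_len <- ncol(X); H <- length(w$Win)
  dz <- (fwd$p - y01) / n                     # BCE gradient at the logit
  g <- list(Win = numeric(H), U = matrix(0, H, H), b = numeric(H),
            wout = drop(crossprod(fwd$hbar, dz)), cout = sum(dz))
  dpool <- outer(dz, w$wout) / T_len          # grad reaching every h_t
  dh_next <- matrix(0, n, H)                  # recurrent grad from t+1
  for (t in rev(seq_len(T_len))) {
    h_t <- fwd$hist[[t]]
    da <- (dpool + dh_next) * (1 - h_t^2)     # through tanh
    g$Win <- g$Win + drop(crossprod(da, X[, t]))
    h_prev <- if (t > 1L) fwd$hist[[t - 1L]] else matrix(0, n, H)
    g$U <- g$U + crossprod(h_prev, da)
    g$b <- g$b + colSums(da)
    dh_next <- da %*% t(w$U)
  }
  g
}

fit_recurrent <- function(train_x, train_y, val_x, val_y, cfg) {
  center <- mean(unlist(train_x))
  scale <- stats::sd(unlist(train_x))
  if (!is.finite(scale) || scale == 0) scale <- 1
  Xtr <- rnn_inputs(train_x, cfg$input_length, center, scale)
  Xva <- rnn_inputs(val_x, cfg$input_length, center, scale)
  ytr <- as.numeric(train_y == "T1")
  w <- rnn_init(cfg$hidden_size, cfg$seed)
  m <- v <- lapply(w, function(p) p * 0)      # Adam moments
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  best <- list(w = w, acc = -Inf)
  for (ep in seq_len(cfg$epochs)) {
    fwd <- rnn_forward(Xtr, w, keep = TRUE)
    g <- rnn_grads(Xtr, ytr, w, fwd)
    for (nm in names(w)) {
      m[[nm]] <- b1 * m[[nm]] + (1 - b1) * g[[nm]]
      v[[nm]] <- b2 * v[[nm]] + (1 - b2) * g[[nm]]^2
      mhat <- m[[nm]] / (1 - b1^ep)
      vhat <- v[[nm]] / (1 - b2^ep)
      w[[nm]] <- w[[nm]] - cfg$learning_rate * mhat / (sqrt(vhat) + eps)
    }
    acc <- mean(ifelse(rnn_forward(Xva, w)$p > 0.5, "T1", "T2") == val_y)
    if (acc > best$acc) best <- list(w = w, acc = acc)
  }
  list(weights = best$w, val_accuracy = best$acc,
       input_length = cfg$input_length, center = center, scale = scale)
}

## ---- experiments ----

#' LF and HF components of one recording
#'
#' Runs resampling, empirical mode decomposition, band assignment and
#' recombination on an RR recording — the full feature-signal pipeline up to
#' (but not including) windowed feature extraction.
#'
#' @param rr an \code{rr_intervals} object.
#' @param fs resampling rate, Hz.
#' @param sift a \code{sift_config}.
#' @param ... further arguments to [assign_bands()].
#' @return A \code{component_signals} object.
#' @export
pipeline_components <- function(rr, fs = 8, sift = sift_config(), ...) {
  d <- emd_decompose(resample_uniform(rr, fs = fs), sift)
  recombine(d, assign_bands(d, ...))
}

#' Endpoint-difference features for every recording at chosen window sizes
#'
#' Computes each recording's LF component once and extracts the
#' endpoint-difference feature at every requested window size.
#'
#' @param ds a \code{labeled_dataset}.
#' @param sizes integer window sizes (resampled points).
#' @param fs resampling rate, Hz.
#' @param sift a \code{sift_config}.
#' @param ... further arguments to [assign_bands()].
#' @return list with \code{features} (named by size: lists of numeric
#'   vectors), \code{labels}, and \code{lf} (the LF component series).
#' @export
dataset_features <- function(ds, sizes = selected_sizes(), fs = 8,
                             sift = sift_config(), ...) {
  stopifnot(inherits(ds, "labeled_dataset"))
  lf <- lapply(ds$recordings, function(rr) {
    pipeline_components(rr, fs = fs, sift = sift, ...)$lf
  })
  features <- lapply(sizes, function(sz) {
    lapply(lf, function(s) endpoint_difference(s, window_config(sz))$values)
  })
  names(features) <- as.character(sizes)
  list(features = features, labels = ds$labels, lf = lf)
}

#' Detection accuracy across window sizes
#'
#' For each window size, repeatedly re-splits the dataset, fits the detector
#' on the train/validation portions of that size's feature series and
#' evaluates on the held-out test set; reports per-repeat and mean accuracy.
#' Deterministic given \code{seed}.
#'
#' @param feats output of [dataset_features()] (computed once; the expensive
#'   decomposition step is shared across sizes and repeats).
#' @param cfg a \code{detector_config} (threshold backend recommended).
#' @param repeats number of random re-splits.
#' @param seed master seed for the split sequence.
#' @param ratios split weights, see [split_dataset()].
#' @return list with \code{detail} (data.frame: window_size, repeat,
#'   split_seed, accuracy) and \code{summary} (data.frame: window_size,
#'   mean_accuracy).
#' @export
window_size_experiment <- function(feats, cfg = detector_config(),
                                   repeats = 5L, seed = 1L,
                                   ratios = c(71, 15, 18)) {
  sizes <- as.integer(names(feats$features))
  n <- length(feats$labels)
  split_seeds <- with_seed(seed, sample.int(1e6, repeats))
  detail <- do.call(rbind, lapply(sizes, function(sz) {
    x <- feats$features[[as.character(sz)]]
    acc <- vapply(split_seeds, function(ss) {
      sp <- split_dataset(n, ratios = ratios, seed = ss)
      det <- fit_detector(x[sp$train], feats$labels[sp$train],
                          x[sp$validation], feats$labels[sp$validation], cfg)
      evaluate_detector(det, x[sp$test], feats$labels[sp$test])
    }, numeric(1))
    data.frame(window_size = sz, rep = seq_len(repeats),
               split_seed = split_seeds, accuracy = acc)
  }))
  summary <- stats::aggregate(accuracy ~ window_size, detail, mean)
  names(summary)[2L] <- "mean_accuracy"
  list(detail = detail, summary = summary)
}

#' Raw-tachogram recurrent baseline
#'
#' Feeds the resampled tachograms themselves (no decomposition, no windowed
#' feature) to the recurrent detector under the same repeated-split protocol,
#' quantifying what the sequence model achieves without the extracted
#' feature. Tachograms are decimated to \code{cfg$input_length} evenly spaced
#' samples before training so the whole recording, not just its head, is
#' seen at a fixed sequence length.
#'
#' @param ds a \code{labeled_dataset}.
#' @param cfg a \code{detector_config}; the recurrent backend is forced.
#' @param repeats number of random re-splits.
#' @param seed master seed (same seed as [window_size_experiment()] yields
#'   the same splits).
#' @param fs resampling rate, Hz.
#' @param ratios split weights.
#' @return list with \code{detail} and \code{mean_accuracy}.
#' @export
raw_baseline <- function(ds, cfg = detector_config(backend = "recurrent"),
                         repeats = 5L, seed = 1L, fs = 8,
                         ratios = c(71, 15, 18)) {
  stopifnot(inherits(ds, "labeled_dataset"))
  cfg$backend <- "recurrent"
  raw <- lapply(ds$recordings, function(rr) {
    v <- resample_uniform(rr, fs = fs)$values
    idx <- unique(round(seq(1, length(v), length.out = cfg$input_length)))
    v[idx]
  })
  n <- length(ds$labels)
  split_seeds <- with_seed(seed, sample.int(1e6, repeats))
  acc <- vapply(split_seeds, function(ss) {
    sp <- split_dataset(n, ratios = ratios, seed = ss)
    det <- fit_detector(raw[sp$train], ds$labels[sp$train],
                        raw[sp$validation], ds$labels[sp$validation], cfg)
    evaluate_detector(det, raw[sp$test], ds$labels[sp$test])
  }, numeric(1))
  list(detail = data.frame(rep = seq_len(repeats), split_seed = split_seeds,
                           accuracy = acc),
       mean_accuracy = mean(acc))
}
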