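#' Large Laplacian spatial filter
#'
#' Re-references each channel by subtracting the mean of its (up to) four
#' nearest neighbouring electrodes, a spatial high-pass that removes
#' common-mode activity and sharpens focal sources. Neighbours are the four
#' nearest channels by Euclidean distance in layout coordinates; a candidate
#' only qualifies if it lies within `reach` times the median nearest-neighbour
#' spacing of the montage, so boundary electrodes fall back to the mean of
#' the neighbours that are actually available (at minimum the single nearest
#' channel, which always qualifies).
#'
#' @param set A [trial_set()] whose layout carries positions.
#' @param reach Neighbour admissibility radius as a multiple of the median
#'   nearest-neighbour spacing (default 1.5).
#' @return The filtered `TrialSet`.
#' @export
apply_large_laplacian <- function(set, reach = 1.5) {
  pos <- set$layout$positions
  nc <- nrow(pos)
  if (nc < 2) stop("large Laplacian needs >= 2 channels to define neighbours")
  d <- as.matrix(stats::dist(pos))
  diag(d) <- Inf
  med_nn <- stats::median(apply(d, 1, min))
  neighbours <- lapply(seq_len(nc), function(i) {
    ord <- order(d[i, ])[1:min(4, nc - 1)]
    nb <- ord[d[i, ord] <= reach * med_nn]
    if (length(nb) == 0) nb <- ord[1]   # the nearest channel always counts
    nb
  })
  map_trials(set, function(tr) {
    x <- tr$data
    out <- x
    for (i in seq_len(nc)) {
      nb <- neighbours[[i]]
      if (length(nb) > 0) {
        out[i, ] <- x[i, ] - colMeans(x[nb, , drop = FALSE])
      }
    }
    eeg_trial(out, tr$rate, tr$cue_index, tr$label)
  })
}

#' Zero-phase band-pass filter
#'
#' 4th-order Butterworth applied forward and backward (`signal::filtfilt`),
#' so the pass band is traversed twice and the phase response is zero.
#' Trial length is preserved.
#'
#' @param set A [trial_set()].
#' @param low_hz,high_hz Band edges in Hz (defaults 1 and 50).
#' @param order Butterworth design order per direction.
#' @return The filtered `TrialSet`.
#' @export
bandpass_trials <- function(set, low_hz = 1, high_hz = 50, order = 4) {
  rate <- set_rate(set)
  if (low_hz >= high_hz) stop("low_hz must be < high_hz")
  if (high_hz >= rate / 2) {
    stop("high_hz (", high_hz, ") must be below the Nyquist frequency ", rate / 2)
  }
  bf <- signal::butter(order, c(low_hz, high_hz) / (rate / 2), type = "pass")
  map_trials(set, function(tr) {
    out <- t(apply(tr$data, 1, function(row) signal::filtfilt(bf, row)))
    eeg_trial(out, tr$rate, tr$cue_index, tr$label)
  })
}

#' Anti-aliased downsampling to a target rate
#'
#' Integer-factor polyphase decimation (`signal::decimate` with an FIR
#' anti-aliasing filter). Only integer ratios are supported; same-rate input
#' is returned unchanged.
#'
#' @param set A [trial_set()].
#' @param target_hz Target sampling frequency (default 250).
#' @return A `TrialSet` at `target_hz`; cue indices are rescaled.
#' @export
resample_trials <- function(set, target_hz = 250) {
  rate <- set_rate(set)
  if (rate == target_hz) return(set)
  q <- rate / target_hz
  if (abs(q - round(q)) > 1e-9 || q < 1) {
    stop("current rate ", rate, " is not an integer multiple of ", target_hz)
  }
  q <- as.integer(round(q))
  map_trials(set, function(tr) {
    out <- t(apply(tr$data, 1, function(row) {
      as.numeric(signal::decimate(row, q, ftype = "fir"))
    }))
    eeg_trial(out, target_hz, as.integer(floor(tr$cue_index / q)), tr$label)
  })
}

#' Baseline correction against the 1-s pre-cue window
#'
#' Subtracts, per channel, the mean over the `baseline_sec` seconds
#' immediately preceding the cue from the entire trial.
#'
#' @param trial An [eeg_trial()] with at least `baseline_sec` seconds of
#'   pre-cue signal.
#' @param baseline_sec Baseline window length in seconds (default 1).
#' @return The corrected `EEGTrial`.
#' @export
baseline_correct <- function(trial, baseline_sec = 1) {
  n_base <- as.integer(round(baseline_sec * trial$rate))
  if (trial$cue_index < n_base) {
    stop("trial has only ", trial$cue_index, " pre-cue samples; ",
         n_base, " required for a ", baseline_sec, " s baseline")
  }
  idx <- (trial$cue_index - n_base + 1):trial$cue_index  # 1-based cols
  mu <- rowMeans(trial$data[, idx, drop = FALSE])
  eeg_trial(trial$data - mu, trial$rate, trial$cue_index, trial$label)
}

#' Fit channel-wise normalization statistics on training trials
#'
#' Pools all samples of all training trials per channel and returns the mean
#' and standard deviation used to standardize both training and held-out
#' data ([apply_channel_stats()]). A channel whose pooled standard deviation
#' is below `1e-12` is flagged as degenerate.
#'
#' @param train A [trial_set()] of training trials.
#' @return A [channel_stats()] object.
#' @export
fit_channel_stats <- function(train) {
  if (length(train$trials) == 0) stop("empty training set")
  pooled <- do.call(cbind, lapply(train$trials, function(tr) tr$data))
  if (ncol(pooled) < 2) stop("need >= 2 pooled samples per channel")
  mu <- rowMeans(pooled)
  sdv <- apply(pooled, 1, stats::sd)
  bad <- which(sdv < 1e-12)
  if (length(bad)) {
    stop("degenerate (constant) channel(s): ",
         paste(train$layout$names[bad], collapse = ", "))
  }
  channel_stats(mu, sdv)
}

#' Standardize trials with previously fitted statistics
#'
#' Applies `(value - mean) / sd` per channel using the supplied (training)
#' statistics; nothing is re-fitted on the argument set, so held-out data
#' keep the training-set scaling.
#'
#' @param stats A [channel_stats()] object.
#' @param set A [trial_set()] with a matching channel count.
#' @return The standardized `TrialSet`.
#' @export
apply_channel_stats <- function(stats, set) {
  if (length(stats$mean) != n_channels(set$layout)) {
    stop("stats cover ", length(stats$mean), " channels, set has ",
         n_channels(set$layout))
  }
  map_trials(set, function(tr) {
    eeg_trial((tr$data - stats$mean) / stats$sd,
              tr$rate, tr$cue_index, tr$label)
  })
}

#' Extract the post-cue task segment
#'
#' Keeps `task_sec` seconds starting at the cue; the cue index of the
#' returned trial is 0.
#'
#' @param trial An [eeg_trial()].
#' @param task_sec Task duration in seconds.
#' @export
extract_task_segment <- function(trial, task_sec = 4) {
  n_task <- as.integer(round(task_sec * trial$rate))
  start <- trial$cue_index + 1L  # 1-based first task sample
  if (start + n_task - 1L > ncol(trial$data)) {
    stop("trial has fewer than ", n_task, " post-cue samples")
  }
  eeg_trial(trial$data[, start:(start + n_task - 1L), drop = FALSE],
            trial$rate, 0L, trial$label)
}

#' Trim filter edge artifacts from both ends of a trial
#'
#' Removes `round(trim_sec * rate)` samples from each end; applied last in
#' the preprocessing chain so that transient filter edges never reach the
#' classifier (a 1000-sample task segment at 250 Hz becomes the canonical
#' 700-sample input).
#'
#' @param trial An [eeg_trial()].
#' @param trim_sec Seconds to remove from each end (default 0.6).
#' @return The cropped `EEGTrial`; the cue index is shifted (clamped at 0).
#' @export
crop_edges <- function(trial, trim_sec = 0.6) {
  n_trim <- as.integer(round(trim_sec * trial$rate))
  if (n_trim == 0) return(trial)
  n <- ncol(trial$data)
  if (n <= 2 * n_trim) {
    stop("trial of ", n, " samples is too short to crop ", n_trim,
         " samples from each end")
  }
  eeg_trial(trial$data[, (n_trim + 1):(n - n_trim), drop = FALSE],
            trial$rate, max(0L, trial$cue_index - n_trim), trial$label)
}

#' Full preprocessing chain
#'
#' Runs the standard pipeline on a training set and, optionally, further
#' sets that must reuse the training normalization statistics: large
#' Laplacian, 1-50 Hz band-pass, resampling to 250 Hz, baseline correction
#' against the pre-cue second, channel-wise standardization (fitted on the
#' training set only), then extraction of the post-cue task segment with
#' 0.6 s trimmed from each end.
#'
#' @param train A [trial_set()] used both as data and to fit normalization.
#' @param others Optional named list of additional `TrialSet`s (e.g. test
#'   data) transformed with the training statistics.
#' @param low_hz,high_hz Band-pass edges (Hz).
#' @param target_hz Resampling target (Hz).
#' @param baseline_sec Pre-cue baseline length (s).
#' @param task_sec Post-cue task duration (s); `NULL` keeps whole trials.
#' @param trim_sec Edge trim per side (s).
#' @param laplacian Apply the large Laplacian filter first?
#' @return If `others` is `NULL`, the processed training `TrialSet`;
#'   otherwise a list `(train = ..., <name> = ...)` plus the fitted
#'   `"stats"`.
#' @export
preprocess_set <- function(train, others = NULL, low_hz = 1, high_hz = 50,
                           target_hz = 250, baseline_sec = 1,
                           task_sec = 4, trim_sec = 0.6, laplacian = TRUE) {
  stage <- function(set) {
    if (laplacian) set <- apply_large_laplacian(set)
    set <- bandpass_trials(set, low_hz, high_hz)
    set <- resample_trials(set, target_hz)
    map_trials(set, function(tr) baseline_correct(tr, baseline_sec))
  }
  finish <- function(set) {
    if (!is.null(task_sec)) {
      set <- map_trials(set, function(tr) extract_task_segment(tr, task_sec))
    }
    map_trials(set, function(tr) crop_edges(tr, trim_sec))
  }
  train2 <- stage(train)
  stats <- fit_channel_stats(train2)
  train_out <- finish(apply_channel_stats(stats, train2))
  if (is.null(others)) return(train_out)
  out <- c(list(train = train_out),
           lapply(others, function(s) finish(apply_channel_stats(stats, stage(s)))))
  out$stats <- stats
  out
}
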