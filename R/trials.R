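#' Single EEG trial
#'
#' A trial is a channels x time numeric matrix with its sampling rate, the
#' sample index of the cue onset (0-based) and, when known, a class label in
#' `1..M`.
#'
#' @param data Numeric matrix, channels x time.
#' @param rate Sampling frequency in Hz.
#' @param cue_index 0-based sample index of the cue onset.
#' @param label Integer class label, or `NA` for an unlabeled trial.
#' @return An `EEGTrial` object.
#' @export
eeg_trial <- function(data, rate, cue_index = 0L, label = NA_integer_) {
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  if (!all(is.finite(data))) stop("trial data must be finite")
  if (nrow(data) < 1 || ncol(data) < 1) stop("trial needs >= 1 channel and >= 1 sample")
  rate <- as.numeric(rate)
  if (!is.finite(rate) || rate <= 0) stop("rate must be a positive number (Hz)")
  cue_index <- as.integer(cue_index)
  if (cue_index < 0 || cue_index >= ncol(data)) {
    stop("cue_index must lie in [0, time): got ", cue_index,
         " for ", ncol(data), " samples")
  }
  if (!is.na(label)) {
    label <- as.integer(label)
    if (label < 1) stop("label must be a positive class index")
  } else {
    label <- NA_integer_
  }
  structure(list(data = data, rate = rate, cue_index = cue_index,
                 label = label),
            class = "EEGTrial")
}

#' @export
print.EEGTrial <- function(x, ...) {
  cat(sprintf("<EEGTrial> %d ch x %d samples @ %g Hz, cue %d, label %s\n",
              nrow(x$data), ncol(x$data), x$rate, x$cue_index,
              ifelse(is.na(x$label), "-", x$label)))
  invisible(x)
}

#' Collection of trials sharing a layout
#'
#' @param trials List of [eeg_trial()] objects with identical channel count
#'   and sampling rate.
#' @param layout A [channel_layout()] matching the trials' channel count.
#' @param n_classes Number of classes `M`; labels present in the trials must
#'   lie in `1..M`.
#' @return A `TrialSet` object.
#' @export
trial_set <- function(trials, layout, n_classes) {
  if (!inherits(layout, "ChannelLayout")) stop("layout must be a ChannelLayout")
  n_classes <- as.integer(n_classes)
  if (n_classes < 1) stop("n_classes must be >= 1")
  nc <- n_channels(layout)
  for (i in seq_along(trials)) {
    tr <- trials[[i]]
    if (!inherits(tr, "EEGTrial")) stop("element ", i, " is not an EEGTrial")
    if (nrow(tr$data) != nc) {
      stop("trial ", i, " has ", nrow(tr$data), " channels, layout has ", nc)
    }
    if (i > 1 && tr$rate != trials[[1]]$rate) {
      stop("trial ", i, " rate ", tr$rate, " differs from ", trials[[1]]$rate)
    }
    if (!is.na(tr$label) && tr$label > n_classes) {
      stop("trial ", i, " label ", tr$label, " exceeds n_classes = ", n_classes)
    }
  }
  structure(list(trials = trials, layout = layout, n_classes = n_classes),
            class = "TrialSet")
}

#' @export
print.TrialSet <- function(x, ...) {
  lab <- labels_of(x)
  cat(sprintf("<TrialSet> %d trials, %d channels, %d classes (%d labeled)\n",
              length(x$trials), n_channels(x$layout), x$n_classes,
              sum(!is.na(lab))))
  invisible(x)
}

#' @export
length.TrialSet <- function(x) length(x$trials)

#' Trial labels as an integer vector (`NA` where unlabeled)
#' @param set A `TrialSet`.
#' @export
labels_of <- function(set) {
  vapply(set$trials, function(tr) tr$label, integer(1))
}

set_rate <- function(set) if (length(set$trials)) set$trials[[1]]$rate else NA_real_

#' Apply a per-trial transformation, keeping layout and class count
#' @param set A `TrialSet`.
#' @param f Function mapping an `EEGTrial` to an `EEGTrial`.
#' @export
map_trials <- function(set, f) {
  trial_set(lapply(set$trials, f), set$layout, set$n_classes)
}

#' Subset a TrialSet by trial index
#' @param set A `TrialSet`.
#' @param idx Integer indices of trials to keep.
#' @export
subset_trials <- function(set, idx) {
  trial_set(set$trials[idx], set$layout, set$n_classes)
}

#' Per-channel normalization statistics
#'
#' Mean and standard deviation per channel, estimated on training data and
#' later applied unchanged to held-out data.
#'
#' @param mean,sd Numeric vectors, one entry per channel; `sd` strictly
#'   positive.
#' @export
channel_stats <- function(mean, sd) {
  if (length(mean) != length(sd)) stop("mean and sd lengths differ")
  if (any(!is.finite(mean)) || any(!is.finite(sd))) stop("stats must be finite")
  if (any(sd <= 0)) stop("sd must be strictly positive")
  structure(list(mean = as.numeric(mean), sd = as.numeric(sd)),
            class = "ChannelStats")
}
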