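#' Sliding-window segmentation of a trial
#'
#' Cuts a trial into contiguous, half-open `[start, start + length)` windows
#' at starts `0, stride, 2*stride, ...` (0-based), yielding
#' `floor((time - length) / stride) + 1` windows; no padding is applied. A
#' 700-sample trial at length 512 and stride 1 yields 189 windows, the
#' standard augmentation for a 2-s decoder input.
#'
#' @param trial An [eeg_trial()] with at least `length` samples.
#' @param length Window length in samples (default 512).
#' @param stride Hop between consecutive window starts (default 1).
#' @param trial_id Provenance index stored with the batch.
#' @return A `WindowBatch`: list with `windows` (array
#'   `n_windows x channels x length`), `starts` (0-based) and `trial_id`.
#' @export
sliding_windows <- function(trial, length = 512, stride = 1, trial_id = 1L) {
  n <- ncol(trial$data)
  length <- as.integer(length); stride <- as.integer(stride)
  if (stride < 1) stop("stride must be >= 1")
  if (length > n) {
    stop("window length ", length, " exceeds trial length ", n)
  }
  starts <- seq.int(0L, n - length, by = stride)
  w <- array(0, dim = c(base::length(starts), nrow(trial$data), length))
  for (i in seq_along(starts)) {
    w[i, , ] <- trial$data[, (starts[i] + 1):(starts[i] + length)]
  }
  structure(list(windows = w, starts = starts, trial_id = trial_id),
            class = "WindowBatch")
}

#' Majority vote over per-window class predictions
#'
#' Returns the most frequent label; ties are broken deterministically in
#' favour of the smallest class index.
#'
#' @param labels Non-empty integer vector of class predictions.
#' @return The winning class as an integer.
#' @export
majority_vote <- function(labels) {
  if (length(labels) == 0) stop("majority_vote needs a non-empty label vector")
  labels <- as.integer(labels)
  counts <- tabulate(labels)
  which.max(counts)  # which.max takes the first (smallest index) maximum
}

#' Stack training windows from a whole TrialSet
#'
#' Windows every trial and concatenates the segments into the 4-d batch
#' tensor consumed by the networks (`n x 1 x channels x length`), with each
#' window inheriting its parent trial's label.
#'
#' @param set A [trial_set()].
#' @param length,stride Window parameters passed to [sliding_windows()].
#' @return List with `x` (array `n x 1 x C x length`), `y` (labels, `NA`
#'   where the parent trial is unlabeled) and `trial_id`.
#' @export
windows_tensor <- function(set, length = 512, stride = 1) {
  batches <- lapply(seq_along(set$trials), function(i) {
    sliding_windows(set$trials[[i]], length, stride, trial_id = i)
  })
  n_tot <- sum(vapply(batches, function(b) dim(b$windows)[1], integer(1)))
  C <- n_channels(set$layout)
  x <- array(0, dim = c(n_tot, 1, C, length))
  y <- integer(n_tot); tid <- integer(n_tot)
  at <- 1L
  for (i in seq_along(batches)) {
    b <- batches[[i]]
    k <- dim(b$windows)[1]
    x[at:(at + k - 1), 1, , ] <- b$windows
    y[at:(at + k - 1)] <- set$trials[[i]]$label
    tid[at:(at + k - 1)] <- i
    at <- at + k
  }
  list(x = x, y = y, trial_id = tid)
}
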