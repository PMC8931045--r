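# Class-conditional motor-imagery-like EEG simulator.
#
# A small set of band-limited cortical sources is mixed into the electrode
# array through a known linear forward model (Gaussian spatial spread over
# the montage, unit-norm columns). Each class attenuates a subset of
# sources after the cue (event-related desynchronization of the mu rhythm),
# on top of class-independent 1/f background and white sensor noise. The
# known mixing columns and class gains are the ground truth against which
# classification, semi-supervised gains and activation-pattern recovery
# are all tested.

#' Oscillatory source specification
#'
#' @param center 2-D scalp coordinate of the source projection centre.
#' @param class_gain Per-class post-cue amplitude multipliers (a value < 1
#'   is desynchronization for that class).
#' @param band `(low, high)` Hz of the source oscillation (default mu,
#'   8-12 Hz).
#' @param spread Gaussian spatial width in layout units.
#' @export
source_spec <- function(center, class_gain, band = c(8, 12), spread = 0.25) {
  if (length(band) != 2 || band[1] <= 0 || band[1] >= band[2]) {
    stop("band must be (low, high) with 0 < low < high")
  }
  if (spread <= 0) stop("spread must be positive")
  if (any(class_gain <= 0)) stop("class_gain entries must be positive")
  structure(list(center = as.numeric(center),
                 class_gain = as.numeric(class_gain),
                 band = as.numeric(band), spread = spread),
            class = "SourceSpec")
}

#' Default 4-class motor-imagery source geometry
#'
#' Five mu-band sources with the canonical class-to-region assignment:
#' left-hand imagery desynchronizes the right central source, right-hand
#' the left central source, feet the midline source, and tongue the
#' bilateral temporal pair.
#'
#' @param erd Post-cue amplitude multiplier of a desynchronized source
#'   (default 0.3, a strong ERD).
#' @return List of [source_spec()]s for classes
#'   (left hand, right hand, feet, tongue).
#' @export
default_mi_sources <- function(erd = 0.3) {
  list(
    source_spec(c( 0.37,  0.00), c(erd, 1, 1, 1)),   # right central (C4)
    source_spec(c(-0.37,  0.00), c(1, erd, 1, 1)),   # left central (C3)
    source_spec(c( 0.00,  0.15), c(1, 1, erd, 1)),   # midline central
    source_spec(c(-0.60, -0.05), c(1, 1, 1, erd)),   # left temporal
    source_spec(c( 0.60, -0.05), c(1, 1, 1, erd))    # right temporal
  )
}

#' Linear forward model over a layout
#'
#' Column `s` of the mixing matrix is the Gaussian spatial profile
#' `exp(-||pos - center_s||^2 / (2 spread_s^2))` over the electrodes,
#' normalized to unit Euclidean norm.
#'
#' @param layout A [channel_layout()].
#' @param sources List of [source_spec()]s.
#' @return A `ForwardModel` with `A_true` (channels x sources), `sources`
#'   and `layout`.
#' @export
build_forward_model <- function(layout, sources) {
  if (length(sources) < 1) stop("need >= 1 source")
  pos <- layout$positions
  A <- vapply(sources, function(src) {
    d2 <- (pos[, 1] - src$center[1])^2 + (pos[, 2] - src$center[2])^2
    col <- exp(-d2 / (2 * src$spread^2))
    nrm <- sqrt(sum(col^2))
    if (nrm < 1e-12) {
      stop("source at (", src$center[1], ", ", src$center[2],
           ") projects to no electrode")
    }
    col / nrm
  }, numeric(nrow(pos)))
  structure(list(A_true = A, sources = sources, layout = layout),
            class = "ForwardModel")
}

#' Simulation configuration
#'
#' @param n_per_class Trials per class.
#' @param rate Sampling rate (Hz).
#' @param baseline_sec Pre-cue baseline duration (s).
#' @param task_sec Post-cue task duration (s).
#' @param snr Source-to-noise power ratio (baseline amplitudes).
#' @param seed RNG seed.
#' @export
sim_config <- function(n_per_class = 40, rate = 250, baseline_sec = 1,
                       task_sec = 4, snr = 10, seed = 1) {
  if (snr <= 0) stop("snr must be positive")
  if (n_per_class < 1 || rate <= 0 || baseline_sec < 0 || task_sec <= 0) {
    stop("invalid simulation parameters")
  }
  structure(list(n_per_class = as.integer(n_per_class), rate = rate,
                 baseline_sec = baseline_sec, task_sec = task_sec,
                 snr = snr, seed = as.integer(seed)),
            class = "SimConfig")
}

# 1/f-shaped noise via spectral shaping of white noise
pink_noise <- function(n) {
  w <- stats::rnorm(n)
  W <- stats::fft(w)
  f <- c(1, seq_len(n - 1))
  f <- pmin(f, n - f + 1)             # two-sided frequency index
  W <- W / sqrt(pmax(f, 1))
  x <- Re(stats::fft(W, inverse = TRUE)) / n
  x / stats::sd(x)
}

#' Simulate class-conditional EEG trials
#'
#' Each trial of class `k` drives every source with band-limited Gaussian
#' noise whose post-cue amplitude is scaled by that source's
#' `class_gain[k]`; channel data are the forward-mixed sources plus 1/f
#' background and white sensor noise scaled so the baseline-source to
#' total-noise power ratio equals `config$snr`. Identical seeds give
#' bitwise-identical sets.
#'
#' @param model A [build_forward_model()].
#' @param config A [sim_config()].
#' @return A labeled [trial_set()] with `cue_index = baseline samples`;
#'   ground truth is recoverable via [ground_truth()].
#' @export
simulate_trials <- function(model, config = sim_config()) {
  set.seed(config$seed)
  M <- length(model$sources[[1]]$class_gain)
  n_base <- as.integer(round(config$baseline_sec * config$rate))
  n_task <- as.integer(round(config$task_sec * config$rate))
  n_time <- n_base + n_task
  C <- nrow(model$A_true)
  nS <- length(model$sources)
  filters <- lapply(model$sources, function(src) {
    signal::butter(4, src$band / (config$rate / 2), type = "pass")
  })
  labels <- rep(seq_len(M), config$n_per_class)
  labels <- labels[sample.int(length(labels))]
  trials <- lapply(labels, function(k) {
    S <- matrix(0, nS, n_time)
    for (s in seq_len(nS)) {
      raw <- signal::filtfilt(filters[[s]], stats::rnorm(n_time + 2 * config$rate))
      raw <- raw[(config$rate + 1):(config$rate + n_time)]  # discard filter edges
      raw <- raw / stats::sd(raw)
      gain <- c(rep(1, n_base), rep(model$sources[[s]]$class_gain[k], n_task))
      S[s, ] <- raw * gain
    }
    sig <- model$A_true %*% S
    noise <- t(vapply(seq_len(C), function(ch) {
      0.8 * pink_noise(n_time) + 0.2 * stats::rnorm(n_time)
    }, numeric(n_time)))
    p_sig <- mean(sig[, seq_len(max(n_base, 1))]^2)
    if (n_base == 0) p_sig <- mean(sig^2)
    p_noise <- mean(noise^2)
    noise <- noise * sqrt(p_sig / (config$snr * p_noise))
    eeg_trial(sig + noise, config$rate, cue_index = n_base, label = k)
  })
  out <- trial_set(trials, model$layout, M)
  attr(out, "ground_truth") <- ground_truth(model)
  out
}

#' Ground truth of a forward model
#'
#' Exposes the true mixing columns and per-source class gains for recovery
#' tests (e.g. cosine similarity of estimated activation patterns with the
#' generating column).
#'
#' @param model A [build_forward_model()].
#' @return List with `A_true` and `class_gain` (sources x classes matrix).
#' @export
ground_truth <- function(model) {
  list(A_true = model$A_true,
       class_gain = do.call(rbind, lapply(model$sources,
                                          function(s) s$class_gain)))
}
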