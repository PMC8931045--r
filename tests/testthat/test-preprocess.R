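# Spatial filtering, band-pass, resampling, baseline, normalization, crop.

test_that("large Laplacian subtracts the mean of available neighbours", {
  # 5 channels on a line, spacing 0.2; centre channel has 4 admissible
  # neighbours, the end channel only 2 within 1.5x the median spacing
  lay <- channel_layout(paste0("c", 1:5), cbind(seq(-0.4, 0.4, 0.2), 0))
  x <- matrix(1, 5, 10)
  x[3, ] <- 2                       # centre: neighbours c1,c2,c4,c5 all 1
  x[1, ] <- 5; x[2, ] <- 1; x[4, ] <- 1; x[5, ] <- 3
  set <- trial_set(list(eeg_trial(x, 100, 0)), lay, 1)
  out <- apply_large_laplacian(set)$trials[[1]]$data
  # c3's four nearest are c1,c2,c4,c5 but only c2 (0.2) and c4 (0.2) and
  # c1/c5 (0.4) -- all within 1.5 * 0.2 = 0.3? no: 0.4 > 0.3, so c3 uses
  # c2 and c4 only: 2 - mean(1, 1) = 1
  expect_equal(out[3, ], rep(1, 10))
  # c1 (value 5) has admissible neighbour c2 only: 5 - 1 = 4
  expect_equal(out[1, ], rep(4, 10))
})

test_that("Laplacian handles full and partial neighbourhoods exactly", {
  # plus-shaped montage: centre with 4 equidistant neighbours
  lay <- channel_layout(c("mid", "up", "down", "left", "right"),
                        rbind(c(0, 0), c(0, 0.2), c(0, -0.2),
                              c(-0.2, 0), c(0.2, 0)))
  x <- matrix(c(2, 1, 1, 1, 1), 5, 8)
  out <- apply_large_laplacian(trial_set(list(eeg_trial(x, 100, 0)), lay, 1))
  expect_equal(out$trials[[1]]$data[1, ], rep(1, 8))  # 2 - mean(1,1,1,1)
  # two-channel boundary case: target 5, neighbours 1 and 3 -> 5 - 2 = 3
  lay2 <- channel_layout(c("a", "b", "c"),
                         rbind(c(0, 0), c(0.2, 0), c(-0.2, 0)))
  x2 <- matrix(c(5, 1, 3), 3, 4)
  out2 <- apply_large_laplacian(trial_set(list(eeg_trial(x2, 100, 0)), lay2, 1))
  expect_equal(out2$trials[[1]]$data[1, ], rep(3, 4))
})

test_that("Laplacian annihilates spatially constant data", {
  set <- tiny_sim(n_per_class = 1, seed = 2)
  const <- map_trials(set, function(tr) {
    eeg_trial(matrix(3.7, nrow(tr$data), ncol(tr$data)), tr$rate,
              tr$cue_index, tr$label)
  })
  out <- apply_large_laplacian(const)
  for (tr in out$trials) expect_lt(max(abs(tr$data)), 1e-12)
  expect_error(apply_large_laplacian(
    trial_set(list(eeg_trial(matrix(1, 1, 5), 10)),
              channel_layout("a", cbind(0, 0)), 1)), "2 channels")
})

test_that("band-pass keeps the passband and rejects DC and stopband", {
  rate <- 250; n <- rate * 4
  t <- seq_len(n) / rate
  mk <- function(v) trial_set(list(eeg_trial(rbind(v, v), rate, 0)),
                              tiny_layout(2), 1)
  trim <- rate:(n - rate)                 # drop the 1-s filter edges
  # DC in -> ~nothing out; the 1-Hz high-pass corner has a seconds-long
  # step transient, so judge DC rejection on a longer record
  n8 <- rate * 8
  dc8 <- trial_set(list(eeg_trial(rbind(rep(1, n8), rep(1, n8)), rate, 0)),
                   tiny_layout(2), 1)
  dc <- bandpass_trials(dc8, 1, 50)$trials[[1]]$data[1, (3 * rate):(n8 - 3 * rate)]
  expect_lt(max(abs(dc)), 0.01)
  # 10 Hz passband tone preserved within 5%
  s10 <- bandpass_trials(mk(sin(2 * pi * 10 * t)), 1, 50)$trials[[1]]$data[1, trim]
  expect_lt(abs(max(abs(s10)) - 1), 0.05)
  # 100 Hz stopband tone attenuated by > 20 dB
  s100 <- bandpass_trials(mk(sin(2 * pi * 100 * t)), 1, 50)$trials[[1]]$data[1, trim]
  expect_lt(20 * log10(max(abs(s100))), -20)
  expect_error(bandpass_trials(mk(rep(0, n)), 50, 1), "low_hz")
  expect_error(bandpass_trials(mk(rep(0, n)), 1, 200), "Nyquist")
})

test_that("resampling decimates 1000 Hz to 250 Hz with the spectrum intact", {
  rate <- 1000; n <- 4000
  t <- seq_len(n) / rate
  v <- sin(2 * pi * 10 * t)
  set <- trial_set(list(eeg_trial(rbind(v, v), rate, 1000)), tiny_layout(2), 1)
  out <- resample_trials(set, 250)
  tr <- out$trials[[1]]
  expect_equal(tr$rate, 250)
  expect_equal(ncol(tr$data), 1000)
  expect_equal(tr$cue_index, 250L)
  # dominant spectral peak still at 10 Hz
  sp <- Mod(stats::fft(tr$data[1, ]))[1:500]
  peak_hz <- (which.max(sp[-1])) * 250 / 1000
  expect_equal(peak_hz, 10, tolerance = 0.3)
  # identity when already at target
  expect_identical(resample_trials(out, 250)$trials[[1]]$data, tr$data)
  expect_error(resample_trials(set, 300), "integer multiple")
})

test_that("baseline correction zeroes the pre-cue mean", {
  tr <- tiny_trial(C = 3, time = 300, rate = 100, cue = 120)
  out <- baseline_correct(tr)
  base_cols <- 21:120                   # the 1 s window before the cue
  expect_lt(max(abs(rowMeans(out$data[, base_cols]))), 1e-9)
  # constant channel becomes all zeros
  cst <- eeg_trial(matrix(3, 2, 200), 100, 150)
  expect_lt(max(abs(baseline_correct(cst)$data)), 1e-12)
  expect_error(baseline_correct(tiny_trial(cue = 50)), "pre-cue")
})

test_that("channel statistics standardize train exactly and transfer to test", {
  train <- tiny_set(n_trials = 4, seed = 3)
  stats <- fit_channel_stats(train)
  normed <- apply_channel_stats(stats, train)
  pooled <- do.call(cbind, lapply(normed$trials, function(tr) tr$data))
  expect_lt(max(abs(rowMeans(pooled))), 1e-6)
  expect_lt(max(abs(apply(pooled, 1, sd) - 1)), 1e-6)
  # hand-computed two-trial case: samples {1,3} and {5,7} on one channel
  lay1 <- channel_layout("only", cbind(0, 0))
  s2 <- trial_set(list(eeg_trial(matrix(c(1, 3), 1, 2), 2, 0),
                       eeg_trial(matrix(c(5, 7), 1, 2), 2, 0)), lay1, 1)
  st <- fit_channel_stats(s2)
  expect_equal(st$mean, 4)
  expect_equal(st$sd, sd(c(1, 3, 5, 7)))
  # (4 - 2) / 2 = 1
  expect_equal(as.numeric(apply_channel_stats(
    channel_stats(2, 2),
    trial_set(list(eeg_trial(matrix(4, 1, 1), 2, 0)), lay1, 1)
  )$trials[[1]]$data), 1)
  # constant channel flagged
  cst <- trial_set(list(eeg_trial(rbind(rep(2, 50), rnorm(50)), 10, 0)),
                   tiny_layout(2), 1)
  expect_error(fit_channel_stats(cst), "degenerate")
  expect_error(apply_channel_stats(st, train), "channels")
})

test_that("task extraction and edge cropping give the canonical lengths", {
  # 250 Hz trial of 1000 post-cue samples -> 700 after 0.6 s per-end crop
  tr <- eeg_trial(matrix(rnorm(2 * 1250), 2, 1250), 250, 250)
  task <- extract_task_segment(tr, 4)
  expect_equal(ncol(task$data), 1000)
  expect_equal(task$cue_index, 0L)
  cropped <- crop_edges(task, 0.6)
  expect_equal(ncol(cropped$data), 700)
  # 100 Hz, 500 samples, 0.6 s trim -> 380
  tr2 <- eeg_trial(matrix(rnorm(500), 1, 500), 100, 200)
  expect_equal(ncol(crop_edges(tr2, 0.6)$data), 380)
  expect_identical(crop_edges(tr2, 0)$data, tr2$data)
  expect_error(crop_edges(eeg_trial(matrix(1, 1, 100), 100, 0), 0.6),
               "too short")
})

test_that("the full chain preserves channel count/order and emits 22x700", {
  set <- tiny_sim(n_per_class = 2, seed = 5)
  test <- tiny_sim(n_per_class = 1, seed = 6)
  out <- preprocess_set(set, others = list(test = test))
  expect_equal(dim(out$train$trials[[1]]$data), c(22, 700))
  expect_equal(dim(out$test$trials[[1]]$data), c(22, 700))
  expect_identical(out$train$layout$names, set$layout$names)
  expect_identical(labels_of(out$train), labels_of(set))
  # test normalization reuses train statistics, not its own
  own <- fit_channel_stats(out$test)
  expect_gt(max(abs(own$mean)), 1e-8)
})
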