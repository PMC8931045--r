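# Forward-model simulator: geometry, mixing, class structure, determinism.

test_that("the default montage has 22 mirror-symmetric on-disc positions", {
  lay <- default_layout_22()
  expect_length(lay$names, 22)
  pos <- lay$positions
  expect_true(all(rowSums(pos^2) <= 1))
  # every off-midline channel has a mirrored counterpart
  for (i in which(abs(pos[, 1]) > 1e-9)) {
    j <- which(abs(pos[, 1] + pos[i, 1]) < 1e-9 &
               abs(pos[, 2] - pos[i, 2]) < 1e-9)
    expect_length(j, 1)
  }
})

test_that("forward-model columns are unit-norm Gaussian profiles", {
  lay <- default_layout_22()
  fm <- build_forward_model(lay, default_mi_sources())
  expect_equal(dim(fm$A_true), c(22, 5))
  expect_lt(max(abs(sqrt(colSums(fm$A_true^2)) - 1)), 1e-9)
  # a source centred on an electrode loads that electrode most
  src <- source_spec(lay$positions["C4", ], c(1, 1))
  col <- build_forward_model(lay, list(src))$A_true[, 1]
  expect_equal(unname(which.max(col)), which(lay$names == "C4"))
  # mirrored sources give mirrored columns
  s_l <- build_forward_model(lay, list(source_spec(c(-0.37, 0), c(1, 1))))$A_true[, 1]
  s_r <- build_forward_model(lay, list(source_spec(c(0.37, 0), c(1, 1))))$A_true[, 1]
  expect_equal(unname(s_l[lay$names == "C3"]), unname(s_r[lay$names == "C4"]),
               tolerance = 1e-9)
  expect_error(build_forward_model(lay, list(source_spec(c(9, 9), 1, spread = 0.05))),
               "no electrode")
  expect_error(build_forward_model(lay, list()), ">= 1 source")
})

test_that("simulation is bitwise seed-reproducible and well-formed", {
  fm <- build_forward_model(default_layout_22(), default_mi_sources())
  cfg <- sim_config(n_per_class = 2, seed = 7)
  a <- simulate_trials(fm, cfg)
  b <- simulate_trials(fm, cfg)
  expect_identical(lapply(a$trials, function(t) t$data),
                   lapply(b$trials, function(t) t$data))
  expect_identical(labels_of(a), labels_of(b))
  expect_equal(sort(table(labels_of(a))), sort(table(c(1, 1, 2, 2, 3, 3, 4, 4))),
               ignore_attr = TRUE)
  expect_equal(a$trials[[1]]$cue_index, 250L)
  expect_equal(ncol(a$trials[[1]]$data), 1250)
  expect_error(simulate_trials(fm, sim_config(snr = -1)), "snr")
})

test_that("realized baseline SNR follows the configured power ratio", {
  # noise is scaled so baseline P_signal / P_noise == snr; pooled broadband
  # baseline power is therefore P_s (1 + 1/snr), so the power ratio between
  # snr = 0.5 and snr = 10 must be (1 + 2) / (1 + 0.1) = 2.73 within 20%
  fm <- build_forward_model(default_layout_22(), default_mi_sources())
  bp <- function(set) {
    mean(vapply(set$trials, function(tr) mean(tr$data[, 1:250]^2), numeric(1)))
  }
  hi <- simulate_trials(fm, sim_config(n_per_class = 4, snr = 10, seed = 3))
  lo <- simulate_trials(fm, sim_config(n_per_class = 4, snr = 0.5, seed = 3))
  expect_equal(bp(lo) / bp(hi), 3 / 1.1, tolerance = 0.2)
})

test_that("class gains produce the expected contralateral ERD signature", {
  fm <- build_forward_model(default_layout_22(), default_mi_sources(erd = 0.3))
  set <- simulate_trials(fm, sim_config(n_per_class = 8, snr = 10, seed = 9))
  lay <- set$layout
  bf <- signal::butter(4, c(8, 12) / 125, "pass")
  task_power <- function(tr, ch) {
    v <- tr$data[ch, 251:1250]
    mean(signal::filtfilt(bf, v)^2)
  }
  y <- labels_of(set)
  c4 <- which(lay$names == "C4")
  # left-hand trials (class 1) suppress the right-central source post-cue
  p_lh <- mean(vapply(set$trials[y == 1], task_power, numeric(1), ch = c4))
  p_other <- mean(vapply(set$trials[y == 2], task_power, numeric(1), ch = c4))
  expect_lt(p_lh, p_other)
  # null construction: equal gains -> no class contrast (10-seed average)
  fm0 <- build_forward_model(default_layout_22(), list(
    source_spec(c(0.37, 0), c(1, 1, 1, 1)),
    source_spec(c(-0.37, 0), c(1, 1, 1, 1))))
  diffs <- vapply(1:5, function(sd) {
    s0 <- simulate_trials(fm0, sim_config(n_per_class = 4, snr = 10, seed = sd))
    y0 <- labels_of(s0)
    mean(vapply(s0$trials[y0 == 1], task_power, numeric(1), ch = c4)) -
      mean(vapply(s0$trials[y0 == 2], task_power, numeric(1), ch = c4))
  }, numeric(1))
  expect_lt(abs(mean(diffs)),
            3 * stats::sd(diffs) / sqrt(length(diffs)) + 0.05)
})

test_that("baseline band power carries no class information", {
  fm <- build_forward_model(default_layout_22(), default_mi_sources())
  bf <- signal::butter(4, c(8, 12) / 125, "pass")
  pooled_p <- pooled_y <- c()
  for (sd in 1:4) {
    set <- simulate_trials(fm, sim_config(n_per_class = 6, snr = 10, seed = sd))
    pooled_y <- c(pooled_y, labels_of(set))
    pooled_p <- c(pooled_p, vapply(set$trials, function(tr) {
      mean(signal::filtfilt(bf, tr$data[12, 1:250])^2)   # C4 channel
    }, numeric(1)))
  }
  p <- stats::wilcox.test(pooled_p[pooled_y == 1], pooled_p[pooled_y == 2])$p.value
  expect_gt(p, 0.01)
})

test_that("ground truth round-trips through the archive metadata", {
  fm <- build_forward_model(default_layout_22(), default_mi_sources())
  gt <- ground_truth(fm)
  expect_identical(gt$A_true, fm$A_true)
  expect_equal(gt$class_gain[1, ], c(0.3, 1, 1, 1))
  set <- simulate_trials(fm, sim_config(n_per_class = 1, seed = 2))
  path <- withr::local_tempdir()
  write_trial_archive(set, path, extra = list(class_gain = gt$class_gain))
  back <- attr(read_trial_archive(path), "extra")
  expect_equal(matrix(unlist(back$class_gain), nrow = 5, byrow = TRUE),
               gt$class_gain, ignore_attr = TRUE)
})

test_that("a band-power LDA reference decoder separates the default classes", {
  skip_if_not_installed("MASS")
  fm <- build_forward_model(default_layout_22(), default_mi_sources(erd = 0.3))
  train <- preprocess_set(simulate_trials(fm, sim_config(n_per_class = 40, snr = 10, seed = 21)))
  test <- preprocess_set(simulate_trials(fm, sim_config(n_per_class = 10, snr = 10, seed = 22)))
  bf <- signal::butter(4, c(8, 12) / 125, "pass")
  feats <- function(set) {
    t(vapply(set$trials, function(tr) {
      log(apply(tr$data, 1, function(v) mean(signal::filtfilt(bf, v)^2)))
    }, numeric(22)))
  }
  fit <- MASS::lda(feats(train), grouping = factor(labels_of(train)))
  pred <- stats::predict(fit, feats(test))$class
  expect_gte(mean(pred == factor(labels_of(test))), 0.9)
})
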