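# Training loop contracts: finiteness, determinism, decision rule,
# learnability on separable data.

small_windows <- function(set, len = 64, stride = 160) {
  windows_tensor(set, length = len, stride = stride)
}

test_that("a 2-epoch adversarial run returns finite curves of length 2", {
  set <- tiny_sim(n_per_class = 2, seed = 23)
  pp <- preprocess_set(set)
  lw <- small_windows(pp)
  m <- shallow_convnet_spec(22, 64, 4, n_filters = 2, k_temporal = 9,
                            pool = c(16, 8))
  for (form in c("log", "wasserstein")) {
    fit <- train_adversarial(m, lw, mode = "gdal",
                             config = train_config(epochs = 2, batch_size = 8,
                                                   lr0 = 0.003, seed = 1),
                             loss = loss_config(adv_form = form))
    expect_equal(nrow(fit$curves), 2)
    expect_true(all(is.finite(unlist(fit$curves))))
    expect_s3_class(fit$gen, "GeneratorModel")
  }
})

test_that("identical seeds give bitwise-identical curves and parameters", {
  set <- tiny_sim(n_per_class = 2, seed = 24)
  pp <- preprocess_set(set)
  lw <- small_windows(pp)
  uw <- small_windows(pp)
  m <- shallow_convnet_spec(22, 64, 4, n_filters = 2, k_temporal = 9,
                            pool = c(16, 8))
  cfg <- train_config(epochs = 2, batch_size = 8, lr0 = 0.003, seed = 77)
  a <- train_adversarial(m, lw, unlabeled = uw, mode = "sgdal", config = cfg)
  b <- train_adversarial(m, lw, unlabeled = uw, mode = "sgdal", config = cfg)
  expect_identical(a$curves, b$curves)
  expect_identical(a$model$params, b$model$params)
  expect_identical(a$gen$params, b$gen$params)
  # a different seed changes the trajectory
  cfg2 <- cfg; cfg2$seed <- 78L
  c <- train_adversarial(m, lw, unlabeled = uw, mode = "sgdal", config = cfg2)
  expect_false(identical(a$curves, c$curves))
})

test_that("mode contracts are enforced", {
  set <- tiny_sim(n_per_class = 1, seed = 25)
  pp <- preprocess_set(set)
  lw <- small_windows(pp)
  m <- shallow_convnet_spec(22, 64, 4, n_filters = 2, k_temporal = 9,
                            pool = c(16, 8))
  expect_error(train_adversarial(m, lw, mode = "sgdal",
                                 config = train_config(epochs = 1)),
               "unlabeled")
  bad <- lw; bad$y[1] <- NA
  expect_error(train_adversarial(m, bad, mode = "vanilla",
                                 config = train_config(epochs = 1)),
               "NA labels")
})

test_that("supervised training learns a separable synthetic task", {
  # strong-ERD simulation is linearly separable in band power; the network
  # must reach >= 0.9 training accuracy within 15 epochs
  fm <- build_forward_model(default_layout_22(), default_mi_sources(0.3))
  train <- preprocess_set(simulate_trials(fm, sim_config(n_per_class = 10,
                                                         snr = 10, seed = 26)))
  lw <- windows_tensor(train, length = 64, stride = 64)
  m <- shallow_convnet_spec(22, 64, 4, n_filters = 8, k_temporal = 13,
                            pool = c(35, 7))
  fit <- train_adversarial(m, lw, mode = "vanilla",
                           config = train_config(epochs = 15, batch_size = 16,
                                                 lr0 = 0.003, beta1 = 0.9,
                                                 beta2 = 0.999, seed = 5))
  acc <- evaluate_accuracy(fit$model, train, stride = 32)
  expect_gte(acc, 0.9)
})

test_that("predict_trial ignores the realness unit and majority-votes", {
  m <- tiny_disc(C = 3, T = 32, M = 2)
  # craft a classifier head that always scores class 1 highest but gives
  # the realness unit the largest raw value
  m$params$classifier[[1]]$W[] <- 0
  m$params$classifier[[1]]$b <- c(2, 1, 50)
  tr <- eeg_trial(matrix(rnorm(3 * 40), 3, 40), 100, 0)
  expect_equal(predict_trial(m, tr), 1L)
  # per-window votes aggregate: flip the head so class 2 wins
  m$params$classifier[[1]]$b <- c(1, 2, 50)
  expect_equal(predict_trial(m, tr), 2L)
  expect_error(predict_trial(m, eeg_trial(matrix(0, 3, 10), 100, 0)),
               "exceeds")
})

test_that("an exact 95/94 window-vote margin decides the trial", {
  # hand-wired band-power classifier on 1 channel: feature is the window's
  # log mean power, class 1 scores +f and class 2 scores -f, so each
  # 2-sample window votes by amplitude; 95 high-power windows against 94
  # low-power windows must yield class 1
  m <- shallow_convnet_spec(1, 2, 2, n_filters = 1, k_temporal = 1,
                            pool = c(2, 1), dropout = 0)
  m <- init_model(m, 1)
  m$params$feature[[1]]$W <- matrix(1, 1, 1); m$params$feature[[1]]$b <- 0
  m$params$feature[[2]]$W <- matrix(1, 1, 1); m$params$feature[[2]]$b <- 0
  m$params$classifier[[1]]$W <- matrix(c(1, -1, 0), 1, 3)
  m$params$classifier[[1]]$b <- rep(0, 3)
  v <- c(rep(10, 95), rep(0.1, 95))           # 190 samples -> 189 windows
  tr <- eeg_trial(matrix(v, 1, 190), 250, 0)
  expect_equal(predict_trial(m, tr), 1L)
  # flip the margin: 94 high vs 95 low -> class 2
  v2 <- c(rep(10, 94), rep(0.1, 96))
  expect_equal(predict_trial(m, eeg_trial(matrix(v2, 1, 190), 250, 0)), 2L)
})
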