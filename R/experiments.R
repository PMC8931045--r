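# Label-ratio protocol runners and statistical comparison.

#' Stratified label subsampling
#'
#' Per class, `round(ratio/100 * n_class)` trials (round-half-up) keep
#' their labels; the remainder are either dropped entirely (`"discard"`,
#' the supervised data-scarcity protocol) or retained with labels removed
#' (`"unlabel"`, the semi-supervised protocol). Selection is seeded and
#' reproducible.
#'
#' @param set A fully labeled [trial_set()].
#' @param ratio Percentage in `{100, 75, 50, 25, 12.5}`.
#' @param mode `"discard"` or `"unlabel"`.
#' @param seed RNG seed for the per-class selection.
#' @return List with `labeled` and `unlabeled` `TrialSet`s (the latter
#'   empty in discard mode or at ratio 100).
#' @export
subsample_labels <- function(set, ratio, mode = c("discard", "unlabel"),
                             seed = 1) {
  mode <- match.arg(mode)
  if (!ratio %in% c(100, 75, 50, 25, 12.5)) {
    stop("ratio must be one of 100, 75, 50, 25, 12.5")
  }
  y <- labels_of(set)
  if (any(is.na(y))) stop("subsample_labels needs a fully labeled set")
  set.seed(seed)
  keep <- integer(0)
  for (k in sort(unique(y))) {
    idx <- which(y == k)
    n_keep <- floor(ratio / 100 * length(idx) + 0.5)  # round half up
    if (n_keep == 0) {
      stop("ratio ", ratio, "% leaves zero labeled trials in class ", k)
    }
    keep <- c(keep, sort(sample(idx, n_keep)))
  }
  rest <- setdiff(seq_along(set$trials), keep)
  labeled <- subset_trials(set, sort(keep))
  unlabeled <- if (mode == "unlabel" && length(rest) > 0) {
    map_trials(subset_trials(set, rest), function(tr) {
      eeg_trial(tr$data, tr$rate, tr$cue_index, NA_integer_)
    })
  } else {
    trial_set(list(), set$layout, set$n_classes)
  }
  list(labeled = labeled, unlabeled = unlabeled)
}

#' Scenario configuration for the protocol runner
#'
#' @param ratios Label percentages to sweep.
#' @param mode `"discard"` (supervised scarcity) or `"unlabel"`
#'   (semi-supervised; enables the sgdal method).
#' @param seeds Integer seeds; each seed redraws the label subset and the
#'   network initialization.
#' @param methods Subset of `c("vanilla", "gdal", "sgdal")`.
#' @param arch Architecture name passed to [discriminator_spec()].
#' @param arch_args List of extra arguments for the architecture builder.
#' @param window_length,train_stride,test_stride Windowing of training and
#'   test trials (samples).
#' @param train,loss [train_config()] / [loss_config()] templates (the
#'   config seed is overridden per cell).
#' @export
scenario_config <- function(ratios = c(100, 25), mode = c("unlabel", "discard"),
                            seeds = 1:3, methods = c("vanilla", "gdal", "sgdal"),
                            arch = "shallow",
                            arch_args = if (identical(arch, "shallow"))
                              list(n_filters = 8, k_temporal = 13,
                                   pool = c(35, 7)) else list(),
                            window_length = 128, train_stride = 128,
                            test_stride = 16,
                            train = train_config(epochs = 15, lr0 = 0.002),
                            loss = loss_config()) {
  mode <- match.arg(mode)
  stopifnot(all(ratios %in% c(100, 75, 50, 25, 12.5)), length(seeds) >= 1)
  methods <- match.arg(methods, several.ok = TRUE)
  structure(list(ratios = ratios, mode = mode, seeds = as.integer(seeds),
                 methods = methods, arch = arch, arch_args = arch_args,
                 window_length = as.integer(window_length),
                 train_stride = as.integer(train_stride),
                 test_stride = as.integer(test_stride),
                 train = train, loss = loss),
            class = "ScenarioConfig")
}

#' Train one protocol cell
#'
#' @param train_set,test_set Preprocessed, labeled [trial_set()]s.
#' @param method `"vanilla"`, `"gdal"` or `"sgdal"`.
#' @param ratio Label percentage.
#' @param seed Cell seed (label subset + training).
#' @param config A [scenario_config()].
#' @return Row list `(method, arch, ratio, seed, accuracy)`.
#' @export
run_cell <- function(train_set, test_set, method, ratio, seed, config) {
  split_mode <- if (method == "sgdal") "unlabel" else config$mode
  sub <- subsample_labels(train_set, ratio, split_mode, seed)
  lw <- windows_tensor(sub$labeled, config$window_length, config$train_stride)
  uw <- if (method == "sgdal" && length(sub$unlabeled$trials) > 0) {
    windows_tensor(sub$unlabeled, config$window_length, config$train_stride)
  } else NULL
  C <- n_channels(train_set$layout)
  model <- do.call(discriminator_spec,
                   c(list(arch = config$arch, C = C,
                          T = config$window_length,
                          M = train_set$n_classes), config$arch_args))
  cfg <- config$train
  cfg$seed <- seed
  fit <- train_adversarial(model, lw, unlabeled = uw,
                           mode = method, config = cfg, loss = config$loss)
  acc <- evaluate_accuracy(fit$model, test_set, stride = config$test_stride)
  list(method = method, arch = config$arch, ratio = ratio, seed = seed,
       accuracy = acc)
}

#' Run the full factorial scenario table
#'
#' Trains every `(ratio, seed, method)` cell on the training split and
#' evaluates windowed majority-vote accuracy on the held-out test split.
#' `sgdal` cells are skipped at ratio 100 (no unlabeled remainder exists)
#' and in discard mode.
#'
#' @inheritParams run_cell
#' @param config A [scenario_config()].
#' @param verbose Print one line per completed cell?
#' @return `ResultsTable` data.frame with columns method, arch, ratio,
#'   seed, accuracy.
#' @export
run_scenarios <- function(train_set, test_set, config = scenario_config(),
                          verbose = FALSE) {
  rows <- list()
  for (ratio in config$ratios) {
    for (seed in config$seeds) {
      for (method in config$methods) {
        if (method == "sgdal" && (ratio == 100 || config$mode == "discard")) next
        row <- tryCatch(
          run_cell(train_set, test_set, method, ratio, seed, config),
          error = function(e) {
            stop("cell (", method, ", ratio ", ratio, ", seed ", seed,
                 ") failed: ", conditionMessage(e))
          })
        rows[[length(rows) + 1]] <- row
        if (verbose) {
          message(sprintf("%-7s ratio %5.1f seed %d  acc %.3f",
                          method, ratio, seed, row$accuracy))
        }
      }
    }
  }
  do.call(rbind, lapply(rows, as.data.frame))
}

#' Desk-scale semi-supervision benchmark on simulated motor imagery
#'
#' The canonical reduced protocol: per seed, a fresh 4-class simulated
#' dataset (40 training and 20 test trials per class at the configured
#' SNR) is generated and preprocessed; a reduced Shallow ConvNet is then
#' trained as `vanilla` (25% labels), `gdal` (25% labels + generator) and
#' `sgdal` (25% labels + 75% unlabeled), and test accuracy is measured by
#' windowed majority voting. Every per-seed replicate redraws the dataset,
#' the label subset and the network initialization.
#'
#' @param seeds Integer seeds, one full replicate each.
#' @param ratio Label percentage (default 25).
#' @param n_train,n_test Trials per class in the training and test splits.
#' @param snr Simulator source-to-noise ratio.
#' @param erd Desynchronization gain of the simulator's sources.
#' @param config A [scenario_config()]; defaults to the reduced protocol.
#' @param verbose Print one line per cell?
#' @return Data.frame (method, arch, ratio, seed, accuracy).
#' @export
mi_benchmark <- function(seeds = 1:10, ratio = 25, n_train = 40, n_test = 20,
                         snr = 10, erd = 0.3,
                         config = benchmark_config(), verbose = FALSE) {
  fm <- build_forward_model(default_layout_22(), default_mi_sources(erd))
  rows <- list()
  for (sd in seeds) {
    train <- simulate_trials(fm, sim_config(n_per_class = n_train, snr = snr,
                                            seed = 20000 + sd))
    test <- simulate_trials(fm, sim_config(n_per_class = n_test, snr = snr,
                                           seed = 40000 + sd))
    pp <- preprocess_set(train, others = list(test = test))
    for (method in config$methods) {
      row <- run_cell(pp$train, pp$test, method, ratio, sd, config)
      rows[[length(rows) + 1]] <- row
      if (verbose) {
        message(sprintf("seed %d %-7s acc %.3f", sd, method, row$accuracy))
      }
    }
  }
  do.call(rbind, lapply(rows, as.data.frame))
}

#' Reduced-protocol configuration used by [mi_benchmark()]
#'
#' 0.26-s windows (64 samples) cut at stride 24 for training and scored at
#' stride 32 at test time, a 8-map / 1x13-kernel Shallow ConvNet, 15
#' epochs of Adam (3e-3, beta 0.9/0.999) with mini-batches of 16, one
#' generator update per two discriminator updates, and the bounded
#' log-realness adversarial objective.
#'
#' @param epochs Training epochs.
#' @param ... Overrides passed to [scenario_config()].
#' @export
benchmark_config <- function(epochs = 15, ...) {
  scenario_config(
    ratios = 25, mode = "unlabel", seeds = 1,
    methods = c("vanilla", "gdal", "sgdal"),
    arch = "shallow",
    arch_args = list(n_filters = 8, k_temporal = 13, pool = c(35, 7)),
    window_length = 64, train_stride = 24, test_stride = 32,
    train = train_config(epochs = epochs, lr0 = 0.003, batch_size = 16,
                         beta1 = 0.9, beta2 = 0.999, n_critic = 4),
    loss = loss_config(adv_form = "log"),
    ...)
}

#' Enumerate the comparison cells of a paired-method design
#'
#' One Wilcoxon comparison is made per (architecture, dataset, ratio)
#' cell of the factorial design; the Bonferroni family size is the number
#' of such cells.
#'
#' @param archs,datasets,ratios Character/numeric vectors of design levels.
#' @return data.frame of cells; `nrow()` is the family size.
#' @export
comparison_cells <- function(archs = c("shallow", "deep", "rstnn"),
                             datasets = c("III-3a", "III-4a", "IV-2a"),
                             ratios = c(100, 75, 50, 25, 12.5)) {
  expand.grid(arch = archs, dataset = datasets, ratio = ratios,
              stringsAsFactors = FALSE)
}

#' Bonferroni family size of the standard design
#' @inheritParams comparison_cells
#' @export
bonferroni_family_size <- function(archs = c("shallow", "deep", "rstnn"),
                                   datasets = c("III-3a", "III-4a", "IV-2a"),
                                   ratios = c(100, 75, 50, 25, 12.5)) {
  nrow(comparison_cells(archs, datasets, ratios))
}

#' Paired Wilcoxon signed-rank test with Bonferroni adjustment
#'
#' Two-tailed signed-rank test on the paired accuracy differences (exact
#' null for n <= 12 pairs without ties or zeros, normal approximation with
#' continuity correction otherwise), with the p-value multiplied by the
#' comparison family size and clamped at 1.
#'
#' @param acc_a,acc_b Paired accuracy vectors (equal length >= 5).
#' @param n_comparisons Bonferroni family size (e.g.
#'   [bonferroni_family_size()]).
#' @return List with `statistic` (V, sum of positive ranks), `p_raw`,
#'   `p_adjusted` and `degenerate` (TRUE when all differences are zero, in
#'   which case p = 1).
#' @export
wilcoxon_bonferroni <- function(acc_a, acc_b, n_comparisons = 45) {
  if (length(acc_a) != length(acc_b)) stop("paired vectors differ in length")
  if (length(acc_a) < 5) stop("need >= 5 pairs")
  d <- acc_a - acc_b
  if (all(d == 0)) {
    return(list(statistic = 0, p_raw = 1, p_adjusted = 1, degenerate = TRUE))
  }
  wt <- suppressWarnings(
    stats::wilcox.test(acc_a, acc_b, paired = TRUE,
                       exact = sum(d != 0) <= 12, correct = TRUE))
  list(statistic = unname(wt$statistic), p_raw = wt$p.value,
       p_adjusted = min(1, wt$p.value * n_comparisons), degenerate = FALSE)
}
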