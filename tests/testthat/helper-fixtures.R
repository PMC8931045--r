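# Shared fixtures: tiny layouts, trial sets and reduced networks built in
# code at test time.

tiny_layout <- function(n = 4) {
  ang <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  channel_layout(paste0("ch", seq_len(n)),
                 cbind(0.7 * cos(ang), 0.7 * sin(ang)))
}

# deterministic multi-channel trial with a known cue position
tiny_trial <- function(C = 4, time = 300, rate = 100, cue = 100, label = 1L,
                       seed = 1) {
  set.seed(seed)
  eeg_trial(matrix(stats::rnorm(C * time), C, time), rate, cue, label)
}

tiny_set <- function(n_trials = 3, C = 4, time = 300, rate = 100, cue = 100,
                     n_classes = 2, seed = 1) {
  set.seed(seed)
  trials <- lapply(seq_len(n_trials), function(i) {
    eeg_trial(matrix(stats::rnorm(C * time), C, time), rate, cue,
              ((i - 1) %% n_classes) + 1L)
  })
  trial_set(trials, tiny_layout(C), n_classes)
}

# small initialized shallow discriminator (kink-free biases for FD checks)
tiny_disc <- function(C = 3, T = 32, M = 2, seed = 7, dropout = 0) {
  m <- shallow_convnet_spec(C, T, M, n_filters = 4, k_temporal = 5,
                            pool = c(8, 4), dropout = dropout)
  m <- init_model(m, seed)
  set.seed(seed + 1)
  for (part in c("feature", "classifier")) {
    for (i in seq_along(m$params[[part]])) {
      if (!is.null(m$params[[part]][[i]])) {
        nb <- length(m$params[[part]][[i]]$b)
        m$params[[part]][[i]]$b <- stats::rnorm(nb, sd = 0.05)
      }
    }
  }
  m
}

rand_batch <- function(n, C, T, seed = 1) {
  set.seed(seed)
  array(stats::rnorm(n * C * T), c(n, 1, C, T))
}

# default 4-class simulation at reduced size for fast tests
tiny_sim <- function(n_per_class = 3, seed = 11, snr = 10, erd = 0.3) {
  fm <- build_forward_model(default_layout_22(), default_mi_sources(erd))
  simulate_trials(fm, sim_config(n_per_class = n_per_class, snr = snr,
                                 seed = seed))
}
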