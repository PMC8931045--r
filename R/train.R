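# Adversarial training loop.
#
# Per mini-batch: n_critic discriminator updates (cross-entropy + Wasserstein
# gap + gradient penalty + optional unlabeled critic term), then one
# generator update (adversarial + feature matching). The gradient penalty's
# parameter gradient needs second-order information (derivative of the
# critic's input-gradient norm with respect to the weights); it is obtained
# by a central directional finite difference on the critic's parameter
# gradient, exact to O(h^2) and costing two extra passes.

scale_grads <- function(grads, s) {
  lapply(grads, function(g) {
    if (is.null(g)) NULL else lapply(g, function(p) p * s)
  })
}

add_grads <- function(a, b) {
  if (is.null(a)) return(b)
  if (is.null(b)) return(a)
  for (i in seq_along(a)) {
    if (is.null(a[[i]])) { a[i] <- b[i]; next }  # [<- keeps NULL slots
    if (is.null(b[[i]])) next
    for (nm in names(a[[i]])) a[[i]][[nm]] <- a[[i]][[nm]] + b[[i]][[nm]]
  }
  a
}

add_model_grads <- function(a, b) {
  list(feature = add_grads(a$feature, b$feature),
       classifier = add_grads(a$classifier, b$classifier))
}

scale_model_grads <- function(g, s) {
  list(feature = scale_grads(g$feature, s),
       classifier = scale_grads(g$classifier, s))
}

# parameter gradient of sum_i critic(x_i) (realness pre-activation)
critic_param_grads <- function(model, x) {
  fwd <- disc_forward(model, x, train = FALSE)
  dsc <- matrix(0, nrow(fwd$scores), ncol(fwd$scores))
  dsc[, model$n_classes + 1] <- 1
  disc_backward(model, fwd, dsc, need_input = FALSE, need_params = TRUE)$grads
}

# gradient penalty: value plus parameter gradients via the directional
# finite-difference curvature step described above
gp_value_and_grads <- function(model, x_hat, lambda_gp) {
  n <- dim(x_hat)[1]
  fwd <- disc_forward(model, x_hat, train = FALSE)
  dsc <- matrix(0, n, model$n_classes + 1)
  dsc[, model$n_classes + 1] <- 1
  g <- disc_backward(model, fwd, dsc, need_params = FALSE)$dx
  norms <- sample_norms(g)
  value <- lambda_gp * mean((norms - 1)^2)
  # direction v_i = (2 lambda / n) (||g_i|| - 1) / ||g_i|| * g_i
  coef <- (2 * lambda_gp / n) * (norms - 1) / pmax(norms, 1e-12)
  v <- g * array(rep(coef, times = length(g) / n), dim(g))
  vmax <- max(abs(v))
  if (vmax < 1e-14) {
    return(list(value = value,
                grads = scale_model_grads(critic_param_grads(model, x_hat), 0)))
  }
  h <- 1e-4 * (1 + max(abs(x_hat))) / vmax
  gp_plus <- critic_param_grads(model, x_hat + h * v)
  gp_minus <- critic_param_grads(model, x_hat - h * v)
  grads <- add_model_grads(gp_plus, scale_model_grads(gp_minus, -1))
  list(value = value, grads = scale_model_grads(grads, 1 / (2 * h)))
}

# x_r_extra: optional additional real windows entering only the realness
# term (variance reduction of the real-side expectation; class loss and
# feature matching stay on the labeled batch proper)
disc_loss_and_grads <- function(model, x_l, y, x_tilde, x_u, cfg_loss,
                                x_r_extra = NULL) {
  M <- model$n_classes
  n_l <- dim(x_l)[1]
  n_f <- dim(x_tilde)[1]
  n_u <- if (is.null(x_u)) 0L else dim(x_u)[1]
  n_e <- if (is.null(x_r_extra)) 0L else dim(x_r_extra)[1]
  n_r <- n_l + n_e                       # rows carrying the real-side term
  if (cfg_loss$adv_form == "log") {
    # one training-mode pass over [real; fake; unlabeled]; realness read
    # through a sigmoid, so adversarial gradients are bounded
    xc <- abind4(list(x_l, if (n_e) x_r_extra, x_tilde, if (n_u) x_u))
    fwd <- disc_forward(model, xc, train = TRUE)
    cls <- supervised_class_loss(fwd$scores[seq_len(n_l), 1:M, drop = FALSE], y)
    s <- sigmoid(fwd$scores[, M + 1])
    i_f <- n_r + seq_len(n_f)
    i_u <- if (n_u) n_r + n_f + seq_len(n_u) else integer(0)
    dsc <- matrix(0, n_r + n_f + n_u, M + 1)
    dsc[seq_len(n_l), 1:M] <- attr(cls, "grad")
    dsc[seq_len(n_r), M + 1] <- (s[seq_len(n_r)] - 1) / n_r
    dsc[i_f, M + 1] <- s[i_f] / n_f
    if (n_u) dsc[i_u, M + 1] <- (s[i_u] - 1) / n_u
    grads <- disc_backward(model, fwd, dsc,
                           need_input = FALSE, need_params = TRUE)$grads
    adv_real <- -mean(log(pmax(s[seq_len(n_r)], 1e-12)))
    adv_fake <- -mean(log(pmax(1 - s[i_f], 1e-12)))
    adv_unl <- if (n_u) -mean(log(pmax(s[i_u], 1e-12))) else 0
    total <- as.numeric(cls) + adv_real + adv_fake + adv_unl
    return(list(total = total, grads = grads,
                f_real = fwd$features[seq_len(n_l), , drop = FALSE],
                components = list(class = as.numeric(cls),
                                  w_real = adv_real, w_fake = adv_fake,
                                  gp = 0, w_unlabeled = adv_unl)))
  }
  # Wasserstein critic with gradient penalty
  fwd_cls <- disc_forward(model, x_l, train = TRUE)
  cls <- supervised_class_loss(fwd_cls$scores[, 1:M, drop = FALSE], y)
  d_cls <- cbind(attr(cls, "grad"), 0)
  g_cls <- disc_backward(model, fwd_cls, d_cls,
                         need_input = FALSE, need_params = TRUE)$grads
  xc <- abind4(list(x_l, if (n_e) x_r_extra, x_tilde, if (n_u) x_u))
  fwd_c <- disc_forward(model, xc, train = FALSE)
  coefs <- c(rep(-1 / n_r, n_r), rep(1 / n_f, n_f),
             if (n_u) rep(-1 / n_u, n_u))
  dsc <- matrix(0, length(coefs), M + 1)
  dsc[, M + 1] <- coefs
  g_crit <- disc_backward(model, fwd_c, dsc,
                          need_input = FALSE, need_params = TRUE)$grads
  crit <- fwd_c$scores[, M + 1]
  w_real <- mean(crit[seq_len(n_r)])
  w_fake <- mean(crit[n_r + seq_len(n_f)])
  w_unl <- if (n_u) mean(crit[n_r + n_f + seq_len(n_u)]) else 0
  grads <- add_model_grads(g_cls, g_crit)
  gp_val <- 0
  if (cfg_loss$lambda_gp > 0) {
    # the penalty is an expectation over interpolates; a 32-sample subset
    # is an unbiased estimate at half the cost of the full batch
    ngp <- min(32L, n_f)
    sel <- if (ngp < n_f) sample.int(n_f, ngp) else seq_len(n_f)
    x_hat <- interpolate_samples(
      x_l[rep_len(seq_len(n_l), n_f)[sel], , , , drop = FALSE],
      x_tilde[sel, , , , drop = FALSE])
    gp <- gp_value_and_grads(model, x_hat, cfg_loss$lambda_gp)
    gp_val <- gp$value
    grads <- add_model_grads(grads, gp$grads)
  }
  total <- as.numeric(cls) - (w_real - w_fake) + gp_val - w_unl
  list(total = total, grads = grads,
       f_real = fwd_c$features[seq_len(n_l), , drop = FALSE],
       components = list(class = as.numeric(cls), w_real = w_real,
                         w_fake = w_fake, gp = gp_val, w_unlabeled = w_unl))
}

gen_loss_and_grads <- function(model, gen, gs, f_real, cfg_loss) {
  n_f <- dim(gs$x)[1]
  fwd <- disc_forward(model, gs$x, train = FALSE)
  M <- model$n_classes
  d_sc <- matrix(0, n_f, M + 1)
  if (cfg_loss$adv_form == "log") {
    # non-saturating generator objective -E[log sigma(critic)]
    s <- sigmoid(fwd$scores[, M + 1])
    adv <- -mean(log(pmax(s, 1e-12)))
    d_sc[, M + 1] <- -(1 - s) / n_f
  } else {
    adv <- -mean(fwd$scores[, M + 1])
    d_sc[, M + 1] <- -1 / n_f
  }
  fm <- feature_matching_loss(f_real, fwd$features)
  d_feat <- NULL
  if (cfg_loss$fm_weight > 0) {
    diff <- colMeans(fwd$features) - colMeans(rbind(f_real))
    d_feat <- matrix(rep(2 * cfg_loss$fm_weight * diff / n_f, each = n_f),
                     n_f, length(diff))
  }
  dx <- as_internal(disc_backward(model, fwd, d_sc, d_features = d_feat,
                                  need_input = TRUE, need_params = FALSE)$dx)
  g_gen <- net_backward(gen$spec, gen$params, gs$caches, dx,
                        need_input = FALSE, need_params = TRUE)$grads
  list(total = adv + cfg_loss$fm_weight * fm, grads = g_gen,
       components = list(adv = adv, fm = fm))
}

# concatenate 4-d batches along the first dimension
abind4 <- function(parts) {
  parts <- Filter(Negate(is.null), parts)
  if (length(parts) == 1) return(parts[[1]])
  d <- dim(parts[[1]])
  n <- sum(vapply(parts, function(p) dim(p)[1], integer(1)))
  out <- array(0, c(n, d[2], d[3], d[4]))
  at <- 0L
  for (p in parts) {
    out[at + seq_len(dim(p)[1]), , , ] <- p
    at <- at + dim(p)[1]
  }
  out
}

#' Train a discriminator (and generator) on windowed trials
#'
#' Runs the adversarial training loop. Modes: `"vanilla"` (supervised
#' cross-entropy only), `"gdal"` (adds the generator, Wasserstein critic
#' with gradient penalty and feature matching), `"sgdal"` (additionally
#' feeds unlabeled real windows through the critic term). The whole run is
#' driven by `config$seed`, so identical seeds and inputs reproduce the
#' loss curves bitwise.
#'
#' @param model An (initialized or not) `DiscriminatorModel`.
#' @param labeled List with `x` (`n x 1 x C x T` array) and `y` (labels),
#'   e.g. from [windows_tensor()].
#' @param unlabeled Optional array of unlabeled windows (same window shape)
#'   or a list with an `x` element; used only in `"sgdal"` mode.
#' @param gen A `GeneratorModel`, or `NULL` to build one by reversing the
#'   model's feature extractor.
#' @param mode `"vanilla"`, `"gdal"` or `"sgdal"`.
#' @param config A [train_config()].
#' @param loss A [loss_config()].
#' @param verbose Print one line per epoch?
#' @return List with the trained `model`, `gen` and `curves` (data.frame of
#'   per-epoch generator, discriminator-adversarial and classification
#'   losses).
#' @export
train_adversarial <- function(model, labeled, unlabeled = NULL, gen = NULL,
                              mode = c("gdal", "sgdal", "vanilla"),
                              config = train_config(), loss = loss_config(),
                              verbose = FALSE) {
  mode <- match.arg(mode)
  set.seed(config$seed)
  x <- labeled$x; y <- labeled$y
  if (any(is.na(y))) stop("labeled windows carry NA labels")
  n <- dim(x)[1]
  if (n < 1) stop("no labeled windows")
  xu <- NULL
  if (mode == "sgdal") {
    xu <- if (is.list(unlabeled)) unlabeled$x else unlabeled
    if (is.null(xu) || dim(xu)[1] == 0) {
      stop("sgdal mode needs unlabeled windows")
    }
  }
  if (is.null(model$params)) model <- init_model(model)
  use_gan <- mode %in% c("gdal", "sgdal")
  if (use_gan && is.null(gen)) {
    gen <- reverse_to_generator(model$feature)
  }
  if (use_gan && is.null(gen$params)) gen <- init_model(gen)
  st_df <- adam_init(model$params$feature)
  st_dc <- adam_init(model$params$classifier)
  st_g <- if (use_gan) adam_init(gen$params) else NULL
  curves <- data.frame(epoch = seq_len(config$epochs), gen_loss = NA_real_,
                       disc_loss = NA_real_, class_loss = NA_real_)
  step_d <- 0L; step_g <- 0L
  for (ep in seq_len(config$epochs)) {
    lr <- lr_schedule(ep - 1, config$lr0, config$lr_decay)
    ord <- sample.int(n)
    nb <- max(1L, n %/% config$batch_size)
    ep_gen <- 0; ep_disc <- 0; ep_cls <- 0; ep_cnt <- 0; ep_gcnt <- 0
    for (b in seq_len(nb)) {
      idx <- ord[((b - 1) * config$batch_size + 1):min(b * config$batch_size, n)]
      xb <- x[idx, , , , drop = FALSE]
      yb <- y[idx]
      if (!use_gan) {
        fwd <- disc_forward(model, xb, train = TRUE)
        M <- model$n_classes
        cls <- supervised_class_loss(fwd$scores[, 1:M, drop = FALSE], yb)
        if (!is.finite(cls)) {
          stop("NaN classification loss at epoch ", ep, ", batch ", b)
        }
        g <- disc_backward(model, fwd, cbind(attr(cls, "grad"), 0),
                           need_input = FALSE, need_params = TRUE)$grads
        step_d <- step_d + 1L
        ud <- adam_step(model$params$feature, g$feature, st_df, lr, step_d,
                        config$beta1, config$beta2)
        model$params$feature <- ud$params; st_df <- ud$state
        uc <- adam_step(model$params$classifier, g$classifier, st_dc, lr, step_d,
                        config$beta1, config$beta2)
        model$params$classifier <- uc$params; st_dc <- uc$state
        ep_cls <- ep_cls + as.numeric(cls)
        ep_disc <- ep_disc + as.numeric(cls)
        ep_cnt <- ep_cnt + 1
        next
      }
      # one discriminator update per mini-batch; a generator update every
      # n_critic-th batch (classic critic/generator alternation)
      gs <- generate_samples(gen, length(idx))
      xub <- NULL
      if (!is.null(xu)) {
        uidx <- sample.int(dim(xu)[1], min(length(idx), 32L, dim(xu)[1]))
        xub <- xu[uidx, , , , drop = FALSE]
      }
      # without unlabeled windows, a second labeled draw enters the
      # realness term so the real-side expectation is estimated on the
      # same batch size as in semi-supervised runs
      xe <- NULL
      if (is.null(xub)) {
        eidx <- sample.int(n, min(length(idx), n))
        xe <- x[eidx, , , , drop = FALSE]
      }
      dl <- disc_loss_and_grads(model, xb, yb, gs$x, xub, loss,
                                x_r_extra = xe)
      if (!is.finite(dl$total)) {
        stop("NaN discriminator loss at epoch ", ep, ", batch ", b)
      }
      step_d <- step_d + 1L
      ud <- adam_step(model$params$feature, dl$grads$feature, st_df, lr,
                      step_d, config$beta1, config$beta2)
      model$params$feature <- ud$params; st_df <- ud$state
      uc <- adam_step(model$params$classifier, dl$grads$classifier, st_dc,
                      lr, step_d, config$beta1, config$beta2)
      model$params$classifier <- uc$params; st_dc <- uc$state
      if (step_d %% config$n_critic == 0) {
        # generator step reuses the critic pass's real features and the
        # just-generated batch (generator unchanged since it was drawn)
        gl <- gen_loss_and_grads(model, gen, gs, dl$f_real, loss)
        if (!is.finite(gl$total)) {
          stop("NaN generator loss at epoch ", ep, ", batch ", b)
        }
        step_g <- step_g + 1L
        ug <- adam_step(gen$params, gl$grads, st_g, lr, step_g,
                        config$beta1, config$beta2)
        gen$params <- ug$params; st_g <- ug$state
        ep_gen <- ep_gen + gl$total
        ep_gcnt <- ep_gcnt + 1
      }
      ep_disc <- ep_disc + dl$total
      ep_cls <- ep_cls + dl$components$class
      ep_cnt <- ep_cnt + 1
    }
    curves$gen_loss[ep] <- if (use_gan && ep_gcnt > 0) ep_gen / ep_gcnt else 0
    curves$disc_loss[ep] <- ep_disc / ep_cnt
    curves$class_loss[ep] <- ep_cls / ep_cnt
    if (verbose) {
      message(sprintf("epoch %3d  lr %.4g  disc %.4f  gen %.4f  cls %.4f",
                      ep, lr, curves$disc_loss[ep], curves$gen_loss[ep],
                      curves$class_loss[ep]))
    }
  }
  list(model = model, gen = gen, curves = curves, mode = mode)
}

#' Classify one trial by windowed majority vote
#'
#' Slides the model's input window over the trial, takes the argmax over
#' the M class units of every window (the realness unit is ignored), and
#' returns the majority vote with smallest-index tie-breaking.
#'
#' @param model An initialized `DiscriminatorModel`.
#' @param trial An [eeg_trial()] at least as long as the model window.
#' @param stride Hop between scored windows (1 scores every window).
#' @param chunk Windows scored per forward pass (memory control).
#' @return Predicted class in `1..M`.
#' @export
predict_trial <- function(model, trial, stride = 1, chunk = 256L) {
  Tw <- model$input_shape[2]
  wb <- sliding_windows(trial, length = Tw, stride = stride)
  n <- dim(wb$windows)[1]
  M <- model$n_classes
  votes <- integer(n)
  for (at in seq.int(1L, n, by = chunk)) {
    idx <- at:min(at + chunk - 1L, n)
    xb <- array(wb$windows[idx, , , drop = FALSE],
                c(length(idx), 1, dim(wb$windows)[2], Tw))
    sc <- disc_forward(model, xb, train = FALSE)$scores
    votes[idx] <- apply(sc[, 1:M, drop = FALSE], 1, which.max)
  }
  majority_vote(votes)
}

#' Accuracy of windowed majority-vote predictions over a TrialSet
#' @param model An initialized `DiscriminatorModel`.
#' @param set A labeled [trial_set()].
#' @param stride Window hop used at test time.
#' @export
evaluate_accuracy <- function(model, set, stride = 1) {
  preds <- vapply(set$trials, function(tr) predict_trial(model, tr, stride),
                  integer(1))
  mean(preds == labels_of(set))
}
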