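# Adversarial objectives.
#
# The discriminator minimizes
#   L_D = CE(x_l, y) - [critic(x_l) - critic(x_tilde)] + lambda * GP(x_hat)
#         - critic(x_u)                      (unlabeled term, when present)
# where critic() is the realness unit's pre-activation and CE is the softmax
# cross-entropy over the M class units; minimizing this is the sign
# convention under which the gradient-norm penalty regularizes the critic.
# The generator minimizes
#   L_G = -critic(G(z)) + fm_weight * || mean f(x_real) - mean f(G(z)) ||^2.

#' Loss hyper-parameters
#'
#' `adv_form` selects the realness objective used during training:
#' `"wasserstein"` is the gradient-penalty-stabilized critic described
#' above; `"log"` is the bounded log-likelihood form (the realness unit
#' read through a sigmoid), whose gradients saturate once real and
#' generated samples are well separated and which is therefore much
#' gentler on the shared feature extractor at small problem sizes.
#'
#' @param lambda_gp Gradient-penalty weight (default 10; Wasserstein form
#'   only).
#' @param fm_weight Feature-matching weight (default 1).
#' @param adv_form `"wasserstein"` or `"log"`.
#' @export
loss_config <- function(lambda_gp = 10, fm_weight = 1,
                        adv_form = c("wasserstein", "log")) {
  if (lambda_gp < 0 || fm_weight < 0) stop("loss weights must be >= 0")
  structure(list(lambda_gp = lambda_gp, fm_weight = fm_weight,
                 adv_form = match.arg(adv_form)),
            class = "LossConfig")
}

sigmoid <- function(s) 1 / (1 + exp(-s))

#' Training hyper-parameters
#'
#' Defaults mirror the standard protocol: mini-batches of 64, 100 epochs,
#' Adam with an exponentially decaying learning rate starting at 3e-2 and
#' decaying by a ratio of 1e-3 per epoch.
#'
#' @param batch_size Mini-batch size.
#' @param epochs Training epochs.
#' @param lr0 Initial learning rate.
#' @param lr_decay Per-epoch exponential decay rate.
#' @param n_critic Discriminator updates per generator update.
#' @param beta1,beta2 Adam moment decay rates.
#' @param seed RNG seed controlling initialization, batching, noise and
#'   dropout.
#' @export
train_config <- function(batch_size = 64, epochs = 100, lr0 = 0.03,
                         lr_decay = 0.001, n_critic = 1,
                         beta1 = 0.5, beta2 = 0.9, seed = 1) {
  if (batch_size < 1 || epochs < 1) stop("batch_size and epochs must be >= 1")
  if (lr0 <= 0) stop("lr0 must be positive")
  structure(list(batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), lr0 = lr0, lr_decay = lr_decay,
                 n_critic = as.integer(n_critic), beta1 = beta1, beta2 = beta2,
                 seed = as.integer(seed)),
            class = "TrainConfig")
}

#' Exponentially decaying learning rate
#'
#' `lr(t) = lr0 * exp(-decay * t)` with `t` the 0-based epoch index.
#'
#' @param epoch 0-based epoch index.
#' @param lr0 Initial rate.
#' @param decay Per-epoch decay ratio.
#' @export
lr_schedule <- function(epoch, lr0 = 0.03, decay = 0.001) {
  if (any(epoch < 0)) stop("epoch must be >= 0")
  lr0 * exp(-decay * epoch)
}

#' Supervised classification loss
#'
#' Mean negative log softmax probability of the true class over the M class
#' scores (the realness unit takes no part). Invariant to adding a constant
#' to all scores of a sample.
#'
#' @param class_scores `n x M` matrix of class-unit pre-activations.
#' @param labels Integer labels in `1..M`.
#' @return Scalar loss; the gradient with respect to the scores is attached
#'   as attribute `"grad"`.
#' @export
supervised_class_loss <- function(class_scores, labels) {
  class_scores <- rbind(class_scores)
  n <- nrow(class_scores); M <- ncol(class_scores)
  labels <- as.integer(labels)
  if (any(labels < 1 | labels > M)) {
    stop("labels must lie in 1..", M)
  }
  shifted <- class_scores - apply(class_scores, 1, max)
  logZ <- log(rowSums(exp(shifted)))
  picked <- shifted[cbind(seq_len(n), labels)]
  loss <- mean(logZ - picked)
  p <- exp(shifted - logZ)
  grad <- p / n
  grad[cbind(seq_len(n), labels)] <- grad[cbind(seq_len(n), labels)] - 1 / n
  attr(loss, "grad") <- grad
  loss
}

#' Interpolate real and generated batches
#'
#' Elementwise `x_hat = eps * x + (1 - eps) * x_tilde` with one mixing draw
#' per sample, the construction on which the gradient penalty is evaluated.
#'
#' @param x,x_tilde Arrays of identical shape (first dimension = samples).
#' @param eps Per-sample mixing coefficients in `[0, 1]`; drawn uniformly
#'   when `NULL`.
#' @export
interpolate_samples <- function(x, x_tilde, eps = NULL) {
  if (!identical(dim(x), dim(x_tilde))) {
    stop("x and x_tilde shapes differ: ", paste(dim(x), collapse = "x"),
         " vs ", paste(dim(x_tilde), collapse = "x"))
  }
  n <- dim(x)[1]
  if (is.null(eps)) eps <- stats::runif(n)
  if (any(eps < 0 | eps > 1)) stop("eps must lie in [0, 1]")
  e <- array(rep(eps, times = length(x) / n), dim(x))
  e * x + (1 - e) * x_tilde
}

# per-sample Euclidean norms over all but the first dimension
sample_norms <- function(g) {
  n <- dim(g)[1]
  gm <- g
  dim(gm) <- c(n, length(g) / n)
  sqrt(rowSums(gm * gm))
}

# per-sample input gradients of a critic; `critic` is either a
# DiscriminatorModel (exact backprop through the realness unit) or a plain
# function of a batch returning one score per sample, optionally carrying a
# "gradient" attribute (analytic); otherwise central finite differences.
critic_input_gradients <- function(critic, x, h = 1e-5) {
  if (inherits(critic, "DiscriminatorModel")) {
    fwd <- disc_forward(critic, x, train = FALSE)
    dsc <- matrix(0, nrow(fwd$scores), ncol(fwd$scores))
    dsc[, critic$n_classes + 1] <- 1
    return(disc_backward(critic, fwd, dsc, need_params = FALSE)$dx)
  }
  gfun <- attr(critic, "gradient")
  if (!is.null(gfun)) return(gfun(x))
  g <- array(0, dim(x))
  n <- dim(x)[1]
  per <- length(x) / n
  for (j in seq_len(per)) {
    xp <- x; xm <- x
    # j-th element of every sample: strided positions in column-major order
    pos <- seq.int(0, n - 1) + (j - 1) * n + 1
    xp[pos] <- xp[pos] + h
    xm[pos] <- xm[pos] - h
    g[pos] <- (critic(xp) - critic(xm)) / (2 * h)
  }
  g
}

#' Wasserstein gradient penalty
#'
#' `lambda * mean_i (|| grad_x critic(x_hat_i) ||_2 - 1)^2`, the two-sided
#' unit-gradient-norm penalty evaluated at interpolated samples.
#'
#' @param critic A `DiscriminatorModel` (the realness-unit pre-activation is
#'   the critic score) or any function mapping a batch array to one scalar
#'   per sample; an analytic per-sample gradient function may be supplied as
#'   attribute `"gradient"`, otherwise finite differences are used.
#' @param x_hat Batch array (first dimension = samples).
#' @param lambda_gp Penalty weight.
#' @return Scalar penalty; the per-sample gradient norms are attached as
#'   attribute `"norms"`.
#' @export
gradient_penalty <- function(critic, x_hat, lambda_gp = 10) {
  if (lambda_gp == 0) {
    out <- 0
    attr(out, "norms") <- rep(NA_real_, dim(x_hat)[1])
    return(out)
  }
  g <- critic_input_gradients(critic, x_hat)
  if (!all(is.finite(g))) stop("non-finite critic gradients at x_hat")
  norms <- sample_norms(g)
  out <- lambda_gp * mean((norms - 1)^2)
  attr(out, "norms") <- norms
  attr(out, "gradients") <- g
  out
}

#' Feature-matching loss
#'
#' Squared Euclidean distance between the batch-mean feature vectors of
#' real and generated samples.
#'
#' @param f_real,f_fake `n x d` feature matrices (possibly different `n`,
#'   same `d`).
#' @export
feature_matching_loss <- function(f_real, f_fake) {
  f_real <- rbind(f_real); f_fake <- rbind(f_fake)
  if (ncol(f_real) != ncol(f_fake)) {
    stop("feature dimensions differ: ", ncol(f_real), " vs ", ncol(f_fake))
  }
  diff <- colMeans(f_real) - colMeans(f_fake)
  sum(diff * diff)
}

#' Discriminator loss on one mini-batch
#'
#' Evaluates the minimized discriminator objective and its components:
#' supervised cross-entropy on the labeled batch, the Wasserstein critic
#' gap against the generated batch, the gradient penalty at interpolates,
#' and (when an unlabeled batch is supplied) the unlabeled critic term.
#' With no unlabeled batch the value reduces exactly to the supervised
#' (GDAL) objective.
#'
#' @param model An initialized `DiscriminatorModel`.
#' @param x_l,y Labeled batch (`n x 1 x C x T` array) and labels.
#' @param x_tilde Generated batch of the same window shape.
#' @param x_u Optional unlabeled real batch (`NULL` for supervised mode).
#' @param config A [loss_config()].
#' @param eps Optional per-sample interpolation draws (for deterministic
#'   evaluation); drawn uniformly when `NULL`.
#' @return Scalar total loss with attribute `"components"` (named list:
#'   `class`, `w_real`, `w_fake`, `gp`, `w_unlabeled`).
#' @export
discriminator_step_loss <- function(model, x_l, y, x_tilde, x_u = NULL,
                                    config = loss_config(), eps = NULL) {
  if (is.null(x_l) || dim(x_l)[1] == 0) stop("labeled batch must be non-empty")
  fwd_l <- disc_forward(model, x_l, train = FALSE)
  M <- model$n_classes
  cls <- supervised_class_loss(fwd_l$scores[, 1:M, drop = FALSE], y)
  crit_real <- fwd_l$scores[, M + 1]
  crit_fake <- disc_forward(model, x_tilde, train = FALSE)$scores[, M + 1]
  has_u <- !is.null(x_u) && dim(x_u)[1] > 0
  crit_unl <- if (has_u) disc_forward(model, x_u, train = FALSE)$scores[, M + 1]
              else numeric(0)
  if (config$adv_form == "log") {
    adv_real <- -mean(log(pmax(sigmoid(crit_real), 1e-12)))
    adv_fake <- -mean(log(pmax(1 - sigmoid(crit_fake), 1e-12)))
    adv_unl <- if (has_u) -mean(log(pmax(sigmoid(crit_unl), 1e-12))) else 0
    total <- as.numeric(cls) + adv_real + adv_fake + adv_unl
    attr(total, "components") <- list(class = as.numeric(cls),
                                      w_real = adv_real, w_fake = adv_fake,
                                      gp = 0, w_unlabeled = adv_unl)
    return(total)
  }
  x_hat <- interpolate_samples(
    x_l[rep_len(seq_len(dim(x_l)[1]), dim(x_tilde)[1]), , , , drop = FALSE],
    x_tilde, eps)
  gp <- gradient_penalty(model, x_hat, config$lambda_gp)
  unl_term <- if (has_u) mean(crit_unl) else 0
  total <- as.numeric(cls) - (mean(crit_real) - mean(crit_fake)) +
    as.numeric(gp) - unl_term
  attr(total, "components") <- list(class = as.numeric(cls),
                                    w_real = mean(crit_real),
                                    w_fake = mean(crit_fake),
                                    gp = as.numeric(gp),
                                    w_unlabeled = unl_term)
  total
}

#' Generator loss on one mini-batch
#'
#' `-mean critic(G(z)) + fm_weight * feature_matching_loss(f_real, F(G(z)))`.
#'
#' @param model An initialized `DiscriminatorModel`.
#' @param gen An initialized `GeneratorModel`.
#' @param z `n x z_dim` noise matrix.
#' @param f_real `n x d` real feature batch (from [disc_forward()]).
#' @param config A [loss_config()].
#' @return Scalar loss with attribute `"components"` (`adv`, `fm`).
#' @export
generator_step_loss <- function(model, gen, z, f_real,
                                config = loss_config()) {
  gs <- generate_samples(gen, z)
  fwd <- disc_forward(model, gs$x, train = FALSE)
  M <- model$n_classes
  adv <- if (config$adv_form == "log") {
    -mean(log(pmax(sigmoid(fwd$scores[, M + 1]), 1e-12)))
  } else {
    -mean(fwd$scores[, M + 1])
  }
  fm <- feature_matching_loss(f_real, fwd$features)
  total <- adv + config$fm_weight * fm
  attr(total, "components") <- list(adv = adv, fm = fm)
  total
}
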