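# Objective components: classification loss, interpolation, gradient
# penalty, feature matching, step losses, learning-rate schedule.

test_that("supervised class loss matches softmax cross-entropy closed forms", {
  # certain correct prediction -> 0
  sc <- matrix(c(100, 0, 0, 0), 1, 4)
  expect_equal(as.numeric(supervised_class_loss(sc, 1)), 0, tolerance = 1e-6)
  # uniform scores over 4 classes -> ln 4
  expect_equal(as.numeric(supervised_class_loss(matrix(0, 1, 4), 2)),
               log(4), tolerance = 1e-12)
  # shift invariance
  s <- matrix(rnorm(8), 2, 4)
  expect_equal(as.numeric(supervised_class_loss(s, c(1, 3))),
               as.numeric(supervised_class_loss(s + 5, c(1, 3))),
               tolerance = 1e-10)
  expect_error(supervised_class_loss(s, c(1, 9)), "labels")
  # gradient sums to zero per sample and matches finite differences
  g <- attr(supervised_class_loss(s, c(1, 3)), "grad")
  expect_lt(max(abs(rowSums(g))), 1e-12)
  h <- 1e-6
  for (k in c(1, 5)) {
    sp <- s; sp[k] <- sp[k] + h
    sm <- s; sm[k] <- sm[k] - h
    num <- (as.numeric(supervised_class_loss(sp, c(1, 3))) -
            as.numeric(supervised_class_loss(sm, c(1, 3)))) / (2 * h)
    expect_equal(g[k], num, tolerance = 1e-6)
  }
})

test_that("interpolation mixes per sample with the documented endpoints", {
  x <- array(2, c(2, 1, 2, 3))
  xt <- array(4, c(2, 1, 2, 3))
  expect_equal(interpolate_samples(x, xt, eps = c(1, 1)), x)
  expect_equal(interpolate_samples(x, xt, eps = c(0, 0)), xt)
  mid <- interpolate_samples(x, xt, eps = c(0.5, 0.5))
  expect_true(all(mid == 3))
  mixed <- interpolate_samples(x, xt, eps = c(1, 0))
  expect_true(all(mixed[1, , , ] == 2) && all(mixed[2, , , ] == 4))
  expect_error(interpolate_samples(x, array(0, c(2, 1, 2, 4))), "shapes")
  expect_error(interpolate_samples(x, xt, eps = c(2, 0)), "eps")
})

test_that("gradient penalty reproduces closed forms and the FD oracle", {
  set.seed(8)
  x_hat <- array(rnorm(3 * 1 * 4 * 4), c(3, 1, 4, 4))
  # linear critic with unit-norm weights -> penalty 0
  w <- rnorm(16); w <- w / sqrt(sum(w * w))
  lin <- function(x) { xm <- x; dim(xm) <- c(dim(x)[1], 16); as.numeric(xm %*% w) }
  attr(lin, "gradient") <- function(x) array(rep(w, each = dim(x)[1]), dim(x))
  expect_equal(as.numeric(gradient_penalty(lin, x_hat, 10)), 0, tolerance = 1e-12)
  # critic 2*sum(x) over 16 elements: |grad| = 2*sqrt(16) = 8 -> 10*(8-1)^2
  dbl <- function(x) { xm <- x; dim(xm) <- c(dim(x)[1], 16); 2 * rowSums(xm) }
  expect_equal(as.numeric(gradient_penalty(dbl, x_hat, 10)), 490)
  expect_equal(as.numeric(gradient_penalty(dbl, x_hat, 0)), 0)
  # finite-difference fallback agrees (no analytic gradient attached)
  expect_equal(as.numeric(gradient_penalty(dbl, x_hat, 10)),
               as.numeric(gradient_penalty(structure(dbl), x_hat, 10)),
               tolerance = 1e-6)
})

test_that("network-critic input gradients match finite differences", {
  m <- tiny_disc()
  x_hat <- rand_batch(2, 3, 32, seed = 12)
  g_bp <- sgdal:::critic_input_gradients(m, x_hat)
  crit_fn <- function(x) disc_forward(m, x)$scores[, 3]
  g_fd <- sgdal:::critic_input_gradients(structure(crit_fn), x_hat)
  rel <- max(abs(g_bp - g_fd)) / max(abs(g_fd))
  expect_lt(rel, 1e-4)
  # and the penalty values agree
  expect_equal(as.numeric(gradient_penalty(m, x_hat, 10)),
               as.numeric(gradient_penalty(structure(crit_fn), x_hat, 10)),
               tolerance = 1e-4)
})

test_that("feature matching is the squared distance of batch means", {
  f <- matrix(rnorm(12), 4, 3)
  expect_equal(feature_matching_loss(f, f), 0)
  expect_equal(feature_matching_loss(matrix(1, 4, 1), matrix(3, 2, 1)), 4)
  # permutation invariance within each batch
  expect_equal(feature_matching_loss(f, f[c(3, 1, 4, 2), ]), 0)
  g <- matrix(rnorm(6), 2, 3)
  expect_equal(feature_matching_loss(f, g),
               feature_matching_loss(f[c(2, 1, 4, 3), ], g[2:1, ]))
  expect_error(feature_matching_loss(f, matrix(0, 2, 2)), "dimensions")
})

test_that("the semi-supervised loss reduces exactly to the supervised one", {
  m <- tiny_disc()
  x_l <- rand_batch(4, 3, 32, seed = 21)
  y <- c(1, 2, 2, 1)
  x_t <- rand_batch(4, 3, 32, seed = 22)
  eps <- c(0.2, 0.9, 0.5, 0.1)
  empty <- array(0, c(0, 1, 3, 32))
  for (cfg in list(loss_config(), loss_config(adv_form = "log"))) {
    with_u <- discriminator_step_loss(m, x_l, y, x_t, x_u = empty,
                                      config = cfg, eps = eps)
    without <- discriminator_step_loss(m, x_l, y, x_t, x_u = NULL,
                                       config = cfg, eps = eps)
    expect_identical(as.numeric(with_u), as.numeric(without))
    expect_equal(attr(with_u, "components")$w_unlabeled, 0)
  }
})

test_that("discriminator loss matches a term-by-term hand expansion", {
  m <- tiny_disc()
  x_l <- rand_batch(2, 3, 32, seed = 31)
  y <- c(1, 2)
  x_t <- rand_batch(2, 3, 32, seed = 32)
  x_u <- rand_batch(2, 3, 32, seed = 33)
  eps <- c(0.3, 0.7)
  cfg <- loss_config(lambda_gp = 10)
  total <- discriminator_step_loss(m, x_l, y, x_t, x_u, cfg, eps = eps)
  # hand expansion from the public primitives
  s_l <- disc_forward(m, x_l)$scores
  s_t <- disc_forward(m, x_t)$scores
  s_u <- disc_forward(m, x_u)$scores
  cls <- as.numeric(supervised_class_loss(s_l[, 1:2], y))
  gp <- as.numeric(gradient_penalty(m, interpolate_samples(x_l, x_t, eps), 10))
  hand <- cls - (mean(s_l[, 3]) - mean(s_t[, 3])) + gp - mean(s_u[, 3])
  expect_equal(as.numeric(total), hand, tolerance = 1e-10)
  expect_error(discriminator_step_loss(m, array(0, c(0, 1, 3, 32)),
                                       integer(0), x_t), "non-empty")
})

test_that("generator loss combines the critic score and feature matching", {
  m <- tiny_disc()
  g <- init_model(reverse_to_generator(m$feature, z_dim = 6), 4)
  z <- matrix(rnorm(3 * 6), 3, 6)
  f_real <- disc_forward(m, rand_batch(3, 3, 32, seed = 41))$features
  # fm_weight 0: loss is just the negated mean critic score
  l0 <- generator_step_loss(m, g, z, f_real, loss_config(fm_weight = 0))
  xt <- generate_samples(g, z)$x
  expect_equal(as.numeric(l0), -mean(disc_forward(m, xt)$scores[, 3]),
               tolerance = 1e-12)
  # generator output identical (in feature space) to real batch -> fm = 0
  f_fake <- disc_forward(m, xt)$features
  l_self <- generator_step_loss(m, g, z, f_fake, loss_config(fm_weight = 1))
  expect_equal(attr(l_self, "components")$fm, 0, tolerance = 1e-12)
  # hand evaluation of the combined loss
  l1 <- generator_step_loss(m, g, z, f_real, loss_config(fm_weight = 2))
  hand <- -mean(disc_forward(m, xt)$scores[, 3]) +
    2 * feature_matching_loss(f_real, f_fake)
  expect_equal(as.numeric(l1), hand, tolerance = 1e-12)
})

test_that("gradient-penalty parameter gradients match loss finite differences", {
  m <- tiny_disc()
  x_hat <- rand_batch(3, 3, 32, seed = 51)
  gp <- sgdal:::gp_value_and_grads(m, x_hat, 10)
  expect_equal(gp$value, as.numeric(gradient_penalty(m, x_hat, 10)),
               tolerance = 1e-10)
  h <- 1e-5
  set.seed(52)
  for (li in c(1, 2)) {
    k <- sample(length(m$params$feature[[li]]$W), 1)
    mp <- m; mp$params$feature[[li]]$W[k] <- mp$params$feature[[li]]$W[k] + h
    mm <- m; mm$params$feature[[li]]$W[k] <- mm$params$feature[[li]]$W[k] - h
    num <- (as.numeric(gradient_penalty(mp, x_hat, 10)) -
            as.numeric(gradient_penalty(mm, x_hat, 10))) / (2 * h)
    expect_equal(gp$grads$feature[[li]]$W[k], num, tolerance = 1e-3)
  }
})

test_that("the learning-rate schedule decays exponentially from 0.03", {
  expect_equal(lr_schedule(0), 0.03)
  expect_equal(lr_schedule(100), 0.03 * exp(-0.1))
  lrs <- lr_schedule(0:99)
  expect_true(all(diff(lrs) < 0))
  expect_error(lr_schedule(-1), ">= 0")
})
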