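# Discriminator builders and the generator-construction rule.
#
# Each discriminator is a feature extractor F (convolution/pooling stack)
# composed with a classifier C (dense stack) whose output layer carries
# M class-score units plus one realness unit. The class scores are trained
# through a softmax over the first M units; the realness unit's
# pre-activation doubles as the Wasserstein critic score.

new_discriminator <- function(feature, classifier, C, T, M, arch) {
  structure(list(feature = feature, classifier = classifier,
                 n_classes = as.integer(M), input_shape = c(C, T),
                 arch = arch, params = NULL),
            class = "DiscriminatorModel")
}

#' @export
print.DiscriminatorModel <- function(x, ...) {
  cat(sprintf("<DiscriminatorModel %s> input %dx%d, %d classes + 1 realness unit%s\n",
              x$arch, x$input_shape[1], x$input_shape[2], x$n_classes,
              if (is.null(x$params)) " (uninitialized)" else ""))
  cat("feature extractor:\n"); print(x$feature)
  cat("classifier:\n"); print(x$classifier)
  invisible(x)
}

#' Shallow ConvNet discriminator
#'
#' A band-power style network: one temporal convolution (linear), one
#' spatial convolution spanning all channels with a squaring activation,
#' mean pooling followed by a log stage, dropout, and a dense head with
#' `M + 1` units (M class scores + 1 realness score). Kernel and pooling
#' defaults follow the published Shallow ConvNet configuration; pass
#' smaller values for reduced desk-scale variants.
#'
#' @param C,T Input channels and window length (samples).
#' @param M Number of classes.
#' @param n_filters Feature maps in both convolutions.
#' @param k_temporal Temporal kernel width.
#' @param pool `(width, stride)` of the mean-pooling stage.
#' @param dropout Dropout probability before the head.
#' @return An uninitialized `DiscriminatorModel`; see [init_model()].
#' @export
shallow_convnet_spec <- function(C, T, M, n_filters = 40, k_temporal = 25,
                                 pool = c(75, 15), dropout = 0.5) {
  feature <- architecture_spec(list(
    layer_spec("temporal_conv", out_maps = n_filters, kw = k_temporal,
               activation = "linear"),
    layer_spec("spatial_conv", out_maps = n_filters, activation = "square"),
    layer_spec("pool", width = pool[1], stride = pool[2], activation = "log"),
    layer_spec("dropout", p = dropout)
  ), input_shape = c(1, C, T))
  classifier <- architecture_spec(list(
    layer_spec("dense", units = M + 1, activation = "linear")
  ), input_shape = prod(feature$output_shape))
  new_discriminator(feature, classifier, C, T, M, "shallow")
}

#' Deep ConvNet discriminator
#'
#' Five convolutions: a linear temporal convolution, a spatial convolution
#' (ELU) spanning all channels, then three temporal convolution blocks
#' (ELU), each block followed by mean pooling; dropout and a dense
#' `M + 1`-unit head close the network. Map counts double per block
#' (25-25-50-100-200 at the published scale).
#'
#' @inheritParams shallow_convnet_spec
#' @param base_filters Maps of the first two convolutions; later blocks
#'   double this progressively.
#' @param k_temporal Temporal kernel width of every temporal convolution.
#' @param pool `(width, stride)` of each pooling stage.
#' @export
deep_convnet_spec <- function(C, T, M, base_filters = 25, k_temporal = 10,
                              pool = c(3, 3), dropout = 0.5) {
  f <- base_filters
  feature <- architecture_spec(list(
    layer_spec("temporal_conv", out_maps = f, kw = k_temporal,
               activation = "linear"),
    layer_spec("spatial_conv", out_maps = f, activation = "elu"),
    layer_spec("pool", width = pool[1], stride = pool[2]),
    layer_spec("temporal_conv", out_maps = 2 * f, kw = k_temporal,
               activation = "elu"),
    layer_spec("pool", width = pool[1], stride = pool[2]),
    layer_spec("temporal_conv", out_maps = 4 * f, kw = k_temporal,
               activation = "elu"),
    layer_spec("pool", width = pool[1], stride = pool[2]),
    layer_spec("temporal_conv", out_maps = 8 * f, kw = k_temporal,
               activation = "elu"),
    layer_spec("pool", width = pool[1], stride = pool[2]),
    layer_spec("dropout", p = dropout)
  ), input_shape = c(1, C, T))
  classifier <- architecture_spec(list(
    layer_spec("dense", units = M + 1, activation = "linear")
  ), input_shape = prod(feature$output_shape))
  new_discriminator(feature, classifier, C, T, M, "deep")
}

#' Recurrent spatio-temporal network (RSTNN) discriminator
#'
#' `n_modules` spatio-temporal modules, each consisting of three 1x9
#' temporal convolutions (an unrolled recurrent convolution stack) followed
#' by one spatial convolution spanning the current channel axis, all with
#' leaky-ReLU activations, plus a mean-pooling stage per module to contract
#' the time axis. A tanh dense hidden layer and the `M + 1`-unit head form
#' the classifier.
#'
#' @inheritParams shallow_convnet_spec
#' @param n_modules 1 or 3 spatio-temporal modules.
#' @param maps Feature maps per module (recycled/truncated to `n_modules`).
#' @param hidden Units of the tanh classifier hidden layer.
#' @export
rstnn_spec <- function(C, T, M, n_modules = 3, maps = c(32, 64, 96),
                       hidden = 64, dropout = 0.5) {
  if (!n_modules %in% c(1L, 3L)) stop("n_modules must be 1 or 3")
  maps <- rep_len(maps, n_modules)
  layers <- list()
  for (mdl in seq_len(n_modules)) {
    for (r in 1:3) {
      layers <- c(layers, list(
        layer_spec("temporal_conv", out_maps = maps[mdl], kw = 9,
                   activation = "lrelu")))
    }
    layers <- c(layers, list(
      layer_spec("spatial_conv", out_maps = maps[mdl], activation = "lrelu"),
      layer_spec("pool", width = 2, stride = 2)))
  }
  layers <- c(layers, list(layer_spec("dropout", p = dropout)))
  feature <- architecture_spec(layers, input_shape = c(1, C, T))
  classifier <- architecture_spec(list(
    layer_spec("dense", units = hidden, activation = "tanh"),
    layer_spec("dense", units = M + 1, activation = "linear")
  ), input_shape = prod(feature$output_shape))
  new_discriminator(feature, classifier, C, T, M, "rstnn")
}

#' Build a discriminator by name
#' @param arch `"shallow"`, `"deep"` or `"rstnn"`.
#' @param C,T,M Input channels, window length, class count.
#' @param ... Passed to the builder (e.g. `n_modules` for RSTNN).
#' @export
discriminator_spec <- function(arch = c("shallow", "deep", "rstnn"),
                               C, T, M, ...) {
  arch <- match.arg(arch)
  switch(arch,
         shallow = shallow_convnet_spec(C, T, M, ...),
         deep = deep_convnet_spec(C, T, M, ...),
         rstnn = rstnn_spec(C, T, M, ...))
}

#' Reverse a feature extractor into a generator
#'
#' Builds the deconvolution network that maps a Gaussian noise vector to an
#' artificial trial window: the feature extractor's convolution layers are
#' emitted in reverse order, pooling layers are dropped, every convolution
#' becomes an `upsample_conv` (bilinear time resize to the forward layer's
#' input extent followed by a same-padded convolution, or a channel
#' expansion where a spatial convolution collapsed the channel axis), all
#' activations become ReLU except the final layer's tanh, and a dense stem
#' maps the noise vector to the innermost feature shape.
#'
#' @param feature_extractor A resolved [architecture_spec()] (the `feature`
#'   component of a discriminator).
#' @param z_dim Noise dimension (default 100).
#' @return An uninitialized `GeneratorModel` whose output shape equals the
#'   extractor's `(channels, time)` input.
#' @export
reverse_to_generator <- function(feature_extractor, z_dim = 100) {
  convs <- Filter(function(ly) ly$kind %in% c("temporal_conv", "spatial_conv"),
                  feature_extractor$layers)
  if (length(convs) == 0) stop("feature extractor contains no convolution layers")
  inner <- convs[[length(convs)]]$out_shape
  layers <- list(layer_spec("dense", units = prod(inner), activation = "relu",
                            reshape_to = inner))
  for (i in rev(seq_along(convs))) {
    ly <- convs[[i]]
    act <- if (i == 1) "tanh" else "relu"
    layers <- c(layers, list(layer_spec(
      "upsample_conv",
      out_maps = ly$in_shape[1],
      out_ch = ly$in_shape[2],
      target_time = ly$in_shape[3],
      kw = if (ly$kind == "temporal_conv") ly$kw else 1,
      activation = act)))
  }
  spec <- architecture_spec(layers, input_shape = z_dim)
  want <- feature_extractor$input_shape
  got <- spec$output_shape
  if (!identical(as.integer(got), as.integer(want))) {
    stop("reversed generator emits ", paste(got, collapse = "x"),
         " but the extractor consumes ", paste(want, collapse = "x"))
  }
  structure(list(spec = spec, z_dim = as.integer(z_dim),
                 out_shape = want[2:3], params = NULL),
            class = "GeneratorModel")
}

#' @export
print.GeneratorModel <- function(x, ...) {
  cat(sprintf("<GeneratorModel> z %d -> %dx%d%s\n", x$z_dim, x$out_shape[1],
              x$out_shape[2], if (is.null(x$params)) " (uninitialized)" else ""))
  print(x$spec)
  invisible(x)
}

#' Initialize a model's parameters (seeded)
#'
#' @param model A `DiscriminatorModel` or `GeneratorModel`.
#' @param seed Optional integer seed (uses the current RNG state when
#'   `NULL`).
#' @return The model with `params` filled in.
#' @export
init_model <- function(model, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (inherits(model, "DiscriminatorModel")) {
    model$params <- list(feature = init_arch_params(model$feature),
                         classifier = init_arch_params(model$classifier))
  } else if (inherits(model, "GeneratorModel")) {
    model$params <- init_arch_params(model$spec)
  } else stop("not a model")
  model
}

#' Total trainable parameters of a model
#' @param model A `DiscriminatorModel` or `GeneratorModel`.
#' @export
n_model_params <- function(model) {
  if (inherits(model, "DiscriminatorModel")) {
    n_arch_params(model$feature) + n_arch_params(model$classifier)
  } else n_arch_params(model$spec)
}

check_initialized <- function(model) {
  if (is.null(model$params)) {
    stop("model parameters are not initialized; call init_model() first")
  }
}

#' Forward pass of a discriminator
#'
#' @param model An initialized `DiscriminatorModel`.
#' @param x Batch array `n x 1 x C x T` (or a single `C x T` matrix).
#' @param train Use dropout (training mode)?
#' @return List with `scores` (`n x (M+1)` pre-activations), `features`
#'   (`n x d` flattened feature-extractor output) and the internal caches.
#' @export
disc_forward <- function(model, x, train = FALSE) {
  check_initialized(model)
  x <- as_internal(x)
  ff <- net_forward(model$feature, model$params$feature, x, train)
  f <- ff$out
  fmat <- f
  if (length(dim(fmat)) > 2) dim(fmat) <- c(dim(f)[1], prod(dim(f)[-1]))
  cf <- net_forward(model$classifier, model$params$classifier, f, train)
  list(scores = cf$out, features = fmat,
       f_raw_dim = dim(f), feature_caches = ff$caches,
       classifier_caches = cf$caches)
}

# combined backward: gradient at the scores plus an optional gradient
# injected at the feature boundary (feature-matching path)
disc_backward <- function(model, fwd, d_scores, d_features = NULL,
                          need_input = TRUE, need_params = TRUE) {
  bw_c <- net_backward(model$classifier, model$params$classifier,
                       fwd$classifier_caches, d_scores,
                       need_input = TRUE, need_params = need_params)
  df <- bw_c$dx
  if (!is.null(d_features)) {
    dfm <- df
    if (length(dim(dfm)) > 2) dim(dfm) <- dim(d_features)
    dfm <- dfm + d_features
    dim(dfm) <- if (is.null(fwd$f_raw_dim)) dim(df) else fwd$f_raw_dim
    df <- dfm
  }
  bw_f <- net_backward(model$feature, model$params$feature,
                       fwd$feature_caches, df,
                       need_input = need_input, need_params = need_params)
  if (need_input && !is.null(bw_f$dx)) bw_f$dx <- as_public(bw_f$dx)
  list(dx = bw_f$dx,
       grads = if (need_params) list(feature = bw_f$grads,
                                     classifier = bw_c$grads) else NULL)
}

#' Generate artificial trial windows
#'
#' @param gen An initialized `GeneratorModel`.
#' @param n Number of samples, or a pre-drawn `n x z_dim` noise matrix.
#' @return List with `x` (`n x 1 x C x T` array, values in `(-1, 1)`), the
#'   noise `z`, and forward caches (for backprop).
#' @export
generate_samples <- function(gen, n) {
  check_initialized(gen)
  z <- if (is.matrix(n)) n else matrix(stats::rnorm(n * gen$z_dim), n, gen$z_dim)
  fw <- net_forward(gen$spec, gen$params, z, train = TRUE)
  list(x = as_public(fw$out), z = z, caches = fw$caches)
}
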