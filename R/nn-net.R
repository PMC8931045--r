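# Layer specs, shape propagation, initialization, and the full
# forward/backward orchestration for a stack of layers.

#' Declare one network layer
#'
#' Layers are declarative: shapes and parameter sizes are resolved against
#' an input shape by [architecture_spec()]. Supported kinds:
#' `temporal_conv` (1 x `kw` kernel shared across channel rows),
#' `spatial_conv` (kernel spanning the whole channel axis), `pool` (mean
#' pooling along time, optionally followed by an activation such as the
#' log stage of band-power style features), `dense`, `dropout`, and
#' `upsample_conv` (generator layer: bilinear time resize to `target_time`,
#' then a same-padded convolution or a 1-to-`out_ch` channel expansion).
#'
#' @param kind Layer kind (see above).
#' @param out_maps Feature maps emitted by a convolution.
#' @param kw Temporal kernel width.
#' @param activation One of linear, relu, lrelu, elu, square, log, tanh.
#' @param width,stride Pooling window and hop.
#' @param units Dense output units.
#' @param p Dropout probability.
#' @param target_time,out_ch Upsample-conv target extents.
#' @param padding `"valid"` or `"same"` for temporal convolutions.
#' @param reshape_to Optional `(maps, channels, time)` shape a dense layer
#'   reshapes its output to (generator stem).
#' @export
layer_spec <- function(kind, out_maps = NULL, kw = NULL, activation = "linear",
                       width = NULL, stride = NULL, units = NULL, p = NULL,
                       target_time = NULL, out_ch = NULL, padding = "valid",
                       reshape_to = NULL) {
  kinds <- c("temporal_conv", "spatial_conv", "pool", "dense", "dropout",
             "upsample_conv")
  if (!kind %in% kinds) stop("unknown layer kind: ", kind)
  if (!activation %in% ACTIVATIONS) stop("unknown activation: ", activation)
  structure(list(kind = kind, out_maps = out_maps, kw = kw,
                 activation = activation, width = width, stride = stride,
                 units = units, p = p, target_time = target_time,
                 out_ch = out_ch, padding = padding, reshape_to = reshape_to),
            class = "LayerSpec")
}

#' Resolve a stack of layers against an input shape
#'
#' Propagates `(maps, channels, time)` (or a flat feature count) through the
#' layer stack, recording every layer's input/output shape and parameter
#' dimensions, and validating that the chain is consistent (positive
#' extents, spatial kernels spanning the current channel axis, pooling
#' windows that fit).
#'
#' @param layers List of [layer_spec()]s.
#' @param input_shape `(maps, channels, time)` vector, or a single integer
#'   for a flat (noise-vector) input.
#' @return An `ArchitectureSpec`: layers annotated with `in_shape`,
#'   `out_shape` and weight dimensions.
#' @export
architecture_spec <- function(layers, input_shape) {
  shape <- input_shape
  resolved <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    ly <- layers[[i]]
    ly$in_shape <- shape
    if (ly$kind == "temporal_conv") {
      if (length(shape) != 3) stop("layer ", i, ": conv needs a (m, ch, t) input")
      t_out <- if (ly$padding == "same") shape[3] else shape[3] - ly$kw + 1
      if (t_out < 1) {
        stop("layer ", i, ": time extent ", shape[3], " too short for kernel ",
             ly$kw, "; need >= ", ly$kw)
      }
      ly$w_dim <- c(shape[1] * ly$kw, ly$out_maps)
      shape <- c(ly$out_maps, shape[2], t_out)
    } else if (ly$kind == "spatial_conv") {
      if (length(shape) != 3) stop("layer ", i, ": conv needs a (m, ch, t) input")
      ly$kh <- shape[2]  # kernel height always equals the channel extent
      ly$w_dim <- c(shape[1] * shape[2], ly$out_maps)
      shape <- c(ly$out_maps, 1, shape[3])
    } else if (ly$kind == "pool") {
      if (shape[3] < ly$width) {
        stop("layer ", i, ": time extent ", shape[3],
             " too short for pooling window ", ly$width)
      }
      shape <- c(shape[1], shape[2], (shape[3] - ly$width) %/% ly$stride + 1)
    } else if (ly$kind == "dense") {
      d_in <- prod(shape)
      ly$w_dim <- c(d_in, ly$units)
      shape <- if (is.null(ly$reshape_to)) ly$units else ly$reshape_to
      if (!is.null(ly$reshape_to) && prod(ly$reshape_to) != ly$units) {
        stop("layer ", i, ": reshape_to ", paste(ly$reshape_to, collapse = "x"),
             " incompatible with ", ly$units, " units")
      }
    } else if (ly$kind == "dropout") {
      # shape unchanged
    } else if (ly$kind == "upsample_conv") {
      if (length(shape) != 3) stop("layer ", i, ": upsample_conv needs (m, ch, t)")
      if (ly$out_ch > shape[2]) {
        if (shape[2] != 1) {
          stop("layer ", i, ": channel expansion requires a collapsed ",
               "(single-row) channel axis, got ", shape[2])
        }
        ly$spatial <- TRUE
        ly$w_dim <- c(shape[1], ly$out_ch * ly$out_maps)
      } else {
        ly$spatial <- FALSE
        ly$w_dim <- c(shape[1] * ly$kw, ly$out_maps)
      }
      shape <- c(ly$out_maps, ly$out_ch, ly$target_time)
    }
    if (any(shape < 1)) stop("layer ", i, " yields a non-positive shape")
    ly$out_shape <- shape
    resolved[[i]] <- ly
  }
  structure(list(layers = resolved, input_shape = input_shape,
                 output_shape = shape),
            class = "ArchitectureSpec")
}

#' @export
format.ArchitectureSpec <- function(x, ...) {
  rows <- vapply(seq_along(x$layers), function(i) {
    ly <- x$layers[[i]]
    detail <- switch(ly$kind,
      temporal_conv = sprintf("1x%d, %d maps", ly$kw, ly$out_maps),
      spatial_conv  = sprintf("%dx1, %d maps", ly$kh, ly$out_maps),
      pool          = sprintf("mean 1x%d stride %d", ly$width, ly$stride),
      dense         = sprintf("%d units", ly$units),
      dropout       = sprintf("p=%.2f", ly$p),
      upsample_conv = sprintf("-> t=%d ch=%d, %d maps%s", ly$target_time,
                              ly$out_ch, ly$out_maps,
                              if (isTRUE(ly$spatial)) " (channel expand)" else ""))
    sprintf("%2d %-13s %-28s %-8s out=%s", i, ly$kind, detail, ly$activation,
            paste(ly$out_shape, collapse = "x"))
  }, character(1))
  paste0("ArchitectureSpec in=", paste(x$input_shape, collapse = "x"), "\n",
         paste(rows, collapse = "\n"))
}

#' @export
print.ArchitectureSpec <- function(x, ...) { cat(format(x), "\n"); invisible(x) }

#' Initialize parameters for an architecture
#'
#' Weights are drawn from a zero-mean Gaussian with standard deviation
#' `sqrt(2 / fan_in)`; biases start at zero. Driven entirely by R's RNG so
#' seeded runs are bitwise reproducible.
#'
#' @param spec An [architecture_spec()].
#' @return List of per-layer parameter lists (`NULL` for parameter-free
#'   layers).
#' @export
init_arch_params <- function(spec) {
  lapply(spec$layers, function(ly) {
    if (is.null(ly$w_dim)) return(NULL)
    fan_in <- ly$w_dim[1]
    W <- matrix(stats::rnorm(prod(ly$w_dim), sd = sqrt(2 / fan_in)),
                ly$w_dim[1], ly$w_dim[2])
    nb <- if (ly$kind == "upsample_conv" && isTRUE(ly$spatial)) ly$out_maps
          else ly$w_dim[2]
    if (ly$kind == "dense") nb <- ly$units
    list(W = W, b = numeric(nb))
  })
}

#' Number of trainable parameters in an architecture
#' @param spec An [architecture_spec()].
#' @export
n_arch_params <- function(spec) {
  sum(vapply(spec$layers, function(ly) {
    if (is.null(ly$w_dim)) return(0)
    nb <- if (ly$kind == "upsample_conv" && isTRUE(ly$spatial)) ly$out_maps
          else ly$w_dim[2]
    prod(ly$w_dim) + nb
  }, numeric(1)))
}

# forward through a resolved stack; caches carry what backward needs
net_forward <- function(spec, params, x, train = FALSE) {
  caches <- vector("list", length(spec$layers))
  for (i in seq_along(spec$layers)) {
    ly <- spec$layers[[i]]
    pm <- params[[i]]
    cache <- list()
    if (ly$kind == "temporal_conv") {
      fw <- tconv_forward(x, pm$W, pm$b, ly$kw, ly$padding)
      z <- fw$z; cache <- fw
    } else if (ly$kind == "spatial_conv") {
      fw <- sconv_forward(x, pm$W, pm$b)
      z <- fw$z; cache <- fw
    } else if (ly$kind == "pool") {
      fw <- pool_forward(x, ly$width, ly$stride)
      z <- fw$z; cache <- fw
    } else if (ly$kind == "dense") {
      xin <- x
      cache$in_dim <- dim(xin)
      if (length(dim(xin)) > 2) dim(xin) <- c(dim(xin)[1], prod(dim(xin)[-1]))
      cache$xm <- xin
      z <- add_bias(xin %*% pm$W, pm$b)
      if (!is.null(ly$reshape_to)) {
        # spec shape (m, ch, t) -> runtime layout (n, ch, t, m)
        rs <- ly$reshape_to
        dim(z) <- c(nrow(xin), rs[2], rs[3], rs[1])
      }
    } else if (ly$kind == "dropout") {
      if (train && ly$p > 0) {
        keep <- 1 - ly$p
        mask <- array(stats::runif(length(x)) < keep, dim(x)) / keep
        cache$mask <- mask
        z <- x * mask
      } else {
        z <- x
      }
    } else if (ly$kind == "upsample_conv") {
      R <- resize_matrix(ly$in_shape[3], ly$target_time)
      xr <- resize_time(x, R)
      cache$R <- R
      if (isTRUE(ly$spatial)) {
        fw <- xconv_forward(xr, pm$W, pm$b, ly$out_ch)
      } else {
        fw <- tconv_forward(xr, pm$W, pm$b, ly$kw, "same")
      }
      z <- fw$z
      cache <- c(cache, fw)
    }
    y <- if (ly$activation == "linear") z else act_forward(z, ly$activation)
    cache$z <- z; cache$y <- y
    caches[[i]] <- cache
    x <- y
  }
  list(out = x, caches = caches)
}

net_backward <- function(spec, params, caches, dout,
                         need_input = TRUE, need_params = TRUE) {
  grads <- if (need_params) vector("list", length(spec$layers)) else NULL
  dy <- dout
  for (i in rev(seq_along(spec$layers))) {
    ly <- spec$layers[[i]]
    pm <- params[[i]]
    cache <- caches[[i]]
    dz <- if (ly$activation == "linear") dy
          else act_backward(dy, cache$z, cache$y, ly$activation)
    want_in <- need_input || i > 1
    if (ly$kind == "temporal_conv") {
      bw <- tconv_backward(dz, cache, pm$W, ly$kw, ly$padding,
                           want_in, need_params)
      dy <- bw$dx
      if (need_params) grads[[i]] <- list(W = bw$dW, b = bw$db)
    } else if (ly$kind == "spatial_conv") {
      bw <- sconv_backward(dz, cache, pm$W, want_in, need_params)
      dy <- bw$dx
      if (need_params) grads[[i]] <- list(W = bw$dW, b = bw$db)
    } else if (ly$kind == "pool") {
      dy <- pool_backward(dz, cache, ly$width, ly$stride)
    } else if (ly$kind == "dense") {
      dzm <- dz
      if (length(dim(dzm)) > 2) dim(dzm) <- c(dim(dzm)[1], prod(dim(dzm)[-1]))
      if (need_params) {
        grads[[i]] <- list(W = crossprod(cache$xm, dzm), b = colSums(dzm))
      }
      if (want_in) {
        dxm <- dzm %*% t(pm$W)
        if (length(cache$in_dim) > 2) dim(dxm) <- cache$in_dim
        dy <- dxm
      } else dy <- NULL
    } else if (ly$kind == "dropout") {
      dy <- if (is.null(cache$mask)) dz else dz * cache$mask
    } else if (ly$kind == "upsample_conv") {
      if (isTRUE(ly$spatial)) {
        bw <- xconv_backward(dz, cache, pm$W, ly$out_ch, want_in, need_params)
      } else {
        bw <- tconv_backward(dz, cache, pm$W, ly$kw, "same", want_in, need_params)
      }
      if (need_params) grads[[i]] <- list(W = bw$dW, b = bw$db)
      dy <- if (want_in) resize_time(bw$dx, t(cache$R)) else NULL
    }
  }
  list(dx = dy, grads = grads)
}

# --- Adam -------------------------------------------------------------------

adam_init <- function(params) {
  lapply(params, function(pl) {
    if (is.null(pl)) return(NULL)
    lapply(pl, function(p) list(m = p * 0, v = p * 0))
  })
}

adam_step <- function(params, grads, state, lr, t,
                      beta1 = 0.5, beta2 = 0.9, eps = 1e-8) {
  upd <- function(p, g, s) {
    s$m <- beta1 * s$m + (1 - beta1) * g
    s$v <- beta2 * s$v + (1 - beta2) * g * g
    mhat <- s$m / (1 - beta1^t)
    vhat <- s$v / (1 - beta2^t)
    list(p = p - lr * mhat / (sqrt(vhat) + eps), s = s)
  }
  for (i in seq_along(params)) {
    if (is.null(params[[i]])) next
    for (nm in names(params[[i]])) {
      r <- upd(params[[i]][[nm]], grads[[i]][[nm]], state[[i]][[nm]])
      params[[i]][[nm]] <- r$p
      state[[i]][[nm]] <- r$s
    }
  }
  list(params = params, state = state)
}
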