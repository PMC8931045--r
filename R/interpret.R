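# Forward-model interpretation of learned spatial filters.
#
# A discriminative spatial filter w maps channel data to a feature; the
# corresponding activation pattern A = Sigma_input W Sigma_output^-1 is the
# forward-model projection that shows WHERE the extracted source expresses
# itself on the scalp, which is what can be read neurophysiologically.

#' Extract spatial-convolution weights from a discriminator
#'
#' Locates every spatial convolution in the feature extractor and returns,
#' per such layer, a channels x filters matrix: entry `(c, j)` is the
#' weight filter `j` applies to channel row `c`, summed over input feature
#' maps (the channel profile the filter applies when all maps carry the
#' same signal).
#'
#' @param model An initialized `DiscriminatorModel`.
#' @return A channels x filters matrix for the first spatial layer whose
#'   channel extent exceeds 1, with all such layers available as attribute
#'   `"all"` (RSTNN modules beyond the first operate on a collapsed channel
#'   axis and are excluded from the primary return).
#' @export
extract_spatial_weights <- function(model) {
  check_initialized(model)
  idx <- which(vapply(model$feature$layers,
                      function(ly) ly$kind == "spatial_conv", logical(1)))
  if (length(idx) == 0) stop("model has no spatial convolution layer")
  mats <- lapply(idx, function(i) {
    ly <- model$feature$layers[[i]]
    W <- model$params$feature[[i]]$W      # (ch * m_in) x m_out, ch fastest
    m_in <- ly$in_shape[1]; ch <- ly$in_shape[2]
    Wa <- array(W, c(ch, m_in, ncol(W)))
    apply(Wa, c(1, 3), sum)               # ch x m_out
  })
  spatial_idx <- idx[vapply(idx, function(i)
    model$feature$layers[[i]]$in_shape[2] > 1, logical(1))]
  primary <- mats[[match(spatial_idx[1], idx)]]
  attr(primary, "all") <- mats
  attr(primary, "layer_index") <- spatial_idx[1]
  primary
}

#' Run windows through the layers preceding a spatial convolution
#'
#' Returns the multi-channel representation presented at the spatial
#' layer's input, reshaped to channels x samples (every input map and time
#' point of every window is one sample), the estimate basis for
#' `Sigma_input` in [activation_patterns()].
#'
#' @param model An initialized `DiscriminatorModel`.
#' @param x Window batch `n x 1 x C x T`.
#' @param layer_index Index of the spatial layer (default: the one chosen
#'   by [extract_spatial_weights()]).
#' @export
spatial_layer_inputs <- function(model, x, layer_index = NULL) {
  check_initialized(model)
  if (is.null(layer_index)) {
    layer_index <- attr(extract_spatial_weights(model), "layer_index")
  }
  x <- as_internal(x)
  if (layer_index > 1) {
    pre <- structure(list(layers = model$feature$layers[seq_len(layer_index - 1)],
                          input_shape = model$feature$input_shape),
                     class = "ArchitectureSpec")
    h <- net_forward(pre, model$params$feature[seq_len(layer_index - 1)],
                     x, train = FALSE)$out
  } else h <- x
  d <- dim(h)                              # internal (n, ch, t, m)
  hm <- aperm(h, c(2, 1, 3, 4))            # ch first
  dim(hm) <- c(d[2], d[1] * d[3] * d[4])
  hm
}

#' Activation patterns from backward weights (forward-model transform)
#'
#' Computes `A = Sigma_input W Sigma_output^-1` where `Sigma_input` is the
#' covariance of the supplied channel samples, `Sigma_output` the
#' covariance of the filter outputs `W' x`, and the inverse is
#' ridge-regularized (`epsilon = 1e-6 trace/filters`) against
#' near-collinear trained filters.
#'
#' @param W Channels x filters matrix of backward (filter) weights.
#' @param inputs Channels x samples matrix presented at the filter's input
#'   (needs more samples than channels).
#' @param ridge Relative ridge strength for the output-covariance inverse.
#' @return An `ActivationPatternSet`: list with `A` (channels x filters),
#'   `W`, `sigma_input`, `sigma_output`.
#' @export
activation_patterns <- function(W, inputs, ridge = 1e-6) {
  W <- as.matrix(W)
  inputs <- as.matrix(inputs)
  if (nrow(inputs) != nrow(W)) {
    stop("inputs have ", nrow(inputs), " channels, W has ", nrow(W))
  }
  if (ncol(inputs) < nrow(inputs) + 1) {
    stop("need at least channels + 1 samples to estimate Sigma_input")
  }
  sigma_in <- stats::cov(t(inputs))
  out <- crossprod(W, inputs)              # filters x samples
  sigma_out <- stats::cov(t(out))
  k <- nrow(sigma_out)
  eps <- ridge * sum(diag(sigma_out)) / k
  sigma_out_r <- sigma_out + diag(eps, k)
  inv <- tryCatch(solve(sigma_out_r), error = function(e) NULL)
  if (is.null(inv)) {
    degenerate <- which(diag(sigma_out) < eps)
    stop("singular output covariance beyond regularization; degenerate ",
         "filter(s): ", paste(degenerate, collapse = ", "))
  }
  A <- sigma_in %*% W %*% inv
  structure(list(A = A, W = W, sigma_input = sigma_in,
                 sigma_output = sigma_out),
            class = "ActivationPatternSet")
}

#' Cosine similarity between two pattern vectors
#' @param a,b Numeric vectors of equal length.
#' @export
pattern_cosine <- function(a, b) {
  sum(a * b) / sqrt(sum(a * a) * sum(b * b))
}

# thin-plate spline basis phi(r) = r^2 log r
tps_phi <- function(r) ifelse(r > 0, r^2 * log(r), 0)

#' Topographic scalp map of a pattern column
#'
#' Thin-plate-spline interpolation of per-channel values onto a square grid
#' over the unit disc (NA outside the disc); the interpolant reproduces the
#' channel values exactly at the electrode positions.
#'
#' @param values Numeric vector, one value per channel.
#' @param layout A [channel_layout()].
#' @param resolution Grid points per axis.
#' @return A `TopographyMap`: list with `grid` (resolution x resolution,
#'   NA outside the scalp disc), axes `x`/`y`, `electrode_values` and
#'   `layout`.
#' @export
topomap <- function(values, layout, resolution = 64) {
  pos <- layout$positions
  n <- nrow(pos)
  if (length(values) != n) stop("one value per channel required")
  if (n < 3) stop("topographic interpolation needs >= 3 channels")
  D <- as.matrix(stats::dist(pos))
  K <- tps_phi(D)
  P <- cbind(1, pos)
  lhs <- rbind(cbind(K, P), cbind(t(P), matrix(0, 3, 3)))
  rhs <- c(values, rep(0, 3))
  coefs <- solve(lhs + diag(1e-12, n + 3), rhs)
  ax <- seq(-1, 1, length.out = resolution)
  gpts <- as.matrix(expand.grid(x = ax, y = ax))
  d2 <- outer(gpts[, 1], pos[, 1], "-")^2 + outer(gpts[, 2], pos[, 2], "-")^2
  G <- tps_phi(sqrt(d2))
  z <- G %*% coefs[1:n] + cbind(1, gpts) %*% coefs[n + 1:3]
  z[gpts[, 1]^2 + gpts[, 2]^2 > 1] <- NA
  grid <- matrix(z, resolution, resolution)  # rows follow x, cols follow y
  structure(list(grid = grid, x = ax, y = ax,
                 electrode_values = as.numeric(values), layout = layout),
            class = "TopographyMap")
}

#' Evaluate a topography at arbitrary points by nearest grid node
#' @param map A [topomap()].
#' @param pts Matrix of `(x, y)` points.
#' @export
topomap_at <- function(map, pts) {
  pts <- rbind(pts)
  vapply(seq_len(nrow(pts)), function(i) {
    ix <- which.min(abs(map$x - pts[i, 1]))
    iy <- which.min(abs(map$y - pts[i, 2]))
    map$grid[ix, iy]
  }, numeric(1))
}

#' @export
plot.TopographyMap <- function(x, main = "", ...) {
  graphics::image(x$x, x$y, x$grid, asp = 1, xlab = "", ylab = "",
                  main = main, axes = FALSE,
                  col = grDevices::hcl.colors(64, "RdBu", rev = TRUE), ...)
  th <- seq(0, 2 * pi, length.out = 200)
  graphics::lines(cos(th), sin(th))
  graphics::points(x$layout$positions, pch = 20, cex = 0.6)
  invisible(x)
}
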