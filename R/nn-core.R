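# Minimal convolutional-network engine on base-R matrix algebra.
#
# Runtime batch tensors are 4-d arrays laid out (n, channels, time, maps):
# with the map axis last, the im2col matrices of temporal convolutions are
# plain `dim<-` reinterpretations (no aperm copies), which is what makes
# CPU training viable. The public window layout (n, 1, C, T) reinterprets
# to the internal one at zero cost (identical element order). Dense layers
# work on (n, units) matrices. Every layer has an exact backward pass.

ACTIVATIONS <- c("linear", "relu", "lrelu", "elu", "square", "log", "tanh")
LRELU_SLOPE <- 0.2
SAFE_LOG_EPS <- 1e-6

act_forward <- function(z, act) {
  switch(act,
    linear = z,
    relu   = pmax(z, 0),
    lrelu  = pmax(z, 0) + LRELU_SLOPE * pmin(z, 0),
    elu    = pmax(z, 0) + expm1(pmin(z, 0)),
    square = z * z,
    log    = log(pmax(z, SAFE_LOG_EPS)),
    tanh   = tanh(z),
    stop("unknown activation: ", act)
  )
}

act_backward <- function(dy, z, y, act) {
  switch(act,
    linear = dy,
    relu   = dy * (z > 0),
    lrelu  = dy * ((z > 0) + LRELU_SLOPE * (z <= 0)),
    elu    = dy * ((z > 0) + (z <= 0) * (y + 1)),
    square = dy * 2 * z,
    log    = dy / pmax(z, SAFE_LOG_EPS),
    tanh   = dy * (1 - y * y),
    stop("unknown activation: ", act)
  )
}

# public (n, 1, C, T) <-> internal (n, C, T, 1): identical element order
as_internal <- function(x) {
  d <- dim(x)
  if (is.matrix(x)) {                     # single C x T trial window
    dim(x) <- c(1, d[1], d[2], 1)
    return(x)
  }
  dim(x) <- c(d[1], d[3], d[4], d[2])
  x
}

as_public <- function(x) {
  d <- dim(x)
  dim(x) <- c(d[1], d[4], d[2], d[3])
  x
}

add_bias <- function(z, b) z + rep(b, each = nrow(z))

# --- temporal convolution (kernel 1 x kw shared across channel rows) -------

# W is (m_in * kw) x m_out with rows ordered (j - 1) * m_in + mi.
# The heavy lifting happens in the compiled kernels (src/conv.cpp), which
# exploit the layout: every kernel tap addresses contiguous columns of the
# (n*ch) x (t*m) matrix view, so no gather/scatter copies are made.
# Same-padding is realized inside the kernel by clipping the tap range.
tconv_forward <- function(x, W, b, kw, padding = "valid") {
  d <- dim(x)
  pl <- if (padding == "same") (kw - 1) %/% 2 else 0L
  t_out <- if (padding == "same") d[3] else d[3] - kw + 1
  z <- conv_t_fwd_cpp(x, d, W, b, kw, pl, t_out)
  dim(z) <- c(d[1], d[2], t_out, ncol(W))
  list(z = z, x_in = x, t_out = t_out, in_dim = d, pl = pl)
}

tconv_backward <- function(dz, cache, W, kw, padding,
                           need_input = TRUE, need_params = TRUE) {
  d <- cache$in_dim
  bw <- conv_t_bwd_cpp(dz, cache$x_in, d, W, kw, cache$pl, cache$t_out,
                       need_input, need_params)
  dx <- bw$dx
  if (!is.null(dx)) dim(dx) <- d
  list(dx = dx, dW = bw$dW, db = if (is.null(bw$db)) NULL else as.numeric(bw$db))
}

# --- spatial convolution (kernel ch x 1, collapses the channel axis) -------

# W is (ch * m_in) x m_out with rows ordered (mi - 1) * ch + c
sconv_forward <- function(x, W, b) {
  d <- dim(x)
  xm <- aperm(x, c(1, 3, 2, 4))           # (n, t, ch, m)
  dim(xm) <- c(d[1] * d[3], d[2] * d[4])
  z <- add_bias(xm %*% W, b)
  dim(z) <- c(d[1], 1, d[3], ncol(W))     # ch axis collapsed to 1
  list(z = z, xm = xm, in_dim = d)
}

sconv_backward <- function(dz, cache, W, need_input = TRUE, need_params = TRUE) {
  d <- cache$in_dim
  m_out <- ncol(W)
  dzm <- dz
  dim(dzm) <- c(d[1] * d[3], m_out)
  dW <- NULL; db <- NULL; dx <- NULL
  if (need_params) {
    dW <- crossprod(cache$xm, dzm)
    db <- colSums(dzm)
  }
  if (need_input) {
    dxm <- dzm %*% t(W)
    dim(dxm) <- c(d[1], d[3], d[2], d[4])
    dx <- aperm(dxm, c(1, 3, 2, 4))
  }
  list(dx = dx, dW = dW, db = db)
}

# --- mean pooling along time ------------------------------------------------

pool_forward <- function(x, width, stride) {
  d <- dim(x)
  t_out <- (d[3] - width) %/% stride + 1
  z <- pool_fwd_cpp(x, d, width, stride, t_out)
  dim(z) <- c(d[1], d[2], t_out, d[4])
  list(z = z, in_dim = d, t_out = t_out)
}

pool_backward <- function(dz, cache, width, stride) {
  dx <- pool_bwd_cpp(dz, cache$in_dim, width, stride, cache$t_out)
  dim(dx) <- cache$in_dim
  dx
}

# --- bilinear time resize (align-corners) ----------------------------------

resize_matrix <- function(t_in, t_out) {
  R <- matrix(0, t_in, t_out)
  if (t_out == 1) {
    u <- (t_in + 1) / 2
    lo <- floor(u); hi <- min(lo + 1, t_in); w <- u - lo
    R[lo, 1] <- R[lo, 1] + (1 - w); R[hi, 1] <- R[hi, 1] + w
    return(R)
  }
  u <- 1 + (seq_len(t_out) - 1) * (t_in - 1) / (t_out - 1)
  lo <- pmax(pmin(floor(u), t_in - if (t_in > 1) 1 else 0), 1)
  hi <- pmin(lo + 1, t_in)
  w <- u - lo
  for (k in seq_len(t_out)) {
    R[lo[k], k] <- R[lo[k], k] + (1 - w[k])
    R[hi[k], k] <- R[hi[k], k] + w[k]
  }
  R
}

# multiply along the time (3rd) axis
resize_time <- function(x, R) {
  d <- dim(x)
  xm <- aperm(x, c(1, 2, 4, 3))
  dim(xm) <- c(d[1] * d[2] * d[4], d[3])
  y <- xm %*% R
  dim(y) <- c(d[1], d[2], d[4], ncol(R))
  aperm(y, c(1, 2, 4, 3))
}

# --- channel-expansion map (reverse of a spatial convolution) ---------------

# W is m_in x (out_ch * m_out) with columns ordered (mo - 1) * out_ch + c
xconv_forward <- function(x, W, b, out_ch) {
  d <- dim(x)                             # (n, 1, t, m_in)
  xm <- x
  dim(xm) <- c(d[1] * d[3], d[4])
  z <- add_bias(xm %*% W, rep(b, each = out_ch))
  m_out <- ncol(W) / out_ch
  dim(z) <- c(d[1], d[3], out_ch, m_out)
  list(z = aperm(z, c(1, 3, 2, 4)), xm = xm, in_dim = d)
}

xconv_backward <- function(dz, cache, W, out_ch, need_input = TRUE,
                           need_params = TRUE) {
  d <- cache$in_dim
  m_out <- ncol(W) / out_ch
  dzm <- aperm(dz, c(1, 3, 2, 4))         # (n, t, ch, m_out)
  dim(dzm) <- c(d[1] * d[3], out_ch * m_out)
  dW <- NULL; db <- NULL; dx <- NULL
  if (need_params) {
    dW <- crossprod(cache$xm, dzm)
    db <- colSums(matrix(colSums(dzm), nrow = out_ch))
  }
  if (need_input) {
    dxm <- dzm %*% t(W)
    dim(dxm) <- c(d[1], 1, d[3], d[4])
    dx <- dxm
  }
  list(dx = dx, dW = dW, db = db)
}
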