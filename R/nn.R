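# Minimal convolutional-network engine used by the 2.5D adversarial
# segmenter: 2D convolutions with hand-derived backward passes expressed as
# BLAS matrix products, leaky-ReLU/sigmoid activations, nearest-neighbour
# up/downsampling and an Adam optimizer over nested parameter lists.
# Tensors are single-sample arrays (H, W, C).

#' @noRd
conv_init <- function(kh, kw, cin, cout) {
  sd <- sqrt(2 / (kh * kw * cin))
  list(W = array(stats::rnorm(kh * kw * cin * cout, 0, sd),
                 c(kh, kw, cin, cout)),
       b = numeric(cout))
}

#' @noRd
pad2 <- function(x, p) {
  if (p == 0) return(x)
  d <- dim(x)
  out <- array(0, c(d[1] + 2 * p, d[2] + 2 * p, d[3]))
  out[(p + 1):(p + d[1]), (p + 1):(p + d[2]), ] <- x
  out
}

# Forward convolution in im2col form: the padded input is gathered into a
# patch matrix (one column block per kernel offset, channel-fastest within
# a block) so the whole convolution is a single BLAS product. The cache
# holds the patch matrix for the backward pass.
#' @noRd
conv_fwd <- function(x, par, stride = 1, pad = 1) {
  d <- dim(par$W)  # (kh, kw, cin, cout)
  xp <- pad2(x, pad)
  dp <- dim(xp)
  ho <- (dp[1] - d[1]) %/% stride + 1L
  wo <- (dp[2] - d[2]) %/% stride + 1L
  n <- ho * wo
  X <- im2col_cpp(xp, dp[1], dp[2], dp[3], d[1], d[2], stride)
  # weight matrix with matching (channel, ki, kj) row order
  Wm <- matrix(aperm(par$W, c(3, 1, 2, 4)), d[1] * d[2] * d[3], d[4])
  out <- X %*% Wm
  out <- out + rep(par$b, each = n)
  list(out = array(out, c(ho, wo, d[4])),
       cache = list(X = X, xpdim = dp, xdim = dim(x), stride = stride,
                    pad = pad, ho = ho, wo = wo))
}

#' @noRd
conv_bwd <- function(dout, par, cache) {
  d <- dim(par$W)
  ho <- cache$ho; wo <- cache$wo
  n <- ho * wo
  dm <- dout
  dim(dm) <- c(n, d[4])
  dWm <- crossprod(cache$X, dm)                  # (cin*kh*kw) x cout
  dW <- aperm(array(dWm, c(d[3], d[1], d[2], d[4])), c(2, 3, 1, 4))
  Wm <- matrix(aperm(par$W, c(3, 1, 2, 4)), d[1] * d[2] * d[3], d[4])
  dX <- tcrossprod(dm, Wm)                       # n x (cin*kh*kw)
  dxp <- array(col2im_cpp(dX, cache$xpdim[1], cache$xpdim[2],
                          cache$xpdim[3], d[1], d[2], cache$stride),
               cache$xpdim)
  p <- cache$pad
  xd <- cache$xdim
  dx <- if (p > 0) dxp[(p + 1):(p + xd[1]), (p + 1):(p + xd[2]), ,
                       drop = FALSE] else dxp
  list(dx = array(dx, xd), grads = list(W = dW, b = colSums(dm)))
}

# Affine instance normalization: per-channel standardization over the
# spatial axes with learned gain/shift. The batch-size-1 counterpart of the
# batch normalization the pix2pix family depends on for conditioning.
#' @noRd
inorm_init <- function(c) list(g = rep(1, c), s = rep(0, c))

#' @noRd
inorm_fwd <- function(x, par, eps = 1e-5) {
  d <- dim(x)
  n <- d[1] * d[2]
  xm <- x
  dim(xm) <- c(n, d[3])
  mu <- colMeans(xm)
  xc <- xm - rep(mu, each = n)
  v <- colSums(xc^2) / n
  isd <- 1 / sqrt(v + eps)
  xhat <- xc * rep(isd, each = n)
  out <- xhat * rep(par$g, each = n) + rep(par$s, each = n)
  dim(out) <- d
  list(out = out, cache = list(xhat = xhat, isd = isd, d = d, n = n))
}

#' @noRd
inorm_bwd <- function(dout, par, cache) {
  n <- cache$n
  dm <- dout
  dim(dm) <- c(n, cache$d[3])
  xhat <- cache$xhat
  dg <- colSums(dm * xhat)
  ds <- colSums(dm)
  dxhat <- dm * rep(par$g, each = n)
  # d/dx of (x - mu)/sd with mu, sd functions of x
  dx <- (dxhat - rep(colMeans(dxhat), each = n) -
           xhat * rep(colMeans(dxhat * xhat), each = n)) *
    rep(cache$isd, each = n)
  dim(dx) <- cache$d
  list(dx = dx, grads = list(g = dg, s = ds))
}

#' @noRd
lrelu_fwd <- function(x, alpha = 0.2) {
  neg <- x < 0
  x[neg] <- alpha * x[neg]
  list(out = x, cache = list(neg = neg, alpha = alpha))
}

#' @noRd
lrelu_bwd <- function(dout, cache) {
  dout[cache$neg] <- cache$alpha * dout[cache$neg]
  dout
}

#' @noRd
sigmoid <- function(x) 1 / (1 + exp(-x))

# nearest-neighbour x2 upsampling and its adjoint
#' @noRd
upsample2_fwd <- function(x) {
  d <- dim(x)
  x[rep(seq_len(d[1]), each = 2), rep(seq_len(d[2]), each = 2), ,
    drop = FALSE]
}

#' @noRd
upsample2_bwd <- function(dout) {
  d <- dim(dout)
  odd1 <- seq(1, d[1], by = 2); odd2 <- seq(1, d[2], by = 2)
  dout[odd1, odd2, , drop = FALSE] +
    dout[odd1 + 1, odd2, , drop = FALSE] +
    dout[odd1, odd2 + 1, , drop = FALSE] +
    dout[odd1 + 1, odd2 + 1, , drop = FALSE]
}

# Adam over a nested list of parameter arrays.
#' @noRd
adam_init <- function(params) {
  zero_like <- function(p) {
    if (is.list(p)) lapply(p, zero_like) else p * 0
  }
  list(m = zero_like(params), v = zero_like(params), t = 0L)
}

#' @noRd
adam_step <- function(params, grads, state, lr, beta1 = 0.5, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  t <- state$t
  walk <- function(p, g, m, v) {
    if (is.list(p)) {
      out_p <- p; out_m <- m; out_v <- v
      for (i in seq_along(p)) {
        if (is.null(p[[i]])) next
        r <- walk(p[[i]], g[[i]], m[[i]], v[[i]])
        out_p[[i]] <- r$p; out_m[[i]] <- r$m; out_v[[i]] <- r$v
      }
      return(list(p = out_p, m = out_m, v = out_v))
    }
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g^2
    mh <- m / (1 - beta1^t)
    vh <- v / (1 - beta2^t)
    list(p = p - lr * mh / (sqrt(vh) + eps), m = m, v = v)
  }
  r <- walk(params, grads, state$m, state$v)
  list(params = r$p, state = list(m = r$m, v = r$v, t = t))
}

# elementwise sum of two grad lists (same structure)
#' @noRd
grads_add <- function(a, b) {
  if (is.null(a)) return(b)
  if (is.list(a)) return(mapply(grads_add, a, b, SIMPLIFY = FALSE))
  a + b
}

#' @noRd
grads_scale <- function(a, s) {
  if (is.list(a)) return(lapply(a, grads_scale, s = s))
  a * s
}
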