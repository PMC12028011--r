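# Minimal dense/conv layer toolkit with explicit forward/backward passes.
#
# Batches are numeric arrays dim c(Z, Y, X, C, N).  Each layer forward
# returns list(out, cache); each backward takes (cache, dout) and returns
# list(dx, grads) with grads mirroring the parameter structure.  No
# autograd: the backward passes are hand-written and are verified against
# numerical differentiation in the test suite.

kaiming_init <- function(fan_in, n) {
  rnorm(n, sd = sqrt(2 / fan_in))
}

conv3d_init <- function(c_in, c_out) {
  list(W = matrix(kaiming_init(c_in * 27, c_out * c_in * 27), nrow = c_out),
       b = rep(0, c_out))
}

conv3d_fwd <- function(par, x) {
  y <- cpp_conv3d_fwd(x, par$W, par$b)
  list(out = y, cache = list(x = x, par = par))
}

conv3d_bwd <- function(cache, dy) {
  g <- cpp_conv3d_bwd(cache$x, cache$par$W, dy)
  list(dx = g$dx, grads = list(W = g$dw, b = as.numeric(g$db)))
}

bn_init <- function(c_out) {
  list(gamma = rep(1, c_out), beta = rep(0, c_out))
}

# Batch norm over (spatial, N) per channel; running stats for eval mode.
bn_fwd <- function(par, state, x, train, momentum = 0.1, eps = 1e-5) {
  d <- dim(x); S <- prod(d[1:3]); C <- d[4]; N <- d[5]
  xm <- array(x, dim = c(S, C, N))
  if (train) {
    mu <- apply(xm, 2, mean)
    v <- apply(xm, 2, function(m) mean((m - mean(m))^2))
    state$mean <- (1 - momentum) * (state$mean %||% mu) + momentum * mu
    state$var <- (1 - momentum) * (state$var %||% v) + momentum * v
  } else {
    mu <- state$mean %||% rep(0, C)
    v <- state$var %||% rep(1, C)
  }
  inv <- 1 / sqrt(v + eps)
  xc <- sweep(xm, 2, mu, "-")
  xhat <- sweep(xc, 2, inv, "*")
  y <- sweep(sweep(xhat, 2, par$gamma, "*"), 2, par$beta, "+")
  dim(y) <- d
  list(out = y, state = state,
       cache = list(xhat = xhat, inv = inv, gamma = par$gamma, d = d,
                    train = train))
}

bn_bwd <- function(cache, dy) {
  d <- cache$d; S <- prod(d[1:3]); C <- d[4]; N <- d[5]
  dym <- array(dy, dim = c(S, C, N))
  dgamma <- apply(dym * cache$xhat, 2, sum)
  dbeta <- apply(dym, 2, sum)
  m <- S * N
  dxhat <- sweep(dym, 2, cache$gamma, "*")
  if (cache$train) {
    s1 <- apply(dxhat, 2, sum)
    s2 <- apply(dxhat * cache$xhat, 2, sum)
    dx <- sweep(dxhat, 2, s1 / m, "-") - sweep(cache$xhat, 2, s2 / m, "*")
    dx <- sweep(dx, 2, cache$inv, "*")
  } else {
    dx <- sweep(dxhat, 2, cache$inv, "*")
  }
  dim(dx) <- d
  list(dx = dx, grads = list(gamma = dgamma, beta = dbeta))
}

relu_fwd <- function(x) {
  mask <- x > 0
  x[!mask] <- 0
  list(out = x, cache = mask)
}

relu_bwd <- function(mask, dy) {
  dy[!mask] <- 0
  dy
}

dropout_fwd <- function(x, p, train) {
  if (!train || p <= 0) return(list(out = x, cache = NULL))
  keep <- array(rbinom(length(x), 1, 1 - p), dim = dim(x)) / (1 - p)
  list(out = x * keep, cache = keep)
}

dropout_bwd <- function(cache, dy) {
  if (is.null(cache)) dy else dy * cache
}

maxpool_fwd <- function(x) {
  r <- cpp_maxpool3d_fwd(x)
  list(out = r$y, cache = list(argmax = r$argmax, xdim = dim(x)))
}

maxpool_bwd <- function(cache, dy) {
  cpp_maxpool3d_bwd(cache$argmax, dy, cache$xdim)
}

# GlobalMaxAvgPool: element-wise mean of the global max-pooled and global
# average-pooled feature maps, yielding one d-dim vector per sample (the
# feature dimension stays C, not 2C).
gmap_fwd <- function(x) {
  d <- dim(x); S <- prod(d[1:3]); C <- d[4]; N <- d[5]
  m <- matrix(x, nrow = S)                 # columns are (C, N) slabs
  amax <- max.col(t(m), ties.method = "first")
  vmax <- m[cbind(amax, seq_len(C * N))]
  vavg <- colMeans(m)
  feat <- matrix(0.5 * (vmax + vavg), nrow = C)  # C x N
  list(out = t(feat),                       # N x C features
       cache = list(amax = amax, d = d))
}

gmap_bwd <- function(cache, dfeat) {
  d <- cache$d; S <- prod(d[1:3]); C <- d[4]; N <- d[5]
  dvec <- as.vector(t(dfeat))               # length C*N, per slab
  dx <- matrix(rep(dvec * 0.5 / S, each = S), nrow = S)
  idx <- cbind(cache$amax, seq_len(C * N))
  dx[idx] <- dx[idx] + 0.5 * dvec
  dim(dx) <- d
  dx
}

linear_init <- function(n_in, n_out) {
  list(W = matrix(kaiming_init(n_in, n_in * n_out), nrow = n_in), b = rep(0, n_out))
}

linear_fwd <- function(par, x) {            # x: N x n_in
  list(out = sweep(x %*% par$W, 2, par$b, "+"),
       cache = list(x = x, par = par))
}

linear_bwd <- function(cache, dy) {
  list(dx = dy %*% t(cache$par$W),
       grads = list(W = t(cache$x) %*% dy, b = colSums(dy)))
}

sigmoid <- function(z) 1 / (1 + exp(-z))

# Numerically stable BCE on logits; returns loss and dlogit.
bce_loss <- function(logit, label) {
  n <- length(logit)
  loss <- mean(pmax(logit, 0) - logit * label + log1p(exp(-abs(logit))))
  dlogit <- (sigmoid(logit) - label) / n
  list(loss = loss, dlogit = dlogit)
}
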