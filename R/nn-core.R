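# Neural-network primitives with hand-derived gradients.
#
# Conventions: batched sequence tensors are 3-D arrays with dims
# (batch, time, channels). `mat3()` flattens to a (batch*time) x channels
# matrix (R's column-major order makes the two layouts share memory order),
# which is the shape all dense algebra runs in. Every layer has a forward
# returning `list(out, cache)` and a backward taking `(cache, d_out)` and
# returning `list(dx, <param gradients>)`.

mat3 <- function(a) {
  d <- dim(a)
  dim(a) <- c(d[1] * d[2], d[3])
  a
}

unmat3 <- function(m, b, t) {
  dim(m) <- c(b, t, ncol(m))
  m
}

sigmoid <- function(x) 1 / (1 + exp(-x))

glorot <- function(fan_in, fan_out, dims = c(fan_in, fan_out)) {
  lim <- sqrt(6 / (fan_in + fan_out))
  array(stats::runif(prod(dims), -lim, lim), dims)
}

## ---- dense -----------------------------------------------------------------

linear_fwd <- function(x, w, b) {
  list(out = sweep(x %*% w, 2, b, "+"), cache = list(x = x, w = w))
}

linear_bwd <- function(cache, dout) {
  list(dx = dout %*% t(cache$w),
       dw = crossprod(cache$x, dout),
       db = colSums(dout))
}

## ---- 1-D convolution over the time axis ------------------------------------

# x: (B, T, Cin); w: (k*Cin) x Cout with rows ordered tap-major
# (tap 1 channels, tap 2 channels, ...); zero padding `pad` on both ends.
conv1d_fwd <- function(x, w, b, k, pad = 0) {
  d <- dim(x); B <- d[1]; T_in <- d[2]; cin <- d[3]
  if (T_in + 2 * pad < k) stop("input shorter than kernel", call. = FALSE)
  if (pad > 0) {
    xp <- array(0, c(B, T_in + 2 * pad, cin))
    xp[, pad + seq_len(T_in), ] <- x
  } else xp <- x
  t_out <- T_in + 2 * pad - k + 1
  u <- matrix(0, B * t_out, k * cin)
  for (j in seq_len(k)) {
    slab <- xp[, j:(j + t_out - 1), , drop = FALSE]
    dim(slab) <- c(B * t_out, cin)
    u[, (j - 1) * cin + seq_len(cin)] <- slab
  }
  out <- sweep(u %*% w, 2, b, "+")
  list(out = unmat3(out, B, t_out),
       cache = list(u = u, w = w, k = k, pad = pad, B = B, T_in = T_in,
                    cin = cin, t_out = t_out))
}

conv1d_bwd <- function(cache, dout) {
  d2 <- mat3(dout)
  dw <- crossprod(cache$u, d2)
  db <- colSums(d2)
  du <- d2 %*% t(cache$w)
  dxp <- array(0, c(cache$B, cache$T_in + 2 * cache$pad, cache$cin))
  for (j in seq_len(cache$k)) {
    blk <- du[, (j - 1) * cache$cin + seq_len(cache$cin), drop = FALSE]
    dim(blk) <- c(cache$B, cache$t_out, cache$cin)
    dxp[, j:(j + cache$t_out - 1), ] <- dxp[, j:(j + cache$t_out - 1), , drop = FALSE] + blk
  }
  dx <- if (cache$pad > 0) dxp[, cache$pad + seq_len(cache$T_in), , drop = FALSE] else dxp
  list(dx = dx, dw = dw, db = db)
}

## ---- batch normalisation (per channel, over batch x time) ------------------

bn_fwd <- function(x2, gamma, beta, run_mean, run_var, train, momentum = 0.1,
                   eps = 1e-5) {
  if (train) {
    mu <- colMeans(x2)
    v <- colMeans(x2^2) - mu^2
    run_mean <- (1 - momentum) * run_mean + momentum * mu
    run_var <- (1 - momentum) * run_var + momentum * v
  } else {
    mu <- run_mean; v <- run_var
  }
  inv_sd <- 1 / sqrt(v + eps)
  xhat <- sweep(sweep(x2, 2, mu), 2, inv_sd, "*")
  out <- sweep(sweep(xhat, 2, gamma, "*"), 2, beta, "+")
  list(out = out,
       cache = list(xhat = xhat, inv_sd = inv_sd, gamma = gamma, train = train),
       run_mean = run_mean, run_var = run_var)
}

bn_bwd <- function(cache, dout) {
  n <- nrow(dout)
  dxhat <- sweep(dout, 2, cache$gamma, "*")
  dgamma <- colSums(dout * cache$xhat)
  dbeta <- colSums(dout)
  if (cache$train) {
    s1 <- colMeans(dxhat)
    s2 <- colMeans(dxhat * cache$xhat)
    dx <- sweep(dxhat, 2, s1) - sweep(cache$xhat, 2, s2, "*")
    dx <- sweep(dx, 2, cache$inv_sd, "*")
  } else {
    dx <- sweep(dxhat, 2, cache$inv_sd, "*")
  }
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

## ---- layer normalisation (per row, over channels) --------------------------

ln_fwd <- function(x2, gamma, beta, eps = 1e-5) {
  mu <- rowMeans(x2)
  xc <- x2 - mu
  v <- rowMeans(xc^2)
  inv_sd <- 1 / sqrt(v + eps)
  xhat <- xc * inv_sd
  out <- sweep(sweep(xhat, 2, gamma, "*"), 2, beta, "+")
  list(out = out, cache = list(xhat = xhat, inv_sd = inv_sd, gamma = gamma))
}

ln_bwd <- function(cache, dout) {
  dxhat <- sweep(dout, 2, cache$gamma, "*")
  dx <- (dxhat - rowMeans(dxhat) - cache$xhat * rowMeans(dxhat * cache$xhat)) *
    cache$inv_sd
  list(dx = dx, dgamma = colSums(dout * cache$xhat), dbeta = colSums(dout))
}

## ---- misc ------------------------------------------------------------------

relu_fwd <- function(x) list(out = pmax(x, 0), cache = x > 0)
relu_bwd <- function(cache, dout) dout * cache

dropout_fwd <- function(x, p, train) {
  if (!train || p <= 0) return(list(out = x, cache = NULL))
  mask <- array(stats::runif(length(x)) >= p, dim(x) %||% length(x)) / (1 - p)
  list(out = x * mask, cache = mask)
}

dropout_bwd <- function(cache, dout) if (is.null(cache)) dout else dout * cache

`%||%` <- function(a, b) if (is.null(a)) b else a

# Fixed linear interpolation of the time axis onto `t_out` uniform points;
# this is the (parameter-free) pooling that aligns the two convolution
# branches to a common sequence length.
time_align_weights <- function(t_in, t_out) {
  pos <- (seq_len(t_out) - 0.5) * t_in / t_out + 0.5
  i1 <- pmin(pmax(floor(pos), 1), t_in)
  i2 <- pmin(i1 + 1, t_in)
  w2 <- pmin(pmax(pos - i1, 0), 1)
  list(i1 = i1, i2 = i2, w1 = 1 - w2, w2 = w2)
}

time_align_fwd <- function(x, t_out) {
  d <- dim(x)
  wts <- time_align_weights(d[2], t_out)
  out <- array(0, c(d[1], t_out, d[3]))
  for (i in seq_len(t_out)) {
    out[, i, ] <- wts$w1[i] * x[, wts$i1[i], ] + wts$w2[i] * x[, wts$i2[i], ]
  }
  list(out = out, cache = list(wts = wts, t_in = d[2]))
}

time_align_bwd <- function(cache, dout) {
  d <- dim(dout)
  dx <- array(0, c(d[1], cache$t_in, d[3]))
  w <- cache$wts
  for (i in seq_len(d[2])) {
    dx[, w$i1[i], ] <- dx[, w$i1[i], ] + w$w1[i] * dout[, i, ]
    dx[, w$i2[i], ] <- dx[, w$i2[i], ] + w$w2[i] * dout[, i, ]
  }
  dx
}

# Sinusoidal positional encoding, T x d.
positional_encoding <- function(t_len, d) {
  pe <- matrix(0, t_len, d)
  pos <- seq_len(t_len) - 1
  for (j in seq_len(d)) {
    i <- (j - 1) %/% 2
    angle <- pos / 10000^(2 * i / d)
    pe[, j] <- if (j %% 2 == 1) sin(angle) else cos(angle)
  }
  pe
}

## ---- Adam ------------------------------------------------------------------

adam_init <- function(params) {
  list(m = lapply(params, function(p) array(0, dim(p) %||% length(p))),
       v = lapply(params, function(p) array(0, dim(p) %||% length(p))),
       t = 0L)
}

adam_step <- function(params, grads, state, lr = 1e-4, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}
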