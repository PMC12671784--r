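# Gated recurrent unit. Gate equations:
#   R_t = sigma(W_r x_t + U_r h_{t-1} + b_r)
#   Z_t = sigma(W_z x_t + U_z h_{t-1} + b_z)
#   h_t = (1 - Z_t) (*) h_{t-1} + Z_t (*) tanh(W_h x_t + R_t (*) (U_h h_{t-1} + b_h))
# with (*) the Hadamard product: the update gate weights the candidate state
# and the bias enters inside the reset-gated term.

#' GRU parameter set
#'
#' Six weight matrices (`W_*` hidden x input, `U_*` hidden x hidden) and
#' three bias vectors, drawn uniformly in a Glorot range when not supplied.
#'
#' @param input_dim input vector dimension.
#' @param hidden_dim hidden state dimension (default 128).
#' @param init `"glorot"` (uses the current RNG) or `"zero"`.
#' @return a `gru_params` list with `W_r, W_z, W_h, U_r, U_z, U_h, b_r, b_z,
#'   b_h`.
#' @export
gru_params <- function(input_dim, hidden_dim = 128, init = "glorot") {
  mk <- function(r, c) {
    if (init == "zero") matrix(0, r, c) else glorot(c, r, dims = c(r, c))
  }
  structure(list(W_r = mk(hidden_dim, input_dim), W_z = mk(hidden_dim, input_dim),
                 W_h = mk(hidden_dim, input_dim),
                 U_r = mk(hidden_dim, hidden_dim), U_z = mk(hidden_dim, hidden_dim),
                 U_h = mk(hidden_dim, hidden_dim),
                 b_r = numeric(hidden_dim), b_z = numeric(hidden_dim),
                 b_h = numeric(hidden_dim)),
            class = "gru_params")
}

#' Run a GRU over one input sequence
#'
#' Applies the gate equations step by step; the output sequence has one
#' hidden vector per input vector.
#'
#' @param x_seq numeric matrix, time steps x input_dim (a vector is taken as
#'   one step).
#' @param h0 initial hidden state (defaults to zeros).
#' @param params a [gru_params()] set.
#' @return matrix time steps x hidden_dim of hidden states.
#' @export
gru_forward <- function(x_seq, h0 = NULL, params) {
  if (is.vector(x_seq)) x_seq <- matrix(x_seq, nrow = 1)
  hdim <- nrow(params$U_r)
  if (ncol(params$W_r) != ncol(x_seq)) {
    stop(sprintf("input dim %d does not match W_r (%d columns)",
                 ncol(x_seq), ncol(params$W_r)), call. = FALSE)
  }
  h <- if (is.null(h0)) numeric(hdim) else as.numeric(h0)
  out <- matrix(0, nrow(x_seq), hdim)
  for (t in seq_len(nrow(x_seq))) {
    xt <- x_seq[t, ]
    r <- sigmoid(as.numeric(params$W_r %*% xt + params$U_r %*% h) + params$b_r)
    z <- sigmoid(as.numeric(params$W_z %*% xt + params$U_z %*% h) + params$b_z)
    cand <- tanh(as.numeric(params$W_h %*% xt) +
                   r * (as.numeric(params$U_h %*% h) + params$b_h))
    h <- (1 - z) * h + z * cand
    out[t, ] <- h
  }
  out
}

## Batched layer used inside the network. Weights here are stored transposed
## (input x hidden) so a batch row-matrix multiplies from the left; the
## algebra is identical to gru_forward.

gru_layer_fwd <- function(x, p) {
  d <- dim(x); B <- d[1]; t_len <- d[2]
  hdim <- ncol(p$gru_Ur)
  h <- matrix(0, B, hdim)
  out <- array(0, c(B, t_len, hdim))
  steps <- vector("list", t_len)
  for (t in seq_len(t_len)) {
    xt <- x[, t, , drop = FALSE]; dim(xt) <- c(B, d[3])
    r <- sigmoid(sweep(xt %*% p$gru_Wr + h %*% p$gru_Ur, 2, p$gru_br, "+"))
    z <- sigmoid(sweep(xt %*% p$gru_Wz + h %*% p$gru_Uz, 2, p$gru_bz, "+"))
    inner <- sweep(h %*% p$gru_Uh, 2, p$gru_bh, "+")
    cand <- tanh(xt %*% p$gru_Wh + r * inner)
    h_new <- (1 - z) * h + z * cand
    steps[[t]] <- list(xt = xt, h_prev = h, r = r, z = z, inner = inner,
                       cand = cand)
    out[, t, ] <- h_new
    h <- h_new
  }
  list(out = out, cache = list(steps = steps, p = p, B = B, t_len = t_len,
                               in_dim = d[3], hdim = hdim))
}

gru_layer_bwd <- function(cache, dout) {
  p <- cache$p
  g <- list(gru_Wr = 0 * p$gru_Wr, gru_Wz = 0 * p$gru_Wz, gru_Wh = 0 * p$gru_Wh,
            gru_Ur = 0 * p$gru_Ur, gru_Uz = 0 * p$gru_Uz, gru_Uh = 0 * p$gru_Uh,
            gru_br = 0 * p$gru_br, gru_bz = 0 * p$gru_bz, gru_bh = 0 * p$gru_bh)
  dx <- array(0, c(cache$B, cache$t_len, cache$in_dim))
  carry <- matrix(0, cache$B, cache$hdim)
  for (t in rev(seq_len(cache$t_len))) {
    s <- cache$steps[[t]]
    dh <- dout[, t, , drop = FALSE]
    dim(dh) <- c(cache$B, cache$hdim)
    dh <- dh + carry
    dz <- dh * (s$cand - s$h_prev)
    da_z <- dz * s$z * (1 - s$z)
    dcand <- dh * s$z
    da_c <- dcand * (1 - s$cand^2)
    dr <- da_c * s$inner
    da_r <- dr * s$r * (1 - s$r)
    dinner <- da_c * s$r
    g$gru_Wr <- g$gru_Wr + crossprod(s$xt, da_r)
    g$gru_Wz <- g$gru_Wz + crossprod(s$xt, da_z)
    g$gru_Wh <- g$gru_Wh + crossprod(s$xt, da_c)
    g$gru_Ur <- g$gru_Ur + crossprod(s$h_prev, da_r)
    g$gru_Uz <- g$gru_Uz + crossprod(s$h_prev, da_z)
    g$gru_Uh <- g$gru_Uh + crossprod(s$h_prev, dinner)
    g$gru_br <- g$gru_br + colSums(da_r)
    g$gru_bz <- g$gru_bz + colSums(da_z)
    g$gru_bh <- g$gru_bh + colSums(dinner)
    dx[, t, ] <- da_r %*% t(p$gru_Wr) + da_z %*% t(p$gru_Wz) +
      da_c %*% t(p$gru_Wh)
    carry <- dh * (1 - s$z) + dinner %*% t(p$gru_Uh) +
      da_r %*% t(p$gru_Ur) + da_z %*% t(p$gru_Uz)
  }
  c(list(dx = dx), g)
}
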