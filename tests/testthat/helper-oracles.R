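# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: band power via smoothed periodograms, attention
# via a direct dense softmax, the GRU via a scalar per-step loop.

welch_band_power <- function(x, fs, lo, hi) {
  sp <- stats::spec.pgram(stats::ts(x, frequency = fs), spans = 31,
                          plot = FALSE, taper = 0.1)
  # mean spectral density over the band: comparable across segment lengths
  mean(sp$spec[sp$freq >= lo & sp$freq <= hi])
}

dense_attention_oracle <- function(Q, K, V, d_k) {
  s <- Q %*% t(K) / sqrt(d_k)
  w <- t(apply(s, 1, function(r) exp(r - max(r)) / sum(exp(r - max(r)))))
  w %*% V
}

# Scalar-loop GRU: every gate element computed one at a time from the gate
# equations, no matrix algebra.
gru_scalar_oracle <- function(x_seq, h0, p) {
  hdim <- length(h0)
  h <- h0
  out <- matrix(0, nrow(x_seq), hdim)
  for (t in seq_len(nrow(x_seq))) {
    r <- z <- cand <- numeric(hdim)
    for (i in seq_len(hdim)) {
      ar <- p$b_r[i]; az <- p$b_z[i]; inner <- p$b_h[i]; wx <- 0
      for (j in seq_len(ncol(x_seq))) {
        ar <- ar + p$W_r[i, j] * x_seq[t, j]
        az <- az + p$W_z[i, j] * x_seq[t, j]
        wx <- wx + p$W_h[i, j] * x_seq[t, j]
      }
      for (j in seq_len(hdim)) {
        ar <- ar + p$U_r[i, j] * h[j]
        az <- az + p$U_z[i, j] * h[j]
        inner <- inner + p$U_h[i, j] * h[j]
      }
      r[i] <- 1 / (1 + exp(-ar))
      z[i] <- 1 / (1 + exp(-az))
      cand[i] <- tanh(wx + r[i] * inner)
    }
    h <- (1 - z) * h + z * cand
    out[t, ] <- h
  }
  out
}

# A small network configuration for fast structural and gradient tests.
tiny_cfg <- function(dropout = 0) {
  cgtnet_config(input_dim = 16 * 4, n_bands = 4,
                branch_large = conv_branch_config(5),
                branch_small = conv_branch_config(3),
                conv_channels = 6, seq_len = 6, gru_hidden = 8,
                encoder_layers = 2, heads = 2, ff_dim = 10,
                dropout = dropout, local_width = 2, stride = 3, k_max = 4)
}

# Separable two-class toy features for the tiny configuration: class 1 gets
# an offset in the first bands of every frame.
toy_separable <- function(n = 32, seed = 4) {
  set.seed(seed)
  y <- rep(0:1, length.out = n)
  x <- matrix(rnorm(n * 64, sd = 0.5), n)
  x[y == 1, seq(1, 64, by = 4)] <- x[y == 1, seq(1, 64, by = 4)] + 2
  list(x = x, y = y)
}

sine_record <- function(freq, fs = 256, dur = 20, channels = 1, amp = 1) {
  t <- seq_len(fs * dur) / fs
  eeg_record(matrix(rep(amp * sin(2 * pi * freq * t), channels),
                    nrow = channels, byrow = TRUE), fs = fs)
}
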