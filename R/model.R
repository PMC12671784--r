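# The CGTNet architecture: two parallel 1-D convolution branches (kernels 62
# and 32, two layers each with batch-normalised rectified activations),
# linear time alignment and per-branch channel projections concatenating to a
# 128-dim sequence, a 128-unit GRU, sinusoidal positional encoding, a
# 2-layer 4-head sparse-masked Transformer encoder, token mean-pooling and a
# 2-logit classification head.
#
# The input is one 2176-dim vector per 64 s window, laid out as 64
# one-second frames x 34 frequency bands. With the default widths below
# (conv layer 1 -> 52 channels, conv layer 2 -> 32, per-branch projection to
# 64, encoder feed-forward width 268) the model has exactly 550,978
# trainable parameters.

#' Convolution branch configuration
#' @param kernel kernel size k in frames.
#' @param stride stride s.
#' @param n_layers number of convolution layers n.
#' @param out_channels channels of the final layer.
#' @param padding padding of the second layer (first layer is unpadded).
#' @return a `conv_branch_config` list.
#' @export
conv_branch_config <- function(kernel, stride = 1, n_layers = 2,
                               out_channels = 32, padding = 1) {
  stopifnot(kernel >= 1, stride >= 1, n_layers >= 1)
  structure(list(kernel = kernel, stride = stride, n_layers = n_layers,
                 out_channels = out_channels, padding = padding),
            class = "conv_branch_config")
}

#' Receptive field of a stack of convolution layers
#'
#' `F = ((n - 1) * s) + k` for n layers of kernel k and stride s.
#'
#' @param n number of layers (>= 1).
#' @param s stride (>= 1).
#' @param k kernel size (>= 1).
#' @return receptive field in samples.
#' @export
receptive_field <- function(n, s, k) {
  if (any(c(n, s, k) < 1)) stop("n, s, k must all be >= 1", call. = FALSE)
  (n - 1) * s + k
}

#' CGTNet model configuration
#'
#' Defaults are the published operating point: input dimension 2176 (64
#' frames x 34 bands), parallel branches with kernels 62 and 32, GRU hidden
#' size 128, a 2-layer encoder with 4 heads of width 32, and a 2-class head.
#' The free internal widths (`conv_channels` 52, `branch_channels` 32,
#' `ff_dim` 268) are fixed by the constraint that the total trainable
#' parameter count equals 550,978.
#'
#' @param input_dim flattened input length (frames x bands).
#' @param n_bands frequency bands per frame.
#' @param branch_large,branch_small [conv_branch_config()]s for the two
#'   branches.
#' @param conv_channels output channels of each branch's first layer.
#' @param seq_len token count the branches are aligned to before the GRU.
#' @param gru_hidden GRU hidden size (also the encoder model dimension).
#' @param encoder_layers,heads encoder depth and head count.
#' @param ff_dim encoder feed-forward width.
#' @param dropout dropout rate used during training.
#' @param n_classes output classes.
#' @param mask_pattern,local_width,stride,k_max sparse-mask parameters, see
#'   [build_sparse_mask()].
#' @param mask_semantics `"additive"` (masked positions excluded from the
#'   softmax) or `"literal"` (scores multiplied by the mask).
#' @param positional `"sinusoidal"` (fixed) or `"none"`.
#' @return a `cgtnet_config` list.
#' @export
cgtnet_config <- function(input_dim = 2176, n_bands = 34,
                          branch_large = conv_branch_config(62),
                          branch_small = conv_branch_config(32),
                          conv_channels = 52, seq_len = 16,
                          gru_hidden = 128, encoder_layers = 2, heads = 4,
                          ff_dim = 268, dropout = 0.3, n_classes = 2,
                          mask_pattern = "local+strided", local_width = 8,
                          stride = 8, k_max = 32,
                          mask_semantics = c("additive", "literal"),
                          positional = c("sinusoidal", "none")) {
  stopifnot(input_dim %% n_bands == 0, gru_hidden %% heads == 0,
            encoder_layers >= 1)
  structure(list(input_dim = input_dim, n_bands = n_bands,
                 n_frames = input_dim %/% n_bands,
                 branch_large = branch_large, branch_small = branch_small,
                 conv_channels = conv_channels, seq_len = seq_len,
                 gru_hidden = gru_hidden, encoder_layers = encoder_layers,
                 heads = heads, head_dim = gru_hidden %/% heads,
                 ff_dim = ff_dim, dropout = dropout, n_classes = n_classes,
                 mask_pattern = mask_pattern, local_width = local_width,
                 stride = stride, k_max = k_max,
                 mask_semantics = match.arg(mask_semantics),
                 positional = match.arg(positional)),
            class = "cgtnet_config")
}

#' Instantiate a CGTNet model
#'
#' @param cfg a [cgtnet_config()].
#' @param seed RNG seed for weight initialisation (default 8).
#' @return a `cgtnet_model` holding the parameter list, batch-norm buffers,
#'   per-head sparse masks and the positional encoding.
#' @export
cgtnet_init <- function(cfg = cgtnet_config(), seed = 8) {
  old_seed <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))
  set.seed(seed)
  nb <- cfg$n_bands; c1 <- cfg$conv_channels
  dm <- cfg$gru_hidden
  p <- list()
  bufs <- list()
  for (br in c("L", "S")) {
    bc <- if (br == "L") cfg$branch_large else cfg$branch_small
    c2 <- bc$out_channels
    p[[paste0("conv1_W_", br)]] <- glorot(bc$kernel * nb, c1,
                                          dims = c(bc$kernel * nb, c1))
    p[[paste0("conv1_b_", br)]] <- numeric(c1)
    p[[paste0("bn1_g_", br)]] <- rep(1, c1)
    p[[paste0("bn1_b_", br)]] <- numeric(c1)
    p[[paste0("conv2_W_", br)]] <- glorot(3 * c1, c2, dims = c(3 * c1, c2))
    p[[paste0("conv2_b_", br)]] <- numeric(c2)
    p[[paste0("bn2_g_", br)]] <- rep(1, c2)
    p[[paste0("bn2_b_", br)]] <- numeric(c2)
    p[[paste0("proj_W_", br)]] <- glorot(c2, dm %/% 2)
    p[[paste0("proj_b_", br)]] <- numeric(dm %/% 2)
    bufs[[paste0("bn1_mean_", br)]] <- numeric(c1)
    bufs[[paste0("bn1_var_", br)]] <- rep(1, c1)
    bufs[[paste0("bn2_mean_", br)]] <- numeric(c2)
    bufs[[paste0("bn2_var_", br)]] <- rep(1, c2)
  }
  p$gru_Wr <- glorot(dm, dm); p$gru_Wz <- glorot(dm, dm); p$gru_Wh <- glorot(dm, dm)
  p$gru_Ur <- glorot(dm, dm); p$gru_Uz <- glorot(dm, dm); p$gru_Uh <- glorot(dm, dm)
  p$gru_br <- numeric(dm); p$gru_bz <- numeric(dm); p$gru_bh <- numeric(dm)
  for (l in seq_len(cfg$encoder_layers)) {
    pre <- sprintf("enc%d_", l)
    for (nm in c("Wq", "Wk", "Wv", "Wo")) p[[paste0(pre, nm)]] <- glorot(dm, dm)
    for (nm in c("bq", "bk", "bv", "bo")) p[[paste0(pre, nm)]] <- numeric(dm)
    p[[paste0(pre, "ln1_g")]] <- rep(1, dm); p[[paste0(pre, "ln1_b")]] <- numeric(dm)
    p[[paste0(pre, "ff_W1")]] <- glorot(dm, cfg$ff_dim)
    p[[paste0(pre, "ff_b1")]] <- numeric(cfg$ff_dim)
    p[[paste0(pre, "ff_W2")]] <- glorot(cfg$ff_dim, dm)
    p[[paste0(pre, "ff_b2")]] <- numeric(dm)
    p[[paste0(pre, "ln2_g")]] <- rep(1, dm); p[[paste0(pre, "ln2_b")]] <- numeric(dm)
  }
  p$head_W <- glorot(dm, cfg$n_classes)
  p$head_b <- numeric(cfg$n_classes)

  masks <- rep(list(build_sparse_mask(cfg$seq_len, cfg$mask_pattern,
                                      cfg$local_width, cfg$stride, cfg$k_max)),
               cfg$heads)
  pe <- if (cfg$positional == "sinusoidal") {
    positional_encoding(cfg$seq_len, dm)
  } else {
    matrix(0, cfg$seq_len, dm)
  }
  structure(list(config = cfg, params = p, buffers = bufs, masks = masks,
                 posenc = pe, scaler = NULL),
            class = "cgtnet_model")
}

#' Count trainable parameters
#'
#' @param model a `cgtnet_model`, or any named list of numeric arrays.
#' @return total number of trainable scalar parameters.
#' @export
count_parameters <- function(model) {
  p <- if (inherits(model, "cgtnet_model")) model$params else model
  sum(vapply(p, length, 0L))
}

## ---- forward / backward ----------------------------------------------------

# Reshape a batch of flat frame-major feature vectors to (B, frames, bands).
input_to_tensor <- function(x, cfg) {
  B <- nrow(x)
  a <- array(0, c(B, cfg$n_frames, cfg$n_bands))
  for (cc in seq_len(cfg$n_bands)) {
    a[, , cc] <- x[, seq(cc, by = cfg$n_bands, length.out = cfg$n_frames),
                   drop = FALSE]
  }
  a
}

branch_fwd <- function(a, p, bufs, br, bc, cfg, train) {
  cache <- list(br = br)
  f1 <- conv1d_fwd(a, p[[paste0("conv1_W_", br)]], p[[paste0("conv1_b_", br)]],
                   bc$kernel, pad = 0)
  B <- dim(f1$out)[1]; t1 <- dim(f1$out)[2]
  b1 <- bn_fwd(mat3(f1$out), p[[paste0("bn1_g_", br)]], p[[paste0("bn1_b_", br)]],
               bufs[[paste0("bn1_mean_", br)]], bufs[[paste0("bn1_var_", br)]],
               train)
  r1 <- relu_fwd(b1$out)
  f2 <- conv1d_fwd(unmat3(r1$out, B, t1), p[[paste0("conv2_W_", br)]],
                   p[[paste0("conv2_b_", br)]], 3, pad = bc$padding)
  t2 <- dim(f2$out)[2]
  b2 <- bn_fwd(mat3(f2$out), p[[paste0("bn2_g_", br)]], p[[paste0("bn2_b_", br)]],
               bufs[[paste0("bn2_mean_", br)]], bufs[[paste0("bn2_var_", br)]],
               train)
  r2 <- relu_fwd(b2$out)
  al <- time_align_fwd(unmat3(r2$out, B, t2), cfg$seq_len)
  pr <- linear_fwd(mat3(al$out), p[[paste0("proj_W_", br)]],
                   p[[paste0("proj_b_", br)]])
  cache[c("f1", "b1", "r1", "f2", "b2", "r2", "al", "pr")] <-
    list(f1$cache, b1$cache, r1$cache, f2$cache, b2$cache, r2$cache,
         al$cache, pr$cache)
  cache$dims <- c(B = B, t1 = t1, t2 = t2)
  bufs[[paste0("bn1_mean_", br)]] <- b1$run_mean
  bufs[[paste0("bn1_var_", br)]] <- b1$run_var
  bufs[[paste0("bn2_mean_", br)]] <- b2$run_mean
  bufs[[paste0("bn2_var_", br)]] <- b2$run_var
  list(out = unmat3(pr$out, B, cfg$seq_len), cache = cache, bufs = bufs)
}

branch_bwd <- function(cache, dout, p) {
  br <- cache$br
  B <- cache$dims["B"]; t1 <- cache$dims["t1"]; t2 <- cache$dims["t2"]
  g <- list()
  lb <- linear_bwd(cache$pr, mat3(dout))
  g[[paste0("proj_W_", br)]] <- lb$dw
  g[[paste0("proj_b_", br)]] <- lb$db
  dal <- time_align_bwd_fix(cache$al, lb$dx, B)
  dr2 <- relu_bwd(cache$r2, mat3(dal))
  bb2 <- bn_bwd(cache$b2, dr2)
  g[[paste0("bn2_g_", br)]] <- bb2$dgamma
  g[[paste0("bn2_b_", br)]] <- bb2$dbeta
  cb2 <- conv1d_bwd(cache$f2, unmat3(bb2$dx, B, t2))
  g[[paste0("conv2_W_", br)]] <- cb2$dw
  g[[paste0("conv2_b_", br)]] <- cb2$db
  dr1 <- relu_bwd(cache$r1, mat3(cb2$dx))
  bb1 <- bn_bwd(cache$b1, dr1)
  g[[paste0("bn1_g_", br)]] <- bb1$dgamma
  g[[paste0("bn1_b_", br)]] <- bb1$dbeta
  cb1 <- conv1d_bwd(cache$f1, unmat3(bb1$dx, B, t1))
  g[[paste0("conv1_W_", br)]] <- cb1$dw
  g[[paste0("conv1_b_", br)]] <- cb1$db
  list(dx = cb1$dx, grads = g)
}

# helper: undo mat3 for the alignment backward (seq_len tokens)
time_align_bwd_fix <- function(al_cache, dx2, B) {
  t_out <- length(al_cache$wts$i1)
  time_align_bwd(al_cache, unmat3(dx2, B, t_out))
}

#' Forward pass of the network
#'
#' @param model a `cgtnet_model`.
#' @param x batch of flattened window features, B x input_dim.
#' @param train logical; training mode enables dropout and batch statistics.
#' @param collect_attention logical; also return per-layer, per-head
#'   attention weight matrices for the batch.
#' @return list with `logits` (B x n_classes), `probs` (softmax rows), the
#'   layer `caches` (training mode), updated `buffers`, and optionally
#'   `attention`.
#' @export
cgtnet_forward <- function(model, x, train = FALSE, collect_attention = FALSE) {
  cfg <- model$config
  p <- model$params
  bufs <- model$buffers
  if (ncol(x) != cfg$input_dim) {
    stop(sprintf("input dim %d does not match model input_dim %d",
                 ncol(x), cfg$input_dim), call. = FALSE)
  }
  B <- nrow(x)
  a <- input_to_tensor(x, cfg)
  caches <- list()
  bl <- branch_fwd(a, p, bufs, "L", cfg$branch_large, cfg, train)
  bufs <- bl$bufs
  bs <- branch_fwd(a, p, bufs, "S", cfg$branch_small, cfg, train)
  bufs <- bs$bufs
  fused <- array(0, c(B, cfg$seq_len, cfg$gru_hidden))
  half <- cfg$gru_hidden %/% 2
  fused[, , seq_len(half)] <- bl$out
  fused[, , half + seq_len(half)] <- bs$out
  caches$branchL <- bl$cache; caches$branchS <- bs$cache

  gr <- gru_layer_fwd(fused, p)
  caches$gru <- gr$cache
  h <- gr$out
  for (t in seq_len(cfg$seq_len)) h[, t, ] <- sweep(
    matrix(h[, t, ], B, cfg$gru_hidden), 2, model$posenc[t, ], "+")

  attn <- list()
  xin <- h
  for (l in seq_len(cfg$encoder_layers)) {
    pre <- sprintf("enc%d_", l)
    at <- mha_fwd(xin, p[[paste0(pre, "Wq")]], p[[paste0(pre, "bq")]],
                  p[[paste0(pre, "Wk")]], p[[paste0(pre, "bk")]],
                  p[[paste0(pre, "Wv")]], p[[paste0(pre, "bv")]],
                  p[[paste0(pre, "Wo")]], p[[paste0(pre, "bo")]],
                  model$masks, cfg$heads, cfg$mask_semantics,
                  collect = collect_attention)
    if (collect_attention) attn[[l]] <- at$weights
    d1 <- dropout_fwd(at$out, cfg$dropout, train)
    ln1 <- ln_fwd(mat3(xin + d1$out), p[[paste0(pre, "ln1_g")]],
                  p[[paste0(pre, "ln1_b")]])
    x1 <- unmat3(ln1$out, B, cfg$seq_len)
    ff1 <- linear_fwd(ln1$out, p[[paste0(pre, "ff_W1")]], p[[paste0(pre, "ff_b1")]])
    fr <- relu_fwd(ff1$out)
    ff2 <- linear_fwd(fr$out, p[[paste0(pre, "ff_W2")]], p[[paste0(pre, "ff_b2")]])
    d2 <- dropout_fwd(ff2$out, cfg$dropout, train)
    ln2 <- ln_fwd(ln1$out + d2$out, p[[paste0(pre, "ln2_g")]],
                  p[[paste0(pre, "ln2_b")]])
    caches[[paste0("enc", l)]] <- list(at = at$cache, d1 = d1$cache,
                                       ln1 = ln1$cache, ff1 = ff1$cache,
                                       fr = fr$cache, ff2 = ff2$cache,
                                       d2 = d2$cache, ln2 = ln2$cache)
    xin <- unmat3(ln2$out, B, cfg$seq_len)
  }

  pooled <- apply(xin, c(1, 3), mean)
  if (B == 1) pooled <- matrix(pooled, 1)
  dp <- dropout_fwd(pooled, cfg$dropout, train)
  hd <- linear_fwd(dp$out, p$head_W, p$head_b)
  caches$pool_dims <- dim(xin)
  caches$dp <- dp$cache
  caches$head <- hd$cache
  logits <- hd$out
  z <- logits - apply(logits, 1, max)
  ez <- exp(z)
  probs <- ez / rowSums(ez)
  out <- list(logits = logits, probs = probs, caches = caches, buffers = bufs)
  if (collect_attention) out$attention <- attn
  out
}

cgtnet_backward <- function(model, caches, dlogits) {
  cfg <- model$config
  p <- model$params
  g <- list()
  hb <- linear_bwd(caches$head, dlogits)
  g$head_W <- hb$dw; g$head_b <- hb$db
  dpooled <- dropout_bwd(caches$dp, hb$dx)
  d <- caches$pool_dims
  dxin <- array(0, d)
  for (t in seq_len(d[2])) dxin[, t, ] <- dpooled / d[2]

  for (l in rev(seq_len(cfg$encoder_layers))) {
    pre <- sprintf("enc%d_", l)
    cc <- caches[[paste0("enc", l)]]
    lb2 <- ln_bwd(cc$ln2, mat3(dxin))
    g[[paste0(pre, "ln2_g")]] <- lb2$dgamma; g[[paste0(pre, "ln2_b")]] <- lb2$dbeta
    dd2 <- dropout_bwd(cc$d2, lb2$dx)
    fb2 <- linear_bwd(cc$ff2, dd2)
    g[[paste0(pre, "ff_W2")]] <- fb2$dw; g[[paste0(pre, "ff_b2")]] <- fb2$db
    dfr <- relu_bwd(cc$fr, fb2$dx)
    fb1 <- linear_bwd(cc$ff1, dfr)
    g[[paste0(pre, "ff_W1")]] <- fb1$dw; g[[paste0(pre, "ff_b1")]] <- fb1$db
    dln1out <- lb2$dx + fb1$dx
    lb1 <- ln_bwd(cc$ln1, dln1out)
    g[[paste0(pre, "ln1_g")]] <- lb1$dgamma; g[[paste0(pre, "ln1_b")]] <- lb1$dbeta
    dres <- unmat3(lb1$dx, d[1], d[2])
    dd1 <- dropout_bwd(cc$d1, dres)
    ab <- mha_bwd(cc$at, dd1)
    g[[paste0(pre, "Wq")]] <- ab$dwq; g[[paste0(pre, "bq")]] <- ab$dbq
    g[[paste0(pre, "Wk")]] <- ab$dwk; g[[paste0(pre, "bk")]] <- ab$dbk
    g[[paste0(pre, "Wv")]] <- ab$dwv; g[[paste0(pre, "bv")]] <- ab$dbv
    g[[paste0(pre, "Wo")]] <- ab$dwo; g[[paste0(pre, "bo")]] <- ab$dbo
    dxin <- dres + ab$dx
  }

  gb <- gru_layer_bwd(caches$gru, dxin)   # posenc is additive: gradient passes
  for (nm in grep("^gru_", names(gb), value = TRUE)) g[[nm]] <- gb[[nm]]
  dfused <- gb$dx
  half <- cfg$gru_hidden %/% 2
  bl <- branch_bwd(caches$branchL, dfused[, , seq_len(half), drop = FALSE], p)
  bs <- branch_bwd(caches$branchS, dfused[, , half + seq_len(half), drop = FALSE], p)
  g <- c(g, bl$grads, bs$grads)
  g
}

#' Fused multi-scale convolution features
#'
#' Runs the two parallel convolution branches on a batch and concatenates
#' their outputs along the feature axis (the sequence fed to the GRU).
#'
#' @param x batch of flattened window features, B x input_dim.
#' @param model a `cgtnet_model`.
#' @return array B x seq_len x gru_hidden; columns `1..gru_hidden/2` are the
#'   large-kernel branch, the rest the small-kernel branch.
#' @export
multiscale_forward <- function(x, model) {
  cfg <- model$config
  a <- input_to_tensor(x, cfg)
  bl <- branch_fwd(a, model$params, model$buffers, "L", cfg$branch_large, cfg, FALSE)
  bs <- branch_fwd(a, model$params, model$buffers, "S", cfg$branch_small, cfg, FALSE)
  half <- cfg$gru_hidden %/% 2
  fused <- array(0, c(nrow(x), cfg$seq_len, cfg$gru_hidden))
  fused[, , seq_len(half)] <- bl$out
  fused[, , half + seq_len(half)] <- bs$out
  fused
}

#' Attention weights and frequency-band aggregate for one window
#'
#' Returns each encoder layer's per-head row-stochastic attention matrices
#' (zero exactly where the head's sparse pattern is zero) and an aggregate
#' that maps the attention mass received by each token back to the input
#' frequency bands: tokens correspond to groups of input frames, and the
#' aggregate is the attention-mass-weighted mean feature energy per band.
#'
#' @param model a `cgtnet_model`.
#' @param x one flattened window feature vector (length input_dim).
#' @return list with `layers` (list over layers of lists over heads of
#'   seq_len x seq_len matrices), `token_mass` (mean attention received per
#'   token) and `band_aggregate` (named by band centre frequency in Hz,
#'   assuming a 0-128 Hz axis).
#' @export
attention_weights <- function(model, x) {
  cfg <- model$config
  x <- matrix(as.numeric(x), nrow = 1)
  if (!is.null(model$scaler)) x <- scale_features(x, model$scaler)
  fw <- cgtnet_forward(model, x, train = FALSE, collect_attention = TRUE)
  layers <- lapply(fw$attention, function(batch) batch[[1]])
  mass <- rowMeans(vapply(unlist(layers, recursive = FALSE), colMeans,
                          numeric(cfg$seq_len)))
  mass <- mass / sum(mass)
  feat <- unflatten_features(as.numeric(x), cfg$n_bands)   # frames x bands
  grp <- ceiling(seq_len(cfg$n_frames) / (cfg$n_frames / cfg$seq_len))
  tok_feat <- rowsum(feat, grp) / as.numeric(table(grp))   # tokens x bands
  agg <- as.numeric(mass %*% tok_feat)
  names(agg) <- sprintf("%.1fHz", (seq_len(cfg$n_bands) - 0.5) * 128 / cfg$n_bands)
  list(layers = layers, token_mass = mass, band_aggregate = agg)
}
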