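test_that("receptive field follows F = (n-1)s + k", {
  expect_equal(receptive_field(1, 1, 62), 62)
  expect_equal(receptive_field(2, 1, 32), 33)
  expect_equal(receptive_field(3, 2, 5), 9)
  expect_error(receptive_field(0, 1, 3), ">= 1")
})

test_that("sparse masks realise their patterns within the row budget", {
  expect_true(all(build_sparse_mask(5, "full")$M == 1))
  m <- build_sparse_mask(4, "local", local_width = 1, k_max = 32)
  expect_equal(rowSums(m$M), c(2, 3, 3, 2))
  ms <- build_sparse_mask(9, "strided", stride = 3, k_max = 32)
  expect_true(all(ms$M[1, c(1, 4, 7)] == 1))
  expect_equal(sum(ms$M[1, ]), 3)
  # budget and diagonal invariants across patterns and sizes
  for (pat in c("local", "strided", "local+strided", "full")) {
    mk <- build_sparse_mask(20, pat, local_width = 4, stride = 5, k_max = 6)
    expect_true(all(diag(mk$M) == 1))
    expect_true(all(rowSums(mk$M) >= 1 & rowSums(mk$M) <= 6))
  }
  expect_error(build_sparse_mask(4, k_max = 0), "k_max")
})

test_that("sparse attention with a full mask equals the dense oracle", {
  set.seed(11)
  full <- build_sparse_mask(10, "full")
  for (i in 1:10) {
    Q <- matrix(rnorm(40), 10); K <- matrix(rnorm(40), 10)
    V <- matrix(rnorm(40), 10)
    got <- sparse_attention(Q, K, V, d_k = 4, mask = full)
    expect_equal(got$out, dense_attention_oracle(Q, K, V, 4), tolerance = 1e-6)
    expect_equal(rowSums(got$weights), rep(1, 10), tolerance = 1e-9)
  }
})

test_that("identity-mask attention returns V rows exactly", {
  set.seed(12)
  Q <- matrix(rnorm(24), 6); K <- matrix(rnorm(24), 6); V <- matrix(rnorm(24), 6)
  got <- sparse_attention(Q, K, V, d_k = 4, mask = diag(6))
  expect_identical(got$out, V)
})

test_that("two-point attention matches the hand-computed softmax", {
  Q <- matrix(c(1, 0), 2); K <- Q; V <- matrix(c(3, 7), 2)
  got <- sparse_attention(Q, K, V, d_k = 1, mask = matrix(1, 2, 2))
  w11 <- exp(1) / (exp(1) + 1)
  expect_equal(got$weights[1, ], c(w11, 1 - w11), tolerance = 1e-12)
  expect_equal(got$out[1, 1], w11 * 3 + (1 - w11) * 7, tolerance = 1e-12)
  expect_equal(got$weights[2, ], c(0.5, 0.5), tolerance = 1e-12)
})

test_that("literal mask semantics keeps exp(0) mass at masked positions", {
  set.seed(13)
  Q <- matrix(rnorm(12), 4); K <- matrix(rnorm(12), 4); V <- matrix(rnorm(12), 4)
  m <- build_sparse_mask(4, "local", local_width = 1, k_max = 4)
  lit <- sparse_attention(Q, K, V, d_k = 3, mask = m, semantics = "literal")
  add <- sparse_attention(Q, K, V, d_k = 3, mask = m, semantics = "additive")
  expect_true(all(lit$weights > 0))            # masked keys still weighted
  expect_true(any(add$weights == 0))
  expect_equal(rowSums(lit$weights), rep(1, 4), tolerance = 1e-9)
})

test_that("score evaluations equal the mask's nonzero count", {
  set.seed(14)
  n <- 12
  m <- build_sparse_mask(n, "local+strided", local_width = 2, stride = 4,
                         k_max = 5)
  Q <- matrix(rnorm(n * 4), n); K <- matrix(rnorm(n * 4), n)
  counter <- new.env()
  sparse_attention(Q, K, Q, d_k = 4, mask = m, counter = counter)
  expect_equal(counter$n, sum(m$M))
  expect_lte(counter$n, n * m$k_max)
  expect_lt(counter$n, n^2)
})

test_that("multi-head attention reduces to dense single-head and is
           permutation-invariant in head order", {
  set.seed(15)
  X <- matrix(rnorm(8 * 12), 8)
  cfg1 <- multihead_config(model_dim = 12, n_heads = 1)
  full <- build_sparse_mask(8, "full")
  got <- multihead_sparse_attention(X, cfg1, full)
  dense <- dense_attention_oracle(X %*% cfg1$params$Wq[[1]],
                                  X %*% cfg1$params$Wk[[1]],
                                  X %*% cfg1$params$Wv[[1]], 12)
  expect_equal(got$out, dense %*% cfg1$params$Wo, tolerance = 1e-6)

  # block-identity output projection exposes the raw concatenation
  cfg2 <- multihead_config(model_dim = 12, n_heads = 3)
  cfg2$params$Wo <- diag(12)
  got2 <- multihead_sparse_attention(X, cfg2, full)
  h2 <- sparse_attention(X %*% cfg2$params$Wq[[2]], X %*% cfg2$params$Wk[[2]],
                         X %*% cfg2$params$Wv[[2]], 4, full)$out
  expect_equal(got2$out[, 5:8], h2, tolerance = 1e-9)

  # permuting heads together with W^O's row blocks leaves the output fixed
  perm <- c(3, 1, 2)
  cfg3 <- cfg2
  cfg3$params$Wq <- cfg2$params$Wq[perm]
  cfg3$params$Wk <- cfg2$params$Wk[perm]
  cfg3$params$Wv <- cfg2$params$Wv[perm]
  rows <- as.vector(outer(1:4, (perm - 1) * 4, "+"))
  cfg3$params$Wo <- cfg2$params$Wo[rows, ]
  cfg2$params$Wo <- matrix(rnorm(144), 12)
  cfg3$params$Wo <- cfg2$params$Wo[rows, ]
  expect_equal(multihead_sparse_attention(X, cfg3, full)$out,
               multihead_sparse_attention(X, cfg2, full)$out,
               tolerance = 1e-9)
})

test_that("GRU forward matches the scalar-loop oracle and its edge cases", {
  set.seed(16)
  p <- gru_params(5, 7)
  x <- matrix(rnorm(5 * 5), 5)
  h0 <- rnorm(7)
  expect_equal(gru_forward(x, h0, p), gru_scalar_oracle(x, h0, p),
               tolerance = 1e-6)
  # all-zero parameters: hidden state stays exactly zero
  p0 <- gru_params(5, 7, init = "zero")
  expect_true(all(gru_forward(x, params = p0) == 0))
  # update gate forced shut: state barely moves
  pz <- p
  pz$b_z <- rep(-20, 7)
  out <- gru_forward(x, h0, pz)
  expect_true(all(abs(sweep(out, 2, h0)) < 1e-6))
  expect_error(gru_forward(matrix(rnorm(8), 2), h0, p), "input dim")
})

test_that("the batched GRU layer equals repeated single-sequence runs", {
  set.seed(17)
  m <- cgtnet_init(tiny_cfg(), seed = 2)
  x <- array(rnorm(3 * 6 * 8), c(3, 6, 8))
  out <- cgtnet:::gru_layer_fwd(x, m$params)$out
  spec_p <- list(W_r = t(m$params$gru_Wr), W_z = t(m$params$gru_Wz),
                 W_h = t(m$params$gru_Wh), U_r = t(m$params$gru_Ur),
                 U_z = t(m$params$gru_Uz), U_h = t(m$params$gru_Uh),
                 b_r = m$params$gru_br, b_z = m$params$gru_bz,
                 b_h = m$params$gru_bh)
  for (b in 1:3) {
    single <- gru_forward(matrix(x[b, , ], 6, 8), params = spec_p)
    expect_equal(matrix(out[b, , ], 6, 8), single, tolerance = 1e-9)
  }
})

test_that("multi-scale fusion is the concatenation of branch outputs", {
  set.seed(18)
  m <- cgtnet_init(tiny_cfg(), seed = 2)
  x <- matrix(rnorm(4 * 64), 4)
  fused <- multiscale_forward(x, m)
  expect_equal(dim(fused), c(4, 6, 8))
  a <- cgtnet:::input_to_tensor(x, m$config)
  bl <- cgtnet:::branch_fwd(a, m$params, m$buffers, "L", m$config$branch_large,
                            m$config, FALSE)
  bs <- cgtnet:::branch_fwd(a, m$params, m$buffers, "S", m$config$branch_small,
                            m$config, FALSE)
  expect_equal(fused[, , 1:4], bl$out, tolerance = 1e-12)
  expect_equal(fused[, , 5:8], bs$out, tolerance = 1e-12)
  # identical inputs give identical fused outputs
  f2 <- multiscale_forward(x[c(1, 1), ], m)
  expect_equal(f2[1, , ], f2[2, , ])
})

test_that("unpadded convolution output length is L - k + 1", {
  set.seed(19)
  for (k in c(2, 5)) {
    x <- array(rnorm(2 * 10 * 3), c(2, 10, 3))
    w <- matrix(rnorm(k * 3 * 4), k * 3, 4)
    out <- cgtnet:::conv1d_fwd(x, w, numeric(4), k, pad = 0)$out
    expect_equal(dim(out)[2], 10 - k + 1)
  }
  expect_error(cgtnet:::conv1d_fwd(array(0, c(1, 3, 2)), matrix(0, 10, 1),
                                   0, k = 5, pad = 0), "shorter")
})

test_that("network forward is pure, normalised and shape-checked", {
  m <- cgtnet_init(tiny_cfg(), seed = 5)
  set.seed(20)
  x <- matrix(rnorm(3 * 64), 3)
  fw <- cgtnet_forward(m, x)
  expect_equal(dim(fw$logits), c(3, 2))
  expect_equal(rowSums(fw$probs), rep(1, 3), tolerance = 1e-6)
  fw2 <- cgtnet_forward(m, x[c(2, 2), ])
  expect_equal(fw2$logits[1, ], fw2$logits[2, ])
  expect_error(cgtnet_forward(m, matrix(0, 2, 63)), "input dim")
})

test_that("parameter counting matches shape arithmetic and the budget", {
  expect_equal(count_parameters(list(W = matrix(0, 3, 2), b = numeric(2))), 8)
  expect_equal(count_parameters(gru_params(128, 128)),
               3 * (128 * 128 + 128 * 128 + 128))
  expect_equal(count_parameters(cgtnet_init()), 550978)
})

test_that("analytic gradients match numerical differentiation", {
  m <- cgtnet_init(tiny_cfg(), seed = 3)
  set.seed(21)
  x <- matrix(rnorm(4 * 64), 4)
  y <- c(1, 0, 1, 0)
  lossfn <- function(model) {
    fw <- cgtnet_forward(model, x, train = TRUE)
    cgtnet:::bce_logit_loss(fw$logits, y, pos_weight = 1.5)$loss
  }
  fw <- cgtnet_forward(m, x, train = TRUE)
  ls <- cgtnet:::bce_logit_loss(fw$logits, y, pos_weight = 1.5)
  g <- cgtnet:::cgtnet_backward(m, fw$caches, ls$dlogits)
  eps <- 1e-6
  for (nm in c("conv1_W_L", "bn2_g_S", "proj_W_L", "gru_Uh", "gru_bz",
               "enc1_Wq", "enc2_ff_W1", "enc1_ln2_g", "head_W")) {
    idx <- sample(length(m$params[[nm]]), 3)
    for (i in idx) {
      mp <- m; mp$params[[nm]][i] <- mp$params[[nm]][i] + eps
      mm <- m; mm$params[[nm]][i] <- mm$params[[nm]][i] - eps
      num <- (lossfn(mp) - lossfn(mm)) / (2 * eps)
      expect_equal(g[[nm]][i], num, tolerance = 1e-4,
                   label = sprintf("grad %s[%d]", nm, i))
    }
  }
})

test_that("one epoch of optimisation strictly decreases the toy loss", {
  toy <- toy_separable(16)
  m <- cgtnet_init(tiny_cfg(), seed = 6)
  eval_loss <- function(model) {
    xs <- if (is.null(model$scaler)) toy$x else
      cgtnet:::scale_features(toy$x, model$scaler)
    fw <- cgtnet_forward(model, xs, train = FALSE)
    cgtnet:::bce_logit_loss(fw$logits, toy$y)$loss
  }
  fit <- cgtnet_train(m, toy$x, toy$y,
                      train_config(epochs = 1, batch_size = 16, seed = 8,
                                   dropout = 0, class_weight = FALSE))
  m0 <- fit$model
  m0$params <- m$params          # same scaler, initial weights
  expect_lt(eval_loss(fit$model), eval_loss(m0))
})

test_that("attention weights are row-stochastic and respect the mask", {
  m <- cgtnet_init(tiny_cfg(), seed = 7)
  set.seed(22)
  aw <- attention_weights(m, rnorm(64))
  expect_length(aw$layers, 2)
  mask <- m$masks[[1]]$M
  for (l in 1:2) for (h in 1:2) {
    P <- aw$layers[[l]][[h]]
    expect_equal(rowSums(P), rep(1, 6), tolerance = 1e-6)
    expect_true(all(P[mask == 0] == 0))
  }
  expect_equal(sum(aw$token_mass), 1, tolerance = 1e-9)
  expect_length(aw$band_aggregate, 4)
})
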