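# Sparse-masked scaled-dot-product attention.
#
# The binary admissibility matrix M restricts which key positions each query
# may attend to, reducing the number of score evaluations from n^2 to the
# mask's nonzero count. Masked positions are excluded from the row softmax
# (additive -Inf semantics); the literal reading of "scores * M inside the
# softmax" (masked scores set to 0 but still exponentiated) is available as
# `semantics = "literal"` for comparison.

#' Build a sparse attention mask
#'
#' Admissible positions are the diagonal, a local band `|i - j| <= local_width`
#' (pattern `"local"`), positions on a stride `j == i (mod stride)` (pattern
#' `"strided"`), their union (`"local+strided"`, the default), or everything
#' (`"full"`). Each row is then clipped to at most `k_max` nonzeros, keeping
#' the nearest keys first (ties broken toward smaller j), so every row keeps
#' its diagonal and holds between 1 and `k_max` ones.
#'
#' @param n sequence length (>= 1).
#' @param pattern one of `"local+strided"`, `"local"`, `"strided"`, `"full"`.
#' @param local_width half-width w of the local band.
#' @param stride stride g of the strided pattern.
#' @param k_max per-row budget of admissible positions (>= 1).
#' @return a `sparse_mask` with the binary `n x n` matrix `M`, `k_max` and
#'   `pattern`.
#' @export
build_sparse_mask <- function(n, pattern = c("local+strided", "local",
                                             "strided", "full"),
                              local_width = 8, stride = 8, k_max = 32) {
  pattern <- match.arg(pattern)
  if (k_max < 1) stop("k_max must be >= 1", call. = FALSE)
  stopifnot(n >= 1)
  M <- matrix(0L, n, n)
  for (i in seq_len(n)) {
    j <- seq_len(n)
    adm <- j == i
    if (pattern %in% c("local", "local+strided")) {
      adm <- adm | abs(i - j) <= local_width
    }
    if (pattern %in% c("strided", "local+strided")) {
      adm <- adm | (i - j) %% stride == 0
    }
    if (pattern == "full") adm <- rep(TRUE, n)
    cand <- j[adm]
    cand <- cand[order(abs(cand - i), cand)]   # nearest first, then smaller j
    M[i, cand[seq_len(min(k_max, length(cand)))]] <- 1L
  }
  structure(list(M = M, k_max = k_max, pattern = pattern),
            class = "sparse_mask")
}

#' Sparse scaled-dot-product attention
#'
#' Computes `softmax(Q K^T / sqrt(d_k)) V` restricted to the mask: scores are
#' evaluated only at admissible positions and each row's softmax runs over
#' its admissible keys, which sum to weight 1. With `semantics = "literal"`
#' inadmissible scores are instead set to zero and kept inside the softmax.
#'
#' @param Q,K,V query/key/value matrices, n x d.
#' @param d_k scaling dimension (defaults to `ncol(Q)`).
#' @param mask a [build_sparse_mask()] result (or a bare binary matrix).
#' @param semantics `"additive"` (masked positions excluded) or `"literal"`.
#' @param counter optional environment; its `n` field is incremented by the
#'   number of score evaluations performed (the mask's nonzero count).
#' @return list with `out` (n x d matrix) and `weights` (n x n row-stochastic
#'   matrix, zero at inadmissible positions under additive semantics).
#' @export
sparse_attention <- function(Q, K, V, d_k = ncol(Q), mask,
                             semantics = c("additive", "literal"),
                             counter = NULL) {
  semantics <- match.arg(semantics)
  M <- if (inherits(mask, "sparse_mask")) mask$M else mask
  n <- nrow(Q)
  stopifnot(nrow(M) == n, ncol(M) == n, nrow(K) == n, nrow(V) == n)
  out <- matrix(0, n, ncol(V))
  W <- matrix(0, n, n)
  scale <- 1 / sqrt(d_k)
  for (i in seq_len(n)) {
    adm <- which(M[i, ] != 0)
    s <- as.numeric(K[adm, , drop = FALSE] %*% Q[i, ]) * scale
    if (!is.null(counter)) counter$n <- (counter$n %||% 0) + length(adm)
    if (semantics == "additive") {
      e <- exp(s - max(s))
      w <- e / sum(e)
      W[i, adm] <- w
      out[i, ] <- as.numeric(w %*% V[adm, , drop = FALSE])
    } else {
      full <- numeric(n)          # masked scores contribute exp(0)
      full[adm] <- s
      e <- exp(full - max(full))
      w <- e / sum(e)
      W[i, ] <- w
      out[i, ] <- as.numeric(w %*% V)
    }
  }
  list(out = out, weights = W)
}

#' Multi-head configuration and projections
#'
#' @param model_dim model dimension d (must be divisible by `n_heads`).
#' @param n_heads number of attention heads h.
#' @param params optional list with per-head projections `Wq`, `Wk`, `Wv`
#'   (each a list of h `d x d/h` matrices) and an output projection `Wo`
#'   (`d x d`); drawn from the current RNG when omitted.
#' @return a `multihead_config`.
#' @export
multihead_config <- function(model_dim = 128, n_heads = 4, params = NULL) {
  if (model_dim %% n_heads != 0) {
    stop("model_dim must be divisible by n_heads", call. = FALSE)
  }
  dk <- model_dim %/% n_heads
  if (is.null(params)) {
    params <- list(
      Wq = lapply(seq_len(n_heads), function(i) glorot(model_dim, dk)),
      Wk = lapply(seq_len(n_heads), function(i) glorot(model_dim, dk)),
      Wv = lapply(seq_len(n_heads), function(i) glorot(model_dim, dk)),
      Wo = glorot(model_dim, model_dim))
  }
  structure(list(model_dim = model_dim, n_heads = n_heads, head_dim = dk,
                 params = params),
            class = "multihead_config")
}

#' Multi-head sparse attention over one sequence
#'
#' Each head applies [sparse_attention()] to its own projections and sparse
#' pattern; head outputs are concatenated and passed through the output
#' projection W^O.
#'
#' @param X input sequence, n x model_dim.
#' @param cfg a [multihead_config()].
#' @param masks a single mask shared by all heads, or a list of per-head
#'   masks S_i.
#' @param semantics see [sparse_attention()].
#' @return list with `out` (n x model_dim) and per-head `weights`.
#' @export
multihead_sparse_attention <- function(X, cfg, masks,
                                       semantics = c("additive", "literal")) {
  semantics <- match.arg(semantics)
  stopifnot(inherits(cfg, "multihead_config"), ncol(X) == cfg$model_dim)
  if (inherits(masks, "sparse_mask") || is.matrix(masks)) {
    masks <- rep(list(masks), cfg$n_heads)
  }
  heads <- vector("list", cfg$n_heads)
  weights <- vector("list", cfg$n_heads)
  for (h in seq_len(cfg$n_heads)) {
    att <- sparse_attention(X %*% cfg$params$Wq[[h]],
                            X %*% cfg$params$Wk[[h]],
                            X %*% cfg$params$Wv[[h]],
                            d_k = cfg$head_dim, mask = masks[[h]],
                            semantics = semantics)
    heads[[h]] <- att$out
    weights[[h]] <- att$weights
  }
  list(out = do.call(cbind, heads) %*% cfg$params$Wo, weights = weights)
}

## ---- batched multi-head attention used inside the encoder ------------------
## Mathematically identical to multihead_sparse_attention with the combined
## projection matrices split into per-head column blocks; organised for
## batched training with cached softmax weights for the backward pass.

mha_fwd <- function(x, wq, bq, wk, bk, wv, bv, wo, bo, masks, n_heads,
                    semantics = "additive", collect = FALSE) {
  d <- dim(x); B <- d[1]; t_len <- d[2]; dm <- d[3]
  dk <- dm %/% n_heads
  scale <- 1 / sqrt(dk)
  x2 <- mat3(x)
  q <- sweep(x2 %*% wq, 2, bq, "+")
  k <- sweep(x2 %*% wk, 2, bk, "+")
  v <- sweep(x2 %*% wv, 2, bv, "+")
  o <- matrix(0, B * t_len, dm)
  P <- vector("list", B)
  neg <- lapply(masks, function(m) {
    M <- if (inherits(m, "sparse_mask")) m$M else m
    ifelse(M != 0, 0, -Inf)
  })
  lit <- lapply(masks, function(m) {
    M <- if (inherits(m, "sparse_mask")) m$M else m
    M != 0
  })
  for (b in seq_len(B)) {
    rows <- b + (seq_len(t_len) - 1L) * B
    P[[b]] <- vector("list", n_heads)
    for (h in seq_len(n_heads)) {
      cols <- (h - 1L) * dk + seq_len(dk)
      qb <- q[rows, cols, drop = FALSE]
      kb <- k[rows, cols, drop = FALSE]
      s <- tcrossprod(qb, kb) * scale
      if (semantics == "additive") {
        s <- s + neg[[h]]
      } else {
        s <- s * lit[[h]]
      }
      s <- s - apply(s, 1, max)
      e <- exp(s)
      p <- e / rowSums(e)
      P[[b]][[h]] <- p
      o[rows, cols] <- p %*% v[rows, cols, drop = FALSE]
    }
  }
  out2 <- sweep(o %*% wo, 2, bo, "+")
  res <- list(out = unmat3(out2, B, t_len),
              cache = list(x2 = x2, q = q, k = k, v = v, o = o, P = P,
                           wq = wq, wk = wk, wv = wv, wo = wo,
                           B = B, t_len = t_len, dm = dm, dk = dk,
                           n_heads = n_heads, scale = scale))
  if (collect) res$weights <- P
  res
}

mha_bwd <- function(cache, dout) {
  B <- cache$B; t_len <- cache$t_len; dk <- cache$dk
  d2 <- mat3(dout)
  dwo <- crossprod(cache$o, d2)
  dbo <- colSums(d2)
  do_ <- d2 %*% t(cache$wo)
  dq <- matrix(0, B * t_len, cache$dm)
  dk_ <- matrix(0, B * t_len, cache$dm)
  dv <- matrix(0, B * t_len, cache$dm)
  for (b in seq_len(B)) {
    rows <- b + (seq_len(t_len) - 1L) * B
    for (h in seq_len(cache$n_heads)) {
      cols <- (h - 1L) * dk + seq_len(dk)
      p <- cache$P[[b]][[h]]
      dob <- do_[rows, cols, drop = FALSE]
      vb <- cache$v[rows, cols, drop = FALSE]
      dp <- tcrossprod(dob, vb)
      dv[rows, cols] <- dv[rows, cols] + crossprod(p, dob)
      ds <- p * (dp - rowSums(dp * p))
      dq[rows, cols] <- ds %*% cache$k[rows, cols, drop = FALSE] * cache$scale
      dk_[rows, cols] <- crossprod(ds, cache$q[rows, cols, drop = FALSE]) * cache$scale
    }
  }
  dx2 <- dq %*% t(cache$wq) + dk_ %*% t(cache$wk) + dv %*% t(cache$wv)
  list(dx = unmat3(dx2, B, t_len),
       dwq = crossprod(cache$x2, dq), dbq = colSums(dq),
       dwk = crossprod(cache$x2, dk_), dbk = colSums(dk_),
       dwv = crossprod(cache$x2, dv), dbv = colSums(dv),
       dwo = dwo, dbo = dbo)
}
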