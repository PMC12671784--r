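# Factor-analysis dimensionality reduction of per-window features: fit
# common factors on standardised features, retain eigenvalue > 1 factors
# (Kaiser criterion) capped at 64, and drop factors uncorrelated with the
# seizure labels.

#' Fit a common-factor model to window features
#'
#' Features are standardised, the sample correlation matrix is
#' eigen-decomposed, and the number of retained factors is the Kaiser count
#' (correlation-scale eigenvalues > 1) capped at `max_factors`. Loadings are
#' estimated by maximum likelihood ([stats::factanal()]); when the ML fit is
#' infeasible (near-singular correlation structure, Heywood cases, or more
#' factors than the ML degrees of freedom allow) the principal-axis solution
#' from the eigen-decomposition is used instead.
#'
#' @param features numeric matrix, n_windows x p, n_windows > max_factors.
#' @param max_factors cap on the number of retained factors (default 64).
#' @return a `factor_model` with elements `mean`, `sd`, `loadings` (p x m),
#'   `noise_var` (p), `eigenvalues` (m, descending), `retained` (logical m),
#'   `score_coef` (p x m regression score coefficients), `dropped` (indices
#'   of constant feature columns removed before fitting).
#' @export
fit_factor_analysis <- function(features, max_factors = 64) {
  if (!all(is.finite(features))) stop("features must be finite", call. = FALSE)
  n <- nrow(features); p0 <- ncol(features)
  if (n <= max_factors) {
    stop(sprintf("need more windows (%d) than factors (%d)", n, max_factors),
         call. = FALSE)
  }
  mu <- colMeans(features)
  sd_all <- apply(features, 2, stats::sd)
  dropped <- which(sd_all < 1e-12)
  if (length(dropped)) {
    warning(sprintf("dropping %d constant feature column(s)", length(dropped)),
            call. = FALSE)
  }
  keep <- setdiff(seq_len(p0), dropped)
  z <- scale(features[, keep, drop = FALSE])
  R <- stats::cor(z)
  ev <- eigen(R, symmetric = TRUE)
  m <- min(max_factors, sum(ev$values > 1))
  m <- max(m, 1L)

  fit_ml <- function() {
    fa <- stats::factanal(covmat = R, factors = m, n.obs = n, rotation = "none")
    list(loadings = matrix(fa$loadings, ncol = m), noise_var = fa$uniquenesses,
         method = "ml")
  }
  fit_pa <- function() {
    L <- ev$vectors[, seq_len(m), drop = FALSE] %*%
      diag(sqrt(ev$values[seq_len(m)]), m)
    list(loadings = L, noise_var = pmax(1 - rowSums(L^2), 0.005),
         method = "principal")
  }
  fit <- tryCatch(fit_ml(), error = function(e) {
    warning("ML factor analysis failed (", conditionMessage(e),
            "); using principal-axis extraction", call. = FALSE)
    fit_pa()
  })

  # fix column signs so the largest-magnitude loading of each factor is
  # positive: refits on identical input are then identical, not just
  # sign-equivalent
  for (j in seq_len(m)) {
    k <- which.max(abs(fit$loadings[, j]))
    if (fit$loadings[k, j] < 0) fit$loadings[, j] <- -fit$loadings[, j]
  }

  structure(list(mean = mu[keep], sd = sd_all[keep],
                 loadings = fit$loadings,
                 noise_var = fit$noise_var,
                 eigenvalues = ev$values[seq_len(m)],
                 retained = ev$values[seq_len(m)] > 1,
                 score_coef = solve(R, fit$loadings),
                 dropped = dropped, p = length(keep), method = fit$method),
            class = "factor_model")
}

#' Factor scores for retained factors
#'
#' Regression (Thomson) scores on the standardised features; on the training
#' set every score column has mean ~ 0.
#'
#' @param features n x p matrix with the same columns the model was fit on.
#' @param model a `factor_model` from [fit_factor_analysis()].
#' @return n x m_retained score matrix.
#' @export
fa_transform <- function(features, model) {
  stopifnot(inherits(model, "factor_model"))
  if (length(model$dropped)) {
    features <- features[, -model$dropped, drop = FALSE]
  }
  if (ncol(features) != model$p) {
    stop(sprintf("feature dimension %d does not match model (%d)",
                 ncol(features), model$p), call. = FALSE)
  }
  z <- sweep(sweep(features, 2, model$mean), 2, model$sd, "/")
  scores <- z %*% model$score_coef
  scores[, model$retained, drop = FALSE]
}

#' Select label-relevant factors
#'
#' Keeps factor i when the point-biserial correlation between its scores and
#' the binary labels exceeds `r_threshold` in magnitude, or when a two-sample
#' t-test between the classes is significant at `p_threshold`. At least one
#' factor (the max-|r| one) is always kept.
#'
#' @param scores n x m factor-score matrix.
#' @param labels 0/1 vector of window labels; both classes must be present.
#' @param r_threshold point-biserial correlation threshold (default 0.05).
#' @param p_threshold class-difference test level (default 0.05).
#' @return logical vector over the m factors.
#' @export
select_label_relevant <- function(scores, labels, r_threshold = 0.05,
                                  p_threshold = 0.05) {
  labels <- as.numeric(labels)
  if (length(unique(labels)) < 2) {
    stop("labels contain a single class", call. = FALSE)
  }
  m <- ncol(scores)
  r <- abs(as.numeric(stats::cor(scores, labels)))
  pv <- vapply(seq_len(m), function(j) {
    stats::t.test(scores[labels == 1, j], scores[labels == 0, j])$p.value
  }, 0)
  keep <- r > r_threshold | pv < p_threshold
  if (!any(keep)) keep[which.max(r)] <- TRUE
  keep
}
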