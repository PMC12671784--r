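# Training protocol: Adam (lr 1e-4), batch size 64, sigmoid cross-entropy on
# the logit difference with optional inverse-prevalence class weighting,
# dropout regularisation, per-patient stratified 5-fold cross-validation,
# seed 8 throughout.

#' Training configuration
#'
#' Defaults follow the published protocol: Adam with learning rate 1e-4,
#' batch size 64, 150 epochs, base seed 8, 5 folds. The loss is binary
#' cross-entropy on the preictal-minus-interictal logit (equivalent to
#' sigmoid cross-entropy on a single logit; probabilities are reported via
#' softmax). `class_weight` scales the positive class by inverse prevalence.
#'
#' @param lr learning rate.
#' @param batch_size minibatch size.
#' @param epochs training epochs.
#' @param seed RNG seed for shuffling and dropout.
#' @param folds cross-validation folds.
#' @param dropout dropout rate.
#' @param class_weight logical; weight the positive class by inverse
#'   prevalence.
#' @return a `train_config` list.
#' @export
train_config <- function(lr = 1e-4, batch_size = 64, epochs = 150, seed = 8,
                         folds = 5, dropout = 0.3, class_weight = TRUE) {
  stopifnot(lr > 0, epochs >= 1, folds >= 2)
  structure(list(lr = lr, batch_size = batch_size, epochs = epochs,
                 seed = as.integer(seed), folds = folds, dropout = dropout,
                 class_weight = class_weight),
            class = "train_config")
}

fit_scaler <- function(x) {
  list(mean = colMeans(x), sd = pmax(apply(x, 2, stats::sd), 1e-8))
}

scale_features <- function(x, scaler) {
  sweep(sweep(x, 2, scaler$mean), 2, scaler$sd, "/")
}

# Weighted sigmoid cross-entropy on the logit difference z = z1 - z0.
# Returns the mean loss and the gradient w.r.t. the two logits.
bce_logit_loss <- function(logits, y, pos_weight = 1) {
  z <- logits[, 2] - logits[, 1]
  w <- ifelse(y == 1, pos_weight, 1)
  l <- pmax(z, 0) - z * y + log1p(exp(-abs(z)))
  loss <- mean(w * l)
  dz <- w * (sigmoid(z) - y) / length(y)
  list(loss = loss, dlogits = cbind(-dz, dz))
}

#' Train a CGTNet model
#'
#' Runs minibatch Adam over shuffled epochs; feature standardisation
#' statistics are estimated on the training set and stored in the model, and
#' batch-norm running statistics are updated during training. Two runs with
#' the same initial model and configuration produce identical loss
#' histories.
#'
#' @param model an initialised `cgtnet_model`.
#' @param x training features, n x input_dim.
#' @param y 0/1 labels (both classes required).
#' @param cfg a [train_config()].
#' @param verbose print the epoch losses.
#' @return list with the trained `model` and the per-epoch mean training
#'   `history`.
#' @export
cgtnet_train <- function(model, x, y, cfg = train_config(), verbose = FALSE) {
  y <- as.numeric(y)
  if (length(unique(y)) < 2) {
    stop("training set contains a single class", call. = FALSE)
  }
  old_seed <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))
  set.seed(cfg$seed)

  model$config$dropout <- cfg$dropout
  model$scaler <- fit_scaler(x)
  xs <- scale_features(x, model$scaler)
  pos_weight <- if (cfg$class_weight) sum(y == 0) / sum(y == 1) else 1

  state <- adam_init(model$params)
  history <- numeric(cfg$epochs)
  n <- nrow(xs)
  for (ep in seq_len(cfg$epochs)) {
    ord <- sample.int(n)
    ep_loss <- 0
    for (start in seq(1, n, by = cfg$batch_size)) {
      idx <- ord[start:min(start + cfg$batch_size - 1, n)]
      fw <- cgtnet_forward(model, xs[idx, , drop = FALSE], train = TRUE)
      model$buffers <- fw$buffers
      ls <- bce_logit_loss(fw$logits, y[idx], pos_weight)
      grads <- cgtnet_backward(model, fw$caches, ls$dlogits)
      upd <- adam_step(model$params, grads, state, lr = cfg$lr)
      model$params <- upd$params
      state <- upd$state
      ep_loss <- ep_loss + ls$loss * length(idx)
    }
    history[ep] <- ep_loss / n
    if (verbose) message(sprintf("epoch %3d  loss %.4f", ep, history[ep]))
  }
  list(model = model, history = history)
}

#' Predicted class probabilities
#'
#' @param model a trained `cgtnet_model`.
#' @param x feature matrix, n x input_dim.
#' @return n x 2 matrix of softmax probabilities; column 2 is P(preictal).
#' @export
cgtnet_predict <- function(model, x) {
  if (!is.null(model$scaler)) x <- scale_features(x, model$scaler)
  cgtnet_forward(model, x, train = FALSE)$probs
}

#' Patient-specific stratified k-fold splits
#'
#' Each patient's windows are split into k disjoint, label-stratified test
#' folds covering all of that patient's windows; no window of one patient
#' ever appears in another patient's folds. Deterministic at a fixed seed.
#'
#' @param windows data frame with columns `patient_id` and `label`.
#' @param k number of folds (default 5).
#' @param seed RNG seed (default 8).
#' @return named list (one entry per patient) of lists of `k`
#'   `list(train, test)` index pairs into `windows`.
#' @export
kfold_patient_splits <- function(windows, k = 5, seed = 8) {
  old_seed <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))
  set.seed(seed)
  out <- list()
  for (pid in unique(windows$patient_id)) {
    rows <- which(windows$patient_id == pid)
    fold_of <- integer(length(rows))
    for (cl in sort(unique(windows$label[rows]))) {
      sub <- which(windows$label[rows] == cl)
      if (length(sub) < k) {
        stop(sprintf("patient %s has only %d window(s) of class %s (need >= %d)",
                     pid, length(sub), cl, k), call. = FALSE)
      }
      fold_of[sample(sub)] <- rep_len(seq_len(k), length(sub))
    }
    out[[pid]] <- lapply(seq_len(k), function(f) {
      list(train = rows[fold_of != f], test = rows[fold_of == f])
    })
  }
  out
}

#' Per-patient cross-validated evaluation
#'
#' For every patient and fold: train a fresh model on the training windows
#' (per-fold seeds derived as `seed + fold`), score the test windows, and
#' compute the classification metrics at the 0.5 threshold.
#'
#' @param x feature matrix over all windows.
#' @param windows data frame with `patient_id` and `label` columns aligned
#'   with `x`.
#' @param model_cfg a [cgtnet_config()].
#' @param train_cfg a [train_config()].
#' @return data frame with one row per (patient, fold): acc, sen, spe, f1,
#'   mcc, auroc, n_test.
#' @export
evaluate_cv <- function(x, windows, model_cfg = cgtnet_config(),
                        train_cfg = train_config()) {
  splits <- kfold_patient_splits(windows, k = train_cfg$folds,
                                 seed = train_cfg$seed)
  rows <- list()
  for (pid in names(splits)) {
    for (f in seq_along(splits[[pid]])) {
      sp <- splits[[pid]][[f]]
      fold_cfg <- train_cfg
      fold_cfg$seed <- train_cfg$seed + f
      model <- cgtnet_init(model_cfg, seed = fold_cfg$seed)
      fit <- cgtnet_train(model, x[sp$train, , drop = FALSE],
                          windows$label[sp$train], fold_cfg)
      pr <- cgtnet_predict(fit$model, x[sp$test, , drop = FALSE])[, 2]
      yte <- windows$label[sp$test]
      cm <- confusion(pr, yte)
      met <- compute_metrics(cm)
      rows[[length(rows) + 1L]] <- data.frame(
        patient_id = pid, fold = f, acc = met$acc, sen = met$sen,
        spe = met$spe, f1 = met$f1, mcc = met$mcc,
        auroc = auroc(pr, yte), n_test = length(yte))
    }
  }
  do.call(rbind, rows)
}
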