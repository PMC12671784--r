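test_that("patient-specific stratified folds cover, stratify and isolate", {
  set.seed(23)
  windows <- data.frame(
    patient_id = rep(c("A", "B"), each = 100),
    label = rep(rep(0:1, c(60, 40)), 2))
  sp <- kfold_patient_splits(windows, k = 5, seed = 8)
  for (pid in c("A", "B")) {
    tests <- lapply(sp[[pid]], `[[`, "test")
    expect_equal(sort(unlist(tests)), which(windows$patient_id == pid))
    expect_equal(vapply(tests, length, 0L), rep(20L, 5))
    for (f in 1:5) {
      expect_equal(sum(windows$label[tests[[f]]] == 1), 8)   # stratified
      expect_length(intersect(sp[[pid]][[f]]$train, tests[[f]]), 0)
      # no cross-patient leakage
      other <- which(windows$patient_id != pid)
      expect_length(intersect(unlist(sp[[pid]][[f]]), other), 0)
    }
  }
  # determinism
  expect_identical(sp, kfold_patient_splits(windows, k = 5, seed = 8))
  small <- data.frame(patient_id = "C", label = c(0, 0, 0, 1, 1, 1, 1, 1))
  expect_error(kfold_patient_splits(small, k = 5), "patient C")
})

test_that("training is deterministic and overfits a separable toy set", {
  toy <- toy_separable(32)
  cfg <- train_config(epochs = 150, batch_size = 32, seed = 8, dropout = 0.1)
  m <- cgtnet_init(tiny_cfg(), seed = 8)
  f1 <- cgtnet_train(m, toy$x, toy$y, cfg)
  f2 <- cgtnet_train(m, toy$x, toy$y, cfg)
  expect_identical(f1$history, f2$history)
  expect_length(f1$history, 150)
  pr <- cgtnet_predict(f1$model, toy$x)[, 2]
  expect_gte(mean((pr >= 0.5) == toy$y), 0.95)
  # the optimiser makes net progress over training
  expect_lt(f1$history[150], f1$history[1])
  expect_error(cgtnet_train(m, toy$x, rep(1, 32), cfg), "single class")
})

test_that("confusion counts follow the inclusive 0.5 threshold", {
  cm <- confusion(c(0.9, 0.1), c(1, 0))
  expect_equal(unclass(cm)[c("TP", "TN", "FP", "FN")],
               list(TP = 1L, TN = 1L, FP = 0L, FN = 0L))
  # a score of exactly 0.5 is classified preictal
  expect_equal(confusion(0.5, 0)$FP, 1L)
  expect_equal(confusion(rep(0, 7), rep(1, 7))$FN, 7L)
  expect_error(confusion(numeric(0), numeric(0)), "empty")
})

test_that("metric formulas reproduce hand-derived values", {
  met <- compute_metrics(list(TP = 9, TN = 9, FP = 1, FN = 1))
  expect_equal(met$acc, 0.9)
  expect_equal(met$sen, 0.9)
  expect_equal(met$spe, 0.9)
  expect_equal(met$f1, 0.9)
  expect_equal(met$mcc, 0.8)
  perfect <- compute_metrics(list(TP = 5, TN = 7, FP = 0, FN = 0))
  expect_equal(unlist(perfect), rep(1, 5), ignore_attr = TRUE)
  # undefined metrics are NA, not zero
  expect_true(is.na(compute_metrics(list(TP = 0, TN = 5, FP = 0, FN = 0))$sen))
  expect_error(compute_metrics(list(TP = 0, TN = 0, FP = 0, FN = 0)), "zero")
})

test_that("metric algebra: Acc between Sen and Spe; MCC = 1 iff exact", {
  set.seed(24)
  for (i in 1:50) {
    c0 <- as.list(stats::rpois(4, 20) + 1)
    names(c0) <- c("TP", "TN", "FP", "FN")
    met <- compute_metrics(c0)
    expect_gte(met$acc, min(met$sen, met$spe) - 1e-12)
    expect_lte(met$acc, max(met$sen, met$spe) + 1e-12)
    expect_lt(met$mcc, 1)
  }
})

test_that("random predictions give MCC near zero", {
  set.seed(25)
  y <- rep(0:1, each = 5000)
  s <- stats::runif(10000)
  met <- compute_metrics(confusion(s, y))
  expect_lt(abs(met$mcc), 0.05)
})

test_that("AUROC equals the pairwise-comparison statistic", {
  expect_equal(auroc(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1)), 1)
  expect_equal(auroc(rep(0.5, 10), rep(0:1, 5)), 0.5)
  scores <- c(0.1, 0.4, 0.35, 0.8); labels <- c(0, 0, 1, 1)
  # brute-force over all positive/negative pairs, ties counted half
  pairs <- expand.grid(p = which(labels == 1), n = which(labels == 0))
  oracle <- mean(ifelse(scores[pairs$p] > scores[pairs$n], 1,
                        ifelse(scores[pairs$p] == scores[pairs$n], 0.5, 0)))
  expect_equal(auroc(scores, labels), oracle)
  expect_equal(oracle, 0.75)
  expect_error(auroc(1:3, c(1, 1, 1)), "both classes")
})

test_that("DeLong's test is internally consistent and flags degeneracy", {
  set.seed(26)
  lab <- rep(0:1, each = 50)
  s <- stats::rnorm(100) + lab
  same <- delong_test(s, s, lab)
  expect_true(same$degenerate)
  expect_equal(same$p, 1)
  expect_equal(same$auc_a, same$auc_b)
  other <- delong_test(s, -s, lab)      # anticorrelated: clearly worse
  expect_equal(other$auc_a, auroc(s, lab))
  expect_equal(other$auc_b, 1 - other$auc_a)
  expect_false(other$degenerate)
  expect_lt(other$p, 0.05)
})

test_that("Wilcoxon signed-rank p-values: exact enumeration and null rate", {
  # n = 6 all-positive differences: 2 of 64 sign assignments are as extreme
  expect_equal(wilcoxon_signed_rank(1 + (1:6) / 100), 2 / 2^6)
  # symmetric +/- pairs of equal rank magnitude sit at the null centre
  expect_gte(wilcoxon_signed_rank(c(1.04, -1.03, 1.02, -1.01, 1.1, -1.2)), 0.5)
  expect_error(wilcoxon_signed_rank(rep(0, 6)), "zero")
  expect_equal(wilcoxon_signed_rank(cbind(2:7 + (1:6) / 100, 1:6)), 2 / 2^6)
  # tied absolute differences: enumeration handles what rank tables cannot
  expect_equal(wilcoxon_signed_rank(rep(1, 6)), 2 / 2^6)
})

test_that("Cohen's d: zero for identical groups, sign flip, known effect", {
  a <- c(1, 2, 3, 4)
  expect_equal(cohens_d(a, a), 0)
  set.seed(27)
  g1 <- stats::rnorm(1e5); g2 <- stats::rnorm(1e5, mean = 1)
  expect_equal(cohens_d(g2, g1), 1, tolerance = 0.02)
  expect_equal(cohens_d(g1, g2), -cohens_d(g2, g1))
  expect_error(cohens_d(c(1, 1), c(1, 1)), "pooled")
})
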