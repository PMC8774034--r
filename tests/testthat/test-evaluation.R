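test_that("confusion metrics evaluate the printed formulas", {
  # TP=50 FP=10 TN=90 FN=5, computed by direct arithmetic
  labels <- c(rep(1, 55), rep(0, 100))
  scores <- c(rep(1, 50), rep(0, 5), rep(1, 10), rep(0, 90))
  r <- confusion_metrics(labels, scores, 0.5)
  expect_equal(c(r$tp, r$fp, r$tn, r$fn), c(50, 10, 90, 5))
  expect_equal(r$sen, 50 / 55, tolerance = 1e-12)
  expect_equal(r$spec, 90 / 100, tolerance = 1e-12)
  expect_equal(r$pre, 50 / 60, tolerance = 1e-12)
  expect_equal(r$f1, 2 * (50 / 60) * (50 / 55) / (50 / 60 + 50 / 55),
               tolerance = 1e-12)
  expect_equal(r$mcc, (50 * 90 - 10 * 5) /
                 sqrt(55) / sqrt(60) / sqrt(95) / sqrt(100), tolerance = 1e-12)
  # perfect separation
  p <- confusion_metrics(c(1, 1, 0, 0), c(0.9, 0.8, 0.2, 0.1), 0.5)
  expect_equal(c(p$sen, p$spec, p$acc, p$pre, p$f1, p$mcc), rep(1, 6))
  # everything predicted positive
  a <- confusion_metrics(c(1, 0), c(1, 1), 0.5)
  expect_equal(c(a$sen, a$spec), c(1, 0))
  expect_error(confusion_metrics(c(1, 1), c(0.1, 0.2), 0.5),
               class = "mdgae_data_error")
})

test_that("MCC equals the symbolic formula on random confusion tables", {
  set.seed(111)
  for (rep in 1:100) {
    tp <- sample(0:30, 1); fp <- sample(0:30, 1)
    tn <- sample(0:30, 1); fn <- sample(0:30, 1)
    if (tp + fn == 0 || tn + fp == 0) next  # need both classes
    labels <- c(rep(1, tp + fn), rep(0, tn + fp))
    scores <- c(rep(1, tp), rep(0, fn), rep(1, fp), rep(0, tn))
    r <- confusion_metrics(labels, scores, 0.5)
    den <- sqrt(as.numeric(tp + fn) * (tp + fp) * (tn + fn) * (tn + fp))
    expected <- if (den == 0) 0 else (tp * tn - fp * fn) / den
    expect_equal(r$mcc, expected, tolerance = 1e-10)
  }
})

test_that("AUROC equals the exhaustive pairwise-comparison oracle", {
  expect_equal(roc_auc(c(1, 1, 0, 0), c(0.9, 0.8, 0.4, 0.1)), 1.0)
  expect_equal(roc_auc(c(1, 0, 1, 0), rep(0.5, 4)), 0.5)
  set.seed(121)
  for (rep in 1:50) {
    n <- sample(4:50, 1)
    labels <- c(1, 0, rbinom(n - 2, 1, 0.4))
    scores <- sample(round(runif(n), 2))  # rounding forces ties
    expect_equal(roc_auc(labels, scores), auroc_oracle(labels, scores),
                 tolerance = 1e-12)
  }
})

test_that("AUPR follows the step-interpolation sweep", {
  expect_equal(pr_auc(c(1, 1, 0, 0), c(0.9, 0.8, 0.4, 0.1)), 1.0)
  # hand case: labels (1,0,1,0) by descending score
  # thresholds: recall 0.5 @ prec 1, recall 0.5 @ prec 0.5, 1 @ 2/3, 1 @ 0.5
  lab <- c(1, 0, 1, 0); sc <- c(0.9, 0.8, 0.7, 0.6)
  expect_equal(pr_auc(lab, sc), 0.5 * 1 + 0.5 * (2 / 3), tolerance = 1e-12)
  # ties: all equal scores -> single threshold, AUPR = prevalence
  expect_equal(pr_auc(c(1, 0, 0, 0), rep(1, 4)), 0.25, tolerance = 1e-12)
})

test_that("rank metrics are invariant under strictly monotone transforms", {
  set.seed(131)
  labels <- rbinom(40, 1, 0.3); labels[1] <- 1; labels[2] <- 0
  scores <- rnorm(40)
  for (f in list(function(x) 2 * x + 3, function(x) exp(x),
                 function(x) x^3)) {
    expect_equal(roc_auc(labels, f(scores)), roc_auc(labels, scores),
                 tolerance = 1e-12)
    expect_equal(pr_auc(labels, f(scores)), pr_auc(labels, scores),
                 tolerance = 1e-12)
  }
})

test_that("fixed-specificity thresholding picks the most sensitive valid point", {
  # perfect separation: sensitivity 1 at specificity >= 0.99
  labels <- c(rep(1, 5), rep(0, 200))
  scores <- c(seq(0.9, 0.98, length.out = 5), runif(200, 0, 0.5))
  r <- sensitivity_at_specificity(labels, scores, 0.99)
  expect_equal(r$sen, 1)
  expect_gte(r$spec, 0.99)
  # 100 negatives below 1 positive: at most one false positive admitted
  labels2 <- c(1, rep(0, 100))
  scores2 <- c(1, seq(0.01, 0.99, length.out = 100))
  r2 <- sensitivity_at_specificity(labels2, scores2, 0.99)
  expect_lte(r2$fp, 1)
  expect_equal(r2$sen, 1)
  # unattainable: too few negatives to resolve the target
  expect_error(sensitivity_at_specificity(c(1, 1, 0, 0), c(4, 3, 2, 1), 0.99),
               class = "mdgae_data_error")
})

test_that("cross-validation partitions cleanly, never leaks, and is deterministic", {
  ds <- simulate_dataset(synthetic_spec(m = 30, n = 20, density = 0.15,
                                        seed = 8))
  Ymat <- unclass(ds$Y)
  pos <- which(Ymat == 1)
  fold_of <- mdgae:::fold_assignment(length(pos), 5L, 42L)
  sizes <- table(fold_of)
  expect_equal(sum(sizes), length(pos))
  expect_lte(diff(range(sizes)), 1)
  # leakage: held-out positives are zero in each fold's training matrix
  for (fold in 1:5) {
    Ytrain <- Ymat
    Ytrain[pos[fold_of == fold]] <- 0
    expect_true(all(Ytrain[pos[fold_of == fold]] == 0))
    expect_equal(sum(Ytrain), length(pos) - sum(fold_of == fold))
  }
  hp <- hyperparams(hidden_dim = 4, inter_dim = 8, max_epochs = 15, seed = 3)
  cv1 <- five_fold_cv(ds$Y, hp, mirna_sim = ds$mirna_sim)
  cv2 <- five_fold_cv(ds$Y, hp, mirna_sim = ds$mirna_sim)
  expect_identical(cv1$folds, cv2$folds)
  expect_equal(nrow(cv1$folds), 5)
  expect_true(all(cv1$folds$auroc >= 0 & cv1$folds$auroc <= 1))
  expect_error(five_fold_cv(association_matrix(matrix(c(1, 0, 0, 0), 2, 2)),
                            hp),
               class = "mdgae_data_error")
})

test_that("the similarity graphs are rebuilt from each fold's training labels", {
  # the Gaussian kernel of the training fold must differ from the full-data
  # kernel whenever a removed positive changes a profile
  ds <- simulate_dataset(synthetic_spec(m = 12, n = 10, density = 0.2, seed = 4))
  Ymat <- unclass(ds$Y)
  pos <- which(Ymat == 1)
  Ytrain <- Ymat; Ytrain[pos[1]] <- 0
  G_full <- gaussian_profile_similarity(ds$Y, "mirna")
  G_fold <- gaussian_profile_similarity(association_matrix(Ytrain), "mirna")
  expect_false(isTRUE(all.equal(unclass(G_full), unclass(G_fold))))
})

test_that("a sweep of size one reduces to plain CV and grids expand by row", {
  ds <- simulate_dataset(synthetic_spec(m = 25, n = 15, density = 0.15,
                                        seed = 6))
  hp <- hyperparams(hidden_dim = 4, inter_dim = 8, max_epochs = 10, seed = 2)
  cv <- five_fold_cv(ds$Y, hp)
  sw <- hyperparameter_sweep(ds$Y, data.frame(alpha = 0.5), hp)
  expect_equal(nrow(sw), 1)
  expect_equal(sw$auroc_mean, cv$summary$auroc_mean, tolerance = 1e-12)
  grid <- data.frame(alpha = c(0.1, 0.3, 0.5, 0.7, 0.9))
  sw5 <- hyperparameter_sweep(ds$Y, grid, hp)
  expect_equal(nrow(sw5), 5)
  expect_equal(sw5$alpha, grid$alpha)
  expect_error(hyperparameter_sweep(ds$Y, data.frame(bogus = 1), hp),
               class = "mdgae_usage_error")
})
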