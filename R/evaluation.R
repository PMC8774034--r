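#' Confusion-matrix metrics at a threshold
#'
#' Predictions are positive when `score >= threshold`.  Reports sensitivity
#' (recall/TPR), specificity, accuracy, precision, F1 and the Matthews
#' correlation coefficient; MCC and precision return 0 when their
#' denominator vanishes (documented convention for degenerate cells).
#'
#' @param labels binary vector (0/1).
#' @param scores numeric vector, same length.
#' @param threshold decision threshold.
#' @return list of class `metric_report` with `sen`, `spec`, `acc`, `pre`,
#'   `f1`, `mcc`, `threshold` and the raw counts.
#' @export
confusion_metrics <- function(labels, scores, threshold) {
  check_two_classes(labels, scores)
  pred <- scores >= threshold
  tp <- sum(pred & labels == 1)
  fp <- sum(pred & labels == 0)
  tn <- sum(!pred & labels == 0)
  fn <- sum(!pred & labels == 1)
  sen <- tp / (tp + fn)
  spec <- tn / (tn + fp)
  acc <- (tp + tn) / (tp + tn + fp + fn)
  pre <- if (tp + fp == 0) 0 else tp / (tp + fp)
  f1 <- if (pre + sen == 0) 0 else 2 * pre * sen / (pre + sen)
  mcc_den <- sqrt(tp + fn) * sqrt(tp + fp) * sqrt(tn + fn) * sqrt(tn + fp)
  mcc <- if (mcc_den == 0) 0 else (tp * tn - fp * fn) / mcc_den
  structure(list(sen = sen, spec = spec, acc = acc, pre = pre, f1 = f1,
                 mcc = mcc, threshold = threshold,
                 tp = tp, fp = fp, tn = tn, fn = fn),
            class = "metric_report")
}

check_two_classes <- function(labels, scores) {
  if (length(labels) != length(scores))
    stop_data("labels and scores differ in length")
  if (!all(labels %in% c(0, 1)))
    stop_data("labels must be 0/1")
  if (all(labels == 1) || all(labels == 0))
    stop_data("both classes must be present")
  invisible(TRUE)
}

#' Area under the ROC curve
#'
#' Computed as the Mann-Whitney rank statistic,
#' `P(score+ > score-) + 0.5 * P(tie)`, which equals trapezoidal
#' integration of the ROC curve with tied scores collapsed onto one
#' threshold.
#'
#' @param labels binary vector.
#' @param scores numeric vector.
#' @return AUROC in `[0, 1]`.
#' @export
roc_auc <- function(labels, scores) {
  check_two_classes(labels, scores)
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == 0)
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Area under the precision-recall curve
#'
#' Step interpolation over the threshold sweep: scores are grouped by
#' unique value (descending); each group contributes
#' `(recall_k - recall_{k-1}) * precision_k`.
#'
#' @inheritParams roc_auc
#' @return AUPR in `[0, 1]`.
#' @export
pr_auc <- function(labels, scores) {
  check_two_classes(labels, scores)
  ord <- order(scores, decreasing = TRUE)
  lab <- labels[ord]
  sc <- scores[ord]
  keep <- !duplicated(sc, fromLast = TRUE)      # last index of each tie group
  tp <- cumsum(lab == 1)[keep]
  fp <- cumsum(lab == 0)[keep]
  n_pos <- sum(labels == 1)
  recall <- tp / n_pos
  precision <- tp / (tp + fp)
  sum(diff(c(0, recall)) * precision)
}

#' Metrics at a fixed specificity
#'
#' Chooses the smallest threshold whose specificity is at least
#' `target_spec` (i.e., the most sensitive operating point satisfying the
#' constraint; tied scores form a single threshold) and reports
#' [confusion_metrics()] there.
#'
#' @inheritParams roc_auc
#' @param target_spec required specificity, default 0.99.
#' @return a `metric_report`.
#' @export
sensitivity_at_specificity <- function(labels, scores, target_spec = 0.99) {
  check_two_classes(labels, scores)
  n_neg <- sum(labels == 0)
  if (n_neg < 1 / (1 - target_spec))
    stop_data("specificity %.3g is unattainable with %d negatives",
              target_spec, n_neg)
  # candidate thresholds: unique scores; tied scores form one threshold.
  # spec(t) = #{negatives < t} / n_neg is non-decreasing in t.
  thr <- sort(unique(scores))
  neg_sorted <- sort(scores[labels == 0])
  spec <- findInterval(thr, neg_sorted, left.open = TRUE) / n_neg
  ok <- thr[spec >= target_spec]
  best <- if (length(ok)) min(ok) else max(scores) + 1  # above all: spec = 1
  confusion_metrics(labels, scores, best)
}

#' Five-fold cross-validation over known associations
#'
#' Positives are shuffled with the seed and split into `n_folds` nearly
#' equal folds.  Per fold the held-out positives are zeroed in a training
#' copy of `Y`; Gaussian-kernel similarities (and hence the fused
#' similarity matrices and normalized graphs) are recomputed from that
#' training matrix so no held-out label leaks through the kernel; the model
#' is trained and the held-out positives are scored against every pair that
#' is zero in the full matrix.
#'
#' @param Y [association_matrix()] with at least `n_folds` positives.
#' @param hp [hyperparams()]; fold seeds derive from `hp$seed`.
#' @param mirna_sim optional curated miRNA similarity (square labeled
#'   matrix over a subset of miRNAs).
#' @param dag optional [disease_dag()] for semantic disease similarity.
#' @param n_repeats number of CV repetitions (fresh shuffles).
#' @param n_folds number of folds, default 5.
#' @param target_spec specificity for the fixed-specificity metrics.
#' @return list of class `mdgae_cv`: `folds` (data.frame: repeat, fold,
#'   auroc, aupr, sen, acc, pre, f1, mcc), `summary` (mean/sd of AUROC and
#'   AUPR), `hp`.
#' @export
five_fold_cv <- function(Y, hp = hyperparams(), mirna_sim = NULL, dag = NULL,
                         n_repeats = 1L, n_folds = 5L, target_spec = 0.99) {
  Ymat <- unclass(as.matrix(Y))
  pos <- which(Ymat == 1)
  if (length(pos) < n_folds)
    stop_data("need at least %d positive entries for %d-fold CV", n_folds, n_folds)
  neg <- which(Ymat == 0)
  rows <- list()
  for (rep_i in seq_len(n_repeats)) {
    fold_of <- fold_assignment(length(pos), n_folds, hp$seed + 7919L * (rep_i - 1L))
    for (fold in seq_len(n_folds)) {
      test_pos <- pos[fold_of == fold]
      if (length(test_pos) == 0L) stop_data("fold %d has no test positives", fold)
      Ytrain <- Ymat
      Ytrain[test_pos] <- 0
      fit <- fit_on_training_matrix(Ytrain, hp, mirna_sim, dag,
                                    seed = hp$seed + 1000L * rep_i + fold)
      scores_mat <- fit$scores$F
      labels <- c(rep(1L, length(test_pos)), rep(0L, length(neg)))
      sc <- c(scores_mat[test_pos], scores_mat[neg])
      mr <- tryCatch(sensitivity_at_specificity(labels, sc, target_spec),
                     mdgae_data_error = function(e) NULL)
      rows[[length(rows) + 1L]] <- data.frame(
        rep = rep_i, fold = fold,
        auroc = roc_auc(labels, sc), aupr = pr_auc(labels, sc),
        sen = if (is.null(mr)) NA_real_ else mr$sen,
        acc = if (is.null(mr)) NA_real_ else mr$acc,
        pre = if (is.null(mr)) NA_real_ else mr$pre,
        f1 = if (is.null(mr)) NA_real_ else mr$f1,
        mcc = if (is.null(mr)) NA_real_ else mr$mcc,
        epochs = fit$epochs)
    }
  }
  folds <- do.call(rbind, rows)
  structure(list(folds = folds,
                 summary = list(auroc_mean = mean(folds$auroc),
                                auroc_sd = stats::sd(folds$auroc),
                                aupr_mean = mean(folds$aupr),
                                aupr_sd = stats::sd(folds$aupr)),
                 hp = hp),
            class = "mdgae_cv")
}

fold_assignment <- function(n, n_folds, seed) {
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  sample(rep(seq_len(n_folds), length.out = n))
}

# Build similarities + graphs from a training association matrix and train.
# Curated / semantic similarities are fixed side information; only the
# Gaussian kernels depend on (and are recomputed from) the training labels.
fit_on_training_matrix <- function(Ytrain, hp, mirna_sim = NULL, dag = NULL,
                                   seed = hp$seed) {
  Yobj <- association_matrix(Ytrain)
  GMS <- gaussian_profile_similarity(Yobj, "mirna")
  Sm <- fuse_mirna_similarity(mirna_sim, GMS)
  GDS <- gaussian_profile_similarity(Yobj, "disease")
  Sd <- if (is.null(dag)) {
    fuse_disease_similarity(NULL, NULL, GDS)
  } else {
    covered <- intersect(names(dag$disease_roots), colnames(Ytrain))
    DS1 <- semantic_similarity_matrix(dag, "wang", hp$delta, covered)
    DS2 <- semantic_similarity_matrix(dag, "xuan", diseases = covered)
    fuse_disease_similarity(DS1, DS2, GDS, covered)
  }
  hp_fold <- hp
  hp_fold$seed <- as.integer(seed %% .Machine$integer.max)
  train_gae(Yobj, normalize_adjacency(Sm), normalize_adjacency(Sd), hp_fold)
}

#' @export
print.mdgae_cv <- function(x, ...) {
  s <- x$summary
  cat(sprintf("mdgae_cv: %d evaluations | AUROC %.4f +/- %.4f | AUPR %.4f +/- %.4f\n",
              nrow(x$folds), s$auroc_mean, s$auroc_sd, s$aupr_mean, s$aupr_sd))
  invisible(x)
}

#' Write a CV report TSV
#'
#' One row per fold plus a trailing `mean`/`sd` summary pair.
#'
#' @param cv an `mdgae_cv`.
#' @param path output path.
#' @export
write_cv_report <- function(cv, path) {
  df <- cv$folds
  df$rep <- as.character(df$rep); df$fold <- as.character(df$fold)
  num_cols <- c("auroc", "aupr", "sen", "acc", "pre", "f1", "mcc", "epochs")
  mean_row <- c(list(rep = "all", fold = "mean"),
                lapply(cv$folds[num_cols], mean))
  sd_row <- c(list(rep = "all", fold = "sd"),
              lapply(cv$folds[num_cols], stats::sd))
  out <- rbind(df, as.data.frame(mean_row), as.data.frame(sd_row))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Hyperparameter sweep
#'
#' Runs [five_fold_cv()] at every row of a grid over `alpha`,
#' `learning_rate` and/or `hidden_dim` (any subset of those columns; other
#' hyperparameters come from `hp`).
#'
#' @param Y [association_matrix()].
#' @param grid data.frame whose columns are hyperparameter names.
#' @param hp baseline [hyperparams()].
#' @param ... forwarded to [five_fold_cv()] (`mirna_sim`, `dag`,
#'   `n_repeats`, ...).
#' @return data.frame: the grid plus `auroc_mean`, `auroc_sd`, `aupr_mean`,
#'   `aupr_sd`.
#' @export
hyperparameter_sweep <- function(Y, grid, hp = hyperparams(), ...) {
  if (!is.data.frame(grid) || nrow(grid) == 0L)
    stop_usage("grid must be a nonempty data.frame")
  bad <- setdiff(names(grid), names(unclass(hp)))
  if (length(bad))
    stop_usage("unknown hyperparameter(s) in grid: %s", paste(bad, collapse = ","))
  res <- lapply(seq_len(nrow(grid)), function(i) {
    hp_i <- unclass(hp)
    for (k in names(grid)) hp_i[[k]] <- grid[[k]][i]
    cv <- five_fold_cv(Y, do.call(hyperparams, hp_i), ...)
    data.frame(grid[i, , drop = FALSE],
               auroc_mean = cv$summary$auroc_mean,
               auroc_sd = cv$summary$auroc_sd,
               aupr_mean = cv$summary$aupr_mean,
               aupr_sd = cv$summary$aupr_sd,
               row.names = NULL)
  })
  do.call(rbind, res)
}
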