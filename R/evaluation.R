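# Confusion metrics, ROC/AUC and stratified k-fold cross-validation.
# Positive class = 1 (fatigue) throughout.

#' Confusion counts
#'
#' Standard 2x2 cross-tabulation with positive class 1 (fatigue).
#'
#' @param y_true,y_pred Equal-length binary (0/1) vectors.
#' @return A `ConfusionCounts` list with `TP`, `TN`, `FP`, `FN`.
#' @export
confusion <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) stop("length mismatch")
  if (!all(y_true %in% c(0, 1)) || !all(y_pred %in% c(0, 1))) {
    stop("inputs must be binary 0/1")
  }
  structure(
    list(TP = sum(y_true == 1 & y_pred == 1),
         TN = sum(y_true == 0 & y_pred == 0),
         FP = sum(y_true == 0 & y_pred == 1),
         FN = sum(y_true == 1 & y_pred == 0)),
    class = "ConfusionCounts"
  )
}

#' Sensitivity, specificity and accuracy from confusion counts
#'
#' Sensitivity (true positive rate) = TP/(TP+FN), specificity (true negative
#' rate) = TN/(TN+FP), accuracy = (TP+TN)/total, all returned as percentages
#' at full precision (reports round to 2 decimals for display). A zero
#' denominator yields `NA` with a warning.
#'
#' @param counts A [confusion()] result (or list with TP/TN/FP/FN).
#' @return List with `sensitivity`, `specificity`, `accuracy` (percent).
#' @export
rates <- function(counts) {
  safe_div <- function(num, den, what) {
    if (den == 0) {
      warning(sprintf("%s undefined: zero denominator", what))
      return(NA_real_)
    }
    num / den
  }
  sens <- safe_div(counts$TP, counts$TP + counts$FN, "sensitivity")
  spec <- safe_div(counts$TN, counts$TN + counts$FP, "specificity")
  acc <- safe_div(counts$TP + counts$TN,
                  counts$TP + counts$TN + counts$FP + counts$FN, "accuracy")
  list(sensitivity = 100 * sens, specificity = 100 * spec,
       accuracy = 100 * acc)
}

#' ROC curve and area under it
#'
#' Thresholds are swept over the unique scores (decision rule: score >=
#' threshold is called positive), giving a monotone curve from (0, 0) to
#' (1, 1). The area is computed by trapezoidal integration, which equals the
#' Mann-Whitney pair statistic with ties counted one half.
#'
#' @param y_true Binary 0/1 labels (both classes must be present).
#' @param scores Continuous classifier outputs.
#' @return List with `roc` (data frame of `fpr`, `tpr`) and `auc`.
#' @export
roc_auc <- function(y_true, scores) {
  if (length(y_true) != length(scores)) stop("length mismatch")
  n_pos <- sum(y_true == 1)
  n_neg <- sum(y_true == 0)
  if (n_pos == 0 || n_neg == 0) stop("both classes must be present")
  ord <- order(scores, decreasing = TRUE)
  y <- y_true[ord]
  s <- scores[ord]
  # cumulative counts at each threshold; collapse tied scores to one point
  tp <- cumsum(y == 1)
  fp <- cumsum(y == 0)
  keep <- c(s[-1] != s[-length(s)], TRUE)
  tpr <- c(0, tp[keep] / n_pos)
  fpr <- c(0, fp[keep] / n_neg)
  auc <- sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
  list(roc = data.frame(fpr = fpr, tpr = tpr), auc = auc)
}

#' Stratified k-fold cross-validation
#'
#' Rows are partitioned into k disjoint folds, stratified by class so every
#' fold carries an (as near as possible) even class split. Each fold serves
#' once as the validation set while the remaining rows train; per-fold
#' accuracy uses the 0.5 decision threshold. Predictions are also pooled
#' across folds for aggregate confusion/ROC analysis.
#'
#' @param features A `FeatureSet` with labels for every row.
#' @param k Number of folds (must not exceed either class count).
#' @param trainer Function `(train_fs, val_fs, fold)` returning an
#'   `RBFNetwork` (or any object with a `predict` method yielding continuous
#'   scores). See [make_tllh_trainer()] and [make_fixed_trainer()].
#' @param seed Integer seed controlling the fold assignment.
#' @return List with `fold_accuracy` (percent, one per fold), `mean`, `sd`
#'   (sample, n-1), `folds` (index list), and `pooled` (list with `y_true`,
#'   `y_pred`, `scores` over all rows, in fold order).
#' @export
kfold_cv <- function(features, k, trainer, seed = 1L) {
  stopifnot(inherits(features, "FeatureSet"), k >= 2L)
  y <- features$y
  n <- length(y)
  if (k > n) stop("k exceeds the number of epochs")
  if (any(is.na(y))) stop("all epochs must be labeled for cross-validation")

  folds <- with_seed(derive_seed(seed, 101L), {
    assign_cls <- function(idx) {
      idx <- sample(idx)
      split(idx, rep_len(seq_len(k), length(idx)))
    }
    f1 <- assign_cls(which(y == 1))
    f0 <- assign_cls(which(y == 0))
    lapply(seq_len(k), function(j) sort(c(f1[[j]], f0[[j]])))
  })

  fold_acc <- numeric(k)
  pooled_true <- integer(0)
  pooled_pred <- integer(0)
  pooled_scores <- numeric(0)
  for (j in seq_len(k)) {
    val_idx <- folds[[j]]
    train_fs <- subset_features(features, setdiff(seq_len(n), val_idx))
    val_fs <- subset_features(features, val_idx)
    net <- trainer(train_fs, val_fs, j)
    sc <- predict(net, val_fs$X)
    pred <- as.integer(sc > 0.5)
    fold_acc[j] <- 100 * mean(pred == val_fs$y)
    pooled_true <- c(pooled_true, val_fs$y)
    pooled_pred <- c(pooled_pred, pred)
    pooled_scores <- c(pooled_scores, sc)
  }
  list(fold_accuracy = fold_acc,
       mean = mean(fold_acc),
       sd = stats::sd(fold_acc),
       folds = folds,
       pooled = list(y_true = pooled_true, y_pred = pooled_pred,
                     scores = pooled_scores))
}

#' Cross-validation trainer running the full two-level hierarchy
#'
#' Returns a trainer closure for [kfold_cv()] that re-runs the swarm search
#' within every fold (fold-specific seeds derived from `seed`). By default
#' the fold's held-out set doubles as the swarm's fitness set — the study
#' protocol, which tunes and reports on the same fold and therefore carries
#' a small optimistic bias. Setting `tune_fraction` (e.g. `1/6`) instead
#' carves a stratified tuning split out of the fold's training rows, leaving
#' the reported fold untouched by the hyperparameter search (three-way
#' split); the final network is refit on all training rows at the selected
#' hyperparameters.
#'
#' @param swarm_size,iterations,space,max_terms,seed See [tllh_train()].
#' @param tune_fraction Fraction of training rows held out for the swarm's
#'   fitness, or `NULL` (default) for the tune-on-reported-fold protocol.
#' @return A function `(train_fs, val_fs, fold) -> RBFNetwork`.
#' @export
make_tllh_trainer <- function(swarm_size = 15L, iterations = 30L,
                              space = default_hyper_space(),
                              max_terms = NULL, seed = 1L,
                              tune_fraction = NULL) {
  function(train_fs, val_fs, fold) {
    fold_seed <- derive_seed(seed, 7L, fold)
    if (is.null(tune_fraction)) {
      return(tllh_train(train_fs, val_fs, space = space,
                        swarm_size = swarm_size, iterations = iterations,
                        max_terms = max_terms, seed = fold_seed)$network)
    }
    n <- nrow(train_fs$X)
    tune_idx <- with_seed(derive_seed(fold_seed, 13L), {
      take <- function(cls) {
        idx <- which(train_fs$y == cls)
        sample(idx)[seq_len(max(1L, round(length(idx) * tune_fraction)))]
      }
      sort(c(take(0L), take(1L)))
    })
    inner <- subset_features(train_fs, setdiff(seq_len(n), tune_idx))
    tune <- subset_features(train_fs, tune_idx)
    res <- tllh_train(inner, tune, space = space, swarm_size = swarm_size,
                      iterations = iterations, max_terms = max_terms,
                      seed = fold_seed)
    rbf_fit(train_fs$X, train_fs$y,
            lambda = res$best_K[["lambda"]], rho = res$best_K[["rho"]],
            beta = res$best_K[["beta"]],
            pipeline_params = res$network$pipeline_params)$network
  }
}

#' Cross-validation trainer with fixed hyperparameters
#'
#' Baseline pathway: no upper-level search, every fold trains a single
#' network at the supplied `(lambda, rho, beta)`.
#'
#' @param lambda,rho,beta Fixed hyperparameters (defaults `rho = 110`,
#'   `beta = 1e-4`).
#' @param max_terms Cap on selected centers (default: training-set size).
#' @return A function `(train_fs, val_fs, fold) -> RBFNetwork`.
#' @export
make_fixed_trainer <- function(lambda = 1e-6, rho = 110, beta = 1e-4,
                               max_terms = NULL) {
  function(train_fs, val_fs, fold) {
    tllh_train(train_fs, val_fs, max_terms = max_terms,
               fixed = list(lambda = lambda, rho = rho, beta = beta))$network
  }
}

#' Full evaluation report for a fitted network
#'
#' @param net An `RBFNetwork`.
#' @param features A labeled `FeatureSet`.
#' @return List with `counts`, `rates` (percent), `roc`, `auc`.
#' @export
evaluate_network <- function(net, features) {
  sc <- predict(net, features$X)
  pred <- as.integer(sc > 0.5)
  cts <- confusion(features$y, pred)
  c(list(counts = cts, rates = rates(cts)), roc_auc(features$y, sc))
}
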