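# Confusion metrics, ROC/AUC, stratified cross-validation.

test_that("confusion counts match hand cases and a loop tally", {
  c1 <- confusion(c(1, 1, 0, 0), c(1, 1, 0, 0))
  expect_equal(unlist(c1[c("TP", "TN", "FP", "FN")]),
               c(TP = 2, TN = 2, FP = 0, FN = 0))

  c2 <- confusion(c(1, 0), c(0, 1))
  expect_equal(unlist(c2[c("TP", "TN", "FP", "FN")]),
               c(TP = 0, TN = 0, FP = 1, FN = 1))

  set.seed(23)
  yt <- rbinom(100, 1, 0.5)
  yp <- rbinom(100, 1, 0.5)
  cc <- confusion(yt, yp)
  tally <- c(TP = 0, TN = 0, FP = 0, FN = 0)
  for (i in 1:100) {
    if (yt[i] == 1 && yp[i] == 1) tally["TP"] <- tally["TP"] + 1
    if (yt[i] == 0 && yp[i] == 0) tally["TN"] <- tally["TN"] + 1
    if (yt[i] == 0 && yp[i] == 1) tally["FP"] <- tally["FP"] + 1
    if (yt[i] == 1 && yp[i] == 0) tally["FN"] <- tally["FN"] + 1
  }
  expect_equal(unlist(cc[c("TP", "TN", "FP", "FN")]), tally)
  expect_equal(cc$TP + cc$FN, sum(yt == 1))
  expect_equal(cc$TN + cc$FP, sum(yt == 0))

  expect_error(confusion(c(1, 2), c(0, 1)), "binary")
})

test_that("rates reproduce the published worked examples", {
  r <- rates(list(TP = 665, TN = 670, FN = 55, FP = 50))
  expect_equal(round(r$sensitivity, 2), 92.36)
  expect_equal(round(r$specificity, 2), 93.06)
  expect_equal(round(r$accuracy, 2), 92.71)

  r2 <- rates(list(TP = 552, TN = 554, FN = 168, FP = 166))
  expect_equal(round(r2$accuracy, 2), 76.81)

  r3 <- rates(list(TP = 7, TN = 7, FP = 0, FN = 0))
  expect_equal(unlist(r3), c(sensitivity = 100, specificity = 100,
                             accuracy = 100))

  expect_warning(r0 <- rates(list(TP = 0, TN = 3, FP = 1, FN = 0)),
                 "undefined")
  expect_true(is.na(r0$sensitivity))
})

test_that("rates are always consistent with counts", {
  set.seed(24)
  for (rep in 1:10) {
    n <- sample(20:60, 1)
    yt <- rbinom(n, 1, 0.5)
    yp <- rbinom(n, 1, 0.5)
    if (length(unique(yt)) < 2) next
    cc <- confusion(yt, yp)
    r <- rates(cc)
    expect_equal(r$accuracy, 100 * (cc$TP + cc$TN) / n)
    expect_equal(r$sensitivity, 100 * cc$TP / (cc$TP + cc$FN))
    expect_equal(r$specificity, 100 * cc$TN / (cc$TN + cc$FP))
  }
})

test_that("ROC/AUC matches hand cases", {
  # perfect separation
  expect_equal(roc_auc(c(0, 0, 1, 1), c(0.1, 0.2, 0.8, 0.9))$auc, 1)
  # the classic 0.75 example (3 of 4 positive-negative pairs correct)
  expect_equal(roc_auc(c(0, 0, 1, 1), c(0.1, 0.4, 0.35, 0.8))$auc, 0.75)
  # uninformative scores
  expect_equal(roc_auc(c(0, 1, 0, 1), rep(0.5, 4))$auc, 0.5)
  expect_error(roc_auc(c(1, 1), c(0.2, 0.3)), "both classes")
})

test_that("ROC curve is monotone from (0,0) to (1,1)", {
  set.seed(25)
  y <- rbinom(50, 1, 0.4)
  s <- rnorm(50) + y
  roc <- roc_auc(y, s)$roc
  expect_equal(roc$fpr[1], 0)
  expect_equal(roc$tpr[1], 0)
  expect_equal(roc$fpr[nrow(roc)], 1)
  expect_equal(roc$tpr[nrow(roc)], 1)
  expect_true(all(diff(roc$fpr) >= 0))
  expect_true(all(diff(roc$tpr) >= 0))
})

test_that("trapezoidal AUC equals the pair-counting statistic", {
  set.seed(26)
  for (rep in 1:25) {
    n <- sample(8:30, 1)
    y <- c(0, 1, rbinom(n - 2, 1, 0.5))
    s <- sample(seq(0, 1, by = 0.1), n, replace = TRUE) # ties likely
    expect_equal(roc_auc(y, s)$auc, auc_pair_count(y, s), tolerance = 1e-12)
  }
})

test_that("fold aggregation reproduces the published mean and SD", {
  acc <- c(89.58, 87.08, 100.00, 100.00, 93.75, 85.83)
  expect_equal(round(mean(acc), 2), 92.71)
  expect_equal(round(stats::sd(acc), 2), 6.26) # sample (n-1) SD
})

test_that("stratified folds are balanced, disjoint and exhaustive", {
  fs <- blob_features(120, d = 3, sep = 5, seed = 91) # 240 epochs, 120/120
  trainer <- make_fixed_trainer(lambda = 1e-4, rho = 10, beta = 1e-5,
                                max_terms = 25L)
  cv <- kfold_cv(fs, 6, trainer, seed = 2)
  expect_length(cv$fold_accuracy, 6)
  sizes <- lengths(cv$folds)
  expect_true(all(sizes == 40))
  for (f in cv$folds) {
    expect_equal(sum(fs$y[f] == 1), 20)
    expect_equal(sum(fs$y[f] == 0), 20)
  }
  expect_equal(sort(unlist(cv$folds)), 1:240)
  expect_equal(cv$mean, mean(cv$fold_accuracy))
  expect_equal(cv$sd, stats::sd(cv$fold_accuracy))
  # easy blobs: the baseline trainer should be near-perfect
  expect_gte(cv$mean, 95)
})

test_that("a constant-prediction trainer scores 50% on balanced data", {
  fs <- blob_features(12, d = 2, sep = 4, seed = 92)
  const_trainer <- function(train_fs, val_fs, fold) {
    # single far-away center: output ~0 everywhere, always predicts alert
    rbf_network(matrix(1e6, 1, 2), rho = 1, theta = 1)
  }
  cv <- kfold_cv(fs, 4, const_trainer, seed = 3)
  expect_true(all(abs(cv$fold_accuracy - 50) < 1e-10))
})

test_that("evaluate_network assembles counts, rates and AUC", {
  fs <- blob_features(15, sep = 8, seed = 93)
  net <- tllh_train(fs, fs, fixed = list(lambda = 1e-4, rho = 20,
                                         beta = 1e-5))$network
  rep <- evaluate_network(net, fs)
  expect_named(rep, c("counts", "rates", "roc", "auc"))
  expect_gte(rep$auc, 0.95)
  expect_equal(rep$counts$TP + rep$counts$TN + rep$counts$FP + rep$counts$FN,
               30)
})
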