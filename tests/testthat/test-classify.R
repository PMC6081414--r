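test_that("a separable toy problem is fit perfectly with interpretable weights", {
  toy <- toy_separable(20)
  m <- train_linear_svm(toy$X, toy$y)
  expect_s3_class(m, "diagnostic_model")
  expect_equal(predict(m, toy$X), toy$y)
  # class-1 blob sits at positive feature values -> positive weights
  expect_true(all(m$weights > 0))
})

test_that("training rejects degenerate inputs", {
  toy <- toy_separable(10)
  expect_error(train_linear_svm(toy$X, rep(1, 20)), "single class")
  expect_error(train_linear_svm(toy$X, c(rep(1, 19), 0)), "2 samples per class")
  Xna <- toy$X; Xna[1, 1] <- NA
  expect_error(train_linear_svm(Xna, toy$y), "missing")
})

test_that("duplicated feature columns split their weight symmetrically, predictions unchanged", {
  toy <- toy_separable(25, gap = 3, seed = 4)
  m1 <- train_linear_svm(toy$X, toy$y)
  Xdup <- cbind(toy$X, f1b = toy$X[, 1])
  m2 <- train_linear_svm(Xdup, toy$y)
  # exact copies are interchangeable in the convex objective: equal split
  expect_equal(m2$weights[["f1"]], m2$weights[["f1b"]], tolerance = 1e-6)
  expect_equal(predict(m2, Xdup), predict(m1, toy$X))
  expect_gt(cor(predict(m2, Xdup, type = "score"),
                predict(m1, toy$X, type = "score")), 0.999)
})

test_that("flipping the labels negates the hyperplane", {
  toy <- toy_separable(25, gap = 3, seed = 9)
  m1 <- train_linear_svm(toy$X, toy$y)
  m2 <- train_linear_svm(toy$X, 1L - toy$y)
  expect_equal(m2$weights, -m1$weights, tolerance = 1e-6)
  expect_equal(m2$intercept, -m1$intercept, tolerance = 1e-6)
  r1 <- weight_sign_report(m1)
  r2 <- weight_sign_report(m2)
  expect_equal(r2$weight[match(r1$feature, r2$feature)], -r1$weight,
               tolerance = 1e-6)
})

test_that("confusion metrics obey their defining identities on random confusion tables", {
  set.seed(3)
  for (r in 1:50) {
    cts <- as.list(sample(0:40, 4, replace = TRUE))
    names(cts) <- c("TP", "FP", "TN", "FN")
    if (cts$TP + cts$FN == 0 || cts$TN + cts$FP == 0) next
    m <- do.call(confusion_metrics, cts)
    n <- cts$TP + cts$FP + cts$TN + cts$FN
    expect_equal(m$accuracy, (cts$TN + cts$TP) / n)
    expect_equal(m$sensitivity, cts$TP / (cts$TP + cts$FN))
    expect_equal(m$specificity, cts$TN / (cts$TN + cts$FP))
    expect_equal(m$TP + m$FP + m$TN + m$FN, n)
  }
  expect_error(confusion_metrics(0, 5, 5, 0), "positive")
  expect_error(confusion_metrics(5, 0, 0, 5), "negative")
  expect_error(confusion_metrics(-1, 2, 3, 4), "nonnegative")
})

test_that("degenerate confusion tables give the expected boundary metrics", {
  perfect <- confusion_metrics(10, 0, 10, 0)
  expect_equal(c(perfect$accuracy, perfect$sensitivity, perfect$specificity),
               c(1, 1, 1))
  worst_pos <- confusion_metrics(0 + 0, 0, 10, 10)
  expect_equal(worst_pos$sensitivity, 0)
  expect_equal(worst_pos$specificity, 1)
  expect_equal(worst_pos$accuracy, 0.5)
})

test_that("AUC matches the normalised Mann-Whitney statistic and its symmetries", {
  # perfectly ordered scores
  y <- c(rep(0, 5), rep(1, 5))
  s <- 1:10
  expect_equal(roc_auc(s, y)$auc, 1)
  expect_equal(roc_auc(-s, y)$auc, 0)
  set.seed(44)
  for (r in 1:20) {
    n <- sample(10:30, 1)
    y <- rbinom(n, 1, 0.5)
    if (length(unique(y)) < 2) next
    s <- sample(round(rnorm(n), 1))  # rounded: forces ties
    out <- roc_auc(s, y)
    expect_equal(out$auc, mann_whitney_auc(s, y), tolerance = 1e-12)
    expect_equal(roc_auc(-s, y)$auc, 1 - out$auc, tolerance = 1e-12)
  }
  # label-independent scores: AUC near 1/2
  hits <- vapply(1:20, function(r) {
    set.seed(500 + r)
    y <- rep(c(0, 1), 1000)
    abs(roc_auc(rnorm(2000), y)$auc - 0.5) <= 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.95)
  expect_error(roc_auc(1:5, rep(1, 5)), "both classes")
})

test_that("LOOCV yields one held-out prediction per subject and is deterministic", {
  toy <- toy_separable(12, gap = 5, seed = 2)
  cv1 <- loocv(toy$X, toy$y)
  cv2 <- loocv(toy$X, toy$y)
  expect_equal(cv1$n, 24)
  expect_length(cv1$scores, 24)
  expect_identical(cv1$scores, cv2$scores)
  expect_equal(cv1$accuracy, 1)
  expect_equal(cv1$auc, 1)
  expect_equal(cv1$TP + cv1$FP + cv1$TN + cv1$FN, 24)
})

test_that("repeated k-fold is reproducible from its master seed", {
  toy <- toy_separable(15, gap = 2, seed = 7)
  r1 <- repeated_kfold(toy$X, toy$y, k = 5, repeats = 3, seed = 11)
  r2 <- repeated_kfold(toy$X, toy$y, k = 5, repeats = 3, seed = 11)
  r3 <- repeated_kfold(toy$X, toy$y, k = 5, repeats = 3, seed = 12)
  expect_identical(r1$performance, r2$performance)
  expect_identical(r1$weights, r2$weights)
  expect_false(identical(r1$performance, r3$performance))
  expect_error(repeated_kfold(toy$X, toy$y, k = 50, repeats = 1, seed = 1),
               "exceed")
})

test_that("stratified folds balance classes to within one subject", {
  set.seed(20)
  y <- c(rep(1L, 33), rep(0L, 47))
  fold <- icnvar:::stratified_folds(y, 10)
  expect_equal(sort(unique(fold)), 1:10)
  per_fold <- table(fold, y)
  expect_lte(diff(range(per_fold[, "1"])), 1)
  expect_lte(diff(range(per_fold[, "0"])), 1)
})

test_that("top-k frequency counts saturate and break ties canonically", {
  W <- matrix(0.1, nrow = 5, ncol = 4,
              dimnames = list(NULL, paste0("f", 1:4)))
  W[, 2] <- 5  # one dominant feature
  tk <- top_k_frequency(W, k = 1)
  expect_equal(tk$count[tk$feature == "f2"], 5)
  expect_equal(sum(tk$count), 5)
  # k = ncol: every feature counted every repeat
  tk_all <- top_k_frequency(W, k = 4)
  expect_true(all(tk_all$count == 5))
  # exact ties resolved by canonical (column) order
  W2 <- matrix(1, nrow = 2, ncol = 3, dimnames = list(NULL, c("a", "b", "c")))
  tk2 <- top_k_frequency(W2, k = 2)
  expect_equal(tk2$count[match(c("a", "b", "c"), tk2$feature)], c(2, 2, 0))
  expect_error(top_k_frequency(W, k = 10), "exceed")
})

test_that("weight reports require a trained model and orient signs by planted direction", {
  expect_error(weight_sign_report(list()), "trained")
  # patients (label 1) shifted upward in feature 1 only
  set.seed(13)
  X <- cbind(sig = c(rnorm(30, 2), rnorm(30, -2)), noise = rnorm(60))
  y <- c(rep(1L, 30), rep(0L, 30))
  rep_tab <- weight_sign_report(train_linear_svm(X, y))
  expect_equal(rep_tab$feature[1], "sig")
  expect_match(rep_tab$direction[1], "increased")
})
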