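#' Classification metrics from a confusion matrix
#'
#' Accuracy = (TN + TP) / (TN + FN + TP + FP), sensitivity = TP / (TP + FN),
#' specificity = TN / (TN + FP), with patients as the positive class.
#'
#' @param TP,FP,TN,FN Nonnegative integer counts; each true class must be
#'   non-empty.
#' @return List with `accuracy`, `sensitivity`, `specificity` and the four
#'   counts.
#' @export
confusion_metrics <- function(TP, FP, TN, FN) {
  counts <- c(TP = TP, FP = FP, TN = TN, FN = FN)
  if (any(!is.finite(counts)) || any(counts < 0) || any(counts != round(counts)))
    stop("confusion counts must be nonnegative integers", call. = FALSE)
  if (TP + FN == 0) stop("no positive instances (TP + FN = 0)", call. = FALSE)
  if (TN + FP == 0) stop("no negative instances (TN + FP = 0)", call. = FALSE)
  list(accuracy = (TN + TP) / (TN + FN + TP + FP),
       sensitivity = TP / (TP + FN),
       specificity = TN / (TN + FP),
       TP = TP, FP = FP, TN = TN, FN = FN)
}

confusion_from_predictions <- function(y, pred) {
  confusion_metrics(TP = sum(pred == 1L & y == 1L),
                    FP = sum(pred == 1L & y == 0L),
                    TN = sum(pred == 0L & y == 0L),
                    FN = sum(pred == 0L & y == 1L))
}

#' ROC curve and AUC from decision scores
#'
#' AUC is the probability that a randomly chosen positive subject scores
#' above a randomly chosen negative one (ties counted 1/2) — equivalently
#' the normalised Mann-Whitney U statistic. Computed with \pkg{pROC}.
#'
#' @param scores Numeric decision values (higher = more patient-like).
#' @param y 0/1 labels (1 = patient).
#' @return List with `auc` and `curve`, a data frame of `fpr`/`tpr` points.
#' @export
roc_auc <- function(scores, y) {
  y01 <- as_binary_labels(y)
  if (length(scores) != length(y01))
    stop("scores and labels differ in length", call. = FALSE)
  if (length(unique(y01)) < 2L)
    stop("both classes must be present", call. = FALSE)
  r <- pROC::roc(response = y01, predictor = as.numeric(scores),
                 levels = c(0, 1), direction = "<", quiet = TRUE)
  list(auc = as.numeric(r$auc),
       curve = data.frame(fpr = rev(1 - r$specificities),
                          tpr = rev(r$sensitivities)))
}

#' Leave-one-out cross-validation of the diagnostic model
#'
#' Runs n train/test iterations, each holding out one subject. The
#' standardisation and the SVM are fit on the training fold only; held-out
#' decision scores are pooled for the ROC. The procedure is deterministic:
#' no randomness enters the fold structure.
#'
#' @param X Subjects x predictors matrix.
#' @param y 0/1 labels (1 = patient).
#' @param C Soft-margin cost (default 1).
#' @return An object of class `cv_performance`: accuracy, sensitivity,
#'   specificity, `auc`, confusion counts, per-subject `scores` and
#'   `predictions`.
#' @export
loocv <- function(X, y, C = 1) {
  X <- as.matrix(X)
  y01 <- as_binary_labels(y)
  n <- nrow(X)
  if (n < 3L) stop("need at least 3 subjects for LOOCV", call. = FALSE)
  scores <- numeric(n)
  pred <- integer(n)
  for (i in seq_len(n)) {
    fit <- train_linear_svm(X[-i, , drop = FALSE], y01[-i], C = C)
    scores[i] <- predict(fit, X[i, , drop = FALSE], type = "score")
    pred[i] <- as.integer(scores[i] > 0)
  }
  cm <- confusion_from_predictions(y01, pred)
  structure(c(cm,
              list(auc = roc_auc(scores, y01)$auc,
                   scores = scores, predictions = pred, n = n,
                   method = "loocv")),
            class = "cv_performance")
}

#' @export
print.cv_performance <- function(x, ...) {
  cat(sprintf("%s: accuracy %.4f, sensitivity %.4f, specificity %.4f, AUC %.4f (n = %d)\n",
              x$method, x$accuracy, x$sensitivity, x$specificity, x$auc, x$n))
  invisible(x)
}

# Stratified fold assignment: within each class, shuffle and deal fold ids
# round-robin so fold sizes and class balance differ by at most one.
stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  for (cls in unique(y)) {
    idx <- which(y == cls)
    fold[sample(idx)] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Repeated stratified k-fold cross-validation
#'
#' For each repeat, a freshly seeded stratified partition into `k` folds is
#' drawn; each fold is held out in turn, the model is trained on the rest,
#' and the held-out confusion counts and decision scores are pooled into one
#' performance record per repeat. The repeat's weight vector is the mean of
#' its k fold-model weight vectors (in standardised units). Repeating the
#' partition many times (the reference protocol uses 1000 repeats) maps out
#' the sensitivity of the performance estimate to the random fold split.
#'
#' All randomness flows from `seed`: the same seed reproduces the identical
#' sequence of partitions and therefore identical results.
#'
#' @param X Subjects x predictors matrix.
#' @param y 0/1 labels (1 = patient).
#' @param k Number of folds (default 10).
#' @param repeats Number of repeated partitions (default 1000).
#' @param C Soft-margin cost (default 1).
#' @param seed Master seed for the partition sequence.
#' @return An object of class `repeated_cv`: `performance` (data frame with
#'   one row per repeat: accuracy, sensitivity, specificity, auc) and
#'   `weights` (repeats x predictors matrix of per-repeat mean weights).
#' @export
repeated_kfold <- function(X, y, k = 10L, repeats = 1000L, C = 1, seed = NULL) {
  X <- as.matrix(X)
  y01 <- as_binary_labels(y)
  n <- nrow(X)
  if (k > n) stop("k cannot exceed the number of subjects", call. = FALSE)
  if (k < 2L) stop("k must be >= 2", call. = FALSE)
  if (any(table(y01) < 1L))
    stop("both classes must be present", call. = FALSE)
  perf <- matrix(NA_real_, repeats, 4L,
                 dimnames = list(NULL, c("accuracy", "sensitivity",
                                         "specificity", "auc")))
  W <- matrix(NA_real_, repeats, ncol(X),
              dimnames = list(NULL, colnames(X)))
  with_seed(seed, {
    for (r in seq_len(repeats)) {
      fold <- stratified_folds(y01, k)
      pred <- integer(n)
      scores <- numeric(n)
      w_sum <- numeric(ncol(X))
      for (f in seq_len(k)) {
        test <- which(fold == f)
        fit <- train_linear_svm(X[-test, , drop = FALSE], y01[-test], C = C)
        s <- predict(fit, X[test, , drop = FALSE], type = "score")
        scores[test] <- s
        pred[test] <- as.integer(s > 0)
        w_sum <- w_sum + fit$weights
      }
      cm <- confusion_from_predictions(y01, pred)
      perf[r, ] <- c(cm$accuracy, cm$sensitivity, cm$specificity,
                     roc_auc(scores, y01)$auc)
      W[r, ] <- w_sum / k
    }
  })
  structure(list(performance = as.data.frame(perf), weights = W,
                 k = k, repeats = repeats, n = n, C = C),
            class = "repeated_cv")
}

#' @export
print.repeated_cv <- function(x, ...) {
  p <- x$performance
  cat(sprintf("repeated %d-fold CV, %d repeats (n = %d):\n", x$k, x$repeats, x$n))
  for (m in names(p))
    cat(sprintf("  %-12s %.4f +/- %.4f\n", m, mean(p[[m]]), sd(p[[m]])))
  invisible(x)
}

#' Top-k weight-frequency report across CV repeats
#'
#' For each repeat, features are ranked by absolute weight and the top `k`
#' recorded; the report counts, per feature, how many repeats placed it in
#' the top `k`, alongside its mean signed weight. Ties in |weight| are
#' broken by canonical feature order (earlier feature wins).
#'
#' @param weights A repeats x features matrix, or a `repeated_cv` object.
#' @param k Size of the per-repeat top set (default 10).
#' @return Data frame with `feature`, `count` (in [0, repeats]) and
#'   `mean_weight`, ordered by decreasing count.
#' @export
top_k_frequency <- function(weights, k = 10L) {
  if (inherits(weights, "repeated_cv")) weights <- weights$weights
  W <- as.matrix(weights)
  if (k > ncol(W)) stop("k cannot exceed the number of features", call. = FALSE)
  if (anyNA(W)) stop("weight matrix contains missing values", call. = FALSE)
  feats <- colnames(W) %||% paste0("f", seq_len(ncol(W)))
  counts <- integer(ncol(W))
  for (r in seq_len(nrow(W))) {
    top <- order(-abs(W[r, ]), seq_len(ncol(W)))[seq_len(k)]
    counts[top] <- counts[top] + 1L
  }
  out <- data.frame(feature = feats, count = counts,
                    mean_weight = colMeans(W), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out[order(-out$count, seq_len(nrow(out))), , drop = FALSE]
}
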