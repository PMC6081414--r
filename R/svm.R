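#' Train the linear-SVM diagnostic model
#'
#' Fits a linear maximum-margin classifier (soft margin, cost `C`) on
#' z-scored predictors and extracts the primal weight vector and intercept,
#' oriented so that a positive decision score `w . x_std + b` predicts the
#' positive class (label 1 = patient). Standardisation statistics are
#' estimated from the training data only and stored in the model, so
#' held-out subjects are scored without information leakage; weights are
#' therefore expressed in standardised-feature units and are directly
#' comparable across predictors.
#'
#' The optimiser is the exact SMO-type solver in [e1071::svm()] (libsvm);
#' any exact solver of the same convex objective reaches the same optimum.
#'
#' @param X Numeric matrix, subjects x predictors.
#' @param y Labels coercible to 0/1 (1 = patient/positive class).
#' @param C Soft-margin cost (default 1).
#' @param standardize Z-score the predictors using training statistics
#'   (default `TRUE`). Zero-variance predictors are centred but left
#'   unscaled.
#' @return An object of class `diagnostic_model`: weights (named),
#'   intercept, centring/scaling vectors, and `C`.
#' @export
train_linear_svm <- function(X, y, C = 1, standardize = TRUE) {
  X <- as.matrix(X)
  y01 <- as_binary_labels(y)
  if (length(unique(y01)) < 2L)
    stop("training data contain a single class", call. = FALSE)
  if (min(table(y01)) < 2L)
    stop("need at least 2 samples per class", call. = FALSE)
  if (anyNA(X) || !all(is.finite(X)))
    stop("predictors contain missing or non-finite values", call. = FALSE)
  stopifnot_scalar(C, "C", positive = TRUE)

  if (standardize) {
    center <- colMeans(X)
    scale_ <- apply(X, 2L, sd)
    scale_[scale_ == 0] <- 1
  } else {
    center <- rep(0, ncol(X))
    scale_ <- rep(1, ncol(X))
  }
  Xs <- sweep(sweep(X, 2L, center), 2L, scale_, "/")

  yf <- factor(y01, levels = c(0L, 1L))
  fit <- e1071::svm(Xs, yf, kernel = "linear", cost = C, scale = FALSE)
  w <- drop(t(fit$coefs) %*% fit$SV)
  b <- -fit$rho
  # Orient the hyperplane so score > 0 <=> predicted class 1.
  pred <- predict(fit, Xs)
  score <- drop(Xs %*% w) + b
  agree <- mean((score > 0) == (pred == "1"))
  if (agree < 0.5) {
    w <- -w
    b <- -b
  }
  names(w) <- colnames(X)
  structure(list(weights = w, intercept = b, center = center,
                 scale = scale_, C = C, n_train = nrow(X)),
            class = "diagnostic_model")
}

as_binary_labels <- function(y) {
  if (is.factor(y)) y <- as.character(y)
  if (is.character(y)) {
    u <- sort(unique(y))
    if (setequal(u, c("0", "1"))) return(as.integer(y))
    if (setequal(tolower(u), c("control", "patient")))
      return(as.integer(tolower(y) == "patient"))
    stop("labels must be 0/1 or control/patient", call. = FALSE)
  }
  y <- as.integer(y)
  if (!all(y %in% c(0L, 1L)))
    stop("labels must be 0/1 (1 = patient)", call. = FALSE)
  y
}

#' Predict from a diagnostic model
#'
#' @param object A `diagnostic_model`.
#' @param newdata Matrix (or vector) of predictors on the original scale.
#' @param type `"class"` for 0/1 labels, `"score"` for the signed distance
#'   proxy `w . x_std + b` (positive = patient side of the hyperplane).
#' @param ... Unused.
#' @return Integer labels or numeric scores.
#' @export
predict.diagnostic_model <- function(object, newdata,
                                     type = c("class", "score"), ...) {
  type <- match.arg(type)
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1L)
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != length(object$weights))
    stop(sprintf("expected %d predictors, got %d", length(object$weights),
                 ncol(newdata)), call. = FALSE)
  Xs <- sweep(sweep(newdata, 2L, object$center), 2L, object$scale, "/")
  score <- drop(Xs %*% object$weights) + object$intercept
  if (type == "score") score else as.integer(score > 0)
}

#' @export
print.diagnostic_model <- function(x, ...) {
  cat(sprintf("Linear-SVM diagnostic model: %d predictors, C = %g, trained on n = %d\n",
              length(x$weights), x$C, x$n_train))
  top <- sort(abs(x$weights), decreasing = TRUE)[seq_len(min(5L, length(x$weights)))]
  cat("largest |weights|:", paste(sprintf("%s (%.3f)", names(top),
                                          x$weights[names(top)]),
                                  collapse = ", "), "\n")
  invisible(x)
}

#' Signed discriminative-weight report
#'
#' Tabulates each predictor's signed weight with its interpretation under
#' the label convention 1 = patient: a positive weight marks a feature
#' elevated in patients, a negative weight one reduced in patients.
#'
#' @param model A trained `diagnostic_model`.
#' @return Data frame with `feature`, `weight` and `direction`, ordered by
#'   decreasing |weight|.
#' @export
weight_sign_report <- function(model) {
  if (!inherits(model, "diagnostic_model") || is.null(model$weights) ||
      length(model$weights) == 0L)
    stop("`model` must be a trained diagnostic_model", call. = FALSE)
  out <- data.frame(
    feature = names(model$weights),
    weight = unname(model$weights),
    direction = ifelse(model$weights > 0, "increased in patients",
                       ifelse(model$weights < 0, "decreased in patients",
                              "no contribution")),
    stringsAsFactors = FALSE
  )
  out[order(-abs(out$weight)), , drop = FALSE]
}
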