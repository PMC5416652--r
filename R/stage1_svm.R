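# Stage-1 classifier: a soft-margin SVM (max-margin hyperplane
# min 1/2 ||w||^2 s.t. y_i (w'x_i - b) >= 1, solved in the dual by libsvm
# through e1071) that separates deep red tongues from the red/light-red
# group using clustering-identifier features. Feature selection via the
# identifiers is what keeps the support-vector count - and hence prediction
# cost - low.

#' @rdname stage1_labels
#' @export
STAGE1_DEEP_RED <- "deep_red"
#' Stage-1 class labels
#'
#' The first stage is binary: `deep_red` versus the pooled
#' `red_or_light_red` group (resolved later by the colour-range rules).
#' @rdname stage1_labels
#' @export
STAGE1_RED_OR_LIGHT <- "red_or_light_red"

# Collapse 3-class truth to the stage-1 binary label.
stage1_label <- function(labels) {
  ifelse(labels == "deep_red", STAGE1_DEEP_RED, STAGE1_RED_OR_LIGHT)
}

.map_kernel <- function(kernel) {
  switch(kernel,
    linear = list(kernel = "linear", degree = 3L),
    rbf = list(kernel = "radial", degree = 3L),
    polynomial = list(kernel = "polynomial", degree = 3L),
    quadratic = list(kernel = "polynomial", degree = 2L),
    stop("unknown kernel: ", kernel,
         " (use linear, rbf, polynomial or quadratic)")
  )
}

#' Train the stage-1 SVM
#'
#' Fits a soft-margin SVM on z-score-standardised features. Standardisation
#' parameters are estimated on the training data only and frozen into the
#' model, so prediction applies exactly the training-time transform.
#' `"quadratic"` is a degree-2 polynomial kernel; `"polynomial"` defaults to
#' degree 3.
#'
#' @param X numeric feature matrix (rows = images).
#' @param y labels: 3-class labels are collapsed to the binary stage-1 task,
#'   or pass `deep_red` / `red_or_light_red` directly.
#' @param kernel one of `"linear"`, `"rbf"`, `"polynomial"`, `"quadratic"`.
#' @param C soft-margin penalty.
#' @param seed integer recorded in the model metadata (the libsvm fit itself
#'   is deterministic given the data).
#' @param ... further solver controls passed to [e1071::svm()] (for example
#'   a tighter `tolerance` for margin diagnostics).
#' @return Object of class `stage1_svm` with the fitted model, the frozen
#'   scaler, `support_vector_count` and training metadata.
#' @export
train_stage1 <- function(X, y, kernel = "linear", C = 1, seed = 0L, ...) {
  X <- as.matrix(X)
  if (anyNA(X) || any(!is.finite(X))) stop("features must be finite (no NaN/NA)")
  y <- stage1_label(as.character(y))
  if (length(y) != nrow(X)) stop("X and y lengths differ")
  if (length(unique(y)) < 2L) {
    stop("training error: both stage-1 classes must be present")
  }
  center <- colMeans(X)
  scale_ <- apply(X, 2, stats::sd)
  scale_[scale_ < 1e-12] <- 1
  Xs <- scale(X, center = center, scale = scale_)
  kern <- .map_kernel(kernel)
  yf <- factor(y, levels = c(STAGE1_RED_OR_LIGHT, STAGE1_DEEP_RED))
  fit <- e1071::svm(x = Xs, y = yf, kernel = kern$kernel,
                    degree = kern$degree, cost = C, scale = FALSE, ...)
  structure(list(
    fit = fit, center = center, scale = scale_,
    kernel = kernel, C = C, seed = seed,
    support_vector_count = fit$tot.nSV,
    n_train = nrow(X), feature_names = colnames(X)
  ), class = "stage1_svm")
}

#' Predict stage-1 labels
#'
#' @param model a `stage1_svm`.
#' @param X feature matrix or single feature vector with the training
#'   dimensionality.
#' @param decision_values also return the signed decision-function values as
#'   an attribute.
#' @return Character vector of `deep_red` / `red_or_light_red` labels.
#' @export
predict_stage1 <- function(model, X, decision_values = FALSE) {
  X <- rbind(X)
  if (ncol(X) != length(model$center)) {
    stop("feature dimension mismatch: model was trained on ",
         length(model$center), " features")
  }
  Xs <- scale(X, center = model$center, scale = model$scale)
  pred <- stats::predict(model$fit, Xs, decision.values = decision_values)
  out <- as.character(pred)
  if (decision_values) {
    attr(out, "decision_values") <- as.numeric(attr(pred, "decision.values"))
  }
  out
}

#' Number of support vectors of a fitted stage-1 model
#'
#' Training points with nonzero dual coefficient. Classification cost scales
#' with this count, which is why identifier features (which collapse each
#' image to two informative cluster colours) beat raw pixels on speed.
#'
#' @param model a `stage1_svm`.
#' @return Integer count.
#' @export
count_support_vectors <- function(model) {
  if (!inherits(model, "stage1_svm") || is.null(model$fit)) {
    stop("not a fitted stage1_svm model")
  }
  model$support_vector_count
}

# Explicit (w, b) of a linear-kernel model on the standardised scale;
# used for margin diagnostics and cross-checks.
linear_hyperplane <- function(model) {
  stopifnot(model$kernel == "linear")
  w <- drop(t(model$fit$coefs) %*% model$fit$SV)
  list(w = w, b = model$fit$rho)
}

#' @export
print.stage1_svm <- function(x, ...) {
  cat(sprintf(
    "<stage1_svm> kernel = %s, C = %g, %d support vectors (of %d)\n",
    x$kernel, x$C, x$support_vector_count, x$n_train))
  invisible(x)
}

#' Classification accuracy rate and confusion counts
#'
#' The accuracy rate is the percentage of correctly classified images,
#' `ACC = 100 * (n_redlight + n_deepred) / N` in the binary stage; the same
#' count-based rate generalises to the 3-class cascade output.
#'
#' @param predicted,truth equal-length label vectors.
#' @param support_vector_count optional count carried into the report.
#' @return Object of class `eval_result`: `accuracy_pct`, `confusion`
#'   (truth in rows, prediction in columns), `n_correct` per class, `N`.
#' @examples
#' classification_accuracy(c("red", "red"), c("red", "light_red"))$accuracy_pct
#' @export
classification_accuracy <- function(predicted, truth,
                                    support_vector_count = NA_integer_) {
  if (length(predicted) != length(truth)) stop("length mismatch")
  N <- length(truth)
  if (N == 0L) stop("no observations")
  lev <- sort(unique(c(predicted, truth)))
  confusion <- table(truth = factor(truth, lev),
                     predicted = factor(predicted, lev))
  n_correct <- diag(confusion)
  structure(list(
    accuracy_pct = 100 * sum(predicted == truth) / N,
    confusion = confusion,
    n_correct = n_correct,
    N = N,
    support_vector_count = support_vector_count
  ), class = "eval_result")
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf("<eval_result> accuracy = %.1f%% (N = %d)\n",
              x$accuracy_pct, x$N))
  print(x$confusion)
  if (!is.na(x$support_vector_count)) {
    cat("support vectors:", x$support_vector_count, "\n")
  }
  invisible(x)
}

#' Write an evaluation report
#'
#' Serialises an `eval_result` (plus arbitrary metadata such as kernel, C
#' and split protocol) as JSON, and the confusion matrix as CSV alongside,
#' so kernel-comparison tables can be assembled by scripts.
#'
#' @param result an `eval_result`.
#' @param path output path for the JSON report; the confusion CSV gets the
#'   same stem with `_confusion.csv`.
#' @param meta named list of extra fields.
#' @return `path`, invisibly.
#' @export
write_eval_report <- function(result, path, meta = list()) {
  payload <- c(list(
    accuracy_pct = result$accuracy_pct,
    N = result$N,
    n_correct = as.list(result$n_correct),
    support_vector_count = result$support_vector_count
  ), meta)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  utils::write.csv(as.data.frame.matrix(result$confusion),
                   sub("\\.json$", "_confusion.csv", path))
  invisible(path)
}
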