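#' SVM hyperparameters for the per-image diagnosis test
#'
#' The classifier is a soft-margin support vector machine with an RBF
#' kernel (via the LIBSVM binding in \pkg{e1071}). RGB features are rescaled
#' from \[0, 255\] to \[0, 1\] before training; `gamma = NULL` applies the
#' common heuristic `1 / (d * var(features))` with `d = 3` computed on the
#' pooled rescaled training features.
#'
#' @param cost Soft-margin cost parameter C.
#' @param gamma RBF kernel width, or `NULL` for the variance heuristic.
#' @param kernel Kernel name passed to [e1071::svm()].
#' @param feature_scale Divisor applied to RGB features before training.
#' @return A list of class `svm_params`.
#' @export
svm_params <- function(cost = 1, gamma = NULL, kernel = "radial",
                       feature_scale = 255) {
  structure(list(cost = cost, gamma = gamma, kernel = kernel,
                 feature_scale = feature_scale),
            class = "svm_params")
}

#' Split a labeled sample table into training and test sets
#'
#' Per class, `n_train_per_class` samples are drawn uniformly without
#' replacement for training and all remaining samples form the test set
#' (a single fixed split per image; the standard design takes 100 of 2000
#' per class for training, leaving 1900 + 1900 = 3800 test samples).
#'
#' @param samples A labeled pixel tibble with a `label` column holding
#'   `"cancer"` and `"noncancer"`.
#' @param n_train_per_class Training samples per class (default 100); must
#'   be strictly smaller than each class size.
#' @param seed Integer seed; the split is deterministic given the seed.
#' @return The input tibble with a `set` column (`"train"`/`"test"`).
#' @export
split_train_test <- function(samples, n_train_per_class = 100, seed = 1L) {
  n_train_per_class <- stopifnot_scalar_count(n_train_per_class,
                                              "n_train_per_class")
  sizes <- table(samples$label)
  for (lb in c("cancer", "noncancer")) {
    n_lb <- if (lb %in% names(sizes)) sizes[[lb]] else 0L
    if (n_lb <= n_train_per_class) {
      abort(sprintf(
        "Class '%s' has %d samples; more than n_train_per_class = %d are required.",
        lb, n_lb, n_train_per_class), class = "chromsep_split_error")
    }
  }
  with_seed(seed, {
    samples$set <- "test"
    for (lb in unique(samples$label)) {
      idx <- which(samples$label == lb)
      samples$set[idx[sample.int(length(idx), n_train_per_class)]] <- "train"
    }
    samples
  })
}

#' Train the per-image pixel classifier
#'
#' Fits the RBF-kernel SVM on the rescaled RGB features of the training
#' samples. Training is deterministic for fixed inputs.
#'
#' @param train A labeled tibble of training samples (`label`, `R`, `G`, `B`).
#' @param params An [svm_params()] object.
#' @return A `pixel_classifier` wrapping the fitted SVM; use
#'   `predict(classifier, samples)` to get `"cancer"`/`"noncancer"` labels.
#' @export
train_pixel_classifier <- function(train, params = svm_params()) {
  stopifnot(inherits(params, "svm_params"))
  x <- as.matrix(train[, c("R", "G", "B")]) / params$feature_scale
  y <- factor(train$label, levels = c("cancer", "noncancer"))
  if (any(table(y) == 0)) {
    abort("Both classes must be present in the training set.",
          class = "chromsep_training_error")
  }
  if (all(apply(x, 2, function(col) length(unique(col)) == 1))) {
    abort("Training data are degenerate: every sample is identical.",
          class = "chromsep_training_error")
  }
  gamma <- params$gamma %||% 1 / (ncol(x) * stats::var(as.vector(x)))
  fit <- e1071::svm(x, y, kernel = params$kernel, cost = params$cost,
                    gamma = gamma, scale = FALSE)
  structure(list(fit = fit, params = params, gamma = gamma),
            class = "pixel_classifier")
}

#' @export
predict.pixel_classifier <- function(object, newdata, ...) {
  x <- as.matrix(newdata[, c("R", "G", "B")]) / object$params$feature_scale
  as.character(predict(object$fit, x))
}

#' Score predictions against ground truth
#'
#' Confusion counts and derived scores with cancer as the positive class:
#' sensitivity (recall) `tp / (tp + fn)`, positive predictive value
#' (precision) `tp / (tp + fp)`, and their harmonic mean, the F1 measure —
#' the per-image diagnosability score. With no true positives, sensitivity,
#' PPV (when undefined) and F1 are all 0, so degenerate classifiers score
#' worst rather than erroring.
#'
#' @param predictions,truths Equal-length character vectors of
#'   `"cancer"`/`"noncancer"` labels.
#' @return A one-row tibble: `tp`, `fp`, `tn`, `fn`, `sensitivity`, `ppv`,
#'   `f1`.
#' @export
#' @examples
#' evaluate_predictions(c("cancer", "cancer", "noncancer"),
#'                      c("cancer", "noncancer", "noncancer"))
evaluate_predictions <- function(predictions, truths) {
  if (length(predictions) != length(truths)) {
    abort(sprintf("Got %d predictions for %d truths.",
                  length(predictions), length(truths)),
          class = "chromsep_evaluation_error")
  }
  tp <- sum(predictions == "cancer" & truths == "cancer")
  fp <- sum(predictions == "cancer" & truths == "noncancer")
  tn <- sum(predictions == "noncancer" & truths == "noncancer")
  fn <- sum(predictions == "noncancer" & truths == "cancer")
  sensitivity <- if (tp + fn > 0) tp / (tp + fn) else 0
  ppv <- if (tp + fp > 0) tp / (tp + fp) else 0
  f1 <- if (sensitivity + ppv > 0) {
    2 * sensitivity * ppv / (sensitivity + ppv)
  } else 0
  tibble(tp = tp, fp = fp, tn = tn, fn = fn,
         sensitivity = sensitivity, ppv = ppv, f1 = f1)
}

#' Per-image SVM diagnosis test
#'
#' The full diagnosability assessment for one image's sample table: split
#' each class into training and held-out test samples, train the SVM on the
#' training samples, classify the test samples, and score with sensitivity,
#' PPV and F1.
#'
#' @param samples Labeled pixel tibble (e.g. from
#'   [luminance_matched_sample()]).
#' @param n_train_per_class Training samples per class (default 100).
#' @param seed Seed for the train/test split.
#' @param params [svm_params()].
#' @return A one-row tibble: `n_train`, `n_test`, `tp`, `fp`, `tn`, `fn`,
#'   `sensitivity`, `ppv`, `f1`.
#' @export
svm_diagnosis <- function(samples, n_train_per_class = 100, seed = 1L,
                          params = svm_params()) {
  split <- split_train_test(samples, n_train_per_class, seed = seed)
  train <- split[split$set == "train", ]
  test <- split[split$set == "test", ]
  clf <- train_pixel_classifier(train, params = params)
  scores <- evaluate_predictions(predict(clf, test), test$label)
  dplyr::bind_cols(tibble(n_train = nrow(train), n_test = nrow(test)), scores)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
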