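#' Specify the classifier used for selection and evaluation
#'
#' Defaults mirror the published configuration: linear kernel, C = 1,
#' gamma = "scale", one-vs-rest decision scheme. An optional `grid` (named
#' list of candidate values per parameter, e.g.
#' `list(C = c(0.1, 1, 10), kernel = c("linear", "rbf"))`) widens the
#' cross-validated search performed by [grid_search_train()].
#'
#' @param kernel `"linear"` or `"rbf"`.
#' @param C Positive soft-margin cost.
#' @param gamma `"scale"` (1 / (p * var(x)), the scikit-learn convention) or
#'   a positive number; only used by the rbf kernel.
#' @param decision_scheme Only `"one-vs-rest"` is supported: per-class
#'   decision scores are aggregated one class against the rest.
#' @param grid Optional named list of candidate parameter values.
#' @return An object of class `ClassifierSpec`.
#' @export
classifier_spec <- function(kernel = c("linear", "rbf"), C = 1,
                            gamma = "scale",
                            decision_scheme = "one-vs-rest",
                            grid = NULL) {
  kernel <- match.arg(kernel)
  if (!identical(decision_scheme, "one-vs-rest"))
    stop("only the one-vs-rest decision scheme is supported")
  if (!is.numeric(C) || C <= 0) stop("C must be positive")
  if (!identical(gamma, "scale") && (!is.numeric(gamma) || gamma <= 0))
    stop("gamma must be \"scale\" or a positive number")
  structure(list(kernel = kernel, C = C, gamma = gamma,
                 decision_scheme = decision_scheme, grid = grid),
            class = "ClassifierSpec")
}

.resolve_gamma <- function(gamma, x) {
  if (identical(gamma, "scale")) {
    v <- mean((x - mean(x))^2)
    if (v == 0) v <- 1
    1 / (ncol(x) * v)
  } else gamma
}

#' Fit the support vector classifier
#'
#' Thin wrapper over [e1071::svm()] with the package's conventions: no
#' internal rescaling (standardization is an explicit pipeline stage) and
#' parameters taken from a [classifier_spec()].
#'
#' @param x Numeric feature matrix (samples x genes).
#' @param y Factor of class labels.
#' @param spec A `ClassifierSpec`.
#' @return The fitted `svm` model.
#' @export
fit_classifier <- function(x, y, spec = classifier_spec()) {
  y <- droplevels(as.factor(y))
  e1071::svm(x, y, kernel = spec$kernel, cost = spec$C,
             gamma = .resolve_gamma(spec$gamma, x),
             scale = FALSE, probability = FALSE)
}

#' Predict labels and per-class decision scores
#'
#' Aggregates the pairwise decision values of the underlying model into one
#' score per class (the sum of signed pairwise margins in which the class
#' participates), giving a one-vs-rest style score matrix usable for ROC
#' analysis; AUC only depends on the ranking of scores.
#'
#' @param model A fitted `svm` model.
#' @param x Feature matrix to predict.
#' @return List with `labels` (factor) and `scores` (samples x classes
#'   matrix).
#' @export
predict_with_scores <- function(model, x) {
  pred <- stats::predict(model, x, decision.values = TRUE)
  dv <- attr(pred, "decision.values")
  classes <- model$levels
  scores <- matrix(0, nrow(x), length(classes),
                   dimnames = list(rownames(x), classes))
  for (j in seq_len(ncol(dv))) {
    pair <- strsplit(colnames(dv)[j], "/", fixed = TRUE)[[1L]]
    scores[, pair[1L]] <- scores[, pair[1L]] + dv[, j]
    scores[, pair[2L]] <- scores[, pair[2L]] - dv[, j]
  }
  list(labels = factor(as.character(pred), levels = classes),
       scores = scores)
}
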