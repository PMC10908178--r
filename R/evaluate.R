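#' Cross-validated grid search and refit
#'
#' Expands the parameter grid of `spec` (a singleton grid -- just the
#' spec's own parameters -- when `spec$grid` is `NULL`), scores every grid
#' point by mean macro-F1 over stratified cross-validation folds of the
#' training data, refits the winner on all of it, and returns the fitted
#' model with the chosen parameters. Deterministic given `seed`; a
#' singleton grid skips cross-validation since the winner is forced.
#'
#' @param train An `ExpressionDataset`.
#' @param spec A [classifier_spec()], optionally with a `grid`.
#' @param folds Number of CV folds (>= 2).
#' @param seed Integer seed for the fold assignment.
#' @return List with `model` (fitted svm), `params` (chosen kernel, C,
#'   gamma) and `cv_scores` (data frame of grid points and mean macro-F1;
#'   `NULL` for a singleton grid).
#' @export
grid_search_train <- function(train, spec = classifier_spec(), folds = 5L,
                              seed = 1L) {
  if (folds < 2L) stop("folds must be >= 2")
  grid <- spec$grid
  base <- list(kernel = spec$kernel, C = spec$C, gamma = spec$gamma)
  if (is.null(grid)) grid <- list()
  for (p in names(base)) if (is.null(grid[[p]])) grid[[p]] <- base[[p]]
  points <- expand.grid(kernel = grid$kernel, C = grid$C,
                        gamma = grid$gamma, stringsAsFactors = FALSE,
                        KEEP.OUT.ATTRS = FALSE)
  y <- train$labels
  classes <- levels(y)
  counts <- table(y)
  if (any(counts > 0 & counts < folds))
    stop("class(es) with fewer samples than folds: ",
         paste(names(counts)[counts > 0 & counts < folds], collapse = ", "))
  cv_scores <- NULL
  if (nrow(points) == 1L) {
    winner <- points[1L, ]
  } else {
    fold_id <- integer(length(y))
    with_seed(seed, for (cl in classes) {
      idx <- sample(which(y == cl))
      fold_id[idx] <- rep_len(seq_len(folds), length(idx))
    })
    score <- numeric(nrow(points))
    for (g in seq_len(nrow(points))) {
      sp <- classifier_spec(kernel = points$kernel[g], C = points$C[g],
                            gamma = if (points$gamma[g] == "scale") "scale"
                                    else as.numeric(points$gamma[g]))
      fold_f1 <- vapply(seq_len(folds), function(f) {
        tr <- fold_id != f
        model <- fit_classifier(train$values[tr, , drop = FALSE], y[tr], sp)
        pred <- stats::predict(model, train$values[!tr, , drop = FALSE])
        .macro_f1(y[!tr], pred, classes)
      }, numeric(1))
      score[g] <- mean(fold_f1)
    }
    cv_scores <- cbind(points, mean_macro_f1 = score)
    winner <- points[which.max(score), ]  # ties: first grid point
  }
  final_spec <- classifier_spec(
    kernel = winner$kernel, C = winner$C,
    gamma = if (identical(winner$gamma, "scale")) "scale"
            else as.numeric(winner$gamma))
  model <- fit_classifier(train$values, y, final_spec)
  list(model = model,
       params = list(kernel = winner$kernel, C = winner$C,
                     gamma = winner$gamma,
                     decision_scheme = spec$decision_scheme),
       cv_scores = cv_scores)
}

#' Evaluate a gene subset on an independent cohort split
#'
#' The second-pipeline evaluation: optionally standardize, restrict both
#' parts to `subset`, grid-search-train on the training part, predict the
#' test part, and assemble the full report -- multiclass confusion matrix,
#' per-subtype one-vs-rest metrics, per-subtype ROC curves with AUC, and
#' the macro-mean AUC used to rank subsets.
#'
#' @param train,test `ExpressionDataset` parts of the evaluation cohort.
#' @param subset Character vector of gene symbols (a full signature is just
#'   the size-`|sig|` subset).
#' @param spec A [classifier_spec()] for the grid search.
#' @param folds,seed Passed to [grid_search_train()].
#' @param scaler_policy `"cohort"` (default) fits the standard scaler on
#'   train and test pooled, mirroring a pipeline that normalizes the whole
#'   cohort before splitting; `"train"` fits on the training part only
#'   (leakage-free); `"none"` assumes pre-standardized input.
#' @return An object of class `EvalReport`: list with `class_order`,
#'   `confusion`, `metrics` (per-class data frame with columns class,
#'   accuracy, precision, recall, f1, auc), `overall_accuracy`, `macro_f1`,
#'   `macro_auc`, `roc` (per-class point data frames), `predicted`, `true`,
#'   `scores`, `params`, `subset`.
#' @export
evaluate_subset <- function(train, test, subset, spec = classifier_spec(),
                            folds = 5L, seed = 1L,
                            scaler_policy = c("cohort", "train", "none")) {
  scaler_policy <- match.arg(scaler_policy)
  genes_avail <- intersect(gene_ids(train), gene_ids(test))
  dropped <- setdiff(subset, genes_avail)
  if (length(dropped)) {
    warning("subset gene(s) absent from a cohort dropped: ",
            paste(dropped, collapse = ", "))
    subset <- intersect(subset, genes_avail)
  }
  if (!length(subset)) stop("no subset genes present in both cohort parts")
  if (scaler_policy != "none") {
    scaler <- if (scaler_policy == "cohort") {
      pooled <- expression_dataset(
        rbind(train$values[, genes_avail, drop = FALSE],
              test$values[, genes_avail, drop = FALSE]),
        c(as.character(train$labels), as.character(test$labels)),
        cohort_name = train$cohort,
        sample_ids = make.unique(c(sample_ids(train), sample_ids(test))),
        label_set = levels(train$labels))
      fit_scaler(pooled)
    } else {
      fit_scaler(train)
    }
    train <- scale_dataset(train, scaler, warn_constant = FALSE)
    test <- scale_dataset(test, scaler, warn_constant = FALSE)
  }
  sub_train <- train; sub_train$values <- train$values[, subset, drop = FALSE]
  fit <- grid_search_train(sub_train, spec, folds = folds, seed = seed)
  pred <- predict_with_scores(fit$model, test$values[, subset, drop = FALSE])
  classes <- levels(train$labels)
  cm <- confusion(test$labels, pred$labels, classes)
  met <- ovr_metrics(cm, warn = FALSE)
  roc <- lapply(classes, function(cl)
    roc_auc(test$labels == cl, pred$scores[, cl]))
  names(roc) <- classes
  auc <- vapply(roc, `[[`, numeric(1), "auc")
  metrics <- met$per_class
  metrics$auc <- auc[metrics$class]
  structure(list(class_order = classes,
                 confusion = cm,
                 metrics = metrics,
                 overall_accuracy = met$overall_accuracy,
                 macro_f1 = met$macro_f1,
                 macro_auc = mean(auc),
                 roc = lapply(roc, `[[`, "points"),
                 predicted = pred$labels,
                 true = test$labels,
                 scores = pred$scores,
                 params = fit$params,
                 subset = subset),
            class = "EvalReport")
}

#' @export
print.EvalReport <- function(x, ...) {
  cat(sprintf("EvalReport: %d genes, %d test samples\n",
              length(x$subset), length(x$true)))
  cat(sprintf("overall accuracy %.3f, macro-F1 %.3f, macro AUC %.3f\n",
              x$overall_accuracy, x$macro_f1, x$macro_auc))
  print(format_metrics_table(x), row.names = FALSE)
  invisible(x)
}

#' Flat metrics table in the conventional results layout
#'
#' One row per subtype with columns Acc / Prec / Rec / F1 / AUC; the Acc
#' column repeats the overall multiclass accuracy on every row.
#'
#' @param report An `EvalReport`.
#' @param digits Rounding for display; `NULL` leaves values untouched.
#' @return A data frame.
#' @export
format_metrics_table <- function(report, digits = 3L) {
  m <- report$metrics
  out <- data.frame(subtype = m$class,
                    Acc = report$overall_accuracy,
                    Prec = m$precision, Rec = m$recall,
                    F1 = m$f1, AUC = m$auc)
  if (!is.null(digits))
    out[-1L] <- lapply(out[-1L], round, digits = digits)
  out
}

#' Serialize an evaluation report
#'
#' Writes `<stem>_metrics.tsv` (the [format_metrics_table()] layout),
#' `<stem>_roc.tsv` (long table of per-class ROC points),
#' `<stem>_confusion.tsv` and `<stem>.json` (everything machine-readable).
#'
#' @param report An `EvalReport`.
#' @param stem Output path stem (no extension).
#' @return Character vector of the files written, invisibly.
#' @export
write_eval_report <- function(report, stem) {
  files <- paste0(stem, c("_metrics.tsv", "_roc.tsv", "_confusion.tsv",
                          ".json"))
  utils::write.table(format_metrics_table(report, digits = NULL), files[1L],
                     sep = "\t", quote = FALSE, row.names = FALSE)
  roc_long <- do.call(rbind, lapply(report$class_order, function(cl)
    cbind(class = cl, report$roc[[cl]])))
  utils::write.table(roc_long, files[2L], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(report$confusion$matrix, files[3L], sep = "\t",
                     quote = FALSE, col.names = NA)
  jsonlite::write_json(
    list(subset = report$subset,
         params = report$params,
         overall_accuracy = report$overall_accuracy,
         macro_f1 = report$macro_f1,
         macro_auc = report$macro_auc,
         metrics = report$metrics,
         confusion = report$confusion$matrix),
    files[4L], auto_unbox = TRUE, digits = NA, matrix = "rowmajor")
  invisible(files)
}
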