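#' Multiclass confusion counts
#'
#' Builds the full multiclass confusion matrix `counts[true, predicted]` and
#' derives, for every class, the one-vs-rest (OvR) true/false
#' positive/negative counts.
#'
#' @param true,predicted Vectors of equal length with values in
#'   `class_order`.
#' @param class_order Character vector fixing the class ordering.
#' @return An object of class `ConfusionCounts`: list with `matrix` (K x K
#'   integer matrix), `ovr` (data frame with columns class, TP, TN, FP, FN),
#'   and `n`.
#' @export
confusion <- function(true, predicted, class_order = levels(as.factor(true))) {
  true <- as.character(true)
  predicted <- as.character(predicted)
  if (length(true) != length(predicted))
    stop("true and predicted labels must have equal length")
  bad <- setdiff(unique(c(true, predicted)), class_order)
  if (length(bad))
    stop("label(s) outside class_order: ", paste(bad, collapse = ", "))
  tf <- factor(true, levels = class_order)
  pf <- factor(predicted, levels = class_order)
  m <- table(true = tf, predicted = pf)
  m <- matrix(as.integer(m), nrow = length(class_order),
              dimnames = list(true = class_order, predicted = class_order))
  n <- length(true)
  tp <- diag(m)
  fn <- rowSums(m) - tp
  fp <- colSums(m) - tp
  tn <- n - tp - fn - fp
  structure(list(matrix = m,
                 ovr = data.frame(class = class_order, TP = tp, TN = tn,
                                  FP = fp, FN = fn, row.names = NULL),
                 n = n),
            class = "ConfusionCounts")
}

#' @export
print.ConfusionCounts <- function(x, ...) {
  print(x$matrix)
  invisible(x)
}

#' F1 score from precision and recall
#'
#' Harmonic mean, `2 * P * R / (P + R)`; defined as 0 when both are 0.
#'
#' @param precision,recall Numeric values in \[0, 1\].
#' @return The F1 score.
#' @export
f1_score <- function(precision, recall) {
  ifelse(precision + recall == 0, 0,
         2 * precision * recall / (precision + recall))
}

#' Per-class one-vs-rest metrics
#'
#' Applies the standard binary formulas to each class's OvR counts:
#' accuracy (TP+TN)/n, precision TP/(TP+FP), recall TP/(TP+FN) and their
#' harmonic mean F1. Zero-denominator precision or recall is reported as 0
#' (optionally with a warning). `overall_accuracy` is the multiclass
#' accuracy trace/n -- the single number conventionally repeated in every
#' subtype column of a results row.
#'
#' @param counts A [confusion()] object.
#' @param warn Warn on zero-denominator precision/recall.
#' @return List with `per_class` (data frame: class, accuracy, precision,
#'   recall, f1), `overall_accuracy` and `macro_f1`.
#' @export
ovr_metrics <- function(counts, warn = TRUE) {
  o <- counts$ovr
  n <- counts$n
  prec_den <- o$TP + o$FP
  rec_den <- o$TP + o$FN
  if (warn && any(prec_den == 0 | rec_den == 0))
    warning("zero-denominator precision/recall reported as 0 for class(es): ",
            paste(o$class[prec_den == 0 | rec_den == 0], collapse = ", "))
  precision <- ifelse(prec_den == 0, 0, o$TP / prec_den)
  recall <- ifelse(rec_den == 0, 0, o$TP / rec_den)
  per_class <- data.frame(
    class = o$class,
    accuracy = (o$TP + o$TN) / n,
    precision = precision,
    recall = recall,
    f1 = f1_score(precision, recall))
  list(per_class = per_class,
       overall_accuracy = sum(diag(counts$matrix)) / n,
       macro_f1 = mean(per_class$f1))
}

# fast macro-F1 for the search hot loop: no warnings, no data frames
.macro_f1 <- function(true, predicted, classes) {
  m <- table(factor(true, levels = classes),
             factor(predicted, levels = classes))
  tp <- diag(m)
  prec_den <- colSums(m)
  rec_den <- rowSums(m)
  p <- ifelse(prec_den == 0, 0, tp / prec_den)
  r <- ifelse(rec_den == 0, 0, tp / rec_den)
  mean(ifelse(p + r == 0, 0, 2 * p * r / (p + r)))
}

#' ROC curve and AUC by threshold sweep
#'
#' Sweeps every distinct score threshold (tied scores grouped), accumulating
#' the true- and false-positive rates, and integrates the curve with the
#' trapezoidal rule. The resulting AUC equals the Mann-Whitney probability
#' that a random positive outranks a random negative, ties counted one half.
#'
#' @param true Binary labels: logical, 0/1, or a factor whose second level
#'   is the positive class; alternatively supply `positive`.
#' @param scores Numeric decision values, larger meaning more positive.
#' @param positive Value of `true` regarded as positive.
#' @return List with `points` (data frame fpr, tpr, threshold; from (0,0) to
#'   (1,1)) and `auc`.
#' @export
roc_auc <- function(true, scores, positive = NULL) {
  if (!is.null(positive)) {
    pos <- true == positive
  } else if (is.logical(true)) {
    pos <- true
  } else if (is.factor(true)) {
    pos <- true == levels(true)[2L]
  } else {
    pos <- true == max(true)
  }
  if (length(pos) != length(scores))
    stop("labels and scores must have equal length")
  np <- sum(pos); nn <- sum(!pos)
  if (np == 0L || nn == 0L)
    stop("both classes must be present to build a ROC curve")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; p <- pos[ord]
  last <- !duplicated(s, fromLast = TRUE)  # group tied scores
  tpr <- c(0, cumsum(p)[last] / np)
  fpr <- c(0, cumsum(!p)[last] / nn)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  list(points = data.frame(fpr = fpr, tpr = tpr,
                           threshold = c(Inf, s[last])),
       auc = auc)
}
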