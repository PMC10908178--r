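#' ROC overlay across subsets
#'
#' One panel per subtype, one curve per evaluated subset; the highlighted
#' subset (typically the full-signature baseline) is drawn on top in red.
#'
#' @param reports Named list of `EvalReport`s.
#' @param highlight Name of the report to emphasize.
#' @return A ggplot object.
#' @export
plot_roc_curves <- function(reports, highlight = NULL) {
  long <- do.call(rbind, lapply(names(reports), function(nm) {
    r <- reports[[nm]]
    do.call(rbind, lapply(r$class_order, function(cl)
      data.frame(subset = nm, subtype = cl,
                 fpr = r$roc[[cl]]$fpr, tpr = r$roc[[cl]]$tpr)))
  }))
  long$emph <- !is.null(highlight) & long$subset == highlight
  p <- ggplot2::ggplot(long, ggplot2::aes(.data$fpr, .data$tpr,
                                          group = .data$subset)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted",
                         colour = "grey60") +
    ggplot2::geom_step(data = long[!long$emph, ], colour = "grey55",
                       linewidth = 0.4) +
    ggplot2::facet_wrap(~subtype) +
    ggplot2::labs(x = "False positive rate", y = "True positive rate") +
    ggplot2::theme_bw()
  if (!is.null(highlight))
    p <- p + ggplot2::geom_step(data = long[long$emph, ], colour = "red",
                                linewidth = 0.7)
  p
}

#' Confusion-matrix heatmap
#'
#' @param report An `EvalReport`.
#' @return A ggplot object.
#' @export
plot_confusion_matrix <- function(report) {
  m <- report$confusion$matrix
  df <- as.data.frame(as.table(m))
  colnames(df) <- c("true", "predicted", "count")
  ggplot2::ggplot(df, ggplot2::aes(.data$predicted, .data$true,
                                   fill = .data$count)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$count)) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue") +
    ggplot2::scale_y_discrete(limits = rev(rownames(m))) +
    ggplot2::labs(x = "Predicted subtype", y = "True subtype") +
    ggplot2::theme_minimal()
}

#' t-SNE scatter with misclassifications marked
#'
#' Points are coloured by true subtype; misclassified samples (prediction
#' differs from truth) are overdrawn with a cross.
#'
#' @param tab An [embedding_table()] with prediction columns.
#' @return A ggplot object.
#' @export
plot_embedding <- function(tab) {
  stopifnot(all(c("x", "y", "true_label") %in% colnames(tab)))
  p <- ggplot2::ggplot(tab, ggplot2::aes(.data$x, .data$y,
                                         colour = .data$true_label)) +
    ggplot2::geom_point(alpha = 0.7, size = 1.6) +
    ggplot2::labs(x = "t-SNE 1", y = "t-SNE 2", colour = "Subtype") +
    ggplot2::theme_bw()
  if ("misclassified" %in% colnames(tab) && any(tab$misclassified))
    p <- p + ggplot2::geom_point(data = tab[tab$misclassified, ],
                                 shape = 4, size = 2.8, stroke = 1,
                                 colour = "black")
  p
}
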