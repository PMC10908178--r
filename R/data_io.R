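#' Construct an expression dataset
#'
#' The canonical container used throughout the package: a samples x genes
#' matrix of continuous expression values together with one subtype label per
#' sample and a cohort tag.
#'
#' @param values Numeric matrix, samples in rows and genes in columns.
#' @param labels Character or factor vector of subtype labels, one per row of
#'   `values`.
#' @param cohort_name Short text tag identifying the cohort.
#' @param sample_ids Unique sample identifiers; defaults to the rownames of
#'   `values`.
#' @param gene_ids Unique gene symbols; defaults to the colnames of `values`.
#' @param label_set Allowed subtype labels. Defaults to the four intrinsic
#'   breast-cancer subtypes ([pam50_subtypes()]).
#' @return An object of class `ExpressionDataset`: a list with elements
#'   `cohort`, `values` (dimnamed matrix), `labels` (factor with levels
#'   `label_set`).
#' @export
expression_dataset <- function(values, labels, cohort_name = "cohort",
                               sample_ids = rownames(values),
                               gene_ids = colnames(values),
                               label_set = pam50_subtypes()) {
  values <- as.matrix(values)
  if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(nrow(values)))
  if (is.null(gene_ids)) stop("gene identifiers are required")
  sample_ids <- as.character(sample_ids)
  gene_ids <- trimws(as.character(gene_ids))
  if (length(sample_ids) != nrow(values))
    stop("number of sample identifiers does not match the number of rows")
  if (length(gene_ids) != ncol(values))
    stop("number of gene identifiers does not match the number of columns")
  .stop_on_duplicates(sample_ids, "sample identifier")
  .stop_on_duplicates(gene_ids, "gene symbol")
  if (length(labels) != nrow(values))
    stop("one label per sample is required")
  labels <- as.character(labels)
  bad <- setdiff(unique(labels), label_set)
  if (length(bad))
    stop("labels outside the configured label set: ", paste(bad, collapse = ", "))
  if (anyNA(values) || any(!is.finite(values)))
    stop("expression values must be finite and non-missing")
  storage.mode(values) <- "double"
  dimnames(values) <- list(sample_ids, gene_ids)
  structure(
    list(cohort = cohort_name, values = values,
         labels = factor(labels, levels = label_set)),
    class = "ExpressionDataset"
  )
}

#' @export
print.ExpressionDataset <- function(x, ...) {
  cat(sprintf("ExpressionDataset '%s': %d samples x %d genes\n",
              x$cohort, nrow(x$values), ncol(x$values)))
  print(table(x$labels))
  invisible(x)
}

#' @export
dim.ExpressionDataset <- function(x) dim(x$values)

#' Sample and gene identifiers of a dataset
#' @param data An `ExpressionDataset`.
#' @return Character vector of identifiers.
#' @export
sample_ids <- function(data) rownames(data$values)

#' @rdname sample_ids
#' @export
gene_ids <- function(data) colnames(data$values)

#' The four intrinsic breast-cancer subtypes
#' @return Character vector `c("Basal", "Her2", "LumA", "LumB")`.
#' @export
pam50_subtypes <- function() c("Basal", "Her2", "LumA", "LumB")

.stop_on_duplicates <- function(x, what) {
  d <- unique(x[duplicated(x)])
  if (length(d))
    stop("duplicate ", what, "s: ", paste(d, collapse = ", "))
  invisible(x)
}

.delim_for <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

#' Read an expression cohort from delimited text
#'
#' Expects a header row. In the canonical `samples-by-genes` orientation the
#' first column holds sample identifiers, one column (`label_column`) holds
#' the subtype label and all remaining columns are genes. In the
#' `genes-by-samples` orientation the first column holds gene symbols, the
#' header row holds sample identifiers, and the row whose first field equals
#' `label_column` carries the labels; the matrix is transposed to the
#' canonical orientation on load. The delimiter is inferred from the file
#' extension (`.csv` comma, anything else tab).
#'
#' @param path Path to a delimited text file.
#' @param label_column Name of the label column (or label row when
#'   transposed).
#' @param orientation `"samples-by-genes"` (default) or `"genes-by-samples"`.
#' @param label_set Allowed subtype labels.
#' @param exclude_unknown If `TRUE`, samples whose label is outside
#'   `label_set` (e.g. Normal-like or unlabeled samples) are dropped with a
#'   message reporting the count; if `FALSE` (default) such labels are an
#'   error.
#' @param cohort_name Cohort tag; defaults to the file name.
#' @return An [expression_dataset()].
#' @export
read_expression <- function(path, label_column = "subtype",
                            orientation = c("samples-by-genes", "genes-by-samples"),
                            label_set = pam50_subtypes(),
                            exclude_unknown = FALSE,
                            cohort_name = NULL) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(cohort_name))
    cohort_name <- sub("\\.[^.]*$", "", basename(path))
  raw <- utils::read.delim(path, sep = .delim_for(path), header = TRUE,
                           check.names = FALSE, stringsAsFactors = FALSE)
  if (orientation == "genes-by-samples") {
    first <- trimws(as.character(raw[[1L]]))
    lab_row <- which(first == label_column)
    if (length(lab_row) != 1L)
      stop("label row '", label_column, "' not found (or duplicated)")
    samples <- colnames(raw)[-1L]
    labels <- as.character(unlist(raw[lab_row, -1L], use.names = FALSE))
    genes <- first[-lab_row]
    mat <- t(as.matrix(raw[-lab_row, -1L, drop = FALSE]))
    storage.mode(mat) <- "double"
    dimnames(mat) <- list(samples, genes)
  } else {
    if (!label_column %in% colnames(raw))
      stop("label column '", label_column, "' not found")
    samples <- trimws(as.character(raw[[1L]]))
    labels <- as.character(raw[[label_column]])
    keep <- setdiff(colnames(raw), c(colnames(raw)[1L], label_column))
    mat <- as.matrix(raw[, keep, drop = FALSE])
    storage.mode(mat) <- "double"
    dimnames(mat) <- list(samples, trimws(keep))
  }
  unknown <- !(labels %in% label_set) | is.na(labels)
  if (any(unknown)) {
    if (!exclude_unknown)
      stop("unknown label value(s): ",
           paste(unique(labels[unknown]), collapse = ", "),
           " (set exclude_unknown = TRUE to drop these samples)")
    message(sum(unknown), " sample(s) with labels outside {",
            paste(label_set, collapse = ", "), "} excluded")
    mat <- mat[!unknown, , drop = FALSE]
    labels <- labels[!unknown]
  }
  if (anyNA(mat)) stop("missing expression values in ", path)
  expression_dataset(mat, labels, cohort_name = cohort_name,
                     label_set = label_set)
}

#' Write an expression cohort as delimited text
#'
#' Inverse of [read_expression()] for the canonical samples-by-genes layout:
#' first column `sample_id`, second column the label, remaining columns
#' genes.
#'
#' @param data An `ExpressionDataset`.
#' @param path Output path; `.csv` writes comma-separated, anything else tab.
#' @param label_column Header for the label column.
#' @return `path`, invisibly.
#' @export
write_expression <- function(data, path, label_column = "subtype") {
  df <- data.frame(sample_id = sample_ids(data),
                   label = as.character(data$labels),
                   data$values, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[2L] <- label_column
  utils::write.table(df, path, sep = .delim_for(path), quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Restrict a dataset to a set of samples
#' @param data An `ExpressionDataset`.
#' @param idx Row indices or sample identifiers.
#' @return An `ExpressionDataset` with the selected samples.
#' @export
subset_samples <- function(data, idx) {
  structure(
    list(cohort = data$cohort,
         values = data$values[idx, , drop = FALSE],
         labels = data$labels[if (is.character(idx))
           match(idx, sample_ids(data)) else idx]),
    class = "ExpressionDataset"
  )
}
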