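# Small in-code fixtures shared across the suite.

# A tiny 4-sample x 3-gene dataset with one sample per subtype.
toy_dataset <- function() {
  m <- matrix(c(1.5, 2.0, 0.5,
                0.2, 1.1, 3.0,
                2.2, 0.4, 1.8,
                0.9, 2.7, 0.3),
              nrow = 4, byrow = TRUE,
              dimnames = list(paste0("S", 1:4), c("GENE1", "GENE2", "GENE3")))
  expression_dataset(m, c("Basal", "Her2", "LumA", "LumB"), "toy")
}

# Balanced separable cohort over a small panel: each subtype shifts its own
# block of `informative` genes by `effect`; remaining genes are pure noise.
toy_cohort <- function(n_per_class = 30, n_genes = 20, informative = 8,
                       effect = 3, seed = 42, cohort = "toyA") {
  subtypes <- pam50_subtypes()
  informative <- min(informative, n_genes)
  genes <- sprintf("G%02d", seq_len(n_genes))
  labels <- rep(subtypes, each = n_per_class)
  n <- length(labels)
  with_seed(seed, {
    x <- matrix(rnorm(n * n_genes), n, n_genes,
                dimnames = list(sprintf("%s%03d", cohort, 1:n), genes))
    owner <- rep_len(1:4, informative)
    for (j in seq_len(informative))
      x[labels == subtypes[owner[j]], j] <-
        x[labels == subtypes[owner[j]], j] + effect
  })
  expression_dataset(x, labels, cohort_name = cohort)
}

toy_signature <- function(n_genes = 20, name = "toy-sig") {
  gene_signature(sprintf("G%02d", seq_len(n_genes)), name = name)
}

# Pre-split separable parts for classifier-level tests.
toy_parts <- function(n_per_class = 30, ...) {
  d <- toy_cohort(n_per_class = n_per_class, ...)
  split_dataset(d, split_spec(seed = 9))
}

write_toy_tsv <- function(path = tempfile(fileext = ".tsv"),
                          extra_label = NULL) {
  d <- toy_dataset()
  if (!is.null(extra_label)) {
    v <- rbind(d$values, S5 = c(1, 1, 1))
    df <- data.frame(sample_id = rownames(v),
                     subtype = c(as.character(d$labels), extra_label),
                     v, check.names = FALSE)
  } else {
    df <- data.frame(sample_id = rownames(d$values),
                     subtype = as.character(d$labels),
                     d$values, check.names = FALSE)
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}
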