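#' Selection pipeline: normalize, filter, split, search
#'
#' Runs the first pipeline end to end on one cohort: standardize the
#' cohort (standard scaler fitted on the full cohort by default, matching
#' the published pipeline; `"train"` refits inside each split for
#' leakage-free operation), filter by the signature, then run `experiments`
#' replicate few-shot searches and pool them. When `out_dir` is given,
#' writes an append-only JSON-lines trial log per experiment, one
#' plain-text signature file per size (directly reusable as
#' [read_signature()] input), the selection result as JSON, and a manifest.
#' With `resume = TRUE`, trials already present in the logs are not rerun;
#' because per-trial seeds are derived from `(experiment seed, size,
#' trial)`, a resumed run reproduces the uninterrupted one exactly.
#'
#' @param cohort An `ExpressionDataset`.
#' @param sig A `GeneSignature` to search within.
#' @param trials Trials per experiment per size.
#' @param experiments Number of replicate experiments (default 3).
#' @param base_seed Integer; experiment e uses seed `base_seed + e - 1`.
#' @param sizes Integer sizes to search; default [size_range()] of `sig`
#'   at `size_fracs`.
#' @param size_fracs Length-2 fraction band for [size_range()].
#' @param split A [split_spec()].
#' @param spec Selection-phase [classifier_spec()].
#' @param combine Score combiner, see [run_trial()].
#' @param scaler_policy `"cohort"` (default) or `"none"`.
#' @param out_dir Optional output directory.
#' @param resume Reuse trial logs found in `out_dir`.
#' @param progress Report per-size progress.
#' @return A `SelectionResult` (see [pool_and_select()]), with the trial
#'   records attached as attribute `"trials"`.
#' @export
select_genes <- function(cohort, sig, trials = 100L, experiments = 3L,
                         base_seed = 1L, sizes = NULL,
                         size_fracs = c(0.10, 0.80),
                         split = split_spec(), spec = classifier_spec(),
                         combine = "mean",
                         scaler_policy = c("cohort", "none"),
                         out_dir = NULL, resume = FALSE,
                         progress = FALSE) {
  scaler_policy <- match.arg(scaler_policy)
  t0 <- Sys.time()
  if (scaler_policy == "cohort")
    cohort <- scale_dataset(cohort, fit_scaler(cohort), warn_constant = FALSE)
  data <- filter_by_signature(cohort, sig)
  eff <- intersect_signature(sig, gene_ids(cohort))
  if (is.null(sizes)) sizes <- size_range(eff, size_fracs[1L], size_fracs[2L])
  seeds <- base_seed + seq_len(experiments) - 1L
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE,
                                    showWarnings = FALSE)
  runs <- lapply(seq_along(seeds), function(e) {
    log_path <- if (!is.null(out_dir))
      file.path(out_dir, sprintf("trials_exp%d.jsonl", e)) else NULL
    done <- NULL
    if (resume && !is.null(log_path) && file.exists(log_path)) {
      done <- read_trial_log(log_path)
      if (!is.null(done) && nrow(done) == trials * length(sizes))
        return(done)
    }
    rec <- run_experiment(data, eff, sizes = sizes, trials = trials,
                          experiment_seed = seeds[e], split = split,
                          spec = spec, combine = combine,
                          experiment_id = e, progress = progress)
    if (!is.null(done) && nrow(done)) {
      key <- function(d) paste(d$k, d$trial_id)
      rec <- rbind(done, rec[!(key(rec) %in% key(done)), ])
      rec <- rec[order(rec$k, rec$trial_id), ]
      rownames(rec) <- NULL
    }
    if (!is.null(log_path)) write_trial_log(rec, log_path)
    rec
  })
  result <- pool_and_select(runs, signature_name = sig$name, sizes = sizes)
  result$experiment_seeds <- seeds
  attr(result, "trials") <- do.call(rbind, runs)
  if (!is.null(out_dir)) {
    for (i in seq_len(nrow(result$best)))
      write_signature(
        gene_signature(split_genes(result$best$genes[i])[[1L]],
                       name = sprintf("%s-best-%d", sig$name,
                                      result$best$k[i])),
        file.path(out_dir, sprintf("best_subset_k%02d.txt",
                                   result$best$k[i])))
    write_selection(result, file.path(out_dir, "selection.json"))
    .write_manifest(file.path(out_dir, "manifest.json"), list(
      stage = "select", cohort = cohort$cohort, signature = sig$name,
      trials = trials, experiments = experiments, base_seed = base_seed,
      sizes = sizes, split = split$fractions, stratified = split$stratified,
      scaler_policy = scaler_policy, combine = combine,
      classifier = list(kernel = spec$kernel, C = spec$C,
                        gamma = spec$gamma),
      elapsed_sec = as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  }
  result
}

#' Serialize a selection result as JSON
#' @param result A `SelectionResult`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_selection <- function(result, path) {
  best <- result$best
  jsonlite::write_json(list(
    signature_name = result$signature_name,
    experiment_seeds = result$experiment_seeds,
    trials_per_size = as.list(result$trials_per_size),
    equivalence_p = as.list(result$equivalence_p),
    best = lapply(seq_len(nrow(best)), function(i) list(
      k = best$k[i], experiment_id = best$experiment_id[i],
      trial_id = best$trial_id[i], seed = best$seed[i],
      genes = split_genes(best$genes[i])[[1L]],
      f1_validation = best$f1_validation[i], f1_test = best$f1_test[i],
      combined_score = best$combined_score[i]))),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Evaluation pipeline: cross-cohort assessment of selected subsets
#'
#' Runs the second pipeline on an independent cohort: split into train and
#' test (no validation part is needed since selection consumed no data
#' from this cohort), then evaluate every supplied subset plus the full
#' signature baseline with [evaluate_subset()]. The summary names the
#' subset with the highest macro-mean AUC. When `out_dir` is given, writes
#' per-subset reports (metrics/ROC/confusion TSV + JSON), the three figure
#' types (ROC overlay with the baseline highlighted, confusion-matrix
#' heatmap, t-SNE embedding of the test samples with misclassifications
#' marked), a summary JSON and a manifest.
#'
#' @param cohort The evaluation `ExpressionDataset`.
#' @param subsets Named list of gene-symbol vectors (or `GeneSignature`s).
#' @param baseline A `GeneSignature` evaluated as the reference (default
#'   the packaged 50-gene signature); `NULL` to skip.
#' @param spec A [classifier_spec()] (set `grid` for a wider search).
#' @param split Fractions for the train/test split; the `validation`
#'   fraction is folded into training.
#' @param folds,seed Passed to [grid_search_train()].
#' @param scaler_policy Passed to [evaluate_subset()].
#' @param tsne Compute the t-SNE embedding of the test samples.
#' @param tsne_perplexity,tsne_iterations t-SNE parameters.
#' @param out_dir Optional output directory.
#' @return List with `reports` (named list of `EvalReport`s), `summary`
#'   (data frame of headline numbers per subset), `best_subset` (name with
#'   the highest macro AUC) and, when computed, `embedding`.
#' @export
evaluate_subsets <- function(cohort, subsets, baseline = pam50(),
                             spec = classifier_spec(),
                             split = split_spec(0.70, 0.15, 0.15),
                             folds = 5L, seed = 1L,
                             scaler_policy = "cohort",
                             tsne = FALSE, tsne_perplexity = 30,
                             tsne_iterations = 500L,
                             out_dir = NULL) {
  t0 <- Sys.time()
  subsets <- lapply(subsets, function(s)
    if (inherits(s, "GeneSignature")) s$genes else as.character(s))
  if (!is.null(baseline))
    subsets <- c(stats::setNames(
      list(intersect(baseline$genes, gene_ids(cohort))), baseline$name),
      subsets)
  if (!length(subsets)) stop("no subsets to evaluate")
  if (is.null(names(subsets)) || any(!nzchar(names(subsets))))
    stop("subsets must be named")
  # two-way split: train absorbs the validation fraction
  fr <- split$fractions
  parts <- split_dataset(cohort, split)
  train <- subset_samples(cohort, c(sample_ids(parts$train),
                                    sample_ids(parts$validation)))
  test <- parts$test
  reports <- lapply(subsets, function(s)
    evaluate_subset(train, test, s, spec = spec, folds = folds,
                    seed = seed, scaler_policy = scaler_policy))
  summary <- data.frame(
    subset = names(reports),
    n_genes = vapply(reports, function(r) length(r$subset), integer(1)),
    overall_accuracy = vapply(reports, `[[`, numeric(1), "overall_accuracy"),
    macro_f1 = vapply(reports, `[[`, numeric(1), "macro_f1"),
    macro_auc = vapply(reports, `[[`, numeric(1), "macro_auc"),
    row.names = NULL)
  best_subset <- summary$subset[which.max(summary$macro_auc)]
  embedding <- NULL
  if (tsne) {
    best_rep <- reports[[best_subset]]
    emb_data <- scale_dataset(test, fit_scaler(test), warn_constant = FALSE)
    embedding <- tsne_embed(
      emb_data$values[, best_rep$subset, drop = FALSE],
      perplexity = min(tsne_perplexity, nrow(test$values) / 4),
      iterations = tsne_iterations, seed = seed)
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (nm in names(reports))
      write_eval_report(reports[[nm]],
                        file.path(out_dir, gsub("[^A-Za-z0-9._-]", "_", nm)))
    jsonlite::write_json(
      list(summary = summary, best_subset = best_subset),
      file.path(out_dir, "summary.json"), auto_unbox = TRUE, digits = NA)
    ggplot2::ggsave(file.path(out_dir, "roc_overlay.png"),
                    plot_roc_curves(reports, highlight = names(reports)[1L]),
                    width = 8, height = 6, dpi = 150)
    ggplot2::ggsave(file.path(out_dir, "confusion_best.png"),
                    plot_confusion_matrix(reports[[best_subset]]),
                    width = 5, height = 4.5, dpi = 150)
    if (!is.null(embedding)) {
      tab <- embedding_table(embedding, reports[[best_subset]],
                             sample_ids(test))
      utils::write.table(tab, file.path(out_dir, "tsne_coordinates.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      ggplot2::ggsave(file.path(out_dir, "tsne_best.png"),
                      plot_embedding(tab), width = 7, height = 5.5,
                      dpi = 150)
    }
    .write_manifest(file.path(out_dir, "manifest.json"), list(
      stage = "evaluate", cohort = cohort$cohort,
      subsets = lapply(subsets, identity), folds = folds, seed = seed,
      split = fr, scaler_policy = scaler_policy,
      classifier = list(kernel = spec$kernel, C = spec$C,
                        gamma = spec$gamma, grid = spec$grid),
      best_subset = best_subset,
      elapsed_sec = as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  }
  list(reports = reports, summary = summary, best_subset = best_subset,
       embedding = embedding)
}

.write_manifest <- function(path, entries) {
  entries$package_version <-
    as.character(utils::packageVersion("fewshotgenes"))
  entries$r_version <- R.version.string
  entries$timestamp <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  jsonlite::write_json(entries, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
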