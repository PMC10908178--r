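#' Subset-size range implied by a signature
#'
#' The range of subset sizes searched is a fraction band of the signature's
#' *nominal* length: lower bound `ceiling(low_frac * nominal)`, upper bound
#' `floor(high_frac * nominal)`. Using the nominal length (not the
#' post-intersection gene count) keeps the advertised range anchored to the
#' published signature: the 50-gene signature at the default 10--80% band
#' gives sizes 5..40 even when only 44 genes survive a platform
#' intersection. Sizes exceeding the available gene count are clipped at
#' sampling time, not here.
#'
#' @param sig A `GeneSignature`.
#' @param low_frac,high_frac Fraction band, `0 < low_frac <= high_frac <= 1`.
#' @return Integer vector of sizes `low..high`.
#' @export
size_range <- function(sig, low_frac = 0.10, high_frac = 0.80) {
  if (!(low_frac > 0 && low_frac <= high_frac && high_frac <= 1))
    stop("need 0 < low_frac <= high_frac <= 1")
  lo <- as.integer(ceiling(low_frac * sig$nominal_length))
  hi <- as.integer(floor(high_frac * sig$nominal_length))
  lo <- max(lo, 1L)
  if (lo > length(sig$genes))
    stop("lower bound ", lo, " exceeds the ", length(sig$genes),
         " available genes")
  seq.int(lo, hi)
}

#' Draw one random gene subset
#'
#' Samples `k` distinct symbols uniformly without replacement from the
#' signature and returns them in the signature's order. Uses (and advances)
#' the global RNG stream; duplicate subsets across successive calls are
#' permitted by design -- at large trial counts and small `k` the
#' combination space is exhausted.
#'
#' @param sig A `GeneSignature`.
#' @param k Subset size, `1 <= k <= length(sig$genes)`.
#' @return Character vector of `k` gene symbols.
#' @export
sample_subset <- function(sig, k) {
  g <- sig$genes
  if (k < 1L || k > length(g))
    stop("k must be between 1 and ", length(g))
  idx <- sample.int(length(g), k)
  g[sort(idx)]
}

.collapse_genes <- function(genes) paste(genes, collapse = ";")

#' Split trial-record gene strings back into vectors
#' @param genes Character vector of ";"-collapsed gene lists.
#' @return List of character vectors.
#' @export
split_genes <- function(genes) strsplit(genes, ";", fixed = TRUE)

.combiner <- function(combine = c("mean", "sum", "min")) {
  switch(match.arg(combine),
         mean = function(v, t) (v + t) / 2,
         sum = function(v, t) v + t,
         min = function(v, t) pmin(v, t))
}

#' Score one candidate gene subset
#'
#' Fits the selection-phase classifier (linear kernel by default) on the
#' train part restricted to `subset`, and computes macro-averaged F1 (the
#' unweighted mean of per-class one-vs-rest F1) on the validation and test
#' parts. The combined score is, by default, the arithmetic mean of the two
#' macro-F1 values.
#'
#' @param train,validation,test `ExpressionDataset` parts sharing a gene
#'   universe containing `subset` and a common label set.
#' @param subset Character vector of gene symbols.
#' @param spec A [classifier_spec()]; the default is the linear C = 1
#'   configuration.
#' @param combine How to combine validation and test macro-F1: `"mean"`
#'   (default), `"sum"` or `"min"`.
#' @param experiment_id,trial_id,seed Bookkeeping carried into the record.
#' @return A one-row data frame (a `TrialRecord`): experiment_id, trial_id,
#'   k, seed, genes (";"-collapsed), f1_validation, f1_test,
#'   combined_score.
#' @export
run_trial <- function(train, validation, test, subset,
                      spec = classifier_spec(), combine = "mean",
                      experiment_id = 1L, trial_id = 1L, seed = NA_integer_) {
  f1 <- .score_subset(train, validation, test, subset, spec)
  data.frame(experiment_id = as.integer(experiment_id),
             trial_id = as.integer(trial_id),
             k = length(subset), seed = as.integer(seed),
             genes = .collapse_genes(subset),
             f1_validation = f1[1L], f1_test = f1[2L],
             combined_score = .combiner(combine)(f1[1L], f1[2L]),
             stringsAsFactors = FALSE)
}

# fit + score one subset; returns c(validation macro-F1, test macro-F1)
.score_subset <- function(train, validation, test, subset, spec) {
  classes <- levels(train$labels)
  absent <- setdiff(classes, as.character(unique(train$labels)))
  if (length(absent))
    stop("class(es) absent from the training part: ",
         paste(absent, collapse = ", "))
  model <- fit_classifier(train$values[, subset, drop = FALSE],
                          train$labels, spec)
  pv <- stats::predict(model, validation$values[, subset, drop = FALSE])
  pt <- stats::predict(model, test$values[, subset, drop = FALSE])
  c(.macro_f1(validation$labels, pv, classes),
    .macro_f1(test$labels, pt, classes))
}

# deterministic per-trial seed from (experiment_seed, k, trial_id);
# kept below 2^31 and collision-scrambled with two multiplicative mixes
trial_seed <- function(experiment_seed, k, trial_id) {
  m <- 2147483647
  s <- (as.numeric(experiment_seed) %% m) * 48271 %% m
  s <- (s + as.numeric(k) * 69621) %% m
  s <- (s * 16807 + as.numeric(trial_id)) %% m
  as.integer(s)
}

#' Run one experiment of the few-shot search
#'
#' One experiment draws a single train/validation/test split from
#' `experiment_seed` (so all trials within the experiment are scored on the
#' same folds and are directly comparable) and then, for every subset size
#' in `sizes`, scores `trials` random subsets. The per-trial RNG seed is
#' derived deterministically from `(experiment_seed, k, trial_id)`, making
#' any single trial reproducible in isolation and making shorter runs exact
#' prefixes of longer ones.
#'
#' @param data A standardized, signature-filtered `ExpressionDataset`.
#' @param sig The search signature (typically already intersected with the
#'   cohort's genes).
#' @param sizes Integer vector of subset sizes; sizes above the available
#'   gene count are clipped with a warning.
#' @param trials Number of trials per size.
#' @param experiment_seed Integer seed identifying the experiment.
#' @param split A [split_spec()]; its `seed` field is overridden by
#'   `experiment_seed`.
#' @param spec Selection-phase [classifier_spec()].
#' @param combine Score combiner, see [run_trial()].
#' @param experiment_id Integer id recorded in every trial.
#' @param progress Print a line per size.
#' @return Data frame of `trials * length(sizes)` trial records.
#' @export
run_experiment <- function(data, sig, sizes = size_range(sig), trials = 100L,
                           experiment_seed = 1L, split = split_spec(),
                           spec = classifier_spec(), combine = "mean",
                           experiment_id = experiment_seed,
                           progress = FALSE) {
  if (trials < 1L) stop("trials must be >= 1")
  eff <- intersect_signature(sig, gene_ids(data))
  avail <- length(eff$genes)
  if (any(sizes > avail)) {
    warning("sizes above the ", avail, " available genes clipped")
    sizes <- sizes[sizes <= avail]
  }
  split$seed <- as.integer(experiment_seed)
  parts <- split_dataset(data, split)
  n_rec <- length(sizes) * trials
  rec_k <- integer(n_rec); rec_t <- integer(n_rec); rec_seed <- integer(n_rec)
  rec_genes <- character(n_rec)
  rec_f1v <- numeric(n_rec); rec_f1t <- numeric(n_rec)
  comb <- .combiner(combine)
  i <- 0L
  for (k in sizes) {
    for (t in seq_len(trials)) {
      sd_t <- trial_seed(experiment_seed, k, t)
      subset <- with_seed(sd_t, sample_subset(eff, k))
      f1 <- .score_subset(parts$train, parts$validation, parts$test,
                          subset, spec)
      i <- i + 1L
      rec_k[i] <- k; rec_t[i] <- t; rec_seed[i] <- sd_t
      rec_genes[i] <- .collapse_genes(subset)
      rec_f1v[i] <- f1[1L]; rec_f1t[i] <- f1[2L]
    }
    if (progress)
      message(sprintf("experiment %d: size %d done (%d trials)",
                      experiment_id, k, trials))
  }
  data.frame(experiment_id = as.integer(experiment_id),
             trial_id = rec_t, k = rec_k, seed = rec_seed,
             genes = rec_genes, f1_validation = rec_f1v, f1_test = rec_f1t,
             combined_score = comb(rec_f1v, rec_f1t),
             stringsAsFactors = FALSE)
}

#' Pool experiments and select the best subset per size
#'
#' Pools the trial records of all experiments and, for every subset size,
#' retains the record with the maximal combined score. Ties are broken by
#' higher test F1, then lower experiment id, then lower trial id, so the
#' selection is invariant to the order in which experiments are supplied.
#' When at least two experiments contribute `min_trials` trials at a size,
#' the cross-experiment equivalence p-value ([compare_experiments()]) is
#' attached for that size.
#'
#' @param experiments A single data frame of trial records or a list of
#'   them.
#' @param signature_name Name recorded in the result.
#' @param sizes Sizes expected in the result; defaults to all sizes present.
#'   Configured sizes with no records are omitted with a warning.
#' @param min_trials Minimum per-experiment trials required for the
#'   equivalence test.
#' @return An object of class `SelectionResult`: list with `best` (data
#'   frame, one row per size), `trials_per_size`, `experiment_seeds`,
#'   `equivalence_p` (named numeric, NA where not computable) and
#'   `signature_name`.
#' @export
pool_and_select <- function(experiments, signature_name = "signature",
                            sizes = NULL, min_trials = 20L) {
  pooled <- if (is.data.frame(experiments)) experiments
            else do.call(rbind, experiments)
  if (is.null(pooled) || !nrow(pooled)) stop("no trial records supplied")
  if (is.null(sizes)) sizes <- sort(unique(pooled$k))
  missing <- setdiff(sizes, pooled$k)
  if (length(missing)) {
    warning("no trials for size(s): ", paste(missing, collapse = ", "))
    sizes <- setdiff(sizes, missing)
  }
  ord <- order(pooled$k, -pooled$combined_score, -pooled$f1_test,
               pooled$experiment_id, pooled$trial_id)
  pooled_sorted <- pooled[ord, ]
  best <- pooled_sorted[!duplicated(pooled_sorted$k), ]
  best <- best[best$k %in% sizes, ]
  rownames(best) <- NULL
  eq <- vapply(sizes, function(k) {
    per_exp <- table(pooled$experiment_id[pooled$k == k])
    if (length(per_exp) >= 2L && all(per_exp >= min_trials))
      compare_experiments(pooled, k, min_trials = min_trials)
    else NA_real_
  }, numeric(1))
  structure(list(signature_name = signature_name,
                 best = best,
                 trials_per_size = stats::setNames(
                   vapply(sizes, function(k) sum(pooled$k == k), integer(1)),
                   sizes),
                 experiment_seeds = sort(unique(pooled$experiment_id)),
                 equivalence_p = stats::setNames(eq, sizes)),
            class = "SelectionResult")
}

#' @export
print.SelectionResult <- function(x, ...) {
  cat(sprintf("SelectionResult for '%s': %d sizes, %s experiments\n",
              x$signature_name, nrow(x$best),
              length(x$experiment_seeds)))
  print(x$best[, c("k", "experiment_id", "trial_id",
                   "f1_validation", "f1_test", "combined_score")])
  invisible(x)
}

#' Cross-experiment equivalence check
#'
#' Kruskal-Wallis rank test on the per-trial combined scores of the
#' experiments at one subset size. A large p-value (> 0.05) indicates the
#' replicate experiments are statistically indistinguishable, i.e. the
#' search protocol is robust to the seed.
#'
#' @param experiments Trial records (data frame or list of data frames).
#' @param k Subset size at which to compare.
#' @param min_trials Required trials per experiment (default 20).
#' @return The Kruskal-Wallis p-value.
#' @export
compare_experiments <- function(experiments, k, min_trials = 20L) {
  pooled <- if (is.data.frame(experiments)) experiments
            else do.call(rbind, experiments)
  sub <- pooled[pooled$k == k, ]
  per_exp <- table(sub$experiment_id)
  if (length(per_exp) < 2L)
    stop("need at least 2 experiments at size ", k)
  if (any(per_exp < min_trials))
    stop("need at least ", min_trials, " trials per experiment at size ", k)
  if (stats::var(sub$combined_score) == 0) return(1)
  stats::kruskal.test(sub$combined_score,
                      factor(sub$experiment_id))$p.value
}

#' Write/read an append-only trial log
#'
#' One JSON object per line per trial record, enabling resumption and
#' post-hoc pooling.
#'
#' @param records Trial-record data frame.
#' @param path Log file path.
#' @param append Append to an existing log.
#' @return `write_trial_log()` returns `path` invisibly; `read_trial_log()`
#'   the records as a data frame.
#' @export
write_trial_log <- function(records, path, append = FALSE) {
  lines <- vapply(seq_len(nrow(records)), function(i)
    jsonlite::toJSON(as.list(records[i, ]), auto_unbox = TRUE,
                     digits = NA),
    character(1))
  con <- file(path, if (append) "a" else "w")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' @rdname write_trial_log
#' @export
read_trial_log <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  do.call(rbind, lapply(lines, function(l)
    as.data.frame(jsonlite::fromJSON(l), stringsAsFactors = FALSE)))
}
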