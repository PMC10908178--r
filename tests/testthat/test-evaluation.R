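test_that("confusion counts match a hand-enumerated example", {
  cls <- c("Basal", "Her2", "LumA", "LumB")
  true <- c("Basal", "Basal", "Her2", "LumA", "LumB", "LumB")
  pred <- c("Basal", "LumA", "Her2", "LumA", "LumB", "Her2")
  cm <- confusion(true, pred, cls)
  expect_equal(cm$matrix["Basal", "Basal"], 1L)
  expect_equal(cm$matrix["Basal", "LumA"], 1L)
  expect_equal(cm$matrix["LumB", "Her2"], 1L)
  expect_equal(sum(cm$matrix), 6L)
  o <- cm$ovr
  expect_equal(o$TP[o$class == "LumA"], 1L)
  expect_equal(o$FP[o$class == "LumA"], 1L)
  expect_equal(o$FN[o$class == "Basal"], 1L)
  expect_equal(o$TN[o$class == "Her2"], 4L)
  # per class TP + FN equals the class support
  expect_equal(o$TP + o$FN, unname(as.integer(table(factor(true, cls)))))
  expect_error(confusion(true, replace(pred, 1, "Other"), cls), "Other")
  expect_error(confusion(true, pred[-1], cls), "equal length")
})

test_that("perfect prediction yields a diagonal confusion matrix", {
  with_seed(11, {
    labs <- sample(pam50_subtypes(), 40, TRUE)
    cm <- confusion(labs, labs, pam50_subtypes())
    expect_true(all(cm$ovr$FP == 0) && all(cm$ovr$FN == 0))
    expect_equal(sum(diag(cm$matrix)), 40L)
    # conservation on random label vectors
    pred <- sample(pam50_subtypes(), 40, TRUE)
    expect_equal(sum(confusion(labs, pred, pam50_subtypes())$matrix), 40L)
  })
})

test_that("F1 follows the harmonic-mean formula", {
  expect_equal(f1_score(0.5, 1.0), 2 / 3)
  expect_equal(f1_score(0.7, 0.7), 0.7)      # equal P and R
  expect_equal(f1_score(0, 0), 0)
  # the published Basal row: P 0.966, R 0.944 -> F1 0.955 at 3 d.p.
  expect_equal(round(f1_score(0.966, 0.944), 3), 0.955)
})

test_that("OvR metrics obey their algebraic bounds", {
  with_seed(21, for (i in 1:20) {
    true <- sample(pam50_subtypes(), 30, TRUE)
    pred <- sample(pam50_subtypes(), 30, TRUE)
    m <- ovr_metrics(confusion(true, pred, pam50_subtypes()), warn = FALSE)
    pc <- m$per_class
    expect_true(all(pc$f1 >= pmin(pc$precision, pc$recall) - 1e-12))
    expect_true(all(pc$f1 <= pmax(pc$precision, pc$recall) + 1e-12))
    expect_true(all(unlist(pc[-1]) >= 0 & unlist(pc[-1]) <= 1))
  })
})

test_that("overall accuracy equals support-weighted OvR recall iff balanced", {
  cls <- c("Basal", "Her2", "LumA", "LumB")
  # balanced case: equality holds
  true_b <- rep(cls, each = 5)
  pred_b <- with_seed(3, sample(rep(cls, each = 5)))
  m <- ovr_metrics(confusion(true_b, pred_b, cls), warn = FALSE)
  support <- as.integer(table(factor(true_b, cls)))
  expect_equal(m$overall_accuracy,
               sum(m$per_class$recall * support) / sum(support))
  # the weighted identity holds for any support; the unweighted mean breaks
  true_u <- c(rep("Basal", 12), rep("Her2", 2), rep("LumA", 3),
              rep("LumB", 3))
  pred_u <- replace(true_u, c(1, 14), c("Her2", "Basal"))
  mu <- ovr_metrics(confusion(true_u, pred_u, cls), warn = FALSE)
  su <- as.integer(table(factor(true_u, cls)))
  expect_equal(mu$overall_accuracy,
               sum(mu$per_class$recall * su) / sum(su))
  expect_false(isTRUE(all.equal(mu$overall_accuracy,
                                mean(mu$per_class$recall))))
})

test_that("zero-denominator precision/recall reports 0 with a warning", {
  cm <- confusion(c("Basal", "Her2"), c("Her2", "Her2"),
                  c("Basal", "Her2"))
  expect_warning(m <- ovr_metrics(cm), "Basal")
  expect_equal(m$per_class$precision[m$per_class$class == "Basal"], 0)
})

test_that("AUC equals the brute-force pairwise ranking probability", {
  pair_oracle <- function(pos, scores) {
    ps <- scores[pos]; ns <- scores[!pos]
    conc <- 0
    for (p in ps) for (q in ns)
      conc <- conc + (p > q) + 0.5 * (p == q)
    conc / (length(ps) * length(ns))
  }
  # 8-point toy with ties
  pos <- c(TRUE, TRUE, TRUE, FALSE, TRUE, FALSE, FALSE, FALSE)
  sc <- c(0.9, 0.8, 0.8, 0.8, 0.3, 0.3, 0.2, 0.1)
  expect_equal(roc_auc(pos, sc)$auc, pair_oracle(pos, sc))
  with_seed(31, for (i in 1:25) {
    pos <- sample(c(TRUE, FALSE), 12, TRUE)
    if (!any(pos) || all(pos)) next
    sc <- sample(seq(0, 1, 0.1), 12, TRUE)  # coarse grid forces ties
    expect_equal(roc_auc(pos, sc)$auc, pair_oracle(pos, sc))
  })
})

test_that("ROC endpoints, monotonicity and AUC invariances hold", {
  with_seed(41, {
    pos <- rep(c(TRUE, FALSE), each = 20)
    sc <- rnorm(40) + 2 * pos
    r <- roc_auc(pos, sc)
    expect_equal(r$points$fpr[1], 0)
    expect_equal(r$points$tpr[1], 0)
    expect_equal(utils::tail(r$points$fpr, 1), 1)
    expect_equal(utils::tail(r$points$tpr, 1), 1)
    expect_true(all(diff(r$points$fpr) >= 0))
    expect_true(all(diff(r$points$tpr) >= 0))
    # invariant under strictly monotone transforms; flips under negation
    expect_equal(roc_auc(pos, exp(sc))$auc, r$auc)
    expect_equal(roc_auc(!pos, sc)$auc, 1 - r$auc)
    # perfect separation and label-independent scores
    expect_equal(roc_auc(pos, as.numeric(pos))$auc, 1)
    aucs <- vapply(1:40, function(i)
      roc_auc(sample(pos), rnorm(40))$auc, numeric(1))
    expect_lt(abs(mean(aucs) - 0.5), 0.08)
  })
  expect_error(roc_auc(rep(TRUE, 5), rnorm(5)), "both classes")
})

test_that("AUC agrees with an established independent implementation", {
  skip_if_not_installed("pROC")
  with_seed(51, {
    pos <- sample(c(TRUE, FALSE), 60, TRUE)
    sc <- rnorm(60) + pos
    ref <- as.numeric(pROC::auc(pROC::roc(pos, sc, quiet = TRUE,
                                          direction = "<")))
    expect_equal(roc_auc(pos, sc)$auc, ref, tolerance = 1e-12)
  })
})

test_that("grid search returns the default parameters for a singleton grid", {
  parts <- toy_parts()
  fit <- grid_search_train(parts$train, classifier_spec(), folds = 3)
  expect_equal(fit$params$kernel, "linear")
  expect_equal(fit$params$C, 1)
  expect_equal(fit$params$gamma, "scale")
  expect_equal(fit$params$decision_scheme, "one-vs-rest")
  expect_null(fit$cv_scores)
})

test_that("grid search prefers the grid point that wins cross-validation", {
  # imbalanced, overlapping classes: a vanishing C collapses to the
  # majority class and provably loses the cross-validated comparison
  d <- toy_cohort(n_per_class = 30, effect = 1.5, seed = 42)
  d <- subset_samples(d, c(1:30, 31:45, 61:90, 91:110))
  parts <- split_dataset(d, split_spec(seed = 9))
  spec <- classifier_spec(grid = list(C = c(1e-6, 1)))
  fit <- grid_search_train(parts$train, spec, folds = 3, seed = 2)
  expect_equal(fit$params$C, 1)  # the degenerate C underfits
  expect_equal(nrow(fit$cv_scores), 2L)
  expect_gt(diff(fit$cv_scores$mean_macro_f1[order(fit$cv_scores$C)]), 0)
  # determinism
  fit2 <- grid_search_train(parts$train, spec, folds = 3, seed = 2)
  expect_identical(fit$params, fit2$params)
  p1 <- predict(fit$model, parts$test$values)
  p2 <- predict(fit2$model, parts$test$values)
  expect_identical(as.character(p1), as.character(p2))
  # a class smaller than the fold count is an error
  small <- subset_samples(parts$train,
                          c(which(parts$train$labels != "Her2"),
                            which(parts$train$labels == "Her2")[1:2]))
  expect_error(grid_search_train(small, spec, folds = 3), "Her2")
})

test_that("evaluate_subset assembles a consistent report", {
  d <- toy_cohort(n_per_class = 25, effect = 4, seed = 12)
  parts <- split_dataset(d, split_spec(0.7, 0.15, 0.15, seed = 3))
  train <- subset_samples(d, c(sample_ids(parts$train),
                               sample_ids(parts$validation)))
  rep1 <- evaluate_subset(train, parts$test, sprintf("G%02d", 1:8))
  expect_s3_class(rep1, "EvalReport")
  expect_true(all(rep1$metrics$auc > 0.95))
  expect_true(all(unlist(rep1$metrics[-1]) >= 0 &
                    unlist(rep1$metrics[-1]) <= 1))
  expect_equal(sum(rep1$confusion$matrix), nrow(parts$test$values))
  expect_equal(rep1$macro_auc, mean(rep1$metrics$auc))
  # Acc column repeats the single overall accuracy
  tab <- format_metrics_table(rep1)
  expect_equal(unique(tab$Acc), round(rep1$overall_accuracy, 3))
  # genes absent from the cohort are dropped with a warning
  expect_warning(
    rep2 <- evaluate_subset(train, parts$test, c("G01", "G02", "NOPE")),
    "NOPE")
  expect_equal(rep2$subset, c("G01", "G02"))
})

test_that("a full signature is just the size-|sig| subset", {
  d <- toy_cohort(n_per_class = 20, effect = 3, seed = 13)
  parts <- split_dataset(d, split_spec(seed = 4))
  train <- subset_samples(d, c(sample_ids(parts$train),
                               sample_ids(parts$validation)))
  sig <- toy_signature(20)
  rep_sig <- evaluate_subset(train, parts$test, sig$genes)
  ev <- evaluate_subsets(d, subsets = list(), baseline = sig,
                         split = split_spec(seed = 4))
  expect_equal(ev$reports[[sig$name]]$metrics, rep_sig$metrics)
  expect_equal(ev$reports[[sig$name]]$confusion$matrix,
               rep_sig$confusion$matrix)
})

test_that("eval reports serialize to TSV and JSON", {
  d <- toy_cohort(n_per_class = 15, effect = 3, seed = 14)
  parts <- split_dataset(d, split_spec(seed = 5))
  train <- subset_samples(d, c(sample_ids(parts$train),
                               sample_ids(parts$validation)))
  r <- evaluate_subset(train, parts$test, sprintf("G%02d", 1:6))
  stem <- file.path(tempdir(), "rep")
  files <- write_eval_report(r, stem)
  expect_true(all(file.exists(files)))
  tsv <- utils::read.delim(files[1])
  expect_equal(tsv$F1, r$metrics$f1)
  js <- jsonlite::fromJSON(files[4])
  expect_equal(js$macro_auc, r$macro_auc)
})
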