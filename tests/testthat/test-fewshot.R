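test_that("subset-size range follows the fraction band on the nominal length", {
  expect_equal(range(size_range(pam50())), c(5L, 40L))
  expect_equal(size_range(toy_signature(10), 0.10, 0.80), 1:8)
  sig44 <- gene_signature(sprintf("g%02d", 1:44), "eff", nominal_length = 44)
  expect_equal(range(size_range(sig44)), c(5L, 35L))
  # nominal length, not the surviving gene count, anchors the range
  eff <- suppressMessages(
    intersect_signature(pam50(), setdiff(pam50()$genes,
                                         aces_missing_genes())))
  expect_equal(range(size_range(eff)), c(5L, 40L))
  expect_error(size_range(gene_signature("a", nominal_length = 50), 0.5, 0.8),
               "available genes")
  expect_error(size_range(pam50(), 0.8, 0.1))
})

test_that("subset sampling is uniform, seeded and in signature order", {
  sig <- toy_signature(12)
  expect_identical(with_seed(3, sample_subset(sig, 12)), sig$genes)
  s1 <- with_seed(8, replicate(5, sample_subset(sig, 4), simplify = FALSE))
  s2 <- with_seed(8, replicate(5, sample_subset(sig, 4), simplify = FALSE))
  expect_identical(s1, s2)
  for (s in s1) expect_identical(s, sig$genes[sig$genes %in% s])
  expect_error(sample_subset(sig, 0))
  expect_error(sample_subset(sig, 13))
  # chi-square uniformity over the 6 pairs of a 4-gene signature
  sig4 <- toy_signature(4)
  draws <- with_seed(99, replicate(6000, paste(sample_subset(sig4, 2),
                                               collapse = "+")))
  counts <- table(draws)
  expect_equal(length(counts), 6L)
  expect_gt(stats::chisq.test(counts)$p.value, 0.01)
})

test_that("trial scoring separates informative from noise subsets", {
  parts <- toy_parts(n_per_class = 30, effect = 4)
  informative <- sprintf("G%02d", 1:8)
  noise <- sprintf("G%02d", 13:20)
  good <- run_trial(parts$train, parts$validation, parts$test, informative)
  bad <- run_trial(parts$train, parts$validation, parts$test, noise)
  expect_gt(good$combined_score, 0.95)
  expect_lt(bad$combined_score, good$combined_score)
  expect_equal(good$combined_score,
               mean(c(good$f1_validation, good$f1_test)), tolerance = 1e-12)
  expect_equal(good$k, 8L)
})

test_that("permuted labels score near 4-class chance", {
  parts <- toy_parts(n_per_class = 30, effect = 4)
  informative <- sprintf("G%02d", 1:8)
  scores <- vapply(1:50, function(i) {
    tr <- parts$train
    tr$labels <- with_seed(1000 + i, sample(tr$labels))
    suppressWarnings(
      run_trial(tr, parts$validation, parts$test, informative))$combined_score
  }, numeric(1))
  expect_lt(abs(mean(scores) - 0.25), 0.08)
})

test_that("a training part missing a class is rejected", {
  parts <- toy_parts()
  tr <- subset_samples(parts$train, which(parts$train$labels != "Her2"))
  expect_error(run_trial(tr, parts$validation, parts$test, "G01"), "Her2")
})

test_that("experiments are deterministic with exact bookkeeping", {
  d <- toy_cohort(n_per_class = 12, n_genes = 12)
  sig <- toy_signature(12)
  r1 <- run_experiment(d, sig, sizes = 5:6, trials = 10,
                       experiment_seed = 21)
  expect_equal(nrow(r1), 20L)
  expect_equal(as.integer(table(r1$k)), c(10L, 10L))
  expect_identical(r1$trial_id, rep(1:10, 2))
  r2 <- run_experiment(d, sig, sizes = 5:6, trials = 10,
                       experiment_seed = 21)
  expect_identical(r1, r2)
  # prefix property: a shorter run is an exact prefix of a longer one
  r100 <- run_experiment(d, sig, sizes = 5L, trials = 30,
                         experiment_seed = 21)
  r10 <- run_experiment(d, sig, sizes = 5L, trials = 10,
                        experiment_seed = 21)
  expect_identical(r10, r100[1:10, ])
  expect_lte(max(r10$combined_score), max(r100$combined_score))
})

test_that("pooled best equals the brute-force max with the tie rules", {
  make_rec <- function(exp_id, n, seed) with_seed(seed, data.frame(
    experiment_id = exp_id, trial_id = 1:n, k = sample(5:6, n, TRUE),
    seed = 1L, genes = "a;b", f1_validation = runif(n),
    f1_test = round(runif(n), 1), combined_score = round(runif(n), 1)))
  exps <- lapply(1:3, function(e) make_rec(e, 10, 400 + e))
  sel <- pool_and_select(exps, "toy")
  pooled <- do.call(rbind, exps)
  for (k in sort(unique(pooled$k))) {
    rows <- pooled[pooled$k == k, ]
    best <- sel$best[sel$best$k == k, ]
    expect_equal(best$combined_score, max(rows$combined_score))
    # tie rules: among max-score rows, max f1_test, then min ids
    cand <- rows[rows$combined_score == max(rows$combined_score), ]
    cand <- cand[cand$f1_test == max(cand$f1_test), ]
    cand <- cand[order(cand$experiment_id, cand$trial_id), ][1, ]
    expect_equal(best$experiment_id, cand$experiment_id)
    expect_equal(best$trial_id, cand$trial_id)
    # pooled best equals the max of per-experiment bests
    per_exp <- vapply(exps, function(e)
      suppressWarnings(max(c(-Inf, e$combined_score[e$k == k]))), numeric(1))
    expect_equal(best$combined_score, max(per_exp))
  }
  # pooling is invariant to experiment order
  sel_rev <- pool_and_select(rev(exps), "toy")
  expect_equal(sel_rev$best, sel$best)
  # identity pooling for a single experiment
  sel1 <- pool_and_select(exps[[1]], "toy")
  for (k in unique(exps[[1]]$k))
    expect_equal(sel1$best$combined_score[sel1$best$k == k],
                 max(exps[[1]]$combined_score[exps[[1]]$k == k]))
  expect_warning(pool_and_select(exps, "toy", sizes = c(5, 6, 9)), "9")
})

test_that("equal-score ties are broken by higher test F1", {
  rec <- data.frame(experiment_id = c(1L, 2L), trial_id = c(1L, 1L),
                    k = 5L, seed = 1L, genes = c("a;b", "c;d"),
                    f1_validation = c(0.9, 0.7), f1_test = c(0.5, 0.7),
                    combined_score = c(0.7, 0.7))
  sel <- pool_and_select(rec, "tie")
  expect_equal(sel$best$genes, "c;d")
})

test_that("combined-score invariants hold on real trial records", {
  d <- toy_cohort(n_per_class = 10, n_genes = 10, effect = 2)
  rec <- run_experiment(d, toy_signature(10), sizes = 3:4, trials = 8,
                        experiment_seed = 5)
  expect_true(all(rec$combined_score >= 0 & rec$combined_score <= 1))
  expect_equal(rec$combined_score, (rec$f1_validation + rec$f1_test) / 2,
               tolerance = 1e-12)
  # alternative combiners stay available
  rec_min <- run_experiment(d, toy_signature(10), sizes = 3L, trials = 4,
                            experiment_seed = 5, combine = "min")
  expect_equal(rec_min$combined_score,
               pmin(rec_min$f1_validation, rec_min$f1_test))
})

test_that("cross-experiment comparison behaves under null and shift", {
  make_scores <- function(exp_id, n, seed, shift = 0) with_seed(seed,
    data.frame(experiment_id = exp_id, trial_id = 1:n, k = 5L, seed = 1L,
               genes = "a", f1_validation = 0, f1_test = 0,
               combined_score = pmin(1, runif(n, 0.4, 0.8) + shift)))
  null3 <- lapply(1:3, function(e) make_scores(e, 40, 70 + e))
  p_null <- compare_experiments(null3, 5)
  expect_true(p_null >= 0 && p_null <= 1)
  shifted <- c(null3[1:2], list(make_scores(3, 40, 99, shift = 0.3)))
  expect_lt(compare_experiments(shifted, 5), 0.01)
  # identical score lists: no between-group variation
  same <- lapply(1:2, function(e) make_scores(e, 30, 123))
  expect_equal(compare_experiments(same, 5), 1)
  expect_error(compare_experiments(lapply(1:2, function(e)
    make_scores(e, 10, e)), 5), "at least 20")
  expect_error(compare_experiments(null3[[1]], 5), "2 experiments")
})

test_that("trial logs round-trip and support pooling", {
  d <- toy_cohort(n_per_class = 10, n_genes = 10)
  rec <- run_experiment(d, toy_signature(10), sizes = 3L, trials = 5,
                        experiment_seed = 2)
  p <- tempfile(fileext = ".jsonl")
  write_trial_log(rec, p)
  back <- read_trial_log(p)
  expect_equal(back, rec)
  write_trial_log(rec[1:2, ], p)
  write_trial_log(rec[3:5, ], p, append = TRUE)
  expect_equal(read_trial_log(p)$trial_id, 1:5)
})
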