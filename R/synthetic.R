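#' Specify a paired synthetic cohort generator
#'
#' Describes two cohorts of four-subtype expression data with the
#' statistical structure the selection method assumes: class-conditional
#' Gaussian mean shifts on a planted set of informative genes, independent
#' Gaussian noise everywhere, and per-cohort affine batch distortions
#' (offset vector and scale factor) emulating cross-platform technical
#' bias. A configurable set of panel genes is withheld from cohort A,
#' emulating signature genes missing from one platform.
#'
#' Each planted gene is assigned one owner subtype round-robin; its mean is
#' shifted by `effect_size` in samples of the owner subtype and 0
#' elsewhere, so all planted genes are equally informative and every
#' subtype owns roughly the same number of marker genes. A custom
#' `class_means` matrix (subtypes x planted genes) overrides this pattern.
#'
#' @param panel Character vector of gene symbols (default: the packaged
#'   50-gene PAM50 list).
#' @param planted Informative genes, a subset of `panel`. Default: 10 genes
#'   spread evenly over the panel genes not withheld from cohort A.
#' @param class_means Optional numeric matrix (4 subtypes x planted genes)
#'   of mean shifts in expression units.
#' @param effect_size Mean shift given to a planted gene in its owner
#'   subtype (expression units). The default 1.6, against unit noise,
#'   yields modest class overlap (pipeline macro-F1 around 0.85-0.95).
#' @param noise_sd Standard deviation of the additive Gaussian noise.
#' @param batch_offset_sd Per-cohort sd of the per-gene batch offset,
#'   named vector for cohorts A and B.
#' @param batch_scale Per-cohort multiplicative factor, named vector.
#' @param samples_per_subtype Named list with per-cohort named integer
#'   vectors of samples per subtype (each >= 3).
#' @param withheld_from_A Panel genes absent from cohort A (default: the
#'   six genes missing from the ACES platform).
#' @param seed Integer master seed.
#' @return An object of class `SyntheticSpec`.
#' @export
synthetic_spec <- function(panel = pam50()$genes,
                           planted = NULL,
                           class_means = NULL,
                           effect_size = 1.6,
                           noise_sd = 1,
                           batch_offset_sd = c(A = 0, B = 2),
                           batch_scale = c(A = 1, B = 1.3),
                           samples_per_subtype = list(
                             A = c(Basal = 40, Her2 = 30, LumA = 60, LumB = 50),
                             B = c(Basal = 40, Her2 = 30, LumA = 60, LumB = 50)),
                           withheld_from_A = aces_missing_genes(),
                           seed = 1L) {
  panel <- trimws(panel)
  .stop_on_duplicates(panel, "panel gene")
  withheld_from_A <- intersect(withheld_from_A, panel)
  shared <- setdiff(panel, withheld_from_A)
  if (is.null(planted)) {
    planted <- shared[unique(round(seq(1, length(shared), length.out = 10)))]
  }
  if (!all(planted %in% panel))
    stop("planted genes must be a subset of the panel")
  if (any(planted %in% withheld_from_A))
    stop("planted genes must be measured in both cohorts")
  subtypes <- pam50_subtypes()
  if (is.null(class_means)) {
    class_means <- matrix(0, length(subtypes), length(planted),
                          dimnames = list(subtypes, planted))
    owner <- rep_len(seq_along(subtypes), length(planted))
    for (j in seq_along(planted))
      class_means[owner[j], j] <- effect_size
  } else {
    class_means <- as.matrix(class_means)
    stopifnot(nrow(class_means) == length(subtypes),
              ncol(class_means) == length(planted))
    dimnames(class_means) <- list(subtypes, planted)
  }
  if (noise_sd <= 0 || any(batch_scale <= 0))
    stop("noise sd and batch scales must be positive")
  for (ch in c("A", "B"))
    if (any(samples_per_subtype[[ch]] < 3L))
      stop("need at least 3 samples per subtype per cohort")
  structure(list(panel = panel, planted = planted,
                 class_means = class_means, noise_sd = noise_sd,
                 batch_offset_sd = batch_offset_sd,
                 batch_scale = batch_scale,
                 samples_per_subtype = samples_per_subtype,
                 withheld_from_A = withheld_from_A,
                 seed = as.integer(seed)),
            class = "SyntheticSpec")
}

#' Generate one synthetic cohort
#'
#' Values are `batch_offset[g] + batch_scale * class_mean[subtype, g] +
#' noise`, with the class mean 0 on non-planted genes. Cohort A lacks the
#' withheld genes. Deterministic given the spec's seed; the two cohorts use
#' disjoint seed offsets, and the batch offset vector is drawn once per
#' cohort from the spec seed.
#'
#' @param spec A [synthetic_spec()].
#' @param cohort `"A"` or `"B"`.
#' @return An `ExpressionDataset`.
#' @export
generate_cohort <- function(spec, cohort = c("A", "B")) {
  cohort <- match.arg(cohort)
  genes <- if (cohort == "A") setdiff(spec$panel, spec$withheld_from_A)
           else spec$panel
  counts <- spec$samples_per_subtype[[cohort]]
  subtypes <- rownames(spec$class_means)
  n <- sum(counts)
  labels <- rep(names(counts), counts)
  seed_off <- if (cohort == "A") 101L else 202L
  with_seed(spec$seed + seed_off, {
    offset <- stats::rnorm(length(genes), 0, spec$batch_offset_sd[[cohort]])
    scale <- spec$batch_scale[[cohort]]
    mu <- matrix(0, n, length(genes), dimnames = list(NULL, genes))
    planted_here <- intersect(spec$planted, genes)
    mu[, planted_here] <-
      spec$class_means[labels, planted_here, drop = FALSE]
    values <- sweep(scale * mu, 2L, offset, "+") +
      matrix(stats::rnorm(n * length(genes), 0, spec$noise_sd),
             n, length(genes))
  })
  expression_dataset(values, labels,
                     cohort_name = paste0("synthetic-", cohort),
                     sample_ids = sprintf("%s%04d", cohort, seq_len(n)),
                     gene_ids = genes,
                     label_set = subtypes)
}

#' Paired cohorts with the shape of the published study
#'
#' A drop-in stand-in for the published data layout: cohort A with 1512
#' samples over 44 genes (six of the 50-gene panel withheld) and cohort B
#' with 515 samples over the full 50-gene panel; four subtypes with
#' imbalanced proportions (Basal well below LumA), 10 planted informative
#' genes shared by both cohorts.
#'
#' @param seed Integer seed.
#' @param ... Overrides passed on to [synthetic_spec()].
#' @return List with `A`, `B` (the two `ExpressionDataset`s) and `spec`.
#' @export
make_study_shaped_pair <- function(seed = 1L, ...) {
  spec <- synthetic_spec(
    samples_per_subtype = list(
      A = c(Basal = 272, Her2 = 181, LumA = 635, LumB = 424),
      B = c(Basal = 93, Her2 = 62, LumA = 216, LumB = 144)),
    seed = seed, ...)
  list(A = generate_cohort(spec, "A"),
       B = generate_cohort(spec, "B"),
       spec = spec)
}
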