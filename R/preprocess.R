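#' Fit a per-gene standard scaler
#'
#' Computes, feature by feature, the arithmetic mean and the population
#' standard deviation (divisor N, not N-1) of each gene over the samples of
#' `data`. Applying the fitted scaler with [scale_dataset()] implements the
#' z-score transform z = (x - mu) / sigma. Zero-variance genes are recorded
#' with sigma = 0 and handled at transform time.
#'
#' @param data An `ExpressionDataset` with at least 2 samples.
#' @return An object of class `ScalerModel`: list with named numeric vectors
#'   `mean` and `sd` (one entry per gene) and `fitted_on`, the number of
#'   samples used.
#' @export
fit_scaler <- function(data) {
  x <- data$values
  if (nrow(x) < 2L) stop("need at least 2 samples to fit a scaler")
  mu <- colMeans(x)
  sigma <- sqrt(colMeans(sweep(x, 2L, mu, "-")^2))
  structure(list(mean = mu, sd = sigma, fitted_on = nrow(x)),
            class = "ScalerModel")
}

#' @export
print.ScalerModel <- function(x, ...) {
  cat(sprintf("ScalerModel: %d genes, fitted on %d samples (%d zero-variance)\n",
              length(x$mean), x$fitted_on, sum(x$sd == 0)))
  invisible(x)
}

#' Apply a fitted standard scaler
#'
#' Replaces every value by (x - mu_g) / sigma_g using the per-gene
#' parameters of `scaler`. Genes with sigma_g = 0 map to 0 everywhere (a
#' centred constant carries no information); a warning lists them.
#'
#' @param data An `ExpressionDataset` whose genes are all covered by
#'   `scaler`.
#' @param scaler A `ScalerModel` from [fit_scaler()].
#' @param warn_constant Warn when zero-variance genes are zeroed out.
#' @return The standardized `ExpressionDataset`.
#' @export
scale_dataset <- function(data, scaler, warn_constant = TRUE) {
  genes <- gene_ids(data)
  missing <- setdiff(genes, names(scaler$mean))
  if (length(missing))
    stop("no scaler parameters for gene(s): ", paste(missing, collapse = ", "))
  mu <- scaler$mean[genes]
  sigma <- scaler$sd[genes]
  z <- sweep(data$values, 2L, mu, "-")
  const <- sigma == 0
  sigma[const] <- 1
  z <- sweep(z, 2L, sigma, "/")
  if (any(const)) {
    z[, const] <- 0
    if (warn_constant)
      warning("zero-variance gene(s) set to 0: ",
              paste(genes[const], collapse = ", "))
  }
  out <- data
  out$values <- z
  out
}

#' Serialize scaler parameters for audit
#'
#' Writes (or reads back) a tab-separated sidecar with columns `gene`,
#' `mean`, `sd`.
#'
#' @param scaler A `ScalerModel`.
#' @param path File path.
#' @return `write_scaler()` returns `path` invisibly; `read_scaler()` a
#'   `ScalerModel`.
#' @export
write_scaler <- function(scaler, path) {
  utils::write.table(
    data.frame(gene = names(scaler$mean), mean = scaler$mean,
               sd = scaler$sd, fitted_on = scaler$fitted_on),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_scaler
#' @export
read_scaler <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  structure(list(mean = stats::setNames(df$mean, df$gene),
                 sd = stats::setNames(df$sd, df$gene),
                 fitted_on = df$fitted_on[1L]),
            class = "ScalerModel")
}

#' Restrict a dataset to the genes of a signature
#'
#' Keeps the columns of `data` named in `sig`, in the signature's order;
#' samples and labels are untouched. Signature genes absent from the dataset
#' are reported by name and dropped; an empty intersection is an error.
#'
#' @param data An `ExpressionDataset`.
#' @param sig A `GeneSignature`.
#' @return The filtered `ExpressionDataset`.
#' @export
filter_by_signature <- function(data, sig) {
  eff <- intersect_signature(sig, gene_ids(data))
  out <- data
  out$values <- data$values[, eff$genes, drop = FALSE]
  out
}

#' Specify a train/validation/test split
#'
#' @param train,validation,test Fractions in (0,1) summing to 1 (tolerance
#'   1e-9). Default 70/15/15.
#' @param stratified Stratify the split by subtype label (default `TRUE`).
#' @param seed Integer seed making the split deterministic.
#' @return An object of class `SplitSpec`.
#' @export
split_spec <- function(train = 0.70, validation = 0.15, test = 0.15,
                       stratified = TRUE, seed = 1L) {
  fr <- c(train = train, validation = validation, test = test)
  if (any(fr <= 0) || any(fr >= 1)) stop("each fraction must be in (0, 1)")
  if (abs(sum(fr) - 1) > 1e-9) stop("fractions must sum to 1")
  structure(list(fractions = fr, stratified = isTRUE(stratified),
                 seed = as.integer(seed)),
            class = "SplitSpec")
}

# largest-remainder apportionment of n into parts proportional to fr
.largest_remainder <- function(n, fr) {
  ideal <- n * fr
  base <- floor(ideal)
  extra <- round(n - sum(base))
  if (extra > 0) {
    ord <- order(ideal - base, decreasing = TRUE)  # ties: earlier part wins
    base[ord[seq_len(extra)]] <- base[ord[seq_len(extra)]] + 1
  }
  as.integer(base)
}

#' Split a dataset into train, validation and test parts
#'
#' Produces a disjoint, exhaustive partition whose part sizes follow the
#' fractions of `spec` after largest-remainder rounding. When stratified
#' (the default), samples are allocated class by class: within each part the
#' per-class counts start from the floor of the ideal count and the part's
#' remaining seats go to the classes with the largest fractional remainders
#' (ties broken by class order), so per-class proportions track the global
#' fractions as closely as integrality allows. Deterministic given
#' `spec$seed`; the global RNG state is left untouched.
#'
#' @param data An `ExpressionDataset`.
#' @param spec A [split_spec()].
#' @return Named list of three `ExpressionDataset`s: `train`, `validation`,
#'   `test`.
#' @export
split_dataset <- function(data, spec) {
  stopifnot(inherits(spec, "SplitSpec"))
  n <- nrow(data$values)
  fr <- spec$fractions
  sizes <- .largest_remainder(n, fr)
  assign_part <- integer(n)
  with_seed(spec$seed, {
    if (spec$stratified) {
      counts <- table(data$labels)
      small <- names(counts)[counts > 0 & counts < 3L]
      if (length(small))
        stop("class too small to stratify: ", paste(small, collapse = ", "))
      classes <- names(counts)[counts > 0]
      pools <- lapply(classes, function(cl)
        sample(which(data$labels == cl)))
      names(pools) <- classes
      taken <- stats::setNames(integer(length(classes)), classes)
      for (p in 1:3) {
        n_c <- as.numeric(counts[classes])
        if (p < 3) {
          ideal <- n_c * fr[p]
          alloc <- floor(ideal)
          room <- n_c - taken - alloc
          extra <- sizes[p] - sum(alloc)
          frac <- ideal - floor(ideal)
          ord <- order(frac, decreasing = TRUE)  # stable: ties by class order
          while (extra > 0 && any(room > 0)) {
            for (cl in ord) {
              if (extra <= 0) break
              if (room[cl] > 0) {
                alloc[cl] <- alloc[cl] + 1
                room[cl] <- room[cl] - 1
                extra <- extra - 1
              }
            }
          }
        } else {
          alloc <- n_c - taken  # last part absorbs the remainder
        }
        for (ci in seq_along(classes)) {
          if (alloc[ci] > 0) {
            idx <- pools[[ci]][taken[ci] + seq_len(alloc[ci])]
            assign_part[idx] <- p
          }
        }
        taken <- taken + alloc
      }
    } else {
      perm <- sample(n)
      assign_part[perm] <- rep.int(1:3, sizes)
    }
  })
  out <- lapply(1:3, function(p) subset_samples(data, which(assign_part == p)))
  names(out) <- c("train", "validation", "test")
  out
}

#' Evaluate code under a temporary RNG seed
#'
#' Runs `code` with the global RNG seeded to `seed` and restores the
#' previous RNG state afterwards.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @export
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  code
}
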