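#' Gaussian input affinities with per-point perplexity calibration
#'
#' Computes the symmetric joint affinities p_ij of t-SNE. For every point i
#' a Gaussian bandwidth sigma_i is found by binary search so that the
#' Shannon entropy H of the conditional neighbour distribution p_{j|i}
#' satisfies 2^H = `perplexity` within `tol`; the conditionals are then
#' symmetrized, p_ij = (p_{j|i} + p_{i|j}) / (2n), giving a symmetric,
#' non-negative, zero-diagonal matrix summing to 1.
#'
#' Setting `global_sigma` skips the calibration and uses a single shared
#' bandwidth with joint normalization -- the literal textbook form of the
#' Gaussian-affinity formula, kept for comparison.
#'
#' @param x Numeric matrix (samples x features) or an `ExpressionDataset`.
#' @param perplexity Target effective neighbour count; must be below the
#'   number of samples.
#' @param tol Convergence tolerance on |2^H - perplexity|.
#' @param max_steps Maximum bisection steps per point after bracketing.
#' @param global_sigma Optional single bandwidth replacing the per-point
#'   search.
#' @return An object of class `AffinityMatrix`: list with `P` (n x n),
#'   `sigma` (per-point bandwidths, or the single shared value),
#'   `perplexity`.
#' @export
compute_affinities <- function(x, perplexity = 30, tol = 1e-5,
                               max_steps = 50L, global_sigma = NULL) {
  if (inherits(x, "ExpressionDataset")) x <- x$values
  x <- as.matrix(x)
  if (anyNA(x) || any(!is.finite(x))) stop("non-finite input values")
  n <- nrow(x)
  if (n < 3L) stop("need at least 3 samples")
  D2 <- .sq_dists(x)
  if (!is.null(global_sigma)) {
    W <- exp(-D2 / (2 * global_sigma^2))
    diag(W) <- 0
    P <- W / sum(W)
    return(structure(list(P = P, sigma = global_sigma,
                          perplexity = NA_real_),
                     class = "AffinityMatrix"))
  }
  if (perplexity >= n)
    stop("perplexity must be below the number of samples")
  if (perplexity <= 1) stop("perplexity must exceed 1")
  target_h <- log2(perplexity)
  Pc <- matrix(0, n, n)
  sigma <- numeric(n)
  for (i in seq_len(n)) {
    d <- D2[i, -i]
    beta <- 1  # precision 1 / (2 sigma^2)
    lo <- 0; hi <- Inf
    h <- .cond_entropy(d, beta)$h
    steps <- 0L
    # bracket, then bisect on the monotone entropy-precision relation
    while (abs(2^h - perplexity) > tol && steps < max_steps + 50L) {
      if (h > target_h) { lo <- beta
        beta <- if (is.finite(hi)) (beta + hi) / 2 else beta * 2
      } else { hi <- beta
        beta <- if (lo > 0) (beta + lo) / 2 else beta / 2
      }
      h <- .cond_entropy(d, beta)$h
      steps <- steps + 1L
    }
    if (abs(2^h - perplexity) > tol)
      stop("perplexity ", perplexity, " infeasible for point ", i)
    Pc[i, -i] <- .cond_entropy(d, beta)$p
    sigma[i] <- sqrt(1 / (2 * beta))
  }
  P <- (Pc + t(Pc)) / (2 * n)
  structure(list(P = P, sigma = sigma, perplexity = perplexity),
            class = "AffinityMatrix")
}

# squared Euclidean distance matrix
.sq_dists <- function(x) {
  s <- rowSums(x^2)
  D2 <- outer(s, s, "+") - 2 * tcrossprod(x)
  D2[D2 < 0] <- 0
  diag(D2) <- 0
  D2
}

# conditional distribution and its Shannon entropy (bits) at precision beta
.cond_entropy <- function(d, beta) {
  w <- exp(-(d - min(d)) * beta)  # shift for numerical stability
  p <- w / sum(w)
  nz <- p > 0
  list(h = -sum(p[nz] * log2(p[nz])), p = p)
}

#' Student-t output affinities
#'
#' The low-dimensional counterpart of the input affinities: a Student-t
#' kernel with one degree of freedom, (1 + ||y_i - y_j||^2)^-1, jointly
#' normalized over all ordered pairs; zero diagonal, sums to 1.
#'
#' @param y Numeric matrix of embedding coordinates (n x 2).
#' @return The n x n affinity matrix Q.
#' @export
low_dim_affinities <- function(y) {
  y <- as.matrix(y)
  if (nrow(y) < 2L) stop("need at least 2 points")
  W <- 1 / (1 + .sq_dists(y))
  diag(W) <- 0
  W / sum(W)
}

#' Kullback-Leibler cost of an embedding
#'
#' C = sum over i != j of p_ij log(p_ij / q_ij); terms with p_ij = 0
#' contribute 0, and q is floored at 1e-12 inside the logarithm.
#'
#' @param p An `AffinityMatrix` or its matrix.
#' @param q Output affinity matrix of matching shape.
#' @return The non-negative KL divergence.
#' @export
kl_cost <- function(p, q) {
  if (inherits(p, "AffinityMatrix")) p <- p$P
  if (!all(dim(p) == dim(q))) stop("shape mismatch between p and q")
  nz <- p > 0
  sum(p[nz] * log(p[nz] / pmax(q[nz], 1e-12)))
}

#' Optimize a 2-D t-SNE embedding
#'
#' Gradient descent on the KL cost with the standard gradient
#' `4 * sum_j (p_ij - q_ij) (y_i - y_j) (1 + ||y_i - y_j||^2)^-1`, momentum,
#' and early exaggeration (the input affinities are multiplied by
#' `exaggeration` for the first `exaggeration_iter` iterations). The
#' embedding is initialized from an isotropic Gaussian with sd 1e-4 under
#' `seed`. The KL trace (computed against the un-exaggerated affinities) is
#' recorded every 10 iterations.
#'
#' @param p An `AffinityMatrix` from [compute_affinities()].
#' @param iterations Number of gradient steps (>= 1).
#' @param learning_rate Step size.
#' @param momentum Length-2 vector: momentum before and after
#'   `momentum_switch`.
#' @param momentum_switch Iteration at which momentum switches.
#' @param exaggeration Early-exaggeration factor.
#' @param exaggeration_iter Iterations during which exaggeration applies.
#' @param seed Integer seed for the initialization.
#' @param trace_every Record the KL cost every this many iterations.
#' @return An object of class `EmbeddingResult`: list with `Y` (n x 2
#'   coordinates), `kl_trace` (data frame iteration, kl) and `params`.
#' @export
tsne_optimize <- function(p, iterations = 1000L, learning_rate = 200,
                          momentum = c(0.5, 0.8), momentum_switch = 250L,
                          exaggeration = 4, exaggeration_iter = 100L,
                          seed = 1L, trace_every = 10L) {
  stopifnot(inherits(p, "AffinityMatrix"))
  if (iterations < 1L) stop("iterations must be >= 1")
  P <- p$P
  n <- nrow(P)
  Y <- with_seed(seed, matrix(stats::rnorm(n * 2, sd = 1e-4), n, 2))
  V <- matrix(0, n, 2)
  trace_it <- integer(0); trace_kl <- numeric(0)
  for (it in seq_len(iterations)) {
    Pe <- if (it <= exaggeration_iter) P * exaggeration else P
    D2 <- .sq_dists(Y)
    Wt <- 1 / (1 + D2)
    diag(Wt) <- 0
    Q <- Wt / sum(Wt)
    G <- (Pe - Q) * Wt
    grad <- 4 * (rowSums(G) * Y - G %*% Y)
    if (any(!is.finite(grad)))
      stop("non-finite gradient at iteration ", it)
    mom <- if (it < momentum_switch) momentum[1L] else momentum[2L]
    V <- mom * V - learning_rate * grad
    Y <- Y + V
    Y <- sweep(Y, 2L, colMeans(Y), "-")
    if (it %% trace_every == 0L || it == iterations) {
      trace_it <- c(trace_it, it)
      trace_kl <- c(trace_kl, kl_cost(P, low_dim_affinities(Y)))
    }
  }
  structure(list(Y = Y,
                 kl_trace = data.frame(iteration = trace_it, kl = trace_kl),
                 params = list(perplexity = p$perplexity,
                               iterations = iterations,
                               learning_rate = learning_rate,
                               momentum = momentum,
                               momentum_switch = momentum_switch,
                               exaggeration = exaggeration,
                               exaggeration_iter = exaggeration_iter,
                               seed = seed)),
            class = "EmbeddingResult")
}

#' Embed a dataset with t-SNE
#'
#' Convenience wrapper: [compute_affinities()] followed by
#' [tsne_optimize()].
#'
#' @param x Matrix or `ExpressionDataset`.
#' @param perplexity Target perplexity.
#' @param ... Passed to [tsne_optimize()].
#' @return An `EmbeddingResult`.
#' @export
tsne_embed <- function(x, perplexity = 30, ...) {
  tsne_optimize(compute_affinities(x, perplexity = perplexity), ...)
}

#' Export embedding coordinates joined with predictions
#'
#' @param embedding An `EmbeddingResult`.
#' @param report An `EvalReport` whose test samples are the embedded points
#'   (optional).
#' @param sample_ids Identifiers for the embedded points.
#' @return Data frame with sample_id, x, y and, when a report is given,
#'   true_label, predicted_label, misclassified.
#' @export
embedding_table <- function(embedding, report = NULL, sample_ids = NULL) {
  n <- nrow(embedding$Y)
  if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(n))
  out <- data.frame(sample_id = sample_ids,
                    x = embedding$Y[, 1L], y = embedding$Y[, 2L])
  if (!is.null(report)) {
    stopifnot(length(report$true) == n)
    out$true_label <- as.character(report$true)
    out$predicted_label <- as.character(report$predicted)
    out$misclassified <- out$true_label != out$predicted_label
  }
  out
}
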