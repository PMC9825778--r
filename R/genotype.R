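#' Posterior probability of each clone-locus mutation state
#'
#' For each cluster k and locus j, computes the posterior probability that
#' the clone genotype `E_kj` is 1 given the observed calls of the cells
#' assigned to k, under the error model
#' `p(X = 1 | E = 0) = alpha` (false positive) and
#' `p(X = 0 | E = 1) = beta` (false negative), with a uniform prior on
#' `E_kj`. Missing observations contribute nothing; a cluster-locus pair
#' with no observed entries gets posterior 0.5. Products are accumulated in
#' log space.
#'
#' @param data a [mutation_matrix()].
#' @param labels integer vector of cluster labels in `1..K`, one per cell;
#'   every cluster must contain at least one cell.
#' @param alpha false-positive rate, in (0, 1).
#' @param beta false-negative rate, in (0, 1).
#' @return K x M numeric matrix of posterior probabilities `p(E_kj = 1)`.
#' @export
genotype_posterior <- function(data, labels, alpha, beta) {
  stopifnot(inherits(data, "mutation_matrix"))
  counts <- cluster_counts(data, labels)
  post <- posterior_from_counts(counts, alpha, beta)
  dimnames(post) <- list(paste0("clone_", seq_len(counts$K)), colnames(data))
  post
}

posterior_from_counts <- function(counts, alpha, beta) {
  if (alpha <= 0 || alpha >= 1 || beta <= 0 || beta >= 1) {
    stop("alpha and beta must lie strictly inside (0, 1)", call. = FALSE)
  }
  n1 <- counts$ones
  n0 <- counts$nonmissing - counts$ones
  ll1 <- n1 * log(1 - beta) + n0 * log(beta)    # log p(data | E = 1)
  ll0 <- n1 * log(alpha) + n0 * log(1 - alpha)  # log p(data | E = 0)
  1 / (1 + exp(ll0 - ll1))
}

rates_from_counts <- function(counts, E, prev_alpha, prev_beta) {
  E <- matrix(as.double(E >= 0.5), nrow(E), ncol(E))
  n1 <- counts$ones
  nm <- counts$nonmissing
  denom0 <- sum((1 - E) * nm)
  denom1 <- sum(E * nm)
  degenerate <- character(0)
  if (denom0 > 0) {
    alpha <- sum((1 - E) * n1) / denom0
  } else {
    alpha <- prev_alpha
    degenerate <- c(degenerate, "alpha")
  }
  if (denom1 > 0) {
    beta <- sum(E * (nm - n1)) / denom1
  } else {
    beta <- prev_beta
    degenerate <- c(degenerate, "beta")
  }
  out <- c(alpha = alpha, beta = beta)
  if (length(degenerate)) attr(out, "degenerate") <- degenerate
  out
}

# per-cluster counts of observed 1s and of non-missing entries (K x M each)
cluster_counts <- function(data, labels) {
  n <- nrow(data)
  labels <- as.integer(labels)
  if (length(labels) != n) {
    stop("labels must have one entry per cell", call. = FALSE)
  }
  k <- max(labels)
  if (min(labels) < 1L || length(unique(labels)) != k) {
    stop("labels must cover 1..K with every cluster non-empty", call. = FALSE)
  }
  v <- unclass(data)
  ones <- rowsum(1L * ((!is.na(v)) & v == 1L), labels)
  nonmissing <- rowsum(1L * !is.na(v), labels)
  list(ones = ones, nonmissing = nonmissing, K = k)
}

#' Maximum-likelihood update of the global error rates
#'
#' Given clone genotypes `E` and cell labels, re-estimates the
#' false-positive rate as the fraction of observed 1s among cell-locus pairs
#' whose clone genotype is 0, and the false-negative rate as the fraction of
#' observed 0s among pairs whose clone genotype is 1. These closed forms are
#' the exact maximizers of the Bernoulli error-model likelihood. Missing
#' entries are excluded from both numerator and denominator. If a rate has
#' an empty denominator (no genotype-0 or genotype-1 pairs) it is left at
#' its previous value and flagged via the `"degenerate"` attribute.
#'
#' @param data a [mutation_matrix()].
#' @param E K x M binary matrix of clone genotypes.
#' @param labels integer cluster labels in `1..K`.
#' @param prev_alpha,prev_beta values returned when the corresponding
#'   denominator is empty (default `NA`).
#' @return Named numeric vector `c(alpha = ..., beta = ...)`.
#' @export
update_error_rates <- function(data, E, labels, prev_alpha = NA_real_,
                               prev_beta = NA_real_) {
  counts <- cluster_counts(data, labels)
  if (!all(dim(E) == dim(counts$ones))) {
    stop("E must be K x M with K matching the labels", call. = FALSE)
  }
  rates_from_counts(counts, E, prev_alpha, prev_beta)
}

#' Infer clone genotypes and error rates by Gibbs sampling
#'
#' Alternates (i) sampling each clone-locus genotype from its exact
#' conditional posterior given the current error rates and (ii) updating the
#' false-positive/false-negative rates by their maximum-likelihood closed
#' forms, starting from `alpha_init = beta_init = 0.01`. The sampler stops
#' when both rates have moved less than `tol` for `tol_streak` consecutive
#' iterations, or at `max_iter` (in which case a convergence warning flag is
#' set). The reported genotype matrix is the posterior recomputed at the
#' final rates, thresholded at 0.5 (exact ties are called 0, i.e. no
#' mutation).
#'
#' @param data a [mutation_matrix()].
#' @param labels integer cluster labels in `1..K`.
#' @param max_iter maximum Gibbs iterations (default 200).
#' @param seed integer seed for the genotype sampling.
#' @param alpha_init,beta_init initial error rates (default 0.01 each).
#' @param tol convergence tolerance on both rate changes (default 1e-4).
#' @param tol_streak consecutive sub-`tol` iterations required (default 5).
#' @return An object of class `clonal_genotypes`: list with `E` (K x M
#'   binary matrix), `alpha`, `beta`, `posterior` (K x M marginal
#'   probabilities at the final rates), `n_iterations` and `converged`.
#' @export
gibbs_infer <- function(data, labels, max_iter = 200L, seed = 1L,
                        alpha_init = 0.01, beta_init = 0.01,
                        tol = 1e-4, tol_streak = 5L) {
  stopifnot(max_iter >= 1L)
  counts <- cluster_counts(data, labels)  # validates labels
  set.seed(seed)
  clamp <- function(r) min(max(r, 1e-6), 1 - 1e-6)
  alpha <- clamp(alpha_init)
  beta <- clamp(beta_init)
  streak <- 0L
  iter <- 0L
  converged <- FALSE
  K <- counts$K
  M <- ncol(data)
  while (iter < max_iter) {
    iter <- iter + 1L
    post <- posterior_from_counts(counts, alpha, beta)
    E <- matrix(stats::rbinom(K * M, 1L, post), K, M)
    rates <- rates_from_counts(counts, E, prev_alpha = alpha, prev_beta = beta)
    new_alpha <- clamp(rates[["alpha"]])
    new_beta <- clamp(rates[["beta"]])
    if (abs(new_alpha - alpha) < tol && abs(new_beta - beta) < tol) {
      streak <- streak + 1L
    } else {
      streak <- 0L
    }
    alpha <- new_alpha
    beta <- new_beta
    if (streak >= tol_streak) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warning(sprintf("Gibbs sampler did not converge within %d iterations", max_iter))
  }
  posterior <- posterior_from_counts(counts, alpha, beta)
  dimnames(posterior) <- list(paste0("clone_", seq_len(K)), colnames(data))
  E <- matrix(as.integer(posterior > 0.5), K, M,
              dimnames = dimnames(posterior))
  structure(list(E = E, alpha = alpha, beta = beta, posterior = posterior,
                 n_iterations = iter, converged = converged),
            class = "clonal_genotypes")
}

#' @export
print.clonal_genotypes <- function(x, ...) {
  cat(sprintf(
    "clonal_genotypes: %d clones x %d loci; alpha = %.4f, beta = %.4f (%s in %d iterations)\n",
    nrow(x$E), ncol(x$E), x$alpha, x$beta,
    if (x$converged) "converged" else "not converged", x$n_iterations
  ))
  invisible(x)
}
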