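#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same cells,
#' computed from the contingency table under the permutation model:
#' 1 for identical partitions (up to relabeling), about 0 for independent
#' ones; can be negative.
#'
#' @param labels_a,labels_b vectors of equal length (>= 2); any label coding.
#' @return Numeric scalar in `[-1, 1]`.
#' @export
adjusted_rand_index <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b)) {
    stop("labelings must have equal length", call. = FALSE)
  }
  n <- length(labels_a)
  stopifnot(n >= 2L)
  tab <- table(labels_a, labels_b)
  choose2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(choose2(tab))
  sum_a <- sum(choose2(rowSums(tab)))
  sum_b <- sum(choose2(colSums(tab)))
  expected <- sum_a * sum_b / choose2(n)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)  # both partitions trivial
  (sum_ij - expected) / (max_index - expected)
}

#' Genotyping accuracy against ground truth
#'
#' Expands the inferred K x M clone genotypes to an N x M cell genotype
#' matrix via the inferred labels and returns the fraction of the N * M
#' entries that match the true cell genotypes. All positions are compared
#' (simulated ground truth is defined even where the observation was
#' missing).
#'
#' @param true_cell_genotypes N x M binary matrix of true cell genotypes.
#' @param inferred_E K x M binary matrix of inferred clone genotypes.
#' @param inferred_labels integer labels in `1..K`, one per cell.
#' @return Fraction in `[0, 1]`.
#' @export
genotyping_accuracy <- function(true_cell_genotypes, inferred_E, inferred_labels) {
  n <- nrow(true_cell_genotypes)
  if (length(inferred_labels) != n) {
    stop("one label per cell is required", call. = FALSE)
  }
  if (min(inferred_labels) < 1L || max(inferred_labels) > nrow(inferred_E)) {
    stop("labels outside 1..K", call. = FALSE)
  }
  if (ncol(true_cell_genotypes) != ncol(inferred_E)) {
    stop("locus count mismatch between truth and inferred genotypes", call. = FALSE)
  }
  expanded <- inferred_E[inferred_labels, , drop = FALSE]
  mean(expanded == true_cell_genotypes)
}

#' Score a pipeline result against simulated ground truth
#'
#' @param sim a `simulated_dataset`.
#' @param assignment a `cluster_assignment`.
#' @param genotypes a `clonal_genotypes` (optional; genotyping accuracy is
#'   `NA` when absent).
#' @param exclude_doublets drop doublet cells from both metrics (default
#'   `FALSE`; doublets count with their host clone as true label).
#' @return A one-row data.frame with `ari`, `genotyping_accuracy`, `k_true`,
#'   `k_inferred`.
#' @export
evaluate_run <- function(sim, assignment, genotypes = NULL,
                         exclude_doublets = FALSE) {
  stopifnot(inherits(sim, "simulated_dataset"),
            inherits(assignment, "cluster_assignment"))
  keep <- if (exclude_doublets) !sim$doublet_flags else rep(TRUE, length(sim$true_labels))
  ari <- adjusted_rand_index(sim$true_labels[keep], assignment$labels[keep])
  acc <- NA_real_
  if (!is.null(genotypes)) {
    acc <- genotyping_accuracy(sim$true_cell_genotypes[keep, , drop = FALSE],
                               genotypes$E, assignment$labels[keep])
  }
  data.frame(ari = ari, genotyping_accuracy = acc,
             k_true = sim$config$n_clones, k_inferred = assignment$K)
}
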