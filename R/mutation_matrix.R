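#' Construct a mutation matrix
#'
#' A `mutation_matrix` holds binary mutation calls for N single cells at M
#' genomic loci: entry `(i, j)` is 1 if mutation j was called present in cell
#' i, 0 if called absent, and `NA` if the site was unobserved (e.g. dropped
#' out during amplification). This is the input representation used by
#' single-cell SNV clustering tools such as SCITE and SiFit.
#'
#' @param values integer matrix with entries in `{0, 1, NA}`; rows are cells,
#'   columns are loci.
#' @param cell_ids character vector of unique cell identifiers (default
#'   `"cell_0" ... "cell_{N-1}"`).
#' @param locus_ids character vector of unique locus identifiers (default
#'   `"locus_0" ... "locus_{M-1}"`).
#' @return An integer matrix of class `mutation_matrix` with `dimnames`
#'   `list(cell_ids, locus_ids)`.
#' @examples
#' m <- mutation_matrix(rbind(c(0L, 1L), c(NA, 0L)))
#' n_cells(m)
#' @export
mutation_matrix <- function(values, cell_ids = NULL, locus_ids = NULL) {
  if (!is.matrix(values)) {
    values <- as.matrix(values)
  }
  storage.mode(values) <- "integer"
  n <- nrow(values)
  m <- ncol(values)
  if (n < 1L || m < 1L) {
    stop("mutation matrix must have at least one cell and one locus", call. = FALSE)
  }
  if (is.null(cell_ids)) cell_ids <- paste0("cell_", seq_len(n) - 1L)
  if (is.null(locus_ids)) locus_ids <- paste0("locus_", seq_len(m) - 1L)
  dimnames(values) <- list(as.character(cell_ids), as.character(locus_ids))
  class(values) <- c("mutation_matrix", "matrix", "array")
  validate_mutation_matrix(values)
}

#' Validate a mutation matrix
#'
#' Checks the invariants of the container: all entries in `{0, 1, NA}`,
#' unique cell and locus identifiers, and at least one observed (non-missing)
#' entry.
#'
#' @param x object of class `mutation_matrix`.
#' @return `x`, invisibly unchanged, if valid; otherwise an error is raised.
#' @export
validate_mutation_matrix <- function(x) {
  stopifnot(inherits(x, "mutation_matrix"))
  v <- unclass(x)
  bad <- !is.na(v) & v != 0L & v != 1L
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1L, ]
    stop(sprintf(
      "invalid genotype value %d at cell %d, locus %d (must be 0, 1 or missing)",
      v[bad][1L], idx[1L], idx[2L]
    ), call. = FALSE)
  }
  if (all(is.na(v))) {
    stop("mutation matrix has no observed entries", call. = FALSE)
  }
  if (anyDuplicated(rownames(x))) stop("cell identifiers are not unique", call. = FALSE)
  if (anyDuplicated(colnames(x))) stop("locus identifiers are not unique", call. = FALSE)
  x
}

#' @export
print.mutation_matrix <- function(x, ...) {
  cat(sprintf(
    "mutation_matrix: %d cells x %d loci (%.1f%% missing, %.1f%% mutated among observed)\n",
    nrow(x), ncol(x), 100 * mean(is.na(x)),
    100 * mean(x[!is.na(x)] == 1L)
  ))
  invisible(x)
}

#' Number of cells / loci in a mutation matrix
#'
#' @param x a `mutation_matrix`.
#' @return integer count.
#' @export
n_cells <- function(x) nrow(x)

#' @rdname n_cells
#' @export
n_loci <- function(x) ncol(x)

#' @export
`[.mutation_matrix` <- function(x, i, j, ..., drop = FALSE) {
  out <- NextMethod(drop = drop)
  if (is.matrix(out)) class(out) <- c("mutation_matrix", "matrix", "array")
  out
}
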