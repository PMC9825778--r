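#' Read a binary genotype matrix from delimited text
#'
#' Parses a cell-by-locus mutation matrix from CSV/TSV. The file may carry a
#' header row of locus identifiers and/or a leading column of cell
#' identifiers; both are auto-detected (a row/column is treated as
#' identifiers when it contains tokens that do not parse as numbers).
#' Missing genotypes are encoded in files by an integer sentinel
#' (`missing_code`, default 3, the convention used by SCITE/SiFit genotype
#' matrices) and are mapped to `NA` in the returned object.
#'
#' @param path path to a delimited text file.
#' @param missing_code integer written in place of unobserved genotypes
#'   (default 3). Must not be 0 or 1.
#' @param orientation `"cells-as-rows"` (default) if each file row is a cell,
#'   `"cells-as-columns"` if each file column is a cell; the returned matrix
#'   is always cells-as-rows.
#' @param sep field separator; `"auto"` (default) tries tab, comma and
#'   whitespace.
#' @return A [mutation_matrix()].
#' @export
read_mutation_matrix <- function(path, missing_code = 3L,
                                 orientation = c("cells-as-rows", "cells-as-columns"),
                                 sep = "auto") {
  orientation <- match.arg(orientation)
  missing_code <- as.integer(missing_code)
  if (missing_code %in% c(0L, 1L)) {
    stop("missing_code must differ from the genotype codes 0 and 1", call. = FALSE)
  }
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  if (file.size(path) == 0L) stop(sprintf("empty file: %s", path), call. = FALSE)
  dt <- data.table::fread(path, header = FALSE, sep = sep,
                          colClasses = "character", data.table = FALSE,
                          strip.white = TRUE)
  if (nrow(dt) == 0L || ncol(dt) == 0L) {
    stop(sprintf("no parseable rows in %s", path), call. = FALSE)
  }
  tab <- as.matrix(dt)

  is_num <- function(x) !is.na(suppressWarnings(as.numeric(x)))
  # header row: every token among columns 2..end of row 1 is non-numeric
  has_header <- nrow(tab) > 1L && all(!is_num(tab[1L, -1L, drop = TRUE]))
  # id column: every token of column 1 below the (putative) header is
  # non-numeric; a lone stray token is a parse error, not an id column
  body_rows <- if (has_header) -1L else seq_len(nrow(tab))
  has_ids <- ncol(tab) > 1L && all(!is_num(tab[body_rows, 1L]))

  row_ids <- col_ids <- NULL
  if (has_header) {
    col_ids <- tab[1L, ]
    tab <- tab[-1L, , drop = FALSE]
  }
  if (has_ids) {
    row_ids <- tab[, 1L]
    tab <- tab[, -1L, drop = FALSE]
    if (!is.null(col_ids)) col_ids <- col_ids[-1L]
  }

  vals <- suppressWarnings(as.numeric(tab))
  bad <- which(is.na(vals) & !(tab %in% c("NA", "")))
  if (length(bad)) {
    i <- (bad[1L] - 1L) %% nrow(tab) + 1L
    j <- (bad[1L] - 1L) %/% nrow(tab) + 1L
    stop(sprintf("unparseable token '%s' at row %d, column %d of %s",
                 tab[bad[1L]], i, j, path), call. = FALSE)
  }
  vals <- matrix(as.integer(vals), nrow(tab), ncol(tab))
  out_of_range <- !is.na(vals) & !(vals %in% c(0L, 1L, missing_code))
  if (any(out_of_range)) {
    idx <- which(out_of_range, arr.ind = TRUE)[1L, ]
    stop(sprintf(
      "genotype value %d at row %d, column %d of %s is outside {0, 1, %d}",
      vals[out_of_range][1L], idx[1L], idx[2L], path, missing_code
    ), call. = FALSE)
  }
  vals[vals == missing_code] <- NA_integer_

  if (orientation == "cells-as-columns") {
    vals <- t(vals)
    tmp <- row_ids; row_ids <- col_ids; col_ids <- tmp
  }
  mutation_matrix(vals, cell_ids = row_ids, locus_ids = col_ids)
}

#' Write a mutation matrix to delimited text
#'
#' Inverse of [read_mutation_matrix()]: writes a TSV with a header row of
#' locus identifiers and a leading `cell_id` column, encoding `NA` as
#' `missing_code`.
#'
#' @param x a [mutation_matrix()].
#' @param path output file path.
#' @param missing_code integer sentinel for missing entries (default 3).
#' @param ids write cell/locus identifiers (default `TRUE`).
#' @return `path`, invisibly.
#' @export
write_mutation_matrix <- function(x, path, missing_code = 3L, ids = TRUE) {
  stopifnot(inherits(x, "mutation_matrix"))
  v <- unclass(x)
  v[is.na(v)] <- as.integer(missing_code)
  if (ids) {
    df <- data.frame(cell_id = rownames(x), v, check.names = FALSE)
    colnames(df) <- c("cell_id", colnames(x))
  } else {
    df <- as.data.frame(v)
  }
  data.table::fwrite(df, path, sep = "\t", col.names = ids)
  invisible(path)
}

#' Write all pipeline outputs to a directory
#'
#' Writes the standard result set of a clustering-plus-genotyping run:
#' \describe{
#'   \item{`labels.tsv`}{`cell_id`, `label` (labels are 0-based, `0..K-1`).}
#'   \item{`genotypes.tsv`}{K rows by M columns of 0/1 clone genotypes with a
#'     locus-id header; row k is the genotype of cluster label `k-1`.}
#'   \item{`latent.tsv`}{`cell_id` plus the D latent coordinates per cell.}
#'   \item{`summary.yaml`}{selected K, estimated error rates alpha and beta,
#'     seed and a config echo.}
#' }
#'
#' @param assignment a `cluster_assignment` from [select_clusters()].
#' @param genotypes a `clonal_genotypes` from [gibbs_infer()].
#' @param embedding a `latent_embedding` from [embed_cells()].
#' @param out_dir output directory, created if absent.
#' @param seed integer seed to record in the summary (optional).
#' @param config list echoed verbatim into the summary (optional).
#' @return Named character vector of the four file paths, invisibly.
#' @export
write_results <- function(assignment, genotypes, embedding, out_dir,
                          seed = NULL, config = NULL) {
  stopifnot(inherits(assignment, "cluster_assignment"),
            inherits(genotypes, "clonal_genotypes"),
            inherits(embedding, "latent_embedding"))
  n <- length(assignment$labels)
  if (nrow(embedding$coords) != n) {
    stop("assignment and embedding refer to different cell sets", call. = FALSE)
  }
  if (assignment$K != nrow(genotypes$E)) {
    stop("assignment K does not match the number of genotype rows", call. = FALSE)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  paths <- c(labels = file.path(out_dir, "labels.tsv"),
             genotypes = file.path(out_dir, "genotypes.tsv"),
             latent = file.path(out_dir, "latent.tsv"),
             summary = file.path(out_dir, "summary.yaml"))

  data.table::fwrite(
    data.frame(cell_id = embedding$cell_ids, label = assignment$labels - 1L),
    paths[["labels"]], sep = "\t"
  )
  geno <- as.data.frame(genotypes$E)
  colnames(geno) <- colnames(genotypes$E)
  data.table::fwrite(geno, paths[["genotypes"]], sep = "\t")
  lat <- data.frame(cell_id = embedding$cell_ids, embedding$coords,
                    check.names = FALSE)
  colnames(lat) <- c("cell_id", paste0("z", seq_len(ncol(embedding$coords)) - 1L))
  data.table::fwrite(lat, paths[["latent"]], sep = "\t")

  summary <- list(
    K = as.integer(assignment$K),
    alpha = as.numeric(genotypes$alpha),
    beta = as.numeric(genotypes$beta),
    gibbs_iterations = as.integer(genotypes$n_iterations),
    gibbs_converged = isTRUE(genotypes$converged),
    seed = if (is.null(seed)) NULL else as.integer(seed),
    config = config
  )
  yaml::write_yaml(summary[!vapply(summary, is.null, logical(1))],
                   paths[["summary"]])
  invisible(paths)
}
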