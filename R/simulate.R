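#' Simulation configuration
#'
#' Parameters of the synthetic single-cell mutation data generator. Defaults
#' describe the reference simulation condition: 1000 cells, 1000 mutation
#' loci, 20 clones, false-positive rate 0.01, false-negative rate 0.3, 2%
#' missing entries and 10% doublet cells.
#'
#' @param alpha false-positive rate in `[0, 1)` (default 0.01).
#' @param beta false-negative rate in `[0, 1)` (default 0.3).
#' @param n_cells number of cells N (default 1000).
#' @param n_loci number of mutation loci M (default 1000).
#' @param n_clones number of clones K (default 20); requires `K <= N` and
#'   `K <= M` so each clone can carry at least one distinguishing mutation.
#' @param missing_rate probability an entry is unobserved (default 0.02).
#' @param doublet_rate fraction of cells replaced by doublets (default 0.10).
#' @param min_clone_fraction lower bound on each clone's share of cells
#'   (default 0.01; automatically capped at `1 / (2 * n_clones)` so that the
#'   constraint is always satisfiable).
#' @param seed integer seed.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(alpha = 0.01, beta = 0.3, n_cells = 1000L,
                              n_loci = 1000L, n_clones = 20L,
                              missing_rate = 0.02, doublet_rate = 0.10,
                              min_clone_fraction = 0.01, seed = 1L) {
  n_cells <- as.integer(n_cells); n_loci <- as.integer(n_loci)
  n_clones <- as.integer(n_clones)
  if (n_clones > n_cells || n_clones > n_loci) {
    stop("need n_clones <= n_cells and n_clones <= n_loci", call. = FALSE)
  }
  stopifnot(alpha >= 0, alpha < 1, beta >= 0, beta < 1,
            missing_rate >= 0, missing_rate < 1,
            doublet_rate >= 0, doublet_rate < 1,
            min_clone_fraction >= 0)
  min_clone_fraction <- min(min_clone_fraction, 1 / (2 * n_clones))
  structure(list(alpha = alpha, beta = beta, n_cells = n_cells,
                 n_loci = n_loci, n_clones = n_clones,
                 missing_rate = missing_rate, doublet_rate = doublet_rate,
                 min_clone_fraction = min_clone_fraction,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

#' Simulation presets for the benchmark sweeps
#'
#' Returns a [simulation_config()] for one level of the six benchmark
#' dataset families, which sweep one factor at a time around the default
#' condition (alpha = 0.01, beta = 0.3, N = 1000, M = 1000, K = 20):
#' \describe{
#'   \item{D1}{false-negative rate beta in `{0.3, 0.4, 0.5, 0.6}`.}
#'   \item{D2}{number of cells N in `{500, 1000, 2000, 5000}`.}
#'   \item{D3}{number of loci M in `{500, 1000, 2000, 5000}`.}
#'   \item{D4}{number of clones K in `{20, 30, 40, 50}`, with N = M = 2000.}
#'   \item{D5}{small data: N in `{100, ..., 500}`, M = 100, K = 5.}
#'   \item{D6}{few mutations: M in `{20, 30, 40, 50, 60}`, N = 500, K = 5.}
#' }
#'
#' @param name one of `"D1"` ... `"D6"`.
#' @param level 1-based index into the swept grid above.
#' @param seed integer seed stored in the config.
#' @return A [simulation_config()].
#' @examples
#' preset("D1", 4)$beta   # 0.6
#' preset("D4", 1)$n_loci # 2000
#' @export
preset <- function(name, level, seed = 1L) {
  grids <- list(
    D1 = list(factor = "beta", values = c(0.3, 0.4, 0.5, 0.6)),
    D2 = list(factor = "n_cells", values = c(500L, 1000L, 2000L, 5000L)),
    D3 = list(factor = "n_loci", values = c(500L, 1000L, 2000L, 5000L)),
    D4 = list(factor = "n_clones", values = c(20L, 30L, 40L, 50L)),
    D5 = list(factor = "n_cells", values = c(100L, 200L, 300L, 400L, 500L)),
    D6 = list(factor = "n_loci", values = c(20L, 30L, 40L, 50L, 60L))
  )
  if (!name %in% names(grids)) {
    stop(sprintf("unknown preset '%s' (expected D1..D6)", name), call. = FALSE)
  }
  g <- grids[[name]]
  level <- as.integer(level)
  if (level < 1L || level > length(g$values)) {
    stop(sprintf("preset %s has levels 1..%d (got %d)", name,
                 length(g$values), level), call. = FALSE)
  }
  args <- list(seed = seed)
  args[[g$factor]] <- g$values[level]
  if (name == "D4") { args$n_cells <- 2000L; args$n_loci <- 2000L }
  if (name == "D5") { args$n_loci <- 100L; args$n_clones <- 5L }
  if (name == "D6") { args$n_cells <- 500L; args$n_clones <- 5L }
  do.call(simulation_config, args)
}

# random recursive tree on K nodes: parent of node i drawn uniformly from
# 1..i-1; node 1 is the root
random_clone_tree <- function(k) {
  if (k == 1L) return(integer(0))
  parents <- integer(k)
  parents[1L] <- 0L
  for (i in 2:k) parents[i] <- sample.int(i - 1L, 1L)
  parents
}

# clone genotypes from a tree: mutations are scattered uniformly over the
# clones (resampling until every clone owns >= 1 private mutation) and each
# clone inherits all mutations on its root path
clone_genotypes_from_tree <- function(k, m, parents) {
  repeat {
    owner <- sample.int(k, m, replace = TRUE)
    if (length(unique(owner)) == k) break
  }
  geno <- matrix(0L, k, m)
  for (node in seq_len(k)) {
    anc <- node
    while (anc != 0L) {
      geno[node, owner == anc] <- 1L
      anc <- if (anc == 1L) 0L else parents[anc]
    }
  }
  geno
}

#' Simulate a single-cell mutation dataset with known clonal structure
#'
#' Generates ground truth and a noisy observed matrix in five steps:
#' \enumerate{
#'   \item Draw a random clonal tree on K nodes and scatter the M mutations
#'     uniformly over the clones (resampling until every clone owns at least
#'     one); each clone's genotype is the union of the mutations on its path
#'     from the root, so genotypes are pairwise distinct and tree-consistent.
#'   \item Draw clone proportions from a symmetric Dirichlet(1) rescaled so
#'     every clone's share is at least `min_clone_fraction`, and assign
#'     cells to clones by sampling from those proportions (re-drawn if any
#'     clone ends up empty).
#'   \item Turn `floor(doublet_rate * N)` randomly chosen cells into
#'     doublets: each doublet's true genotype is the entrywise OR of its
#'     host clone's genotype and the genotype of a second clone chosen
#'     uniformly among the others. Doublets keep the host clone as their
#'     ground-truth label.
#'   \item Corrupt entries independently: a true 1 is observed as 0 with
#'     probability `beta` (allele dropout / false negative) and a true 0 as
#'     1 with probability `alpha` (false positive).
#'   \item Mask each entry as missing independently with probability
#'     `missing_rate`.
#' }
#'
#' @param config a [simulation_config()].
#' @return An object of class `simulated_dataset`: list with `observed`
#'   (a [mutation_matrix()]), `true_labels` (N integers in `1..K`),
#'   `true_clone_genotypes` (K x M), `true_cell_genotypes` (N x M),
#'   `doublet_flags` (N logicals) and `config`.
#' @export
simulate_dataset <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  n <- config$n_cells; m <- config$n_loci; k <- config$n_clones

  parents <- random_clone_tree(k)
  clone_geno <- clone_genotypes_from_tree(k, m, parents)

  # clone proportions: shifted symmetric Dirichlet(1) guaranteeing the
  # minimum clone fraction
  w <- stats::rgamma(k, shape = 1)
  props <- config$min_clone_fraction +
    (1 - k * config$min_clone_fraction) * w / sum(w)
  repeat {
    labels <- sample.int(k, n, replace = TRUE, prob = props)
    if (length(unique(labels)) == k) break
  }

  cell_geno <- clone_geno[labels, , drop = FALSE]
  n_doublets <- floor(config$doublet_rate * n)
  doublet_flags <- rep(FALSE, n)
  if (n_doublets >= 1L && k >= 2L) {
    dbl <- sample.int(n, n_doublets)
    doublet_flags[dbl] <- TRUE
    for (i in dbl) {
      other <- sample(setdiff(seq_len(k), labels[i]), 1L)
      cell_geno[i, ] <- pmax(cell_geno[i, ], clone_geno[other, ])
    }
  }

  observed <- cell_geno
  flips_to_zero <- cell_geno == 1L & matrix(stats::runif(n * m), n, m) < config$beta
  flips_to_one <- cell_geno == 0L & matrix(stats::runif(n * m), n, m) < config$alpha
  observed[flips_to_zero] <- 0L
  observed[flips_to_one] <- 1L
  if (config$missing_rate > 0) {
    observed[matrix(stats::runif(n * m), n, m) < config$missing_rate] <- NA_integer_
  }

  structure(list(observed = mutation_matrix(observed),
                 true_labels = as.integer(labels),
                 true_clone_genotypes = clone_geno,
                 true_cell_genotypes = cell_geno,
                 doublet_flags = doublet_flags,
                 clone_tree_parents = parents,
                 config = config),
            class = "simulated_dataset")
}

#' @export
print.simulated_dataset <- function(x, ...) {
  cat(sprintf(
    "simulated_dataset: %d cells x %d loci, %d clones, %d doublets (alpha = %g, beta = %g)\n",
    nrow(x$observed), ncol(x$observed), x$config$n_clones,
    sum(x$doublet_flags), x$config$alpha, x$config$beta
  ))
  invisible(x)
}

#' Write a simulated dataset and its ground truth to a directory
#'
#' Writes `matrix.tsv` (observed genotypes, 0/1/3 dialect),
#' `truth_labels.tsv` (cell_id, 0-based clone label, doublet flag) and
#' `truth_genotypes.tsv` (K x M clone genotypes).
#'
#' @param sim a `simulated_dataset`.
#' @param out_dir output directory, created if absent.
#' @param missing_code sentinel for missing entries (default 3).
#' @return Named character vector of file paths, invisibly.
#' @export
write_simulated_dataset <- function(sim, out_dir, missing_code = 3L) {
  stopifnot(inherits(sim, "simulated_dataset"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(matrix = file.path(out_dir, "matrix.tsv"),
             labels = file.path(out_dir, "truth_labels.tsv"),
             genotypes = file.path(out_dir, "truth_genotypes.tsv"))
  write_mutation_matrix(sim$observed, paths[["matrix"]], missing_code = missing_code)
  data.table::fwrite(
    data.frame(cell_id = rownames(sim$observed),
               label = sim$true_labels - 1L,
               doublet = as.integer(sim$doublet_flags)),
    paths[["labels"]], sep = "\t"
  )
  geno <- as.data.frame(sim$true_clone_genotypes)
  colnames(geno) <- colnames(sim$observed)
  data.table::fwrite(geno, paths[["genotypes"]], sep = "\t")
  invisible(paths)
}
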