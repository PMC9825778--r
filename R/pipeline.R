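#' Pipeline configuration
#'
#' Bundles the stage configurations of the full workflow. A single top-level
#' `seed` deterministically derives the per-stage seeds (VAE training,
#' mixture fitting, Gibbs sampling), so one integer reproduces a whole run.
#'
#' @param seed top-level integer seed (default 1).
#' @param vae a [vae_config()]; its `seed` is overwritten by the derived
#'   stage seed.
#' @param max_clusters,patience cluster-selection settings (see
#'   [select_clusters()]).
#' @param gibbs_max_iter,gibbs_tol,alpha_init,beta_init Gibbs settings (see
#'   [gibbs_infer()]).
#' @param missing_code,orientation input-parsing settings (see
#'   [read_mutation_matrix()]).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, vae = vae_config(),
                            max_clusters = NULL, patience = 10L,
                            gibbs_max_iter = 200L, gibbs_tol = 1e-4,
                            alpha_init = 0.01, beta_init = 0.01,
                            missing_code = 3L,
                            orientation = "cells-as-rows") {
  seed <- as.integer(seed)
  # derived stage seeds, kept inside the 32-bit integer range
  stage_seed <- function(offset) as.integer((abs(seed) + offset) %% .Machine$integer.max)
  vae$seed <- stage_seed(1L)
  structure(list(seed = seed, vae = vae,
                 max_clusters = max_clusters, patience = as.integer(patience),
                 gmm_seed = stage_seed(2L),
                 gibbs_max_iter = as.integer(gibbs_max_iter),
                 gibbs_tol = gibbs_tol,
                 alpha_init = alpha_init, beta_init = beta_init,
                 gibbs_seed = stage_seed(3L),
                 missing_code = as.integer(missing_code),
                 orientation = orientation),
            class = "pipeline_config")
}

#' Run the full clustering-and-genotyping workflow
#'
#' Executes the three stages end to end on a binary mutation matrix:
#' dimensionality reduction with the variational autoencoder
#' ([train_vae()], [embed_cells()]), cell clustering with a BIC-selected
#' Gaussian mixture ([select_clusters()]) and clone genotype plus error-rate
#' estimation by Gibbs sampling ([gibbs_infer()]). If `out_dir` is given,
#' all results are written there via [write_results()].
#'
#' @param input a [mutation_matrix()], or a path to a delimited genotype
#'   matrix readable by [read_mutation_matrix()].
#' @param config a [pipeline_config()].
#' @param out_dir optional output directory.
#' @param verbose print stage progress and timings (default `FALSE`).
#' @return A list of class `pipeline_result` with `assignment`, `genotypes`,
#'   `embedding`, `model` and `timings` (seconds per stage).
#' @export
run_pipeline <- function(input, config = pipeline_config(), out_dir = NULL,
                         verbose = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  data <- if (inherits(input, "mutation_matrix")) {
    input
  } else {
    read_mutation_matrix(input, missing_code = config$missing_code,
                         orientation = config$orientation)
  }
  say <- function(...) if (verbose) message(sprintf(...))
  timings <- c(vae = NA_real_, cluster = NA_real_, gibbs = NA_real_)

  say("training VAE on %d cells x %d loci ...", nrow(data), ncol(data))
  t0 <- proc.time()[["elapsed"]]
  model <- train_vae(data, config$vae)
  embedding <- embed_cells(data, model)
  timings[["vae"]] <- proc.time()[["elapsed"]] - t0

  say("selecting clusters by BIC ...")
  t0 <- proc.time()[["elapsed"]]
  assignment <- select_clusters(embedding, max_clusters = config$max_clusters,
                                patience = config$patience,
                                seed = config$gmm_seed)
  timings[["cluster"]] <- proc.time()[["elapsed"]] - t0
  say("selected K = %d", assignment$K)

  say("estimating genotypes and error rates by Gibbs sampling ...")
  t0 <- proc.time()[["elapsed"]]
  genotypes <- gibbs_infer(data, assignment$labels,
                           max_iter = config$gibbs_max_iter,
                           seed = config$gibbs_seed,
                           alpha_init = config$alpha_init,
                           beta_init = config$beta_init,
                           tol = config$gibbs_tol)
  timings[["gibbs"]] <- proc.time()[["elapsed"]] - t0
  say("alpha = %.4f, beta = %.4f", genotypes$alpha, genotypes$beta)

  if (!is.null(out_dir)) {
    write_results(assignment, genotypes, embedding, out_dir,
                  seed = config$seed,
                  config = list(
                    latent_dim = config$vae$latent_dim,
                    kl_weight = config$vae$kl_weight,
                    learning_rate = config$vae$learning_rate,
                    batch_size = config$vae$batch_size,
                    epochs = config$vae$epochs,
                    patience = config$patience,
                    gibbs_max_iter = config$gibbs_max_iter,
                    gibbs_tol = config$gibbs_tol,
                    alpha_init = config$alpha_init,
                    beta_init = config$beta_init
                  ))
  }
  structure(list(assignment = assignment, genotypes = genotypes,
                 embedding = embedding, model = model, timings = timings),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf(
    "pipeline_result: %d cells, K = %d, alpha = %.4f, beta = %.4f\n",
    length(x$assignment$labels), x$assignment$K,
    x$genotypes$alpha, x$genotypes$beta
  ))
  invisible(x)
}
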