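test_that("posterior matches hand-evaluated cases", {
  # one cell observed mutated
  m1 <- mutation_matrix(matrix(1L, 1, 1))
  expect_equal(genotype_posterior(m1, 1L, 0.01, 0.01)[1, 1],
               0.99 / (0.99 + 0.01))
  # two cells both observed unmutated
  m2 <- mutation_matrix(matrix(0L, 2, 1))
  expect_equal(genotype_posterior(m2, c(1L, 1L), 0.01, 0.3)[1, 1],
               0.3^2 / (0.3^2 + 0.99^2))
  # a fully missing cluster-locus pair falls back to the uniform prior
  m3 <- mutation_matrix(rbind(c(NA, 1L), c(NA, 0L)))
  expect_equal(genotype_posterior(m3, c(1L, 1L), 0.01, 0.3)[1, 1], 0.5)
})

test_that("posterior normalizes across the two genotype states", {
  set.seed(21)
  for (rep in 1:10) {
    n <- sample(5:40, 1); m <- sample(3:25, 1); k <- sample(1:4, 1)
    v <- matrix(sample(c(0L, 1L, NA), n * m, replace = TRUE,
                       prob = c(0.5, 0.4, 0.1)), n, m)
    if (all(is.na(v))) v[1, 1] <- 1L
    labels <- sample(seq_len(k), n, replace = TRUE)
    labels[seq_len(k)] <- seq_len(k)  # every cluster non-empty
    alpha <- runif(1, 0.005, 0.2); beta <- runif(1, 0.05, 0.6)
    data <- mutation_matrix(v)
    p1 <- genotype_posterior(data, labels, alpha, beta)
    # complementary run: relabel 0<->1 and swap the error roles
    v2 <- v; v2[v == 0L] <- 1L; v2[v == 1L] <- 0L
    p0 <- genotype_posterior(mutation_matrix(v2), labels, beta, alpha)
    expect_equal(p1 + p0, matrix(1, k, m), ignore_attr = TRUE, tolerance = 1e-12)
  }
})

test_that("rate updates match hand evaluation and leave empty cases unchanged", {
  d <- mutation_matrix(matrix(c(1L, 0L, 0L, 0L), 1, 4))
  r <- update_error_rates(d, matrix(0L, 1, 4), 1L,
                          prev_alpha = 0.33, prev_beta = 0.44)
  expect_equal(r[["alpha"]], 0.25)
  expect_equal(r[["beta"]], 0.44)
  expect_equal(attr(r, "degenerate"), "beta")
})

test_that("noiseless data yield zero error rates", {
  sim <- clean_sim(seed = 12, n = 40, m = 30, k = 3)
  r <- update_error_rates(sim$observed, sim$true_clone_genotypes, sim$true_labels)
  expect_equal(unname(r), c(0, 0))
})

test_that("closed-form rate updates equal the brute-force grid MLE", {
  set.seed(31)
  for (rep in 1:5) {
    n <- 50; m <- 20; k <- 3
    labels <- c(seq_len(k), sample(seq_len(k), n - k, replace = TRUE))
    E <- matrix(sample(c(0L, 1L), k * m, replace = TRUE), k, m)
    truth <- E[labels, ]
    v <- truth
    flip1 <- truth == 1L & matrix(runif(n * m), n, m) < 0.25
    flip0 <- truth == 0L & matrix(runif(n * m), n, m) < 0.08
    v[flip1] <- 0L; v[flip0] <- 1L
    v[matrix(runif(n * m), n, m) < 0.05] <- NA
    if (all(is.na(v))) v[1, 1] <- 1L
    data <- mutation_matrix(v)
    closed <- update_error_rates(data, E, labels,
                                 prev_alpha = 0.5, prev_beta = 0.5)
    grid <- grid_mle_rates(data, E, labels)
    expect_lt(abs(closed[["alpha"]] - grid[["alpha"]]), 1e-3)
    expect_lt(abs(closed[["beta"]] - grid[["beta"]]), 1e-3)
  }
})

test_that("adding false positives never decreases the alpha estimate", {
  set.seed(41)
  k <- 2; m <- 15; n <- 30
  labels <- c(1L, 2L, sample(1:2, n - 2, replace = TRUE))
  E <- matrix(sample(c(0L, 1L), k * m, replace = TRUE), k, m)
  v <- E[labels, ]
  zero_pos <- which(v == 0L)
  prev <- -Inf
  for (extra in c(0, 5, 15, 40)) {
    v2 <- v
    v2[zero_pos[seq_len(extra)]] <- 1L
    r <- update_error_rates(mutation_matrix(v2), E, labels)
    expect_gte(r[["alpha"]], prev)
    prev <- r[["alpha"]]
  }
})

test_that("Gibbs inference recovers the consensus genotype on clean data", {
  sim <- clean_sim(seed = 19, n = 60, m = 40, k = 4)
  g <- gibbs_infer(sim$observed, sim$true_labels, seed = 2)
  expect_equal(unname(g$E), unname(sim$true_clone_genotypes))
  expect_lt(g$alpha, 1e-3)
  expect_lt(g$beta, 1e-3)
  expect_true(g$converged)
})

test_that("Gibbs inference is reproducible and flags non-convergence", {
  sim <- simulate_dataset(simulation_config(
    n_cells = 80, n_loci = 40, n_clones = 4, beta = 0.3, seed = 23
  ))
  g1 <- suppressWarnings(gibbs_infer(sim$observed, sim$true_labels, seed = 9))
  g2 <- suppressWarnings(gibbs_infer(sim$observed, sim$true_labels, seed = 9))
  expect_identical(g1$E, g2$E)
  expect_identical(g1$alpha, g2$alpha)
  expect_warning(gibbs_infer(sim$observed, sim$true_labels, max_iter = 2, seed = 1),
                 "did not converge")
})

test_that("error-rate recovery from ground-truth labels is accurate", {
  sim <- simulate_dataset(simulation_config(seed = 71, n_cells = 300,
                                            n_loci = 300, n_clones = 8,
                                            doublet_rate = 0))
  g <- suppressWarnings(gibbs_infer(sim$observed, sim$true_labels, seed = 4))
  expect_lt(abs(g$beta - 0.3), 0.05)
  expect_lt(abs(g$alpha - 0.01), 0.02)
})

test_that("posterior and E are consistent and labels are validated", {
  sim <- simulate_dataset(simulation_config(n_cells = 50, n_loci = 30,
                                            n_clones = 3, seed = 13))
  g <- suppressWarnings(gibbs_infer(sim$observed, sim$true_labels, seed = 1))
  expect_identical(unname(g$E), unname(matrix(as.integer(g$posterior > 0.5),
                                              nrow(g$E), ncol(g$E))))
  expect_true(all(g$posterior >= 0 & g$posterior <= 1))
  expect_error(genotype_posterior(sim$observed, rep(2L, 50), 0.01, 0.3),
               "labels")
  expect_error(genotype_posterior(sim$observed, sim$true_labels, 0, 0.3),
               "strictly inside")
})
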