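test_that("noiseless simulation reproduces the cell genotypes exactly", {
  sim <- clean_sim(seed = 2)
  expect_identical(unname(unclass(sim$observed)), unname(sim$true_cell_genotypes))
  expect_equal(sum(sim$doublet_flags), 0L)
  expect_equal(sum(is.na(sim$observed)), 0L)
})

test_that("clone genotypes are distinct and tree-consistent", {
  for (seed in c(1, 2, 3)) {
    sim <- simulate_dataset(simulation_config(n_cells = 50, n_loci = 40,
                                              n_clones = 8, seed = seed))
    g <- sim$true_clone_genotypes
    expect_equal(nrow(unique(g)), 8L)
    parents <- sim$clone_tree_parents
    for (node in 2:8) {
      p <- parents[node]
      # child inherits every parental mutation
      expect_true(all(g[node, g[p, ] == 1L] == 1L))
    }
    # non-doublet cells carry their clone's genotype
    nd <- which(!sim$doublet_flags)
    expect_identical(sim$true_cell_genotypes[nd, ],
                     g[sim$true_labels[nd], ])
  }
})

test_that("realized corruption rates concentrate around alpha and beta", {
  cfg <- simulation_config(seed = 33, alpha = 0.02, beta = 0.3,
                           missing_rate = 0, doublet_rate = 0,
                           n_cells = 400, n_loci = 400, n_clones = 10)
  sim <- simulate_dataset(cfg)
  truth <- sim$true_cell_genotypes
  obs <- unclass(sim$observed)
  n1 <- sum(truth == 1L)
  n0 <- sum(truth == 0L)
  beta_hat <- sum(obs == 0L & truth == 1L) / n1
  alpha_hat <- sum(obs == 1L & truth == 0L) / n0
  expect_lt(abs(beta_hat - 0.3), 3 * sqrt(0.3 * 0.7 / n1))
  expect_lt(abs(alpha_hat - 0.02), 3 * sqrt(0.02 * 0.98 / n0))
})

test_that("doublets are OR-merges of two clone genotypes at the stated rate", {
  sim <- simulate_dataset(simulation_config(seed = 9, n_cells = 200,
                                            n_loci = 100, n_clones = 6,
                                            alpha = 0, beta = 0,
                                            missing_rate = 0))
  expect_equal(sum(sim$doublet_flags), 20L)  # floor(0.10 * 200)
  g <- sim$true_clone_genotypes
  for (i in which(sim$doublet_flags)) {
    host <- sim$true_labels[i]
    prof <- sim$true_cell_genotypes[i, ]
    # profile contains the host genotype plus exactly one other clone's
    expect_true(all(prof[g[host, ] == 1L] == 1L))
    partners <- which(vapply(seq_len(6), function(k2) {
      k2 != host && all(prof == pmax(g[host, ], g[k2, ]))
    }, logical(1)))
    expect_gte(length(partners), 1L)
  }
})

test_that("missing entries appear at the configured rate", {
  sim <- simulate_dataset(simulation_config(seed = 10, n_cells = 300,
                                            n_loci = 300, missing_rate = 0.05,
                                            n_clones = 5))
  frac <- mean(is.na(sim$observed))
  expect_lt(abs(frac - 0.05), 3 * sqrt(0.05 * 0.95 / (300 * 300)))
})

test_that("the same seed reproduces a dataset bit-for-bit", {
  cfg <- simulation_config(seed = 77, n_cells = 60, n_loci = 50, n_clones = 4)
  s1 <- simulate_dataset(cfg)
  s2 <- simulate_dataset(cfg)
  expect_identical(s1$observed, s2$observed)
  expect_identical(s1$true_labels, s2$true_labels)
  expect_identical(s1$doublet_flags, s2$doublet_flags)
})

test_that("presets encode the benchmark grids", {
  p13 <- preset("D1", 4)
  expect_equal(p13$beta, 0.6)
  expect_equal(p13$n_cells, 1000L)
  expect_equal(p13$n_loci, 1000L)
  expect_equal(p13$n_clones, 20L)
  p4 <- preset("D4", 1)
  expect_equal(p4$n_clones, 20L)
  expect_equal(p4$n_cells, 2000L)
  expect_equal(p4$n_loci, 2000L)
  p6 <- preset("D6", 2)
  expect_equal(p6$n_loci, 30L)
  expect_equal(p6$n_cells, 500L)
  expect_equal(p6$n_clones, 5L)
  p5 <- preset("D5", 1)
  expect_equal(p5$n_cells, 100L)
  expect_equal(p5$n_loci, 100L)
  expect_error(preset("D7", 1), "unknown preset")
  expect_error(preset("D1", 9), "levels 1..4")
})

test_that("infeasible configurations are rejected", {
  expect_error(simulation_config(n_clones = 30, n_cells = 20), "n_clones")
  expect_error(simulation_config(n_clones = 30, n_loci = 20), "n_clones")
  expect_error(simulation_config(beta = 1.2))
})

test_that("simulated datasets write and re-read consistently", {
  sim <- simulate_dataset(simulation_config(seed = 3, n_cells = 40,
                                            n_loci = 30, n_clones = 3))
  out <- withr::local_tempdir()
  paths <- write_simulated_dataset(sim, out)
  back <- read_mutation_matrix(paths[["matrix"]])
  expect_identical(unclass(back), unclass(sim$observed))
  labs <- data.table::fread(paths[["labels"]])
  expect_equal(labs$label, sim$true_labels - 1L)
  expect_equal(as.logical(labs$doublet), sim$doublet_flags)
})
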