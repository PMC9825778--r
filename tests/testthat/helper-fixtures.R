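# Small fixture builders shared across test files.

# a tiny deterministic matrix with one missing entry
tiny_matrix <- function() {
  mutation_matrix(rbind(c(0L, 1L, 1L),
                        c(NA, 0L, 1L),
                        c(1L, 1L, 0L)))
}

# three tight, well-separated spherical blobs in 3-D
blob_coords <- function(n_per = 100, centers = rbind(c(-10, 0, 0),
                                                     c(10, 0, 0),
                                                     c(0, 10, 0)),
                        sd = 0.1, seed = 99) {
  set.seed(seed)
  k <- nrow(centers)
  coords <- do.call(rbind, lapply(seq_len(k), function(i) {
    matrix(rnorm(n_per * 3, sd = sd), n_per, 3) +
      matrix(centers[i, ], n_per, 3, byrow = TRUE)
  }))
  list(coords = coords, labels = rep(seq_len(k), each = n_per))
}

# noiseless small simulation: clean clones, no doublets, no missing data
clean_sim <- function(seed = 5, n = 150, m = 60, k = 3) {
  simulate_dataset(simulation_config(
    alpha = 0, beta = 0, missing_rate = 0, doublet_rate = 0,
    n_cells = n, n_loci = m, n_clones = k, seed = seed
  ))
}

# brute-force grid-search MLE of the error rates given truth assignment;
# independent oracle for the closed-form rate updates
grid_mle_rates <- function(data, E, labels, res = 1e-3) {
  v <- unclass(data)
  expanded <- E[labels, , drop = FALSE]
  obs <- !is.na(v)
  x <- v[obs]
  e <- expanded[obs]
  n10 <- sum(x == 1 & e == 0)  # false positives
  n00 <- sum(x == 0 & e == 0)
  n01 <- sum(x == 0 & e == 1)  # false negatives
  n11 <- sum(x == 1 & e == 1)
  grid <- seq(res, 1 - res, by = res)
  ll_a <- n10 * log(grid) + n00 * log(1 - grid)
  ll_b <- n01 * log(grid) + n11 * log(1 - grid)
  c(alpha = grid[which.max(ll_a)], beta = grid[which.max(ll_b)])
}
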