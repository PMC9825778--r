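# Shared machinery for the benchmark-level tests: each heavy simulation
# condition is run once per test session and reused across assertions.

.bench_cache <- new.env(parent = emptyenv())

bench_run <- function(name, level, data_seed, run_seed) {
  key <- sprintf("%s_%d_%d", name, level, data_seed)
  if (!is.null(.bench_cache[[key]])) return(.bench_cache[[key]])
  sim <- simulate_dataset(preset(name, level, seed = data_seed))
  res <- suppressWarnings(run_pipeline(sim$observed,
                                       pipeline_config(seed = run_seed)))
  ev <- evaluate_run(sim, res$assignment, res$genotypes,
                     exclude_doublets = TRUE)
  .bench_cache[[key]] <- ev
  ev
}

bench_replicates <- function(name, level, n_rep, seed0) {
  do.call(rbind, lapply(seq_len(n_rep), function(i) {
    bench_run(name, level, data_seed = seed0 + i, run_seed = seed0 + 500 + i)
  }))
}
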