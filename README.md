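# bmvae

Inference of tumor subpopulations from noisy binary single-cell mutation
matrices.

Single-cell DNA sequencing produces, after variant calling, an N cells ×
M loci matrix of binary mutation presence calls. The calls are unreliable:
allele dropout turns true 1s into 0s at a false-negative rate β that can
reach 0.3–0.7, artifacts add false positives at a rate α ≈ 0.01, some
entries are unobserved, and ~10% of "cells" are doublets. `bmvae`
reconstructs the clonal architecture from such a matrix in three stages:

1. **Dimensionality reduction** — a variational autoencoder with a masked
   Bernoulli reconstruction loss embeds each cell's profile into a
   3-dimensional latent space,
   `min λ·KL(q(z|x) ‖ N(0,I)) − Σ_{j observed} [x_j log x̂_j + (1−x_j) log(1−x̂_j)]`.
2. **Clustering** — a full-covariance Gaussian mixture is fitted to the
   embedding for k = 1, 2, 3, …; BIC with a patience rule (stop after κ = 10
   consecutive non-improvements) selects the number of clones K.
3. **Genotyping** — given the labels, a Gibbs sampler alternates sampling
   each clone–locus genotype `E_kj` from its exact conditional posterior
   under the error model `p(1|0) = α, p(0|1) = β` with closed-form
   maximum-likelihood updates of (α, β), and reports the thresholded
   marginal posterior plus the estimated error rates.

A synthetic-data generator (`simulate_dataset()`, `preset()`) reproduces
the standard clone-structured benchmark families (clonal tree, skewed
clone sizes, entrywise noise, missing data, OR-merged doublets), and
`evaluate_run()` scores results by adjusted Rand index and genotyping
accuracy. See `vignette("methods", package = "bmvae")` for the full model
description and design rationale.

## Worked example

```r
library(bmvae)

# a benchmark-style dataset: 1000 cells, 1000 loci, 20 clones,
# alpha = 0.01, beta = 0.3, 2% missing, 10% doublets
sim <- simulate_dataset(simulation_config(seed = 11))
sim$observed
#> mutation_matrix: 1000 cells x 1000 loci (2.0% missing, 15.0% mutated among observed)

res <- run_pipeline(sim$observed, pipeline_config(seed = 7), out_dir = "out/")
res
#> pipeline_result: 1000 cells, K = 19, alpha = 0.0170, beta = 0.3274

evaluate_run(sim, res$assignment, res$genotypes, exclude_doublets = TRUE)
#>         ari genotyping_accuracy k_true k_inferred
#> 1 0.9782555           0.9947533     20         19
```

The pipeline recovered 19 clusters for the 20 simulated clones (two small
clones merged), assigned singlet cells to clones nearly perfectly
(ARI 0.978), recovered 99.5% of the cell–locus mutational states, and
estimated the error rates close to the simulated α = 0.01, β = 0.3
(doublet cells, which the model does not represent, bias α̂ slightly
upward). A non-convergence warning from the Gibbs stage is routine: on a
10⁶-entry matrix the per-iteration sampling jitter on the rates exceeds
the 10⁻⁴ tolerance while the rates fluctuate tightly around the MLE.
`out/` now contains `labels.tsv`, `genotypes.tsv`, `latent.tsv` and
`summary.yaml`.

The same workflow runs from a shell on any delimited 0/1/3 genotype
matrix (3 = missing, the SCITE/SiFit convention):

```sh
bmvae run --input matrix.tsv --out results/ --seed 7
bmvae simulate --preset D1 --level 1 --seed 7 --out data/
bmvae evaluate --truth data/ --pred results/ --exclude-doublets
```

(the `bmvae` script is installed under `exec/` in the package directory;
add it to `PATH` or call it via `Rscript`.)

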