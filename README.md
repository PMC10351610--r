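# comodica

Sparse consensus independent component analysis for discovering
competitive-endogenous-RNA (ceRNA) **co-modules** — sets of mRNAs, miRNAs
and lncRNAs that share a common latent activation pattern — from
sample-matched multi-block expression matrices.

`comodica` is aimed at computational biologists who have two or more
expression matrices (features × samples, any RNA types) over a shared
sample set and want joint, cross-block modules rather than per-block
clusters.

## Method at a glance

The blocks are concatenated along the feature axis and factorized as

    X = (X1, ..., XK) = A · S,   S = (S1, ..., SK)

where `A` is a common basis over (PCA-reduced) sample space and the rows
of the module matrix `S` hold per-feature loadings. Each unmixing
direction `w` maximizes the log-cosh negentropy approximation

    J(w) = ( E[G(wᵀz)] − E[G(v)] )²,  G(u) = log cosh u,  v ~ N(0,1)

subject to the unit-variance equality constraint `E[(wᵀz)²] − 1 = 0`,
solved by an augmented-Lagrangian fixed-point iteration with symmetric
decorrelation. ICA operates on wavelet-packet coefficients `C_X`
(`X = C_X · Φ`, best-basis selected by a Gini sparsity criterion); the
decomposition is repeated over many seeded runs, the pooled basis
columns are clustered by affinity propagation under a sign-free
similarity, each cluster's sign-aligned signature is averaged, and
co-module members are selected per block at a two-sided z-score
threshold (`|z| ≥ 1.96` at `alpha = 0.05`).

## Worked example

Simulate three RNA blocks (60 shared samples; 400/80/200 features) with
four planted co-modules at SNR ≈ 5, fit the consensus pipeline, and
score recovery against the planted truth:

```r
library(comodica)

sim <- simulate_comodules(seed = 1)           # reference conditions
fit <- scica(sim$ms, n_components = 4, n_runs = 20,
             normalize = "none", combine = "union", seed = 1)
print(fit)
#> Sparse consensus ICA co-module fit
#>   blocks: mRNA, miRNA, lncRNA | 60 samples, 680 features
#>   PCA dimension: 19 of 60 samples (threshold 0.90)
#>   runs: 20 x 4 components -> 80 pooled basis columns
#>   consensus: 5 cluster(s) by affinity propagation
#>   final co-module [mRNA]: 111 features
#>   final co-module [miRNA]: 38 features
#>   final co-module [lncRNA]: 68 features

set_recovery(planted_union(sim$truth), fit$comodules$final)
#>    block precision recall    f1
#> 1   mRNA     0.901      1 0.948
#> 2  miRNA     0.842      1 0.914
#> 3 lncRNA     0.882      1 0.938
#> 4 pooled     0.885      1 0.939
```

The printout reads: 90% of sample variance needs 19 principal
components; 20 runs × 4 components give 80 pooled basis columns, which
affinity propagation groups into 5 consensus clusters (the 4 planted
modules plus one noise cluster); the union of the per-cluster selections
recovers the planted membership at pooled F1 ≈ 0.94 — every planted
feature is found, with a small number of false positives.

`summary(fit)` adds per-block sample-wise reconstruction correlations,
`fitted()`/`residuals()` return the per-block reconstruction `A·Sᵢ`
mapped back to the original geometry, `coef(fit, "signatures")` returns
the aggregated cluster signatures, and `plot(fit)` draws the per-block
histograms of sample-wise correlations. Real data enter through
`read_expression()` + `align_samples()`; `write_comodules()` exports
GMT-like sets plus a z-score TSV. A thin command-line wrapper with
`simulate`, `run` and `evaluate` subcommands is installed at
`inst/scripts/scica`.

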