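# drivernmf

Prioritization of mutated cancer driver genes from binary somatic-mutation
profiles by **robust and sparse co-regularized nonnegative matrix
factorization**.

Somatic mutation calls for a tumor cohort form a binary matrix
X (n samples × p genes) in which true driver genes are buried under
passenger noise: many passengers recur by chance, and drivers of a small
subtype can be rarer than noise. `drivernmf` is for computational cancer
biologists who want to rank the mutated gene universe by evidence of driver
activity, using two sources of prior information that are almost always
available alongside the mutation calls:

* **expression-derived sample similarity** — samples with correlated mRNA
  profiles (e.g. the same molecular subtype) should have similar
  low-dimensional mutation representations;
* **a gene–gene interaction network** — interacting genes should have
  similar latent representations, because drivers cluster in pathways.

## The model

X is factorized as X ≈ U Vᵀ with nonnegative factors U (n × K, sample
representations) and V (p × K, latent mutation profiles), minimizing

```
J(U, V) = ||X − U Vᵀ||²_F
        + λ_LU Tr(Uᵀ L_W U)        sample-graph smoothness
        + λ_RU ||U||²_F            robustness (anti-overfitting) ridge
        + λ_LV Tr(Vᵀ L̂_Â V)        gene-network smoothness
        + λ_RV Σ_k ( Σ_j |v_jk| )²  sparsity of each latent gene profile
```

where W is the sample-similarity kernel
`W_ij = exp(−|1 − ρ_ij|² / (2σ²))` built from the expression correlation
ρ with bandwidth σ = 1, L_W = D_W − W its (un-normalized) Laplacian, and
L̂_Â = I − D_A^{−1/2} A D_A^{−1/2} the symmetrically normalized Laplacian of
the interaction network (its degree matrix reduces to the identity).
Defaults are K = 4 and λ_LU = λ_RU = λ_LV = λ_RV = 1.

J is minimized by alternating multiplicative updates that keep the factors
nonnegative and the objective monotonically non-increasing:

```
U_ij ← U_ij (X V + λ_LU W U)_ij / (U VᵀV + λ_LU D_W U + λ_RU U + ε)_ij
V_ij ← V_ij (Xᵀ U + λ_LV Â V)_ij / (V UᵀU + λ_LV V + λ_RV E V + ε)_ij
```

(E is the all-ones matrix; E V is computed as broadcast column sums.)
Each gene's **mutation score** is the maximum of its K coefficients in V —
a gene loading strongly on any one latent mutation profile scores highly
even if that profile describes a small subtype — and genes are ranked by
this score. Evaluation utilities compute precision–recall curves and their
AUC against benchmark driver lists, one-sided Fisher's exact enrichment of
the top-k candidates (default cutoffs 50/100/150/200), top-k overlap counts
between methods, and the mutation-frequency baseline every method should
beat.

## Worked example

A fully synthetic cohort with planted drivers (no external data needed):

```r
library(drivernmf)

cohort <- generate_cohort(simulation_config(seed = 3))
cohort
#> <synthetic_cohort: 100 samples x 300 genes, 3 subtypes, 30 planted drivers>

ds     <- align_datasets(cohort$mutation, cohort$expression, cohort$network)
priors <- build_priors(ds)                       # kernel W + normalized Laplacian
fit    <- crnmf(ds, priors, crnmf_config(seed = 3))
fit
#> <crnmf_fit: 100 samples x 300 genes, K = 4; 100 iterations, converged; objective 1684.16>

ranking <- rank_genes(gene_scores(fit),
                      tiebreak_freq = mutation_frequency_scores(ds$mutation))
pr_auc(precision_recall(ranking, cohort$true_drivers))
#> [1] 0.829807
```

The AUC of ~0.83 is the area under the precision–recall curve for
recovering the 30 planted drivers among 300 genes; the same cohort scored
by raw mutation frequency and by prior-free NMF gives lower or comparable
values, and `recovery_experiment()` repeats this comparison across seeds
and ablation variants (`variant_config()`: proposed / only_network /
only_expression / no_prior). `autoplot()` works on fits (objective trace)
and PR curves; `tidy()`/`glance()` return broom-style tibbles.

File-based pipelines use `run_simulate()`, `run_discover()` and
`run_evaluate()` (or the `inst/cli/drivernmf.R` Rscript wrapper with
subcommands `simulate`, `discover`, `evaluate`), reading/writing TSV
matrices, edge lists, gene lists and ranking tables.

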