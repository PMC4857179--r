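# mixbn — learning Bayesian networks from correlated data

Bayesian-network structure learning assumes independent observations, but
family studies and longitudinal designs sample *clusters*: relatives share
genetic background, repeated measures share a subject. When the ordinary
per-node regressions behind a K2-style forward search are applied to such
data, both the trait and many candidate predictors (genotypes, biomarkers)
are correlated within clusters, the tests over-reject, and learned networks
accumulate false edges.

`mixbn` parameterizes each node with a cluster-structured random effect and
scores it with the likelihood in which that effect is integrated out:

* **Gaussian nodes** — `y = Xβ + α + e` with `α ~ N(0, γ²A)`, `A = 2K` the
  additive relationship matrix from the pedigree (or an
  exchangeable/AR1 block structure for repeated measures). The integrated
  likelihood is the exact `N(Xβ, γ²A + σ²I)` density, computed per family
  block via cached eigendecompositions; ML fitting profiles the
  heritability `h² = γ²/(γ² + σ²)` on `[0, 1)`.
* **Survival nodes** — Cox proportional hazards with correlated log-normal
  frailty on the log-hazard scale, `λ_i(t) = λ₀(t) exp(x_iᵀβ + R_i)`,
  `R ~ N(0, γ²A)`; the integrated partial likelihood uses a Laplace
  approximation around the penalized-likelihood mode (Breslow ties), with
  the frailty variance profiled on a log scale.

On top of the node models sit nine selection metrics (BIC with full,
Jones', family-exchangeable, and cluster-count effective sample sizes; AIC;
mixed and naive likelihood-ratio tests), forward selection per node,
ordering enumeration with root/sink constraints, Markov-blanket reporting,
and a simulation harness that measures false positive rate (FPR, errors per
test), family-wise error rate (FWER, replicates with ≥ 1 error), and power.
Pedigree utilities (PED files, recursive kinship computation, gene-dropped
SNP genotypes) and generators for kinship-correlated Gaussian traits and
frailty survival times are included, plus a `mixbn` command-line front end
(`inst/exec/mixbn`) with `kinship`, `learn`, `simulate-study`, and
`simulate-data` subcommands.

## Worked example

Build a synthetic 120-family cohort (8 sampled members each), simulate a
heritable trait (`h² = 0.5`) with 10 null SNP covariates gene-dropped
through the pedigree, and compare forward selection with the mixed-model
LRT against the naive LRT that ignores family structure:

```r
library(mixbn)
ped  <- make_synthetic_cohort(n_families = 120)
kin  <- kinship_from_pedigree(ped)
corr <- correlation_model("kinship", kinship = kin)
y    <- simulate_gaussian_trait(corr, gamma2 = 1, sigma2 = 1, seed = 2)
snps <- gene_drop_snps(ped, q = 10, maf_min = 0.05, seed = 3)

fit_gaussian_mixed(y, matrix(1, length(y), 1), corr)
#> <gaussian_mixed_model> kind=kinship n=960 loglik=-1669.241 gamma2=1.1765 sigma2=0.9252 h2=0.560

dat  <- data.frame(y = y, snps)
node <- node_spec("y", "gaussian", candidates = colnames(snps))
forward_select_node(node, dat, corr, score_config("LRT_M"))$parents
#> character(0)                      # mixed LRT: nothing selected (correct)
forward_select_node(node, dat, corr, score_config("LRT_F"))$parents
#> [1] "snp07"                       # naive LRT: a false edge
```

The variance components recover the generating values (`γ̂² = 1.18`,
`σ̂² = 0.93`, `ĥ² = 0.56`), and on this replicate the naive test already
picks up a spurious SNP. A 100-replicate null study quantifies the
inflation:

```r
sc  <- simulation_scenario("gaussian", gamma2 = 1, n_families = 120,
                           reps = 100, seed = 4)
run_null_study(sc, metrics = c("LRT_M", "LRT_F", "BIC_M", "BIC_C"))
#> <study_result> 100 replicates
#>   metric fp_l1 fp_l2 fp_l3 fp_l4 fp_l5plus tot_test      fpr fwer   se_fpr
#> 1  LRT_M    52     9     0     0         0     1459 0.041809 0.43 0.004442
#> 2  LRT_F    98    32     6     1         0     1853 0.073934 0.68 0.006941
#> 3  BIC_M     4     0     0     0         0     1036 0.003861 0.04 0.001835
#> 4  BIC_C    28     3     0     0         0     1258 0.024642 0.26 0.003888
```

Read: the integrated-likelihood LRT at α = 0.05 stays just below the
nominal per-test error (FPR 0.042), while the same test ignoring the family
correlation rejects at 0.074 — roughly 1.8× too often — and flags at least
one false SNP in 68% of searches. BIC with the full sample size is very
conservative; shrinking the effective sample size toward the number of
families (`BIC_C`) trades that conservatism for a higher error rate.

Full-cohort studies (582 families, n = 4656, 1000 replicates) behave the
same way; they are exactly what `scripts/acceptance.R` runs.

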