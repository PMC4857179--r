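---
title: "Learning Bayesian networks from correlated data: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Learning Bayesian networks from correlated data: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(mixbn)
```

## The problem

Score-based structure learning of a Bayesian network (BN) decomposes into
per-node regressions: under a node ordering, the joint density factorizes as
$\prod_i p(y_i \mid pa(y_i), \theta_i)$, and a K2-style forward search picks
each node's parents by a model-selection metric. The standard theory assumes
independent observations. Family studies and longitudinal designs violate
that assumption: relatives share genetic background, repeated measures share
a subject. Both the trait *and* many candidate predictors (e.g. genotypes)
are then correlated within clusters, and the naive per-node tests reject too
often — every spurious rejection becomes a spurious edge, so learned networks
become systematically too dense.

`mixbn` implements node models whose likelihoods integrate out a
cluster-structured random effect, the family of selection metrics built on
them, the ordering-constrained forward search, and a simulation harness that
measures false positive rates (FPR), family-wise error rates (FWER), and
power of each metric on synthetic cohorts.

## Node models

### Gaussian nodes

For a Gaussian node $y$ with design matrix $X$ (parents plus intercept) the
model is

$$ y = X\beta + \alpha + e, \qquad \alpha \sim N(0, \gamma^2 A), \quad
   e \sim N(0, \sigma^2 I), $$

where $A = 2K$ is the additive genetic relationship matrix (twice the
kinship coefficients; the covariance of two relatives is $2k_{ij}\gamma^2$).
For repeated measures $A$ is replaced by a block-diagonal exchangeable or
AR1 correlation structure over subjects. The integrated likelihood — the
exact $N(X\beta, \gamma^2 A + \sigma^2 I)$ density — is computed per cluster
block after rotating into the eigenbasis of $A_f$: with
$A_f = U_f S_f U_f^T$, the rotated observations are independent with
variances $\sigma^2 + \gamma^2 s_i$. The rotation is computed once per data
set and cached; all candidate-parent fits reuse it, which is what makes
10 candidate evaluations per node per replicate affordable at $n = 4656$.

Fitting is by maximum likelihood (not REML: the metrics compare models with
different fixed effects, for which REML likelihoods are not comparable). The
heritability $h^2 = \gamma^2 / (\gamma^2 + \sigma^2)$ is profiled by Brent
search on $[0, 1 - 10^{-6}]$ with tolerance $10^{-8}$; $\beta$ is profiled
by GLS and the total variance in closed form at each $h^2$. The boundary
$\hat\gamma^2 = 0$ is explicitly allowed. The naive comparator is the OLS
fit with ML error variance. Parameter counts: fixed effects + 2 variance
components (mixed) or + 1 (naive).

### Survival nodes

Time-to-event nodes use a Cox proportional-hazards model with a correlated
log-normal frailty on the log-hazard scale:

$$ \lambda_i(t) = \lambda_0(t)\, e^{x_i^T\beta + R_i}, \qquad
   R \sim N(0, \gamma^2 A). $$

The frailty-integrated partial likelihood has no closed form; a Laplace
approximation is used: Newton–Raphson maximizes the penalized partial
log-likelihood $\ell_{cox}(\beta, R) - \tfrac12 R^T (\gamma^2 A)^{-1} R$
(Breslow tie handling), and the integrated value is the penalized optimum
minus $\tfrac12 \log\det(I + \gamma^2 A H)$ with $H$ the curvature of the
partial likelihood at the mode. The frailty variance is profiled by an outer
Brent search of $\log\gamma^2$ over $[10^{-6}, 10]$. Laplace was chosen over
quadrature because the kinship matrix couples all members of a family —
the integral does not factor below the family level, and risk sets couple
families besides — while quadrature remains feasible (and is used as a test
oracle) only on toy pedigrees of 2–3 subjects.

Two numerical points matter for speed. First, because Breslow risk sets are
nested, the $n \times n$ curvature has the semiseparable form
$\mathrm{diag}(\mu) - D_e M D_e$ with $M_{jl} = G_{\min(j,l)}$ in
time-sorted order, so it is assembled in $O(n^2)$ rather than
$O(d\,n^2)$. Second, during forward selection the candidate refits are warm
started from the null model's mode, and the outer variance search is a local
quadratic refinement (three points around the incumbent
$\hat\gamma^2$ plus the parabola vertex, falling back to a full bracketed
Brent search whenever the parabola disagrees); the null model of each node
still gets the full search. The outer tolerances (Brent $10^{-3}$ on
$\log\gamma^2$; $5\times10^{-3}$ inside the search loop) were set so that
the induced error in a likelihood-ratio statistic is well below $10^{-2}$,
which is negligible against the $\chi^2_1$ scale; nested fits additionally
always evaluate the reduced model's $\hat\gamma^2$, so the LRT statistic
cannot go materially negative. Near-singular relationship blocks receive a
$10^{-8}$ ridge. For survival nodes the BIC sample size is the number of
events.

## Selection metrics

Nine metrics share the interface: `BIC_M`, `BIC_J`, `BIC_Y`, `BIC_C`,
`AIC_M`, `LRT_M` use the integrated likelihood; `BIC_F`, `AIC_F`, `LRT_F`
use the naive IID likelihood. BIC variants are $-2\ell + p\log n_e$ with
different effective sample sizes:

* full $n_e = n$ (`BIC_M`, `BIC_F`);
* Jones' correction $n_e = 1^T C^{-1} 1$, with $C$ the correlation matrix of
  $\hat\gamma^2 A + \hat\sigma^2 I$, computed per family block from the
  cached eigendecompositions and re-evaluated at each search level from the
  current reduced model's variance components (`BIC_J`);
* a family-exchangeable correction $n_e = \sum_f n_f^2 / (1^T C_f 1)$
  (`BIC_Y`). By Cauchy–Schwarz this never exceeds Jones' value on the same
  correlation matrix, so the liberality ordering
  $n \ge n_{Jones} \ge n_{exch} \ge n_{clusters}$ is guaranteed. Its default
  evaluates the family correlation at full relatedness ($h^2 = 1$,
  structure-only), making it a genuinely more aggressive correction than
  Jones'; at $h^2 = 0$ it reduces to $n$.
* the liberal correction $n_e$ = number of clusters (`BIC_C`).

The LRT metrics test each candidate by
$2(\ell_{full} - \ell_{reduced}) \sim \chi^2_1$, with the variance
components re-estimated under both models; since the random effect is
present under both hypotheses, no boundary correction is needed for the
fixed-effect test. In application mode a per-node Bonferroni correction
divides $\alpha$ by the node's number of level-1 candidate parents, held
fixed across levels.

## Forward search and error accounting

At each level every remaining candidate is evaluated (one logged test); for
BIC/AIC a candidate *passes* when it lowers the current score, for LRT when
its p-value is below the (possibly adjusted) level. The best passing
candidate is added; the search stops at the first level with no pass. In the
null studies **every passing test counts as a false positive** at its level
— not only the single added candidate — and FPR is total false positives
over total tests, while FWER is the fraction of replicates with at least one
pass. Ties among equal-scoring candidates break to the lowest column index
for determinism. No backward elimination is performed.

`learn_network()` enumerates all orderings of the free nodes (forced roots
first, forced sinks last; capped at 8 free nodes) and runs the forward
search per node with candidates restricted to predecessors. Structures are
ranked by a metric-consistent global score — the sum of per-node penalized
scores, or for LRT metrics the deviance plus the per-edge $\chi^2$
acceptance threshold — rather than by the raw likelihood sum. This was a
deliberate design change: a spurious extra edge can only increase the raw
likelihood (for Gaussian data, the complete DAG attains the saturated
likelihood under *every* ordering), so raw-likelihood ranking would always
prefer the densest structure found in any ordering and could never recover
a sparse generating network. The raw global log-likelihood is still
reported on each structure. Duplicate edge sets arising from different
orderings are collapsed; tied structures are all returned.

## The synthetic cohort

The reference cohort emulates a family study of healthy aging in which a
typical enrolled family contributes a proband and a consenting sibling, both
with spouses and children. The default template has 8 *sampled* members per
family — two full siblings (their parents exist in the pedigree but are
unsampled), two unrelated spouses, and four children — giving within-family
relationships $2k \in \{0.5, 0.25, 0.125, 0\}$, and 582 template families
give $n = 4656$. Exact family compositions of the real study are not
public, so any fixed template is an approximation; this is the main reason
the error-rate checks carry absolute tolerances (±0.01 on FPR, ±0.05 on
FWER at 1000 replicates) on top of Monte-Carlo error.

Traits are simulated exactly from their model: $y = UD^{1/2}z$ per family
block with $V = \gamma^2 A + \sigma^2 I$, so the sample covariance matches
$V$ in distribution. The variance scale is anchored at $\sigma^2 = 1$,
with $\gamma^2 \in \{1/3, 1, 3\}$ giving $h^2 \in \{0.25, 0.5, 0.75\}$.
Null covariates are gene-dropped SNPs: founder allele frequencies are drawn
uniformly on $(0.05, 0.5)$, alleles are transmitted by Mendelian sampling,
and columns are redrawn until the sample MAF reaches 5%. Gene-dropped
genotypes carry the familial correlation (genotype correlation between
relatives equals $A_{ij}$) that drives the naive metrics' inflation; they do
*not* emulate linkage disequilibrium, a realistic MAF spectrum, or
genotyping error, so passing tests say nothing about those features of real
genome-wide data.

Survival times invert the baseline survival of a Weibull(shape 2, scale 2):
$T = 2\sqrt{-\log(U)\,e^{-\eta}}$. The censoring mechanism of the study
being emulated is unreported; the default draws censoring times uniformly on
$(0, c_0)$ with $c_0$ solved numerically so that ~20% of subjects are
censored at the null. Effect tiers for power studies are likewise not
printed anywhere; they are *defined* here by calibration — a coefficient
whose single-covariate test at level 0.005 on the reference cohort has power
0.3 (weak), 0.6 (moderate), or 0.9 (strong), using the noncentrality
$\beta^2\,\mathrm{tr}(V^{-1})$. Absolute power values are therefore
package-defined; only power *orderings* between metrics are meaningful
comparisons.

## Study problem sizes

The packaged studies use these sizes, chosen to keep a full reproduction on
one CPU comfortable: the continuous null study runs the full 582 families ×
1000 replicates (the per-family eigendecomposition cache makes this a
few-minute computation); the survival null study runs 40 families × 150
replicates, which keeps the Monte-Carlo standard error of an FPR near 0.005
while the Laplace refits stay cheap; the test suite re-runs the continuous
study at 200 replicates and the survival study at 30 families × 60
replicates with tolerances widened by three Monte-Carlo standard errors.

## Known limitations

* Categorical nodes are not supported; only Gaussian and time-to-event
  variables have integrated likelihoods here.
* The Laplace approximation's error is bounded empirically (quadrature
  agreement to 0.1 on toy clusters), not theoretically.
* One variance component per node: no simultaneous kinship + household or
  heteroscedastic errors.
* Ordering enumeration is factorial; beyond 8 free nodes a single
  user-supplied ordering is the intended mode.
* Markov equivalence is not collapsed beyond identical edge sets: two
  returned structures can be likelihood-equivalent reorientations.
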