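---
title: "Models and methods behind landgen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind landgen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`landgen` chains five analyses that are usually run through a patchwork of
separate programs — diversity statistics, multivariate clustering, landscape
attribution of genetic structure, coalescent ABC, and ensemble species
distribution modelling — into one tested R package. This vignette explains
the models each stage fits, the assumptions they make, the defaults and why
they were chosen, and what the synthetic-data generators do and do not
emulate.

## Diversity and differentiation statistics

Expected heterozygosity is the unbiased gene diversity
$\hat H_e = \frac{2n}{2n-1}\,(1 - \sum_i p_i^2)$ per locus (with $2n$ the
observed gene copies), averaged over loci; observed heterozygosity is the
fraction of heterozygous non-missing calls. Because published tables rarely
state whether the small-sample factor was applied, third-decimal agreement
of $F_{IS} = (H_e-H_o)/H_e$ with any particular published table should not
be expected.

Pairwise $F_{ST}$ uses the Nei $G_{ST}$-style estimator
$(H_T - H_S)/H_T$, with $H_S$ the mean within-group gene diversity
(uncorrected) and $H_T$ the gene diversity of the pooled mean frequencies,
both averaged over loci, clipped at zero. This follows the estimator family
the source analyses cite; it is *not* Weir–Cockerham $\theta$, and absolute
values differ slightly between the two (roughly by the within-group
sample-size correction). Nei's standard distance is $D=-\ln I$ with the
normalised identity $I$ averaged over loci; group pairs sharing no alleles
get an infinite, flagged entry.

UPGMA is implemented directly (average linkage, node height = half the
merge distance) with deterministic lowest-index tie-breaking, and is checked
in the tests against an independent implementation (`phangorn::upgma`).

Hardy–Weinberg and linkage screens are permutation tests rather than the
classical MCMC exact tests: HWE re-pairs the observed allele pool at random
(statistic $|H_o - H_e|$; $H_e$ is invariant under re-pairing), LD shuffles
one locus's genotypes among individuals (statistic: G-test of the two-locus
genotype table). Both use the one-sided, +1-corrected permutation p-value
$p = (1 + \#\{T_{perm} \ge T_{obs}\})/(1 + n_{perm})$, which is exactly
uniform on its attainable grid under the null — the calibration suite in
`test-acceptance.R` verifies 5% type-I error empirically for every
permutation test in the package.

## Clustering: PCA, K-means/BIC, majority merge, DAPC

The dosage matrix codes each (locus, allele) as a 0/1/2 count. Missing
calls are mean-imputed (twice the dataset-wide allele frequency) by default
— the convention of the multivariate toolchain this stage mirrors — with a
`zero` option for sensitivity checks. PCA retention supports both a fixed
count and a cumulative-variance target, since descriptions of this
protocol conflate the two ("first 100 PCs explaining >95%"); both modes are
available and the pipeline default is the 95% target.

K-means (k-means++ seeding, 20 restarts, fixed recorded seed) is scanned
over K and scored with the spherical Gaussian-mixture BIC (the X-means
formulation: pooled spherical variance $\hat\sigma^2 = WSS/(d(n-K))$,
mixing-proportion term $\sum_k n_k\log(n_k/n)$, and $(K-1)+dK+1$ free
parameters). This was a genuinely open design point: the bare
$n\log(WSS/n)+K\log n$ heuristic of the popular genotype-clustering
implementation overfits strongly in low dimension (it selects $K_{max}$
even on homogeneous data), while multiplying the penalty by the
dimensionality collapses realistic genotype PCA scores to $K=1$. The
X-means criterion recovers well-separated groups, returns $K=1$ on
unstructured data, and selects the true subpopulation number on the
package's study-shaped fixture, so it is the default.

The *majority merge* post-processes an intentionally fine-grained K-means
solution: while any site lacks a cluster holding a strict majority (>50%)
of its individuals, the site's two most frequent clusters are unioned
across the entire dataset. Sites are visited in ascending site-ID order and
ties broken toward the smaller cluster index, making the procedure
deterministic; each merge reduces K by one, so at most $K-1$ merges occur,
and final clusters are always unions of initial clusters (both properties
are asserted on randomised inputs).

DAPC fits an LDA with equal priors on the retained PC scores; the Q-matrix
is the LDA posterior. The a-score (observed reassignment rate minus its
mean under random label permutations, averaged over groups) selects the PC
count; it is near zero for noise and penalises overfit large PC counts.
Membership is summarised at the conventional Q > 0.5 threshold
(configurable).

## Spatial attribution

Distances are great-circle (haversine, sphere radius 6371 km); at the
spatial scale of a single region the difference from projected planar
distances is negligible. The connection network uses inverse-square
weights $W_{ij}=d_{ij}^{-2}$, row-standardised to the lag matrix $L$; sPCA
eigen-decomposes $\frac1n X'HX$ with $H=(L+L')/2$ symmetrised so all
eigenvalues are real. Each axis satisfies
$\lambda_k = \mathrm{var}(s_k)\,I(s_k)\,\frac{\sum H}{n}$, verified
numerically in the tests; positive eigenvalues capture global (cline/patch)
structure, negative ones local neighbour contrasts. sPCA operates on
site-level allele frequencies because the downstream ordination partitions
site scores. Monte Carlo tests permute site rows of the frequency matrix,
using the extreme eigenvalue as the statistic; published "r_obs" values
from other implementations use a different internal statistic, so only
significance patterns — not statistic values — are comparable.

Partial Mantel tests permute the rows/columns of the *residual* matrix of
A given C (rather than the raw matrix), which gives better type-I control;
PERMANOVA permutes reduced-model residuals (Freedman–Lane) with 999
permutations by default. Variance partitioning reports, per landscape
factor, the partial RDA conditioned on all other factors plus the
coordinates, an unconditioned isolation-by-distance row, and the
unexplained remainder; a factor fully absorbed by the conditioning set
(e.g. a river barrier that coincides with a basin boundary) is reported
with 0% and p = 1 rather than an error. Land-use proportions are computed
over grid cells whose centres fall within a great-circle buffer radius;
both 15 km and 5 km radii appear in published protocols of this kind, so
the radius is an explicit argument with no canonical default.

## Coalescent ABC

The simulator runs a continuous-time coalescent per tree branch (pair rate
$k(k-1)/4N$ per generation for diploid size $N$), pooling lineages at
merge events; mutations are Poisson on gene-tree branches and move the
repeat count by ±1 with equal probability (strict single-step SMM; the
geometric multi-step extension some packages offer is deliberately
omitted). The root allele is 100 repeats. Under this model the expected
within-population allele-size variance is $\theta/2$ with $\theta=4N\mu$,
which the tests use as a closed-form oracle. The engine is written in C++
for the reference-table throughput ABC needs (~2,500 two-population,
11-locus simulations per second); the R-level summary functions are the
authoritative definitions and the C++ kernel is asserted to match them.

Priors follow the published protocol: population sizes and divergence
times uniform on integers 1–20,000 (times resampled until tree-ordered,
which preserves marginal uniformity subject to the constraints); the mean
mutation rate is log-uniform on $[10^{-4},10^{-3}]$ and per-locus rates
log-uniform within a factor of 10 of the mean, truncated to
$[10^{-5},10^{-2}]$ — the published account states only these ranges, not
the hierarchy's law, so the log-uniform hierarchy is this package's
documented choice. Rejection ABC standardises each summary statistic by
its simulation-wide MAD, accepts the closest `tolerance` fraction in
Euclidean distance (default 0.5% of 100,000 simulations; the reference
protocol used 10⁶ — the default is scaled to desk hardware and
configurable), and optionally applies the Epanechnikov-weighted
local-linear adjustment with results clamped to the prior support.

One identifiability caveat the tests surfaced and users should know: the
per-population summary set (mean allele count, heterozygosity, allele-size
variance) is *marginally invariant to the divergence time* when all
branches share one population size, because the within-sample genealogy of
an exchangeable sample does not see the split. With that set alone the
posterior for $t$ reproduces the prior; divergence time is identified by
the two-sample statistics (pairwise $F_{ST}$ and the assignment
log-likelihoods, floored at $1/(2n_j+1)$ for unseen alleles) of the second
set. The package's recovery experiments therefore check coverage under
both sets but rank-consistency of the posterior median only under the
two-sample set.

## Ensemble species distribution model

Candidate predictors are pruned by iterated VIF (threshold 10, removing
the largest each round, perfectly collinear columns first). The logistic
component enumerates all non-empty variable subsets (guarded at 12
predictors), keeps the set within ΔBIC < 2 of the minimum — the standard
reading of "models with BIC values < 2", which is impossible literally for
BIC magnitudes — and averages member predictions unweighted; complete
separation triggers a ridge-penalised refit with a warning. BIOCLIM scores
a point per variable by the two-tailed presence percentile
$2\min(p, 1-p)$ (zero outside the presence range) and takes the minimum
over variables. Mahalanobis suitability maps $D^2$ through the $\chi^2_d$
survival function — bounded in [0,1] and rank-equivalent to the
traditional unbounded $1-D^2$ score, so nothing changes after the
per-component min–max rescaling. A plugin slot accepts externally computed
scores (e.g. Maxent output) so a fourth method can join the ensemble
without re-implementing external software.

Validation uses K random folds (default 4): each method is fitted on K−1
folds and scored on the held-out fold with the rank-based (Mann–Whitney,
ties = ½) AUC, giving methods × K component models weighted by
$w=(\mathrm{AUC}-0.5)^2$. Component grids are min–max rescaled over the
prediction extent (the published protocol says only "rescaled to the same
scale"; min–max is this package's documented default) and combined as
$\sum w\,\hat p/\sum w$. The binary range map maximises sensitivity +
specificity over the training points, a rank-based rule unchanged by
monotone transforms of the suitability. Projection applies the stored
component fits to a new co-registered stack and re-combines with the
stored weights. Grids are read and written as ESRI ASCII text; that is the
supported raster interchange format.

## Synthetic data: what it emulates, and what it does not

The genotype generator uses the Balding–Nichols construction: per locus an
ancestral frequency vector over 5–25 alleles on a two-repeat ladder, then
Dirichlet draws down a major → (optional subpopulation) → site hierarchy.
Divergence parameters are calibrated analytically from the pairwise-GST
targets via $E[G_{ST}] \approx (F/2)/(1-F/2)$, so a target of 0.09 between
major clusters is realised within ±0.02 (verified across seeds); the
default study-shaped fixture is 41 sites × 30 diploids × 11 loci with 2
majors and 10 nested subpopulations, matching the sampling design the
package mirrors. The isolation-by-distance generator interpolates locus
frequencies along a west–east cline over a 600 km square; the barrier
generator perturbs each river side with an independent Balding–Nichols
draw sized so cross-barrier pairs gain the requested FST increment while
within-side pairs are untouched.

Climate stacks are Gaussian-smoothed white-noise fields (optionally with
west–east gradients and a mixing matrix to manufacture collinearity for
VIF tests), standardised per layer; presences are drawn proportional to a
logistic suitability surface. The SDM recovery experiment uses a sharply
defined niche (β = (8, −6) on two layers, intercept −10, i.e. roughly the
top sixth of cells suitable): with presences drawn proportionally to a
*diffuse* suitability surface, even the Bayes-optimal ranker cannot exceed
an AUC of about 0.75 against uniform background, so a concentrated niche
is the regime in which a ~0.9-AUC ensemble — the regime reported for real
ensembles of this kind — is attainable at all.

These generators reproduce the *statistical* structure the analyses assume
(drift-driven hierarchical differentiation, distance decay, barrier
offsets, autocorrelated climate, logistic occupancy). They do not emulate
null alleles, genotyping error, allele-size homoplasy, uneven sampling,
real hydrography, or non-equilibrium demography — so passing recovery
tests demonstrates correctness of the estimators and pipeline, not
robustness to those artefacts.

## Numerical choices and problem sizes

Permutation p-values always use the +1 correction and one-sided "greater"
alternatives. UPGMA and majority-merge tie-breaks are lowest-index,
making every pipeline stage bit-reproducible under a fixed seed
(asserted by the pipeline tests). RDA drops aliased columns with a
warning, and treats constraints whose residual norm after conditioning
falls below 10⁻⁸ of their original norm as fully absorbed. The Mahalanobis
covariance is ridge-regularised when its condition number exceeds 10¹⁰.

The test suite's experiment sizes are chosen to give stable verdicts on
desk hardware: 500 replicates for each type-I-error calibration (binomial
SE ≈ 0.01 at α = 0.05), 25 replicates × 50,000 simulations for ABC
coverage, and 20 seeds for the SDM recovery sign test. The package
functions themselves default to the published protocol sizes (999
permutations, 100,000 simulations) where a published size exists.
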