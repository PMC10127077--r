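---
title: "Methods: multi-omics network analysis of hybrid-grass family pools"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-omics network analysis of hybrid-grass family pools}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The analysis in one paragraph

`poolnet` implements a complete analysis chain for breeding programmes
that phenotype *family pools* rather than individual plants: two
pedigree classes of tetraploid full-sib families (hybrid ryegrass and
Festulolium-type crosses), connected through shared *Lolium perenne*
parents in sparse diallels, each profiled with pooled-sequencing allele
frequencies, transcript expression and NMR metabolomics, and field
phenotypes. The chain builds an allele-frequency genomic relationship
matrix (GRM), corrects each omics layer for population stratification,
estimates one sparse Gaussian graphical model per pedigree class with a
fused joint graphical lasso (JGL), reduces the networks to modules and
conserved hub features, links hubs to phenotypes with bivariate REML
and a boundary likelihood-ratio test, and quantifies the predictive
value of hub features with random forests. A synthetic-data generator
reproduces the study design with known ground truth so that every stage
is testable without access to field or sequencing data.

## Genomic relationships from pooled allele frequencies

Family pools yield *allele frequencies*, not genotype calls. With
`F` the families-by-SNP matrix of alternative-allele frequencies, the
kernel is

    G = M M' / ( (1/ploidy) * sum_j p_j (1 - p_j) ),   M = F - colMeans(F),

the VanRaden-type cross-product scaled by the expected SNP variance at
the material's ploidy (4 for these tetraploids). Column centring makes
the grand sum of `G` exactly zero, so relationships are expressed
against the population mean. Missing frequencies are mean-imputed per
SNP *before* centring; an imputed cell then contributes exactly zero to
`M`, the most conservative choice.

Pooled sequencing adds binomial read-sampling noise that accumulates
only on the diagonal of `G`. `diagonal_correction()` subtracts
`c_i = sum_j p_j(1-p_j) / (depth_i * ploidy) / denominator` per sample
(a pluggable function, since noise models vary with the assay). The
corrected kernel can carry small negative eigenvalues, of order
`1/depth`; wherever a factorization is needed (simulation, REML) the
kernel is *bent* by flooring eigenvalues at a small positive value —
standard practice for corrected genomic kernels.

Stratification control uses the top 10 eigenvectors of the class GRM,
scaled by the square roots of their eigenvalues. Each omics feature is
replaced by its residual from an OLS fit on those scores
(`regress_out_pcs()`); NMR buckets are mean-centred and Pareto-scaled
(divide by the square root of the standard deviation) first, which
damps high-intensity spectral regions without equalizing them.

## Fused joint graphical lasso

For classes `k = 1, 2` with corrected feature matrices `X(k)`, the
class precision matrices maximize

    sum_k w_k [ log det Theta(k) - tr( S(k) Theta(k) ) ]
      - lambda1 * sum_k sum_{i != j} |theta_ij(k)|
      - lambda2 * sum_{i,j} |theta_ij(1) - theta_ij(2)|

with `S(k) = X(k) X(k)' / n_k`. The class weights `w_k` default to 1
(`weights = "equal"`), the convention of the standard JGL software,
under which a given `lambda1` corresponds to the same soft threshold
regardless of sample size and the canonical grids (30 log-spaced
`lambda1` from 0.01 to 20 crossed with 15 `lambda2` from 0 to 0.5 for
metabolomics; 15 x 10 for transcriptomics) span the full path from
dense to empty. `weights = "n"` provides the literal likelihood
scaling; the two are reparametrizations of each other along the path.

The solver is ADMM. The `Theta` update is the spectral step (an
eigendecomposition per class and iteration), which keeps every iterate
positive definite; the consensus update applies the exact closed-form
two-class fused proximal operator (fuse the pair, then soft-threshold
off-diagonals); the scaled dual update follows, with the usual adaptive
rescaling of the penalty parameter when primal and dual residuals drift
apart by more than a factor of ten. Tolerances are `1e-6` absolute and
`1e-5` relative (tighter than typical defaults so that the reported
support is unambiguous), capped at 500 iterations; non-convergence is
flagged, never silently accepted. Off-diagonal entries whose consensus
copy is exactly zero, or whose magnitude falls below `1e-6`, are set to
exact zeros, so `to_adjacency()` is a pure support indicator.

### Penalty selection

The selection criterion is the BIC

    sum_k [ n_k { tr(S(k) Theta(k)) - log det Theta(k) }
            + log(n_k) * #{ i <= j : theta_ij(k) != 0 } ].

One design decision matters here. Evaluating the likelihood term at the
*penalized* estimates makes the criterion drift toward over-dense
models: the retained entries of a sparse fit are shrunken toward zero,
so sparse candidates are charged for shrinkage bias as well as for
their support, and relaxing the penalty buys large spurious likelihood
gains from debiasing. `jgl_grid_search()` therefore scores each
candidate *support* at its maximized likelihood — the
support-constrained Gaussian MLE computed by `ggm_refit()` (covariance
selection via blockwise coordinate descent) — which is the textbook
definition of the likelihood entering BIC. The shrunken-estimate
variant remains available (`bic = "penalized"`), and `bic_jgl()`
evaluates the printed formula exactly for any given fit. Supports too
dense for the sample size (no MLE) score `Inf` and are never selected.
Ties are broken toward the sparser model, and the search warm-starts
along descending `lambda1` within each `lambda2`.

Features are standardized to unit variance before the covariances
(`standardize = TRUE`): the canonical grids presume correlation-scale
data, and partial correlations — hence supports — are invariant to
per-feature scaling. Partial correlations are reported as
`-theta_ij / sqrt(theta_ii theta_jj)`.

## Modules, hubs, conserved hubs

Estimated supports become unweighted graphs (`A_ij = 1` iff
`theta_ij != 0`, `i != j`). Modules come from multi-level modularity
optimization (Louvain, via igraph) under a fixed seed. Hub scores are
Kleinberg's hub centrality — the principal eigenvector of `A A'`,
which for an undirected graph coincides with the leading eigenvector
of `A` itself — computed by power iteration (tolerance `1e-10`). When
`A^2` has tied leading eigenvalues (bipartite components, e.g. a pure
star), the iteration runs on `A^2 + 0.01 A`; because `A` and `A^2`
commute this leaves untied eigenvectors exactly unchanged and resolves
ties toward the Perron vector of `A`, matching the convention of
standard graph software. Scores are max-normalized per graph; the top
five per non-singleton module are hubs (ties broken by degree, then
feature id), and the *conserved* hubs are the intersection of the two
classes' hub lists by feature identity, module labels ignored.
Whole-graph scoring ranked within modules is the default; per-module
subgraph scoring is available via `score_scope = "module"`.

## Heritability, spatial adjustment, and omics-phenotype integration

Single omic features follow `y = 1 mu + u + e` with
`u ~ N(0, G sigma_u2)`; REML uses the eigendecomposition fast path
(rotate by the eigenvectors of `G`, profile the residual variance,
optimize the variance ratio in one dimension), so thousands of features
reuse one decomposition. Heritability is
`h2 = sigma_u2 * gbar / (sigma_u2 * gbar + sigma_e2)` with `gbar` the
average GRM diagonal — the genetic variance is expressed on the scale
of an average family.

Plot-level phenotypes add fixed trial-block effects and a sliding
spatial window: each plot links to a shared spatial-effect vector at
itself plus 10 cross-shaped neighbours (three up, three down, two left,
two right; arms truncated at field edges — the window size is fixed at
11, the arm lengths are configurable). With
`s ~ N(0, I sigma_s2)` summed over the window,
`h2 = sigma_u2 * gbar / (sigma_u2 * gbar + 11 sigma_s2 + sigma_e2)`.

The integration model is bivariate: one omic feature (one record per
family, intercept plus three genomic PC covariates) jointly with one
trait (plot records, trial-block plus the same PCs and the spatial
term), genetic effects sharing `G` through a 2 x 2 Kronecker covariance
and residuals independent between sub-models. Variances are
parameterized on the log scale and the genetic correlation through
Fisher's z. Because the residual covariance is zero and the fixed
effects separate, the constrained model (genetic covariance zero)
factorizes *exactly* into the two univariate fits — those fits are both
the null likelihood and the starting values for the full fit. The full
fit uses average-information REML with step halving (the covariance is
linear in its six parameters, so the derivative matrices are constant),
falling back to Nelder-Mead on the transformed scale if the AI updates
stall; a fit is declared non-converged when a genetic variance pins at
the boundary (making `rg` undefined) or the optimizer fails.

### The 0.5-df boundary LRT

Significance uses `p = 0.5 * P(chisq_1 >= D)` with
`D = 2(ll_full - ll_constrained)` floored at zero; `D = 0` gives
`p = 0.5`. A subtlety: for an *unconstrained* genetic covariance the
null hypothesis is interior, the LRT is asymptotically chi-square with
1 df, and halving its tail doubles the type-I error (about 0.10 at
nominal 0.05). The 50:50 mixture is the exact null of the *one-tailed*
test, in which the covariance is constrained non-negative — then `D` is
zero with probability one half under the null. `lrt_boundary()` exposes
both: `alternative = "greater"` uses the one-tailed statistic (the
calibrated test, and what the calibration study in the test suite
verifies), while the default two-sided variant applies the same formula
to the unconstrained statistic, as is common practice when signed
genetic correlations are wanted for a network; its anti-conservatism is
documented rather than hidden. FDR control is Benjamini-Hochberg at
0.05, applied across traits *within* each omic feature. The edge table
of converged pairs, weighted by `|rg|`, is the omics-phenotype network;
`hub_covariate_ztest()` cross-checks edges by refitting the phenotype
model with the hub as a fixed covariate.

## Omics-assisted prediction

Missing pool frequencies are imputed by chained random forests inside
complete-linkage clusters (distance `1 - |cor|`, k = 30 groups) looped
one chromosome at a time, with the study's forest settings (100 trees,
sample fraction 0.1, depth 6, extremely randomized splits), sweeping
until imputed values stabilise; observed cells are never touched.
Family BLUEs come from refitting the spatial phenotype model with
families as fixed effects and no PC scores, mean-centred within
location, then merged across classes. Prediction uses regression
random forests (2,000 trees, minimum node size 5,
`mtry = floor(sqrt(p))`), reporting out-of-bag accuracy — the Pearson
correlation between OOB predictions and the response — with permutation
importance. Three scenarios are compared per trait and layer: the
conserved-hub predictor set (SNPs tagging hub genes within +-5 kb of
their spans, hub genes, hub NMR variables), twenty random same-size
draws (mean and standard error), and all features.

## What the synthetic generator does and does not emulate

The generator reproduces the design quantitatively where the study
states numbers, and by explicit choice elsewhere:

* **Diallels.** 31 shared perenne parents; 79 and 4 class-specific
  partner parents; 79 and 65 families; tetraploid dosages; pools of
  120 plants contributing `pool_size * ploidy` allele copies per locus
  (binomial sampling); 5% missingness completely at random; 7
  chromosomes. Parental genomes are mosaics of 8 ancestral haplotypes
  switching with probability 0.05 between adjacent loci, which creates
  realistic linkage disequilibrium along chromosomes — without LD,
  genotype imputation would have nothing to learn.
* **Field design.** Five trials of ~16 entries in two complete blocks
  per class, plots on a grid, fixed trial-block shifts, the 11-cell
  spatial window applied exactly as in the analysis model, and
  residual variance 1.
* **Omics.** Features decompose into `u + e` with `u ~ N(0, G s2)` and
  network residuals drawn from the planted precision matrices;
  per-feature heritabilities follow Beta(1.5, 8), echoing the low
  medians typical of transcript and NMR features. Genetic correlations
  with traits are induced by drawing hub and trait effects from the
  same 2 x 2 Kronecker structure the estimator assumes.
* **Planted networks.** Block-diagonal module structure, one or more
  designated hubs per module wired to most module members, a
  configurable fraction of edge support identical across classes, and
  positive definiteness enforced by diagonal dominance (diagonal = 1 +
  absolute row sum). Under diagonal dominance a hub edge's partial
  correlation is bounded near `1/sqrt(degree)`, so edge weights
  (defaults 2.5 for hub edges, 2.0 for member edges, hub link
  probability 0.4, member edge probability 0.10) were chosen once so
  that planted partial correlations (~0.35-0.6) sit above the
  finite-sample detection ceiling `sqrt(2 log m / n)` (~0.27 at
  n = 200 with ~1,200 candidate pairs). This is a deliberate
  identifiability calibration: recovery experiments measure the
  estimator, which requires a recoverable truth. Real transcriptome
  networks contain many edges *below* this ceiling; support recovery
  there is necessarily partial, and the package makes no claim
  otherwise.

Not emulated: raw reads or spectra, selfing and pollen contamination
(the study observed extraneous offspring patterns; the generator keeps
crosses clean), homeolog expression bias, and location-by-genotype
interaction beyond the class/location confounding built into the
design. Passing tests therefore demonstrate correctness of the
estimators under the stated generative model, not robustness to every
artefact of field data.

## Problem sizes and numerical conventions

The packaged analyses and tests run at desk scale, chosen as the
smallest sizes at which each statistical claim is meaningful: network
recovery at p = 50 features and n = 200 families per class;
heritability recovery over 100 features at 200 families; genetic
correlation recovery over 30 replicates; null calibration of the LRT
over 500 replicates at 100 families; the demo pipeline at the study's
own family counts (79 + 65) with 500 SNPs and 60 + 40 features.
Degenerate inputs are handled explicitly: empty filter results,
monomorphic SNP panels and all-missing columns raise errors; constant
NMR features are flagged, not scaled; aliased design columns are
dropped with a warning naming them; collinear PC covariates likewise.
All stochastic stages take explicit seeds, and a single master seed
fans out to per-stage seeds (`derive_seed()`) so any stage can be
rerun in isolation bit-identically.

## Known limitations

* The JGL handles exactly two classes (the study's setting); the
  general-K fused prox is not implemented.
* BIC selection, even refitted, inherits the noise floor of
  finite-sample partial correlations; edges below ~`sqrt(2 log m / n)`
  are invisible to any support estimator at these sample sizes.
* The two-sided use of the 0.5-df mixture p-value is anti-conservative
  (see above); for strict error control use the one-tailed test or
  treat the two-sided p-values as ranking scores feeding FDR.
* BLUEs absorb trial means when families are nested in trials (as in
  the study design); mean-centring within location mitigates but does
  not remove this.
* REML here is dense-matrix; it is comfortable to a few thousand
  observations but not intended for national-evaluation scale.
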