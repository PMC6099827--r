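---
title: "Methods: resistance surfaces, circuit theory and MLPE models in lgflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: resistance surfaces, circuit theory and MLPE models in lgflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`lgflow` implements a group-based isolation-by-resistance analysis for
species sampled at communal breeding sites. This vignette documents the
statistical models, the defaults and why they were chosen, the design of
the synthetic-data generator, and the numerical decisions a maintainer
or reviewer would want spelled out.

## The analysis model

### Lek clustering and QC

Samples are filtered first: individuals missing genotypes at more than
five loci (of a 15-locus microsatellite panel, both configurable) are
removed, and exact duplicate multilocus genotypes are collapsed to one
record — a stand-in for a full multi-capture screen, adequate once
genotypes have been error-checked upstream. Sampling locations are then
grouped by agglomerative complete-linkage clustering (the
Lance–Williams recurrence with $\alpha_i=\alpha_j=0.5$, $\beta=0$,
$\gamma=0.5$, computed via `stats::hclust`) with the tree cut at 25 km:
locations merge while their complete-linkage diameter stays at or below
the cut, so clusters separated by more than 25 km — a maximum seasonal
movement distance for the motivating species — remain distinct. Clusters
with fewer than 8 genotyped individuals are dropped; below that,
frequency estimates are too unstable for pairwise differentiation.

### Differentiation

For each cluster pair ($k=2$), per-locus expected heterozygosities
within ($H_S$, the mean of the two groups) and total ($H_T$, from mean
frequencies) are averaged across loci *before* forming ratios (the
standard multilocus convention; averaging per-locus ratios is noisier
and ill-defined at weakly variable loci):

$$G_{ST} = \frac{H_T - H_S}{H_T},\qquad
  G'_{ST} = G_{ST}\,\frac{k-1+H_S}{(k-1)(1-H_S)},\qquad
  D = \frac{H_T-H_S}{1-H_S}\cdot\frac{k}{k-1}.$$

The plug-in estimators are the default; a Nei–Chesser-style
small-sample correction ($H_S$ scaled by $2n/(2n-1)$ per group, $H_T$
augmented by $H_S/(2\tilde n k)$) is available behind
`bias_correct = TRUE`. Both are standard and the choice is exposed
rather than hidden because the plug-in $G'_{ST}$ carries a positive
finite-sample bias that the $(1+H_S)/(1-H_S)$ standardization
amplifies — at 30 diploids and high marker diversity it is of order
0.05, which matters when interpreting sampling-only baselines.
Negative point estimates clamp to 0 so all matrices live in $[0,1]$
for regression. Pairs with $H_T = 0$ are defined as 0.

Individual-based differentiation uses Bray–Curtis dissimilarity on
allele-count vectors, restricted per pair to loci called in both
individuals (pairwise deletion); a pair sharing no called loci is
flagged missing rather than imputed.

### Resistance surfaces

Each continuous predictor raster is resampled to the 1.2 km analysis
resolution by bilinear interpolation, optionally summarised by a
circular focal mean (6.44 km radius default in the motivating study),
and thresholded into binary habitat (resistance 1) / nonhabitat
(resistance $r>1$). Boundary semantics: `>=` threshold is habitat for
positive associations, `<=` for negative ones — the inclusive boundary
mirrors the "$p \ge 0.65$" habitat rule, and the negative direction
takes the symmetric closure since no convention is established.
Percentile thresholds (top-90/70/50% of cell mass) serve zero-skewed
layers like abundance kernels.

Nonhabitat resistance magnitudes are not free parameters to tune per
surface: they are selected by a decorrelation search. For candidates
{5, 10, 20}, the smallest value whose three threshold-specific
resistance matrices average Pearson $r \le 0.7$ with the
geographic-null matrix (in at least one zone) becomes the low value;
the high value is the smallest of {50, 100, 200} similarly decorrelated
from the low-value matrices. Degenerate landscapes (no nonhabitat)
cannot decorrelate; the search then returns the largest candidate with
a warning. The full audit table (every zone × candidate × threshold
correlation) is returned because "decorrelated from distance",
"decorrelated from each other", or both are all defensible readings of
the selection rule.

The combined landscape surface sums *excess* resistance:
$1 + \sum_s (r_s - 1)$. Naive summation of $S$ surfaces would give
habitat cells resistance $S$, destroying the resistance-1 baseline;
the excess-sum preserves it and remains commutative and associative.

### Circuit theory

The resistance raster becomes a weighted graph: nodes are unmasked
cells; 8-neighbourhood edges (4 available by flag) carry conductance
$\tfrac12(1/r_a + 1/r_b)$, diagonals divided by $\sqrt 2$ for the
longer centre-to-centre distance — the common raster stencil in
circuit-theoretic connectivity tools. All cells of a lek cluster are
contracted into one supernode (zero internal resistance), matching
"nodes are clusters"; a centroid-cell alternative can be had by passing
single-cell node sets. Effective resistance for a pair $(s,t)$ grounds
one node and solves the reduced sparse Laplacian by Cholesky
factorisation (one permuted factorisation per connected component,
reused across all pairs in it):
$R_{\mathrm{eff}}(s,t) = (e_s - e_t)^\top L_g^{-1} (e_s - e_t)$.
Pairs in different components are returned as `NA` and *excluded* from
regressions — assigning a large constant would inject an arbitrary
scale into the response-predictor relationship.

The geographic null is the same computation on an all-ones surface
over the same mask: a "distance" that respects study-area constraints,
used as the null predictor everywhere.

All-to-one flow maps ground each focal cluster in turn, inject one
ampere at every other cluster in its component, and accumulate per-cell
current as half the sum of absolute incident edge currents (so a
source/ground cell shows half its throughput — the convention follows
from counting edge currents only). The map is the mean over focal
solves, with 5%-step percentile bins attached for display.

### MLPE models and selection

Pairwise differentiation is modelled as

$$y_{ij} = \beta_0 + \sum_k \beta_k x_{k,ij} + u_i + u_j +
  \varepsilon_{ij},\quad u \sim N(0, \sigma_u^2),\ \varepsilon \sim
  N(0, \sigma^2),$$

the maximum-likelihood population-effects structure: each cluster's
random effect loads every pair containing it, absorbing the
non-independence of pairwise data. The likelihood is profiled over
$\lambda = \sigma_u^2/\sigma^2$; the covariance
$\sigma^2(I + \lambda ZZ^\top)$ is inverted with the Woodbury identity
so only group-sized ($g \times g$) systems are factorised, and the 1-D
profile is maximised by L-BFGS-B on $\log\lambda$ from two starts with
an explicit boundary check at $\sigma_u^2 = 0$. ML is the default
because models with different fixed effects are compared by AIC; REML
is available to report residual log-likelihoods. Predictors are
z-scored by default (standardized coefficients); the response is left
untransformed. The parameter count is fixed effects + 2 variance
components, and AICc uses $n =$ number of pairs — pairs are the
modelled observations, although they are not independent, so AICc here
is a conventional small-sample penalty rather than an exact one.

Within-variable selection ranks a variable's six candidate matrices
(3 thresholds × 2 resistance values) by AIC of `y ~ RD`; ties break by
label order for reproducibility. The two-model significance rule
declares a surface significant only when the resistance coefficient's
95% CI is positive both alone and alongside the geographic null; if
the two predictors correlate above |r| = 0.999 the pair is flagged
collinear and declared non-significant, since no data can separate
them. Between-variable comparison pools each significant variable's
best matrix, the combined additive surface and the habitat predictors
into one AICc table with Akaike weights, with distance-only as its own
row.

### Validation

Monte Carlo cross-validation splits the *pairwise observations*
80/20 (100 iterations default). Pair-splitting matches "split the
data" most literally but leaks shared-population information between
train and test through the random effects; a cluster-level split mode
is provided for a stricter test. Held-out pairs are predicted from
fixed effects only — by construction the random effect of a held-out
pair's structure is unavailable. Absolute errors are grouped into five
equal-width bins over the observed differentiation range, shared
across iterations; bins empty in every iteration are reported missing,
not zero. The individual-based rerun expands cluster-level predictors
to individual pairs by cluster-pair lookup, excludes within-cluster
pairs (they carry no between-cluster resistance), and refits the
between-variable table with per-individual random effects.

## The synthetic-data generator

The generator defines the study conditions for every test. Defaults:
a 100 × 100 grid of 1.2 km cells, habitat autocorrelation range 5
cells, true threshold 0.5, nonhabitat resistance 10, 8 lek clusters at
least 30 km apart (clearing the 25 km cut), 15 individuals per
cluster, 15 loci with up to 6 alleles, and noise
$\sigma_u = \sigma_e = 0.01$ around the resistance-differentiation
line — marker panel and sampling intensity chosen to mirror a typical
microsatellite landscape-genetics study, with noise small relative to
a differentiation range of a few tenths.

**Landscape.** Gaussian white noise smoothed by a separable Gaussian
kernel (sd = autocorrelation range, boundary-renormalised) and
rank-transformed to uniform: exact $[0,1]$ range with controllable
autocorrelation. A range of 1 means no smoothing (white noise).

**Leks.** Cluster centroids are sampled greedily (bounded retries)
from cells above the median habitat index — leks sit in habitat — with
enforced minimum spacing; each cluster holds 1–5 lek cells in the
centroid's immediate habitat neighbourhood.

**Genotypes.** Pairwise targets are
$T_{ij} = \mathrm{clamp}(\text{drift\_scale}\cdot R_{ij} + u_i + u_j +
\varepsilon_{ij},\,0,\,0.95)$ — exactly the error structure the MLPE
model assumes, with the 0.95 clamp avoiding degenerate fixed-allele
clusters. Because the targets are *pairwise*, independent per-cluster
frequency draws (e.g. a Dirichlet per cluster) cannot realise them;
instead the generator uses a logistic-normal divergence model.
A monotone lookup from target $G'_{ST}$ to the variance $s$ of
between-cluster differences of per-allele log-frequency deviations is
built once by simulation (frequency draws only, 400 loci per grid
point, fixed internal seed, memoised per allele count) and inverted by
interpolation. The pairwise variances $S_{ij}$ are embedded in a
cluster covariance by the classical multidimensional-scaling
construction ($C_{ii} = s_{\max}/2$, $C_{ij} = (s_{\max}-S_{ij})/2$),
eigenvalue-clipped to positive semidefinite — effective resistance is
itself a squared-Euclidean-embeddable distance, so the clipping is a
small correction, not a rebuild. Per locus and allele, deviations
across clusters are drawn from $N(0, C)$, added to log base
frequencies (Dirichlet-like Gamma(2) base draws), softmax-normalised,
and individuals are sampled under Hardy–Weinberg.

What the generator does *not* emulate: coalescent genealogies,
linkage, mutation, temporal structure, genotyping error beyond
missingness, and anisotropic or temporally varying landscapes. Passing
tests therefore demonstrate that the pipeline recovers the structures
it assumes, at realistic sizes — not that those assumptions hold in
field data.

## Numerical choices and problem sizes

- Sparse solves: `Matrix::Cholesky(..., perm = TRUE)`, one
  factorisation per component per grounding, exact to solver precision
  (the test suite checks 1e-8 against a dense pseudo-inverse oracle).
- MLPE optimisation: L-BFGS-B on $\log\lambda \in [-25, 25]$, two
  starts, boundary candidate $\lambda = 0$ always evaluated.
- Parameter-recovery testing allows the estimator's known finite-sample
  bias (about $10^{-3}$ on variance components at 25 groups) on top of
  two Monte Carlo standard errors; the bias does not shrink with
  replicates, the MC error does.
- Tie-breaks: AIC ties by label order; clustering relabelled by first
  appearance; all generators take explicit seeds and restore RNG state.
- Test problem sizes (chosen to exercise the full pipeline while
  keeping the suite quick): landscapes 40–50 cells square, 4–8
  clusters, 8–30 individuals and loci; oracle checks use ≤ 100-node
  graphs (100 replicates), 200 Rayleigh perturbations, a 3 × 3 MLPE
  recovery grid with 100 replicates per cell, and 50-replicate
  threshold-recovery and cross-validation studies.

## Known limitations

- GeoTIFF I/O is not implemented; rasters exchange as ESRI ASCII
  grids. Anything that reads GeoTIFF can export that format.
- The genotype generator's calibration is built for its own frequency
  model; extreme configurations (2 alleles, very high targets) saturate
  near the clamp and realised differentiation compresses there.
- AICc's sample size (number of pairs) overstates the effective sample
  size of correlated pairwise data; model ranks are unaffected within
  a fixed pair set but absolute AICc values should not be compared
  across differently sized analyses.
- Resistance-value selection evaluates every candidate for the audit
  table, which is the slow path of `run_pipeline()` on large grids.
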