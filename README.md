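# lgflow

Landscape genetics of gene flow for clustered, lek-breeding species:
from multilocus genotypes and raster habitat layers to thresholded
resistance surfaces, circuit-theory effective resistances, MLPE model
selection, cross-validated predictive differentiation and current-flow
connectivity maps.

## Who this is for

Population geneticists and conservation planners doing
isolation-by-resistance analyses at management-zone scale — the workflow
developed for range-wide sage-grouse connectivity, generalised: samples
are collected at communal breeding sites (leks), grouped into genetic
clusters by spatial proximity, and the question is which landscape
features resist gene flow among clusters over and above geographic
distance.

## What it computes

**Differentiation.** For clusters *k* = 2 at a time, per-locus expected
heterozygosities are combined across loci (means of H_S and H_T before
the ratio), giving

- G_ST = (H_T − H_S) / H_T
- Hedrick's G′_ST = G_ST · (k − 1 + H_S) / ((k − 1)(1 − H_S))
- Jost's D = ((H_T − H_S)/(1 − H_S)) · k/(k − 1)

plus individual Bray–Curtis allele dissimilarity, probability of
identity for panel power, and the QC rule that removes samples missing
more than five loci.

**Resistance.** Continuous layers are thresholded into binary
habitat (resistance 1) / nonhabitat (resistance r > 1) surfaces —
cells above the threshold are habitat for positively associated
variables, below for negative ones. Nonhabitat resistance values are
chosen by a decorrelation search over {5, 10, 20} then {50, 100, 200}
(mean Pearson correlation ≤ 0.7 rule). Effective resistances between
lek clusters come from a sparse graph-Laplacian solver: cells are
nodes, neighbouring cells share an edge of conductance
mean(1/r_a, 1/r_b) (diagonals ÷ √2), and each cluster's cells are
contracted into one supernode.

**Models.** Pairwise G′_ST is regressed on resistance with
maximum-likelihood population-effects (MLPE) models — a mixed model
with one random effect per cluster entering every pair that contains
it — compared by AIC/AICc against a distance-only null computed on an
undifferentiated (all-ones) landscape. A surface is *significant* when
the standardized resistance coefficient has a positive 95% CI both
alone and alongside distance. Validation: Monte Carlo cross-validation
(100 × 80/20 splits, errors binned over five differentiation classes)
and an individual-based Bray–Curtis rerun. Connectivity maps use
all-to-one current flow averaged over focal clusters.

A synthetic-data generator (autocorrelated habitat fields, spaced lek
clusters, genotypes whose pairwise differentiation follows
`clamp(drift_scale · R_ij + u_i + u_j + ε_ij, 0, 0.95)`) makes the
whole pipeline testable without field data.

## Worked example

```r
library(lgflow)

cfg <- synth_config(grid_rows = 50, grid_cols = 50, n_clusters = 7,
                    cluster_spacing = 14000, inds_per_cluster = 20,
                    n_loci = 15, seed = 11)
habitat <- generate_landscape(cfg)
leks    <- generate_lek_clusters(habitat, cfg)
nodes   <- lek_cell_sets(leks)

truth   <- threshold_surface(habitat, 0.5, "positive", 10, variable = "bh")
rd_true <- effective_resistance_pairwise(build_graph(truth), nodes)
cfg$drift_scale <- 0.35 / max(rd_true[upper.tri(rd_true)])
gt  <- simulate_genotypes(leks, rd_true, cfg)

y   <- pairwise_differentiation(allele_frequencies(gt, "cluster"))
geo <- null_distance_matrix(habitat, nodes)
cands <- lapply(c(t035 = 0.35, t050 = 0.50, t065 = 0.65), function(th)
  effective_resistance_pairwise(
    build_graph(threshold_surface(habitat, th, "positive", 10)), nodes))
sel <- within_variable_selection(y, cands, geo)
sel$table
#>   candidate       AIC delta_AIC cor_with_distance
#> 1      t050 -72.64791   0.00000         0.7278379
#> 2      t035 -66.38368   6.26423         0.9203862
#> 3      t065 -47.97513  24.67278         0.7328716
```

The candidate thresholded at 0.50 — the value used to generate the
data — wins by 6.3 AIC over its nearest rival; its correlation audit
shows why the 0.35 surface is harder to separate from plain distance
(r = 0.92). The winning fit:

```r
sel$best_fit
#> <mlpe_fit> ML, 21 pairs over 7 groups
#>         term estimate       se ci_lower ci_upper
#>  (Intercept)  0.24091 0.007740  0.22574  0.25608
#>           rd  0.08433 0.007931  0.06878  0.09987
#>   sigma_u^2 = 0, sigma^2 = 0.001258
#>   logLik = 40.3240, AIC = -72.648, AICc = -70.148
sel$significance$significant
#> [1] TRUE
```

The standardized resistance coefficient (0.084, CI entirely positive,
also when distance is added) says differentiation grows by 0.084 per
standard deviation of effective resistance. Cross-validation:

```r
monte_carlo_cv(y, cands[[sel$best]], geo, iterations = 100, seed = 1)
#> pooled mean abs error: resistance 0.03054, distance 0.04872
```

The resistance model predicts held-out pair differentiation ~40%
better than distance alone. `run_pipeline()` chains all of the above
(plus resistance-value selection, the additive combined landscape
surface, and the all-to-one flow map) from one configuration object,
and writes every artifact with a provenance sidecar.

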