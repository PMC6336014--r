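# seedfda

Functional data analysis of seed germination time courses and physical
dormancy.

## What it is for

Physical seed dormancy (PY) — imposed by a water-impermeable testa — is
released as imbibition, and a germination assay records, per accession and
temperature regime, the cumulative number of imbibed seeds day by day.
Scalar summaries (final percentage, LT50, mean germination time,
coefficient of velocity) each compress the time course to one number and
cannot distinguish germination patterns that differ in shape. `seedfda`
treats each count series as a smooth *absolute germination distribution
function* (AGDF) and uses the whole curve in the analyses a dormancy
ecologist needs downstream:

* **Curve modelling** — penalized B-spline regression (degree 4, knots
  every 2 d on [0, 28], first-derivative L2 roughness penalty, GCV-chosen
  λ): `fit_agdf()`, `agdf_area()`, `classical_indices()`,
  `smooth_regression()`.
* **Dormancy classification** — UPGMA/Euclidean clustering of B-spline
  coefficients (per regime) or AUC pairs (combined), labelled
  N / R / D — non-dormant, temperature-responsive, dormant:
  `classify_dormancy()`, `cut_and_label()`.
* **Spatial statistics** — haversine distances, equal-frequency distance
  classes, Moran's I correlograms with permutation p-values and a global
  Bonferroni verdict, Dutilleul's modified t-test (effective sample size
  from the spatial covariance of both variables), PCNM spatial
  eigenvectors, 5-km raster buffer means:
  `morans_i_correlogram()`, `dutilleul_modified_t()`,
  `pcnm_eigenvectors()`, `buffer_mean_extract()`.
* **Ordination** — collinearity pruning (|r| ≥ 0.90), unstandardized PCA
  (PC1 = "germination responsivity"), RDA with Ezekiel-adjusted R²,
  Monte Carlo permutation tests (999), forward selection with the double
  stopping rule, BH-FDR, and pure/shared variance partitioning between
  environment and space: `pca_unstandardized()`, `rda_adjusted_r2()`,
  `forward_select()`, `variance_partition()`.
* **Niche overlap** — Schoener's D and Hellinger-based I on normalized
  suitability surfaces, a climate-envelope baseline model behind a
  pluggable interface, 300-km background buffers, and the pooling
  equivalency permutation test: `overlap_indices()`, `envelope_model()`,
  `equivalency_test()`.
* **Seed-coat traits** — Kruskal–Wallis on testa thickness,
  proportional-odds ordinal regression with AIC model choice, AN(C)OVA of
  the soluble/insoluble proanthocyanidin ratio with custom contrasts:
  `kruskal_wallis()`, `ordinal_logistic()`, `ancova_ratio()`.
* **Synthetic studies** — `simulate_study()` generates complete studies
  (97 accessions in three latent classes, 25 seeds × 2 replicates × 28 d ×
  2 regimes, spatially autocorrelated environmental fields with one
  class-linked variable, class-structured traits) so the whole pipeline is
  testable without any data download.

The core model: for counts $y_i$ at days $t_i$, the AGDF minimizes
$\sum_i (y_i - s(t_i))^2 + \lambda \int_0^T s'(t)^2 dt$ over degree-4
splines on a fixed knot grid, with a (0, 0) anchor; the fitted B-spline
coefficient vector is the multivariate descriptor carried into clustering
and ordination. See `vignettes/seedfda-methods.Rmd` for the full methods
account.

## Worked example

```r
library(seedfda)

cfg   <- simulation_config()            # the default 97-accession design
study <- simulate_study(cfg, seed = 1)

summed <- sum_replicates(study$records) # one series per accession x regime
fit_agdf(summed[[1]])
#> AGDF fit: accession ACC001, treatment T25_15
#>   degree 4, 18 basis functions, lambda = 0.1, edf = 15.67
#>   AUC = 916.96 seed-days, RSS = 6.581

desc <- agdf_descriptors(summed)
mats <- descriptor_matrices(desc$table)
cls  <- classify_dormancy(mats$auc, mats$final)
table(cls$assignment$category)
#>  D  R  N
#> 29 40 28

pca <- pca_unstandardized(mats$coefficients)
#> PC1 84.3%, PC2 14.3% of variance

forward_select(mats$coefficients, study$env, n_permutations = 999, seed = 2)
#>                variable f_statistic p_value adj_r2_cum
#> bio7_analog bio7_analog   30.891075   0.001  0.2374360
#> env5               env5    4.966661   0.017  0.2680002

pcnm <- pcnm_eigenvectors(study$coords)
variance_partition(mats$coefficients,
                   study$env[, "bio7_analog", drop = FALSE],
                   as.data.frame(pcnm$vectors[, 1:5]),
                   n_permutations = 999, seed = 3)
#>      fraction   adj_r2 df f_statistic p_value
#> 1     pure_X1  0.04406  2      3.6410   0.013
#> 2     pure_X2 -0.02714  5      0.3278   0.955
#> 3      shared  0.22394 NA          NA      NA
#> 4 unexplained  0.75914 NA          NA      NA
```

Reading the output: the three dormancy categories are recovered at the
configured 29/40/28 split; the first principal component of the coefficient
matrix (germination responsivity) carries 84% of the variance; forward
selection picks the class-linked temperature-annual-range analogue first
(p = 0.001, the minimum attainable with 999 permutations); and after
accounting for spatial structure (PCNM axes) the linked variable retains a
small significant pure effect (4.4% of variation, p = 0.013) with a large
fraction shared between environment and space — the signature of a
spatially structured environmental driver. On the trait side,

```r
kw <- kruskal_wallis(study$traits$thickness_um,
                     cls$assignment$category[match(study$traits$accession_id,
                                                   cls$assignment$accession_id)])
#> Kruskal-Wallis H = 42.2, df = 2, p = 7e-10
```

dormant and responsive accessions have markedly thicker testa than
non-dormant ones, as the generator builds in.

`run_full_analysis(run_config(study = study, output_dir = "out"))` runs
every stage in order and writes the result CSVs, a Newick dendrogram and a
seed/parameter log.

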