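---
title: "Methods: functional data analysis of physical seed dormancy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: functional data analysis of physical seed dormancy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seedfda)
```

## The problem

Physical seed dormancy (PY) is imposed by a water-impermeable seed coat
(testa); dormancy release is observable as imbibition, the uptake of water.
In a germination assay, seeds of many accessions are plated under alternating
temperature regimes (here 25/15 °C and 35/15 °C day/night) and the cumulative
number of imbibed seeds is scored daily over a fixed horizon (28 days, 25
seeds × 2 replicate dishes per accession and regime). Classical scalar
summaries — final percentage, LT50, mean germination time, coefficient of
velocity — each capture one facet of the time course and cannot separate, for
instance, a slow-but-complete germinator from a fast-but-partial one.
`seedfda` instead treats the daily counts as discrete observations of a
smooth, non-decreasing *absolute germination distribution function* (AGDF)
and carries the whole curve — through its B-spline coefficients — into the
downstream multivariate, spatial and trait analyses.

## The AGDF model

For one accession × regime series with counts $y_i$ at days $t_i$, the AGDF
$s(t)$ is the minimizer of the penalized least-squares functional

$$\sum_i \bigl(y_i - s(t_i)\bigr)^2 \;+\; \lambda \int_0^T s'(t)^2\,dt$$

over splines of degree $k = 4$ on a fixed knot grid. The defaults place
interior knots every 2 days on $[0, 28]$, giving an 18-dimensional B-spline
basis; the exact knot layout of the original analyses is not documented
anywhere we could rely on, so an even grid at the scoring resolution is used
and both degree and knots are configurable (`agdf_control()`). The penalty
Gram matrix $\int B_i' B_j'$ is computed exactly by Gauss–Legendre quadrature
per inter-knot interval (the integrand is piecewise polynomial, so quadrature
at `degree` nodes is exact). A $(0, 0)$ anchor observation is prepended by
default: seeds start ungerminated, and the anchor makes the integration
domain identical across accessions so areas are comparable.

Tunable parameters:

* `lambda` (≥ 0, dimensionless): roughness penalty. Default is generalized
  cross-validation over the log grid $10^{-4} \ldots 10^4$; a fixed value
  gives exact reproducibility.
* `degree` (default 4) and `knot_spacing` (default 2 days).
* `monotone_tol` (default 0.02): the soft monotonicity tolerance, as a
  fraction of the seed total, applied to the minimum of the fitted first
  derivative on a 0.1-day grid.

Replicate dishes are summed into one series per accession × regime before
fitting (a per-replicate mode is available by simply not summing); the
summed series carries the summed seed total.

### Monotonicity

A cumulative count curve is non-decreasing, but the fit is deliberately
*unconstrained*: a hard monotone fit changes the estimator's linear-in-data
algebra and was judged unnecessary for descriptor extraction. Instead the
package (i) warns when the fitted derivative dips below
`-monotone_tol × seeds_total`, and (ii) offers an isotonic projection of the
evaluated curve before area computation (`agdf_area(..., monotone = TRUE)`).
One caveat discovered during development is worth stating plainly: for
sharp, almost noise-free sigmoid series (a fast germinator that saturates
early), GCV legitimately selects near-interpolating fits, and a degree-4
spline then rings at the corner, with derivative excursions of several seeds
per day. This is a property of unconstrained interpolation, not a defect of
the solver: moderate fixed smoothing (λ ≈ 2 on the default basis) removes
the ringing at a modest residual cost. Users who need guaranteed
near-monotone curves should fix λ or use the isotonic projection; the
descriptor analyses below are insensitive to the choice because the ringing
is local and small relative to the seed total.

### Areas and classical indices

The area under the AGDF (seed·days) is computed by the composite trapezoidal
rule on a 0.1-day grid; for raw counts the piecewise-linear interpolant
through the anchored points is integrated, which the trapezoid reproduces
exactly. `classical_indices()` provides final proportion, AUC, LT50 (first
crossing of half the final count, linearly interpolated; the observation day
itself when the level is hit exactly), MGT (increment-weighted mean day) and
CV = 100/MGT. All three rate indices are undefined — returned as `NA`, never
zero — when nothing germinates.

### Scatterplot smoothing

`smooth_regression()` applies the same engine to scattered $(x, y)$ pairs
(no anchor, knots over the range of $x$), playing the role of a
single-smooth Gaussian additive model, e.g. germination responsivity against
a bioclimatic predictor. Its F test against the intercept-only model is
computed from the *unpenalized* projection onto the spline basis — an exact
Gaussian F test with $(K-1, n-K)$ df. An effective-degrees-of-freedom test at
a GCV-chosen λ is anti-conservative (the smoothing parameter is selected on
the same data; in our null simulations the size was ~25% at nominal 5%),
while the exact-basis test holds its size by construction. Note also that
because the penalty is on the *first* derivative, its null space is the
constants: the heavy-smoothing limit of the fit is the sample mean, not a
regression line.

## Dormancy classification

Accessions are clustered by UPGMA (average linkage) on Euclidean distances —
of the per-regime B-spline coefficient vectors for single-regime analyses,
and of the 2-vector of AUCs (25/15, 35/15) for the combined analysis. UPGMA
is delegated to `stats::hclust`; merge heights are monotone and the
cophenetic matrix ultrametric. Equal-height merge ties are resolved by
`hclust`'s deterministic agglomeration order; with continuous descriptors
exact ties have probability zero, so no custom tie-break was layered on top.

The $k$-cluster cut (default $k = 3$) is labelled from per-cluster mean
final germination. The labelling contract is relative, with thresholds as
guards (`label_thresholds()`):

* **R** (responsive): mean 25/15 germination at or below `nondormant_min`
  and a rise of at least `responsive_gain` (default 0.25) from 25/15 to
  35/15;
* **N** (non-dormant): above `nondormant_min` (default 0.80) at both
  regimes;
* **D** (dormant): 35/15 mean below `dormant_max` (default 0.20), or, for
  borderline clusters, a lower mean nearer the dormant archetype.

The borderline fallback matters: a dormant group whose true 35/15 fraction
is near 0.20 produces cluster means that straddle a hard threshold about
half the time, so a pure threshold rule is unstable by construction.
Subgroup labels (D1, D2, …, numbering within category by decreasing mean
germination) are descriptive only.

## Spatial statistics

Distances are spherical (haversine, Earth radius 6371.0088 km), adequate at
the 5-km buffer and continental correlogram scales involved; no projected
systems are supported. Distance classes default to ten equal-frequency
(quantile) classes — the standard correlogram practice when class widths are
unequal, keeping per-class pair counts stable — with the largest class
excluded from testing. Moran's I per class uses binary pair-in-class
weights; p-values come from 999 value randomizations (two-sided around the
null expectation $-1/(n-1)$), preferred over the normal approximation at
these sample sizes; the correlogram is globally significant iff some tested
class is significant at the Bonferroni level $\alpha/k$.

Dutilleul's modified t-test corrects the correlation of two spatial
processes for autocorrelation in both: each process's spatial covariance is
estimated empirically by distance-class binning (the same class set as the
correlogram, for determinism and reuse), an effective sample size is formed
from trace operations on the two centered covariance matrices, and the t
statistic is referred to $\hat n - 2$ df, with $\hat n \le n$ enforced. In
the package's calibration simulations (50 points, shared exponential
autocorrelation with range half the extent), the corrected test held ~5%
size where the classical test rejected ~39% of null cases.

PCNM spatial eigenvectors are delegated to `vegan::pcnm`: truncation at the
longest minimum-spanning-tree edge, beyond-truncation distances replaced by
4× truncation (the originating literature's constant), positive-eigenvalue
axes returned in eigenvalue order.

Environmental values at collection sites are taken as means over a 5-km
great-circle buffer of raster cells, which smooths coordinate uncertainty in
genebank passport data.

## Ordination and variance partitioning

Collinear environmental variables are pruned greedily at $|r| \ge 0.90$:
the member of the worst pair with the larger mean absolute correlation to
all other variables is dropped, and every removal is logged.

PCA of the B-spline coefficient matrix is column-centered but *not*
standardized — the coefficients share the seed-count scale, and
standardization would inflate low-variance basis regions. Coefficient
blocks from both regimes are concatenated per accession (the natural way to
make one germination-pattern descriptor per accession; treating regimes
separately is available by subsetting). Axis signs follow a fixed rule
(largest-magnitude loading positive); the pipeline additionally orients PC1
so that it correlates positively with mean final germination, making
"germination responsivity" point from dormant to non-dormant.

RDA is implemented as multivariate least squares: explained variance is
adjusted by Ezekiel's formula ($1-(1-R^2)(n-1)/(n-p-1)$, the unbiased
estimator of explained variation), partial models residualize response and
predictors on the conditioning set, and significance comes from Monte Carlo
permutation (999 by default; Freedman–Lane residual permutation for partial
models — the standard scheme for partial constrained ordination). Forward
selection uses the double stopping rule: stop when the best candidate's
permutation p exceeds α = 0.05 or when the cumulative adjusted $R^2$
exceeds that of the all-candidate model. Two-set variance partitioning
reports pure fractions as semipartial differences of Ezekiel-adjusted
values — pure(X1) = adj(X1∪X2) − adj(X2) — so the identity
pure1 + pure2 + shared = adj(X1∪X2) holds exactly; the shared fraction is
not permutable and is reported untested. These fractions agree with
`vegan::varpart` to numerical precision, which the test suite uses as an
independent cross-check.

## Niche overlap

Overlap between groups' suitability surfaces uses Schoener's
$D = 1 - \tfrac12\sum|p_1 - p_2|$ and the Hellinger-based
$I = 1 - \tfrac12\sum(\sqrt{p_1}-\sqrt{p_2})^2$ on surfaces normalized to
probability over the union of the groups' backgrounds (300-km great-circle
buffers around each group's occurrences). $D \le I$ is not asserted — it is
not a theorem — but both are 1 iff the surfaces coincide and 0 iff supports
are disjoint.

The niche model is a pluggable interface; the built-in baseline is a
climate envelope: per predictor, suitability is 1 inside the central 5th–95th
percentile envelope of values at the occurrences, tapering linearly to 0 at
the observed extremes; cell suitability is the product over predictors,
restricted to the background. Externally produced suitability rasters
(e.g. from a maximum-entropy model) can be supplied wherever a surface is
accepted — the package's contribution here is the overlap and equivalency
testing, not the niche model itself. The equivalency test pools both
groups' occurrences, repartitions at the observed group sizes, refits and
recomputes $D$ and $I$ (default 100 replicates — the replicate count is not
standardized in the literature and is configurable); the p-value is
one-sided, $(1 + \#\{\text{null} \le \text{observed}\})/(1 + N)$, since
lower-than-null overlap is what signals niche divergence.

## Seed-trait statistics

Testa thickness across dormancy categories uses Kruskal–Wallis with tie
correction (a fully tied sample returns $H = 0$, $p = 1$); medians carry
distribution-free binomial order-statistic confidence intervals. Ordinal
logistic regression of category on morphology uses the proportional-odds
model (maximum likelihood via `MASS::polr`; a two-level response collapses
to binary logistic regression) with the response ordered D < R < N —
increasing germination propensity, matching the responsivity axis — and
candidate models compared by AIC. The soluble/insoluble proanthocyanidin
ratio is analysed by ANCOVA (`ratio ~ category + totalPA`, type-III F by
default) and by the covariate-free ANOVA; least-squares category means are
predictions at the covariate grand mean, and custom contrasts (e.g. D+R
vs. N with weights ½, ½, −1) are tested by F on the LS means, equivalent to
a reduced-versus-full nested model comparison.

## The synthetic-study generator

`simulate_study()` generates complete studies with the statistical
structure the analysis assumes:

* **Design**: 97 accessions split 28 N / 40 R / 29 D, 25 seeds × 2
  replicates per regime, 28-day daily scoring. (The three published group
  sizes total 98 against 97 accessions; the responsive group absorbs the
  difference.)
* **Germination**: each seed is independently "willing" with the class ×
  regime final fraction — N (0.92, 0.95), R (0.15, 0.75), D (0.15, 0.20)
  for (25/15, 35/15), echoing the reference group means — and willing seeds
  draw a log-normal imbibition time (class-specific medians of 5–14 days,
  log-sd 0.35), censored at day 28. Log-normal was chosen for right-skewed
  positive support; any two-parameter positive distribution could be
  substituted.
* **Landscape**: clustered collection sites over a Mediterranean-scale
  extent (10° W–40° E, 30–45° N); environmental fields are Gaussian
  processes with exponential covariance (range 400 km) sampled at sites and
  optionally on an exported 0.5° raster (sites then inherit their cell's
  value). One field, the `bio7_analog` (temperature annual range analogue),
  drives class membership through a logistic latent score — 2 log-odds per
  field SD by default, with dormant accessions at low values — ranked so
  configured class counts are met exactly; strength 0 decouples classes
  from the environment.
* **Traits**: testa thickness from class log-normals (medians 138/140/84 µm
  for D/R/N, N with the largest spread), total PA from class normals
  (means 2.18/1.87/1.77 mg g⁻¹) truncated to the observed 1.21–4.70 range,
  a dominant soluble fraction (94–99%) that rises with total PA and is
  slightly higher for D and R, and morphology linked to class only through
  the length-to-width ratio.

The generator reproduces *statistical structure* — class separation,
spatial autocorrelation, an environment–class link, trait contrasts — not
real Mediterranean climate values, genotype effects, inter-annual
variation, scoring error, or fungal-loss censoring. Green tests therefore
demonstrate that the pipeline recovers known structure at realistic effect
sizes and sample sizes; they do not validate the biological conclusions one
would draw from real accessions.

## Numerical choices and degenerate inputs

Rank-deficient normal systems at λ = 0 are reported with a suggestion to
use λ > 0 rather than silently pseudo-inverted. Evaluation outside the
fitted domain is an error (no extrapolation). Aliased RDA predictors are
dropped with a warning naming them. Constant surfaces make Moran's I
undefined (error), constant predictors are removed before correlation
pruning (warning), an all-zero suitability surface cannot be normalized
(error), and an effective sample size below 3 aborts the corrected t-test.
Permutation p-values always use the $(1 + \#)/(1 + N)$ form, so the minimum
attainable p is $1/(N+1)$.

## Problem sizes used by the test suite

The packaged checks run at deliberately modest sizes chosen to exercise the
statistics well: the spline oracle on 20 random 28-day fixtures; Moran null
calibration on 200 replicates of 20 points (199 randomizations each);
corrected-vs-classical t-test size on 500 simulations of 50 points;
equivalency-test calibration on 50 meta-replicates of 100-permutation
tests over a 24 × 40 grid; end-to-end recovery on the default 97-accession
study plus 100 replicate studies for selection stability; and
proportional-odds recovery at n = 500. `scripts/acceptance.R` re-runs the
same computations from scratch under a caller-supplied seed and writes the
headline numbers as JSON.

## Known limitations

* The AGDF fit is unconstrained; monotonicity is diagnostic/projection
  only (discussed above).
* The Dutilleul covariance estimate is binned, not model-based; very small
  n (< ~15) makes the effective sample size noisy.
* The envelope niche model is a baseline: it ignores predictor
  interactions and occurrence density, and is intended for calibration and
  as a stand-in where an external model's rasters are unavailable.
* Only two predictor sets are partitioned (environment vs. space); no
  three-set partitioning, no CCA, no kriging, and no projected coordinate
  systems.
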