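---
title: "Quantifying ecogeographic isolation with ensemble niche models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying ecogeographic isolation with ensemble niche models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecogeoiso)
```

## The question and the statistic

Ecogeographic isolation is the earliest-acting reproductive barrier
between related species: because each lineage is adapted to a different
climate, their geographic ranges overlap only partially, and most mating
opportunities never arise in the first place. `ecogeoiso` quantifies this
barrier from ecological niche models. For an ordered pair of species, let
$S$ be the number of grid cells where both are predicted to occur and
$U_A$ the number of cells suitable for species A but not B. Then

$$\mathrm{RI}_A \;=\; 1 - \frac{S}{S + U_A}$$

is the share of A's suitable habitat that it does **not** share with B:
0 when A's entire range is shared, 1 when the ranges are disjoint. The
index is deliberately asymmetric — a narrow endemic nested inside a
widespread relative is strongly isolated from it ($\mathrm{RI}$ near 1)
while the widespread species is barely isolated at all — so the package
always reports both directions of every pair. By convention RI is a
cell-count statistic; `ri_ecogeo(..., area_weighted = TRUE)` substitutes
spherical cell areas when latitudinal distortion matters.

## The modelling pipeline

The analysis follows the standard ensemble-SDM recipe and `run_pipeline()`
wires it together end to end:

1. **Data preparation.** Occurrence CSVs are cleaned (unparseable
   coordinates dropped, exact duplicates collapsed), clipped to the study
   window, and thinned to one record per grid cell. Thinning keeps the
   first record in file order, a deterministic tie-break; records on
   masked cells are removed. Clipping precedes thinning, so the thinning
   grid is exactly the analysis grid. Cell membership uses half-open
   intervals closed at the lower/left edge; coordinates are WGS84
   lon/lat; grid registration is cell-centre.
2. **Predictor screening.** Collinear covariates are removed with the
   usual two-stage rule: while any pair has $|r| \ge 0.75$, drop the
   member of the worst pair with the larger mean absolute correlation to
   everything else; then drop the largest-VIF variable until all
   VIF $\le 10$. Ties break by input order so the result is reproducible.
   Correlation and VIF are scale-free, so screening is invariant to
   variable units. `pca_habitat()` (correlation-matrix PCA — the
   covariates have incommensurate units) and `dfa_habitat()` (linear
   discriminant axes, priors proportional to group sizes) give the
   habitat-divergence ordinations.
3. **Model fitting.** Presences are contrasted with uniformly sampled
   background ("pseudo-absence") cells. Each replicate splits presences
   and background independently 70/30, fits one of three families, and is
   evaluated on the held-out 30%:
   * `GLM` — binomial regression with linear + quadratic terms, the
     classical parametric response-curve model;
   * `MAXENT` — an L1-penalized binomial background-contrast regression
     on linear, quadratic and two-sided hinge features. This is the
     statistical core of the Maxent approach (Maxent's exponential model
     is equivalent to a penalized logistic contrast of presences against
     background); suitability is read as the fitted probability rescaled
     so the best training cell maps to 1;
   * `MARS` — forward/backward hinge-basis least squares pruned by
     generalized cross-validation (penalty 2 per basis function, the
     standard additive-MARS default).
   Complete separation in the GLM falls back to a ridge-penalized fit and
   is recorded in the fit metadata.
4. **Evaluation.** AUC is computed by rank comparison (ties count ½) and
   TSS = sensitivity + specificity − 1 is maximized over all distinct
   score thresholds, reporting the smallest maximizing threshold. Both
   implementations are tested against exhaustive pair-counting and
   threshold-scan oracles.
5. **Ensembling.** Replicates with test TSS ≥ 0.8 are admitted and
   averaged with weights proportional to TSS; the binarization cutoff is
   the TSS-weighted mean of the members' TSS-maximizing thresholds. A
   committee-of-binaries alternative (`rule = "committee"`: members vote
   with their own thresholds, majority cutoff 0.5) is available. The
   weighted-mean rule was adopted as the default because it preserves a
   continuous suitability surface for the overlap statistics.
6. **Projection.** Scenario stacks reuse the weights and cutoff frozen at
   current-climate calibration, so projected ranges measure environmental
   transfer only. Several scenario stacks can be averaged cellwise
   (`average_scenarios()`), the usual abstraction of multi-GCM
   assembly.
7. **Isolation.** Binarized ranges feed `isolation_matrix()` (all ordered
   pairs), `area_dynamics()` (per-species habitat area in $10^5$ km²
   with signed deltas against the baseline), and
   `isolation_shift_summary()` (per-pair RI change against the identity
   line, plus the mean over ordered pairs — 12 values for four species).

## Niche statistics

Continuous suitability surfaces are normalized to probability surfaces
(`niche_distribution()`), on which the package computes Schoener's
$D = 1 - \tfrac12\sum_i |p_i - q_i|$, Warren's
$I = 1 - \tfrac12\sum_i(\sqrt{p_i} - \sqrt{q_i})^2$ (the Bhattacharyya
coefficient), and Levins' breadth $B = 1/\sum_i p_i^2$, standardized to
$[0,1]$ as $(B-1)/(n-1)$. $I \ge D$ always; both are symmetric and equal
1 only for identical surfaces.

The **niche identity test** asks whether two species' modelled niches
could have come from one pooled distribution: observed $D$ and $I$ come
from single-family (GLM) surfaces fitted to each species against one
shared background sample; the null repartitions the pooled occurrences
into groups of the original sizes and refits both surfaces per
pseudoreplicate. The one-tailed p-value uses the add-one estimator
$p = (1 + \#\{\text{null} \le \text{obs}\})/(n_{\mathrm{reps}}+1)$, so
$p > 0$ always, and is directed toward divergence (small when the
observed overlap is below the null). The background sample is held fixed
across pseudoreplicates: the test then isolates occurrence-label
exchangeability, which is what the null hypothesis states. A single fast
family is used for all surfaces because the null requires hundreds of
refits; re-running the full multi-family ensemble per pseudoreplicate
would change nothing about the exchangeability argument at two orders of
magnitude more cost.

Niche breadth comparisons bootstrap the occurrences (refit, recompute
$B_{std}$; default 100 replicates) and compare samples with a two-sided
Mann–Whitney U test — exact by enumeration of label assignments (valid
under ties) when $\binom{n_1+n_2}{n_1} \le 2\cdot 10^5$, otherwise the
tie-corrected normal approximation with continuity correction.

## The virtual-landscape generator

Every stage is testable without downloads because the package can
simulate the inputs it expects:

* **Layers.** Each environmental layer is a Gaussian random field: white
  noise smoothed with a Gaussian kernel (`spatial_range` cells wide),
  standardized, empirically whitened, then mixed through a factor
  decomposition of the target inter-layer correlation matrix. Whitening
  makes the sample correlations match the target exactly (the
  `mvrnorm(empirical = TRUE)` convention) — without it, spatial
  autocorrelation inflates sample correlations between nominally
  independent fields. Layers are finally rescaled to plausible units
  (e.g. bio1 in °C with mean 8 and SD 6, bio12 in mm with mean 800 and
  SD 300) so that niche centres and breadths are stated in natural
  units. The default grid is 200×200 cells over 91–125° E, 20–47° N — a
  coarse rendering of a mountainous East Asian study window — with six
  layers named for the commonly retained bioclimatic variables (bio1,
  bio3, bio7, bio12, bio15, srad12).
* **Species.** A virtual species is a Gaussian bell in breadth-scaled
  environmental space: suitability
  $= s_{\max}\exp(-\tfrac12\sum_l ((x_l-c_l)/b_l)^2)$. This is the
  standard virtual-species convention; it guarantees a unique optimum,
  symmetry in scaled distance, and monotone response to widening
  breadths.
* **Sampling.** Presences are drawn with probability proportional to
  suitability and placed at cell centres, so grid thinning is exactly
  testable. Default sample sizes are 50–150 records per species (100 in
  the shipped configurations), matching the scale of herbarium-record
  studies.
* **Scenarios.** A scenario is a per-layer affine map
  $x \mapsto fx + a$ — an abstract stand-in for past/future layer sets.
  No attempt is made to mimic actual GCM bias patterns.

What the generator does **not** emulate: sampling bias along roads and
rivers, spatial clustering of collections, positional error, non-Gaussian
niche shapes, and biotic interactions. Passing tests on synthetic data
therefore demonstrate the correctness of the computations and the
recoverability of known signal, not robustness to the observational
pathologies of real occurrence data.

## Determinism and numerical choices

Every random step is a pure function of an explicit seed; `run_pipeline()`
derives all stage seeds from one master seed and records a configuration
hash in the manifest, so a report is reproducible from (config, seed)
alone. Generators save and restore the session RNG state. Numerical
details worth knowing:

* suitability values are clamped to $[0,1]$; MARS predictions (least
  squares on a 0/1 response) are clamped likewise;
* the TSS threshold scan uses observed scores as candidates and reports
  the smallest maximizer; with near-perfect separation the TSS plateau is
  wide and its lower edge varies between replicates, which is the main
  source of spread in ensemble cutoffs at small sample sizes;
* empty projected ranges yield RI = `NA` with an explicit flag rather
  than 1 — a range that does not exist is not "isolated";
* zero-variance variables abort PCA with the variable named, and are
  dropped with a recorded reason during screening;
* spherical cell areas use the authalic radius 6371.0088 km and the exact
  sine-difference quadrilateral formula.

## Desk-scale defaults and limitations

Classic ensemble studies run 100 replicates per family against 200,000
background points. The package defaults are 10 replicates and 10,000
background points — enough for stable ensembles on the 200×200 synthetic
landscape — and both are plain configuration fields when the full-scale
setting is wanted. The shipped test-suite and acceptance configurations
use 120×120 grids, 3 replicates per family and 5,000 background points so
the complete four-species analysis runs in seconds.

Raster I/O is ESRI ASCII grid only (with the DX/DY header extension for
non-square cells); the format is plain text, lossless at the printed
precision, and readable by every GIS. There is no reprojection: all
inputs must already share one geographic lon/lat grid, and
`read_raster(expected_grid =)` enforces co-registration to 10⁻⁹ degrees.
The Mann–Whitney exact enumeration is quadratic-exponential in sample
size and hands over to the normal approximation beyond
$\binom{n_1+n_2}{n_1} > 2\cdot10^5$. The identity test holds the
background fixed and uses one model family; both choices are deliberate
(see above) but mean the test's null accounts for occurrence resampling
only.
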