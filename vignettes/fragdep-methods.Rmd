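---
title: "Methods: forest dependency of small-mammal communities in fragmented landscapes"
author: "fragdep"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: forest dependency in fragmented landscapes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fragdep)
```

## The problem

Deforestation frontiers convert continuous tropical forest into mosaics of
variable-sized forest patches embedded in an open-habitat matrix (mostly
cattle pasture). Small-mammal assemblages respond to this in two opposed
ways: forest-dependent species decline or disappear from small patches,
while open-habitat species from the surrounding matrix invade them. Plain
species counts can therefore stay flat across a patch-size gradient even
while composition turns over completely. `fragdep` implements an analysis
chain built around a species-level *forest-dependency index* and its
community-weighted mean, which makes that turnover measurable, relatable to
patch, landscape and habitat-quality covariates, and projectable over
multi-decade deforestation chronosequences.

## Effort standardization and sampling adequacy

Surveys mix live-trap transects and pitfall arrays, with a reduced design
in very small patches (below 2 ha by default: 1 live-trap transect and 2
pitfall arrays instead of 3 and 4) and a single live-trap transect in the
matrix adjacent to each patch (pitfalls are not deployed in the matrix).
`designEffort()` turns this design into trap-night records
(`traps x nights`, exact integer arithmetic), but real surveys deviate
from design defaults, so effort tables are first-class inputs everywhere:
any analysis accepts measured per-site trap-nights.

`standardizeAbundance()` converts counts to rates per 1000 trap-nights
(the unit is a configuration knob; it cancels in the dependency ratio, so
nothing downstream depends on it). Trap classes are pooled by summing
counts over summed effort, i.e. the pooled rate is the effort-weighted
mean of per-class rates. The result is a `CommunityMatrix`, a
`SummarizedExperiment` subclass with species as rows, sites as columns and
site covariates in `colData`.

Sampling adequacy is assessed with the abundance-based sample-coverage
estimator from singleton and doubleton counts,

$$\hat C = 1 - \frac{f_1}{n}\cdot\frac{(n-1)f_1}{(n-1)f_1 + 2 f_2},$$

which is 1 when no species is a singleton and 0 when every individual is a
singleton. The abundance-based (not incidence-based) form is used because
counts of individuals are what the capture tables record.

## The forest-dependency index

For each species, live-trap capture rates are pooled across sites within
each stratum and compared:

$$FD = \log_{10}\frac{r_F + c}{r_M + c}, \qquad c = 0.01 .$$

Only live-trap data enter the index because the matrix stratum carries no
pitfall effort; using both classes would bias the ratio for species with
class-specific detectability. The published form of this index, "ratio of
abundances (log10 x + 0.01)", is ambiguous about where the offset enters.
The default here adds the pseudo-count to *both* rates inside the ratio:
this keeps the index defined when a species was never captured in the
matrix, makes it antisymmetric (`FD(a,b) = -FD(b,a)`), zero exactly at
equal rates, and negative exactly when the matrix rate exceeds the forest
rate — which is what the open-habitat classification requires. The literal
reading `log10(rF/rM + 0.01)` is available as the `ratio_then_offset`
variant; it requires a positive matrix rate.

The standard error propagates between-site variability of the rates by the
delta method on the log ratio,

$$se(FD) = \frac{1}{\ln 10}\sqrt{\frac{sd_F^2}{(\bar r_F + c)^2} +
\frac{sd_M^2}{(\bar r_M + c)^2}},$$

chosen because it is symmetric and reproducible; a plug-in variant
(evaluate the index at mean ± SD, opposite directions in the two strata,
truncated at zero) is selectable when an asymmetry-preserving summary is
preferred.

Classification uses a data-driven threshold: `tau` is the maximum FD among
species recorded at least once in the matrix. `FD < 0` is open-habitat,
`0 <= FD <= tau` matrix-tolerant, `FD > tau` forest-dependent. The
boundary `FD = tau` is matrix-tolerant because the threshold species is by
construction matrix-recorded. Species detected only by pitfall traps have
no measured index; `imputeFD()` borrows the value of a user-designated
donor (typically a congener) and refuses chained imputation so provenance
stays one step deep.

The community-averaged index at a site is the abundance-weighted mean over
the species present, computed from the forest-stratum community matrix
with live and pitfall data pooled (the index itself is live-trap only; the
weights should reflect the whole assemblage). As a weighted mean it is
bounded by the species' extreme FD values, and increasing the share of
open-habitat individuals strictly decreases it.

## Community structure

Richness is the count of species with positive standardized abundance;
total abundance is the column sum, optionally log10 (undefined for empty
sites, flagged rather than silently dropped). Compositional distance is
quantitative Bray–Curtis (via `vegan::vegdist`); the source material calls
the input a "similarity matrix", but ordination needs a dissimilarity, so
the standard dissimilarity form is used. Pairs of two empty sites, where
the ratio is 0/0, are defined as 0 and flagged.

`pcoaOrdination()` performs classical PCoA (Gower double-centering and
eigendecomposition via `stats::cmdscale`). No Cailliez or Lingoes
correction is applied by default; instead the summed magnitude of negative
eigenvalues is reported so users can see how non-Euclidean their
dissimilarity is. Because downstream regressions use axis 1 as a response,
axis orientation matters for coefficient signs: every axis is
deterministically oriented so its largest-magnitude coordinate is
positive. This is a convention, not a correction — flipping it flips the
sign of any slope fitted against the axis, which is documented rather than
hidden.

## Model inference

All fits are Gaussian GLMs (ordinary least squares) with the maximum-
likelihood bookkeeping: `sigma^2 = rss/n`, `k` counts the intercept, the
slopes and the residual variance, `AICc = AIC + 2k(k+1)/(n-k-1)`.
Predictors are standardized to mean 0, sd 1 (n−1 denominator) so averaged
coefficients are comparable.

The multi-model chain mirrors standard information-theoretic practice:

* `screenCollinearity()` flags pairs with |r| > 0.75 and prunes by VIF
  (threshold 5), removing the worst offender iteratively and logging the
  order.
* `allSubsets()` enumerates every additive combination (2^p models,
  exhaustive, no stepwise shortcut — with p ≤ 7 this is at most 128 fits).
  A quadratic term obeys the marginality principle: it enters only
  together with its linear term.
* `confidenceSet()` keeps models with ΔAICc ≤ 2 (the best model always
  included) and renormalizes weights. The inequality is sometimes printed
  in self-contradictory forms in the applied literature; ΔAICc ≤ 2 is the
  convention of the framework this follows.
* `averageModel()` does conditional (natural) averaging: coefficients are
  averaged only over the models containing the term, with weights
  renormalized over that subset. Unconditional standard errors follow
  Burnham–Anderson (`sum w_i sqrt(se_i^2 + (b_i - bbar)^2)`), CIs are the
  normal approximation ±1.96 se, and relative importance is the sum of
  confidence-set weights of the models containing the term (renormalized
  weights, so RI = 1 means "in every plausible model"). Full-model
  averaging and raw-weight RI are defensible alternatives; the choices are
  recorded in the output so they are auditable.
* `hierarchicalPartition()` implements the Chevan–Sutherland decomposition
  over all 2^p subsets; the independent effects sum to the full-model R²
  exactly (to machine precision), which the tests verify.
* `selectBuffer()` ranks candidate buffer radii by mean AIC rank across
  responses (ties to higher mean R²), and `refitExcluding()` refits after
  *declared* outlier removal — exclusions are explicit user input, echoed
  in the result; there is no automatic outlier detection.

## Landscape projection

`labelPatches()` delineates forest patches on binary grids by connected-
component labeling (a small compiled flood fill). 8-connectivity is the
default since diagonal pixel contact usually reflects continuous canopy at
Landsat resolution; 4-connectivity is available. Patch ids follow the
raster-scan order of each patch's first pixel, so outputs are identical
across runs and platforms. Areas are exact: pixel count × pixel area.

The proximity index of a focal patch is the standard form
`sum(area_s / d_s^2)` over non-focal patches within the search radius,
with `d_s` the edge-to-edge distance between nearest pixel boundaries (not
centroids); touching patches are excluded and an isolated patch scores 0.
A published verbal description ("sum of areas divided by the squared sum
of distances") conflicts with the standard index it cites; the standard
form is the default and the literal reading is available behind
`variant = "literal"`. The search radius is configurable (500 m and
1000 m are both in common use). Continuous-forest reference sites take the
conventional surrogate `CF_PROXIMITY = 1e9`, and the continuous-forest
area surrogate is 144,800 ha — one order of magnitude above the largest
patch in the emulated design.

`projectCFD()` applies `cfd = b0 + b1 log10(area) + b2 (log10 area)^2`
to every patch; the defaults (0, 0.35, −0.04) are the dependency–area
relationship this projection module is designed around. The intercept
defaults to 0 to match the published projection equation, but is exposed
because fitted regressions carry one; note that with a zero intercept the
projected value at 1 ha is exactly 0, so the sign map of very small
patches is sensitive to that choice. `chronosequenceSummary()` and
`transitionMetric()` aggregate by exact pixel arithmetic. The transition
metric has two denominators, exposed because the natural-language
definition is ambiguous: `"forest_a"` divides by the above-threshold
forest area of the first year (so complete deforestation gives exactly 1),
`"forest_b"` by the total forest area of the second year. Neither is
asserted as "the" definition.

## The synthetic-data generator

The generator produces data with the statistical structure the analysis
assumes, at the scale of the emulated study design: 19 patches with areas
log-uniform over 1.4–14,480.5 ha (four orders of magnitude; log-uniform
because only the range is stated for the design emulated), 3
continuous-forest sites with the surrogate metrics above, and matrix
strata adjacent to patches. Log area and log proximity share a latent
factor with target correlation 0.8, matching the strong area–isolation
collinearity of real patch mosaics. Habitat covariates are drawn within
the documented ranges (cover 5.8–100%, shape 1.69–18.88, matrix
complexity 1–10 skewed towards simple pasture, burn 0–4, cattle presence
~42%, age 1–25 yr, logging 1–5).

The species pool holds three habitat-preference archetypes (default 12
forest-dependent, 5 matrix-tolerant, 3 open-habitat). Defaults (captures
per 1000 trap-nights): forest-dependent 20 in forest, exactly 0 in the
matrix, increasing with area; matrix-tolerant 20 and 6; open-habitat 3 in
forest (decreasing with area) and 25 in the matrix, favouring structurally
simple matrices. Species-level lognormal variation (sd 0.3 on the log
scale) individualizes rates. Counts are Poisson with mean
`rate x trap_nights / 1000 x detectability` (pitfall detectability 0.4);
Poisson is an assumption, not an inference — no dispersion model is stated
for the data the generator emulates — so negative-binomial overdispersion
is exposed as an option rather than a default.

Deforestation chronosequences are monotone by construction: cleared pixels
accumulate. The default region-growing mode expands clearings from random
nuclei (about one per 2000 pixels) by 8-neighbourhood dilation, so
remnant forest fragments into many small patches as clearings coalesce —
the spatial signature of an advancing agricultural frontier; independent
random clearing is available for comparison.

What the generator does *not* emulate: spatial autocorrelation of species
composition between neighbouring sites, season and weather effects on
trappability, trap saturation, species interactions, and georeferencing
beyond a uniform pixel size. Passing tests on synthetic data therefore
demonstrate correctness of the computations and recoverability of the
built-in structure, not field realism.

## Numerical choices and problem sizes

Degenerate inputs are handled explicitly: perfect fits report infinite
likelihood and `AIC = -Inf` rather than failing; empty sites are flagged
(`NA`) in log abundance and community FD; empty-empty Bray–Curtis pairs
are 0 with a flag; rank-deficient designs and constant predictors are
errors naming the offending terms; AICc-infeasible subsets are skipped
with a warning. Ties in nested-model comparison go to the smaller model.
All generators take integer seeds and are byte-reproducible.

The test suite and the acceptance script verify, among other things:
coefficient agreement with a normal-equations oracle to 1e-8 (100 random
designs, n ≤ 30, p ≤ 5); the partition identity to 1e-8 up to p = 6; PCoA
exactness on Euclidean input to 1e-8; archetype recovery of the FD
classification across 50 replicate surveys at the default design
(≥ 95% expected); 95% CI coverage of the quadratic dependency–area
coefficients (truth b1 = 0.35, b2 = −0.04, noise sd 0.3, 100 sites, 200
replicates; noise sd chosen so the signal-to-noise ratio resembles a
strong but not deterministic field relationship); and byte-identical
reruns of a 512×512, three-snapshot chronosequence projection. These
problem sizes keep the default runs comfortably under a minute or two per
component while leaving enough replication for the stochastic checks to be
stable.

## Known limitations

* The FD unit convention of historical datasets (per-100 vs per-1000
  trap-nights) is generally not recoverable; the unit is configurable and
  FD values are only comparable within one convention.
* Observed community FD (a weighted mean of species values, typically
  positive) and the zero-intercept projection equation live on different
  scales; the package computes both and does not reconcile them.
* Conditional averaging, renormalized-weight RI, and the normal CI
  approximation are documented choices; profile or bootstrap intervals are
  out of scope.
* The proximity index assumes a flat, uniformly gridded landscape; there
  is no CRS handling or reprojection.
* No mixed models: species-level incidence/abundance modelling with random
  species effects is outside this package's scope.
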