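# fragdep

Forest dependency of small-mammal communities in fragmented landscapes.

Agricultural frontiers turn continuous tropical forest into mosaics of
forest patches embedded in an open-habitat matrix (mostly cattle pasture).
Small mammals respond in two opposed ways — forest specialists drop out of
small patches while open-habitat species invade them — so species richness
alone can look flat across a patch-size gradient even as composition turns
over completely. `fragdep` is for ecologists analysing patch-matrix survey
data who need that turnover quantified: it standardizes capture tables by
trapping effort, scores each species' habitat preference, summarises
community structure, relates it to patch/landscape/habitat covariates by
multi-model inference, and projects the fitted relationship over
deforestation chronosequences.

## The core index

For each species, live-trap capture rates (per 1000 trap-nights) are pooled
within the forest and matrix strata and compared on the log scale:

    FD = log10( (r_F + c) / (r_M + c) ),   c = 0.01

`FD < 0` marks open-habitat species; species with `FD` above the maximum
observed among matrix-recorded species (`tau`) are strictly
forest-dependent; the rest are matrix-tolerant. The community-averaged
index at a site is the abundance-weighted mean of species FD — a
community-weighted mean trait that tracks compositional turnover along the
patch-size gradient and, once regressed on `log10(area)` (with a quadratic
term when AIC favours it), can be projected onto every patch of a
landscape raster.

Around this sit: the abundance-based sample-coverage estimator
(singletons/doubletons), Bray–Curtis + PCoA composition axes, all-subsets
AICc selection with ΔAICc ≤ 2 confidence sets, conditional model averaging
with relative importance, hierarchical partitioning of R² (exact
Chevan–Sutherland decomposition), buffer-radius selection, declared
outlier-exclusion refits, connected-component patch delineation, a
proximity (isolation) index, and seeded synthetic-data generators for all
of it.

## Worked example

A full synthetic survey at the default design scale (19 patches spanning
1.4–14,480.5 ha, 3 continuous-forest sites, 20 species in three
habitat-preference archetypes):

```r
library(fragdep)

cfg   <- simulationConfig(seed = 42)
sites <- generateLandscape(cfg)
pool  <- generateSpeciesPool(cfg)
eff   <- designEffort(sites, cfg$design)
cap   <- simulateCaptures(sites, pool, eff, seed = 42)

prof <- speciesProfiles(cap, eff)
head(prof[, c("species_id", "rate_forest", "rate_matrix",
              "fd", "fd_se", "fd_class")], 4)
#>   species_id rate_forest rate_matrix   fd fd_se         fd_class
#> 1       sp01        23.0           0 3.36 0.259 forest_dependent
#> 2       sp02        12.1           0 3.08 0.229 forest_dependent
#> 3       sp03        19.4           0 3.29 0.240 forest_dependent
#> 4       sp04        24.7           0 3.39 0.239 forest_dependent
attr(prof, "tau")
#> [1] 0.7434805
table(prof$fd_class)
#> forest_dependent  matrix_tolerant     open_habitat
#>               12                5                3
```

The rates are captures per 1000 live-trap-nights in each stratum; `fd` is
the log ratio (3.36 means effectively never captured in the matrix), and
the classification recovers the three simulated archetypes exactly, with
`tau = 0.74` the largest index among matrix-recorded species.

```r
cm  <- standardizeAbundance(cap, eff)      # forest stratum, live + pitfall
cfd <- communityFD(cm, prof)
head(cfd, 3)
#>   site_id  cfd total_abundance defined
#> 1     CF1 2.81             463    TRUE
#> 2     CF2 2.90             428    TRUE
#> 3     CF3 2.88             398    TRUE

la <- log10(sites$area_ha[match(cfd$site_id, sites$site_id)])
fitGaussian(cfd$cfd, data.frame(la = la, la_sq = la^2),
            c("la", "la_sq"), response = "community_fd")
#> ModelFit [community_fd ~ la + la_sq]
#>   n = 22, k = 4, AICc = -20.087, R2 = 0.857
```

Continuous-forest sites sit near the top of the community FD scale
(weighted mean ≈ 2.8–2.9 on the log10 index scale), and log10 patch area
with its quadratic explains 86% of the between-site variance in community
forest dependency — the relationship the projection module then applies to
whole-landscape patch mosaics:

```r
ch  <- generateChronosequence(c(512, 512), 0.09,
                              c(y1985 = 0.15, y2015 = 0.55), seed = 42)
psl <- lapply(ch, function(g) projectCFD(labelPatches(g)))
chronosequenceSummary(psl)
transitionMetric(psl[[1]], psl[[2]], denominator = "forest_a")
```

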