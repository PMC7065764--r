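#' Habitat-preference archetype of a simulated species
#'
#' Each simulated species belongs to one of three archetypes that differ in
#' where individuals are captured: `forest_dependent` species are never
#' captured in the matrix (matrix rate exactly 0), `matrix_tolerant`
#' species use both strata but prefer forest, and `open_habitat` species
#' are captured more often in the matrix than in forest. Rates are expected
#' live-trap captures per 1000 trap-nights; slopes act multiplicatively as
#' `exp(slope * z)` on the rate, with `z` the standardized covariate
#' (log10 area, log10 proximity, matrix complexity).
#'
#' @param archetype one of `"forest_dependent"`, `"matrix_tolerant"`,
#'   `"open_habitat"`.
#' @param baseRateForest,baseRateMatrix expected captures per 1000
#'   trap-nights in continuous forest / matrix.
#' @param areaSlope,proxSlope per-unit effect of standardized log10 area /
#'   log10 proximity on the forest rate.
#' @param matrixComplexitySlope per-unit effect of standardized matrix
#'   complexity on the matrix rate.
#' @return an `archetype_spec` list.
#' @export
archetypeSpec <- function(archetype = c("forest_dependent", "matrix_tolerant",
                                        "open_habitat"),
                          baseRateForest, baseRateMatrix,
                          areaSlope = 0, proxSlope = 0,
                          matrixComplexitySlope = 0) {
  archetype <- match.arg(archetype)
  if (baseRateForest < 0 || baseRateMatrix < 0)
    stop("rates must be non-negative")
  if (archetype == "forest_dependent" && baseRateMatrix != 0)
    stop("forest_dependent archetype must have zero matrix rate")
  if (archetype == "open_habitat" && baseRateMatrix <= baseRateForest)
    stop("open_habitat archetype must have matrix rate above forest rate")
  structure(list(archetype = archetype,
                 baseRateForest = baseRateForest,
                 baseRateMatrix = baseRateMatrix,
                 areaSlope = areaSlope, proxSlope = proxSlope,
                 matrixComplexitySlope = matrixComplexitySlope),
            class = "archetype_spec")
}

#' Default archetype set
#'
#' Forest-dependent species are common in forest, absent from the matrix
#' and increase with patch area; matrix-tolerant species use both strata
#' with a clear forest preference; open-habitat species are scarce in
#' forest (decreasing with area) and common in the matrix, favouring
#' structurally simple (low-complexity) matrix habitats.
#'
#' @return list of three [archetypeSpec()]s.
#' @export
defaultArchetypes <- function() {
  list(
    archetypeSpec("forest_dependent", baseRateForest = 20,
                  baseRateMatrix = 0, areaSlope = 0.3, proxSlope = 0.1),
    archetypeSpec("matrix_tolerant", baseRateForest = 20,
                  baseRateMatrix = 6, matrixComplexitySlope = 0.2),
    archetypeSpec("open_habitat", baseRateForest = 3,
                  baseRateMatrix = 25, areaSlope = -0.5,
                  matrixComplexitySlope = -0.3))
}

#' Simulation configuration
#'
#' Defaults emulate a fragmentation survey: 19 forest patches with areas
#' spanning four orders of magnitude (1.4 to 14,480.5 ha) plus 3
#' continuous-forest reference sites, patch area and proximity correlated
#' on the log scale (target r = 0.8), a species pool of 12 forest-dependent
#' + 5 matrix-tolerant + 3 open-habitat species, Poisson capture counts
#' proportional to trap-night effort, and monotone deforestation
#' chronosequences.
#'
#' @param nPatches number of forest patches (>= 2).
#' @param nContinuous number of continuous-forest sites.
#' @param areaRangeHa patch-area range in ha (log-uniform sampling).
#' @param nSpeciesPerArchetype species counts for the archetypes of
#'   [defaultArchetypes()] order.
#' @param areaProxCorrelation target correlation between log10 area and
#'   log10 proximity.
#' @param overdispersion optional negative-binomial overdispersion
#'   (variance = mu + overdispersion * mu^2); NULL (default) for Poisson.
#' @param design a [trapDesign()].
#' @param seed integer seed; a fixed seed makes every generator output
#'   reproducible.
#' @return a `simulation_config` list.
#' @export
simulationConfig <- function(nPatches = 19, nContinuous = 3,
                             areaRangeHa = c(1.4, 14480.5),
                             nSpeciesPerArchetype = c(12, 5, 3),
                             areaProxCorrelation = 0.8,
                             overdispersion = NULL,
                             design = trapDesign(), seed = 1) {
  if (any(areaRangeHa <= 0) || diff(areaRangeHa) <= 0)
    stop("area range must be positive with min < max")
  if (nPatches < 2) stop("at least two patches are required")
  if (areaProxCorrelation < 0 || areaProxCorrelation > 1)
    stop("correlation must be in [0, 1]")
  structure(list(nPatches = nPatches, nContinuous = nContinuous,
                 areaRangeHa = areaRangeHa,
                 nSpeciesPerArchetype = nSpeciesPerArchetype,
                 areaProxCorrelation = areaProxCorrelation,
                 overdispersion = overdispersion,
                 design = design, seed = as.integer(seed)),
            class = "simulation_config")
}

#' Generate a synthetic fragmented landscape
#'
#' Patch areas are drawn log-uniformly over the configured range; log10
#' proximity is generated from a latent factor shared with log10 area so
#' the two are positively correlated (target `areaProxCorrelation`), as in
#' real patch mosaics where large patches sit in better-connected
#' neighbourhoods. Habitat covariates are drawn within realistic ranges:
#' forest cover 5.8-100%, shape index 1.69-18.88, matrix complexity 1-10
#' (skewed towards simple pasture), vegetation class 1-3, burn 0-4, cattle
#' presence 0/1, isolation age 1-25 yr, logging intensity 1-5. Continuous-
#' forest sites get the conventional surrogate metrics: area 144,800 ha,
#' shape 1, proximity 1e9, cover 100%, matrix complexity 10, no burn or
#' cattle, age 0-1 yr.
#'
#' @param config a [simulationConfig()].
#' @return data.frame (one row per site) with `site_id`, `site_type`,
#'   `area_ha`, `shape`, `prox`, `cover`, `matrix_complexity`, `veg`,
#'   `burn`, `cattle`, `age`, `logging`.
#' @export
generateLandscape <- function(config = simulationConfig()) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  n <- config$nPatches
  la <- stats::runif(n, log10(config$areaRangeHa[1]),
                     log10(config$areaRangeHa[2]))
  r <- config$areaProxCorrelation
  z <- as.numeric(scale(la))
  lp <- r * z + sqrt(1 - r^2) * stats::rnorm(n)
  # linear map of the latent score onto the observed proximity range
  proxRange <- log10(c(0.8, 5.1e6))
  lp <- proxRange[1] + (lp - min(lp)) / max(diff(range(lp)), 1e-12) *
    diff(proxRange)
  patches <- data.frame(
    site_id = sprintf("P%02d", seq_len(n)),
    site_type = "patch",
    area_ha = 10^la,
    shape = stats::runif(n, 1.69, 18.88),
    prox = 10^lp,
    cover = pmin(100, pmax(5.8, 41.2 + 30.7 * (0.5 * z +
                                                 sqrt(0.75) * stats::rnorm(n)))),
    matrix_complexity = sample(1:10, n, replace = TRUE,
                               prob = 0.55^(0:9)),
    veg = sample(1:3, n, replace = TRUE),
    burn = sample(0:4, n, replace = TRUE),
    cattle = stats::rbinom(n, 1, 0.42),
    age = sample(1:25, n, replace = TRUE),
    logging = sample(1:5, n, replace = TRUE, prob = c(2, 3, 2, 1.5, 1)))
  if (config$nContinuous > 0) {
    m <- config$nContinuous
    cf <- data.frame(
      site_id = sprintf("CF%d", seq_len(m)),
      site_type = "continuous",
      area_ha = 144800, shape = 1, prox = CF_PROXIMITY, cover = 100,
      matrix_complexity = 10, veg = 3, burn = 0, cattle = 0,
      age = c(1, rep(0, m - 1)), logging = 1)
    patches <- rbind(patches, cf)
  }
  rownames(patches) <- NULL
  patches
}

#' Generate a synthetic species pool
#'
#' Creates `nSpeciesPerArchetype[i]` species for each archetype, with
#' species-level lognormal variation around the archetype base rates
#' (forest-dependent matrix rates stay exactly zero) and randomized
#' eco-morphological traits (taxon, body mass, diet, locomotion,
#' geographic range). Identifiers are stable under the seed.
#'
#' @param config a [simulationConfig()].
#' @param archetypes list of [archetypeSpec()]s (default
#'   [defaultArchetypes()]), matched by position to
#'   `config$nSpeciesPerArchetype`.
#' @return data.frame with one row per species, including the generating
#'   `archetype` and per-species rate parameters.
#' @export
generateSpeciesPool <- function(config = simulationConfig(),
                                archetypes = defaultArchetypes()) {
  if (!length(archetypes)) stop("at least one archetype is required")
  set.seed(config$seed + 1L)
  counts <- rep(config$nSpeciesPerArchetype,
                length.out = length(archetypes))
  rows <- list()
  for (i in seq_along(archetypes)) {
    a <- archetypes[[i]]
    ni <- counts[i]
    if (ni == 0) next
    mult <- exp(stats::rnorm(ni, 0, 0.3))
    rows[[i]] <- data.frame(
      archetype = a$archetype,
      base_rate_forest = a$baseRateForest * mult,
      base_rate_matrix = if (a$baseRateMatrix == 0) 0
                         else a$baseRateMatrix * exp(stats::rnorm(ni, 0, 0.3)),
      area_slope = a$areaSlope, prox_slope = a$proxSlope,
      matrix_complexity_slope = a$matrixComplexitySlope,
      taxon = sample(c("rodent", "marsupial"), ni, replace = TRUE),
      body_mass_g = round(exp(stats::rnorm(ni, log(60), 0.9)), 1),
      diet = sample(c("insectivore", "frugivore", "granivore", "omnivore"),
                    ni, replace = TRUE),
      locomotion = sample(c("terrestrial", "scansorial", "arboreal"),
                          ni, replace = TRUE),
      geo_range = sample(c("narrow", "intermediate", "wide"),
                         ni, replace = TRUE))
  }
  pool <- do.call(rbind, rows)
  pool <- data.frame(species_id = sprintf("sp%02d", seq_len(nrow(pool))),
                     pool)
  pool$live_detect <- 1
  pool$pitfall_detect <- 0.4
  rownames(pool) <- NULL
  pool
}

#' Simulate a capture table
#'
#' Expected counts are `rate x trap_nights / 1000 x detectability`, with
#' the per-site rate `base_rate_forest x exp(areaSlope zA + proxSlope zP)`
#' in the forest stratum and
#' `base_rate_matrix x exp(matrixComplexitySlope zM)` in the matrix (z
#' scores of log10 area, log10 proximity and matrix complexity across
#' sites). Counts are Poisson by default, negative binomial when
#' `overdispersion` is set (variance `mu + od mu^2`). Forest-dependent
#' species have zero expected matrix captures, hence zero matrix counts
#' with probability one.
#'
#' @param sites site table from [generateLandscape()].
#' @param pool species pool from [generateSpeciesPool()].
#' @param effort effort table, e.g. [designEffort()]; every record
#'   generates counts for every species.
#' @param seed integer seed.
#' @param overdispersion optional NB overdispersion; NULL for Poisson.
#' @return long data.frame `site_id`, `stratum`, `species_id`,
#'   `trap_class`, `count` (complete grid, zeros included).
#' @export
simulateCaptures <- function(sites, pool, effort, seed = 1,
                             overdispersion = NULL) {
  stopifnot(all(effort$site_id %in% sites$site_id))
  if (any(effort$trap_nights < 0)) stop("negative effort")
  set.seed(as.integer(seed))
  scl <- function(v) {
    s <- stats::sd(v)
    if (is.na(s) || s == 0) rep(0, length(v)) else (v - mean(v)) / s
  }
  zA <- scl(log10(sites$area_ha))
  zP <- scl(log10(sites$prox))
  zM <- scl(sites$matrix_complexity)
  names(zA) <- names(zP) <- names(zM) <- sites$site_id

  grid <- merge(effort, pool, by = NULL)
  i <- grid$site_id
  rate <- ifelse(
    grid$stratum == "forest",
    grid$base_rate_forest * exp(grid$area_slope * zA[i] +
                                  grid$prox_slope * zP[i]),
    grid$base_rate_matrix * exp(grid$matrix_complexity_slope * zM[i]))
  if (any(rate < 0)) stop("negative rates")
  detect <- ifelse(grid$trap_class == "live", grid$live_detect,
                   grid$pitfall_detect)
  mu <- rate * grid$trap_nights / 1000 * detect
  n <- length(mu)
  cnt <- if (is.null(overdispersion)) stats::rpois(n, mu)
         else stats::rnbinom(n, size = 1 / overdispersion, mu = mu)
  cnt[mu == 0] <- 0L
  out <- data.frame(site_id = grid$site_id, stratum = grid$stratum,
                    species_id = grid$species_id,
                    trap_class = grid$trap_class, count = cnt)
  out[order(out$site_id, out$stratum, out$trap_class, out$species_id), ,
      drop = FALSE] -> out
  rownames(out) <- NULL
  out
}

.dilate8 <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  out <- m
  out[-1, ] <- out[-1, ] | m[-nr, ]
  out[-nr, ] <- out[-nr, ] | m[-1, ]
  out[, -1] <- out[, -1] | m[, -nc]
  out[, -nc] <- out[, -nc] | m[, -1]
  out[-1, -1] <- out[-1, -1] | m[-nr, -nc]
  out[-nr, -nc] <- out[-nr, -nc] | m[-1, -1]
  out[-1, -nc] <- out[-1, -nc] | m[-nr, -1]
  out[-nr, -1] <- out[-nr, -1] | m[-1, -nc]
  out
}

#' Generate a deforestation chronosequence
#'
#' Produces per-year binary forest grids with monotone forest loss: the
#' cleared pixels of each year are a superset of the previous year's. The
#' default `"region"` mode grows clearings from random seed pixels by
#' 8-neighbourhood expansion, which leaves many small remnant forest
#' patches as clearings coalesce — the spatial signature of an advancing
#' agricultural frontier. `"random"` clears pixels independently.
#'
#' @param gridShape `c(rows, cols)`.
#' @param pixelAreaHa pixel area in ha.
#' @param clearingFractions per-year cleared fractions, non-decreasing,
#'   each in \[0, 1\]; names (if any) become year labels.
#' @param seed integer seed.
#' @param mode `"region"` (default) or `"random"`.
#' @param nSeeds number of clearing nuclei for region growth; the default
#'   scales with grid size (about one nucleus per 2000 pixels) so that
#'   remnant forest fragments into many small patches as clearings coalesce.
#' @return list of \linkS4class{ForestGrid}, one per year.
#' @export
generateChronosequence <- function(gridShape = c(256, 256), pixelAreaHa = 0.09,
                                   clearingFractions, seed = 1,
                                   mode = c("region", "random"),
                                   nSeeds = max(10, round(prod(gridShape) /
                                                            2000))) {
  mode <- match.arg(mode)
  cf <- clearingFractions
  if (any(cf < 0 | cf > 1)) stop("clearing fractions must be in [0, 1]")
  if (is.unsorted(cf, strictly = FALSE))
    stop("clearing fractions must be non-decreasing (monotone forest loss)")
  set.seed(as.integer(seed))
  nr <- gridShape[1]; nc <- gridShape[2]
  npix <- nr * nc
  cleared <- matrix(FALSE, nr, nc)
  years <- names(cf)
  if (is.null(years)) years <- paste0("y", seq_along(cf))
  out <- vector("list", length(cf))
  for (t in seq_along(cf)) {
    target <- round(cf[t] * npix)
    while (sum(cleared) < target) {
      need <- target - sum(cleared)
      if (mode == "random") {
        open <- which(!cleared)
        cleared[sample(open, need)] <- TRUE
        break
      }
      if (!any(cleared)) {
        open <- which(!cleared)
        cleared[sample(open, min(nSeeds, need))] <- TRUE
        next
      }
      frontier <- which(.dilate8(cleared) & !cleared)
      if (!length(frontier)) {
        cleared[sample(which(!cleared), 1)] <- TRUE
        next
      }
      if (length(frontier) > need) frontier <- sample(frontier, need)
      cleared[frontier] <- TRUE
    }
    out[[t]] <- ForestGrid(matrix(as.integer(!cleared), nr, nc),
                           pixelAreaHa, years[t])
  }
  names(out) <- years
  out
}
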