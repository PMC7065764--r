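#' Configuration of the forest-dependency index
#'
#' The index is a log10 ratio of effort-standardized capture rates in forest
#' versus matrix habitat. A small pseudo-count keeps the ratio defined for
#' species never captured in one stratum. Two formula variants are
#' supported: the default `"ratio_offset_both"` adds the pseudo-count to
#' both rates inside the ratio, `FD = log10((rF + c) / (rM + c))`, which is
#' antisymmetric and negative exactly when the matrix rate exceeds the
#' forest rate; `"ratio_then_offset"` computes `log10(rF / rM + c)` and
#' requires a positive matrix rate.
#'
#' @param pseudoCount rate offset `c` (> 0, default 0.01).
#' @param rateUnit trap-night denominator the rates are expressed in
#'   (bookkeeping only; the unit cancels in the ratio).
#' @param formulaVariant `"ratio_offset_both"` (default) or
#'   `"ratio_then_offset"`.
#' @param seMethod `"delta"` (default) or `"plugin"`, see [speciesFDSE()].
#' @param thresholdOverride optional fixed classification threshold, used by
#'   [fdThreshold()] when no species was recorded in the matrix.
#' @return an `fd_config` list.
#' @export
fdConfig <- function(pseudoCount = 0.01, rateUnit = 1000,
                     formulaVariant = c("ratio_offset_both",
                                        "ratio_then_offset"),
                     seMethod = c("delta", "plugin"),
                     thresholdOverride = NULL) {
  if (pseudoCount <= 0) stop("pseudoCount must be positive")
  structure(list(pseudoCount = pseudoCount, rateUnit = rateUnit,
                 formulaVariant = match.arg(formulaVariant),
                 seMethod = match.arg(seMethod),
                 thresholdOverride = thresholdOverride),
            class = "fd_config")
}

#' Species forest-dependency index
#'
#' `FD = log10((rF + c) / (rM + c))` under the default variant, where `rF`
#' and `rM` are the species' live-trap capture rates (per common effort
#' unit) in forest and matrix strata. `FD > 0` indicates forest preference,
#' `FD < 0` a species recorded relatively more often in the open-habitat
#' matrix.
#'
#' @param rateForest,rateMatrix non-negative standardized live-trap rates
#'   (vectorized).
#' @param config an [fdConfig()].
#' @return numeric FD values.
#' @examples
#' speciesFD(10, 0)   # ~ 3.0004: never caught in the matrix
#' speciesFD(5, 5)    # 0: equal rates
#' speciesFD(1, 10)   # < 0: open-habitat signature
#' @export
speciesFD <- function(rateForest, rateMatrix, config = fdConfig()) {
  if (any(rateForest < 0) || any(rateMatrix < 0))
    stop("rates must be non-negative")
  c0 <- config$pseudoCount
  switch(config$formulaVariant,
         ratio_offset_both = log10((rateForest + c0) / (rateMatrix + c0)),
         ratio_then_offset = {
           if (any(rateMatrix == 0))
             stop("ratio_then_offset variant requires positive matrix rates")
           log10(rateForest / rateMatrix + c0)
         })
}

#' Standard error of the forest-dependency index
#'
#' Propagates between-site variability of the standardized rates into the
#' log-ratio. The default delta method gives
#' \deqn{se = \frac{1}{\ln 10}\sqrt{\frac{sd_F^2}{(\bar r_F + c)^2} +
#'   \frac{sd_M^2}{(\bar r_M + c)^2}}}
#' The `"plugin"` alternative evaluates the index at mean +/- SD of the
#' rates (shifting the two strata in opposite directions, truncating at
#' zero) and reports half the spread.
#'
#' @param ratesForestBySite,ratesMatrixBySite per-site standardized
#'   live-trap rates (include zeros for sites where the species was absent).
#' @param config an [fdConfig()]; `config$seMethod` picks the method.
#' @return standard error on the FD (log10) scale.
#' @export
speciesFDSE <- function(ratesForestBySite, ratesMatrixBySite,
                        config = fdConfig()) {
  if (!length(ratesForestBySite) || !length(ratesMatrixBySite))
    stop("at least one site per stratum is required")
  c0 <- config$pseudoCount
  mF <- mean(ratesForestBySite); mM <- mean(ratesMatrixBySite)
  sdF <- if (length(ratesForestBySite) > 1) stats::sd(ratesForestBySite) else 0
  sdM <- if (length(ratesMatrixBySite) > 1) stats::sd(ratesMatrixBySite) else 0
  if (config$seMethod == "delta") {
    sqrt(sdF^2 / (mF + c0)^2 + sdM^2 / (mM + c0)^2) / log(10)
  } else {
    hi <- speciesFD(mF + sdF, max(mM - sdM, 0), config)
    lo <- speciesFD(max(mF - sdF, 0), mM + sdM, config)
    (hi - lo) / 2
  }
}

#' Forest-dependency classification threshold
#'
#' The threshold `tau` separating matrix-tolerant from strictly
#' forest-dependent species is the maximum FD among species recorded at
#' least once in the matrix: by construction any species with FD above it
#' was never seen outside forest.
#'
#' @param fdValues named numeric FD values per species.
#' @param matrixRecorded character ids of species with at least one matrix
#'   capture.
#' @param config an [fdConfig()]; its `thresholdOverride` is used when
#'   `matrixRecorded` is empty.
#' @return the threshold `tau`.
#' @export
fdThreshold <- function(fdValues, matrixRecorded, config = fdConfig()) {
  matrixRecorded <- intersect(matrixRecorded, names(fdValues))
  if (!length(matrixRecorded)) {
    if (is.null(config$thresholdOverride))
      stop("no matrix-recorded species: supply thresholdOverride")
    return(config$thresholdOverride)
  }
  max(fdValues[matrixRecorded], na.rm = TRUE)
}

#' Classify species by forest dependency
#'
#' Partitions the FD scale: `FD < 0` is `"open_habitat"`,
#' `0 <= FD <= tau` is `"matrix_tolerant"` and `FD > tau` is
#' `"forest_dependent"`. The boundary `FD = tau` falls to matrix-tolerant
#' because the threshold species is itself matrix-recorded.
#'
#' @param fdValue numeric FD value(s), finite.
#' @param tau classification threshold from [fdThreshold()].
#' @return factor-like character vector of classes.
#' @export
classifySpecies <- function(fdValue, tau) {
  if (any(!is.finite(fdValue))) stop("FD values must be finite")
  if (!is.finite(tau)) stop("threshold must be finite")
  ifelse(fdValue < 0, "open_habitat",
         ifelse(fdValue <= tau, "matrix_tolerant", "forest_dependent"))
}

#' Impute FD values from donor species
#'
#' Species detected only by pitfall traps have no live-trap rates and hence
#' no measured FD; following standard practice their FD is borrowed from a
#' designated (e.g. congeneric) donor. Chained imputation is refused: a
#' donor must itself have a measured FD.
#'
#' @param profiles species-profile data.frame from [speciesProfiles()] (or
#'   any data.frame with `species_id`, `fd`, `imputed` columns).
#' @param donorMap named character vector: `names()` are recipients,
#'   values their donors.
#' @param tau threshold for reclassification of imputed values (optional;
#'   if missing, classes of imputed species are set only when a `fd_class`
#'   column and threshold attribute are available).
#' @return `profiles` with imputed `fd`, `imputed` flag, `donor_species`
#'   and recomputed `fd_class` for the recipients.
#' @export
imputeFD <- function(profiles, donorMap, tau = attr(profiles, "tau")) {
  stopifnot(all(c("species_id", "fd", "imputed") %in% names(profiles)))
  if (!"donor_species" %in% names(profiles)) profiles$donor_species <- NA_character_
  for (sp in names(donorMap)) {
    donor <- donorMap[[sp]]
    i <- match(sp, profiles$species_id)
    j <- match(donor, profiles$species_id)
    if (is.na(j)) stop(sprintf("donor '%s' for '%s' is missing", donor, sp))
    if (isTRUE(profiles$imputed[j]))
      stop(sprintf("donor '%s' is itself imputed: chained imputation refused",
                   donor))
    if (is.na(profiles$fd[j]))
      stop(sprintf("donor '%s' has no measured FD", donor))
    if (is.na(i)) stop(sprintf("species '%s' not in profiles", sp))
    profiles$fd[i] <- profiles$fd[j]
    profiles$imputed[i] <- TRUE
    profiles$donor_species[i] <- donor
    if (!is.null(tau) && "fd_class" %in% names(profiles))
      profiles$fd_class[i] <- classifySpecies(profiles$fd[i], tau)
  }
  profiles
}

#' Build species forest-dependency profiles from captures and effort
#'
#' End-to-end species scoring: pools live-trap captures over sites within
#' each stratum, standardizes by the pooled live-trap effort, computes FD
#' and its standard error (from per-site rate variability), derives the
#' matrix-recorded threshold and classifies every species. Species with no
#' live-trap captures anywhere (typically pitfall-only) get `fd = NA` and
#' can be completed with [imputeFD()].
#'
#' @param captures long capture table (`site_id`, `stratum`, `species_id`,
#'   `trap_class`, `count`).
#' @param effort effort table (`site_id`, `stratum`, `trap_class`,
#'   `trap_nights`).
#' @param config an [fdConfig()].
#' @param donorMap optional named character vector passed to [imputeFD()].
#' @return data.frame with one row per species: pooled rates, `fd`,
#'   `fd_se`, `matrix_recorded`, `fd_class`, `imputed`, `donor_species`;
#'   the threshold is attached as attribute `"tau"`.
#' @export
speciesProfiles <- function(captures, effort, config = fdConfig(),
                            donorMap = NULL) {
  if (!any(effort$stratum == "matrix" & effort$trap_class == "live" &
             effort$trap_nights > 0))
    stop("matrix-stratum live-trap effort is required to compute FD")
  cmF <- standardizeAbundance(captures, effort, stratum = "forest",
                              trapClasses = "live",
                              rateUnit = config$rateUnit)
  cmM <- standardizeAbundance(captures, effort, stratum = "matrix",
                              trapClasses = "live",
                              rateUnit = config$rateUnit)
  species <- sort(unique(captures$species_id))

  pooledRate <- function(stratum) {
    eff <- effort[effort$stratum == stratum & effort$trap_class == "live", ]
    tn <- sum(eff$trap_nights)
    cap <- captures[captures$stratum == stratum &
                      captures$trap_class == "live", ]
    cnt <- tapply(cap$count, factor(cap$species_id, levels = species), sum)
    cnt[is.na(cnt)] <- 0
    rate <- if (tn > 0) as.numeric(cnt) / tn * config$rateUnit
            else rep(0, length(cnt))
    list(rate = rate, count = as.numeric(cnt))
  }
  fr <- pooledRate("forest")
  mr <- pooledRate("matrix")

  liveTotal <- fr$count + mr$count
  fd <- ifelse(liveTotal > 0,
               speciesFD(fr$rate, mr$rate, config), NA_real_)
  fdse <- vapply(seq_along(species), function(i) {
    if (liveTotal[i] == 0) return(NA_real_)
    speciesFDSE(abundances(cmF)[species[i], ],
                abundances(cmM)[species[i], ], config)
  }, numeric(1))

  capM <- captures[captures$stratum == "matrix" & captures$count > 0, ]
  matrixRecorded <- unique(capM$species_id)
  names(fd) <- species
  tau <- fdThreshold(fd[!is.na(fd)], matrixRecorded, config)

  prof <- data.frame(species_id = species,
                     rate_forest = fr$rate, rate_matrix = mr$rate,
                     fd = as.numeric(fd), fd_se = fdse,
                     matrix_recorded = species %in% matrixRecorded,
                     fd_class = NA_character_,
                     imputed = FALSE, donor_species = NA_character_,
                     stringsAsFactors = FALSE)
  ok <- !is.na(prof$fd)
  prof$fd_class[ok] <- classifySpecies(prof$fd[ok], tau)
  attr(prof, "tau") <- tau
  if (!is.null(donorMap)) prof <- imputeFD(prof, donorMap, tau = tau)
  prof
}

#' Community-averaged forest dependency
#'
#' The abundance-weighted mean FD at each site,
#' `cfd_j = sum_s a_sj FD_s / sum_s a_sj`, with `a_sj` the standardized
#' abundances of a forest-stratum \linkS4class{CommunityMatrix} (live and
#' pitfall pooled) and `FD_s` the species values (measured or imputed). A
#' community-weighted mean trait: bounded by the minimum and maximum FD of
#' the species present.
#'
#' @param x a forest-stratum \linkS4class{CommunityMatrix}, or a plain
#'   species x sites abundance matrix.
#' @param profiles data.frame from [speciesProfiles()] (needs `species_id`
#'   and `fd`), or a named numeric vector of FD values.
#' @param ... unused.
#' @return data.frame with `site_id`, `cfd`, `total_abundance`, `defined`;
#'   sites with zero total abundance get `cfd = NA` and `defined = FALSE`.
#' @rdname communityFD
#' @export
setMethod("communityFD", "CommunityMatrix", function(x, profiles, ...) {
  communityFD(abundances(x), profiles)
})

#' @rdname communityFD
#' @export
setMethod("communityFD", "matrix", function(x, profiles, ...) {
  fd <- if (is.data.frame(profiles))
    stats::setNames(profiles$fd, profiles$species_id) else profiles
  present <- rownames(x)[rowSums(x) > 0]
  missing <- present[!(present %in% names(fd)) | is.na(fd[present])]
  if (length(missing))
    stop("species without an FD value (measured or imputed): ",
         paste(missing, collapse = ", "))
  tot <- colSums(x)
  num <- as.numeric(crossprod(x, ifelse(is.na(fd[rownames(x)]), 0,
                                        fd[rownames(x)])))
  data.frame(site_id = colnames(x),
             cfd = ifelse(tot > 0, num / tot, NA_real_),
             total_abundance = tot,
             defined = tot > 0,
             row.names = NULL)
})
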