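#' Trap-design parameters
#'
#' Describes the standard sampling design: live-trap transects of paired
#' traps at regularly spaced stations and Y-shaped pitfall arrays, with a
#' reduced design in very small patches and a single live-trap transect (no
#' pitfalls) in the matrix adjacent to each patch. Defaults correspond to
#' one 10-night session with 5-station transects of 2 live traps each, 4
#' buckets per pitfall array, and the 2-ha threshold below which patches get
#' the reduced design (1 transect + 2 arrays instead of 3 + 4).
#'
#' @param liveTransectsSmall,liveTransectsLarge live-trap transects in
#'   patches below/at-or-above the small-patch threshold.
#' @param stationsPerTransect stations per live-trap transect.
#' @param liveTrapsPerStation traps per station.
#' @param pitfallArraysSmall,pitfallArraysLarge pitfall arrays below/at-or-
#'   above the threshold.
#' @param pitfallsPerArray buckets per array.
#' @param matrixTransects live-trap transects in the matrix stratum.
#' @param nights consecutive trapping nights.
#' @param smallPatchThresholdHa area threshold (ha) for the reduced design.
#' @return a `trap_design` list.
#' @examples
#' trapDesign()  # the default design
#' @export
trapDesign <- function(liveTransectsSmall = 1, liveTransectsLarge = 3,
                       stationsPerTransect = 5, liveTrapsPerStation = 2,
                       pitfallArraysSmall = 2, pitfallArraysLarge = 4,
                       pitfallsPerArray = 4, matrixTransects = 1,
                       nights = 10, smallPatchThresholdHa = 2) {
  d <- list(liveTransectsSmall = liveTransectsSmall,
            liveTransectsLarge = liveTransectsLarge,
            stationsPerTransect = stationsPerTransect,
            liveTrapsPerStation = liveTrapsPerStation,
            pitfallArraysSmall = pitfallArraysSmall,
            pitfallArraysLarge = pitfallArraysLarge,
            pitfallsPerArray = pitfallsPerArray,
            matrixTransects = matrixTransects,
            nights = nights,
            smallPatchThresholdHa = smallPatchThresholdHa)
  counts <- unlist(d[1:8])
  if (any(counts < 0)) stop("trap counts must be non-negative")
  if (nights < 1) stop("nights must be >= 1")
  if (smallPatchThresholdHa <= 0) stop("small-patch threshold must be positive")
  structure(d, class = "trap_design")
}

#' Derive trap-night effort records from the sampling design
#'
#' Applies a [trapDesign()] to a site table and returns one effort record
#' per site, stratum and trap class, with `trap_nights = traps x nights`.
#' Patches smaller than the design threshold receive the reduced design;
#' larger patches and continuous-forest sites the full design. The matrix
#' stratum (present only for patch sites) receives live traps only, since no
#' pitfall arrays are deployed there.
#'
#' @param sites data.frame with columns `site_id`, `area_ha` and `site_type`
#'   (`"patch"` or `"continuous"`), e.g. from [generateLandscape()].
#' @param design a [trapDesign()].
#' @param matrixStratum logical; also emit matrix-stratum records for patch
#'   sites (default TRUE).
#' @return data.frame with columns `site_id`, `stratum`, `trap_class`,
#'   `trap_nights`.
#' @examples
#' s <- data.frame(site_id = c("P1", "CF1"), area_ha = c(1.4, 144800),
#'                 site_type = c("patch", "continuous"))
#' designEffort(s)
#' @export
designEffort <- function(sites, design = trapDesign(), matrixStratum = TRUE) {
  stopifnot(all(c("site_id", "area_ha", "site_type") %in% names(sites)))
  if (anyNA(sites$area_ha[sites$site_type == "patch"]))
    stop("patch sites must have a valid area")
  rows <- lapply(seq_len(nrow(sites)), function(i) {
    s <- sites[i, ]
    small <- s$site_type == "patch" && s$area_ha < design$smallPatchThresholdHa
    nLiveTr <- if (small) design$liveTransectsSmall else design$liveTransectsLarge
    nArrays <- if (small) design$pitfallArraysSmall else design$pitfallArraysLarge
    live <- nLiveTr * design$stationsPerTransect * design$liveTrapsPerStation
    pit <- nArrays * design$pitfallsPerArray
    out <- data.frame(site_id = s$site_id,
                      stratum = "forest",
                      trap_class = c("live", "pitfall"),
                      trap_nights = c(live, pit) * design$nights)
    if (matrixStratum && s$site_type == "patch") {
      mlive <- design$matrixTransects * design$stationsPerTransect *
        design$liveTrapsPerStation
      out <- rbind(out,
                   data.frame(site_id = s$site_id, stratum = "matrix",
                              trap_class = c("live", "pitfall"),
                              trap_nights = c(mlive * design$nights, 0)))
    }
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Summarise trapping effort by stratum
#'
#' @param effort effort table (`site_id`, `stratum`, `trap_class`,
#'   `trap_nights`).
#' @return data.frame of trap-night totals per stratum plus a `"total"` row.
#' @examples
#' effortSummary(data.frame(site_id = "all", stratum = c("forest", "matrix"),
#'                          trap_class = "live", trap_nights = c(15868, 5700)))
#' @export
effortSummary <- function(effort) {
  stopifnot(all(c("stratum", "trap_nights") %in% names(effort)))
  if (any(effort$trap_nights < 0)) stop("trap_nights must be non-negative")
  agg <- stats::aggregate(trap_nights ~ stratum, data = effort, FUN = sum)
  rbind(agg, data.frame(stratum = "total",
                        trap_nights = sum(effort$trap_nights)))
}

#' Effort-standardize capture counts into a CommunityMatrix
#'
#' Converts raw counts to capture rates per `rateUnit` trap-nights. Within a
#' site, counts from the selected trap classes are pooled by summing counts
#' and summing effort, i.e. the pooled rate is the effort-weighted mean of
#' the per-class rates:
#' `rate = rateUnit * sum(counts) / sum(trap_nights)`.
#'
#' @param captures long capture table with columns `site_id`, `stratum`,
#'   `species_id`, `trap_class`, `count`.
#' @param effort effort table (`site_id`, `stratum`, `trap_class`,
#'   `trap_nights`); every capture record must have a matching record with
#'   positive effort.
#' @param stratum stratum to standardize (`"forest"` or `"matrix"`).
#' @param trapClasses trap classes to pool (default both `"live"` and
#'   `"pitfall"`).
#' @param rateUnit trap-night denominator (default 1000).
#' @param siteData optional per-site covariates forwarded to the result.
#' @return a \linkS4class{CommunityMatrix} (species x sites). Sites are all
#'   sites with effort in the stratum; species are all species in `captures`.
#' @examples
#' cap <- data.frame(site_id = "P1", stratum = "forest", species_id = "sp1",
#'                   trap_class = "live", count = 46)
#' eff <- data.frame(site_id = "P1", stratum = "forest", trap_class = "live",
#'                   trap_nights = 460)
#' abundances(standardizeAbundance(cap, eff))  # 100 per 1000 trap-nights
#' @export
standardizeAbundance <- function(captures, effort,
                                 stratum = c("forest", "matrix"),
                                 trapClasses = c("live", "pitfall"),
                                 rateUnit = 1000, siteData = NULL) {
  stratum <- match.arg(stratum)
  needC <- c("site_id", "stratum", "species_id", "trap_class", "count")
  needE <- c("site_id", "stratum", "trap_class", "trap_nights")
  stopifnot(all(needC %in% names(captures)), all(needE %in% names(effort)))
  if (any(captures$count < 0)) stop("counts must be non-negative")

  eff <- effort[effort$stratum == stratum & effort$trap_class %in% trapClasses, ]
  cap <- captures[captures$stratum == stratum &
                    captures$trap_class %in% trapClasses, ]
  # every non-empty capture record needs matching positive effort
  key <- function(d) paste(d$site_id, d$trap_class, sep = "\r")
  effTN <- tapply(eff$trap_nights, key(eff), sum)
  bad <- cap$count > 0 &
    (!(key(cap) %in% names(effTN)) | effTN[key(cap)] <= 0)
  if (any(bad)) {
    b <- cap[which(bad)[1], ]
    stop(sprintf("captures at site '%s' (%s traps) have zero recorded effort",
                 b$site_id, b$trap_class))
  }

  siteTN <- tapply(eff$trap_nights, eff$site_id, sum)
  sites <- names(siteTN)
  species <- sort(unique(captures$species_id))
  m <- matrix(0, length(species), length(sites),
              dimnames = list(species, sites))
  if (nrow(cap)) {
    cap <- cap[cap$site_id %in% sites, ]
    counts <- tapply(cap$count, list(cap$species_id, cap$site_id), sum)
    counts[is.na(counts)] <- 0
    m[rownames(counts), colnames(counts)] <- counts
  }
  tn <- as.numeric(siteTN[sites])
  if (any(tn <= 0 & colSums(m) > 0))
    stop("site with captures but zero total effort")
  rate <- sweep(m, 2, ifelse(tn > 0, tn, 1), "/") * rateUnit
  rate[, tn <= 0] <- 0
  CommunityMatrix(rate, siteData = siteData, stratum = stratum,
                  rateUnit = rateUnit)
}

#' Abundance-based sample coverage
#'
#' Estimated proportion of individuals in the assemblage belonging to
#' species already represented in the sample, from singleton and doubleton
#' counts:
#' \deqn{\hat C = 1 - \frac{f_1}{n}\,
#'   \frac{(n-1) f_1}{(n-1) f_1 + 2 f_2}}
#' where `n` is the number of individuals, `f1` the number of species seen
#' exactly once and `f2` the number seen exactly twice. Returns 1 when there
#' are no singletons.
#'
#' @param counts non-negative integer per-species abundances at one site.
#' @return coverage in \[0, 1\].
#' @examples
#' sampleCoverage(c(3, 5, 2))          # no singletons -> 1
#' sampleCoverage(rep(1, 6))           # all singletons -> 0
#' @export
sampleCoverage <- function(counts) {
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  n <- sum(counts)
  if (n < 1) stop("empty sample: coverage is undefined")
  f1 <- sum(counts == 1)
  f2 <- sum(counts == 2)
  if (f1 == 0) return(1)
  1 - (f1 / n) * ((n - 1) * f1 / ((n - 1) * f1 + 2 * f2))
}
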