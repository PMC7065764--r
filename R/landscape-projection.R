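#' Delineate forest patches by connected-component labeling
#'
#' Labels connected components of forest pixels under 8-connectivity
#' (default; diagonal neighbours connected) or 4-connectivity. Patch ids
#' are deterministic: patches are numbered by the row-major raster-scan
#' order of their first pixel. Patch area is exactly
#' `pixel count x pixel area`.
#'
#' @param grid a \linkS4class{ForestGrid}.
#' @param connectivity 4 or 8 (default 8).
#' @return a \linkS4class{PatchSet}; its [patchTable()] has columns
#'   `patch_id`, `year`, `n_pixels`, `area_ha`, `centroid_row`,
#'   `centroid_col`.
#' @export
labelPatches <- function(grid, connectivity = 8) {
  stopifnot(is(grid, "ForestGrid"))
  connectivity <- as.integer(connectivity)
  if (!connectivity %in% c(4L, 8L)) stop("connectivity must be 4 or 8")
  cells <- grid@cells
  if (!all(cells %in% c(0, 1))) stop("grid must be binary")
  lab <- .ccLabel(matrix(as.integer(cells), nrow(cells)), connectivity)
  np <- max(lab)
  if (np == 0) {
    tab <- data.frame(patch_id = integer(0), year = character(0),
                      n_pixels = integer(0), area_ha = numeric(0),
                      centroid_row = numeric(0), centroid_col = numeric(0))
  } else {
    idx <- which(lab > 0, arr.ind = TRUE)
    l <- lab[lab > 0]
    npix <- tabulate(l, nbins = np)
    tab <- data.frame(patch_id = seq_len(np),
                      year = grid@year,
                      n_pixels = npix,
                      area_ha = npix * grid@pixelAreaHa,
                      centroid_row = as.numeric(tapply(idx[, 1], l, mean)),
                      centroid_col = as.numeric(tapply(idx[, 2], l, mean)))
  }
  methods::new("PatchSet", labels = lab, table = tab,
               pixelAreaHa = grid@pixelAreaHa, year = grid@year,
               connectivity = connectivity)
}

#' Surrogate proximity value assigned to continuous forest
#'
#' Continuous-forest reference sites have no meaningful patch geometry; a
#' large constant is conventionally assigned to their proximity index.
#' @export
CF_PROXIMITY <- 1.0e9

.boundaryPixels <- function(lab, id) {
  idx <- which(lab == id, arr.ind = TRUE)
  nr <- nrow(lab); nc <- ncol(lab)
  isBoundary <- vapply(seq_len(nrow(idx)), function(i) {
    r <- idx[i, 1]; c <- idx[i, 2]
    if (r == 1 || r == nr || c == 1 || c == nc) return(TRUE)
    any(lab[(r - 1):(r + 1), (c - 1):(c + 1)] != id)
  }, logical(1))
  idx[isBoundary, , drop = FALSE]
}

.edgeDistance <- function(a, b, side) {
  # nearest distance between the pixel squares of two pixel sets
  best <- Inf
  for (i in seq_len(nrow(a))) {
    dr <- pmax(abs(b[, 1] - a[i, 1]) - 1, 0)
    dc <- pmax(abs(b[, 2] - a[i, 2]) - 1, 0)
    best <- min(best, min(dr^2 + dc^2))
  }
  sqrt(best) * side
}

#' Proximity index of a focal patch
#'
#' The standard proximity index: the sum, over all non-focal patches whose
#' edge-to-edge distance from the focal patch is positive and at most the
#' search radius, of `area / distance^2` (area in ha, distance in m).
#' Larger values mean less isolation; an isolated patch scores 0. Distances
#' are measured between nearest pixel boundaries, not centroids; patches
#' touching the focal patch are excluded. A `"literal"` variant computes
#' `sum(areas) / (sum(distances))^2` over the qualifying patches instead.
#'
#' @param ps a \linkS4class{PatchSet}.
#' @param focalID patch id of the focal patch.
#' @param radiusM search radius in metres (default 1000).
#' @param variant `"standard"` (default) or `"literal"`.
#' @return the proximity value. For continuous-forest reference sites use
#'   the assignment constant [CF_PROXIMITY].
#' @export
proximityIndex <- function(ps, focalID, radiusM = 1000,
                           variant = c("standard", "literal")) {
  variant <- match.arg(variant)
  tab <- ps@table
  if (!focalID %in% tab$patch_id) stop("unknown focal patch id")
  side <- sqrt(ps@pixelAreaHa * 1e4)   # pixel side in metres
  lab <- ps@labels
  focalPix <- .boundaryPixels(lab, focalID)
  others <- setdiff(tab$patch_id, focalID)
  dist <- vapply(others, function(id)
    .edgeDistance(focalPix, .boundaryPixels(lab, id), side), numeric(1))
  keep <- dist > 0 & dist <= radiusM
  if (!any(keep)) return(0)
  areas <- tab$area_ha[match(others[keep], tab$patch_id)]
  if (variant == "standard") sum(areas / dist[keep]^2)
  else sum(areas) / sum(dist[keep])^2
}

#' Coefficients of the community forest-dependency projection
#'
#' Quadratic relationship between projected community-averaged forest
#' dependency and patch area:
#' `cfd = b0 + b1 log10(area) + b2 (log10 area)^2`. The default slope and
#' curvature (0.35 and -0.04 per log10 ha) correspond to the fitted
#' dependency-area relationship the projection module is designed around;
#' the intercept defaults to 0 but is exposed because fitted regressions
#' carry one.
#'
#' @param b0,b1,b2 finite coefficients.
#' @return a `projection_coefficients` list.
#' @export
projectionCoefficients <- function(b0 = 0, b1 = 0.35, b2 = -0.04) {
  v <- c(b0 = b0, b1 = b1, b2 = b2)
  if (any(!is.finite(v))) stop("coefficients must be finite")
  structure(as.list(v), class = "projection_coefficients")
}

#' Project community forest dependency onto patches
#'
#' Applies the quadratic area relationship to every patch:
#' `cfd = b0 + b1 log10(area_ha) + b2 (log10 area_ha)^2`, and records its
#' sign. Monotone increasing in area up to the vertex at
#' `log10(area) = -b1 / (2 b2)`.
#'
#' @param ps a \linkS4class{PatchSet} with positive patch areas.
#' @param coeffs a [projectionCoefficients()].
#' @return the \linkS4class{PatchSet} with `cfd` and `cfd_sign` columns
#'   added to its table.
#' @export
projectCFD <- function(ps, coeffs = projectionCoefficients()) {
  tab <- ps@table
  if (nrow(tab) && any(tab$area_ha <= 0)) stop("non-positive patch area")
  la <- log10(tab$area_ha)
  tab$cfd <- coeffs$b0 + coeffs$b1 * la + coeffs$b2 * la^2
  tab$cfd_sign <- sign(tab$cfd)
  ps@table <- tab
  ps
}

#' Summarise a chronosequence of labelled patch sets
#'
#' Per-year patch counts, forest area, and the count and area fraction of
#' patches with negative projected community forest dependency. All values
#' are exact integer pixel arithmetic times the pixel area.
#'
#' @param psList list of \linkS4class{PatchSet} (one per year), each with
#'   projected `cfd` (see [projectCFD()]); pixel areas must agree.
#' @return data.frame with one row per year: `year`, `n_patches`,
#'   `n_negative_cfd`, `forest_area_ha`, `area_fraction_negative`.
#' @export
chronosequenceSummary <- function(psList) {
  if (!length(psList)) stop("at least one year is required")
  pa <- vapply(psList, function(p) p@pixelAreaHa, numeric(1))
  if (max(pa) - min(pa) > 1e-12)
    stop("inconsistent pixel areas across years")
  rows <- lapply(psList, function(p) {
    tab <- p@table
    if (nrow(tab) && !"cfd" %in% names(tab))
      stop("patch tables must carry projected cfd (run projectCFD first)")
    forest <- sum(tab$area_ha)
    neg <- if (nrow(tab)) tab$cfd < 0 else logical(0)
    data.frame(year = p@year,
               n_patches = nrow(tab),
               n_negative_cfd = sum(neg),
               forest_area_ha = forest,
               area_fraction_negative =
                 if (forest > 0) sum(tab$area_ha[neg]) / forest else 0)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Loss of high-dependency forest between two snapshots
#'
#' Fraction of the year-A forest belonging to patches with projected
#' community forest dependency above `threshold` that, by year B, is either
#' deforested or in a patch at or below the threshold. With
#' `denominator = "forest_a"` the fraction is relative to the
#' above-threshold forest area in year A (so complete deforestation gives
#' exactly 1); with `"forest_b"` it is relative to the total forest area
#' remaining in year B.
#'
#' @param psA,psB \linkS4class{PatchSet}s of equal grid extent with
#'   projected `cfd`.
#' @param threshold cfd threshold (default 0).
#' @param denominator `"forest_a"` or `"forest_b"`.
#' @return the fraction (numerator and denominator areas as attributes).
#' @export
transitionMetric <- function(psA, psB, threshold = 0,
                             denominator = c("forest_a", "forest_b")) {
  denominator <- match.arg(denominator)
  if (!identical(dim(psA@labels), dim(psB@labels)))
    stop("grids must have the same extent")
  pa <- psA@pixelAreaHa
  cfdPix <- function(ps) {
    m <- matrix(NA_real_, nrow(ps@labels), ncol(ps@labels))
    f <- ps@labels > 0
    m[f] <- ps@table$cfd[ps@labels[f]]
    m
  }
  ca <- cfdPix(psA); cb <- cfdPix(psB)
  qualA <- !is.na(ca) & ca > threshold
  lost <- qualA & (is.na(cb) | cb <= threshold)
  num <- sum(lost) * pa
  den <- switch(denominator,
                forest_a = sum(qualA) * pa,
                forest_b = sum(psB@labels > 0) * pa)
  if (den <= 0) stop("zero denominator area")
  structure(num / den, numerator_ha = num, denominator_ha = den)
}
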