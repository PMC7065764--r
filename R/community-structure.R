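#' Per-site species richness
#'
#' Number of species with positive standardized abundance at each site.
#'
#' @param x a \linkS4class{CommunityMatrix} or species x sites matrix.
#' @param ... unused.
#' @return named integer vector, one entry per site.
#' @rdname richness
#' @export
setMethod("richness", "CommunityMatrix", function(x, ...)
  richness(abundances(x)))

#' @rdname richness
#' @export
setMethod("richness", "matrix", function(x, ...) colSums(x > 0))

#' Per-site total standardized abundance
#'
#' Column sums of the community matrix, optionally log10-transformed.
#' Empty sites have total 0; with `log10transform = TRUE` they are
#' returned as `NA` (flagged via attribute `"undefined"`).
#'
#' @param x a \linkS4class{CommunityMatrix} or species x sites matrix.
#' @param log10transform apply log10 to the totals.
#' @param ... unused.
#' @return named numeric vector per site.
#' @rdname totalAbundance
#' @export
setMethod("totalAbundance", "CommunityMatrix",
          function(x, log10transform = FALSE, ...)
            totalAbundance(abundances(x), log10transform))

#' @rdname totalAbundance
#' @export
setMethod("totalAbundance", "matrix", function(x, log10transform = FALSE, ...) {
  if (any(x < 0)) stop("abundances must be non-negative")
  tot <- colSums(x)
  if (!log10transform) return(tot)
  out <- ifelse(tot > 0, log10(tot), NA_real_)
  names(out) <- colnames(x)
  if (any(tot == 0)) attr(out, "undefined") <- names(out)[tot == 0]
  out
})

#' Bray-Curtis dissimilarity between sites
#'
#' Quantitative compositional dissimilarity
#' `d_jk = sum_s |a_sj - a_sk| / sum_s (a_sj + a_sk)`, bounded in \[0, 1\]
#' and invariant to all-zero species. Pairs of two empty sites, for which
#' the ratio is undefined, are set to 0 and reported in attribute
#' `"empty_pairs"`.
#'
#' @param x a \linkS4class{CommunityMatrix} or species x sites matrix with
#'   non-negative values (at least two sites).
#' @param ... unused.
#' @return a `dist` object over sites.
#' @rdname brayCurtis
#' @export
setMethod("brayCurtis", "CommunityMatrix", function(x, ...)
  brayCurtis(abundances(x)))

#' @rdname brayCurtis
#' @export
setMethod("brayCurtis", "matrix", function(x, ...) {
  if (ncol(x) < 2) stop("at least two sites are required")
  if (any(x < 0)) stop("abundances must be non-negative")
  d <- suppressWarnings(vegan::vegdist(t(x), method = "bray"))
  if (anyNA(d)) {
    m <- as.matrix(d)
    empty <- colnames(x)[colSums(x) == 0]
    pairs <- which(is.na(m) & upper.tri(m), arr.ind = TRUE)
    attr(d, "empty_pairs") <- cbind(rownames(m)[pairs[, 1]],
                                    colnames(m)[pairs[, 2]])
    d[is.na(d)] <- 0
  }
  d
})

#' Principal coordinates analysis
#'
#' Metric ordination of a dissimilarity matrix by Gower double-centering
#' and symmetric eigendecomposition (via [stats::cmdscale()]). Coordinates
#' are returned for axes with positive eigenvalues, scaled by
#' `sqrt(eigenvalue)`, in decreasing eigenvalue order. No Cailliez/Lingoes
#' correction is applied; the summed magnitude of negative eigenvalues is
#' reported instead so metric distortion is visible. For reproducibility a
#' deterministic sign convention is applied: each axis is oriented so that
#' its largest-magnitude coordinate is positive (ties broken by site
#' order). On Euclidean input distances the embedding is exact.
#'
#' @param d a `dist` or symmetric zero-diagonal matrix of dissimilarities.
#' @return an \linkS4class{Ordination}; the first column of [scores()] is
#'   the dominant composition axis (PCoA1).
#' @export
pcoaOrdination <- function(d) {
  if (is.matrix(d)) {
    if (!isSymmetric(unname(d), tol = 1e-8))
      stop("dissimilarity matrix must be symmetric")
    d <- stats::as.dist(d)
  }
  n <- attr(d, "Size")
  ids <- attr(d, "Labels")
  if (is.null(ids)) ids <- as.character(seq_len(n))
  # k = n - 1 requested; cmdscale warns when trailing eigenvalues are not
  # positive, which is expected and handled below
  fit <- suppressWarnings(stats::cmdscale(d, k = n - 1, eig = TRUE))
  eig <- sort(fit$eig, decreasing = TRUE)
  pos <- fit$eig > max(fit$eig) * 1e-12 & fit$eig > 0
  pts <- fit$points
  # cmdscale may return fewer columns than requested when eigenvalues
  # vanish; keep only strictly positive axes
  keep <- seq_len(min(ncol(pts), sum(pos)))
  pts <- pts[, keep, drop = FALSE]
  for (j in seq_len(ncol(pts))) {
    i <- which.max(abs(pts[, j]))
    if (pts[i, j] < 0) pts[, j] <- -pts[, j]
  }
  dimnames(pts) <- list(ids, paste0("PCoA", seq_len(ncol(pts))))
  methods::new("Ordination", siteIDs = ids, coordinates = pts,
               eigenvalues = eig,
               negativeEigenvalueMass = sum(abs(eig[eig < 0])))
}
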