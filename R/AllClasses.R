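#' CommunityMatrix: effort-standardized site-by-species abundances
#'
#' A thin \linkS4class{SummarizedExperiment} subclass holding one assay,
#' \code{"abundance"}, with species as rows and survey sites as columns.
#' Values are capture rates standardized to a common effort unit (by default
#' captures per 1000 trap-nights, see [standardizeAbundance()]). Site
#' covariates live in \code{colData}, species annotation in \code{rowData};
#' the sampled stratum (\code{"forest"} or \code{"matrix"}) and the rate unit
#' are kept in \code{metadata}.
#'
#' @slot .. inherited from \code{SummarizedExperiment}.
#' @seealso [standardizeAbundance()], [richness()], [brayCurtis()],
#'   [communityFD()]
#' @export
setClass("CommunityMatrix", contains = "SummarizedExperiment")

setValidity("CommunityMatrix", function(object) {
  if (!"abundance" %in% SummarizedExperiment::assayNames(object))
    return("assay 'abundance' is required")
  a <- SummarizedExperiment::assay(object, "abundance")
  if (is.null(rownames(a)) || is.null(colnames(a)))
    return("species (row) and site (column) names are required")
  if (any(!is.finite(a)))
    return("abundances must be finite")
  if (any(a < 0))
    return("abundances must be non-negative")
  TRUE
})

#' Construct a CommunityMatrix
#'
#' @param abundance numeric matrix, species x sites, non-negative and finite,
#'   with dimnames.
#' @param siteData optional `DataFrame`/`data.frame` of per-site covariates
#'   (rows matched to columns of `abundance`).
#' @param speciesData optional per-species annotation.
#' @param stratum sampling stratum the rates refer to, `"forest"` or
#'   `"matrix"`.
#' @param rateUnit trap-night denominator of the rates (default 1000).
#' @return a \linkS4class{CommunityMatrix}.
#' @examples
#' a <- matrix(c(10, 0, 5, 20), 2, 2,
#'             dimnames = list(c("sp1", "sp2"), c("P1", "P2")))
#' CommunityMatrix(a)
#' @export
CommunityMatrix <- function(abundance, siteData = NULL, speciesData = NULL,
                            stratum = c("forest", "matrix"), rateUnit = 1000) {
  stratum <- match.arg(stratum)
  abundance <- as.matrix(abundance)
  if (is.null(siteData))
    siteData <- S4Vectors::DataFrame(row.names = colnames(abundance))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(abundance = abundance),
    colData = siteData)
  if (!is.null(speciesData))
    SummarizedExperiment::rowData(se) <- speciesData
  out <- methods::new("CommunityMatrix", se)
  S4Vectors::metadata(out)$stratum <- stratum
  S4Vectors::metadata(out)$rateUnit <- rateUnit
  methods::validObject(out)
  out
}

#' ForestGrid: a binary forest/non-forest raster snapshot
#'
#' @slot cells integer/numeric matrix of 0 (non-forest) and 1 (forest).
#' @slot pixelAreaHa area of one pixel in hectares.
#' @slot year label of the snapshot (free-form, e.g. "1985").
#' @seealso [labelPatches()], [generateChronosequence()]
#' @export
setClass("ForestGrid",
         representation(cells = "matrix", pixelAreaHa = "numeric",
                        year = "character"))

setValidity("ForestGrid", function(object) {
  if (!all(object@cells %in% c(0, 1)))
    return("grid cells must be 0/1")
  if (length(object@pixelAreaHa) != 1L || !is.finite(object@pixelAreaHa) ||
      object@pixelAreaHa <= 0)
    return("pixelAreaHa must be a single positive number")
  TRUE
})

#' Construct a ForestGrid
#'
#' @param cells 0/1 matrix (1 = forest).
#' @param pixelAreaHa pixel area in hectares (> 0).
#' @param year snapshot label.
#' @return a \linkS4class{ForestGrid}.
#' @export
ForestGrid <- function(cells, pixelAreaHa, year = "y0") {
  methods::new("ForestGrid", cells = as.matrix(cells),
               pixelAreaHa = as.numeric(pixelAreaHa),
               year = as.character(year))
}

#' PatchSet: delineated forest patches of one grid snapshot
#'
#' Produced by [labelPatches()]. Holds the integer label raster (0 =
#' non-forest, k = patch k) plus a per-patch table with pixel counts, areas
#' and centroids; [projectCFD()] adds projected community forest-dependency
#' columns.
#'
#' @slot labels integer matrix of patch labels.
#' @slot table data.frame with one row per patch.
#' @slot pixelAreaHa pixel area in hectares.
#' @slot year snapshot label.
#' @slot connectivity 4 or 8.
#' @export
setClass("PatchSet",
         representation(labels = "matrix", table = "data.frame",
                        pixelAreaHa = "numeric", year = "character",
                        connectivity = "integer"))

setValidity("PatchSet", function(object) {
  tab <- object@table
  need <- c("patch_id", "n_pixels", "area_ha")
  if (!all(need %in% names(tab)))
    return("patch table must have patch_id, n_pixels, area_ha")
  if (anyDuplicated(tab$patch_id))
    return("patch_ids must be unique")
  if (nrow(tab) &&
      max(abs(tab$area_ha - tab$n_pixels * object@pixelAreaHa)) > 1e-9)
    return("area_ha must equal n_pixels * pixelAreaHa")
  if (!object@connectivity %in% c(4L, 8L))
    return("connectivity must be 4 or 8")
  TRUE
})

#' Ordination: principal coordinates of a dissimilarity matrix
#'
#' @slot siteIDs site identifiers.
#' @slot coordinates sites x axes matrix (axes with positive eigenvalues).
#' @slot eigenvalues all eigenvalues, sorted decreasingly.
#' @slot negativeEigenvalueMass sum of absolute negative eigenvalues,
#'   a measure of how non-Euclidean the input dissimilarity is.
#' @seealso [pcoaOrdination()]
#' @export
setClass("Ordination",
         representation(siteIDs = "character", coordinates = "matrix",
                        eigenvalues = "numeric",
                        negativeEigenvalueMass = "numeric"))

setValidity("Ordination", function(object) {
  if (is.unsorted(rev(object@eigenvalues), strictly = FALSE))
    return("eigenvalues must be sorted decreasingly")
  if (ncol(object@coordinates) > length(object@siteIDs) - 1L)
    return("at most n - 1 axes are possible")
  TRUE
})

#' ModelFit: a single Gaussian GLM fit with information criteria
#'
#' @slot response response name.
#' @slot terms predictor terms (excluding the intercept).
#' @slot coefficients named coefficient vector (incl. `(Intercept)`).
#' @slot se coefficient standard errors.
#' @slot n number of observations.
#' @slot k parameter count (coefficients plus the residual variance).
#' @slot rss residual sum of squares.
#' @slot loglik Gaussian maximum log-likelihood.
#' @slot aic,aicc information criteria (`aicc` has the small-sample
#'   correction `2k(k+1)/(n-k-1)`).
#' @slot r2 coefficient of determination.
#' @slot fitted fitted values.
#' @seealso [fitGaussian()]
#' @export
setClass("ModelFit",
         representation(response = "character", terms = "character",
                        coefficients = "numeric", se = "numeric",
                        n = "integer", k = "integer", rss = "numeric",
                        loglik = "numeric", aic = "numeric", aicc = "numeric",
                        r2 = "numeric", fitted = "numeric"))

#' ModelSet: AICc-ranked collection of Gaussian GLM fits
#'
#' @slot fits list of \linkS4class{ModelFit}, sorted by AICc.
#' @slot table ranking table (model, k, aicc, delta, weight).
#' @slot meta bookkeeping (e.g. confidence-set threshold).
#' @seealso [allSubsets()], [confidenceSet()]
#' @export
setClass("ModelSet",
         representation(fits = "list", table = "data.frame", meta = "list"))

setValidity("ModelSet", function(object) {
  if (!nrow(object@table)) return("empty model set")
  w <- object@table$weight
  if (abs(sum(w) - 1) > 1e-8) return("weights must sum to 1")
  if (abs(object@table$delta[1]) > 1e-12)
    return("best model must have delta 0")
  TRUE
})

#' AveragedModel: confidence-set averaged coefficients
#'
#' Conditional (natural) model-averaged estimates with unconditional
#' standard errors, normal 95% confidence intervals and relative importance
#' (sum of renormalized Akaike weights of the models containing the term).
#'
#' @slot table data.frame with term, estimate, se, ci_lower, ci_upper, ri.
#' @slot nModels number of models averaged over.
#' @seealso [averageModel()]
#' @export
setClass("AveragedModel",
         representation(table = "data.frame", nModels = "integer"))
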