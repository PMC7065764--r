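#' Accessors for fragdep S4 containers
#'
#' Small, read-only accessors: `abundances()` returns the standardized
#' species x site rate matrix of a \linkS4class{CommunityMatrix};
#' `siteIDs()`/`speciesIDs()` its dimnames; `patchTable()`, `patchLabels()`
#' and `pixelArea()` expose a \linkS4class{PatchSet}; `gridCells()` the 0/1
#' matrix of a \linkS4class{ForestGrid}; `scores()` and `eigenvalues()` the
#' coordinates and spectrum of an \linkS4class{Ordination}; `modelTable()`,
#' `modelFits()` and `averagedTable()` the inference containers.
#'
#' @param x an object of the documented class.
#' @param ... unused.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setMethod("abundances", "CommunityMatrix", function(x, ...)
  SummarizedExperiment::assay(x, "abundance"))

#' @rdname accessors
#' @export
setMethod("siteIDs", "CommunityMatrix", function(x, ...) colnames(x))

#' @rdname accessors
#' @export
setMethod("speciesIDs", "CommunityMatrix", function(x, ...) rownames(x))

#' @rdname accessors
#' @export
setMethod("patchTable", "PatchSet", function(x, ...) x@table)

#' @rdname accessors
#' @export
setMethod("patchLabels", "PatchSet", function(x, ...) x@labels)

#' @rdname accessors
#' @export
setMethod("pixelArea", "PatchSet", function(x, ...) x@pixelAreaHa)

#' @rdname accessors
#' @export
setMethod("pixelArea", "ForestGrid", function(x, ...) x@pixelAreaHa)

#' @rdname accessors
#' @export
setMethod("gridCells", "ForestGrid", function(x, ...) x@cells)

#' @rdname accessors
#' @export
setMethod("scores", "Ordination", function(x, ...) x@coordinates)

#' @rdname accessors
#' @export
setMethod("eigenvalues", "Ordination", function(x, ...) x@eigenvalues)

#' @rdname accessors
#' @export
setMethod("siteIDs", "Ordination", function(x, ...) x@siteIDs)

#' @rdname accessors
#' @export
setMethod("modelTable", "ModelSet", function(x, ...) x@table)

#' @rdname accessors
#' @export
setMethod("modelFits", "ModelSet", function(x, ...) x@fits)

#' @rdname accessors
#' @export
setMethod("averagedTable", "AveragedModel", function(x, ...) x@table)

setMethod("show", "CommunityMatrix", function(object) {
  cat(sprintf("CommunityMatrix: %d species x %d sites (stratum: %s, per %g trap-nights)\n",
              nrow(object), ncol(object),
              S4Vectors::metadata(object)$stratum,
              S4Vectors::metadata(object)$rateUnit))
  if (ncol(SummarizedExperiment::colData(object)))
    cat("site covariates:",
        paste(colnames(SummarizedExperiment::colData(object)), collapse = ", "),
        "\n")
})

setMethod("show", "ForestGrid", function(object) {
  cat(sprintf("ForestGrid '%s': %d x %d pixels (%.4g ha each), forest fraction %.3f\n",
              object@year, nrow(object@cells), ncol(object@cells),
              object@pixelAreaHa, mean(object@cells)))
})

setMethod("show", "PatchSet", function(object) {
  cat(sprintf("PatchSet '%s': %d patches, %.4g ha forest (connectivity %d)\n",
              object@year, nrow(object@table),
              sum(object@table$area_ha), object@connectivity))
})

setMethod("show", "Ordination", function(object) {
  pos <- sum(object@eigenvalues > 0)
  cat(sprintf("Ordination: %d sites, %d positive axes, negative eigenvalue mass %.4g\n",
              length(object@siteIDs), pos, object@negativeEigenvalueMass))
})

setMethod("show", "ModelFit", function(object) {
  cat(sprintf("ModelFit [%s ~ %s]\n", object@response,
              if (length(object@terms)) paste(object@terms, collapse = " + ")
              else "1"))
  cat(sprintf("  n = %d, k = %d, AICc = %.3f, R2 = %.3f\n",
              object@n, object@k, object@aicc, object@r2))
})

setMethod("show", "ModelSet", function(object) {
  cat(sprintf("ModelSet: %d models, best = '%s'\n",
              nrow(object@table), object@table$model[1]))
  print(utils::head(object@table, 5))
  if (nrow(object@table) > 5) cat("  ...\n")
})

setMethod("show", "AveragedModel", function(object) {
  cat(sprintf("AveragedModel over %d models\n", object@nModels))
  print(object@table)
})
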