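#' @rdname accessors
#' @export
setGeneric("abundances", function(x, ...) standardGeneric("abundances"))

#' @rdname accessors
#' @export
setGeneric("siteIDs", function(x, ...) standardGeneric("siteIDs"))

#' @rdname accessors
#' @export
setGeneric("speciesIDs", function(x, ...) standardGeneric("speciesIDs"))

#' @rdname richness
#' @export
setGeneric("richness", function(x, ...) standardGeneric("richness"))

#' @rdname totalAbundance
#' @export
setGeneric("totalAbundance",
           function(x, log10transform = FALSE, ...)
             standardGeneric("totalAbundance"))

#' @rdname brayCurtis
#' @export
setGeneric("brayCurtis", function(x, ...) standardGeneric("brayCurtis"))

#' @rdname communityFD
#' @export
setGeneric("communityFD",
           function(x, profiles, ...) standardGeneric("communityFD"))

#' @rdname accessors
#' @export
setGeneric("patchTable", function(x, ...) standardGeneric("patchTable"))

#' @rdname accessors
#' @export
setGeneric("patchLabels", function(x, ...) standardGeneric("patchLabels"))

#' @rdname accessors
#' @export
setGeneric("gridCells", function(x, ...) standardGeneric("gridCells"))

#' @rdname accessors
#' @export
setGeneric("pixelArea", function(x, ...) standardGeneric("pixelArea"))

#' @rdname accessors
#' @export
setGeneric("scores", function(x, ...) standardGeneric("scores"))

#' @rdname accessors
#' @export
setGeneric("eigenvalues", function(x, ...) standardGeneric("eigenvalues"))

#' @rdname accessors
#' @export
setGeneric("modelTable", function(x, ...) standardGeneric("modelTable"))

#' @rdname accessors
#' @export
setGeneric("modelFits", function(x, ...) standardGeneric("modelFits"))

#' @rdname accessors
#' @export
setGeneric("averagedTable", function(x, ...) standardGeneric("averagedTable"))
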