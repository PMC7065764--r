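#' Read and write plain-text data exchanged by the workflow
#'
#' Capture, effort and site tables travel as UTF-8 comma-separated text
#' with a header row; binary forest grids as whitespace-separated 0/1
#' matrices. `readCaptures()`, `readEffort()` and `readSites()` validate
#' the required columns on the way in.
#'
#' @param path file path.
#' @param x object to write.
#' @name fragdep-io
NULL

.readChecked <- function(path, need) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop(sprintf("%s: missing column(s) %s", path,
                 paste(miss, collapse = ", ")))
  d
}

#' @rdname fragdep-io
#' @export
readCaptures <- function(path)
  .readChecked(path, c("site_id", "stratum", "species_id", "trap_class",
                       "count"))

#' @rdname fragdep-io
#' @export
readEffort <- function(path)
  .readChecked(path, c("site_id", "stratum", "trap_class", "trap_nights"))

#' @rdname fragdep-io
#' @export
readSites <- function(path)
  .readChecked(path, c("site_id", "site_type", "area_ha"))

#' @rdname fragdep-io
#' @export
writeTable <- function(x, path)
  utils::write.csv(x, path, row.names = FALSE, quote = FALSE)

#' @param pixelAreaHa pixel area in hectares for the grid being read.
#' @param year snapshot label.
#' @rdname fragdep-io
#' @export
readGridMatrix <- function(path, pixelAreaHa, year = "y0") {
  m <- as.matrix(utils::read.table(path, header = FALSE))
  dimnames(m) <- NULL
  ForestGrid(m, pixelAreaHa, year)
}

#' @param grid a \linkS4class{ForestGrid}.
#' @rdname fragdep-io
#' @export
writeGridMatrix <- function(grid, path) {
  stopifnot(methods::is(grid, "ForestGrid"))
  utils::write.table(grid@cells, path, row.names = FALSE,
                     col.names = FALSE)
}
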