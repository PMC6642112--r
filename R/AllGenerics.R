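#' @rdname accessors
#' @export
setGeneric("exprValues", function(x) standardGeneric("exprValues"))

#' @rdname accessors
#' @export
setGeneric("avgExpr", function(x) standardGeneric("avgExpr"))

#' @rdname accessors
#' @export
setGeneric("datasetId", function(x) standardGeneric("datasetId"))

#' @rdname accessors
#' @export
setGeneric("cellTypes", function(x) standardGeneric("cellTypes"))

#' @rdname accessors
#' @export
setGeneric("profileSpecies", function(x) standardGeneric("profileSpecies"))

#' @rdname accessors
#' @export
setGeneric("geneZ", function(x) standardGeneric("geneZ"))

#' @rdname accessors
#' @export
setGeneric("confounders", function(x) standardGeneric("confounders"))

#' @rdname accessors
#' @export
setGeneric("geneCorr", function(x) standardGeneric("geneCorr"))

#' @rdname accessors
#' @export
setGeneric("traitId", function(x) standardGeneric("traitId"))
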