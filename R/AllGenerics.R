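#' @rdname exprValues
#' @export
setGeneric("exprValues", function(x) standardGeneric("exprValues"))

#' @rdname traitData
#' @export
setGeneric("traitData", function(x) standardGeneric("traitData"))

#' @rdname moduleLabels
#' @export
setGeneric("moduleLabels", function(x) standardGeneric("moduleLabels"))

#' @rdname moduleGenes
#' @export
setGeneric("moduleGenes", function(x, module) standardGeneric("moduleGenes"))

#' @rdname moduleSizes
#' @export
setGeneric("moduleSizes", function(x) standardGeneric("moduleSizes"))

#' @rdname geneUniverse
#' @export
setGeneric("geneUniverse", function(x) standardGeneric("geneUniverse"))

#' @rdname unassignedGenes
#' @export
setGeneric("unassignedGenes", function(x) standardGeneric("unassignedGenes"))

#' @rdname conceptProfile
#' @export
setGeneric("conceptProfile", function(x, concept) standardGeneric("conceptProfile"))

#' @rdname conceptProfile
#' @export
setGeneric("hasProfile", function(x, concept) standardGeneric("hasProfile"))

#' @rdname annotationTable
#' @export
setGeneric("annotationTable", function(x) standardGeneric("annotationTable"))

#' @rdname annotationConcepts
#' @export
setGeneric("annotationConcepts",
           function(x, module, category) standardGeneric("annotationConcepts"))

#' @rdname significanceTable
#' @export
setGeneric("significanceTable", function(x) standardGeneric("significanceTable"))
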