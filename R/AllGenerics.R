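#' @title Generics defined by polysomeTE
#' @name polysomeTE-generics
#' @description Generic functions with methods for the classes of this
#'   package. See the individual methods for details.
#' @keywords internal
NULL

#' @export
setGeneric("relativeExpression", function(x, ...)
    standardGeneric("relativeExpression"))

#' @export
setGeneric("translationalEfficiency", function(x, ...)
    standardGeneric("translationalEfficiency"))

#' @export
setGeneric("sampleDesign", function(x) standardGeneric("sampleDesign"))

#' @export
setGeneric("expressionRange", function(x) standardGeneric("expressionRange"))

#' @export
setGeneric("cellLines", function(x) standardGeneric("cellLines"))

#' @export
setGeneric("treatments", function(x) standardGeneric("treatments"))

#' @export
setGeneric("perReplicateRE", function(x, ...) standardGeneric("perReplicateRE"))

#' @export
setGeneric("averagedRE", function(x, ...) standardGeneric("averagedRE"))

#' @export
setGeneric("transReg", function(x, ...) standardGeneric("transReg"))

#' @export
setGeneric("txnReg", function(x, ...) standardGeneric("txnReg"))

#' @export
setGeneric("geneSets", function(x) standardGeneric("geneSets"))

#' @export
setGeneric("setDescriptions", function(x) standardGeneric("setDescriptions"))
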