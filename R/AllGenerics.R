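#' @rdname LRDatabase-class
#' @param x,object an object of the documented class.
#' @export
setGeneric("pairIds", function(x) standardGeneric("pairIds"))

#' @rdname LRDatabase-class
#' @export
setGeneric("ligandSubunits", function(x) standardGeneric("ligandSubunits"))

#' @rdname LRDatabase-class
#' @export
setGeneric("receptorSubunits", function(x) standardGeneric("receptorSubunits"))

#' @rdname ExpressionProfile-class
#' @export
setGeneric("exprValues", function(x) standardGeneric("exprValues"))

#' @rdname ExpressionProfile-class
#' @export
setGeneric("conditionLabel", function(x) standardGeneric("conditionLabel"))

#' @rdname ExpressionProfile-class
#' @export
setGeneric("geneSymbols", function(x) standardGeneric("geneSymbols"))

#' @rdname DEGTable-class
#' @export
setGeneric("degStats", function(x) standardGeneric("degStats"))

#' @rdname CommunicationResult-class
#' @export
setGeneric("scoredPairs", function(x) standardGeneric("scoredPairs"))

#' @rdname CommunicationResult-class
#' @export
setGeneric("activePairs", function(x) standardGeneric("activePairs"))

#' @rdname CommunicationResult-class
#' @param k number of top-ranked active pairs to return; defaults to the
#'   `topK` of the configuration the result was computed with.
#' @export
setGeneric("topPairs", function(x, k = NULL) standardGeneric("topPairs"))

#' @rdname CommunicationResult-class
#' @export
setGeneric("provenance", function(x) standardGeneric("provenance"))
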