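#' @rdname ExpressionCohort
#' @param x an `ExpressionCohort`.
#' @export
setGeneric("datasetId", function(x) standardGeneric("datasetId"))

#' @rdname ExpressionCohort
#' @export
setGeneric("sampleGroups", function(x) standardGeneric("sampleGroups"))

#' @rdname ExpressionCohort
#' @export
setGeneric("exprValues", function(x) standardGeneric("exprValues"))

#' @rdname DegScreen-class
#' @param x a `DegScreen`.
#' @export
setGeneric("degTable", function(x) standardGeneric("degTable"))

#' @rdname DegScreen-class
#' @export
setGeneric("nSignificant", function(x) standardGeneric("nSignificant"))

#' @rdname DegScreen-class
#' @export
setGeneric("degDirections", function(x) standardGeneric("degDirections"))

#' @rdname ScoreTable-class
#' @param x a `ScoreTable`.
#' @export
setGeneric("cumulativeScore", function(x) standardGeneric("cumulativeScore"))

#' @rdname ScoreTable-class
#' @export
setGeneric("geneRanks", function(x) standardGeneric("geneRanks"))

#' @rdname ScoreTable-class
#' @export
setGeneric("pairScores", function(x) standardGeneric("pairScores"))
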