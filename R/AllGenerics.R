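#' @rdname labelMap
#' @export
setGeneric("labelMap", function(x) standardGeneric("labelMap"))

#' @rdname spots
#' @export
setGeneric("spots", function(x) standardGeneric("spots"))

#' @rdname nucleusTable
#' @export
setGeneric("nucleusTable", function(x) standardGeneric("nucleusTable"))

#' @rdname trueCounts
#' @export
setGeneric("trueCounts", function(x) standardGeneric("trueCounts"))

#' @rdname cellCounts
#' @export
setGeneric("cellCounts", function(x) standardGeneric("cellCounts"))

#' @rdname unassignedCounts
#' @export
setGeneric("unassignedCounts", function(x) standardGeneric("unassignedCounts"))

#' @rdname channelImage
#' @export
setGeneric("channelImage", function(x, channel) standardGeneric("channelImage"))

#' @rdname intakeTable
#' @export
setGeneric("intakeTable", function(x) standardGeneric("intakeTable"))

#' @rdname escalators
#' @export
setGeneric("escalators", function(x) standardGeneric("escalators"))
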