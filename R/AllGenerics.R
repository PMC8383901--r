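#' @rdname TimeGrid-class
#' @param x object
#' @export
setGeneric("boundaries", function(x) standardGeneric("boundaries"))

#' @rdname TimeGrid-class
#' @export
setGeneric("nBins", function(x) standardGeneric("nBins"))

#' @rdname TimeGrid-class
#' @export
setGeneric("tOut", function(x) standardGeneric("tOut"))

#' @rdname TimeGrid-class
#' @export
setGeneric("generationTime", function(x) standardGeneric("generationTime"))

#' @rdname PiecewiseRate-class
#' @param x object
#' @export
setGeneric("rates", function(x) standardGeneric("rates"))

#' @rdname TimeGrid-class
#' @export
setGeneric("timeGrid", function(x) standardGeneric("timeGrid"))

#' Mutation records of a table
#' @param x a [DatedMutationTable-class]
#' @return data.frame of mutation records
#' @export
setGeneric("mutations", function(x) standardGeneric("mutations"))

#' Per-epoch diploid effective population size
#'
#' The inverse coalescence rate, `1 / (2 * rate)`, interpretable as a
#' diploid effective population size when target and reference are drawn
#' from the same population.
#'
#' @param x a [CoalRateEstimate-class]
#' @return numeric vector, one value per epoch
#' @export
setGeneric("effectiveSize", function(x) standardGeneric("effectiveSize"))
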