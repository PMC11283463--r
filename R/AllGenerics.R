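#' @rdname ConcentrationEstimate-class
#' @param x an object.
#' @export
setGeneric("copiesPerUl", function(x) standardGeneric("copiesPerUl"))

#' @rdname ConcentrationEstimate-class
#' @export
setGeneric("lambdaHat", function(x) standardGeneric("lambdaHat"))

#' @rdname AbcRegion-class
#' @export
setGeneric("regionSequence", function(x) standardGeneric("regionSequence"))

#' @rdname AbcRegion-class
#' @export
setGeneric("cpgPositions", function(x) standardGeneric("cpgPositions"))

#' @rdname AbcRegion-class
#' @export
setGeneric("motifHits", function(x) standardGeneric("motifHits"))

#' @rdname ProbePanel-class
#' @export
setGeneric("probeTable", function(x) standardGeneric("probeTable"))

#' @rdname ProbePanel-class
#' @export
setGeneric("chamberVolume", function(x) standardGeneric("chamberVolume"))

#' @rdname ProbePanel-class
#' @export
setGeneric("referenceChannel", function(x) standardGeneric("referenceChannel"))

#' @rdname PartitionRun-class
#' @export
setGeneric("channelLabels", function(x) standardGeneric("channelLabels"))

#' @rdname ChannelCalls-class
#' @export
setGeneric("callsMatrix", function(x) standardGeneric("callsMatrix"))

#' @rdname ChannelCalls-class
#' @export
setGeneric("thresholds", function(x) standardGeneric("thresholds"))

#' @rdname IndelProfile-class
#' @export
setGeneric("profileTable", function(x) standardGeneric("profileTable"))

#' @rdname IndelProfile-class
#' @export
setGeneric("indelEvents", function(x) standardGeneric("indelEvents"))
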