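#' @rdname AbcRegion-class
setMethod("regionSequence", "AbcRegion", function(x) x@sequence)

#' @rdname AbcRegion-class
setMethod("cpgPositions", "AbcRegion", function(x) x@cpgPositions)

#' @rdname AbcRegion-class
setMethod("motifHits", "AbcRegion", function(x) x@motifHits)

#' @rdname ProbePanel-class
setMethod("channelLabels", "ProbePanel", function(x) x@probes$channel)

#' @rdname ProbePanel-class
setMethod("probeTable", "ProbePanel", function(x) x@probes)

#' @rdname ProbePanel-class
setMethod("chamberVolume", "ProbePanel", function(x) x@chamberVolume)

#' @rdname ProbePanel-class
setMethod("referenceChannel", "ProbePanel",
          function(x) x@probes$channel[x@probes$is_reference])

#' @rdname PartitionRun-class
setMethod("channelLabels", "PartitionRun", function(x) x@channelLabels)

#' @rdname ChannelCalls-class
setMethod("callsMatrix", "ChannelCalls", function(x) x@calls)

#' @rdname ChannelCalls-class
setMethod("thresholds", "ChannelCalls", function(x) x@thresholds)

#' @rdname ConcentrationEstimate-class
setMethod("copiesPerUl", "ConcentrationEstimate", function(x) x@copiesPerUl)

#' @rdname ConcentrationEstimate-class
setMethod("lambdaHat", "ConcentrationEstimate", function(x) x@lambdaHat)

#' @rdname IndelProfile-class
setMethod("indelEvents", "IndelProfile", function(x) x@events)

#' @rdname IndelProfile-class
setMethod("profileTable", "IndelProfile", function(x) {
  L <- length(x@region@sequence)
  depth <- x@depth
  saf <- function(cnt) ifelse(depth > 0L, cnt / depth, 0)
  data.frame(
    offset = seq_len(L) - 1L,
    position = x@region@start + seq_len(L) - 1L,
    ref_base = strsplit(as.character(x@region@sequence), "")[[1L]],
    depth = depth,
    del = x@deletionCount,
    ins = x@insertionCount,
    sub = x@substitutionCount,
    del_freq = saf(x@deletionCount),
    ins_freq = saf(x@insertionCount),
    sub_freq = saf(x@substitutionCount),
    artifact_flag = x@artifactFlags
  )
})

setMethod("show", "AbcRegion", function(object) {
  cat(sprintf("AbcRegion '%s' %s:%s-%s (%d nt)\n", object@name, object@chrom,
              format(object@start, big.mark = ","),
              format(object@end, big.mark = ","),
              length(object@sequence)))
  cat(sprintf("  CpG sites: %d | motif hits: %d\n",
              length(object@cpgPositions), nrow(object@motifHits)))
})

setMethod("show", "ProbePanel", function(object) {
  cat(sprintf("ProbePanel over '%s': %d probes (%s), reference = %s\n",
              object@region@name, nrow(object@probes),
              paste(object@probes$channel, collapse = ", "),
              referenceChannel(object)))
  cat(sprintf("  chamber volume: %.3g uL\n", object@chamberVolume))
})

setMethod("show", "PartitionRun", function(object) {
  cat(sprintf("PartitionRun '%s': %d chambers x %d channels (%s)\n",
              object@sampleId, nrow(object@fluorescence),
              ncol(object@fluorescence),
              paste(object@channelLabels, collapse = ", ")))
})

setMethod("show", "ChannelCalls", function(object) {
  pos <- colSums(object@calls)
  cat(sprintf("ChannelCalls (%s): %d chambers\n", object@method,
              nrow(object@calls)))
  for (ch in colnames(object@calls))
    cat(sprintf("  %s: %d positive (threshold %.4g)\n", ch, pos[[ch]],
                object@thresholds[[ch]]))
})

setMethod("show", "ConcentrationEstimate", function(object) {
  cat(sprintf("ConcentrationEstimate '%s': %.4g copies/uL [%.4g, %.4g] (%d%% CI)\n",
              object@target, object@copiesPerUl, object@ciLow, object@ciHigh,
              round(100 * object@ciLevel)))
  cat(sprintf("  lambda = %.6g from %d/%d negative chambers\n",
              object@lambdaHat, object@nNegative, object@nChambers))
})

setMethod("show", "IndelProfile", function(object) {
  cat(sprintf("IndelProfile over '%s' (%d nt)\n", object@region@name,
              length(object@region@sequence)))
  cat(sprintf("  events: %d del, %d ins, %d sub | max depth %d\n",
              sum(object@events$type == "del"),
              sum(object@events$type == "ins"),
              sum(object@events$type == "sub"),
              if (length(object@depth)) max(object@depth) else 0L))
})
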