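#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importClassesFrom S4Vectors DataFrame
#' @importClassesFrom Biostrings DNAString
NULL

setClassUnion("DNAStringOrNULL", c("DNAString", "NULL"))

#' AbcRegion: an AID break cluster target region
#'
#' Represents one AID break cluster (ABC) amplicon: its genomic location
#' (1-based inclusive coordinates as printed in genome browsers), its sequence,
#' the offsets of every CpG dinucleotide and the AID target-motif hits within
#' it. All offsets stored in the object are 0-based region-relative.
#'
#' @slot name region label, e.g. \code{"CRLF2_ABC"}.
#' @slot chrom chromosome label.
#' @slot start,end 1-based inclusive genomic coordinates.
#' @slot sequence a \link[Biostrings]{DNAString} of length \code{end - start + 1}.
#' @slot cpgPositions integer vector of 0-based offsets of the C of each CpG.
#' @slot motifHits a \link[S4Vectors]{DataFrame} with columns
#'   \code{motif_class}, \code{strand}, \code{offset}, \code{matched}.
#'
#' @seealso [AbcRegion()], [scanCpG()], [scanAidMotifs()]
#' @exportClass AbcRegion
setClass("AbcRegion",
  slots = c(
    name = "character",
    chrom = "character",
    start = "numeric",
    end = "numeric",
    sequence = "DNAString",
    cpgPositions = "integer",
    motifHits = "DataFrame"
  )
)

setValidity("AbcRegion", function(object) {
  msg <- character()
  L <- length(object@sequence)
  if (length(object@name) != 1L || !nzchar(object@name))
    msg <- c(msg, "'name' must be a single non-empty string")
  if (object@end < object@start)
    msg <- c(msg, "'end' must be >= 'start'")
  if (L != object@end - object@start + 1)
    msg <- c(msg, sprintf("sequence length (%d) != end - start + 1 (%d)",
                          L, object@end - object@start + 1))
  s <- as.character(object@sequence)
  if (grepl("[^ACGTN]", s))
    msg <- c(msg, "sequence may only contain A, C, G, T, N")
  cp <- object@cpgPositions
  if (length(cp)) {
    if (any(cp < 0L) || any(cp > L - 2L))
      msg <- c(msg, "cpgPositions out of range")
    else if (!all(substring(s, cp + 1L, cp + 2L) == "CG"))
      msg <- c(msg, "every cpgPosition must point at a CpG dinucleotide")
  }
  if (length(msg)) msg else TRUE
})

#' ProbePanel: drop-off probe geometry over an AbcRegion
#'
#' A multiplexed TaqMan panel: several drop-off probes placed over mutable
#' (CpG/AID-motif) sites plus exactly one reference probe placed where no AID
#' target has been mapped, each read out on its own optical channel. Probe
#' windows are stored 0-based half-open, region-relative.
#'
#' @slot region the [AbcRegion-class] the probes bind.
#' @slot probes a \link[S4Vectors]{DataFrame} with columns \code{probe},
#'   \code{channel}, \code{window_start}, \code{window_end} (0-based half-open)
#'   and \code{is_reference}.
#' @slot chamberVolume per-microchamber volume in microliters.
#'
#' @seealso [loadPanel()], [syntheticPanel()]
#' @exportClass ProbePanel
setClass("ProbePanel",
  slots = c(
    region = "AbcRegion",
    probes = "DataFrame",
    chamberVolume = "numeric"
  )
)

setValidity("ProbePanel", function(object) {
  msg <- character()
  pr <- object@probes
  need <- c("probe", "channel", "window_start", "window_end", "is_reference")
  if (!all(need %in% colnames(pr)))
    return(paste("probes must have columns:", paste(need, collapse = ", ")))
  if (anyDuplicated(pr$channel))
    msg <- c(msg, "channel labels must be unique")
  nref <- sum(pr$is_reference)
  if (nref != 1L)
    msg <- c(msg, sprintf("exactly one reference probe required (found %d)", nref))
  L <- length(object@region@sequence)
  if (any(pr$window_start < 0L) || any(pr$window_end > L) ||
      any(pr$window_end <= pr$window_start))
    msg <- c(msg, "probe windows must lie within the region (0-based half-open)")
  if (nref == 1L) {
    ref <- pr[pr$is_reference, , drop = FALSE]
    cp <- object@region@cpgPositions
    ## the reference probe must sit where no CpG can be scarred: neither base of
    ## any CpG may fall inside its window
    covered <- any(cp >= ref$window_start & cp < ref$window_end) ||
      any((cp + 1L) >= ref$window_start & (cp + 1L) < ref$window_end)
    if (covered)
      msg <- c(msg, "reference probe window overlaps a CpG site")
  }
  if (length(object@chamberVolume) != 1L || object@chamberVolume <= 0)
    msg <- c(msg, "chamberVolume must be a single positive number")
  if (length(msg)) msg else TRUE
})

#' MoleculeClass: one template species in a simulated reaction
#'
#' A molecule class is defined by which probe sites remain intact on the
#' template (mutation at a probe site prevents binding, so the corresponding
#' channel stays dark for that molecule) and by its pre-partition concentration.
#'
#' @slot label class label, e.g. \code{"WT"} or \code{"TAMRA_dropout"}.
#' @slot intactChannels channels whose probe sites are unmutated.
#' @slot concentration copies per microliter in the bulk reaction.
#'
#' @exportClass MoleculeClass
setClass("MoleculeClass",
  slots = c(label = "character", intactChannels = "character",
            concentration = "numeric")
)

setValidity("MoleculeClass", function(object) {
  msg <- character()
  if (length(object@concentration) != 1L || is.na(object@concentration) ||
      object@concentration < 0)
    msg <- c(msg, "concentration must be a single number >= 0")
  if (anyDuplicated(object@intactChannels))
    msg <- c(msg, "intactChannels must be unique")
  if (length(msg)) msg else TRUE
})

#' SimulationConfig: parameters of the synthetic partition run
#'
#' Everything needed to forward-simulate a digital PCR run: chamber count and
#' volume, the molecule classes loaded into the reaction, and a two-component
#' Gaussian fluorescence model per optical channel.
#'
#' @slot chamberCount number of microchambers (default 20000).
#' @slot chamberVolume microliters per chamber (default 4.5e-4, i.e. a 9 uL
#'   reaction split over 20,000 chambers).
#' @slot channels optical channel labels.
#' @slot classes list of [MoleculeClass-class] objects.
#' @slot fluorescence \link[S4Vectors]{DataFrame} with columns \code{channel},
#'   \code{neg_mean}, \code{neg_sd}, \code{pos_mean}, \code{pos_sd}.
#' @slot dropoutRate per-molecule probability that an occupying molecule fails
#'   to light its channels (default 0; occupancy is otherwise deterministic).
#' @slot seed integer seed.
#'
#' @seealso [simulationConfig()], [simulatePartitionRun()]
#' @exportClass SimulationConfig
setClass("SimulationConfig",
  slots = c(
    chamberCount = "integer",
    chamberVolume = "numeric",
    channels = "character",
    classes = "list",
    fluorescence = "DataFrame",
    dropoutRate = "numeric",
    seed = "integer"
  )
)

setValidity("SimulationConfig", function(object) {
  msg <- character()
  if (object@chamberCount < 1L)
    msg <- c(msg, "chamberCount must be >= 1")
  if (object@chamberVolume <= 0)
    msg <- c(msg, "chamberVolume must be > 0")
  if (!length(object@channels) || anyDuplicated(object@channels))
    msg <- c(msg, "channels must be non-empty and unique")
  for (cl in object@classes) {
    if (!is(cl, "MoleculeClass")) {
      msg <- c(msg, "classes must all be MoleculeClass objects")
      break
    }
    if (!all(cl@intactChannels %in% object@channels))
      msg <- c(msg, sprintf("class '%s' names channels outside the panel", cl@label))
  }
  fl <- object@fluorescence
  need <- c("channel", "neg_mean", "neg_sd", "pos_mean", "pos_sd")
  if (!all(need %in% colnames(fl))) {
    msg <- c(msg, paste("fluorescence must have columns:", paste(need, collapse = ", ")))
  } else {
    if (!setequal(fl$channel, object@channels))
      msg <- c(msg, "fluorescence rows must cover exactly the panel channels")
    if (any(fl$pos_mean <= fl$neg_mean))
      msg <- c(msg, "pos_mean must exceed neg_mean for every channel")
    if (any(fl$neg_sd <= 0) || any(fl$pos_sd <= 0))
      msg <- c(msg, "fluorescence sds must be > 0")
  }
  if (object@dropoutRate < 0 || object@dropoutRate > 1)
    msg <- c(msg, "dropoutRate must be in [0,1]")
  if (length(msg)) msg else TRUE
})

#' MutationModel: the AID mutation-scar placement model
#'
#' Per-molecule model of AID-derived scars: C-to-T substitutions (G-to-A on the
#' minus strand) at WRC/RCG/CpG contexts, and NHEJ-style indels whose placement
#' follows a CpG-proximity kernel: with probability \code{cpgKernel} the indel
#' midpoint lands within \code{cpgWindow} bp of a CpG, with exact-CpG positions
#' upweighted by \code{atCpgBias}.
#'
#' @slot substitutionRate per-molecule probability of one context substitution.
#' @slot indelRate per-molecule probability of one indel.
#' @slot cpgKernel probability that the indel midpoint falls within
#'   \code{cpgWindow} bp of a CpG (default 0.70).
#' @slot cpgWindow proximity window in bp (default 8).
#' @slot atCpgBias relative weight of placement exactly on a CpG base
#'   (default 1.3, i.e. 30\% upweighted).
#' @slot deletionFraction probability an indel is a deletion (default 0.8).
#' @slot lengthGeometricP geometric parameter for indel length (support 1, 2, ...).
#'
#' @seealso [mutationModel()], [simulateAmpliconReads()]
#' @exportClass MutationModel
setClass("MutationModel",
  slots = c(
    substitutionRate = "numeric",
    indelRate = "numeric",
    cpgKernel = "numeric",
    cpgWindow = "integer",
    atCpgBias = "numeric",
    deletionFraction = "numeric",
    lengthGeometricP = "numeric"
  )
)

setValidity("MutationModel", function(object) {
  p <- c(object@substitutionRate, object@indelRate, object@cpgKernel,
         object@deletionFraction)
  msg <- character()
  if (any(p < 0) || any(p > 1))
    msg <- c(msg, "rates and kernel probabilities must be in [0,1]")
  if (object@cpgWindow < 0L)
    msg <- c(msg, "cpgWindow must be >= 0")
  if (object@atCpgBias < 0)
    msg <- c(msg, "atCpgBias must be >= 0")
  if (object@lengthGeometricP <= 0 || object@lengthGeometricP > 1)
    msg <- c(msg, "lengthGeometricP must be in (0,1]")
  if (length(msg)) msg else TRUE
})

#' ReadSimConfig: amplicon read simulation parameters
#'
#' @slot readCount number of reads to simulate.
#' @slot readLength aligned read length; must not exceed the region length.
#' @slot errorRate per-base sequencing substitution error rate.
#' @slot artifactRange optional 0-based half-open offset range (length-2
#'   integer, or empty for none) where library-prep homopolymer artifacts fall.
#' @slot artifactRate per-read probability of one artifact indel in that range.
#' @slot seed integer seed.
#'
#' @seealso [readSimConfig()], [simulateAmpliconReads()]
#' @exportClass ReadSimConfig
setClass("ReadSimConfig",
  slots = c(
    readCount = "integer",
    readLength = "integer",
    errorRate = "numeric",
    artifactRange = "integer",
    artifactRate = "numeric",
    seed = "integer"
  )
)

setValidity("ReadSimConfig", function(object) {
  msg <- character()
  if (object@readCount < 0L) msg <- c(msg, "readCount must be >= 0")
  if (object@readLength < 1L) msg <- c(msg, "readLength must be >= 1")
  if (object@errorRate < 0 || object@errorRate > 1)
    msg <- c(msg, "errorRate must be in [0,1]")
  if (!length(object@artifactRange) %in% c(0L, 2L))
    msg <- c(msg, "artifactRange must be empty or length 2")
  if (length(object@artifactRange) == 2L &&
      object@artifactRange[2L] <= object@artifactRange[1L])
    msg <- c(msg, "artifactRange must be a half-open interval with end > start")
  if (object@artifactRate < 0 || object@artifactRate > 1)
    msg <- c(msg, "artifactRate must be in [0,1]")
  if (length(msg)) msg else TRUE
})

#' PartitionRun: one digital PCR run's chamber-level fluorescence
#'
#' @slot sampleId sample label.
#' @slot fluorescence numeric matrix, chambers x channels, column names are the
#'   channel labels.
#' @slot channelLabels channel labels (matches the matrix columns).
#'
#' @seealso [partitionRun()], [classifyChambers()]
#' @exportClass PartitionRun
setClass("PartitionRun",
  slots = c(sampleId = "character", fluorescence = "matrix",
            channelLabels = "character")
)

setValidity("PartitionRun", function(object) {
  msg <- character()
  fl <- object@fluorescence
  if (!is.numeric(fl)) msg <- c(msg, "fluorescence must be numeric")
  if (anyNA(fl)) msg <- c(msg, "fluorescence must have no missing values")
  if (nrow(fl) < 100L)
    msg <- c(msg, sprintf("need >= 100 chambers, got %d", nrow(fl)))
  if (!identical(colnames(fl), object@channelLabels))
    msg <- c(msg, "fluorescence column names must equal channelLabels")
  if (length(msg)) msg else TRUE
})

#' ChannelCalls: boolean positivity calls per chamber and channel
#'
#' @slot calls logical matrix, chambers x channels.
#' @slot thresholds named per-channel fluorescence cut values.
#' @slot method \code{"fixed"} or \code{"auto"}.
#'
#' @seealso [classifyChambers()], [patternTable()]
#' @exportClass ChannelCalls
setClass("ChannelCalls",
  slots = c(calls = "matrix", thresholds = "numeric", method = "character")
)

setValidity("ChannelCalls", function(object) {
  msg <- character()
  if (!is.logical(object@calls)) msg <- c(msg, "calls must be logical")
  if (is.null(colnames(object@calls)))
    msg <- c(msg, "calls must have channel column names")
  if (!identical(sort(names(object@thresholds)), sort(colnames(object@calls))))
    msg <- c(msg, "thresholds must be named by the call columns")
  if (!object@method %in% c("fixed", "auto"))
    msg <- c(msg, "method must be 'fixed' or 'auto'")
  if (length(msg)) msg else TRUE
})

#' ConcentrationEstimate: Poisson-inferred target concentration
#'
#' The digital PCR estimator: with \code{n} chambers of volume \code{V} and
#' \code{n_neg} negative for the target, the mean occupying copies per chamber
#' is \code{lambda = -log(n_neg / n)} and the bulk concentration is
#' \code{lambda / V} copies per microliter. The confidence interval is a Wilson
#' interval on the negative fraction mapped through the (monotone) inversion.
#'
#' @slot target channel/target label.
#' @slot lambdaHat mean occupying copies per chamber.
#' @slot copiesPerUl \code{lambdaHat / chamberVolume}.
#' @slot ciLow,ciHigh confidence bounds on copies per microliter.
#' @slot ciLevel nominal level.
#' @slot nChambers,nNegative chamber counts behind the estimate.
#'
#' @seealso [estimateConcentration()]
#' @exportClass ConcentrationEstimate
setClass("ConcentrationEstimate",
  slots = c(
    target = "character",
    lambdaHat = "numeric",
    copiesPerUl = "numeric",
    ciLow = "numeric",
    ciHigh = "numeric",
    ciLevel = "numeric",
    nChambers = "integer",
    nNegative = "integer"
  )
)

setValidity("ConcentrationEstimate", function(object) {
  msg <- character()
  if (object@nNegative > object@nChambers)
    msg <- c(msg, "nNegative cannot exceed nChambers")
  if (object@lambdaHat < 0 || object@copiesPerUl < 0)
    msg <- c(msg, "estimates must be >= 0")
  if (!(object@ciLow <= object@copiesPerUl + 1e-12 &&
        object@copiesPerUl <= object@ciHigh + 1e-12))
    msg <- c(msg, "CI must bracket the point estimate")
  if (length(msg)) msg else TRUE
})

#' IndelProfile: per-position mutation profile of an amplicon
#'
#' Per-reference-position depth and deletion/insertion/substitution counts over
#' an [AbcRegion-class], plus the event-level records (type, start, length)
#' recovered from the alignments and per-position homopolymer artifact flags.
#'
#' @slot region the profiled [AbcRegion-class].
#' @slot depth,deletionCount,insertionCount,substitutionCount integer vectors of
#'   the region length. Deleted positions count toward depth; insertions attach
#'   to the reference base to their left.
#' @slot events \link[S4Vectors]{DataFrame} with columns \code{type}
#'   (\code{del}/\code{ins}/\code{sub}), \code{start} (0-based offset),
#'   \code{length}.
#' @slot artifactFlags logical vector marking homopolymer-run positions.
#'
#' @seealso [profileFromAlignments()], [cpgProximitySummary()]
#' @exportClass IndelProfile
setClass("IndelProfile",
  slots = c(
    region = "AbcRegion",
    depth = "integer",
    deletionCount = "integer",
    insertionCount = "integer",
    substitutionCount = "integer",
    events = "DataFrame",
    artifactFlags = "logical"
  )
)

setValidity("IndelProfile", function(object) {
  L <- length(object@region@sequence)
  msg <- character()
  lens <- c(length(object@depth), length(object@deletionCount),
            length(object@insertionCount), length(object@substitutionCount),
            length(object@artifactFlags))
  if (!all(lens == L))
    msg <- c(msg, "per-position arrays must match the region length")
  else if (any(object@deletionCount > object@depth))
    msg <- c(msg, "deletionCount cannot exceed depth")
  if (length(msg)) msg else TRUE
})
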