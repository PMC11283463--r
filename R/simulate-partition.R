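#' @importFrom stats rpois rnorm rbinom kmeans qnorm pnorm sd rgeom runif
#'   t.test setNames
NULL

#' Construct a MoleculeClass
#'
#' @param label class label.
#' @param intactChannels channels whose probe sites are unmutated on this
#'   template (a wild-type class is intact on all channels).
#' @param concentration copies per microliter in the bulk reaction.
#' @return a [MoleculeClass-class].
#' @export
moleculeClass <- function(label, intactChannels, concentration) {
  new("MoleculeClass", label = label,
      intactChannels = as.character(intactChannels),
      concentration = as.numeric(concentration))
}

#' Default two-component fluorescence model
#'
#' One Gaussian pair per channel, in arbitrary fluorescence units: negatives at
#' mean 1 (sd 0.3), positives at mean 6 (sd 0.6). The wide separation mirrors
#' the clearly bimodal per-channel clouds seen on chamber scatterplots.
#'
#' @param channels channel labels.
#' @return a \link[S4Vectors]{DataFrame} usable as the \code{fluorescence}
#'   slot of a [SimulationConfig-class].
#' @export
fluorescenceDefaults <- function(channels) {
  DataFrame(channel = channels, neg_mean = 1.0, neg_sd = 0.3,
            pos_mean = 6.0, pos_sd = 0.6)
}

#' Construct a SimulationConfig
#'
#' Defaults follow the assay's operating scale: 20,000 microchambers of
#' 4.5e-4 uL each (a 9 uL reaction).
#'
#' @param classes list of [MoleculeClass-class] objects.
#' @param channels channel labels; defaults to the union of the classes'
#'   intact channels.
#' @param chamberCount number of chambers (default 20000).
#' @param chamberVolume uL per chamber (default 4.5e-4).
#' @param fluorescence per-channel fluorescence model (default
#'   [fluorescenceDefaults()]).
#' @param dropoutRate per-molecule amplification-failure probability
#'   (default 0).
#' @param seed integer seed.
#' @return a [SimulationConfig-class].
#' @export
simulationConfig <- function(classes,
                             channels = NULL,
                             chamberCount = 20000L,
                             chamberVolume = 4.5e-4,
                             fluorescence = NULL,
                             dropoutRate = 0,
                             seed = 1L) {
  if (is(classes, "MoleculeClass")) classes <- list(classes)
  if (is.null(channels))
    channels <- unique(unlist(lapply(classes, function(x) x@intactChannels)))
  if (is.null(fluorescence)) fluorescence <- fluorescenceDefaults(channels)
  new("SimulationConfig",
      chamberCount = as.integer(chamberCount),
      chamberVolume = as.numeric(chamberVolume),
      channels = as.character(channels),
      classes = classes,
      fluorescence = fluorescence,
      dropoutRate = as.numeric(dropoutRate),
      seed = as.integer(seed))
}

#' Construct a PartitionRun from a fluorescence matrix
#'
#' @param fluorescence numeric chambers x channels matrix with channel column
#'   names.
#' @param sampleId sample label.
#' @return a [PartitionRun-class].
#' @export
partitionRun <- function(fluorescence, sampleId = "sample") {
  new("PartitionRun", sampleId = sampleId,
      fluorescence = as.matrix(fluorescence),
      channelLabels = colnames(fluorescence))
}

## chamber x class molecule counts -> chamber x channel occupancy
occupancyFromCounts <- function(counts, classes, channels) {
  n <- nrow(counts)
  occ <- matrix(FALSE, n, length(channels), dimnames = list(NULL, channels))
  for (j in seq_along(classes)) {
    ch <- classes[[j]]@intactChannels
    if (!length(ch)) next
    present <- counts[, j] > 0L
    occ[, ch] <- occ[, ch] | present
  }
  occ
}

#' Simulate one digital PCR partition run
#'
#' Forward model of the Poisson partition assay: each chamber receives an
#' independent Poisson number of molecules of each class with mean
#' \code{concentration * chamberVolume}; a channel is occupied iff at least one
#' molecule of a class intact on that channel is present (less per-molecule
#' dropout, if configured); chamber fluorescence is drawn from the channel's
#' positive Gaussian component when occupied, else the negative component.
#'
#' @param config a [SimulationConfig-class].
#' @param sampleId sample label for the returned run.
#' @return a list with elements \code{run} (a [PartitionRun-class]),
#'   \code{truth} (list: per-chamber class-count matrix, occupancy matrix,
#'   class concentrations, chamber volume, seed).
#' @examples
#' cfg <- simulationConfig(list(
#'   moleculeClass("WT", c("SUN", "TAMRA"), 99),
#'   moleculeClass("mut", "SUN", 11)), chamberCount = 1000L, seed = 7L)
#' sim <- simulatePartitionRun(cfg)
#' colMeans(callsMatrix(classifyChambers(sim$run)))
#' @export
simulatePartitionRun <- function(config, sampleId = "sim") {
  validObject(config)
  withSeed(config@seed, {
    n <- config@chamberCount
    V <- config@chamberVolume
    classes <- config@classes
    channels <- config@channels
    counts <- vapply(classes, function(cl) rpois(n, cl@concentration * V),
                     integer(n))
    counts <- matrix(counts, nrow = n,
                     dimnames = list(NULL, vapply(classes, slot, character(1L),
                                                  "label")))
    eff <- counts
    if (config@dropoutRate > 0) {
      for (j in seq_len(ncol(eff)))
        eff[, j] <- rbinom(n, counts[, j], 1 - config@dropoutRate)
    }
    occ <- occupancyFromCounts(eff, classes, channels)
    fl <- config@fluorescence
    fmat <- matrix(0, n, length(channels), dimnames = list(NULL, channels))
    for (ch in channels) {
      i <- match(ch, fl$channel)
      fmat[, ch] <- ifelse(occ[, ch],
                           rnorm(n, fl$pos_mean[i], fl$pos_sd[i]),
                           rnorm(n, fl$neg_mean[i], fl$neg_sd[i]))
    }
    truth <- list(
      classCounts = counts,
      occupancy = occ,
      concentrations = setNames(vapply(classes, slot, numeric(1L),
                                       "concentration"),
                                colnames(counts)),
      chamberVolume = V,
      seed = config@seed
    )
    list(run = partitionRun(fmat, sampleId), truth = truth)
  })
}

#' Simulate occupancy calls only (no fluorescence layer)
#'
#' Fast path for estimator studies: draws the same Poisson occupancy model as
#' [simulatePartitionRun()] but returns a [ChannelCalls-class] directly,
#' skipping the fluorescence mixture and classification.
#'
#' @inheritParams simulatePartitionRun
#' @return a list with \code{calls} (a [ChannelCalls-class]) and \code{truth}.
#' @export
simulateCalls <- function(config) {
  validObject(config)
  withSeed(config@seed, {
    n <- config@chamberCount
    V <- config@chamberVolume
    classes <- config@classes
    counts <- vapply(classes, function(cl) rpois(n, cl@concentration * V),
                     integer(n))
    counts <- matrix(counts, nrow = n,
                     dimnames = list(NULL, vapply(classes, slot, character(1L),
                                                  "label")))
    occ <- occupancyFromCounts(counts, classes, config@channels)
    calls <- new("ChannelCalls", calls = occ,
                 thresholds = setNames(rep(NA_real_, length(config@channels)),
                                       config@channels),
                 method = "fixed")
    ## thresholds are not meaningful for truth occupancy; store 0s
    calls@thresholds[] <- 0
    truth <- list(classCounts = counts, occupancy = occ,
                  concentrations = setNames(vapply(classes, slot, numeric(1L),
                                                   "concentration"),
                                            colnames(counts)),
                  chamberVolume = V, seed = config@seed)
    list(calls = calls, truth = truth)
  })
}

#' Write / read a chamber table
#'
#' Chamber tables are the interchange format between the simulator and the
#' quantifier: CSV with a \code{chamber_id} column and one fluorescence column
#' per channel. The truth record, when given, is written as a JSON sidecar
#' (same path with extension \code{.truth.json}) holding the class
#' concentrations, chamber volume, seed and per-channel truth-positive counts.
#'
#' @param run a [PartitionRun-class].
#' @param path output CSV path.
#' @param truth optional truth record from [simulatePartitionRun()].
#' @return the path, invisibly.
#' @export
writeRun <- function(run, path, truth = NULL) {
  df <- data.frame(chamber_id = seq_len(nrow(run@fluorescence)))
  ## %.17g guarantees doubles survive the text round trip bit-exactly
  for (ch in run@channelLabels) df[[ch]] <- sprintf("%.17g", run@fluorescence[, ch])
  ok <- try(utils::write.csv(df, path, row.names = FALSE, quote = FALSE),
            silent = TRUE)
  if (inherits(ok, "try-error"))
    abcIOError(paste("cannot write chamber table:", path))
  if (!is.null(truth)) {
    side <- list(
      sample_id = run@sampleId,
      concentrations = as.list(truth$concentrations),
      chamber_volume = truth$chamberVolume,
      seed = truth$seed,
      truth_positive = as.list(colSums(truth$occupancy))
    )
    jsonlite::write_json(side, sub("\\.csv$", ".truth.json", path),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' @rdname writeRun
#' @param sampleId sample label for the read-back run.
#' @export
readRun <- function(path, sampleId = NULL) {
  if (!file.exists(path))
    abcIOError(paste("chamber table not found:", path))
  df <- utils::read.csv(path, check.names = FALSE)
  if (!"chamber_id" %in% colnames(df))
    abcValidationError("chamber table must have a 'chamber_id' column")
  channels <- setdiff(colnames(df), "chamber_id")
  m <- as.matrix(df[, channels, drop = FALSE])
  if (is.null(sampleId))
    sampleId <- sub("\\.csv$", "", basename(path))
  partitionRun(m, sampleId)
}
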