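#' Classify chambers as positive/negative per channel
#'
#' With explicit \code{thresholds}, a chamber is positive on a channel when its
#' fluorescence is at or above the channel's threshold. Without thresholds,
#' each channel is auto-thresholded at the midpoint between the two cluster
#' centers of a one-dimensional two-cluster split (k-means with deterministic
#' extreme-quantile initialisation) of that channel's values. A channel whose
#' two cluster centers are closer than twice the pooled (quadrature-combined)
#' within-cluster standard deviation is considered unimodal and raises a
#' no-separation error naming the channel.
#'
#' @param run a [PartitionRun-class].
#' @param thresholds optional named per-channel cut values (one per channel).
#' @return a [ChannelCalls-class].
#' @export
classifyChambers <- function(run, thresholds = NULL) {
  validObject(run)
  fl <- run@fluorescence
  channels <- run@channelLabels
  if (!is.null(thresholds)) {
    if (is.null(names(thresholds)))
      names(thresholds) <- channels
    if (!setequal(names(thresholds), channels) ||
        length(thresholds) != length(channels))
      abcValidationError("need exactly one threshold per channel")
    thr <- thresholds[channels]
    method <- "fixed"
  } else {
    thr <- vapply(channels, function(ch) autoThreshold(fl[, ch], ch),
                  numeric(1L))
    method <- "auto"
  }
  calls <- sweep(fl, 2L, thr[channels], `>=`)
  storage.mode(calls) <- "logical"
  new("ChannelCalls", calls = calls, thresholds = thr, method = method)
}

## 1-D two-cluster split; returns the midpoint of the two centers
autoThreshold <- function(x, channel) {
  init <- stats::quantile(x, c(0.01, 0.99), names = FALSE)
  if (diff(init) < sqrt(.Machine$double.eps))
    abcNoSeparationError(sprintf("channel '%s': constant fluorescence", channel),
                         channel = channel)
  km <- kmeans(x, centers = matrix(init, ncol = 1L))
  centers <- sort(as.numeric(km$centers))
  ## cluster sds pooled in quadrature: a single Gaussian cloud splits into
  ## halves whose centers sit ~1.6 sd apart, under this 2x bound, while two
  ## genuinely separated fluorescence clusters clear it by a wide margin
  clusterSd <- sqrt(km$withinss / pmax(km$size, 1L))
  pooledSd <- sqrt(sum(clusterSd^2))
  if (diff(centers) < 2 * pooledSd)
    abcNoSeparationError(
      sprintf("channel '%s': no separation between clusters (centers %.3g, %.3g; pooled sd %.3g)",
              channel, centers[1L], centers[2L], pooledSd),
      channel = channel)
  mean(centers)
}

#' Tabulate chamber positivity patterns
#'
#' Counts chambers over all \code{2^K} channel positivity patterns. Patterns
#' are keyed by the sorted \code{+}-joined subset of positive channel labels
#' (the all-negative pattern is keyed \code{""}), and every pattern appears
#' even when its count is zero.
#'
#' @param calls a [ChannelCalls-class] with at most 8 channels.
#' @return a data.frame with columns \code{pattern} and \code{count}; counts
#'   sum to the chamber count.
#' @export
patternTable <- function(calls) {
  m <- calls@calls
  K <- ncol(m)
  if (K > 8L)
    abcValidationError("patternTable supports at most 8 channels")
  channels <- colnames(m)
  keyOf <- function(bits) {
    on <- sort(channels[bits])
    paste(on, collapse = "+")
  }
  allKeys <- vapply(0:(2^K - 1L), function(i)
    keyOf(bitwAnd(i, 2^(seq_len(K) - 1L)) > 0L), character(1L))
  codes <- as.integer(m %*% 2^(seq_len(K) - 1L))
  tab <- tabulate(codes + 1L, nbins = 2^K)
  data.frame(pattern = allKeys, count = tab, stringsAsFactors = FALSE)
}
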