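## Poisson partition inference: lambda = -ln(negative fraction), concentration
## = lambda / chamber volume. Intervals are Wilson on the negative fraction,
## mapped through the monotone inversion; differences use the delta method on
## the correlated negative fractions; the joint estimator inverts the channel-
## subset negativity lattice (Moebius inversion).

wilsonInterval <- function(x, n, level) {
  z <- qnorm(1 - (1 - level) / 2)
  p <- x / n
  denom <- 1 + z^2 / n
  center <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  c(low = max(0, center - half), high = min(1, center + half))
}

## saturation guard: spec'd dynamic-range floor on the negative fraction
SATURATION_FLOOR <- 0.005

#' Estimate a target concentration from chamber calls
#'
#' Computes \code{lambda = -log(n_negative / n)} occupying copies per chamber
#' and \code{lambda / chamberVolume} copies per microliter, with a Wilson
#' confidence interval on the negative fraction mapped through the inversion
#' (monotone, so the endpoints map directly; the upper bound on the negative
#' fraction gives the lower concentration bound).
#'
#' Runs with fewer than 0.5\% negative chambers on the channel are out of the
#' assay's dynamic range and raise a saturation error; a fully saturated
#' channel (\code{n_negative == 0}) reports the detectable lower bound in the
#' error. A fully negative channel returns a zero estimate with a one-sided
#' upper bound.
#'
#' @param calls a [ChannelCalls-class].
#' @param channel channel label to estimate.
#' @param chamberVolume microliters per chamber.
#' @param ciLevel nominal confidence level (default 0.95).
#' @return a [ConcentrationEstimate-class].
#' @examples
#' m <- matrix(rep(c(TRUE, FALSE), c(6321, 3679)), ncol = 1,
#'             dimnames = list(NULL, "FAM"))
#' cc <- new("ChannelCalls", calls = m, thresholds = c(FAM = 0), method = "fixed")
#' estimateConcentration(cc, "FAM", 4.5e-4)  # ~2222 copies/uL
#' @export
estimateConcentration <- function(calls, channel, chamberVolume,
                                  ciLevel = 0.95) {
  m <- calls@calls
  if (!channel %in% colnames(m))
    abcValidationError(sprintf("channel '%s' not present in calls", channel))
  n <- nrow(m)
  nNeg <- sum(!m[, channel])
  if (nNeg == 0L)
    abcSaturationError(sprintf(
      "channel '%s' saturated: all %d chambers positive; concentration exceeds ~%.4g copies/uL",
      channel, n, log(n) / chamberVolume), channel = channel)
  if (nNeg / n < SATURATION_FLOOR)
    abcSaturationError(sprintf(
      "channel '%s' out of dynamic range: %.2f%% positive chambers",
      channel, 100 * (1 - nNeg / n)), channel = channel)
  lam <- -log(nNeg / n)
  wi <- wilsonInterval(nNeg, n, ciLevel)
  ## x == n: the upper Wilson bound is exactly 1 analytically; guard rounding
  ciLow <- if (nNeg == n) 0 else -log(wi[["high"]]) / chamberVolume
  ciHigh <- if (wi[["low"]] > 0) -log(wi[["low"]]) / chamberVolume else Inf
  new("ConcentrationEstimate", target = channel, lambdaHat = lam,
      copiesPerUl = lam / chamberVolume,
      ciLow = max(0, ciLow), ciHigh = ciHigh, ciLevel = ciLevel,
      nChambers = as.integer(n), nNegative = as.integer(nNeg))
}

## delta-method variance pieces for -log of a negative fraction
lambdaVar <- function(p, n) (1 - p) / (n * p)

#' Estimate per-probe drop-off concentrations
#'
#' A drop-off product is an amplicon on which a probe can no longer bind
#' (mutation or repair scarring at its site) while the reference probe still
#' detects the amplicon.
#'
#' \strong{difference} (default): drop-off(P) = concentration(reference) -
#' concentration(P), per-channel marginal Poisson estimates with a delta-method
#' confidence interval that accounts for the correlation of the two negative
#' fractions through their observed joint counts.
#'
#' \strong{joint}: models every channel subset T as a molecule class intact
#' exactly on T. Chamber negativity on a channel set S has probability
#' \code{exp(-Lambda_S V)} where \code{Lambda_S} sums the classes intact on at
#' least one channel of S, so \code{Lambda_S = -log(f_neg_S) / V} for every
#' subset, and class concentrations follow by Moebius inversion over the
#' subset lattice. drop-off(P) sums the classes not intact on P but intact on
#' the reference; intervals are delta-method on the multinomial pattern
#' frequencies. Any required all-negative fraction of zero raises a
#' saturated-pattern error naming the subset; a class estimate below
#' \code{-tol} attaches an \code{inconsistent-pattern} flag.
#'
#' @param calls a [ChannelCalls-class]; its channels must cover the panel's.
#' @param panel a [ProbePanel-class].
#' @param method \code{"difference"} or \code{"joint"}.
#' @param ciLevel nominal confidence level.
#' @param tol negativity tolerance for flagging inconsistent joint estimates.
#' @return a \link[S4Vectors]{DataFrame} with one row per non-reference probe:
#'   \code{probe}, \code{channel}, \code{method}, \code{copies_per_ul},
#'   \code{ci_low}, \code{ci_high}, \code{dropoff_fraction} (relative to the
#'   reference concentration) and \code{flags}. Negative point estimates are
#'   reported as-is with a \code{negative-estimate} flag, never clamped.
#'   Metadata carries the reference channel and its estimate.
#' @export
estimateDropoff <- function(calls, panel, method = c("difference", "joint"),
                            ciLevel = 0.95, tol = 1e-8) {
  method <- match.arg(method)
  m <- calls@calls
  channels <- channelLabels(panel)
  if (!all(channels %in% colnames(m)))
    abcValidationError("calls do not cover all panel channels")
  pr <- panel@probes
  ref <- referenceChannel(panel)
  V <- panel@chamberVolume
  n <- nrow(m)
  z <- qnorm(1 - (1 - ciLevel) / 2)
  targets <- pr[!pr$is_reference, , drop = FALSE]

  if (method == "difference") {
    estRef <- estimateConcentration(calls, ref, V, ciLevel)
    rows <- lapply(seq_len(nrow(targets)), function(i) {
      ch <- targets$channel[i]
      estT <- estimateConcentration(calls, ch, V, ciLevel)
      pR <- estRef@nNegative / n
      pT <- estT@nNegative / n
      pBoth <- sum(!m[, ref] & !m[, ch]) / n
      covP <- (pBoth - pR * pT) / n
      covLam <- covP / (pR * pT)
      varD <- lambdaVar(pR, n) + lambdaVar(pT, n) - 2 * covLam
      seD <- sqrt(max(0, varD)) / V
      d <- estRef@copiesPerUl - estT@copiesPerUl
      flags <- character(0)
      if (d < 0) flags <- "negative-estimate"
      DataFrame(probe = targets$probe[i], channel = ch, method = method,
                copies_per_ul = d, ci_low = d - z * seD, ci_high = d + z * seD,
                dropoff_fraction = d / estRef@copiesPerUl,
                flags = paste(flags, collapse = ";"))
    })
    out <- do.call(rbind, rows)
    metadata(out) <- list(reference = ref, reference_estimate = estRef,
                          ci_level = ciLevel)
    return(out)
  }

  ## joint: Moebius inversion over the channel-subset lattice
  jt <- jointClassEstimates(m, channels, n, tol = tol)
  refBit <- 2^(match(ref, channels) - 1L)
  lamRef <- -log(sum(!m[, ref]) / n)
  rows <- lapply(seq_len(nrow(targets)), function(i) {
    ch <- targets$channel[i]
    chBit <- 2^(match(ch, channels) - 1L)
    sel <- bitwAnd(jt$subset, refBit) > 0L & bitwAnd(jt$subset, chBit) == 0L
    lamD <- sum(jt$c[sel])
    w <- as.numeric(sel)
    varD <- drop(t(w) %*% jt$covC %*% w)
    seD <- sqrt(max(0, varD)) / V
    d <- lamD / V
    flags <- character(0)
    if (d < 0) flags <- c(flags, "negative-estimate")
    if (jt$inconsistent) flags <- c(flags, "inconsistent-pattern")
    DataFrame(probe = targets$probe[i], channel = ch, method = method,
              copies_per_ul = d, ci_low = d - z * seD, ci_high = d + z * seD,
              dropoff_fraction = d / (lamRef / V),
              flags = paste(flags, collapse = ";"))
  })
  out <- do.call(rbind, rows)
  metadata(out) <- list(reference = ref, ci_level = ciLevel,
                        class_estimates = jt$classTable(V))
  out
}

## Core of the joint estimator. Subsets are bitmasks over `channels`;
## returns class estimates in lambda (per-chamber) units plus their
## delta-method covariance.
jointClassEstimates <- function(m, channels, n, tol = 1e-8) {
  K <- length(channels)
  if (K > 8L)
    abcValidationError("joint estimator supports at most 8 channels")
  nSub <- 2^K
  full <- nSub - 1L
  bits <- 2^(seq_len(K) - 1L)
  codes <- as.integer(m[, channels, drop = FALSE] %*% bits)
  counts <- tabulate(codes + 1L, nbins = nSub)   # pattern counts, index q+1
  piHat <- counts / n
  ## f[S+1] = fraction of chambers negative on every channel of S
  f <- vapply(0:full, function(S)
    sum(piHat[bitwAnd(0:full, S) == 0L]), numeric(1L))
  zero <- which(f == 0) - 1L
  if (length(zero)) {
    S <- zero[1L]
    lab <- paste(channels[bitwAnd(S, bits) > 0L], collapse = "+")
    abcSaturationError(
      sprintf("saturated pattern: no chamber negative on {%s}", lab),
      subset = lab)
  }
  Lam <- -log(f)                                  # Lam[1] = 0 (empty set)
  G <- Lam[full + 1L] - Lam[bitwXor(0:full, full) + 1L]  # G[U+1]
  popcount <- vapply(0:full, function(x) sum(bitwAnd(x, bits) > 0L), numeric(1L))
  ## Moebius inversion: c_T = sum_{U subset T} (-1)^{|T|-|U|} G(U)
  cHat <- numeric(nSub)
  A <- matrix(0, nSub, nSub)                      # dc/dLambda
  for (T in 1:full) {
    U <- which(bitwAnd(0:full, T) == (0:full)) - 1L  # all U subset T (incl. empty)
    sgn <- (-1)^(popcount[T + 1L] - popcount[U + 1L])
    cHat[T + 1L] <- sum(sgn * G[U + 1L])
    ## G(U) = Lam(full) - Lam(comp U)
    A[T + 1L, full + 1L] <- A[T + 1L, full + 1L] + sum(sgn)
    comp <- bitwXor(U, full)
    for (k in seq_along(U))
      A[T + 1L, comp[k] + 1L] <- A[T + 1L, comp[k] + 1L] - sgn[k]
  }
  ## J = dLambda/dpi: J[S, q] = -1{q cap S = 0} / f_S  (row S = empty is 0)
  J <- matrix(0, nSub, nSub)
  for (S in 1:full)
    J[S + 1L, ] <- -(bitwAnd(0:full, S) == 0L) / f[S + 1L]
  SigmaPi <- (diag(piHat) - tcrossprod(piHat)) / n
  covC <- A %*% J %*% SigmaPi %*% t(J) %*% t(A)
  inconsistent <- any(cHat[-1L] < -tol)
  list(
    subset = 0:full, c = cHat, covC = covC, inconsistent = inconsistent,
    classTable = function(V) {
      nonEmpty <- 1:full
      DataFrame(
        intact = vapply(nonEmpty, function(S)
          paste(channels[bitwAnd(S, bits) > 0L], collapse = "+"),
          character(1L)),
        copies_per_ul = cHat[nonEmpty + 1L] / V
      )
    }
  )
}
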