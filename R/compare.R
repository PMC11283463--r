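## Group comparison of drop-off estimates, following the reporting conventions
## of the assay's figures: group means +/- SEM, Welch two-sample tests, and a
## Dunnett-style many-to-one comparison of each drop-off probe against the
## reference probe with a multiplicity-adjusted p-value.

welchParts <- function(x, y) {
  vx <- stats::var(x) / length(x)
  vy <- stats::var(y) / length(y)
  se <- sqrt(vx + vy)
  t <- (mean(x) - mean(y)) / se
  df <- se^4 / (vx^2 / (length(x) - 1) + vy^2 / (length(y) - 1))
  list(t = t, df = df, se = se, p = 2 * stats::pt(-abs(t), df))
}

## Monte Carlo Dunnett adjustment: given observed statistics t_obs and the
## correlation matrix of the contrasts (induced by the shared reference
## group), p_adj_j = P(max_i |Z_i| >= |t_obs_j|) under Z ~ N(0, R).
## Seeded so reports are reproducible; falls back to Bonferroni when R is not
## positive definite.
dunnettAdjust <- function(tObs, R, mcSamples = 50000L, mcSeed = 20240901L) {
  k <- length(tObs)
  if (k == 1L) return(2 * pnorm(-abs(tObs)))
  ch <- try(chol(R), silent = TRUE)
  if (inherits(ch, "try-error"))
    return(pmin(1, k * 2 * pnorm(-abs(tObs))))
  withSeed(mcSeed, {
    Z <- matrix(rnorm(mcSamples * k), mcSamples, k) %*% ch
    maxAbs <- apply(abs(Z), 1L, max)
    vapply(abs(tObs), function(t0) mean(maxAbs >= t0), numeric(1L))
  })
}

#' Compare drop-off estimates between groups or probes
#'
#' \strong{two_sample}: per probe, a Welch two-sample location test on the
#' per-replicate copies/uL of the two groups.
#'
#' \strong{vs_reference_multi}: each non-reference probe is compared with the
#' reference probe (Welch contrasts) and p-values are multiplicity-adjusted by
#' a seeded Monte Carlo Dunnett procedure over the max-|Z| distribution of the
#' correlated contrasts (Bonferroni fallback on degenerate correlation).
#'
#' Groups or probes with a single replicate yield descriptive output only,
#' flagged \code{no-test}.
#'
#' @param data a data.frame with columns \code{probe}, \code{value}
#'   (copies/uL per replicate) and, for \code{two_sample}, \code{group}.
#' @param design \code{"two_sample"} or \code{"vs_reference_multi"}.
#' @param referenceProbe reference probe label (required for
#'   \code{vs_reference_multi}).
#' @param mcSamples,mcSeed Monte Carlo settings for the Dunnett adjustment.
#' @return a data.frame report: per comparison the group/probe means with SEM
#'   (the figure-legend convention), the mean difference, Welch statistic and
#'   degrees of freedom, and raw plus (where applicable) adjusted p-values.
#' @export
compareGroups <- function(data, design = c("two_sample", "vs_reference_multi"),
                          referenceProbe = NULL, mcSamples = 50000L,
                          mcSeed = 20240901L) {
  design <- match.arg(design)
  if (!all(c("probe", "value") %in% colnames(data)))
    abcValidationError("data needs 'probe' and 'value' columns")
  sem <- function(x) if (length(x) > 1L) sd(x) / sqrt(length(x)) else NA_real_

  if (design == "two_sample") {
    if (!"group" %in% colnames(data))
      abcValidationError("two_sample design needs a 'group' column")
    groups <- unique(data$group)
    if (length(groups) != 2L)
      abcValidationError("two_sample design needs exactly two groups")
    rows <- lapply(unique(data$probe), function(pb) {
      x <- data$value[data$probe == pb & data$group == groups[1L]]
      y <- data$value[data$probe == pb & data$group == groups[2L]]
      base <- data.frame(probe = pb, group1 = groups[1L], group2 = groups[2L],
                         n1 = length(x), n2 = length(y),
                         mean1 = mean(x), sem1 = sem(x),
                         mean2 = mean(y), sem2 = sem(y),
                         diff = mean(x) - mean(y))
      if (length(x) < 2L || length(y) < 2L) {
        cbind(base, t = NA_real_, df = NA_real_, p_value = NA_real_,
              flags = "no-test")
      } else {
        w <- welchParts(x, y)
        cbind(base, t = w$t, df = w$df, p_value = w$p, flags = "")
      }
    })
    return(do.call(rbind, rows))
  }

  if (is.null(referenceProbe))
    abcValidationError("vs_reference_multi design needs 'referenceProbe'")
  if (!referenceProbe %in% data$probe)
    abcValidationError(sprintf("reference probe '%s' absent from data",
                               referenceProbe))
  refVals <- data$value[data$probe == referenceProbe]
  others <- setdiff(unique(data$probe), referenceProbe)
  stats <- lapply(others, function(pb) {
    x <- data$value[data$probe == pb]
    list(probe = pb, x = x,
         ok = length(x) >= 2L && length(refVals) >= 2L)
  })
  vRef <- if (length(refVals) > 1L) stats::var(refVals) / length(refVals)
          else NA_real_
  testable <- vapply(stats, `[[`, logical(1L), "ok")
  tObs <- df <- pRaw <- rep(NA_real_, length(stats))
  v <- rep(NA_real_, length(stats))
  for (i in seq_along(stats)) {
    if (!testable[i]) next
    w <- welchParts(stats[[i]]$x, refVals)
    tObs[i] <- w$t; df[i] <- w$df; pRaw[i] <- w$p
    v[i] <- stats::var(stats[[i]]$x) / length(stats[[i]]$x)
  }
  pAdj <- rep(NA_real_, length(stats))
  if (any(testable)) {
    idx <- which(testable)
    R <- outer(idx, idx, function(i, j)
      vRef / sqrt((v[i] + vRef) * (v[j] + vRef)))
    diag(R) <- 1
    pAdj[idx] <- dunnettAdjust(tObs[idx], R, mcSamples, mcSeed)
  }
  out <- do.call(rbind, lapply(seq_along(stats), function(i) {
    x <- stats[[i]]$x
    data.frame(probe = stats[[i]]$probe, reference = referenceProbe,
               n = length(x), mean = mean(x), sem = sem(x),
               ref_mean = mean(refVals), ref_sem = sem(refVals),
               diff = mean(x) - mean(refVals),
               t = tObs[i], df = df[i], p_value = pRaw[i],
               p_adjusted = pAdj[i],
               flags = if (testable[i]) "" else "no-test")
  }))
  out
}
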