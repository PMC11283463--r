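panel <- fixturePanel()
channels <- channelLabels(panel)
V <- chamberVolume(panel)

mkCalls <- function(m) {
  new("ChannelCalls", calls = m,
      thresholds = setNames(rep(0, ncol(m)), colnames(m)), method = "fixed")
}

test_that("fixed-threshold classification is the literal comparison", {
  fl <- matrix(0, 120L, 2L, dimnames = list(NULL, c("FAM", "SUN")))
  run <- partitionRun(fl)
  calls <- classifyChambers(run, thresholds = c(FAM = 1, SUN = 1))
  expect_false(any(callsMatrix(calls)))
  expect_identical(calls@method, "fixed")
  fl[5L, "FAM"] <- 2
  calls2 <- classifyChambers(partitionRun(fl), thresholds = c(FAM = 1, SUN = 1))
  expect_identical(which(callsMatrix(calls2)[, "FAM"]), 5L)
})

test_that("auto thresholds agree with truth occupancy and with fixed reuse", {
  cfg <- fixtureSimConfig(panel, seed = 61L)
  sim <- simulatePartitionRun(cfg)
  auto <- classifyChambers(sim$run)
  expect_identical(auto@method, "auto")
  agreement <- mean(callsMatrix(auto) == sim$truth$occupancy)
  expect_gte(agreement, 0.99)
  ## feeding the auto thresholds back as fixed reproduces the calls exactly
  fixed <- classifyChambers(sim$run, thresholds = thresholds(auto))
  expect_identical(callsMatrix(fixed), callsMatrix(auto))
})

test_that("unseparable channels raise a no-separation error naming the channel", {
  fl <- matrix(1, 200L, 2L, dimnames = list(NULL, c("FAM", "SUN")))
  fl[, "SUN"] <- rnorm(200L, 1, 0.3)
  expect_error(classifyChambers(partitionRun(fl)), "FAM")
  ## a single Gaussian cloud (e.g. an all-positive channel) is unimodal
  set.seed(67)
  fl2 <- cbind(FAM = rnorm(200, 6, 0.6),
               SUN = c(rnorm(150, 1, 0.3), rnorm(50, 6, 0.6)))
  err <- tryCatch(classifyChambers(partitionRun(fl2)), condition = identity)
  expect_s3_class(err, "abcNoSeparationError")
  expect_match(conditionMessage(err), "FAM")
})

test_that("pattern table enumerates all subsets and conserves counts", {
  m <- matrix(FALSE, 10L, 2L, dimnames = list(NULL, c("FAM", "SUN")))
  tab <- patternTable(mkCalls(m))
  expect_setequal(tab$pattern, c("", "FAM", "SUN", "FAM+SUN"))
  expect_identical(tab$count[tab$pattern == ""], 10L)
  expect_identical(sum(tab$count), 10L)

  ## hand-built 6-chamber matrix tallied manually
  m6 <- rbind(c(TRUE, TRUE), c(TRUE, FALSE), c(FALSE, TRUE),
              c(TRUE, TRUE), c(FALSE, FALSE), c(TRUE, TRUE))
  colnames(m6) <- c("TAMRA", "SUN")
  tab6 <- patternTable(mkCalls(m6))
  expect_identical(tab6$count[match(c("", "TAMRA", "SUN", "SUN+TAMRA"),
                                    tab6$pattern)],
                   c(1L, 1L, 1L, 3L))
  ## marginals recomputed from the table equal the call column sums
  for (ch in colnames(m6)) {
    inPattern <- vapply(strsplit(tab6$pattern, "\\+"), function(x) ch %in% x,
                        logical(1L))
    expect_identical(sum(tab6$count[inPattern]), sum(m6[, ch]))
  }
})

test_that("concentration estimation matches the closed-form inversion", {
  m <- matrix(rep(c(TRUE, FALSE), c(10000L - 3679L, 3679L)), ncol = 1L,
              dimnames = list(NULL, "FAM"))
  est <- estimateConcentration(mkCalls(m), "FAM", 4.5e-4)
  expect_equal(lambdaHat(est), -log(0.3679), tolerance = 1e-12)
  expect_equal(copiesPerUl(est), -log(0.3679) / 4.5e-4, tolerance = 1e-12)
  expect_equal(copiesPerUl(est), 2222, tolerance = 1e-3)
  expect_lte(est@ciLow, copiesPerUl(est))
  expect_gte(est@ciHigh, copiesPerUl(est))
})

test_that("all-negative and saturated channels hit their documented edges", {
  mNeg <- matrix(FALSE, 20000L, 1L, dimnames = list(NULL, "FAM"))
  est <- estimateConcentration(mkCalls(mNeg), "FAM", 4.5e-4)
  expect_identical(copiesPerUl(est), 0)
  expect_identical(est@ciLow, 0)
  expect_gt(est@ciHigh, 0)

  mPos <- matrix(TRUE, 1000L, 1L, dimnames = list(NULL, "FAM"))
  err <- tryCatch(estimateConcentration(mkCalls(mPos), "FAM", 4.5e-4),
                  condition = identity)
  expect_s3_class(err, "abcSaturationError")
  expect_match(conditionMessage(err), "saturated")

  mAlmost <- matrix(rep(c(TRUE, FALSE), c(999L, 1L)), ncol = 1L,
                    dimnames = list(NULL, "FAM"))
  expect_error(estimateConcentration(mkCalls(mAlmost), "FAM", 4.5e-4),
               "dynamic range")
})

test_that("Poisson inversion equals an independent computation on random calls", {
  set.seed(71)
  for (i in 1:50) {
    n <- sample(200:2000, 1L)
    p <- runif(1L, 0.1, 0.9)
    m <- matrix(runif(n) > p, ncol = 1L, dimnames = list(NULL, "X"))
    nNeg <- sum(!m[, 1L])
    if (nNeg == 0L || nNeg / n < 0.005) next
    est <- estimateConcentration(mkCalls(m), "X", 4.5e-4)
    expect_identical(copiesPerUl(est), -log(nNeg / n) / 4.5e-4)
  }
})

test_that("wild-type-only runs give near-zero drop-off on every probe", {
  cfg <- fixtureSimConfig(panel, wt = 110, mutant = 0, seed = 73L)
  sim <- simulateCalls(cfg)
  for (method in c("difference", "joint")) {
    est <- estimateDropoff(sim$calls, panel, method = method)
    z <- qnorm(0.975)
    for (i in seq_len(nrow(est))) {
      se <- (est$ci_high[i] - est$ci_low[i]) / (2 * z)
      expect_lte(abs(est$copies_per_ul[i]), 3 * se)
    }
  }
})

test_that("both estimators recover a known mutant concentration", {
  ## 11 copies/uL TAMRA-dropped among 110 total, replicated runs
  nrep <- 60L
  ests <- vapply(seq_len(nrep), function(i) {
    sim <- simulateCalls(fixtureSimConfig(panel, seed = 100L + i))
    d <- estimateDropoff(sim$calls, panel, method = "difference")
    j <- estimateDropoff(sim$calls, panel, method = "joint")
    c(d$copies_per_ul[d$channel == "TAMRA"],
      j$copies_per_ul[j$channel == "TAMRA"])
  }, numeric(2L))
  for (k in 1:2) {
    se <- sd(ests[k, ]) / sqrt(nrep)
    expect_lt(abs(mean(ests[k, ]) - 11), 3 * se)
  }
})

test_that("difference and joint estimates agree within combined uncertainty", {
  z <- qnorm(0.975)
  for (i in 1:10) {
    sim <- simulateCalls(fixtureSimConfig(panel, seed = 200L + i))
    d <- estimateDropoff(sim$calls, panel, method = "difference")
    j <- estimateDropoff(sim$calls, panel, method = "joint")
    for (ch in d$channel) {
      di <- d[d$channel == ch, ]; ji <- j[j$channel == ch, ]
      seD <- (di$ci_high - di$ci_low) / (2 * z)
      seJ <- (ji$ci_high - ji$ci_low) / (2 * z)
      expect_lt(abs(di$copies_per_ul - ji$copies_per_ul),
                3 * sqrt(seD^2 + seJ^2) + 1e-9)
    }
  }
})

test_that("joint class estimates satisfy the total-concentration identity", {
  sim <- simulateCalls(fixtureSimConfig(panel, seed = 79L))
  m <- callsMatrix(sim$calls)
  jt <- abcdPCR:::jointClassEstimates(m, channels, nrow(m))
  totalLambda <- -log(mean(rowSums(m) == 0L))
  expect_equal(sum(jt$c), totalLambda, tolerance = 1e-12)
})

test_that("K=2 joint estimator matches a brute-force likelihood fit", {
  ## saturated two-channel model: multinomial MLE over the three class
  ## intensities must coincide with the Moebius inversion
  ch2 <- c("SUN", "TAMRA")
  set.seed(83)
  for (i in 1:5) {
    lam <- runif(3L, 0.01, 0.4)  # {SUN}, {TAMRA}, {SUN,TAMRA}
    n <- 5000L
    pS <- exp(-(lam[1L] + lam[3L]))   # SUN negative
    pT <- exp(-(lam[2L] + lam[3L]))   # TAMRA negative
    p00 <- exp(-sum(lam))
    probs <- c(p00, pT - p00, pS - p00, 1 - pS - pT + p00)
    cnt <- as.integer(stats::rmultinom(1L, n, probs))
    m <- rbind(
      matrix(FALSE, cnt[1L], 2L),
      matrix(rep(c(TRUE, FALSE), times = c(1L, 1L)), cnt[2L], 2L, byrow = TRUE),
      matrix(rep(c(FALSE, TRUE), times = c(1L, 1L)), cnt[3L], 2L, byrow = TRUE),
      matrix(TRUE, cnt[4L], 2L))
    colnames(m) <- ch2
    jt <- abcdPCR:::jointClassEstimates(m, ch2, n)
    negLL <- function(logLam) {
      l <- exp(logLam)
      pS <- exp(-(l[1L] + l[3L])); pT <- exp(-(l[2L] + l[3L]))
      p00 <- exp(-sum(l))
      pr <- c(p00, pT - p00, pS - p00, 1 - pS - pT + p00)
      if (any(pr <= 0)) return(1e10)
      -sum(cnt * log(pr))
    }
    fit <- optim(log(pmax(jt$c[2:4] * c(1.3, 0.7, 1.1), 1e-4)), negLL,
                 method = "BFGS",
                 control = list(maxit = 5000L, reltol = 1e-15))
    ## subset bitmasks: 1 = {SUN}, 2 = {TAMRA}, 3 = both
    expect_equal(exp(fit$par), unname(jt$c[2:4]), tolerance = 1e-6)
  }
})

test_that("fully positive patterns raise a saturated-pattern error in joint mode", {
  m <- matrix(TRUE, 200L, 4L, dimnames = list(NULL, channels))
  m[, "TAMRA"] <- FALSE
  err <- tryCatch(estimateDropoff(mkCalls(m), panel, method = "joint"),
                  condition = identity)
  expect_s3_class(err, "abcSaturationError")
  expect_match(conditionMessage(err), "saturated pattern")
})

test_that("raising the true mutant concentration raises the expected estimate", {
  grid <- c(2, 5, 11, 20, 40)
  nrep <- 60L
  means <- vapply(seq_along(grid), function(g) {
    ests <- vapply(seq_len(nrep), function(i) {
      cfg <- fixtureSimConfig(panel, wt = 110 - grid[g], mutant = grid[g],
                              seed = 1000L * g + i)
      est <- estimateDropoff(simulateCalls(cfg)$calls, panel)
      est$copies_per_ul[est$channel == "TAMRA"]
    }, numeric(1L))
    mean(ests)
  }, numeric(1L))
  expect_true(all(diff(means) > 0))
})

test_that("the difference estimator is nearly unbiased at the assay scale", {
  nrep <- 300L
  ests <- vapply(seq_len(nrep), function(i) {
    sim <- simulateCalls(fixtureSimConfig(panel, seed = 5000L + i))
    est <- estimateDropoff(sim$calls, panel)
    est$copies_per_ul[est$channel == "TAMRA"]
  }, numeric(1L))
  expect_lt(abs(mean(ests) - 11), 0.05 * 11)
})

test_that("negative drop-off point estimates are flagged, not clamped", {
  ## target channel with *more* positives than the reference
  set.seed(89)
  m <- matrix(FALSE, 5000L, 4L, dimnames = list(NULL, channels))
  m[1:400, "SUN"] <- TRUE
  m[1:500, "TAMRA"] <- TRUE
  m[1:400, "FAM"] <- TRUE
  m[1:400, "Cy5"] <- TRUE
  est <- estimateDropoff(mkCalls(m), panel)
  row <- est[est$channel == "TAMRA", ]
  expect_lt(row$copies_per_ul, 0)
  expect_match(row$flags, "negative-estimate")
})
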