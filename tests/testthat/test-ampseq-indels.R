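region <- fixtureRegion()
L <- length(regionSequence(region))

## minimal alignment-record builder for hand-crafted CIGAR cases
mkAln <- function(pos, cigar, seq, mapq = 60L, qual = NULL) {
  if (is.null(qual)) qual <- strrep("I", nchar(seq))
  data.frame(rname = region@name, pos = pos, cigar = cigar, seq = seq,
             qual = qual, mapq = mapq)
}

refSub <- function(from, to) {  # 0-based half-open slice of the region
  substring(as.character(regionSequence(region)), from + 1L, to)
}

test_that("a 10M2D10M read counts deletions over the spanned positions", {
  seq <- paste0(refSub(0, 10), refSub(12, 22))
  prof <- profileFromAlignments(mkAln(1L, "10M2D10M", seq), region)
  expect_identical(which(prof@deletionCount == 1L), 11:12)  # offsets 10, 11
  expect_identical(which(prof@depth == 1L), 1:22)           # offsets 0..21
  expect_identical(sum(prof@insertionCount), 0L)
  expect_identical(sum(prof@substitutionCount), 0L)
})

test_that("a 5M3I5M read attaches its insertion to the left flanking base", {
  seq <- paste0(refSub(0, 5), "AAA", refSub(5, 10))
  prof <- profileFromAlignments(mkAln(1L, "5M3I5M", seq), region)
  expect_identical(which(prof@insertionCount == 1L), 5L)    # offset 4
  expect_identical(sum(prof@insertionCount), 1L)
  expect_identical(which(prof@depth == 1L), 1:10)
})

test_that("substitutions honour the base-quality floor", {
  seq <- refSub(0, 10)
  flip <- if (substring(seq, 3L, 3L) == "A") "C" else "A"
  substring(seq, 3L, 3L) <- flip
  lowq <- paste0("II", rawToChar(as.raw(33L + 10L)), strrep("I", 7L))
  profLow <- profileFromAlignments(mkAln(1L, "10M", seq, qual = lowq), region)
  expect_identical(sum(profLow@substitutionCount), 0L)
  profHigh <- profileFromAlignments(mkAln(1L, "10M", seq), region)
  expect_identical(which(profHigh@substitutionCount == 1L), 3L)
})

test_that("mapping-quality and reference-name filters apply", {
  aln <- mkAln(1L, "10M", refSub(0, 10), mapq = 5L)
  prof <- profileFromAlignments(aln, region, minMapq = 20L)
  expect_identical(sum(prof@depth), 0L)
  bad <- aln; bad$rname <- "other_region"
  expect_error(profileFromAlignments(bad, region), "do not match region")
})

test_that("empty input warns and returns an all-zero profile", {
  expect_warning(prof <- profileFromAlignments(mkAln(1L, "1M", "A")[0, ],
                                               region),
                 "no alignments")
  expect_identical(sum(prof@depth), 0L)
  expect_identical(nrow(indelEvents(prof)), 0L)
})

test_that("profiles equal generator truth tables exactly on simulated reads", {
  mm <- mutationModel(substitutionRate = 0.15, indelRate = 0.4,
                      deletionFraction = 0.7)
  rc <- readSimConfig(readCount = 1000L, errorRate = 0.002, seed = 101L)
  sim <- simulateAmpliconReads(region, mm, rc)
  prof <- profileFromAlignments(sim$reads, region)
  want <- tallyTruth(sim$truth, L)
  expect_identical(prof@deletionCount, want$del)
  expect_identical(prof@insertionCount, want$ins)
  expect_identical(prof@substitutionCount, want$sub)
  expect_true(all(prof@depth == 1000L))
  ## conservation: per-position deletion mass equals summed deleted bases
  expect_identical(sum(prof@deletionCount),
                   sum(sim$truth$length[sim$truth$type == "del"]))
})

test_that("the profile goes through SAM parsing unchanged and ignores read order", {
  mm <- mutationModel(indelRate = 0.5)
  rc <- readSimConfig(readCount = 200L, seed = 103L)
  sim <- simulateAmpliconReads(region, mm, rc)
  sam <- withr::local_tempfile(fileext = ".sam")
  writeReads(sim, region, sam)
  profSam <- profileFromAlignments(sam, region)
  profDf <- profileFromAlignments(sim$reads, region)
  shuffled <- sim$reads[sample(nrow(sim$reads)), ]
  profShuf <- profileFromAlignments(shuffled, region)
  for (slotName in c("depth", "deletionCount", "insertionCount",
                     "substitutionCount")) {
    expect_identical(slot(profSam, slotName), slot(profDf, slotName))
    expect_identical(slot(profShuf, slotName), slot(profDf, slotName))
  }
})

test_that("homopolymer flagging matches the stated examples and a brute oracle", {
  expect_identical(flagHomopolymers("AAAAAC"),
                   c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE))
  expect_identical(flagHomopolymers("ACGTACGT"), rep(FALSE, 8L))
  set.seed(107)
  for (i in 1:100) {
    s <- paste0(randomSequence(sample(10:200, 1L)),
                strrep(sample(c("A", "T"), 1L), sample(0:8, 1L)),
                randomSequence(sample(5:50, 1L)))
    expect_identical(flagHomopolymers(s), bruteHomopolymerFlags(s))
    expect_identical(flagHomopolymers(s, minRun = 3L),
                     bruteHomopolymerFlags(s, minRun = 3L))
  }
})

test_that("CpG proximity summary handles point cases and empty profiles", {
  cp1 <- cpgPositions(region)[1L]
  aln <- mkAln(cp1, paste0(cp1, "M1D", 10L, "M"),
               paste0(refSub(cp1 - 1L, cp1), refSub(cp1 + 1L, cp1 + 11L)))
  ## the single deletion sits exactly on the CpG C (offset cp1)
  prof <- profileFromAlignments(mkAln(1L, paste0(cp1, "M1D", 5L, "M"),
                                      paste0(refSub(0, cp1),
                                             refSub(cp1 + 1L, cp1 + 6L))),
                                region)
  summ <- cpgProximitySummary(prof)
  expect_identical(summ$n_indels, 1L)
  expect_equal(summ$frac_at_cpg, 1.0)
  expect_equal(summ$frac_within_window, 1.0)

  expect_warning(empty <- profileFromAlignments(mkAln(1L, "1M", "A")[0, ],
                                                region))
  se <- cpgProximitySummary(empty)
  expect_identical(se$n_indels, 0L)
  expect_true(is.na(se$frac_within_window))
  expect_error(cpgProximitySummary(prof, window = -1L), "window")
})

test_that("simulated profiles reproduce the configured proximity kernel", {
  mm <- mutationModel(substitutionRate = 0, indelRate = 1, cpgKernel = 0.70)
  rc <- readSimConfig(readCount = 3000L, errorRate = 0, seed = 109L)
  sim <- simulateAmpliconReads(region, mm, rc)
  prof <- profileFromAlignments(sim$reads, region)
  summ <- cpgProximitySummary(prof)
  se <- sqrt(0.7 * 0.3 / summ$n_indels)
  expect_lt(abs(summ$frac_within_window - 0.70), 3 * se)
})

test_that("artifact exclusion restores the kernel that artifacts distort", {
  ## artifacts land only in the leading homopolymer A-run (offsets 9..14),
  ## far from any CpG, so they drag the proximity fraction down
  mm <- mutationModel(substitutionRate = 0, indelRate = 0.5, cpgKernel = 0.70)
  rc <- readSimConfig(readCount = 4000L, errorRate = 0,
                      artifactRange = c(9L, 15L), artifactRate = 0.5,
                      seed = 113L)
  sim <- simulateAmpliconReads(region, mm, rc)
  prof <- profileFromAlignments(sim$reads, region)
  with_ <- cpgProximitySummary(prof, excludeArtifacts = TRUE)
  without <- cpgProximitySummary(prof, excludeArtifacts = FALSE)
  expect_lt(abs(with_$frac_within_window - 0.70),
            abs(without$frac_within_window - 0.70))
  expect_lt(without$frac_within_window, 0.65)
  se <- sqrt(0.7 * 0.3 / with_$n_indels)
  expect_lt(abs(with_$frac_within_window - 0.70), 3 * se)
})

test_that("profile overlays subtract frequencies position by position", {
  mm <- mutationModel(indelRate = 0.3)
  simA <- simulateAmpliconReads(region, mm, readSimConfig(readCount = 300L,
                                                          seed = 127L))
  simB <- simulateAmpliconReads(region, mm, readSimConfig(readCount = 400L,
                                                          seed = 131L))
  profA <- profileFromAlignments(simA$reads, region)
  profB <- profileFromAlignments(simB$reads, region)
  same <- overlayProfiles(profA, profA)
  expect_true(all(same$d_del_freq == 0))
  expect_true(all(same$d_ins_freq == 0))
  ab <- overlayProfiles(profA, profB)
  ## independent recomputation from raw counts
  expect_equal(ab$d_del_freq,
               profB@deletionCount / profB@depth -
                 profA@deletionCount / profA@depth)
  other <- syntheticAbcRegion(length = 300L, seed = 5L, name = "other")
  profC <- profileFromAlignments(
    simulateAmpliconReads(other, mm,
                          readSimConfig(readCount = 10L, seed = 1L))$reads,
    other)
  expect_error(overlayProfiles(profA, profC), "different regions")
})

test_that("profile TSV and bedGraph exports are readable and consistent", {
  mm <- mutationModel(indelRate = 0.4)
  sim <- simulateAmpliconReads(region, mm, readSimConfig(readCount = 100L,
                                                         seed = 137L))
  prof <- profileFromAlignments(sim$reads, region)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeProfile(prof, tsv)
  back <- utils::read.delim(tsv)
  expect_identical(nrow(back), L)
  expect_equal(back$del_freq, prof@deletionCount / prof@depth)
  bg <- withr::local_tempfile(fileext = ".bedgraph")
  exportBedgraph(prof, bg)
  gr <- rtracklayer::import(bg)
  expect_equal(sum(gr$score > 0), sum(prof@deletionCount > 0))
})
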