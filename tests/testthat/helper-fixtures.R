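## Shared fixtures and independent oracles. Oracles are deliberately naive
## (character loops, exhaustive enumeration) so they share no code with the
## implementation they check.

fixtureRegion <- function(...) syntheticAbcRegion(...)

fixturePanel <- function(region = fixtureRegion(), ...)
  syntheticPanel(region, ...)

## panel-shaped simulation config for a WT + one-dropout mixture
fixtureSimConfig <- function(panel, wt = 99, mutant = 11,
                             dropChannel = "TAMRA", chambers = 20000L,
                             seed = 1L) {
  ch <- channelLabels(panel)
  classes <- list(moleculeClass("WT", ch, wt))
  if (mutant > 0)
    classes <- c(classes, moleculeClass("mutant", setdiff(ch, dropChannel),
                                        mutant))
  simulationConfig(classes, channels = ch, chamberCount = chambers,
                   chamberVolume = chamberVolume(panel), seed = seed)
}

## --- naive sequence oracles ---------------------------------------------

iupacMatch <- function(base, code) {
  switch(code,
         A = base == "A", C = base == "C", G = base == "G", T = base == "T",
         W = base %in% c("A", "T"), R = base %in% c("A", "G"),
         stop("unhandled code ", code))
}

reverseComplementChars <- function(chars) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  rev(unname(comp[chars]))
}

bruteCpG <- function(s) {
  chars <- strsplit(s, "")[[1L]]
  out <- integer(0)
  for (i in seq_len(length(chars) - 1L))
    if (chars[i] == "C" && chars[i + 1L] == "G") out <- c(out, i - 1L)
  out
}

## exhaustive both-strand motif enumerator; returns data.frame sorted like
## scanAidMotifs output
bruteMotifs <- function(s, classes) {
  chars <- strsplit(s, "")[[1L]]
  L <- length(chars)
  hitAt <- function(chars, i, pattern) {
    codes <- strsplit(pattern, "")[[1L]]
    w <- length(codes)
    if (i + w - 1L > length(chars)) return(FALSE)
    all(vapply(seq_len(w), function(k)
      iupacMatch(chars[i + k - 1L], codes[k]), logical(1L)))
  }
  rows <- list()
  add <- function(cls, strand, offset, matched)
    rows[[length(rows) + 1L]] <<- data.frame(
      motif_class = cls, strand = strand, offset = offset, matched = matched)
  rcChars <- reverseComplementChars(chars)
  for (cls in intersect(classes, c("WRC", "RCG", "WGCW"))) {
    w <- nchar(cls)
    for (i in seq_len(L)) {
      if (hitAt(chars, i, cls))
        add(cls, "+", i - 1L, paste(chars[i:(i + w - 1L)], collapse = ""))
      if (hitAt(rcChars, i, cls))
        add(cls, "-", L - (i - 1L) - w,
            paste(rcChars[i:(i + w - 1L)], collapse = ""))
    }
  }
  if ("CRYPTIC_RSS" %in% classes) {
    for (strand in c("+", "-")) {
      sc <- if (strand == "+") chars else rcChars
      for (i in seq_len(L)) {
        if (hitAt(sc, i, "CAC")) {
          matched <- if (i + 3L <= L && sc[i + 3L] == "A") "CACA" else "CAC"
          w <- nchar(matched)
          off <- if (strand == "+") i - 1L else L - (i - 1L) - w
          add("CRYPTIC_RSS", strand, off, matched)
        }
      }
    }
  }
  if (!length(rows))
    return(data.frame(motif_class = character(), strand = character(),
                      offset = integer(), matched = character()))
  out <- do.call(rbind, rows)
  out[order(out$offset, out$motif_class, out$strand), , drop = FALSE]
}

bruteHomopolymerFlags <- function(s, minRun = 5L) {
  chars <- strsplit(s, "")[[1L]]
  L <- length(chars)
  flags <- logical(L)
  for (i in seq_len(L)) {
    j <- i
    while (j <= L && chars[j] == chars[i]) j <- j + 1L
    if (j - i >= minRun) flags[i:(j - 1L)] <- TRUE
  }
  flags
}

randomSequence <- function(len)
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")

## --- truth-table tallies -------------------------------------------------

tallyTruth <- function(truth, L) {
  del <- ins <- subc <- integer(L)
  for (i in seq_len(nrow(truth))) {
    if (truth$type[i] == "del") {
      span <- (truth$start[i] + 1L):(truth$start[i] + truth$length[i])
      del[span] <- del[span] + 1L
    } else if (truth$type[i] == "ins") {
      ins[truth$start[i] + 1L] <- ins[truth$start[i] + 1L] + 1L
    } else {
      subc[truth$start[i] + 1L] <- subc[truth$start[i] + 1L] + 1L
    }
  }
  list(del = del, ins = ins, sub = subc)
}

## linear-system oracle for the joint (subset-lattice) estimator: solves
## Lambda_S = sum_{T : T intersects S} c_T directly with base::solve
bruteJointSolve <- function(callsMatrix, channels) {
  K <- length(channels)
  full <- 2^K - 1L
  n <- nrow(callsMatrix)
  lam <- vapply(1:full, function(S) {
    inS <- channels[bitwAnd(2^(seq_len(K) - 1L), S) > 0L]
    fneg <- mean(rowSums(callsMatrix[, inS, drop = FALSE]) == 0L)
    -log(fneg)
  }, numeric(1L))
  A <- outer(1:full, 1:full, function(S, T) as.numeric(bitwAnd(S, T) > 0L))
  setNames(solve(A, lam), 1:full)
}
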