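#' @importFrom Biostrings DNAString DNAStringSet matchPattern reverseComplement
#'   readDNAStringSet writeXStringSet
#' @importFrom IRanges IRanges
#' @importFrom GenomicRanges GRanges
NULL

checkSequence <- function(sequence) {
  s <- toupper(as.character(sequence))
  if (!nzchar(s))
    abcValidationError("sequence must be non-empty")
  if (grepl("[^ACGTN]", s))
    abcValidationError("invalid sequence: only A, C, G, T, N allowed")
  s
}

#' Scan a sequence for CpG dinucleotides
#'
#' Returns the 0-based offset of the C of every CpG on the plus strand. CpG is
#' palindromic, so a single-strand scan covers both strands.
#'
#' @param sequence a DNA string (character or \link[Biostrings]{DNAString})
#'   over A, C, G, T, N.
#' @return integer vector of 0-based offsets, ascending.
#' @examples
#' scanCpG("ACGT")   # 1
#' scanCpG("AAAA")   # integer(0)
#' @export
scanCpG <- function(sequence) {
  s <- checkSequence(sequence)
  m <- matchPattern("CG", DNAString(s))
  as.integer(BiocGenerics::start(m)) - 1L
}

motifWidth <- c(WRC = 3L, RCG = 3L, WGCW = 4L)

#' Scan a sequence for AID target motifs and cryptic RSS cores
#'
#' Scans both strands for the AID deamination contexts WRC, RCG and the WGCW
#' overlap hotspot (IUPAC: W = A/T, R = A/G), and for the CAC/CACA core of
#' cryptic recombination signal sequences. Minus-strand hits are reported at
#' their plus-strand start offset, with \code{matched} given in motif (minus
#' strand) orientation. N bases never match. For \code{CRYPTIC_RSS} the maximal
#' match per start is reported (CACA when present, else CAC).
#'
#' @param sequence a DNA string over A, C, G, T, N.
#' @param classes subset of \code{c("WRC","RCG","WGCW","CRYPTIC_RSS")}.
#' @return a \link[S4Vectors]{DataFrame} with columns \code{motif_class},
#'   \code{strand}, \code{offset} (0-based plus-strand start) and
#'   \code{matched}, sorted by offset.
#' @examples
#' scanAidMotifs("AGCT", classes = "WGCW")
#' @export
scanAidMotifs <- function(sequence, classes = MOTIF_CLASSES) {
  s <- checkSequence(sequence)
  bad <- setdiff(classes, MOTIF_CLASSES)
  if (length(bad))
    abcValidationError(paste("unknown motif class:", paste(bad, collapse = ", ")))
  subj <- DNAString(s)
  L <- length(subj)
  rows <- list()
  addHits <- function(cls, pattern) {
    w <- nchar(pattern)
    for (strand in c("+", "-")) {
      target <- if (strand == "+") subj else reverseComplement(subj)
      m <- matchPattern(pattern, target, fixed = "subject")
      st <- BiocGenerics::start(m)
      if (!length(st)) next
      off <- if (strand == "+") st - 1L else L - (st - 1L) - w
      rows[[length(rows) + 1L]] <<- DataFrame(
        motif_class = cls, strand = strand, offset = as.integer(off),
        matched = as.character(m)
      )
    }
  }
  for (cls in intersect(classes, names(motifWidth)))
    addHits(cls, cls)
  if ("CRYPTIC_RSS" %in% classes) {
    for (strand in c("+", "-")) {
      target <- if (strand == "+") subj else reverseComplement(subj)
      m <- matchPattern("CAC", target, fixed = "subject")
      st <- BiocGenerics::start(m)
      if (!length(st)) next
      tc <- as.character(target)
      matched <- vapply(st, function(i) {
        if (i + 3L <= nchar(tc) && substring(tc, i, i + 3L) == "CACA")
          "CACA" else "CAC"
      }, character(1L))
      w <- nchar(matched)
      off <- if (strand == "+") st - 1L else L - (st - 1L) - w
      rows[[length(rows) + 1L]] <- DataFrame(
        motif_class = "CRYPTIC_RSS", strand = strand,
        offset = as.integer(off), matched = matched
      )
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    DataFrame(motif_class = character(), strand = character(),
              offset = integer(), matched = character())
  out[order(out$offset, out$motif_class, out$strand), , drop = FALSE]
}

#' Construct an AbcRegion
#'
#' CpG offsets and motif hits are computed eagerly from the sequence.
#'
#' @param name region label.
#' @param chrom chromosome label.
#' @param start,end 1-based inclusive genomic coordinates.
#' @param sequence DNA string of length \code{end - start + 1}.
#' @param motifClasses motif classes to annotate (default all).
#' @return an [AbcRegion-class].
#' @export
AbcRegion <- function(name, chrom, start, end, sequence,
                      motifClasses = MOTIF_CLASSES) {
  s <- checkSequence(sequence)
  new("AbcRegion", name = name, chrom = chrom, start = as.numeric(start),
      end = as.numeric(end), sequence = DNAString(s),
      cpgPositions = scanCpG(s),
      motifHits = scanAidMotifs(s, motifClasses))
}

#' Read an AbcRegion from a FASTA file
#'
#' The record to use is selected by \code{name}; genomic coordinates are taken
#' from the arguments (they cannot be carried in plain FASTA).
#'
#' @param fasta path to a FASTA file.
#' @param name region label; must match a FASTA record name (first word).
#' @inheritParams AbcRegion
#' @return an [AbcRegion-class].
#' @export
readAbcRegion <- function(fasta, name, chrom, start, end,
                          motifClasses = MOTIF_CLASSES) {
  if (!file.exists(fasta))
    abcIOError(paste("FASTA not found:", fasta))
  seqs <- readDNAStringSet(fasta)
  ids <- vapply(strsplit(names(seqs), "\\s+"), `[[`, character(1L), 1L)
  i <- match(name, ids)
  if (is.na(i))
    abcValidationError(sprintf("record '%s' not found in %s", name, fasta))
  AbcRegion(name, chrom, start, end, as.character(seqs[[i]]), motifClasses)
}

#' Generate a synthetic ABC-like test region
#'
#' Builds a seeded random region of the stated length with CpG sites, AID
#' motifs and (optionally) homopolymer runs embedded, mimicking the sequence
#' features of an AID break cluster amplicon. This is a synthetic stand-in for
#' bench regions whose reference sequence is not redistributed with the
#' package; coordinates default to the published CRLF2 ABC interval so printed
#' positions stay realistic, but the sequence is random.
#'
#' @param length region length in nt (default 660).
#' @param nCpg number of CpG islands to embed (approximate lower bound; random
#'   background may add more).
#' @param homopolymer if TRUE (default) embed one A-run and one T-run of 6 nt,
#'   emulating library-prep artifact hotspots.
#' @param seed integer seed.
#' @param name,chrom,start region identity; \code{end} is derived.
#' @return an [AbcRegion-class].
#' @export
syntheticAbcRegion <- function(length = 660L, nCpg = 8L, homopolymer = TRUE,
                               seed = 100L, name = "synthetic_ABC",
                               chrom = "chrX", start = 1228310) {
  length <- as.integer(length)
  stopifnot(length >= 50L)
  withSeed(seed, {
    base <- sample(c("A", "C", "G", "T"), length, replace = TRUE,
                   prob = c(0.3, 0.2, 0.2, 0.3))
    ## embed CpG islands flanked by AID contexts (AGCTACGT: a WGCW core
    ## followed by a CpG sitting in WRC/RCG context)
    slots <- floor(seq(30L, length - 60L, length.out = nCpg))
    motif <- c("A", "G", "C", "T", "A", "C", "G", "T")
    for (p in slots) base[p:(p + 7L)] <- motif
    if (homopolymer) {
      base[10L:15L] <- "A"
      base[(length - 20L):(length - 15L)] <- "T"
    }
    ## scrub background CpGs so the embedded sites are the only ones; the
    ## placement kernel then has a clean proximal/non-proximal split
    embeddedC <- slots + 5L - 1L            # 0-based offset of embedded CpG C
    repeat {
      cg <- scanCpG(paste(base, collapse = ""))
      stray <- setdiff(cg, embeddedC)
      if (!length(stray)) break
      base[stray + 2L] <- "T"               # replace the G of each stray CpG
    }
    s <- paste(base, collapse = "")
    AbcRegion(name, chrom, start, start + length - 1, s)
  })
}

#' Export motif hits and probe windows as BED
#'
#' Writes 0-based half-open BED records in genomic coordinates via
#' \pkg{rtracklayer}.
#'
#' @param x an [AbcRegion-class] or [ProbePanel-class].
#' @param path output BED path.
#' @return the path, invisibly.
#' @export
exportBed <- function(x, path) {
  if (is(x, "ProbePanel")) {
    region <- x@region
    pr <- x@probes
    gr <- GRanges(region@chrom,
                  IRanges(start = region@start + pr$window_start,
                          end = region@start + pr$window_end - 1L),
                  strand = "*")
    names(gr) <- pr$probe
  } else if (is(x, "AbcRegion")) {
    mh <- x@motifHits
    if (!nrow(mh)) {
      gr <- GRanges()
    } else {
      w <- nchar(mh$matched)
      gr <- GRanges(x@chrom,
                    IRanges(start = x@start + mh$offset,
                            end = x@start + mh$offset + w - 1L),
                    strand = mh$strand)
      names(gr) <- paste0(mh$motif_class, "_", mh$offset)
    }
  } else {
    abcValidationError("exportBed expects an AbcRegion or ProbePanel")
  }
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}
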