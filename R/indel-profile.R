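#' @importFrom Rsamtools asBam ScanBamParam scanBamFlag BamFile
#' @importFrom GenomicAlignments readGAlignments cigar qwidth
NULL

#' Flag homopolymer-run positions in a region
#'
#' Positions lying inside any single-nucleotide run of at least \code{minRun}
#' bases are flagged; amplicon indel artifacts concentrate in such runs and
#' should be separable from AID-derived scars.
#'
#' @param region an [AbcRegion-class] (or a plain DNA string).
#' @param minRun minimum run length to flag (default 5).
#' @return logical vector, one element per position.
#' @examples
#' flagHomopolymers("AAAAAC")  # TRUE x5, FALSE
#' @export
flagHomopolymers <- function(region, minRun = 5L) {
  s <- if (is(region, "AbcRegion")) as.character(region@sequence)
       else checkSequence(region)
  r <- rle(strsplit(s, "")[[1L]])
  rep(r$lengths >= minRun, r$lengths)
}

#' Build a per-position indel profile from aligned amplicon reads
#'
#' Walks each read's CIGAR against the region: \code{M/=/X} advance both
#' sequences and contribute to depth, with mismatching bases of quality at
#' least \code{minBaseq} counted as substitutions; \code{D} advances the
#' reference, counting depth and a deletion at every deleted position;
#' \code{I} counts one insertion at the reference base immediately left of the
#' inserted bases; \code{S}/\code{H} are ignored. Reads below \code{minMapq}
#' and secondary/supplementary alignments are skipped.
#'
#' @param alignments path to a SAM or BAM file over the region, or a
#'   data.frame of alignment records (columns \code{rname}, \code{pos},
#'   \code{cigar}, \code{seq}, \code{qual}, \code{mapq}) as produced by
#'   [simulateAmpliconReads()].
#' @param region the [AbcRegion-class] the reads were aligned to; its name
#'   must match the alignment reference.
#' @param minMapq minimum mapping quality (default 0).
#' @param minBaseq minimum base quality for substitution calls (default 20).
#' @param minRun homopolymer run length used for artifact flags (default 5).
#' @return an [IndelProfile-class].
#' @export
profileFromAlignments <- function(alignments, region, minMapq = 0L,
                                  minBaseq = 20L, minRun = 5L) {
  if (is.character(alignments)) {
    alignments <- readAlignmentTable(alignments)
  } else if (!is.data.frame(alignments)) {
    abcValidationError("alignments must be a SAM/BAM path or a data.frame")
  }
  al <- alignments
  L <- length(region@sequence)
  if (nrow(al) && !all(al$rname == region@name))
    abcValidationError(sprintf(
      "alignment reference(s) %s do not match region '%s'",
      paste(unique(setdiff(al$rname, region@name)), collapse = ", "),
      region@name))
  refChars <- strsplit(as.character(region@sequence), "")[[1L]]
  depth <- del <- ins <- subc <- integer(L)
  events <- list()
  if (!nrow(al))
    warning("no alignments: returning an all-zero profile")
  keep <- al$mapq >= minMapq
  al <- al[keep, , drop = FALSE]
  for (r in seq_len(nrow(al))) {
    ops <- GenomicAlignments::explodeCigarOps(al$cigar[r])[[1L]]
    lens <- GenomicAlignments::explodeCigarOpLengths(al$cigar[r])[[1L]]
    refPos <- al$pos[r] - 1L              # 0-based region offset
    readPos <- 0L                          # 0-based offset into read
    readChars <- strsplit(al$seq[r], "")[[1L]]
    quals <- utf8ToInt(al$qual[r]) - 33L
    for (k in seq_along(ops)) {
      op <- ops[k]; len <- lens[k]
      if (op %in% c("M", "=", "X")) {
        span <- (refPos + 1L):(refPos + len)
        depth[span] <- depth[span] + 1L
        mism <- which(readChars[readPos + seq_len(len)] != refChars[span] &
                        quals[readPos + seq_len(len)] >= minBaseq)
        if (length(mism)) {
          subc[refPos + mism] <- subc[refPos + mism] + 1L
          for (p in mism)
            events[[length(events) + 1L]] <-
              c(type = "sub", start = refPos + p - 1L, length = 1L)
        }
        refPos <- refPos + len; readPos <- readPos + len
      } else if (op == "D") {
        span <- (refPos + 1L):(refPos + len)
        depth[span] <- depth[span] + 1L
        del[span] <- del[span] + 1L
        events[[length(events) + 1L]] <-
          c(type = "del", start = refPos, length = len)
        refPos <- refPos + len
      } else if (op == "I") {
        if (refPos >= 1L) {                # attaches to base refPos-1 (0-based)
          ins[refPos] <- ins[refPos] + 1L
          events[[length(events) + 1L]] <-
            c(type = "ins", start = refPos - 1L, length = len)
        }
        readPos <- readPos + len
      } else if (op == "S") {
        readPos <- readPos + len
      } else if (op == "N") {
        refPos <- refPos + len
      }                                    # H, P consume nothing tracked here
    }
  }
  ev <- if (length(events)) {
    md <- do.call(rbind, events)
    DataFrame(type = md[, "type"], start = as.integer(md[, "start"]),
              length = as.integer(md[, "length"]))
  } else {
    DataFrame(type = character(), start = integer(), length = integer())
  }
  new("IndelProfile", region = region, depth = depth, deletionCount = del,
      insertionCount = ins, substitutionCount = subc, events = ev,
      artifactFlags = flagHomopolymers(region, minRun))
}

## Read a SAM/BAM into the plain alignment table the profiler walks.
## SAM is converted through Rsamtools so parsing and flag semantics come from
## the reference implementation, not hand-rolled code.
readAlignmentTable <- function(path) {
  if (!file.exists(path))
    abcIOError(paste("alignment file not found:", path))
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    bam <- asBam(path, destination = dest, overwrite = TRUE,
                 indexDestination = TRUE)
  }
  param <- ScanBamParam(
    flag = scanBamFlag(isSecondaryAlignment = FALSE,
                       isSupplementaryAlignment = FALSE,
                       isUnmappedQuery = FALSE),
    what = c("seq", "qual", "mapq")
  )
  ga <- readGAlignments(BamFile(bam), param = param)
  md <- S4Vectors::mcols(ga)
  data.frame(
    rname = as.character(GenomeInfoDb::seqnames(ga)),
    pos = BiocGenerics::start(ga),
    cigar = cigar(ga),
    seq = as.character(md$seq),
    qual = as.character(md$qual),
    mapq = md$mapq
  )
}

#' Summarise indel events by CpG proximity
#'
#' Event midpoints (deletion midpoints; the attached base for insertions) are
#' compared against the region's CpG sites: reported are the total indel
#' events, the events landing exactly on a CpG base, the events within
#' \code{window} bp of any CpG, and the corresponding fractions. With
#' \code{excludeArtifacts}, events whose midpoint is flagged as homopolymer
#' artifact territory are dropped first.
#'
#' @param profile an [IndelProfile-class].
#' @param window proximity window in bp (default 8).
#' @param excludeArtifacts drop events at artifact-flagged positions.
#' @return a list: \code{n_indels}, \code{n_at_cpg}, \code{n_within_window},
#'   \code{frac_at_cpg}, \code{frac_within_window} (fractions are \code{NA}
#'   when there are no events).
#' @export
cpgProximitySummary <- function(profile, window = 8L,
                                excludeArtifacts = FALSE) {
  if (window < 0L)
    abcValidationError("window must be >= 0")
  region <- profile@region
  masks <- cpgMasks(region, as.integer(window))
  ev <- profile@events
  ev <- ev[ev$type %in% c("del", "ins"), , drop = FALSE]
  mid <- ev$start + ifelse(ev$type == "del", (ev$length - 1L) %/% 2L, 0L)
  if (excludeArtifacts && nrow(ev)) {
    keep <- !profile@artifactFlags[mid + 1L]
    ev <- ev[keep, , drop = FALSE]
    mid <- mid[keep]
  }
  n <- nrow(ev)
  atCpg <- if (n) sum(masks$atCpg[mid + 1L]) else 0L
  within <- if (n) sum(masks$prox[mid + 1L]) else 0L
  list(n_indels = n, n_at_cpg = atCpg, n_within_window = within,
       frac_at_cpg = if (n) atCpg / n else NA_real_,
       frac_within_window = if (n) within / n else NA_real_)
}

#' Overlay two indel profiles over the same region
#'
#' @param a,b two [IndelProfile-class] objects over the same region; deltas
#'   are \code{b - a} (e.g. induced minus baseline).
#' @return a data.frame with per-position frequencies of both profiles and
#'   their differences (\code{d_del_freq}, \code{d_ins_freq},
#'   \code{d_sub_freq}).
#' @export
overlayProfiles <- function(a, b) {
  if (a@region@name != b@region@name ||
      length(a@region@sequence) != length(b@region@sequence))
    abcValidationError("profiles are over different regions")
  ta <- profileTable(a); tb <- profileTable(b)
  data.frame(
    offset = ta$offset, position = ta$position, ref_base = ta$ref_base,
    del_freq_a = ta$del_freq, del_freq_b = tb$del_freq,
    ins_freq_a = ta$ins_freq, ins_freq_b = tb$ins_freq,
    sub_freq_a = ta$sub_freq, sub_freq_b = tb$sub_freq,
    d_del_freq = tb$del_freq - ta$del_freq,
    d_ins_freq = tb$ins_freq - ta$ins_freq,
    d_sub_freq = tb$sub_freq - ta$sub_freq,
    artifact_flag = ta$artifact_flag
  )
}

#' Write an indel profile as TSV / export deletion frequency as bedGraph
#'
#' @param profile an [IndelProfile-class].
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeProfile <- function(profile, path) {
  ok <- try(utils::write.table(profileTable(profile), path, sep = "\t",
                               quote = FALSE, row.names = FALSE),
            silent = TRUE)
  if (inherits(ok, "try-error"))
    abcIOError(paste("cannot write profile:", path))
  invisible(path)
}

#' @rdname writeProfile
#' @export
exportBedgraph <- function(profile, path) {
  tab <- profileTable(profile)
  region <- profile@region
  gr <- GRanges(region@chrom,
                IRanges(start = tab$position, width = 1L),
                score = tab$del_freq)
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}
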