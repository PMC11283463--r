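#' Construct a MutationModel
#'
#' Defaults encode the AID placement model used throughout: indels fall within
#' 8 bp of a CpG with probability 0.70, exact-CpG positions are upweighted by
#' 1.3, and deletions dominate insertions.
#'
#' @param substitutionRate per-molecule probability of one C-to-T (G-to-A on
#'   the minus strand) substitution at a WRC/RCG/CpG context.
#' @param indelRate per-molecule probability of one indel.
#' @param cpgKernel probability the indel midpoint lands within
#'   \code{cpgWindow} bp of a CpG (default 0.70).
#' @param cpgWindow proximity window in bp (default 8).
#' @param atCpgBias relative placement weight of exact-CpG positions
#'   (default 1.3).
#' @param deletionFraction probability an indel is a deletion (default 0.8).
#' @param lengthGeometricP geometric length parameter; indel length is
#'   \code{1 + rgeom(lengthGeometricP)} (default 0.6, mean 1.67 nt).
#' @return a [MutationModel-class].
#' @export
mutationModel <- function(substitutionRate = 0.02, indelRate = 0.05,
                          cpgKernel = 0.70, cpgWindow = 8L, atCpgBias = 1.3,
                          deletionFraction = 0.8, lengthGeometricP = 0.6) {
  new("MutationModel", substitutionRate = substitutionRate,
      indelRate = indelRate, cpgKernel = cpgKernel,
      cpgWindow = as.integer(cpgWindow), atCpgBias = atCpgBias,
      deletionFraction = deletionFraction,
      lengthGeometricP = lengthGeometricP)
}

#' Construct a ReadSimConfig
#'
#' @param readCount number of reads (default 5000).
#' @param readLength aligned reference span per read; \code{NULL} (default)
#'   means full amplicon length.
#' @param errorRate per-base sequencing substitution error rate (default 1e-3).
#' @param artifactRange optional 0-based half-open offset range for
#'   library-prep artifact indels (e.g. a homopolymer run).
#' @param artifactRate per-read probability of one artifact indel (default 0).
#' @param seed integer seed.
#' @return a [ReadSimConfig-class].
#' @export
readSimConfig <- function(readCount = 5000L, readLength = NULL,
                          errorRate = 1e-3, artifactRange = integer(0),
                          artifactRate = 0, seed = 1L) {
  new("ReadSimConfig", readCount = as.integer(readCount),
      readLength = as.integer(if (is.null(readLength)) .Machine$integer.max
                              else readLength),
      errorRate = errorRate, artifactRange = as.integer(artifactRange),
      artifactRate = artifactRate, seed = as.integer(seed))
}

## Offsets (0-based) of mutable cytosines, on either strand, derived from the
## region's WRC/RCG motif hits and CpG sites. strand "+" means a plus-strand C
## (C->T); "-" means a plus-strand G whose minus-strand C is in context (G->A).
aidSubstitutionSites <- function(region) {
  mh <- region@motifHits
  mh <- mh[mh$motif_class %in% c("WRC", "RCG"), , drop = FALSE]
  pos <- integer(0); strand <- character(0)
  if (nrow(mh)) {
    ## offset of the mutable C within the motif, in plus-strand coordinates:
    ## WRC: C is the last base (+) / first base (-); RCG: C is the middle base
    cOff <- ifelse(mh$motif_class == "WRC",
                   ifelse(mh$strand == "+", 2L, 0L), 1L)
    pos <- mh$offset + cOff
    strand <- mh$strand
  }
  cp <- region@cpgPositions
  pos <- c(pos, cp, cp + 1L)
  strand <- c(strand, rep("+", length(cp)), rep("-", length(cp)))
  keep <- !duplicated(paste(pos, strand))
  list(pos = as.integer(pos[keep]), strand = strand[keep])
}

## CpG proximity masks over the region (0-based logic on 1-based vectors)
cpgMasks <- function(region, window) {
  L <- length(region@sequence)
  cp <- region@cpgPositions
  atCpg <- logical(L); prox <- logical(L)
  for (c0 in cp) {
    atCpg[c0 + 1L] <- TRUE
    if (c0 + 2L <= L) atCpg[c0 + 2L] <- TRUE
    lo <- max(1L, c0 + 1L - window)
    hi <- min(L, c0 + 2L + window)
    prox[lo:hi] <- TRUE
  }
  list(atCpg = atCpg, prox = prox)
}

#' Simulate aligned amplicon reads carrying AID mutation scars
#'
#' Each read observes one independent template molecule. Per molecule, with
#' probability \code{indelRate} one indel is placed by the CpG-proximity
#' kernel (midpoint within \code{cpgWindow} bp of a CpG with probability
#' \code{cpgKernel}, exact-CpG positions upweighted by \code{atCpgBias};
#' otherwise uniform over non-proximal positions); with probability
#' \code{substitutionRate} one context C-to-T (G-to-A on minus strand)
#' substitution is made; sequencing errors hit matched bases at
#' \code{errorRate}; optional library-prep artifact indels are injected
#' independently inside \code{artifactRange} and flagged in the truth table.
#' An indel that would overrun the read's reference span is resampled within
#' its kernel branch, with a hard cap of 10 retries before an error.
#'
#' Insertions attach to the reference base to their left; reads are emitted as
#' SAM-style alignment records whose CIGAR encodes every introduced event.
#'
#' @param region an [AbcRegion-class].
#' @param model a [MutationModel-class].
#' @param rc a [ReadSimConfig-class].
#' @return a list with \code{reads} (data.frame: qname, flag, rname, pos,
#'   mapq, cigar, seq, qual) and \code{truth} (data.frame: qname, type
#'   (\code{del}/\code{ins}/\code{sub}), start = 0-based region offset (for
#'   insertions, the left-attached base), length, origin (\code{aid},
#'   \code{artifact}, \code{error})).
#' @export
simulateAmpliconReads <- function(region, model, rc) {
  validObject(model); validObject(rc)
  L <- length(region@sequence)
  readLen <- min(rc@readLength, L)
  if (rc@readLength != .Machine$integer.max && rc@readLength > L)
    abcValidationError("readLength exceeds the amplicon length")
  refChars <- strsplit(as.character(region@sequence), "")[[1L]]
  masks <- cpgMasks(region, model@cpgWindow)
  proxIdx <- which(masks$prox)            # 1-based positions
  proxWeights <- ifelse(masks$atCpg[proxIdx], model@atCpgBias, 1)
  nonProxIdx <- which(!masks$prox)
  if (model@indelRate > 0) {
    if (!length(proxIdx) && model@cpgKernel > 0)
      abcValidationError("region has no CpG-proximal positions but cpgKernel > 0")
    if (!length(nonProxIdx) && model@cpgKernel < 1)
      abcValidationError("region is entirely CpG-proximal but cpgKernel < 1")
  }
  subSites <- aidSubstitutionSites(region)
  OTHER <- list(A = c("C", "G", "T"), C = c("A", "G", "T"),
                G = c("A", "C", "T"), T = c("A", "C", "G"),
                N = c("A", "C", "G", "T"))

  drawIndelLength <- function() 1L + rgeom(1L, model@lengthGeometricP)

  withSeed(rc@seed, {
    nr <- rc@readCount
    reads <- vector("list", nr)
    truths <- vector("list", nr)
    for (r in seq_len(nr)) {
      start <- if (readLen < L) sample.int(L - readLen + 1L, 1L) - 1L else 0L
      spanEnd <- start + readLen          # half-open
      events <- list()                    # each: type, start, length, origin

      placeIndel <- function(origin) {
        isDel <- runif(1L) < model@deletionFraction
        if (origin == "aid") {
          nearCpg <- runif(1L) < model@cpgKernel
          for (try in seq_len(10L)) {
            len <- drawIndelLength()
            mid <- if (nearCpg) {
              proxIdx[sample.int(length(proxIdx), 1L, prob = proxWeights)] - 1L
            } else {
              nonProxIdx[sample.int(length(nonProxIdx), 1L)] - 1L
            }
            if (isDel) {
              s <- mid - (len - 1L) %/% 2L
              if (s >= start && s + len <= spanEnd)
                return(list(type = "del", start = s, length = len,
                            origin = origin))
            } else {
              if (mid >= start && mid < spanEnd - 1L)
                return(list(type = "ins", start = mid, length = len,
                            origin = origin))
            }
          }
          abcValidationError("indel placement failed after 10 retries")
        } else {
          lo <- max(start, rc@artifactRange[1L])
          hi <- min(spanEnd - 1L, rc@artifactRange[2L] - 1L)
          if (lo > hi) return(NULL)
          s <- lo + sample.int(hi - lo + 1L, 1L) - 1L
          list(type = if (isDel) "del" else "ins", start = s, length = 1L,
               origin = origin)
        }
      }

      overlaps <- function(ev, events) {
        for (e in events) {
          eEnd <- e$start + if (e$type == "del") e$length else 1L
          evEnd <- ev$start + if (ev$type == "del") ev$length else 1L
          if (ev$start < eEnd && e$start < evEnd) return(TRUE)
        }
        FALSE
      }

      if (runif(1L) < model@indelRate)
        events[[length(events) + 1L]] <- placeIndel("aid")
      if (rc@artifactRate > 0 && length(rc@artifactRange) == 2L &&
          runif(1L) < rc@artifactRate) {
        for (try in seq_len(10L)) {
          ev <- placeIndel("artifact")
          if (is.null(ev)) break
          if (!overlaps(ev, events)) {
            events[[length(events) + 1L]] <- ev
            break
          }
        }
      }

      delMask <- logical(L)               # 1-based; TRUE where base deleted
      for (e in events) if (e$type == "del")
        delMask[(e$start + 1L):(e$start + e$length)] <- TRUE

      ## one AID context substitution on a surviving base inside the span
      subs <- list()
      if (runif(1L) < model@substitutionRate) {
        ok <- subSites$pos >= start & subSites$pos < spanEnd &
          !delMask[subSites$pos + 1L]
        if (any(ok)) {
          k <- which(ok)[sample.int(sum(ok), 1L)]
          p <- subSites$pos[k]
          newBase <- if (subSites$strand[k] == "+") "T" else "A"
          subs[[length(subs) + 1L]] <- list(pos = p, base = newBase,
                                            origin = "aid")
        }
      }

      ## sequencing errors on matched, not-yet-substituted bases
      if (rc@errorRate > 0) {
        cand <- setdiff(which(!delMask[(start + 1L):spanEnd]) + start - 1L,
                        vapply(subs, `[[`, integer(1L), "pos"))
        hit <- cand[runif(length(cand)) < rc@errorRate]
        for (p in hit) {
          ref <- refChars[p + 1L]
          alt <- OTHER[[ref]][sample.int(length(OTHER[[ref]]), 1L)]
          subs[[length(subs) + 1L]] <- list(pos = p, base = alt,
                                            origin = "error")
        }
      }

      ## assemble CIGAR and read sequence
      indels <- events[order(vapply(events, `[[`, integer(1L), "start"),
                             vapply(events, function(e)
                               if (e$type == "ins") 1L else 0L, integer(1L)))]
      subBase <- character(0)
      if (length(subs)) {
        subBase <- vapply(subs, `[[`, character(1L), "base")
        names(subBase) <- vapply(subs, `[[`, integer(1L), "pos")
      }
      emitM <- function(a, b) {           # ref offsets [a, b) -> read chars
        if (b <= a) return(character(0))
        seg <- refChars[(a + 1L):b]
        if (length(subBase)) {
          idx <- as.integer(names(subBase))
          inSeg <- idx >= a & idx < b
          if (any(inSeg)) seg[idx[inSeg] - a + 1L] <- subBase[inSeg]
        }
        seg
      }
      cig <- character(0); outChars <- character(0); cur <- start
      for (e in indels) {
        if (e$type == "del") {
          if (e$start > cur) {
            cig <- c(cig, paste0(e$start - cur, "M"))
            outChars <- c(outChars, emitM(cur, e$start))
          }
          cig <- c(cig, paste0(e$length, "D"))
          cur <- e$start + e$length
        } else {
          upto <- e$start + 1L
          if (upto > cur) {
            cig <- c(cig, paste0(upto - cur, "M"))
            outChars <- c(outChars, emitM(cur, upto))
          }
          cig <- c(cig, paste0(e$length, "I"))
          outChars <- c(outChars,
                        sample(c("A", "C", "G", "T"), e$length, replace = TRUE))
          cur <- upto
        }
      }
      if (spanEnd > cur) {
        cig <- c(cig, paste0(spanEnd - cur, "M"))
        outChars <- c(outChars, emitM(cur, spanEnd))
      }
      qname <- sprintf("read%06d", r)
      seqStr <- paste(outChars, collapse = "")
      reads[[r]] <- data.frame(
        qname = qname, flag = 0L, rname = region@name, pos = start + 1L,
        mapq = 60L, cigar = paste(cig, collapse = ""), seq = seqStr,
        qual = strrep("I", nchar(seqStr))
      )
      tr <- list()
      for (e in indels)
        tr[[length(tr) + 1L]] <- data.frame(qname = qname, type = e$type,
                                            start = e$start,
                                            length = e$length,
                                            origin = e$origin)
      for (sb in subs)
        tr[[length(tr) + 1L]] <- data.frame(qname = qname, type = "sub",
                                            start = sb$pos, length = 1L,
                                            origin = sb$origin)
      truths[[r]] <- if (length(tr)) do.call(rbind, tr) else NULL
    }
    truth <- do.call(rbind, c(truths[!vapply(truths, is.null, logical(1L))],
                              list(data.frame(qname = character(),
                                              type = character(),
                                              start = integer(),
                                              length = integer(),
                                              origin = character()))))
    list(reads = do.call(rbind, reads), truth = truth)
  })
}

#' Write simulated reads as SAM (and optionally FASTQ plus a truth sidecar)
#'
#' The SAM carries a minimal header (\code{@HD}, one \code{@SQ} line for the
#' region). FASTQ is written through \pkg{Biostrings}. The truth table is
#' written as JSON.
#'
#' @param sim result of [simulateAmpliconReads()].
#' @param region the [AbcRegion-class] the reads align to.
#' @param samPath output SAM path.
#' @param fastqPath optional FASTQ path.
#' @param truthPath optional truth JSON path.
#' @return \code{samPath}, invisibly.
#' @export
writeReads <- function(sim, region, samPath, fastqPath = NULL,
                       truthPath = NULL) {
  rd <- sim$reads
  header <- c("@HD\tVN:1.6\tSO:unsorted",
              sprintf("@SQ\tSN:%s\tLN:%d", region@name,
                      length(region@sequence)))
  body <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t%s",
                  rd$qname, rd$flag, rd$rname, rd$pos, rd$mapq, rd$cigar,
                  rd$seq, rd$qual)
  ok <- try(writeLines(c(header, body), samPath), silent = TRUE)
  if (inherits(ok, "try-error"))
    abcIOError(paste("cannot write SAM:", samPath))
  if (!is.null(fastqPath)) {
    seqs <- DNAStringSet(rd$seq)
    names(seqs) <- rd$qname
    writeXStringSet(seqs, fastqPath, format = "fastq",
                    qualities = Biostrings::BStringSet(rd$qual))
  }
  if (!is.null(truthPath))
    jsonlite::write_json(sim$truth, truthPath, dataframe = "rows",
                         auto_unbox = TRUE, digits = NA)
  invisible(samPath)
}
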