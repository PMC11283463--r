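## Panel configuration: YAML in, validated ProbePanel out. Config coordinates
## are 1-based inclusive genomic (copy-pasteable from a browser); internal
## windows are 0-based half-open region offsets.

#' Load a probe panel from a YAML config
#'
#' The config has a \code{region} block (name, chrom, start, end and either an
#' inline \code{sequence} or a \code{fasta} path, resolved relative to the
#' config file) and a \code{panel} block (\code{chamber_volume} plus a
#' \code{probes} list; each probe has \code{probe}, \code{channel},
#' \code{window} as a 1-based inclusive genomic \code{[start, end]} pair, and
#' \code{reference}). All panel invariants (exactly one reference probe,
#' windows inside the region, CpG-free reference window) are checked eagerly.
#'
#' @param path YAML config path.
#' @return a validated [ProbePanel-class].
#' @export
loadPanel <- function(path) {
  if (!file.exists(path))
    abcIOError(paste("panel config not found:", path))
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$region) || is.null(cfg$panel))
    abcValidationError("panel config needs 'region' and 'panel' blocks")
  panelFromConfig(cfg, dir = dirname(path))
}

panelFromConfig <- function(cfg, dir = ".") {
  rg <- cfg$region
  for (f in c("name", "chrom", "start", "end"))
    if (is.null(rg[[f]]))
      abcValidationError(paste("region block missing field:", f))
  region <- if (!is.null(rg$sequence)) {
    AbcRegion(rg$name, rg$chrom, rg$start, rg$end, rg$sequence)
  } else if (!is.null(rg$fasta)) {
    fa <- rg$fasta
    if (!file.exists(fa)) fa <- file.path(dir, rg$fasta)
    readAbcRegion(fa, rg$name, rg$chrom, rg$start, rg$end)
  } else {
    abcValidationError("region block needs 'sequence' or 'fasta'")
  }
  pn <- cfg$panel
  if (is.null(pn$chamber_volume))
    abcValidationError("panel block missing 'chamber_volume'")
  if (!length(pn$probes))
    abcValidationError("panel block has no probes")
  rows <- lapply(pn$probes, function(p) {
    for (f in c("probe", "channel", "window"))
      if (is.null(p[[f]]))
        abcValidationError(paste("probe entry missing field:", f))
    if (length(p$window) != 2L)
      abcValidationError(sprintf("probe '%s': window must be [start, end]", p$probe))
    DataFrame(probe = p$probe, channel = p$channel,
              window_start = as.integer(p$window[[1L]] - region@start),
              window_end = as.integer(p$window[[2L]] - region@start + 1L),
              is_reference = isTRUE(p$reference))
  })
  probes <- do.call(rbind, rows)
  out <- try(new("ProbePanel", region = region, probes = probes,
                 chamberVolume = as.numeric(pn$chamber_volume)), silent = TRUE)
  if (inherits(out, "try-error"))
    abcValidationError(paste("invalid panel:", attr(out, "condition")$message))
  out
}

#' Write a probe panel back to YAML
#'
#' The written config round-trips through [loadPanel()] unchanged (the region
#' sequence is inlined).
#'
#' @param panel a [ProbePanel-class].
#' @param path output YAML path.
#' @return the path, invisibly.
#' @export
writePanel <- function(panel, path) {
  rg <- panel@region
  pr <- panel@probes
  cfg <- list(
    region = list(name = rg@name, chrom = rg@chrom,
                  start = as.integer(rg@start), end = as.integer(rg@end),
                  sequence = as.character(rg@sequence)),
    panel = list(
      chamber_volume = panel@chamberVolume,
      probes = lapply(seq_len(nrow(pr)), function(i) list(
        probe = pr$probe[i], channel = pr$channel[i],
        window = as.integer(c(rg@start + pr$window_start[i],
                              rg@start + pr$window_end[i] - 1L)),
        reference = pr$is_reference[i]
      ))
    )
  )
  ok <- try(yaml::write_yaml(cfg, path), silent = TRUE)
  if (inherits(ok, "try-error"))
    abcIOError(paste("cannot write panel config:", path))
  invisible(path)
}

#' Build a synthetic 4-channel drop-off panel over a region
#'
#' Places three drop-off probes (FAM, TAMRA, Cy5) over the first three CpG
#' sites of the region and one reference probe (SUN) over a CpG-free window,
#' mirroring the published panel layout: drop-off probes at AID-preferred CpG
#' sites, the reference where no CpG or break has been mapped. Window
#' coordinates are synthetic placeholders, not bench assay coordinates.
#'
#' @param region an [AbcRegion-class] with at least three CpG sites.
#' @param chamberVolume microliters per chamber (default 4.5e-4: a 9 uL
#'   reaction over 20,000 chambers).
#' @param probeWidth probe window width in nt (default 20).
#' @return a [ProbePanel-class].
#' @export
syntheticPanel <- function(region, chamberVolume = 4.5e-4, probeWidth = 20L) {
  cp <- region@cpgPositions
  L <- length(region@sequence)
  if (length(cp) < 3L)
    abcValidationError("synthetic panel needs a region with >= 3 CpG sites")
  half <- probeWidth %/% 2L
  mkWin <- function(center) {
    s <- max(0L, as.integer(center) - half)
    c(s, min(L, s + probeWidth))
  }
  dropoff <- lapply(cp[1:3], mkWin)
  ## reference window: first CpG-free, homopolymer-free stretch of probeWidth
  ## nt that does not overlap a drop-off probe window
  occupied <- flagHomopolymers(region)
  occupied[c(cp + 1L, cp + 2L)] <- TRUE  # both bases of each CpG (1-based)
  for (w in dropoff) occupied[(w[1L] + 1L):w[2L]] <- TRUE
  refStart <- NA_integer_
  for (s in 0:(L - probeWidth)) {
    if (!any(occupied[(s + 1L):(s + probeWidth)])) { refStart <- s; break }
  }
  if (is.na(refStart))
    abcValidationError("no CpG-free window available for the reference probe")
  probes <- DataFrame(
    probe = c("FAM_drop", "TAMRA_drop", "Cy5_drop", "SUN_ref"),
    channel = c("FAM", "TAMRA", "Cy5", "SUN"),
    window_start = as.integer(c(vapply(dropoff, `[`, integer(1L), 1L),
                                refStart)),
    window_end = as.integer(c(vapply(dropoff, `[`, integer(1L), 2L),
                              refStart + probeWidth)),
    is_reference = c(FALSE, FALSE, FALSE, TRUE)
  )
  new("ProbePanel", region = region, probes = probes,
      chamberVolume = chamberVolume)
}
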