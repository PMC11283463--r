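## Structured conditions so the command-line wrapper can map error families to
## exit codes (validation 2, saturation/no-separation 3, I/O 4).

abcError <- function(msg, class, ...) {
  stop(errorCondition(msg, ..., class = c(class, "abcdPCRError")))
}

#' @noRd
abcValidationError <- function(msg, ...) {
  abcError(msg, "abcValidationError", ...)
}

#' @noRd
abcSaturationError <- function(msg, ...) {
  abcError(msg, "abcSaturationError", ...)
}

#' @noRd
abcNoSeparationError <- function(msg, ...) {
  abcError(msg, "abcNoSeparationError", ...)
}

#' @noRd
abcIOError <- function(msg, ...) {
  abcError(msg, "abcIOError", ...)
}

## Run an expression with a private RNG stream seeded from `seed`, restoring the
## caller's .Random.seed afterwards, so seeded helpers do not perturb user code.
withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

## Single place defining the IUPAC patterns the motif scanners use.
MOTIF_CLASSES <- c("WRC", "RCG", "WGCW", "CRYPTIC_RSS")
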