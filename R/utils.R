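## Internal helpers shared across the package.

#' @importFrom methods new validObject is slot
#' @importFrom utils head tail
NULL

DNA_ALPHABET <- c("A", "C", "G", "T")

## Abort with a classed condition so callers can distinguish failure modes.
cbStop <- function(class, fmt, ...) {
  msg <- sprintf(fmt, ...)
  stop(structure(
    class = c(class, "cloneBrickError", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

assertNucSequence <- function(x, what = "sequence", allowEmpty = FALSE) {
  if (!is.character(x) || length(x) != 1L || is.na(x))
    cbStop("alphabetError", "%s must be a single character string", what)
  if (nzchar(x)) {
    if (grepl("[^ACGT]", x))
      cbStop("alphabetError",
             "%s contains characters outside A/C/G/T (ambiguity codes are rejected): '%s'",
             what, x)
  } else if (!allowEmpty) {
    cbStop("alphabetError", "%s must be non-empty", what)
  }
  invisible(x)
}

#' Reverse complement of a DNA sequence
#'
#' Strict Watson-Crick reverse complement over the A/C/G/T alphabet.
#' IUPAC ambiguity codes are rejected rather than expanded: every sequence
#' handled by this package is fully specified and digestion semantics must
#' stay exact.
#'
#' @param x A single string over A/C/G/T (the empty string is allowed and
#'   returned unchanged).
#' @return The reverse-complemented string.
#' @examples
#' revComp("GGATCC")  # palindrome
#' revComp("GATCGG")
#' @export
revComp <- function(x) {
  assertNucSequence(x, "sequence", allowEmpty = TRUE)
  if (!nzchar(x)) return(x)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

## Run expr with a fixed RNG state, restoring the caller's state afterwards.
withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

randomBases <- function(n) {
  if (n <= 0) return("")
  paste(sample(DNA_ALPHABET, n, replace = TRUE), collapse = "")
}

## Count non-overlapping... actually all (possibly overlapping) occurrences of
## a fixed pattern; used for site bookkeeping where overlaps matter.
countOccurrences <- function(subject, pattern) {
  length(allOccurrences(subject, pattern))
}

allOccurrences <- function(subject, pattern) {
  n <- nchar(subject); m <- nchar(pattern)
  if (m == 0L || n < m) return(integer(0))
  hits <- gregexpr(pattern, subject, fixed = TRUE)[[1L]]
  if (hits[1L] == -1L) return(integer(0))
  ## gregexpr skips overlapping matches; rescan from inside each hit
  out <- integer(0)
  i <- 1L
  while (i <= n - m + 1L) {
    j <- regexpr(pattern, substr(subject, i, n), fixed = TRUE)
    if (j == -1L) break
    out <- c(out, i + j - 1L)
    i <- i + j  # allow overlap
  }
  out
}

## Empty feature table (the canonical annotation container).
emptyFeatures <- function() {
  data.frame(
    label = character(0), role = character(0),
    start = integer(0), end = integer(0),
    regulator = character(0), mode = character(0), inducer = character(0),
    strength = character(0), truncated = logical(0),
    stringsAsFactors = FALSE
  )
}

FEATURE_ROLES <- c("mcs_upstream", "downstream_region", "rbs", "cds",
                   "operator", "promoter_core", "expression_cassette")

makeFeature <- function(label, role, start, end, regulator = NA_character_,
                        mode = NA_character_, inducer = NA_character_,
                        strength = NA_character_, truncated = FALSE) {
  stopifnot(role %in% FEATURE_ROLES)
  data.frame(label = label, role = role,
             start = as.integer(start), end = as.integer(end),
             regulator = regulator, mode = mode, inducer = inducer,
             strength = strength, truncated = truncated,
             stringsAsFactors = FALSE)
}

rbindFeatures <- function(...) {
  xs <- Filter(function(f) !is.null(f) && nrow(f) > 0, list(...))
  if (!length(xs)) return(emptyFeatures())
  do.call(rbind, c(xs, list(make.row.names = FALSE)))
}
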