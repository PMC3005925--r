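## Double-stranded motif search over linear and circular molecules.

#' Find a motif on both strands of a molecule
#'
#' Reports every 1-based top-strand start position at which the motif occurs
#' on the top strand or on the bottom strand (a bottom-strand hit is located
#' by where its reverse complement sits on the top strand). Circular
#' molecules are scanned across the origin; positions are reported in
#' [1, length]. A palindromic motif matches both strands at the same locus
#' and is reported once, as a top-strand hit. The scan covers the full
#' virtual sequence including single-stranded overhang bases; use
#' \code{\link{findSites}} when duplex DNA is required.
#'
#' @param molecule A \linkS4class{DuplexFragment}.
#' @param motif Motif sequence (A/C/G/T).
#' @return A data.frame with columns \code{position} and \code{strand}
#'   ("top"/"bottom"), ordered by position; zero rows if absent.
#' @examples
#' frag <- duplexFragment("GGAGATCTGTCGGATAACGCGTGAGATTAAAGAGGAGAAATACTAGATG")
#' findMotif(frag, "AGATCT")
#' @export
findMotif <- function(molecule, motif) {
  if (!is(molecule, "DuplexFragment"))
    cbStop("typeError", "molecule must be a DuplexFragment")
  assertNucSequence(motif, "motif")
  seq <- virtualSeq(molecule)
  L <- nchar(seq); m <- nchar(motif)
  subject <- if (isCircular(molecule) && m > 1L)
    paste0(seq, substr(seq, 1L, m - 1L)) else seq
  scan <- function(pat) {
    hits <- matchStarts(subject, pat)
    hits[hits <= L]
  }
  top <- scan(motif)
  rcm <- revComp(motif)
  if (rcm == motif) {
    bottom <- integer(0)  # palindrome: one locus, reported once
  } else {
    bottom <- scan(rcm)
  }
  out <- data.frame(
    position = c(top, bottom),
    strand = c(rep("top", length(top)), rep("bottom", length(bottom))),
    stringsAsFactors = FALSE
  )
  out[order(out$position, out$strand), , drop = FALSE]
}

## All (overlap-allowing) start positions of a fixed pattern, via Biostrings.
matchStarts <- function(subject, pattern) {
  if (nchar(subject) < nchar(pattern)) return(integer(0))
  as.integer(Biostrings::start(Biostrings::matchPattern(
    Biostrings::DNAString(pattern), Biostrings::DNAString(subject)
  )))
}
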