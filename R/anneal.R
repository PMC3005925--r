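## Oligonucleotide annealing: exact-complementarity duplex formation.

#' Anneal two oligonucleotides into a linear duplex
#'
#' Finds the ungapped antiparallel alignment of the two oligos in which every
#' paired position is Watson-Crick complementary and unpaired positions occur
#' only as terminal 5' extensions (which become the duplex's 5' overhangs).
#' Alignment is by exact complementarity only -- no thermodynamics, no
#' mismatch tolerance. The alignment must be unique among all candidates with
#' at least \code{minOverlap} paired bases; ties are refused rather than
#' silently resolved, since picking the wrong register would assemble the
#' wrong part. The default \code{minOverlap} of 6 is the shortest duplex the
#' toolkit treats as stable (a 6-bp blunt palindrome pair anneals; spurious
#' 1-2 bp terminal pairings are ignored).
#'
#' @param topOligo,bottomOligo The two oligo sequences, each written 5'->3'.
#' @param minOverlap Minimum number of paired bases for a valid alignment.
#' @param name Name for the resulting fragment.
#' @return A linear \linkS4class{DuplexFragment} whose left/right
#'   \linkS4class{StickyEnd}s are blunt or 5' overhangs as implied by the
#'   alignment.
#' @examples
#' frag <- annealOligos("GAATTC", "GAATTC")  # blunt self-complementary 6-mer
#' leftEnd(frag)
#' @export
annealOligos <- function(topOligo, bottomOligo, minOverlap = 6L,
                         name = "annealed") {
  assertNucSequence(topOligo, "top oligo")
  assertNucSequence(bottomOligo, "bottom oligo")
  n <- nchar(topOligo); m <- nchar(bottomOligo)
  B <- revComp(bottomOligo)  # bottom oligo in top-strand orientation
  hits <- integer(0)
  ## shift s = number of unpaired 5' bases on the top oligo; the bottom
  ## oligo's 3' end may not stick out left (that would be a 3' extension),
  ## nor may the top oligo's 3' end stick out right.
  for (s in 0:(n - 1L)) {
    paired <- n - s
    if (s + m < n) next                 # top 3' extension -> invalid
    if (paired < minOverlap) next
    if (substr(topOligo, s + 1L, n) == substr(B, 1L, paired))
      hits <- c(hits, s)
  }
  if (length(hits) == 0L)
    cbStop("annealingError",
           "no valid ungapped antiparallel alignment (>= %d complementary bp, 5' extensions only)",
           minOverlap)
  if (length(hits) > 1L)
    cbStop("ambiguityError",
           "oligos admit %d valid alignments (shifts %s); refusing to guess",
           length(hits), paste(hits, collapse = ", "))
  s <- hits
  leftOv <- substr(topOligo, 1L, s)
  rightLen <- s + m - n
  rightOv <- substr(bottomOligo, 1L, rightLen)  # 5'->3' on the bottom strand
  core <- substr(topOligo, s + 1L, n)
  le <- if (nzchar(leftOv)) stickyEnd("five_prime", leftOv, "top") else bluntEnd()
  re <- if (nzchar(rightOv)) stickyEnd("five_prime", rightOv, "bottom") else bluntEnd()
  duplexFragment(core, "linear", leftEnd = le, rightEnd = re, name = name)
}
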