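# Independent oracles and generators used across the suite. These stay
# deliberately naive and separate from the package's own code paths.

BASES <- c("A", "C", "G", "T")

randomSeq <- function(n) paste(sample(BASES, n, replace = TRUE), collapse = "")

# reverse complement by lookup table + reversal (independent of Biostrings)
oracleRevComp <- function(x) {
  if (!nzchar(x)) return(x)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  paste(rev(comp[strsplit(x, "")[[1]]]), collapse = "")
}

# naive O(n*m) double-strand window scan for a palindromic recognition
# sequence; circular scan crosses the origin
oracleSites <- function(seqchar, recognition, circular = FALSE) {
  m <- nchar(recognition)
  subject <- if (circular) paste0(seqchar, substr(seqchar, 1, m - 1)) else seqchar
  n <- nchar(subject)
  if (n < m) return(integer(0))
  starts <- 1:(n - m + 1)
  hits <- starts[substring(subject, starts, starts + m - 1) == recognition]
  hits[hits <= nchar(seqchar)]
}

# per-strand nucleotide counts of a fragment (top, bottom)
strandCounts <- function(frag) {
  c(top = nchar(topStrand(frag)), bottom = nchar(bottomStrand(frag)))
}

# is `a` a rotation of `b`?
isRotation <- function(a, b) {
  nchar(a) == nchar(b) && grepl(a, paste0(b, b), fixed = TRUE)
}

# a compact platform backbone for high-repetition property tests (the
# full-size defaults are exercised by the reference-construct tests)
compactBackbone <- function(seed = 42L) {
  buildSyntheticBackbone(
    backboneSpec(reporterCdsLength = 120L, fillerLength = 200L, seed = seed),
    name = sprintf("compact_platform_s%d", seed))
}

# random conforming downstream part payload: operator 16-30 nt not starting
# with T, spacer 1-8 nt ending in A, free of the six forbidden sites
randomConformingPart <- function(label = "rand") {
  repeat {
    opLen <- sample(16:30, 1)
    op <- paste0(sample(c("A", "C", "G"), 1), randomSeq(opLen - 1))
    spacer <- paste0(randomSeq(sample(0:7, 1)), "A")
    reg <- regulatorSpec(paste0("R", label), "repressor",
                         paste0("I", label))
    d <- tryCatch(designDownstreamPart(op, spacer, reg,
                                       name = paste0("part_", label)),
                  designError = function(e) NULL)
    if (!is.null(d)) return(d$part)
  }
}

# printed oligonucleotide pairs (fixtures)
PRINTED <- list(
  lacO_top = "GATCGGAATTGTGAGCGGATAACAATTCCAGATCTATCGTAA",
  lacO_bottom = "CGCGTTACGATAGATCTGGAATTGTTATCCGCTCACAATTCC",
  placq_top = "TCGACCGTGACGGATCCTGGTGCAAAACCTTTCGCGGTATGGCATGATAGCGCC",
  placq_bottom = "GATCGGCGCTATCATGCCATACCGCGAAAGGTTTTGCACCAGGATCCGTCACGG",
  primer_bglmlu = "GGAGATCTGTCGGATAACGCGTGAGATTAAAGAGGAGAAATACTAGATG",
  primer_bamsal = "GACAGGATCCAGTCGTCAGTCGACCTCTAGAAGCGGCCGCG"
)
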