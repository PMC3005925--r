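## Built-in parts: the two parts whose oligonucleotides are known exactly,
## plus a synthetic stand-in for the LuxR activator cassette.

## Printed oligonucleotide pairs (Methods of the assembly standard).
LACO_TOP <- "GATCGGAATTGTGAGCGGATAACAATTCCAGATCTATCGTAA"
LACO_BOTTOM <- "CGCGTTACGATAGATCTGGAATTGTTATCCGCTCACAATTCC"
PLACQ_TOP <- "TCGACCGTGACGGATCCTGGTGCAAAACCTTTCGCGGTATGGCATGATAGCGCC"
PLACQ_BOTTOM <- "GATCGGCGCTATCATGCCATACCGCGAAAGGTTTTGCACCAGGATCCGTCACGG"

#' The LacI operator part
#'
#' The downstream-class part carrying the symmetric lac operator: GATC
#' (BamHI-compatible) overhang + lacO + AGATCT + spacer ATCGTAA + CGCG
#' (MluI) overhang, annealed from its two oligonucleotides.
#'
#' @return An \linkS4class{OperatorPart}.
#' @export
lacOperatorPart <- function() {
  d <- designDownstreamPart(
    operatorSeq = "GGAATTGTGAGCGGATAACAATTCC", spacer = "ATCGTAA",
    regulator = regulatorSpec("LacI", "repressor", "IPTG"),
    name = "LacI_operator_part")
  stopifnot(d$topOligo == LACO_TOP, d$bottomOligo == LACO_BOTTOM)
  d$part
}

#' The Placq constitutive promoter part
#'
#' Upstream-class part annealed from its two oligonucleotides: SalI TCGA
#' overhang, the lacq promoter core (a strong constitutive -35/-10 with no
#' operator), and a GATC overhang compatible with BamHI- or BglII-cut ends.
#' It carries one internal BamHI site, which becomes the multi-cloning
#' region's BamHI after insertion.
#'
#' @return An \linkS4class{OperatorPart}.
#' @export
placqPart <- function() {
  frag <- annealOligos(PLACQ_TOP, PLACQ_BOTTOM, name = "Placq")
  frag <- addFeature(frag, "Placq (lacq -35/-10)", "promoter_core",
                     5L, 4L + nchar(frag@core),
                     strength = "strong_constitutive")
  new("OperatorPart", name = "Placq", partClass = "upstream", fragment = frag,
      regulator = NULL, spacer = "",
      carriesPromoterCore = TRUE, carriesExpressionCassette = FALSE)
}

## Synthetic LuxR cassette stand-in (the real activator-cassette sequence
## is not published): a constitutive promoter + RBS + short luxR
## placeholder CDS, the lux box operator, and the weak luxpR -35/-10.
## End geometry is that of an EcoRI x SpeI excision: AATT left overhang
## with the core starting in C (EcoRI regenerates on ligation), CTAG right
## overhang with the core ending in A (the XbaI/SpeI scar is re-cuttable by
## neither enzyme). The literal is free of all seven recognition sites.
LUXR_CASSETTE_CORE <- paste0(
  "C",
  "TTGACAGCTAGCTCAGTCCTAGGTATAATGCTAGC",  # constitutive promoter (cassette)
  "AAAGAGGAGAAA",                          # cassette RBS
  "ATGAAAAACATCAACGCCGACGACACCTACCGCATCATCAACAAAATCAAAACCTGCCGCTAA",  # luxR placeholder CDS
  "TT",
  "ACCTGTAGGATCGTACAGGT",                  # lux box (LuxR operator)
  "TGTTATAGTCGAATAAATGGTATAATCCGGTAT",     # weak luxpR -35/-10 region
  "A"
)

#' The LuxR activator cassette part (synthetic stand-in)
#'
#' A synthetic upstream-class part emulating an EcoRI/SpeI-excised LuxR
#' activator device: a LuxR expression cassette (constitutive promoter,
#' RBS, placeholder luxR CDS), the lux box operator and the weak
#' activator-dependent luxpR promoter core. The true cassette sequence is
#' not available, so this stand-in preserves only the properties the
#' assembly and logic layers depend on: end geometry, site cleanliness and
#' the cassette/operator/promoter anatomy.
#'
#' @return An \linkS4class{OperatorPart}.
#' @export
luxRCassettePartSynthetic <- function() {
  core <- LUXR_CASSETTE_CORE
  frag <- duplexFragment(
    core, "linear",
    leftEnd = stickyEnd("five_prime", "AATT", "top"),
    rightEnd = stickyEnd("five_prime", "CTAG", "bottom"),
    name = "PLuxR_cassette_synthetic")
  lux <- regulatorSpec("LuxR", "activator", "AHL")
  ## virtual coordinates: AATT = 1..4, core from 5
  frag <- addFeature(frag, "LuxR expression cassette (synthetic)",
                     "expression_cassette", 6L, 115L, regulator = "LuxR",
                     mode = "activator", inducer = "AHL")
  frag <- addFeature(frag, "lux box (LuxR operator)", "operator",
                     118L, 137L, regulator = "LuxR", mode = "activator",
                     inducer = "AHL")
  frag <- addFeature(frag, "luxpR weak -35/-10", "promoter_core",
                     138L, 170L, regulator = "LuxR",
                     strength = "weak_activator_dependent")
  new("OperatorPart", name = "PLuxR_cassette", partClass = "upstream",
      fragment = frag, regulator = lux, spacer = "",
      carriesPromoterCore = TRUE, carriesExpressionCassette = TRUE)
}

#' Built-in strain table
#'
#' @return Named list: strain name -> character vector of regulators the
#'   strain expresses (DH5alphaLacI carries a LacI-expressing plasmid;
#'   plain DH5alpha expresses neither regulator).
#' @export
builtinStrains <- function() {
  path <- system.file("extdata", "strains.yaml", package = "cloneBrick",
                      mustWork = TRUE)
  readStrainsFile(path)
}

#' The built-in part library
#'
#' @return A \linkS4class{PartLibrary} with the LacI operator part, the
#'   Placq promoter part and the synthetic LuxR cassette, the builtin
#'   enzyme table and the builtin strains.
#' @export
builtinPartLibrary <- function() {
  parts <- list(
    lacO = lacOperatorPart(),
    Placq = placqPart(),
    PLuxR_cassette = luxRCassettePartSynthetic()
  )
  new("PartLibrary", parts = parts, enzymes = builtinEnzymes(),
      strains = builtinStrains())
}

setMethod("show", "PartLibrary", function(object) {
  cat(sprintf("PartLibrary: %d part(s), %d enzyme(s), %d strain(s)\n",
              length(object@parts), length(object@enzymes),
              length(object@strains)))
  for (nm in names(object@parts)) cat("  part:", nm, "\n")
  invisible(NULL)
})
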