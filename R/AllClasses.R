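## S4 class definitions for the double-stranded DNA model and the part standard.

#' StickyEnd: a terminus of a linear DNA duplex
#'
#' Describes one end of a linear double-stranded fragment: blunt, or a
#' 5' overhang whose protruding single-stranded bases are stored 5'->3' on
#' the protruding strand. For a 5' overhang the protruding strand is fixed by
#' geometry: the left end of a duplex protrudes on the top strand, the right
#' end on the bottom strand. 3' overhangs are representable (reserved kind)
#' but rejected by every operation: no enzyme in scope produces them.
#'
#' @slot kind One of \code{"blunt"}, \code{"five_prime"}, \code{"three_prime"}.
#' @slot overhang Protruding bases, 5'->3' on the protruding strand
#'   (empty iff blunt).
#' @slot protruding Which strand protrudes: \code{"top"}, \code{"bottom"} or
#'   \code{"none"} for blunt ends.
#' @export
setClass("StickyEnd", representation(
  kind = "character", overhang = "character", protruding = "character"
))

setValidity("StickyEnd", function(object) {
  if (!object@kind %in% c("blunt", "five_prime", "three_prime"))
    return("kind must be blunt, five_prime or three_prime")
  if (object@kind == "blunt") {
    if (nzchar(object@overhang)) return("blunt ends carry no overhang")
    if (object@protruding != "none") return("blunt ends have no protruding strand")
  } else {
    if (!nzchar(object@overhang)) return("overhang ends need overhang bases")
    if (grepl("[^ACGT]", object@overhang)) return("overhang outside ACGT")
    if (!object@protruding %in% c("top", "bottom"))
      return("protruding must be top or bottom")
  }
  TRUE
})

#' DuplexFragment: a double-stranded DNA molecule
#'
#' Exact representation of a linear or circular duplex. The fully base-paired
#' region ("core") is stored as its top strand 5'->3'; the bottom strand is
#' always derivable as the reverse complement. Linear molecules additionally
#' carry a \linkS4class{StickyEnd} at each terminus; overhang bases belong to
#' exactly one strand and are not part of the core. Circular molecules have
#' no ends.
#'
#' Annotations live in a feature table (label, role, start, end plus regulator
#' metadata) in 1-based inclusive coordinates on the \emph{virtual} top strand
#' returned by \code{\link{virtualSeq}}: left overhang + core + the top-strand
#' image of the right overhang. Junction (ligation scar) records accumulate in
#' the \code{junctions} table.
#'
#' @slot name Molecule name.
#' @slot core Top strand of the double-stranded core, 5'->3'.
#' @slot topology \code{"linear"} or \code{"circular"}.
#' @slot leftEnd,rightEnd \linkS4class{StickyEnd} objects (blunt placeholders
#'   on circular molecules).
#' @slot features Feature annotation table.
#' @slot junctions Ligation-scar table (position, sealed window, re-cutting
#'   enzymes).
#' @export
setClass("DuplexFragment", representation(
  name = "character", core = "character", topology = "character",
  leftEnd = "StickyEnd", rightEnd = "StickyEnd",
  features = "data.frame", junctions = "data.frame"
))

setValidity("DuplexFragment", function(object) {
  if (!nzchar(object@core)) return("core must be non-empty")
  if (grepl("[^ACGT]", object@core)) return("core outside ACGT")
  if (!object@topology %in% c("linear", "circular"))
    return("topology must be linear or circular")
  if (object@topology == "circular") {
    if (object@leftEnd@kind != "blunt" || object@rightEnd@kind != "blunt")
      return("circular molecules have no ends")
  } else {
    if (object@leftEnd@kind == "five_prime" && object@leftEnd@protruding != "top")
      return("a left 5' overhang protrudes on the top strand")
    if (object@rightEnd@kind == "five_prime" && object@rightEnd@protruding != "bottom")
      return("a right 5' overhang protrudes on the bottom strand")
  }
  f <- object@features
  if (nrow(f)) {
    L <- nchar(object@core) +
      (if (object@topology == "linear")
         nchar(object@leftEnd@overhang) + nchar(object@rightEnd@overhang) else 0L)
    if (any(f$start < 1L) || any(f$end > L) || any(f$start > f$end))
      return("feature coordinates out of range")
    if (!all(f$role %in% FEATURE_ROLES)) return("unknown feature role")
  }
  TRUE
})

#' Enzyme: a palindromic type-II restriction enzyme
#'
#' @slot name Enzyme name (e.g. "BglII").
#' @slot recognition Palindromic recognition sequence (equals its own
#'   reverse complement), length 6-8.
#' @slot cutOffsetTop Bases from the recognition start to the top-strand cut;
#'   the symmetric bottom cut leaves a 5' overhang of length
#'   \code{nchar(recognition) - 2 * cutOffsetTop}.
#' @export
setClass("Enzyme", representation(
  name = "character", recognition = "character", cutOffsetTop = "integer"
))

setValidity("Enzyme", function(object) {
  r <- object@recognition
  if (nchar(r) < 6 || nchar(r) > 8) return("recognition length must be 6-8")
  if (grepl("[^ACGT]", r)) return("recognition outside ACGT")
  if (r != revComp(r)) return("recognition must be palindromic")
  o <- object@cutOffsetTop
  if (o < 0 || o >= nchar(r) / 2)
    return("cut offset must satisfy 0 <= offset < recognition length / 2")
  TRUE
})

#' RegulatorSpec: a transcription regulator archetype
#'
#' Exactly the two induction archetypes in scope are supported: a repressor
#' whose inducer releases it from the operator (LacI/IPTG style) and an
#' activator whose inducer enables DNA binding (LuxR/AHL style). Other
#' regulation logics are rejected loudly rather than half-supported.
#'
#' @slot name Regulator name (e.g. "LacI").
#' @slot mode \code{"repressor"} or \code{"activator"}.
#' @slot inducer Inducer name (e.g. "IPTG").
#' @slot inducerEffect \code{"releases_repressor"} or
#'   \code{"enables_activator"}; forced by \code{mode}.
#' @export
setClass("RegulatorSpec", representation(
  name = "character", mode = "character", inducer = "character",
  inducerEffect = "character"
))

setValidity("RegulatorSpec", function(object) {
  if (!object@mode %in% c("repressor", "activator"))
    return("mode must be repressor or activator")
  want <- if (object@mode == "repressor") "releases_repressor" else "enables_activator"
  if (object@inducerEffect != want)
    return(sprintf("a %s requires inducerEffect '%s'", object@mode, want))
  if (!nzchar(object@name) || !nzchar(object@inducer))
    return("name and inducer must be non-empty")
  TRUE
})

#' OperatorPart: a standardized insertable fragment
#'
#' Wraps the annealed \linkS4class{DuplexFragment} of a part together with its
#' regulator metadata (which travels in a sidecar file, never inferred from
#' sequence). Downstream-class parts carry a GATC (BamHI-compatible) left end,
#' the operator, an internal BglII site, a spacer and a CGCG (MluI) right end;
#' upstream-class parts use one of the sanctioned upstream end pairs.
#'
#' @slot name Part name.
#' @slot partClass \code{"downstream"} or \code{"upstream"}.
#' @slot fragment The annealed duplex.
#' @slot regulator \linkS4class{RegulatorSpec} bound by the operator (may be
#'   a promoter-only part with no operator).
#' @slot spacer Spacer sequence between the part's BglII site and the MluI end.
#' @slot carriesPromoterCore,carriesExpressionCassette Payload flags.
#' @export
setClass("OperatorPart", representation(
  name = "character", partClass = "character", fragment = "DuplexFragment",
  regulator = "ANY", spacer = "character",
  carriesPromoterCore = "logical", carriesExpressionCassette = "logical"
))

setValidity("OperatorPart", function(object) {
  if (!object@partClass %in% c("downstream", "upstream"))
    return("partClass must be downstream or upstream")
  if (!is.null(object@regulator) && !is(object@regulator, "RegulatorSpec"))
    return("regulator must be NULL or a RegulatorSpec")
  TRUE
})

#' PlatformReport: result of a standard-conformance validation
#'
#' @slot conforms TRUE iff every mandatory check passed.
#' @slot findings Table with columns check, status
#'   ("pass"/"fail"/"superseded"), detail. "superseded" marks upstream
#'   multi-cloning-region checks that stop being mandatory once a promoter
#'   part occupies the region.
#' @export
setClass("PlatformReport", representation(
  conforms = "logical", findings = "data.frame"
))

#' RegulatoryModel: Boolean transcription model of a regulatory region
#'
#' @slot promoter List with elements \code{strength}
#'   (strong_constitutive / weak_activator_dependent / absent),
#'   \code{linkedRegulator} (activator name or NA) and \code{label}.
#' @slot operators Table of operators 5'->3' (regulator, mode, inducer,
#'   position relative to the promoter core, start coordinate).
#' @slot regulators Names of regulators available in the host (strain
#'   background plus plasmid-borne expression cassettes).
#' @slot regulatorSpecs Named list of \linkS4class{RegulatorSpec} for every
#'   regulator the model mentions.
#' @export
setClass("RegulatoryModel", representation(
  promoter = "list", operators = "data.frame", regulators = "character",
  regulatorSpecs = "list"
))

#' TruthTable: complete Boolean input/output map of a model
#'
#' @slot inputs Ordered inducer names.
#' @slot rows Table with one logical column per inducer, a \code{combo} key
#'   and the \code{output} ("ON"/"OFF") of every one of the 2^n input states.
#' @slot gate Gate classification label.
#' @export
setClass("TruthTable", representation(
  inputs = "character", rows = "data.frame", gate = "character"
))

#' BackboneSpec: parameters of the synthetic reporter backbone
#'
#' The published reporter plasmid map is unavailable; the backbone generator
#' builds a synthetic stand-in from the engineered-region sequences plus a
#' seeded, recognition-site-free filler. See \code{\link{backboneSpec}}.
#'
#' @slot mcsSequence Upstream multi-cloning region (top strand, after the
#'   EcoRI site).
#' @slot downstreamSequence Downstream standard region; embeds exactly one
#'   AGATCT then one ACGCGT.
#' @slot rbsToCds Ribosome-binding-site region; ends in ATG (the CDS start).
#' @slot reporterCdsLength Length of the generated reporter CDS (nt,
#'   multiple of 3, includes start and stop codons).
#' @slot fillerLength Length of the generated origin/marker filler (nt).
#' @slot seed Integer seed controlling the generated portions.
#' @export
setClass("BackboneSpec", representation(
  mcsSequence = "character", downstreamSequence = "character",
  rbsToCds = "character", reporterCdsLength = "integer",
  fillerLength = "integer", seed = "integer"
))

setValidity("BackboneSpec", function(object) {
  d <- object@downstreamSequence
  if (countOccurrences(d, "AGATCT") != 1L || countOccurrences(d, "ACGCGT") != 1L)
    return("downstream sequence must embed exactly one AGATCT and one ACGCGT")
  if (allOccurrences(d, "AGATCT")[1L] > allOccurrences(d, "ACGCGT")[1L])
    return("AGATCT must precede ACGCGT in the downstream sequence")
  if (!endsWith(object@rbsToCds, "ATG"))
    return("rbsToCds must end in ATG")
  if (object@reporterCdsLength %% 3L != 0L || object@reporterCdsLength < 6L)
    return("reporterCdsLength must be a positive multiple of 3")
  if (object@fillerLength < 0L) return("fillerLength must be >= 0")
  TRUE
})

#' PartLibrary: a named collection of parts, enzymes and strains
#'
#' @slot parts Named list of \linkS4class{OperatorPart}.
#' @slot enzymes Named list of \linkS4class{Enzyme} (defaults to the builtin
#'   table).
#' @slot strains Named list mapping strain name to the character vector of
#'   regulators the strain expresses.
#' @export
setClass("PartLibrary", representation(
  parts = "list", enzymes = "list", strains = "list"
))

setValidity("PartLibrary", function(object) {
  if (length(object@parts) && is.null(names(object@parts)))
    return("parts must be named")
  if (anyDuplicated(names(object@parts))) return("part names must be unique")
  if (anyDuplicated(names(object@strains))) return("strain names must be unique")
  TRUE
})
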