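## Design and validation of standardized operator parts.

#' Construct a regulator specification
#'
#' @param name Regulator name (e.g. "LacI", "LuxR").
#' @param mode "repressor" (inducer releases it from the operator) or
#'   "activator" (inducer enables DNA binding).
#' @param inducer Inducer name (e.g. "IPTG", "AHL").
#' @return A \linkS4class{RegulatorSpec}; the inducer effect is derived from
#'   the mode.
#' @examples
#' regulatorSpec("LacI", "repressor", "IPTG")
#' @export
regulatorSpec <- function(name, mode = c("repressor", "activator"), inducer) {
  mode <- match.arg(mode)
  new("RegulatorSpec", name = name, mode = mode, inducer = inducer,
      inducerEffect = if (mode == "repressor") "releases_repressor"
                      else "enables_activator")
}

setMethod("show", "RegulatorSpec", function(object) {
  cat(sprintf("RegulatorSpec %s: %s, inducer %s (%s)\n", object@name,
              object@mode, object@inducer, object@inducerEffect))
  invisible(NULL)
})

## Enzymes whose sites may not appear inside downstream-part payloads: the
## four multi-cloning-region enzymes plus the two downstream-region enzymes.
DOWNSTREAM_FORBIDDEN <- c("EcoRI", "XbaI", "SalI", "BamHI", "BglII", "MluI")

#' Design a downstream operator part
#'
#' Builds the oligonucleotide pair whose annealed duplex is a conforming
#' downstream part: a BamHI-compatible GATC 5' overhang, the operator, an
#' internal BglII site (AGATCT), a spacer, and an MluI CGCG 5' overhang:
#' \preformatted{top    = GATC + operator + AGATCT + spacer
#' bottom = CGCG + revComp(operator + AGATCT + spacer)}
#'
#' Two sequence rules guarantee the platform invariants on religation:
#' the part core must end in A (the base that, sealed against the backbone's
#' CGCG overhang and flanking T, rebuilds the MluI site ACGCGT), and the
#' operator may not begin with T (which would rebuild AGATCT across the
#' BamHI/BglII joint and duplicate the BglII site). Payloads containing any
#' of the six platform recognition sites are refused by name.
#'
#' @param operatorSeq Operator (regulator binding site) sequence.
#' @param spacer Spacer between the BglII site and the MluI end. Under the
#'   default rules it must end in A (an empty spacer leaves the core ending
#'   in AGATCT's T and is refused).
#' @param regulator A \linkS4class{RegulatorSpec}.
#' @param name Part name.
#' @param enforceMluIRestore Enforce the terminal-A rule (default). Setting
#'   this to FALSE builds the part by formula anyway; the resulting product
#'   of an insertion will lack a downstream MluI site and fail platform
#'   validation.
#' @return List with \code{topOligo}, \code{bottomOligo} and \code{part}
#'   (an \linkS4class{OperatorPart} whose fragment is the annealed duplex,
#'   with the operator annotated).
#' @examples
#' d <- designDownstreamPart("GGAATTGTGAGCGGATAACAATTCC", "ATCGTAA",
#'                           regulatorSpec("LacI", "repressor", "IPTG"))
#' d$topOligo
#' @export
designDownstreamPart <- function(operatorSeq, spacer, regulator,
                                 name = paste0(regulator@name, "_operator_part"),
                                 enforceMluIRestore = TRUE) {
  assertNucSequence(operatorSeq, "operator sequence")
  assertNucSequence(spacer, "spacer", allowEmpty = TRUE)
  if (!is(regulator, "RegulatorSpec"))
    cbStop("typeError", "regulator must be a RegulatorSpec")
  enzymes <- builtinEnzymes()
  core <- paste0(operatorSeq, "AGATCT", spacer)
  for (nm in DOWNSTREAM_FORBIDDEN) {
    rec <- enzymes[[nm]]@recognition
    limit <- if (nm == "BglII") 1L else 0L
    n <- countOccurrences(core, rec)
    if (n > limit)
      cbStop("designError",
             "payload would carry %d internal %s site(s) (%s); forbidden by the standard",
             n - limit, nm, rec)
  }
  if (startsWith(operatorSeq, "T"))
    cbStop("designError",
           "operator may not begin with T: religation would rebuild AGATCT across the BamHI/BglII joint")
  if (enforceMluIRestore && !endsWith(core, "A"))
    cbStop("designError",
           "part core must end in A to rebuild the MluI site (ACGCGT) on religation; use a spacer ending in A")
  topOligo <- paste0("GATC", core)
  bottomOligo <- paste0("CGCG", revComp(core))
  frag <- annealOligos(topOligo, bottomOligo, name = name)
  frag <- addFeature(frag, paste0(regulator@name, " operator"), "operator",
                     5L, 4L + nchar(operatorSeq),
                     regulator = regulator@name, mode = regulator@mode,
                     inducer = regulator@inducer)
  part <- new("OperatorPart", name = name, partClass = "downstream",
              fragment = frag, regulator = regulator, spacer = spacer,
              carriesPromoterCore = FALSE, carriesExpressionCassette = FALSE)
  list(topOligo = topOligo, bottomOligo = bottomOligo, part = part)
}

#' Validate a downstream operator part
#'
#' Checks the anatomy a downstream part must have to keep the platform's
#' repeat-insertion guarantee: (1) left 5' overhang GATC protruding on the
#' top strand, (2) right 5' overhang CGCG protruding on the bottom strand,
#' (3) exactly one internal AGATCT (the replacement BglII site), (4) no
#' internal ACGCGT, (5) the operator annotation, when present, lies 5' of
#' the BglII site, and (6) the core ends in A so the MluI site is rebuilt on
#' religation. Failures are report findings, not errors.
#'
#' @param part A linear \linkS4class{DuplexFragment} or
#'   \linkS4class{OperatorPart}.
#' @return A \linkS4class{PlatformReport}.
#' @export
validateDownstreamPart <- function(part) {
  if (is(part, "OperatorPart")) part <- part@fragment
  if (!is(part, "DuplexFragment") || isCircular(part))
    cbStop("typeError", "part must be a linear DuplexFragment")
  f <- list()
  add <- function(check, ok, detail)
    f[[length(f) + 1L]] <<- data.frame(check = check,
                                       status = if (ok) "pass" else "fail",
                                       detail = detail, stringsAsFactors = FALSE)
  le <- part@leftEnd; re <- part@rightEnd
  add("left_end_GATC",
      le@kind == "five_prime" && le@overhang == "GATC" && le@protruding == "top",
      sprintf("left end: %s '%s' (%s)", le@kind, le@overhang, le@protruding))
  add("right_end_CGCG",
      re@kind == "five_prime" && re@overhang == "CGCG" && re@protruding == "bottom",
      sprintf("right end: %s '%s' (%s)", re@kind, re@overhang, re@protruding))
  nBgl <- countOccurrences(part@core, "AGATCT")
  add("one_internal_BglII", nBgl == 1L, sprintf("%d internal AGATCT", nBgl))
  nMlu <- countOccurrences(part@core, "ACGCGT")
  add("no_internal_MluI", nMlu == 0L, sprintf("%d internal ACGCGT", nMlu))
  ops <- part@features[part@features$role == "operator", , drop = FALSE]
  if (nrow(ops) && nBgl >= 1L) {
    bgl <- allOccurrences(virtualSeq(part), "AGATCT")[1L]
    add("operator_before_BglII", all(ops$end < bgl),
        sprintf("operator ends %s, BglII at %d",
                paste(ops$end, collapse = ","), bgl))
  } else {
    add("operator_before_BglII", TRUE,
        if (nrow(ops)) "no BglII site to compare" else
          "no operator annotation to verify (metadata travels in the part file)")
  }
  add("core_ends_in_A", endsWith(part@core, "A"),
      sprintf("core ends in %s", substr(part@core, nchar(part@core), nchar(part@core))))
  findings <- do.call(rbind, c(f, list(make.row.names = FALSE)))
  new("PlatformReport", conforms = all(findings$status == "pass"),
      findings = findings)
}

setMethod("show", "PlatformReport", function(object) {
  cat(sprintf("PlatformReport: %s\n",
              if (object@conforms) "conforms" else "DOES NOT conform"))
  for (i in seq_len(nrow(object@findings)))
    cat(sprintf("  [%s] %s: %s\n", object@findings$status[i],
                object@findings$check[i], object@findings$detail[i]))
  invisible(NULL)
})

setMethod("show", "OperatorPart", function(object) {
  cat(sprintf("OperatorPart '%s' (%s class, %d nt)\n", object@name,
              object@partClass, fragmentLength(object@fragment)))
  if (!is.null(object@regulator))
    cat(sprintf("  regulator: %s (%s, inducer %s)\n", object@regulator@name,
                object@regulator@mode, object@regulator@inducer))
  if (object@carriesPromoterCore) cat("  carries a promoter core\n")
  if (object@carriesExpressionCassette) cat("  carries an expression cassette\n")
  invisible(NULL)
})
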