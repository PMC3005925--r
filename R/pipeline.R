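## The reference construction pipeline: from the synthetic backbone to the
## two-input AND-gate plasmid, reproducing every named construct.

#' Extract the downstream standard region sequence of a plasmid
#'
#' @param plasmid Annotated circular \linkS4class{DuplexFragment}.
#' @return The top-strand sequence of the downstream_region feature.
#' @export
downstreamRegionSeq <- function(plasmid) {
  f <- plasmid@features[plasmid@features$role == "downstream_region", ,
                        drop = FALSE]
  if (nrow(f) != 1L)
    cbStop("annotationError", "expected one downstream_region feature, found %d",
           nrow(f))
  substr(virtualSeq(plasmid), f$start[1L], f$end[1L])
}

#' Extract the upstream multi-cloning region sequence of a plasmid
#'
#' @param plasmid Annotated circular \linkS4class{DuplexFragment}.
#' @return The top-strand sequence of the mcs_upstream feature.
#' @export
upstreamRegionSeq <- function(plasmid) {
  f <- plasmid@features[plasmid@features$role == "mcs_upstream", , drop = FALSE]
  if (nrow(f) != 1L)
    cbStop("annotationError", "expected one mcs_upstream feature, found %d",
           nrow(f))
  substr(virtualSeq(plasmid), f$start[1L], f$end[1L])
}

#' Build the full set of reference plasmids
#'
#' Constructs, by simulated digestion and ligation only, the six named
#' plasmids: the promoterless reporter backbone; the constitutive control
#' (Placq promoter part inserted upstream); the single and tandem LacI
#' operator insertions; the LuxR activator construct (synthetic cassette
#' inserted via EcoRI/XbaI); and the AND gate (two LacI operator parts
#' inserted sequentially downstream of the LuxR construct).
#'
#' The Placq part is inserted via the (SalI, BamHI) route, which leaves the
#' downstream BglII/MluI pair intact (see the vignette for why the
#' (SalI, BglII) route cannot yield a re-insertable platform under complete
#' digestion).
#'
#' @param seed Seed for the synthetic backbone's generated portions.
#' @return Named list of circular \linkS4class{DuplexFragment}s.
#' @export
buildReferencePlasmids <- function(seed = 1L) {
  lib <- builtinPartLibrary()
  psb <- buildSyntheticBackbone(backboneSpec(seed = seed), name = "pSB-GFP")
  placqGfp <- insertUpstream(psb, lib@parts$Placq, c("SalI", "BamHI"),
                             name = "Placq-GFP")
  placqLacI <- insertDownstream(placqGfp, lib@parts$lacO,
                                name = "Placq-LacI-GFP")
  placqTandem <- insertDownstream(placqLacI, lib@parts$lacO,
                                  name = "Placq-LacItandem-GFP")
  pluxr <- insertUpstream(psb, lib@parts$PLuxR_cassette, c("EcoRI", "XbaI"),
                          name = "PLuxR-GFP")
  pluxrLacI <- insertDownstream(pluxr, lib@parts$lacO,
                                name = "PLuxR-LacI-GFP")
  pluxrTandem <- insertDownstream(pluxrLacI, lib@parts$lacO,
                                  name = "PLuxR-LacItandem-GFP")
  list(`pSB-GFP` = psb, `Placq-GFP` = placqGfp,
       `Placq-LacI-GFP` = placqLacI, `Placq-LacItandem-GFP` = placqTandem,
       `PLuxR-GFP` = pluxr, `PLuxR-LacItandem-GFP` = pluxrTandem)
}

#' Run the full AND-gate construction and simulation pipeline
#'
#' Builds the reference plasmids, derives the truth table of each under the
#' given strain background, and optionally writes GenBank records plus the
#' AND-gate truth table as JSON. Deterministic: the same seed yields
#' byte-identical outputs.
#'
#' @param strain Strain name from the strain table ("DH5alphaLacI" or
#'   "DH5alpha" builtin).
#' @param seed Backbone generation seed.
#' @param outdir Optional output directory for GenBank + JSON files.
#' @param strains Strain table (defaults to \code{\link{builtinStrains}}).
#' @return Invisibly, a list with \code{plasmids}, \code{tables} (named
#'   \linkS4class{TruthTable}s) and \code{json} (the AND-gate truth table
#'   as a JSON string).
#' @export
makeAndGate <- function(strain = "DH5alphaLacI", seed = 1L, outdir = NULL,
                        strains = builtinStrains()) {
  if (!strain %in% names(strains))
    cbStop("argumentError", "unknown strain '%s' (known: %s)", strain,
           paste(names(strains), collapse = ", "))
  regs <- strains[[strain]]
  plasmids <- buildReferencePlasmids(seed = seed)
  for (p in plasmids[-1L]) {
    rep <- validatePlatform(p)
    if (!rep@conforms)
      cbStop("standardViolationError", "plasmid '%s' failed validation", p@name)
  }
  tables <- lapply(plasmids, function(p)
    truthTable(extractRegulatoryModel(p, regs)))
  json <- jsonlite::toJSON(
    truthTableAsList(tables[["PLuxR-LacItandem-GFP"]]),
    auto_unbox = TRUE, pretty = TRUE)
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    for (nm in names(plasmids))
      writeGenBank(plasmids[[nm]], file.path(outdir, paste0(nm, ".gb")))
    writeLines(json, file.path(outdir, "and_gate_truth_table.json"))
  }
  invisible(list(plasmids = plasmids, tables = tables, json = as.character(json)))
}
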