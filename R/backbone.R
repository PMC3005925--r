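## Synthetic reporter backbone: a stand-in for the unpublished reporter
## plasmid, built around the two engineered-region sequences (the
## downstream-standard/RBS region and the upstream multi-cloning region)
## plus seeded, recognition-site-free generated portions for the reporter
## CDS body and the origin/marker filler.

## Upstream multi-cloning region, top strand (reverse complement of the
## engineered-region mutagenesis primer): NotI-XbaI-SalI-BamHI after the
## EcoRI site. The NotI site is preserved but NotI is not in the enzyme
## table (never used by the standard).
MCS_PLUS_DEFAULT <- "CGCGGCCGCTTCTAGAGGTCGACTGACGACTGGATCCTGTC"
DOWNSTREAM_DEFAULT <- "GGAGATCTGTCGGATAACGCGT"
RBS_TO_CDS_DEFAULT <- "GAGATTAAAGAGGAGAAATACTAGATG"

#' Parameters for the synthetic reporter backbone
#'
#' Defaults reproduce the standardized regulatory region exactly (EcoRI
#' site, multi-cloning region, BglII/MluI downstream standard region, RBS,
#' reporter CDS start) and fill the rest of the plasmid with a seeded
#' random sequence kept free of all seven recognition sites. The default
#' reporter CDS length (720 nt) matches a GFP-sized reporter; the default
#' filler (2000 nt) stands in for the replication origin and resistance
#' marker of a small reporter plasmid (~2.8 kb total).
#'
#' @param mcsSequence Upstream multi-cloning region (after the EcoRI site).
#' @param downstreamSequence Downstream standard region (one AGATCT, then
#'   one ACGCGT).
#' @param rbsToCds RBS region ending in the CDS start codon ATG.
#' @param reporterCdsLength Total reporter CDS length (nt, multiple of 3).
#' @param fillerLength Generated filler length (nt).
#' @param seed Integer seed for the generated portions.
#' @return A \linkS4class{BackboneSpec}.
#' @export
backboneSpec <- function(mcsSequence = MCS_PLUS_DEFAULT,
                         downstreamSequence = DOWNSTREAM_DEFAULT,
                         rbsToCds = RBS_TO_CDS_DEFAULT,
                         reporterCdsLength = 720L,
                         fillerLength = 2000L,
                         seed = 1L) {
  new("BackboneSpec", mcsSequence = mcsSequence,
      downstreamSequence = downstreamSequence, rbsToCds = rbsToCds,
      reporterCdsLength = as.integer(reporterCdsLength),
      fillerLength = as.integer(fillerLength), seed = as.integer(seed))
}

## Generate n random bases none of which completes a recognition site, given
## up to 5 bases of preceding context. The seven recognitions have pairwise
## distinct 5-base prefixes, so at most one base is ever forbidden and a
## valid base always exists.
generateSiteFree <- function(n, context = "", recognitions) {
  if (n <= 0L) return("")
  out <- character(n)
  ctx <- context
  for (i in seq_len(n)) {
    repeat {
      b <- sample(DNA_ALPHABET, 1L)
      window <- paste0(substr(ctx, max(1L, nchar(ctx) - 4L), nchar(ctx)), b)
      if (!any(vapply(recognitions, function(r)
        endsWith(window, r) || (nchar(window) >= 6L &&
          substr(window, nchar(window) - 5L, nchar(window)) == r),
        logical(1)))) break
    }
    out[i] <- b
    ctx <- paste0(substr(ctx, max(1L, nchar(ctx) - 9L), nchar(ctx)), b)
  }
  paste(out, collapse = "")
}

#' Build the synthetic reporter backbone
#'
#' Assembles the circular promoterless reporter plasmid: EcoRI site +
#' multi-cloning region + downstream standard region + RBS + reporter CDS
#' (ATG from the RBS region, generated body, TAA) + generated filler. The
#' generated portions are seeded and kept free of every recognition site in
#' the enzyme table; the assembled plasmid is verified to carry exactly one
#' site for each of EcoRI, XbaI, SalI, BamHI, BglII and MluI and none for
#' SpeI, with bounded retries if a site arises across a segment boundary.
#' The result is annotated (mcs_upstream, downstream_region, rbs, cds) and
#' passes \code{\link{validatePlatform}}.
#'
#' @param spec A \linkS4class{BackboneSpec}.
#' @param name Plasmid name.
#' @param maxRetries Retry bound for whole-plasmid site verification.
#' @return A circular annotated \linkS4class{DuplexFragment}.
#' @examples
#' bb <- buildSyntheticBackbone(backboneSpec(seed = 1))
#' validatePlatform(bb)@conforms
#' @export
buildSyntheticBackbone <- function(spec = backboneSpec(), name = "pSB-GFP",
                                   maxRetries = 1000L) {
  validObject(spec)
  enz <- builtinEnzymes()
  recs <- vapply(enz, function(e) e@recognition, character(1))
  expected <- c(EcoRI = 1L, XbaI = 1L, SalI = 1L, BamHI = 1L, BglII = 1L,
                MluI = 1L, SpeI = 0L)
  fixed <- paste0("GAATTC", spec@mcsSequence, spec@downstreamSequence,
                  spec@rbsToCds)
  bodyLen <- spec@reporterCdsLength - 6L  # ATG supplied by rbsToCds, TAA added
  withSeed(spec@seed, {
    for (attempt in seq_len(maxRetries)) {
      body <- generateSiteFree(bodyLen, context = fixed, recs)
      cdsRest <- paste0(body, "TAA")
      filler <- generateSiteFree(spec@fillerLength,
                                 context = paste0(fixed, cdsRest), recs)
      seqFull <- paste0(fixed, cdsRest, filler)
      plasmid <- duplexFragment(seqFull, "circular", name = name)
      counts <- vapply(names(expected), function(nm)
        length(findSites(plasmid, enz[[nm]])$positions), integer(1))
      if (identical(unname(counts), unname(expected))) {
        ok <- plasmid
        break
      }
      ok <- NULL
    }
    if (is.null(ok))
      cbStop("generationError",
             "could not generate a site-clean backbone in %d attempts", maxRetries)
    mcsEnd <- 6L + nchar(spec@mcsSequence)
    dsEnd <- mcsEnd + nchar(spec@downstreamSequence)
    rbsEnd <- dsEnd + nchar(spec@rbsToCds) - 3L   # up to the base before ATG
    cdsStart <- rbsEnd + 1L
    cdsEnd <- cdsStart + spec@reporterCdsLength - 1L
    ok <- addFeature(ok, "upstream multi-cloning region", "mcs_upstream",
                     1L, mcsEnd)
    ok <- addFeature(ok, "downstream standard region", "downstream_region",
                     mcsEnd + 1L, dsEnd)
    ok <- addFeature(ok, "RBS", "rbs", dsEnd + 1L, rbsEnd)
    ok <- addFeature(ok, "gfp reporter (synthetic placeholder)", "cds",
                     cdsStart, cdsEnd)
    ok
  })
}
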