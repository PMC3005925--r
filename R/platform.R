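## Platform-level validation and the standardized insertion entry points.

siteStartsIn <- function(positions, span, m) {
  positions[positions >= span[1L] & (positions + m - 1L) <= span[2L]]
}

#' Validate a plasmid against the standardized-platform layout
#'
#' The platform divides the regulatory region of the reporter plasmid into
#' an upstream multi-cloning region (EcoRI, XbaI, SalI, BamHI; one site
#' each) and a downstream standard region (exactly one BglII site 5' of
#' exactly one MluI site), with the ribosome-binding site between the MluI
#' site and the reporter CDS. BglII/MluI sites anywhere outside the
#' downstream region break the repeat-insertion guarantee and are always
#' failures.
#'
#' Once a promoter part occupies the upstream region (a promoter_core
#' feature is annotated) the four multi-cloning-region site checks stop
#' being mandatory: inserting a promoter legitimately consumes or rebuilds
#' upstream sites (e.g. an XbaI/SpeI scar is re-cuttable by neither enzyme).
#' Such checks are reported with status "superseded".
#'
#' @param plasmid A circular annotated \linkS4class{DuplexFragment} with
#'   mcs_upstream, downstream_region, rbs and cds features.
#' @return A \linkS4class{PlatformReport}; \code{conforms} is TRUE iff all
#'   mandatory checks pass.
#' @export
validatePlatform <- function(plasmid) {
  if (!is(plasmid, "DuplexFragment") || !isCircular(plasmid))
    cbStop("typeError", "plasmid must be a circular DuplexFragment")
  feats <- plasmid@features
  need <- c("mcs_upstream", "downstream_region", "rbs", "cds")
  missing <- setdiff(need, feats$role)
  if (length(missing))
    cbStop("annotationError", "plasmid lacks required annotation(s): %s",
           paste(missing, collapse = ", "))
  span <- function(role) {
    f <- feats[feats$role == role, , drop = FALSE]
    c(min(f$start), max(f$end))
  }
  mcs <- span("mcs_upstream"); ds <- span("downstream_region")
  rbs <- span("rbs"); cds <- span("cds")
  enz <- builtinEnzymes()
  promoterPresent <- "promoter_core" %in% feats$role
  f <- list()
  add <- function(check, ok, detail, mandatory = TRUE)
    f[[length(f) + 1L]] <<- data.frame(
      check = check,
      status = if (ok) "pass" else if (mandatory) "fail" else "superseded",
      detail = detail, stringsAsFactors = FALSE)
  for (nm in c("EcoRI", "XbaI", "SalI", "BamHI")) {
    pos <- findSites(plasmid, enz[[nm]])$positions
    inMcs <- siteStartsIn(pos, mcs, nchar(enz[[nm]]@recognition))
    add(paste0("mcs_", nm), length(inMcs) == 1L,
        sprintf("%d %s site(s) in the upstream multi-cloning region%s",
                length(inMcs), nm,
                if (promoterPresent) " (promoter part installed)" else ""),
        mandatory = !promoterPresent)
  }
  for (nm in c("BglII", "MluI")) {
    pos <- findSites(plasmid, enz[[nm]])$positions
    m <- nchar(enz[[nm]]@recognition)
    inDs <- siteStartsIn(pos, ds, m)
    add(paste0("downstream_", nm), length(inDs) == 1L,
        sprintf("%d %s site(s) in the downstream standard region", length(inDs), nm))
    outside <- setdiff(pos, inDs)
    add(paste0("no_stray_", nm), length(outside) == 0L,
        sprintf("%d %s site(s) outside the downstream region", length(outside), nm))
  }
  bgl <- siteStartsIn(findSites(plasmid, enz$BglII)$positions, ds, 6L)
  mlu <- siteStartsIn(findSites(plasmid, enz$MluI)$positions, ds, 6L)
  add("BglII_before_MluI",
      length(bgl) == 1L && length(mlu) == 1L && bgl < mlu,
      sprintf("BglII at %s, MluI at %s",
              paste(bgl, collapse = ","), paste(mlu, collapse = ",")))
  mluEnd <- if (length(mlu) == 1L) mlu + 5L else ds[2L]
  add("rbs_between_MluI_and_cds",
      mluEnd < rbs[1L] && rbs[2L] < cds[1L],
      sprintf("MluI ends %d, rbs %d..%d, cds starts %d",
              mluEnd, rbs[1L], rbs[2L], cds[1L]))
  findings <- do.call(rbind, c(f, list(make.row.names = FALSE)))
  new("PlatformReport", conforms = all(findings$status != "fail"),
      findings = findings)
}

#' Insert an operator part into the downstream standard region
#'
#' The core operation of the assembly standard: the plasmid is digested
#' with BglII and MluI, the stuffer between them discarded, and the part
#' ligated in via its BamHI-compatible GATC end (sealing the BglII cut into
#' a joint re-cuttable by neither enzyme) and its MluI end (rebuilding
#' ACGCGT). The part's internal AGATCT becomes the product's new downstream
#' BglII site, so the operation can be repeated; each new operator lands 3'
#' of all previously inserted operators and 5' of the ribosome-binding
#' site. Both the plasmid and the part must conform to the standard before
#' insertion, and the product is re-validated.
#'
#' @param plasmid Conforming circular platform plasmid.
#' @param part Conforming downstream \linkS4class{OperatorPart} (or bare
#'   fragment).
#' @param name Product name.
#' @return The product plasmid.
#' @export
insertDownstream <- function(plasmid, part, name = NULL) {
  vp <- validatePlatform(plasmid)
  if (!vp@conforms)
    cbStop("standardViolationError",
           "plasmid '%s' does not conform to the platform standard", plasmid@name)
  pr <- validateDownstreamPart(part)
  if (!pr@conforms)
    cbStop("standardViolationError",
           "part does not conform to the downstream part standard")
  product <- insertPart(plasmid, part, list("BglII", "MluI"), name = name)
  out <- validatePlatform(product)
  if (!out@conforms)
    cbStop("standardViolationError",
           "internal error: insertion product fails platform validation")
  product
}

UPSTREAM_PAIRS <- list(
  c("SalI", "BglII"), c("SalI", "BamHI"), c("EcoRI", "XbaI")
)

#' Insert a promoter/operator part into the upstream multi-cloning region
#'
#' Opens the plasmid with one of the sanctioned upstream enzyme pairs and
#' ligates a compatible part (XbaI accepts SpeI-ended parts through the
#' isocaudamer scar, which is re-cuttable by neither enzyme). Note that the
#' (SalI, BglII) pair consumes the plasmid's downstream BglII site and the
#' joint cannot restore it unless the part itself ends in A, so a platform
#' meant to accept further downstream insertions should be opened with
#' (SalI, BamHI) instead; see the package vignette.
#'
#' @param plasmid Conforming circular platform plasmid.
#' @param part Upstream-class \linkS4class{OperatorPart} (or bare fragment).
#' @param pair Character vector of two enzyme names; one of
#'   (SalI, BglII), (SalI, BamHI), (EcoRI, XbaI).
#' @param name Product name.
#' @return The product plasmid (not re-validated: promoter insertion
#'   legitimately supersedes upstream checks, which
#'   \code{\link{validatePlatform}} reports as such).
#' @export
insertUpstream <- function(plasmid, part, pair, name = NULL) {
  ok <- any(vapply(UPSTREAM_PAIRS, function(p) identical(p, as.character(pair)),
                   logical(1)))
  if (!ok)
    cbStop("argumentError",
           "pair must be one of (SalI,BglII), (SalI,BamHI), (EcoRI,XbaI)")
  vp <- validatePlatform(plasmid)
  if (!vp@conforms)
    cbStop("standardViolationError",
           "plasmid '%s' does not conform to the platform standard", plasmid@name)
  insertPart(plasmid, part, as.list(pair), name = name)
}
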