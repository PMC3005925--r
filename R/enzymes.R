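## The restriction enzymes used by the assembly standard, and site finding.
##
## Recognition sequences and cut offsets follow the standard REBASE
## definitions (the assembly standard names the enzymes but not their
## geometries). The table ships as a plain data file so it can be audited or
## overridden without touching code.

.enzymeCache <- new.env(parent = emptyenv())

#' Construct a restriction enzyme
#'
#' @param name Enzyme name.
#' @param recognition Palindromic recognition sequence.
#' @param cutOffsetTop Bases from recognition start to the top-strand cut.
#' @return An \linkS4class{Enzyme}.
#' @export
enzyme <- function(name, recognition, cutOffsetTop) {
  new("Enzyme", name = name, recognition = recognition,
      cutOffsetTop = as.integer(cutOffsetTop))
}

#' @rdname enzymeAccessors
#' @export
setGeneric("overhangSeq", function(x) standardGeneric("overhangSeq"))
#' Enzyme accessors
#'
#' \code{overhangSeq} returns the 5' overhang an enzyme leaves, written in
#' top-strand letters (the protruding bases of the downstream fragment's top
#' strand); \code{overhangLength} its length.
#'
#' @param x An \linkS4class{Enzyme}.
#' @name enzymeAccessors
#' @rdname enzymeAccessors
#' @export
setMethod("overhangSeq", "Enzyme", function(x) {
  substr(x@recognition, x@cutOffsetTop + 1L,
         nchar(x@recognition) - x@cutOffsetTop)
})

#' @rdname enzymeAccessors
#' @export
setGeneric("overhangLength", function(x) standardGeneric("overhangLength"))
#' @rdname enzymeAccessors
#' @export
setMethod("overhangLength", "Enzyme", function(x) nchar(overhangSeq(x)))

setMethod("show", "Enzyme", function(object) {
  r <- object@recognition; o <- object@cutOffsetTop
  cat(sprintf("Enzyme %s: %s^%s (5'-%s overhang)\n", object@name,
              substr(r, 1L, o), substr(r, o + 1L, nchar(r)),
              overhangSeq(object)))
  invisible(NULL)
})

#' Load an enzyme table
#'
#' Reads a tab-separated enzyme table (columns name, recognition,
#' cut_offset_top). With no argument, returns the seven enzymes of the
#' assembly standard: EcoRI G^AATTC, XbaI T^CTAGA, SalI G^TCGAC,
#' BamHI G^GATCC, BglII A^GATCT, MluI A^CGCGT, SpeI A^CTAGT -- all leaving
#' 4-nt 5' overhangs. NotI is deliberately absent (its site is preserved in
#' the backbone fixture but never used).
#'
#' @param path Optional path to an alternative table.
#' @return Named list of \linkS4class{Enzyme} objects.
#' @examples
#' builtinEnzymes()[["BglII"]]
#' @export
builtinEnzymes <- function(path = NULL) {
  if (is.null(path)) {
    if (!is.null(.enzymeCache$builtin)) return(.enzymeCache$builtin)
    path <- system.file("extdata", "enzymes.tsv", package = "cloneBrick",
                        mustWork = TRUE)
    .enzymeCache$builtin <- builtinEnzymes(path)
    return(.enzymeCache$builtin)
  }
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  enz <- lapply(seq_len(nrow(tab)), function(i)
    enzyme(tab$name[i], tab$recognition[i], tab$cut_offset_top[i]))
  names(enz) <- tab$name
  enz
}

#' Look up a builtin enzyme by name
#'
#' @param name Enzyme name (e.g. "MluI").
#' @param enzymes Enzyme list to search (defaults to the builtin table).
#' @return An \linkS4class{Enzyme}.
#' @export
enzymeByName <- function(name, enzymes = builtinEnzymes()) {
  if (!name %in% names(enzymes))
    cbStop("unknownEnzymeError", "unknown enzyme '%s' (known: %s)",
           name, paste(names(enzymes), collapse = ", "))
  enzymes[[name]]
}

#' Find the restriction sites of an enzyme on a molecule
#'
#' Locates every recognition locus. The recognition sequence is palindromic,
#' so each occurrence is a single double-strand site reported once by its
#' 1-based top-strand start. Circular molecules are scanned across the
#' origin. On linear fragments, a recognition span that would extend into a
#' single-stranded overhang is \emph{not} reported: the enzyme needs fully
#' duplex DNA.
#'
#' @param molecule A \linkS4class{DuplexFragment}.
#' @param enz An \linkS4class{Enzyme}.
#' @return A list with elements \code{enzyme} (the name) and
#'   \code{positions} (sorted integer recognition starts; may be empty).
#' @examples
#' findSites(duplexFragment("GGAATTCC"), enzymeByName("EcoRI"))
#' @export
findSites <- function(molecule, enz) {
  if (!is(molecule, "DuplexFragment"))
    cbStop("typeError", "molecule must be a DuplexFragment")
  if (!is(enz, "Enzyme")) cbStop("typeError", "enz must be an Enzyme")
  seq <- virtualSeq(molecule)
  L <- nchar(seq); m <- nchar(enz@recognition)
  if (isCircular(molecule)) {
    subject <- paste0(seq, substr(seq, 1L, m - 1L))
    pos <- matchStarts(subject, enz@recognition)
    pos <- pos[pos <= L]
  } else {
    dr <- duplexRegion(molecule)
    pos <- matchStarts(seq, enz@recognition)
    pos <- pos[pos >= dr[1L] & (pos + m - 1L) <= dr[2L]]
  }
  list(enzyme = enz@name, positions = sort(unique(as.integer(pos))))
}
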