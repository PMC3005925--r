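## Sticky-end compatibility, ligation with junction (scar) analysis, and the
## standardized insertion operation.

#' Can two sticky ends be ligated?
#'
#' TRUE iff both ends are blunt, or both are 5' overhangs of equal length
#' whose protruding sequences are reverse complements of each other when
#' each is read 5'->3' on its own protruding strand. For the 4-nt
#' palindromic overhangs produced by the enzymes in scope this reduces to
#' sequence equality, which is what makes the BamHI/BglII and XbaI/SpeI
#' isocaudamer pairs compatible.
#'
#' @param a,b \linkS4class{StickyEnd}s.
#' @return Logical.
#' @examples
#' bglII <- stickyEnd("five_prime", "GATC", "bottom")
#' bamHI <- stickyEnd("five_prime", "GATC", "top")
#' endsCompatible(bglII, bamHI)
#' @export
endsCompatible <- function(a, b) {
  for (e in list(a, b))
    if (e@kind == "three_prime")
      cbStop("unsupportedEndError",
             "3' overhangs are reserved but unsupported (no enzyme in scope produces them)")
  if (a@kind == "blunt" && b@kind == "blunt") return(TRUE)
  if (a@kind != b@kind) return(FALSE)
  nchar(a@overhang) == nchar(b@overhang) && a@overhang == revComp(b@overhang)
}

## Scan a sealed junction window against an enzyme table.
recuttableBy <- function(window, enzymes) {
  hits <- vapply(enzymes, function(e)
    countOccurrences(window, e@recognition) > 0L, logical(1))
  names(enzymes)[hits]
}

#' Ligate an ordered list of fragments
#'
#' Seals each adjacent pair of compatible ends (and the last-to-first pair
#' when circularising) into one molecule. Each shared overhang is written
#' once; every joint is recorded as a junction with the 8-bp sealed window
#' (4-nt overhang plus 2 bp of context on each side, where available) and
#' the set of enzymes able to re-cut it. Annotations of all fragments are
#' carried over with recomputed coordinates.
#'
#' @param fragments Ordered list of linear \linkS4class{DuplexFragment}s.
#' @param circularize Seal the last fragment's right end to the first
#'   fragment's left end, producing a circular molecule.
#' @param name Product name.
#' @param enzymes Enzyme table used for junction re-cut analysis.
#' @return A \linkS4class{DuplexFragment}.
#' @export
ligate <- function(fragments, circularize = FALSE, name = "ligation_product",
                   enzymes = builtinEnzymes()) {
  if (is(fragments, "DuplexFragment")) fragments <- list(fragments)
  k <- length(fragments)
  if (!k) cbStop("argumentError", "no fragments to ligate")
  for (f in fragments)
    if (isCircular(f))
      cbStop("topologyError", "cannot ligate a circular molecule")
  nJoint <- if (circularize) k else k - 1L
  for (i in seq_len(nJoint)) {
    a <- fragments[[i]]; b <- fragments[[if (i < k) i + 1L else 1L]]
    if (!endsCompatible(rightEnd(a), leftEnd(b)))
      cbStop("ligationError",
             "incompatible ends at joint %d ('%s' right end vs '%s' left end)",
             i, a@name, b@name)
  }
  lo <- vapply(fragments, function(f)
    if (f@leftEnd@kind == "five_prime") f@leftEnd@overhang else "", character(1))
  cores <- vapply(fragments, function(f) f@core, character(1))
  offsets <- cumsum(c(0L, head(nchar(lo) + nchar(cores), -1L)))
  feats <- list(); juncs <- list()
  if (circularize) {
    core <- paste0(paste0(lo, cores), collapse = "")
    Ltot <- nchar(core)
    product <- duplexFragment(core, "circular", name = name)
  } else {
    first <- fragments[[1L]]; last <- fragments[[k]]
    core <- paste0(cores[1L],
                   paste0(lo[-1L], cores[-1L], collapse = ""), collapse = "")
    product <- duplexFragment(core, "linear", leftEnd = first@leftEnd,
                              rightEnd = last@rightEnd, name = name)
    Ltot <- fragmentLength(product)
  }
  V <- virtualSeq(product)
  wrapPos <- function(p) if (circularize) ((p - 1L) %% Ltot) + 1L else p
  for (i in seq_len(k)) {
    f <- fragments[[i]]
    ff <- f@features
    if (nrow(ff)) {
      ff$start <- wrapPos(ff$start + offsets[i])
      ff$end <- wrapPos(ff$end + offsets[i])
      wrapped <- ff$end < ff$start
      if (any(wrapped)) {
        ## a feature landing across the product origin is kept as two
        ## truncated pieces rather than dropped
        pre <- ff[wrapped, , drop = FALSE]; post <- pre
        pre$end <- rep(Ltot, nrow(pre)); pre$truncated <- TRUE
        post$start <- rep(1L, nrow(post)); post$truncated <- TRUE
        ff <- rbindFeatures(ff[!wrapped, , drop = FALSE], pre, post)
      }
      feats[[length(feats) + 1L]] <- ff
    }
    fj <- f@junctions
    if (nrow(fj)) {
      fj$position <- wrapPos(fj$position + offsets[i])
      juncs[[length(juncs) + 1L]] <- fj
    }
  }
  for (i in seq_len(nJoint)) {
    nxt <- if (i < k) i + 1L else 1L
    at <- if (nxt == 1L) Ltot + 1L else offsets[nxt] + 1L
    g <- nchar(lo[nxt])  # 0 for blunt joints
    from <- at - 2L; to <- at + g + 1L
    if (circularize) {
      window <- substrWrap(V, ((from - 1L) %% Ltot) + 1L,
                           ((from - 1L) %% Ltot) + (to - from + 1L))
    } else {
      window <- substr(V, max(1L, from), min(Ltot, to))
    }
    juncs[[length(juncs) + 1L]] <- data.frame(
      position = wrapPos(at), sealed = window,
      recuttable = paste(recuttableBy(window, enzymes), collapse = ","),
      stringsAsFactors = FALSE)
  }
  product@features <- do.call(rbindFeatures, feats)
  product@junctions <- if (length(juncs))
    do.call(rbind, c(juncs, list(make.row.names = FALSE))) else emptyJunctions()
  validObject(product)
  product
}

## Merge the (possibly cut-split) pieces of a region-level role back into a
## single feature after an insertion; rotates the product if the merged arc
## would span the origin. Returns the (possibly rotated) molecule.
mergeRegionFeature <- function(x, role, label) {
  idx <- which(x@features$role == role)
  if (length(idx) < 2L) {
    if (length(idx) == 1L) x@features$truncated[idx] <- FALSE
    return(x)
  }
  L <- nchar(x@core)
  p <- x@features[idx, , drop = FALSE]
  p <- p[order(p$start), , drop = FALSE]
  ## choose the arc covering all pieces whose complement is the largest gap
  gapAfter <- vapply(seq_len(nrow(p)), function(i) {
    nxt <- if (i < nrow(p)) i + 1L else 1L
    ((p$start[nxt] - p$end[i] - 1L) %% L)
  }, numeric(1))
  cutAt <- which.max(gapAfter)
  firstPiece <- if (cutAt < nrow(p)) cutAt + 1L else 1L
  s <- p$start[firstPiece]
  if (p$end[cutAt] < s) {  # arc wraps the origin: rotate it away
    x <- rotateOriginSafe(x, s)
    return(mergeRegionFeature(x, role, label))
  }
  e <- p$end[cutAt]
  keep <- x@features[-idx, , drop = FALSE]
  x@features <- rbindFeatures(keep, makeFeature(label, role, s, e))
  x
}

## rotateOrigin that tolerates features spanning the target by dropping the
## wrap check: used internally where targets are known cut boundaries.
rotateOriginSafe <- function(x, newStart) {
  tryCatch(rotateOrigin(x, newStart), error = function(e)
    cbStop("annotationError", "cannot rotate product to %d: %s",
           newStart, conditionMessage(e)))
}

#' Insert a part between two unique restriction sites of a circular backbone
#'
#' The standardized insertion: the backbone is digested with the two named
#' enzymes (each of which must cut exactly once -- more than one site means a
#' malformed platform and is refused), the fragment carrying the payload is
#' retained (the larger fragment, or the one carrying a named annotation),
#' the part is ligated in its unique compatible orientation and the product
#' re-circularised. Backbone annotations are preserved; the part's
#' annotations are added with recomputed coordinates; region-level
#' annotations split by the digestion are re-merged across the insert.
#' Orientation is never guessed: a part compatible in zero or in both
#' orientations is refused.
#'
#' @param backbone Circular \linkS4class{DuplexFragment}.
#' @param part Linear \linkS4class{DuplexFragment} (or
#'   \linkS4class{OperatorPart}).
#' @param enzymes List/vector of two \linkS4class{Enzyme}s (or names).
#' @param keep NULL to retain the larger digestion fragment, or a feature
#'   label selecting the fragment to retain.
#' @param name Product name; default derives from the inputs.
#' @return Circular \linkS4class{DuplexFragment}.
#' @export
insertPart <- function(backbone, part, enzymes, keep = NULL, name = NULL) {
  if (is(part, "OperatorPart")) {
    if (is.null(name)) name <- paste0(backbone@name, "+", part@name)
    part <- part@fragment
  }
  if (!isCircular(backbone))
    cbStop("topologyError", "backbone must be circular")
  if (isCircular(part)) cbStop("topologyError", "part must be linear")
  enzymes <- lapply(enzymes, function(e)
    if (is.character(e)) enzymeByName(e) else e)
  if (length(enzymes) != 2L)
    cbStop("argumentError", "exactly two backbone enzymes are required")
  for (e in enzymes) {
    n <- length(findSites(backbone, e)$positions)
    if (n == 0L)
      cbStop("missingSiteError", "backbone '%s' has no %s site",
             backbone@name, e@name)
    if (n > 1L)
      cbStop("ambiguityError",
             "backbone '%s' has %d %s sites; the standard guarantees uniqueness",
             backbone@name, n, e@name)
  }
  frags <- digest(backbone, enzymes)
  if (length(frags) != 2L)
    cbStop("digestError", "expected 2 backbone fragments, got %d", length(frags))
  if (is.null(keep)) {
    retained <- frags[[which.max(vapply(frags, fragmentLength, numeric(1)))]]
  } else {
    has <- vapply(frags, function(f) keep %in% f@features$label, logical(1))
    if (sum(has) != 1L)
      cbStop("annotationError", "feature label '%s' does not select a unique fragment", keep)
    retained <- frags[[which(has)]]
  }
  orientations <- list(forward = part, flipped = flipFragment(part))
  fits <- vapply(orientations, function(p)
    endsCompatible(rightEnd(retained), leftEnd(p)) &&
      endsCompatible(rightEnd(p), leftEnd(retained)), logical(1))
  if (sum(fits) == 0L)
    cbStop("orientationError",
           "part '%s' is compatible with the opened backbone in no orientation",
           part@name)
  if (sum(fits) == 2L)
    cbStop("orientationError",
           "part '%s' has symmetric ends (compatible in both orientations); refusing to guess",
           part@name)
  oriented <- orientations[[which(fits)]]
  if (is.null(name)) name <- paste0(backbone@name, "+", part@name)
  product <- ligate(list(retained, oriented), circularize = TRUE, name = name)
  product <- mergeRegionFeature(product, "downstream_region",
                                "downstream standard region")
  product <- mergeRegionFeature(product, "mcs_upstream",
                                "upstream multi-cloning region")
  mcs <- which(product@features$role == "mcs_upstream")
  if (length(mcs) == 1L)
    product <- rotateOriginSafe(product, product@features$start[mcs])
  product
}
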