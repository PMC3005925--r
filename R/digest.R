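## Complete restriction digestion of linear and circular duplexes.

## substring on a circular sequence; from in [1, L], to may exceed L.
substrWrap <- function(seq, from, to) {
  L <- nchar(seq)
  if (to <= L) return(substr(seq, from, to))
  paste0(substr(seq, from, L), substr(seq, 1L, to - L))
}

## A double-strand cut: top strand severed after position t, bottom strand
## (in top coordinates) after position b; the staggered region (t, b] is the
## 4-nt 5' overhang in top-strand letters.
collectCuts <- function(molecule, enzymes) {
  seq <- virtualSeq(molecule)
  L <- nchar(seq)
  cuts <- data.frame(t = integer(0), b = integer(0), enzyme = character(0),
                     stringsAsFactors = FALSE)
  for (enz in enzymes) {
    m <- nchar(enz@recognition)
    pos <- findSites(molecule, enz)$positions
    if (!length(pos)) next
    t <- pos + enz@cutOffsetTop - 1L
    b <- pos + m - enz@cutOffsetTop - 1L
    if (isCircular(molecule)) t <- ((t - 1L) %% L) + 1L  # b kept unwrapped >= t
    cuts <- rbind(cuts, data.frame(t = t, b = b, enzyme = enz@name,
                                   stringsAsFactors = FALSE))
  }
  cuts <- cuts[order(cuts$t), , drop = FALSE]
  ## Overlapping or immediately adjacent staggered cuts (possible for
  ## site pairs like TCTAGATCT for XbaI+BglII, or sites exactly one
  ## overhang apart like GAATTCTAGA) cannot both fire: the first cut leaves
  ## the second recognition site nicked or single-stranded. Resolve
  ## greedily 5'->3' and warn.
  if (nrow(cuts) > 1L) {
    keep <- logical(nrow(cuts)); keep[1L] <- TRUE; lastB <- cuts$b[1L]
    for (i in 2L:nrow(cuts)) {
      if (cuts$t[i] > lastB) { keep[i] <- TRUE; lastB <- cuts$b[i] }
    }
    if (isCircular(molecule) && sum(keep) > 1L) {
      ## wrap check: last kept cut's overhang may not reach the first cut
      ks <- which(keep)
      if (cuts$b[ks[length(ks)]] - nchar(seq) >= cuts$t[ks[1L]]) {
        keep[ks[length(ks)]] <- FALSE
      }
    }
    if (!all(keep)) {
      warning(sprintf("%d overlapping cut(s) skipped (conflicting staggered sites)",
                      sum(!keep)), call. = FALSE)
      cuts <- cuts[keep, , drop = FALSE]
    }
  }
  cuts
}

## Map parent features onto a fragment occupying parent virtual span
## [vstart, vend] (vend may exceed L on circular parents).
clipFeatures <- function(feats, vstart, vend, L, circular) {
  if (!nrow(feats)) return(emptyFeatures())
  pieces <- list()
  cand <- feats
  if (circular) {
    shifted <- feats
    shifted$start <- shifted$start + L; shifted$end <- shifted$end + L
    cand <- rbindFeatures(feats, shifted)
  }
  for (i in seq_len(nrow(cand))) {
    s <- max(cand$start[i], vstart); e <- min(cand$end[i], vend)
    if (s > e) next
    f <- cand[i, , drop = FALSE]
    f$truncated <- f$truncated || s > cand$start[i] || e < cand$end[i]
    f$start <- s - vstart + 1L; f$end <- e - vstart + 1L
    pieces[[length(pieces) + 1L]] <- f
  }
  out <- do.call(rbindFeatures, pieces)
  if (nrow(out)) out <- out[!duplicated(out[c("label", "role", "start", "end")]), ,
                            drop = FALSE]
  out
}

#' Digest a molecule with a set of restriction enzymes
#'
#' Simulates complete digestion: every accessible site of every enzyme is
#' cut (partial digestion is not modelled). A circular molecule with k cuts
#' yields k linear fragments; a linear molecule with k cuts yields k+1. Each
#' new terminus carries the cutting enzyme's 5' overhang. Fragments are
#' returned in top-strand order from the origin, with parent annotations
#' clipped onto them (features split by a cut are kept as truncated pieces).
#' Per-strand nucleotide counts are conserved across the digestion.
#'
#' A circular molecule with no site for any of the enzymes is returned
#' unchanged (a one-element list) with a warning and attribute
#' \code{uncut = TRUE}.
#'
#' @param molecule A \linkS4class{DuplexFragment}.
#' @param enzymes A list of \linkS4class{Enzyme} objects (or a single one).
#' @return List of linear \linkS4class{DuplexFragment}s.
#' @examples
#' frags <- digest(duplexFragment("GGAATTCC"), enzymeByName("EcoRI"))
#' vapply(frags, topStrand, character(1))
#' @export
digest <- function(molecule, enzymes) {
  if (is(enzymes, "Enzyme")) enzymes <- list(enzymes)
  if (!length(enzymes)) cbStop("argumentError", "enzyme set must be non-empty")
  seq <- virtualSeq(molecule)
  L <- nchar(seq)
  cuts <- collectCuts(molecule, enzymes)
  k <- nrow(cuts)
  circ <- isCircular(molecule)
  if (k == 0L) {
    if (circ) {
      warning(sprintf("no site on circular molecule '%s'; returned uncut",
                      molecule@name), call. = FALSE)
      out <- list(molecule)
      attr(out, "uncut") <- TRUE
      return(out)
    }
    return(list(molecule))
  }
  feats <- molecule@features
  mkEnd <- function(gap, side) {
    if (!nzchar(gap)) return(bluntEnd())
    if (side == "left") stickyEnd("five_prime", gap, "top")
    else stickyEnd("five_prime", revComp(gap), "bottom")
  }
  frags <- list()
  if (circ) {
    for (i in seq_len(k)) {
      tL <- cuts$t[i]; bL <- cuts$b[i]
      nxt <- if (i < k) i + 1L else 1L
      tR <- cuts$t[nxt]; bR <- cuts$b[nxt]
      if (tR <= tL) { tR <- tR + L; bR <- bR + L }
      ## spans below are written (from, length) against the circle
      lo <- substrWrap(seq, (tL %% L) + 1L, (tL %% L) + (bL - tL))       # (tL, bL]
      core <- substrWrap(seq, (bL %% L) + 1L, (bL %% L) + (tR - bL))     # (bL, tR]
      gap <- substrWrap(seq, (tR %% L) + 1L, (tR %% L) + (bR - tR))      # (tR, bR]
      f <- duplexFragment(core, "linear",
                          leftEnd = mkEnd(lo, "left"),
                          rightEnd = mkEnd(gap, "right"),
                          name = sprintf("%s_frag%d", molecule@name, i))
      f@features <- clipFeatures(feats, tL + 1L, bR, L, TRUE)
      validObject(f)
      frags[[i]] <- f
    }
  } else {
    dr <- duplexRegion(molecule)
    bounds <- rbind(c(t = 0L, b = dr[1L] - 1L), as.matrix(cuts[c("t", "b")]),
                    c(t = dr[2L], b = L))
    for (i in seq_len(k + 1L)) {
      bL <- bounds[i, "b"]; tR <- bounds[i + 1L, "t"]; bR <- bounds[i + 1L, "b"]
      core <- substr(seq, bL + 1L, tR)
      le <- if (i == 1L) molecule@leftEnd
            else mkEnd(substr(seq, bounds[i, "t"] + 1L, bL), "left")
      re <- if (i == k + 1L) molecule@rightEnd
            else mkEnd(substr(seq, tR + 1L, bR), "right")
      f <- duplexFragment(core, "linear", leftEnd = le, rightEnd = re,
                          name = sprintf("%s_frag%d", molecule@name, i))
      vstart <- if (i == 1L) 1L else bounds[i, "t"] + 1L
      vend <- if (i == k + 1L) L else bR
      f@features <- clipFeatures(feats, vstart, vend, L, FALSE)
      validObject(f)
      frags[[i]] <- f
    }
  }
  frags
}
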