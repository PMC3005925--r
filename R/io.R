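## File I/O: FASTA for bare sequences, a minimal feature-annotated GenBank
## dialect for plasmids/fragments, YAML part and strain files.

#' Write a fragment to FASTA
#'
#' Writes the virtual top strand; topology is conveyed by a description
#' token \code{[topology=circular]} / \code{[topology=linear]}. Sticky-end
#' structure is not representable in FASTA (use GenBank for that).
#'
#' @param x A \linkS4class{DuplexFragment} or list of them.
#' @param path Output path.
#' @export
writeFastaFragment <- function(x, path) {
  if (is(x, "DuplexFragment")) x <- list(x)
  seqs <- Biostrings::DNAStringSet(vapply(x, virtualSeq, character(1)))
  names(seqs) <- vapply(x, function(f)
    sprintf("%s [topology=%s]", f@name, f@topology), character(1))
  Biostrings::writeXStringSet(seqs, filepath = path)
  invisible(path)
}

#' Read fragments from FASTA
#'
#' @param path FASTA file; a \code{[topology=circular]} description token
#'   marks circular records (default linear, blunt ends).
#' @return List of \linkS4class{DuplexFragment}s.
#' @export
readFastaFragment <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  lapply(seq_along(seqs), function(i) {
    desc <- names(seqs)[i]
    topo <- if (grepl("[topology=circular]", desc, fixed = TRUE))
      "circular" else "linear"
    nm <- sub("\\s*\\[topology=(circular|linear)\\]\\s*", "", desc)
    duplexFragment(as.character(seqs[[i]]), topo, name = trimws(nm))
  })
}

## ---- GenBank ----
## A deliberately small dialect: LOCUS (name, length, topology), COMMENT
## lines carrying sticky-end structure for linear fragments, FEATURES as
## misc_feature entries with /label, /role and regulator qualifiers, ORIGIN.

#' Write a fragment as an annotated GenBank record
#'
#' Round-trips sequence, topology, features and (via COMMENT lines) the
#' sticky-end structure of linear fragments. Ligation junctions are written
#' as additional misc_feature entries with a scar note.
#'
#' @param x A \linkS4class{DuplexFragment}.
#' @param path Output path.
#' @export
writeGenBank <- function(x, path) {
  L <- fragmentLength(x)
  con <- file(path, "w"); on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  w("LOCUS       %-16s %d bp    DNA     %-8s SYN",
    substr(gsub("\\s", "_", x@name), 1L, 16L), L, x@topology)
  w("DEFINITION  %s.", x@name)
  if (!isCircular(x)) {
    fe <- function(e) if (e@kind == "blunt") "blunt"
      else paste(e@kind, e@overhang, e@protruding, sep = ":")
    w("COMMENT     clonebrick_left_end=%s", fe(x@leftEnd))
    w("COMMENT     clonebrick_right_end=%s", fe(x@rightEnd))
  }
  w("FEATURES             Location/Qualifiers")
  w("     source          1..%d", L)
  qf <- function(k, v) if (!is.na(v) && nzchar(v))
    w("                     /%s=\"%s\"", k, v)
  f <- x@features
  for (i in seq_len(nrow(f))) {
    w("     misc_feature    %d..%d", f$start[i], f$end[i])
    qf("label", f$label[i]); qf("role", f$role[i])
    qf("regulator", f$regulator[i]); qf("mode", f$mode[i])
    qf("inducer", f$inducer[i]); qf("strength", f$strength[i])
  }
  j <- x@junctions
  for (i in seq_len(nrow(j))) {
    w("     misc_feature    %d..%d", j$position[i],
      min(L, j$position[i] + nchar(j$sealed[i]) - 1L))
    qf("label", sprintf("junction %d", i))
    qf("note", sprintf("scar=%s;recuttable=%s", j$sealed[i],
                       if (nzchar(j$recuttable[i])) j$recuttable[i] else "none"))
  }
  w("ORIGIN")
  seq <- tolower(virtualSeq(x))
  for (s in seq(1L, nchar(seq), by = 60L)) {
    chunk <- substr(seq, s, min(nchar(seq), s + 59L))
    groups <- substring(chunk, seq(1L, nchar(chunk), 10L),
                        pmin(nchar(chunk), seq(10L, nchar(chunk) + 9L, 10L)))
    w("%9d %s", s, paste(groups, collapse = " "))
  }
  w("//")
  invisible(path)
}

#' Read an annotated GenBank record
#'
#' Parses the dialect written by \code{\link{writeGenBank}} (and tolerant
#' subsets of standard records). misc_feature entries without a /role
#' qualifier are loaded and reported via a message rather than silently
#' dropped (they carry no role and are excluded from the feature table).
#'
#' @param path GenBank file.
#' @return A \linkS4class{DuplexFragment}.
#' @export
readGenBank <- function(path) {
  lines <- readLines(path, warn = FALSE)
  locus <- grep("^LOCUS", lines, value = TRUE)
  if (!length(locus))
    cbStop("parseError", "no LOCUS line in '%s'", path)
  topo <- if (grepl("circular", locus[1L])) "circular" else "linear"
  nm <- strsplit(trimws(sub("^LOCUS", "", locus[1L])), "\\s+")[[1L]][1L]
  parseEnd <- function(tag) {
    ln <- grep(paste0("clonebrick_", tag, "_end="), lines, value = TRUE)
    if (!length(ln)) return(bluntEnd())
    v <- sub(paste0(".*clonebrick_", tag, "_end="), "", ln[1L])
    if (v == "blunt") return(bluntEnd())
    p <- strsplit(v, ":", fixed = TRUE)[[1L]]
    stickyEnd(p[1L], p[2L], p[3L])
  }
  oi <- grep("^ORIGIN", lines)
  if (!length(oi)) cbStop("parseError", "no ORIGIN block in '%s'", path)
  seqLines <- lines[(oi[1L] + 1L):length(lines)]
  seqLines <- seqLines[!grepl("^//", seqLines)]
  seqFull <- toupper(gsub("[^acgtACGT]", "", paste(seqLines, collapse = "")))
  ## features
  fi <- grep("^FEATURES", lines)
  feats <- emptyFeatures(); dropped <- 0L
  if (length(fi)) {
    block <- lines[(fi[1L] + 1L):(oi[1L] - 1L)]
    starts <- grep("^     \\S", block)
    for (k in seq_along(starts)) {
      from <- starts[k]
      to <- if (k < length(starts)) starts[k + 1L] - 1L else length(block)
      entry <- block[from:to]
      header <- strsplit(trimws(entry[1L]), "\\s+")[[1L]]
      if (header[1L] != "misc_feature") next
      loc <- regmatches(header[2L], regexec("(\\d+)\\.\\.(\\d+)", header[2L]))[[1L]]
      if (length(loc) != 3L) next
      getq <- function(q) {
        ln <- grep(sprintf('/%s="', q), entry, value = TRUE, fixed = TRUE)
        if (!length(ln)) return(NA_character_)
        sub('".*$', "", sub(sprintf('.*/%s="', q), "", ln[1L]))
      }
      role <- getq("role")
      if (is.na(role) || !role %in% FEATURE_ROLES) {
        dropped <- dropped + 1L
        next
      }
      feats <- rbindFeatures(feats, makeFeature(
        label = if (is.na(getq("label"))) role else getq("label"),
        role = role, start = as.integer(loc[2L]), end = as.integer(loc[3L]),
        regulator = getq("regulator"), mode = getq("mode"),
        inducer = getq("inducer"), strength = getq("strength")))
    }
  }
  if (dropped)
    message(sprintf("readGenBank: %d feature(s) without a recognised role qualifier were not imported", dropped))
  frag <- duplexFragment(seqFull, topo, name = nm)
  if (topo == "linear") {
    le <- parseEnd("left"); re <- parseEnd("right")
    loN <- if (le@kind == "five_prime") nchar(le@overhang) else 0L
    roN <- if (re@kind == "five_prime") nchar(re@overhang) else 0L
    core <- substr(seqFull, loN + 1L, nchar(seqFull) - roN)
    frag <- duplexFragment(core, "linear", leftEnd = le, rightEnd = re,
                           name = nm)
  }
  frag@features <- feats
  validObject(frag)
  frag
}

## ---- part and strain files ----

#' Write an OperatorPart to a YAML part file
#'
#' Part metadata travels in this sidecar file (bit-exact oligo strings plus
#' regulator information); it is never inferred from sequence.
#'
#' @param part An \linkS4class{OperatorPart}.
#' @param path Output path.
#' @export
writePartFile <- function(part, path) {
  frag <- part@fragment
  ops <- frag@features[frag@features$role == "operator", , drop = FALSE]
  doc <- list(
    name = part@name,
    class = part@partClass,
    top_oligo = topStrand(frag),
    bottom_oligo = bottomStrand(frag),
    operator_span = if (nrow(ops)) c(ops$start[1L], ops$end[1L]) else NULL,
    regulator = if (!is.null(part@regulator)) list(
      name = part@regulator@name, mode = part@regulator@mode,
      inducer = part@regulator@inducer) else NULL,
    spacer = part@spacer,
    carries_promoter_core = part@carriesPromoterCore,
    carries_expression_cassette = part@carriesExpressionCassette
  )
  yaml::write_yaml(doc, path)
  invisible(path)
}

#' Read an OperatorPart from a YAML part file
#'
#' The oligos are re-annealed, so the file is validated against the duplex
#' model on load.
#'
#' @param path Part file.
#' @return An \linkS4class{OperatorPart}.
#' @export
readPartFile <- function(path) {
  doc <- yaml::read_yaml(path)
  for (k in c("name", "class", "top_oligo", "bottom_oligo"))
    if (is.null(doc[[k]]))
      cbStop("parseError", "part file '%s' lacks field '%s'", path, k)
  frag <- annealOligos(doc$top_oligo, doc$bottom_oligo, name = doc$name)
  reg <- NULL
  if (!is.null(doc$regulator)) {
    reg <- regulatorSpec(doc$regulator$name, doc$regulator$mode,
                         doc$regulator$inducer)
    if (!is.null(doc$operator_span)) {
      sp <- as.integer(doc$operator_span)
      frag <- addFeature(frag, paste0(reg@name, " operator"), "operator",
                         sp[1L], sp[2L], regulator = reg@name,
                         mode = reg@mode, inducer = reg@inducer)
    }
  }
  new("OperatorPart", name = doc$name, partClass = doc$class, fragment = frag,
      regulator = reg, spacer = if (is.null(doc$spacer)) "" else doc$spacer,
      carriesPromoterCore = isTRUE(doc$carries_promoter_core),
      carriesExpressionCassette = isTRUE(doc$carries_expression_cassette))
}

#' Read a strain configuration file
#'
#' @param path YAML file mapping strain name to the list of regulators the
#'   strain expresses.
#' @return Named list of character vectors.
#' @export
readStrainsFile <- function(path) {
  doc <- yaml::read_yaml(path)
  lapply(doc, function(v) as.character(unlist(v)))
}
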