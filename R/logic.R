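## Boolean transcription semantics of an assembled regulatory region.
##
## The model is deliberately qualitative: transcription is ON or OFF. RNA
## polymerase binds the core promoter either constitutively (a strong
## -35/-10 element) or only with the help of a bound activator (a weak
## element such as luxpR); any repressor bound to any operator of the
## region silences it. Inducers act through the two archetypes: IPTG-style
## inducers release a repressor from its operator, AHL-style inducers
## enable an activator to bind. Fold-change prediction is a non-goal: no
## kinetic model is attached.

## Known regulator archetypes used to resolve metadata from annotations.
defaultRegulatorSpecs <- function() {
  list(LacI = regulatorSpec("LacI", "repressor", "IPTG"),
       LuxR = regulatorSpec("LuxR", "activator", "AHL"))
}

#' Extract the Boolean regulatory model of a plasmid
#'
#' Reads the plasmid's annotations: the promoter_core feature fixes the
#' promoter strength class (absent = promoterless control), operator
#' features (ordered 5'->3') supply the regulator/mode/inducer bindings,
#' and expression_cassette features add their regulators to the available
#' set alongside the host strain's. An operator annotated without regulator
#' metadata is a metadata error.
#'
#' @param plasmid Annotated \linkS4class{DuplexFragment}.
#' @param strainRegulators Character vector of regulators expressed by the
#'   host strain (e.g. \code{"LacI"} for DH5alphaLacI).
#' @return A \linkS4class{RegulatoryModel}.
#' @export
extractRegulatoryModel <- function(plasmid, strainRegulators = character(0)) {
  feats <- plasmid@features
  specs <- defaultRegulatorSpecs()
  prom <- feats[feats$role == "promoter_core", , drop = FALSE]
  if (nrow(prom) > 1L)
    cbStop("metadataError", "multiple promoter_core annotations")
  if (nrow(prom) == 0L) {
    promoter <- list(strength = "absent", linkedRegulator = NA_character_,
                     label = "promoterless")
  } else {
    strength <- prom$strength[1L]
    if (is.na(strength) ||
        !strength %in% c("strong_constitutive", "weak_activator_dependent"))
      cbStop("metadataError",
             "promoter_core must be annotated strong_constitutive or weak_activator_dependent")
    linked <- prom$regulator[1L]
    if (strength == "weak_activator_dependent" && is.na(linked))
      cbStop("metadataError",
             "a weak activator-dependent promoter needs a linked activator")
    promoter <- list(strength = strength, linkedRegulator = linked,
                     label = prom$label[1L])
  }
  ops <- feats[feats$role == "operator", , drop = FALSE]
  ops <- ops[order(ops$start), , drop = FALSE]
  if (nrow(ops)) {
    if (any(is.na(ops$regulator) | is.na(ops$mode) | is.na(ops$inducer)))
      cbStop("metadataError",
             "operator annotation without regulator metadata on '%s'", plasmid@name)
    position <- if (nrow(prom) == 1L)
      ifelse(ops$end < prom$start[1L], "upstream_of_core", "downstream_of_core")
    else rep("downstream_of_core", nrow(ops))
    operators <- data.frame(regulator = ops$regulator, mode = ops$mode,
                            inducer = ops$inducer, position = position,
                            start = ops$start, stringsAsFactors = FALSE)
  } else {
    operators <- data.frame(regulator = character(0), mode = character(0),
                            inducer = character(0), position = character(0),
                            start = integer(0), stringsAsFactors = FALSE)
  }
  cassettes <- feats[feats$role == "expression_cassette", , drop = FALSE]
  available <- unique(c(strainRegulators,
                        cassettes$regulator[!is.na(cassettes$regulator)]))
  for (i in seq_len(nrow(operators)))
    if (!operators$regulator[i] %in% names(specs))
      specs[[operators$regulator[i]]] <-
        regulatorSpec(operators$regulator[i], operators$mode[i],
                      operators$inducer[i])
  new("RegulatoryModel", promoter = promoter, operators = operators,
      regulators = available, regulatorSpecs = specs)
}

#' Evaluate a regulatory model under one input state
#'
#' OFF if the promoter is absent. Otherwise polymerase engages iff the core
#' is strong, or it is weak and its linked activator is available with its
#' inducer present. The region is repressed iff any repressor-mode operator
#' has its regulator available and that regulator's inducer absent. Output
#' is ON iff polymerase engages and the region is not repressed. Operators
#' whose regulator is unavailable are inert; multiple copies of the same
#' operator are logically idempotent at this Boolean layer.
#'
#' @param model A \linkS4class{RegulatoryModel}.
#' @param presentInducers Character vector of inducers present.
#' @return \code{"ON"} or \code{"OFF"}.
#' @export
evaluateState <- function(model, presentInducers = character(0)) {
  p <- model@promoter
  if (p$strength == "absent") return("OFF")
  if (p$strength == "strong_constitutive") {
    polymeraseOk <- TRUE
  } else {
    act <- p$linkedRegulator
    spec <- model@regulatorSpecs[[act]]
    if (is.null(spec))
      cbStop("metadataError", "no regulator spec for linked activator '%s'", act)
    polymeraseOk <- act %in% model@regulators && spec@inducer %in% presentInducers
  }
  ops <- model@operators
  repressed <- FALSE
  for (i in seq_len(nrow(ops))) {
    if (ops$mode[i] != "repressor") next
    if (ops$regulator[i] %in% model@regulators &&
        !(ops$inducer[i] %in% presentInducers)) repressed <- TRUE
  }
  if (polymeraseOk && !repressed) "ON" else "OFF"
}

modelInducers <- function(model) {
  ind <- model@operators$inducer
  p <- model@promoter
  if (p$strength == "weak_activator_dependent") {
    spec <- model@regulatorSpecs[[p$linkedRegulator]]
    if (!is.null(spec)) ind <- c(ind, spec@inducer)
  }
  sort(unique(ind))
}

comboKey <- function(inputs, on) {
  if (!any(on)) "none" else paste(inputs[on], collapse = "+")
}

#' Enumerate the full truth table of a regulatory model
#'
#' Evaluates the model over all 2^n combinations of its known inducers
#' (every inducer mentioned by an operator or by the promoter's linked
#' activator, whether or not the corresponding regulator is available) and
#' classifies the resulting gate.
#'
#' @param model A \linkS4class{RegulatoryModel}.
#' @return A \linkS4class{TruthTable}.
#' @export
truthTable <- function(model) {
  inputs <- modelInducers(model)
  n <- length(inputs)
  if (n > 8L)
    cbStop("sizeError", "refusing to enumerate 2^%d input combinations", n)
  combos <- if (n) expand.grid(rep(list(c(FALSE, TRUE)), n),
                               KEEP.OUT.ATTRS = FALSE)
            else data.frame(row.names = 1L)
  if (n) names(combos) <- inputs
  rows <- do.call(rbind, lapply(seq_len(max(1L, 2L^n)), function(i) {
    on <- if (n) unlist(combos[i, , drop = TRUE]) else logical(0)
    st <- if (n) inputs[on] else character(0)
    out <- data.frame(combo = comboKey(inputs, on),
                      output = evaluateState(model, st),
                      stringsAsFactors = FALSE)
    if (n) out <- cbind(combos[i, , drop = FALSE], out, row.names = NULL)
    out
  }))
  tt <- new("TruthTable", inputs = inputs, rows = rows, gate = "OTHER")
  tt@gate <- classifyGate(tt)
  tt
}

#' Classify the gate type of a truth table
#'
#' NULL = always OFF; CONSTITUTIVE = always ON. For one input: BUFFER (ON
#' iff present) or NOT (ON iff absent). For two inputs: AND (ON only with
#' both present) or OR (OFF only with both absent). For more inputs only
#' the all-present-only AND and the any-present OR shapes are named.
#' Everything else is OTHER.
#'
#' @param table A \linkS4class{TruthTable}.
#' @return One of "NULL", "CONSTITUTIVE", "BUFFER", "NOT", "AND", "OR",
#'   "OTHER".
#' @export
classifyGate <- function(table) {
  rows <- table@rows; inputs <- table@inputs; n <- length(inputs)
  if (nrow(rows) != 2L^n)
    cbStop("tableError", "incomplete truth table (%d rows for %d inputs)",
           nrow(rows), n)
  on <- rows$output == "ON"
  if (!any(on)) return("NULL")
  if (all(on)) return("CONSTITUTIVE")
  nPresent <- if (n) rowSums(as.matrix(rows[, inputs, drop = FALSE])) else
    rep(0L, nrow(rows))
  if (n == 1L) return(if (on[nPresent == 1L]) "BUFFER" else "NOT")
  allPresentOnly <- all(on == (nPresent == n))
  anyPresent <- all(on == (nPresent > 0L))
  if (allPresentOnly) return("AND")
  if (anyPresent) return("OR")
  "OTHER"
}

setMethod("show", "TruthTable", function(object) {
  cat(sprintf("TruthTable over {%s} -- gate: %s\n",
              paste(object@inputs, collapse = ", "), object@gate))
  for (i in seq_len(nrow(object@rows)))
    cat(sprintf("  %-20s %s\n", object@rows$combo[i], object@rows$output[i]))
  invisible(NULL)
})

setMethod("show", "RegulatoryModel", function(object) {
  p <- object@promoter
  cat(sprintf("RegulatoryModel: promoter %s (%s)\n", p$label, p$strength))
  if (nrow(object@operators))
    for (i in seq_len(nrow(object@operators)))
      cat(sprintf("  operator %d: %s (%s, inducer %s, %s)\n", i,
                  object@operators$regulator[i], object@operators$mode[i],
                  object@operators$inducer[i], object@operators$position[i]))
  cat(sprintf("  available regulators: %s\n",
              if (length(object@regulators))
                paste(object@regulators, collapse = ", ") else "(none)"))
  invisible(NULL)
})

#' Truth table as a JSON-ready list
#'
#' @param table A \linkS4class{TruthTable}.
#' @return List with elements \code{inputs}, \code{rows} (named ON/OFF map)
#'   and \code{gate}, matching the CLI's JSON output.
#' @export
truthTableAsList <- function(table) {
  rows <- as.list(table@rows$output)
  names(rows) <- table@rows$combo
  list(inputs = as.list(table@inputs), rows = rows, gate = table@gate)
}
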