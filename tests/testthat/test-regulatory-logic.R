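referenceSet <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- buildReferencePlasmids(seed = 1L)
    cache
  }
})

test_that("model extraction reads promoter, operators and cassettes", {
  ref <- referenceSet()
  m <- extractRegulatoryModel(ref[["PLuxR-LacItandem-GFP"]], "LacI")
  expect_equal(m@promoter$strength, "weak_activator_dependent")
  expect_equal(m@promoter$linkedRegulator, "LuxR")
  expect_equal(m@operators$regulator, c("LuxR", "LacI", "LacI"))
  expect_equal(m@operators$position,
               c("upstream_of_core", "downstream_of_core", "downstream_of_core"))
  expect_setequal(m@regulators, c("LacI", "LuxR"))  # cassette adds LuxR

  mNull <- extractRegulatoryModel(ref[["pSB-GFP"]], "LacI")
  expect_equal(mNull@promoter$strength, "absent")

  mConst <- extractRegulatoryModel(ref[["Placq-GFP"]], character(0))
  expect_equal(mConst@promoter$strength, "strong_constitutive")
  expect_equal(nrow(mConst@operators), 0)
})

test_that("an operator annotated without regulator metadata is refused", {
  frag <- duplexFragment("AAACCCGGGTTTAAACCC", "circular")
  frag <- addFeature(frag, "orphan operator", "operator", 4, 9)
  expect_error(extractRegulatoryModel(frag, "LacI"), class = "metadataError")
})

test_that("state evaluation reproduces the reporter-assay logic", {
  ref <- referenceSet()
  tandem <- extractRegulatoryModel(ref[["Placq-LacItandem-GFP"]], "LacI")
  expect_equal(evaluateState(tandem, "IPTG"), "ON")
  expect_equal(evaluateState(tandem, character(0)), "OFF")

  luxr <- extractRegulatoryModel(ref[["PLuxR-GFP"]], "LacI")
  expect_equal(evaluateState(luxr, "AHL"), "ON")
  expect_equal(evaluateState(luxr, character(0)), "OFF")

  gate <- extractRegulatoryModel(ref[["PLuxR-LacItandem-GFP"]], "LacI")
  expect_equal(evaluateState(gate, character(0)), "OFF")
  expect_equal(evaluateState(gate, "IPTG"), "OFF")
  expect_equal(evaluateState(gate, "AHL"), "OFF")
  expect_equal(evaluateState(gate, c("IPTG", "AHL")), "ON")
})

test_that("truth tables and gate labels match the construct behaviours", {
  ref <- referenceSet()
  gates <- vapply(ref, function(p)
    truthTable(extractRegulatoryModel(p, "LacI"))@gate, character(1))
  expect_identical(unname(gates[c("pSB-GFP", "Placq-GFP", "Placq-LacI-GFP",
                                  "Placq-LacItandem-GFP", "PLuxR-GFP",
                                  "PLuxR-LacItandem-GFP")]),
                   c("NULL", "CONSTITUTIVE", "BUFFER", "BUFFER", "BUFFER",
                     "AND"))
  tt <- truthTable(extractRegulatoryModel(ref[["PLuxR-LacItandem-GFP"]], "LacI"))
  expect_equal(sum(tt@rows$output == "ON"), 1)
  expect_equal(nrow(tt@rows), 4)
  expect_equal(tt@rows$combo[tt@rows$output == "ON"], "AHL+IPTG")
})

test_that("without LacI in the host the repressor operators are inert", {
  ref <- referenceSet()
  tt <- truthTable(extractRegulatoryModel(ref[["PLuxR-LacItandem-GFP"]],
                                          character(0)))
  on <- tt@rows$combo[tt@rows$output == "ON"]
  expect_setequal(on, c("AHL", "AHL+IPTG"))
  expect_equal(tt@gate, "OTHER")
})

test_that("gate classification covers the taxonomy", {
  mkTable <- function(inputs, onRows) {
    n <- length(inputs)
    combos <- expand.grid(rep(list(c(FALSE, TRUE)), n), KEEP.OUT.ATTRS = FALSE)
    names(combos) <- inputs
    key <- apply(combos, 1, function(r)
      if (!any(r)) "none" else paste(inputs[as.logical(r)], collapse = "+"))
    rows <- cbind(combos, data.frame(
      combo = key, output = ifelse(key %in% onRows, "ON", "OFF"),
      stringsAsFactors = FALSE))
    new("TruthTable", inputs = inputs, rows = rows, gate = "OTHER")
  }
  expect_equal(classifyGate(mkTable("X", character(0))), "NULL")
  expect_equal(classifyGate(mkTable("X", c("none", "X"))), "CONSTITUTIVE")
  expect_equal(classifyGate(mkTable("X", "X")), "BUFFER")
  expect_equal(classifyGate(mkTable("X", "none")), "NOT")
  expect_equal(classifyGate(mkTable(c("A", "B"), "A+B")), "AND")
  expect_equal(classifyGate(mkTable(c("A", "B"), c("A", "B", "A+B"))), "OR")
  expect_equal(classifyGate(mkTable(c("A", "B"), c("A"))), "OTHER")
  expect_equal(classifyGate(mkTable(c("A", "B", "C"), "A+B+C")), "AND")
  bad <- mkTable(c("A", "B"), "A+B")
  bad@rows <- bad@rows[-1, ]
  expect_error(classifyGate(bad), class = "tableError")
})

## random archetype models for the property tests
randomModel <- function() {
  nOps <- sample(0:3, 1)
  regs <- sprintf("Rep%d", seq_len(nOps))
  specs <- defaultSpecsPlus(regs)
  operators <- data.frame(
    regulator = regs, mode = rep("repressor", nOps),
    inducer = sprintf("ind%d", seq_len(nOps)),
    position = rep("downstream_of_core", nOps),
    start = seq_len(nOps) * 10L, stringsAsFactors = FALSE)
  weak <- runif(1) < 0.5
  if (weak) {
    operators <- rbind(data.frame(
      regulator = "LuxR", mode = "activator", inducer = "AHL",
      position = "upstream_of_core", start = 1L, stringsAsFactors = FALSE),
      operators)
  }
  available <- c(sample(regs, size = sample(0:nOps, 1)),
                 if (weak && runif(1) < 0.8) "LuxR")
  new("RegulatoryModel",
      promoter = list(
        strength = if (weak) "weak_activator_dependent" else "strong_constitutive",
        linkedRegulator = if (weak) "LuxR" else NA_character_,
        label = "test"),
      operators = operators, regulators = as.character(available),
      regulatorSpecs = specs)
}

defaultSpecsPlus <- function(regs) {
  specs <- list(LuxR = regulatorSpec("LuxR", "activator", "AHL"))
  for (i in seq_along(regs))
    specs[[regs[i]]] <- regulatorSpec(regs[i], "repressor", paste0("ind", i))
  specs
}

test_that("adding an inducer never switches the output ON -> OFF", {
  set.seed(88)
  for (rep in 1:40) {
    m <- randomModel()
    tt <- truthTable(m)
    inputs <- tt@inputs
    if (!length(inputs)) next  # constitutive, operator-free model: one row
    for (i in seq_len(nrow(tt@rows))) {
      on <- unlist(tt@rows[i, inputs, drop = TRUE])
      if (tt@rows$output[i] != "ON") next
      for (j in which(!on)) {
        withJ <- inputs[on | seq_along(inputs) == j]
        expect_equal(evaluateState(m, withJ), "ON")
      }
    }
  }
})

test_that("adding a repressor operator only shrinks the ON set", {
  set.seed(89)
  for (rep in 1:25) {
    m <- randomModel()
    m2 <- m
    m2@operators <- rbind(m2@operators, data.frame(
      regulator = "Extra", mode = "repressor", inducer = "xtra",
      position = "downstream_of_core", start = 99L, stringsAsFactors = FALSE))
    m2@regulators <- unique(c(m2@regulators, "Extra"))
    m2@regulatorSpecs$Extra <- regulatorSpec("Extra", "repressor", "xtra")
    base <- truthTable(m)
    ext <- truthTable(m2)
    for (i in seq_len(nrow(ext@rows))) {
      on <- unlist(ext@rows[i, ext@inputs, drop = TRUE])
      state <- ext@inputs[on]
      if (ext@rows$output[i] == "ON")
        expect_equal(evaluateState(m, state), "ON")
    }
  }
})

test_that("a weak promoter without its activator available is a NULL device", {
  m <- new("RegulatoryModel",
           promoter = list(strength = "weak_activator_dependent",
                           linkedRegulator = "LuxR", label = "luxpR"),
           operators = data.frame(regulator = "LuxR", mode = "activator",
                                  inducer = "AHL",
                                  position = "upstream_of_core", start = 1L,
                                  stringsAsFactors = FALSE),
           regulators = character(0),  # no LuxR anywhere
           regulatorSpecs = list(LuxR = regulatorSpec("LuxR", "activator", "AHL")))
  expect_equal(truthTable(m)@gate, "NULL")
})
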