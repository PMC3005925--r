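test_that("the design formula reproduces the printed LacI-part oligos byte-exactly", {
  d <- designDownstreamPart("GGAATTGTGAGCGGATAACAATTCC", "ATCGTAA",
                            regulatorSpec("LacI", "repressor", "IPTG"))
  expect_identical(d$topOligo, PRINTED$lacO_top)
  expect_identical(d$bottomOligo, PRINTED$lacO_bottom)
  expect_true(validateDownstreamPart(d$part)@conforms)
})

test_that("design rejects forbidden payloads with a named site", {
  reg <- regulatorSpec("LacI", "repressor", "IPTG")
  expect_error(designDownstreamPart("AAACGCGTAAAA", "CCA", reg),
               regexp = "MluI", class = "designError")
  expect_error(designDownstreamPart("AAGGATCCAAAA", "CCA", reg),
               regexp = "BamHI", class = "designError")
  expect_error(designDownstreamPart("AAAGATCTAAAA", "CCA", reg),
               regexp = "BglII", class = "designError")
  # T-start would rebuild AGATCT across the BamHI/BglII joint
  expect_error(designDownstreamPart("TAAACCCAAA", "CCA", reg),
               class = "designError")
  # empty spacer leaves the core ending in ...AGATCT: MluI cannot rebuild
  expect_error(designDownstreamPart("AAAATTTT", "", reg),
               class = "designError")
  # construction by formula is still available with the rule relaxed
  d <- designDownstreamPart("AAAATTTT", "", reg, enforceMluIRestore = FALSE)
  expect_identical(d$topOligo, "GATCAAAATTTTAGATCT")
  expect_identical(d$bottomOligo, paste0("CGCG", revComp("AAAATTTTAGATCT")))
  expect_false(validateDownstreamPart(d$part)@conforms)
})

test_that("part validation reports each anatomical defect", {
  lacO <- lacOperatorPart()
  rep <- validateDownstreamPart(lacO)
  expect_true(rep@conforms)
  expect_true(all(rep@findings$status == "pass"))

  flipped <- flipFragment(lacO@fragment)   # overhangs swapped
  repF <- validateDownstreamPart(flipped)
  expect_false(repF@conforms)
  bad <- repF@findings[repF@findings$status == "fail", "check"]
  expect_true(all(c("left_end_GATC", "right_end_CGCG") %in% bad))

  twoBgl <- annealOligos(paste0("GATC", "AAGGCCAGATCTCCGGAAGATCT", "A"),
                         paste0("CGCG", revComp("AAGGCCAGATCTCCGGAAGATCTA")))
  repT <- validateDownstreamPart(twoBgl)
  expect_false(repT@conforms)
  expect_true("one_internal_BglII" %in%
                repT@findings[repT@findings$status == "fail", "check"])
})

test_that("the synthetic platform passes validation and defects are caught", {
  bb <- compactBackbone(11)
  expect_true(validatePlatform(bb)@conforms)
  # knock out the MluI site
  mutated <- bb
  mutated@core <- sub("ACGCGT", "ACGCAT", mutated@core, fixed = TRUE)
  repM <- validatePlatform(mutated)
  expect_false(repM@conforms)
  # unannotated plasmid is an annotation error, not a finding
  bare <- duplexFragment(bb@core, "circular")
  expect_error(validatePlatform(bare), class = "annotationError")
})

test_that("design -> anneal -> validate conforms for random payloads", {
  set.seed(401)
  for (i in 1:60) {
    part <- randomConformingPart(label = paste0("p", i))
    frag <- annealOligos(topStrand(part@fragment),
                         bottomStrand(part@fragment))
    expect_true(validateDownstreamPart(frag)@conforms)
  }
})

test_that("part files round-trip bit-exactly", {
  path <- tempfile(fileext = ".yaml")
  on.exit(unlink(path))
  lacO <- lacOperatorPart()
  writePartFile(lacO, path)
  back <- readPartFile(path)
  expect_identical(topStrand(back@fragment), PRINTED$lacO_top)
  expect_identical(bottomStrand(back@fragment), PRINTED$lacO_bottom)
  expect_identical(back@regulator@name, "LacI")
  expect_identical(back@regulator@inducer, "IPTG")
  expect_identical(back@partClass, "downstream")
})

test_that("upstream insertion enforces the sanctioned enzyme pairs", {
  bb <- compactBackbone(12)
  expect_error(insertUpstream(bb, placqPart(), c("BamHI", "MluI")),
               class = "argumentError")
  # Placq's TCGA/GATC ends cannot serve the EcoRI/XbaI route
  expect_error(insertUpstream(bb, placqPart(), c("EcoRI", "XbaI")),
               class = "orientationError")
})

test_that("the SalI/BglII route consumes the downstream BglII irrecoverably", {
  bb <- compactBackbone(13)
  viaBgl <- insertUpstream(bb, placqPart(), c("SalI", "BglII"),
                           name = "Placq-GFP-viaBglII")
  expect_length(findSites(viaBgl, enzymeByName("BglII"))$positions, 0)
  expect_false(validatePlatform(viaBgl)@conforms)
  # the SalI/BamHI route leaves the downstream pair intact and the product
  # conforms (SalI regenerated at the joint, Placq-internal BamHI in the MCS)
  viaBam <- insertUpstream(bb, placqPart(), c("SalI", "BamHI"),
                           name = "Placq-GFP")
  expect_true(validatePlatform(viaBam)@conforms)
  expect_length(findSites(viaBam, enzymeByName("BglII"))$positions, 1)
  expect_length(findSites(viaBam, enzymeByName("SalI"))$positions, 1)
})

test_that("sequential downstream insertion preserves conformance and order", {
  plasmid <- insertUpstream(compactBackbone(14), placqPart(),
                            c("SalI", "BamHI"), name = "chain")
  lacO <- lacOperatorPart()
  for (i in 1:4) {
    plasmid <- insertDownstream(plasmid, lacO)
    expect_true(validatePlatform(plasmid)@conforms)
  }
  ops <- plasmid@features[plasmid@features$role == "operator", ]
  expect_equal(nrow(ops), 4)
  expect_true(all(diff(sort(ops$start)) > 0))
  rbs <- plasmid@features[plasmid@features$role == "rbs", ]
  expect_true(all(ops$end < rbs$start))  # operators stay 5' of the RBS
})
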