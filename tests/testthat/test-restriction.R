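test_that("the builtin enzyme table encodes the seven standard geometries", {
  enz <- builtinEnzymes()
  expect_setequal(names(enz),
                  c("EcoRI", "XbaI", "SalI", "BamHI", "BglII", "MluI", "SpeI"))
  expect_equal(enz$BglII@recognition, "AGATCT")
  expect_equal(overhangSeq(enz$BglII), "GATC")
  expect_equal(enz$MluI@recognition, "ACGCGT")
  expect_equal(overhangSeq(enz$MluI), "CGCG")
  for (e in enz) {
    expect_identical(e@recognition, revComp(e@recognition))  # type-II palindromes
    expect_equal(overhangLength(e), 4L)                      # all 4-nt 5' overhangs
  }
  expect_error(enzymeByName("NotI"), class = "unknownEnzymeError")
})

test_that("site finding matches the engineered-region fixtures", {
  frag <- duplexFragment(PRINTED$primer_bglmlu)
  expect_equal(findSites(frag, enzymeByName("BglII"))$positions, 3L)
  expect_equal(findSites(frag, enzymeByName("MluI"))$positions, 17L)
  expect_length(findSites(frag, enzymeByName("EcoRI"))$positions, 0)
})

test_that("a recognition span reaching into a single-stranded overhang is uncuttable", {
  frags <- digest(duplexFragment("GGAGATCTGT"), enzymeByName("BglII"))
  expect_length(frags, 2)
  for (f in frags)  # the split site is single-stranded at both new ends
    expect_length(findSites(f, enzymeByName("BglII"))$positions, 0)
})

test_that("linear digestion applies the G^AATTC offsets exactly", {
  frags <- digest(duplexFragment("GGAATTCC"), enzymeByName("EcoRI"))
  expect_length(frags, 2)
  expect_identical(topStrand(frags[[1]]), "GG")
  expect_identical(bottomStrand(frags[[1]]), "AATTCC")
  expect_identical(rightEnd(frags[[1]])@overhang, "AATT")
  expect_identical(topStrand(frags[[2]]), "AATTCC")
  expect_identical(frags[[2]]@core, "CC")
  expect_identical(leftEnd(frags[[2]])@overhang, "AATT")
  # per-strand conservation
  parent <- strandCounts(duplexFragment("GGAATTCC"))
  got <- Reduce(`+`, lapply(frags, strandCounts))
  expect_equal(got, parent)
})

test_that("circular digestion with BglII+MluI releases the expected stuffer", {
  bb <- compactBackbone(1)
  enz <- builtinEnzymes()
  frags <- digest(bb, list(enz$BglII, enz$MluI))
  expect_length(frags, 2)
  small <- frags[[which.min(vapply(frags, fragmentLength, numeric(1)))]]
  expect_identical(leftEnd(small)@overhang, "GATC")
  expect_identical(rightEnd(small)@overhang, "CGCG")
  expect_identical(topStrand(small), "GATCTGTCGGATAA")
  parent <- strandCounts(bb)
  got <- Reduce(`+`, lapply(frags, strandCounts))
  expect_equal(got, parent)
})

test_that("a circular molecule with no site is returned uncut with a warning", {
  circ <- duplexFragment("AAACCCGGGTTTAAACCCGGG", "circular")
  expect_warning(out <- digest(circ, enzymeByName("EcoRI")), "no site")
  expect_length(out, 1)
  expect_true(attr(out, "uncut"))
  expect_identical(out[[1]]@core, circ@core)
})

test_that("overlapping staggered sites are resolved greedily with a warning", {
  # XbaI and BglII sites interleave in TCTAGATCT; both cannot fire
  mol <- duplexFragment("AAACCCTCTAGATCTGGGAAA")
  enz <- builtinEnzymes()
  expect_warning(frags <- digest(mol, list(enz$XbaI, enz$BglII)),
                 "overlapping")
  parent <- strandCounts(mol)
  expect_equal(Reduce(`+`, lapply(frags, strandCounts)), parent)
})

test_that("site finding and conservation agree with the naive oracle on random molecules", {
  set.seed(97)
  enz <- builtinEnzymes()
  for (i in 1:40) {
    s <- randomSeq(500)
    for (topo in c("linear", "circular")) {
      mol <- duplexFragment(s, topo)
      for (e in enz) {
        expect_identical(findSites(mol, e)$positions,
                         as.integer(oracleSites(s, e@recognition,
                                                topo == "circular")))
      }
      frags <- suppressWarnings(digest(mol, enz))
      expect_equal(Reduce(`+`, lapply(frags, strandCounts)), strandCounts(mol))
    }
  }
})

test_that("digestion then ligation round-trips a circular molecule up to rotation", {
  set.seed(5)
  enz <- builtinEnzymes()
  done <- 0
  for (i in 1:40) {
    s <- randomSeq(600)
    mol <- duplexFragment(s, "circular")
    frags <- suppressWarnings(digest(mol, enz))
    if (isTRUE(attr(frags, "uncut"))) next
    back <- ligate(frags, circularize = TRUE)
    expect_true(isRotation(back@core, mol@core))
    done <- done + 1
  }
  expect_gt(done, 10)  # most random 600-mers carry at least one site
})
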