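test_that("sticky-end compatibility captures the isocaudamer trick", {
  bglII <- stickyEnd("five_prime", "GATC", "bottom")  # a BglII-cut right end
  bamHI <- stickyEnd("five_prime", "GATC", "top")     # a BamHI-cut left end
  xbaI <- stickyEnd("five_prime", "CTAG", "bottom")
  speI <- stickyEnd("five_prime", "CTAG", "top")
  ecoRI <- stickyEnd("five_prime", "AATT", "top")
  mluI <- stickyEnd("five_prime", "CGCG", "bottom")
  expect_true(endsCompatible(bglII, bamHI))
  expect_true(endsCompatible(xbaI, speI))
  expect_false(endsCompatible(ecoRI, mluI))
  expect_true(endsCompatible(bluntA <- stickyEnd("blunt"), stickyEnd("blunt")))
  expect_false(endsCompatible(stickyEnd("blunt"), bamHI))
  # non-palindromic overhangs pair by reverse complementarity
  expect_true(endsCompatible(stickyEnd("five_prime", "AAGG", "bottom"),
                             stickyEnd("five_prime", "CCTT", "top")))
  expect_error(endsCompatible(stickyEnd("three_prime", "AAGG", "top"), bamHI),
               class = "unsupportedEndError")
})

test_that("ligation concatenates blunt fragments and refuses bad joints", {
  a <- duplexFragment("AAACCC"); b <- duplexFragment("GGGTTT")
  out <- ligate(list(a, b))
  expect_identical(out@core, "AAACCCGGGTTT")
  expect_equal(nrow(out@junctions), 1)
  lacO <- annealOligos(PRINTED$lacO_top, PRINTED$lacO_bottom)
  expect_error(ligate(list(a, lacO)), class = "ligationError")
})

test_that("downstream insertion seals the expected scars", {
  bb <- compactBackbone(3)
  product <- insertDownstream(bb, lacOperatorPart(), name = "test-product")
  j <- fragJunctions(product)
  expect_equal(nrow(j), 2)
  rec <- strsplit(j$recuttable, ",", fixed = TRUE)
  # BamHI/BglII joint: re-cuttable by neither enzyme
  expect_false(any(c("BamHI", "BglII") %in% rec[[1]]))
  # MluI joint: ACGCGT regenerated
  expect_true("MluI" %in% rec[[2]])
  expect_true(grepl("ACGCGT", j$sealed[2], fixed = TRUE))
})

test_that("a part offered in the wrong orientation is refused", {
  bb <- compactBackbone(4)
  enz <- builtinEnzymes()
  frags <- digest(bb, list(enz$BglII, enz$MluI))
  big <- frags[[which.max(vapply(frags, fragmentLength, numeric(1)))]]
  lacO <- annealOligos(PRINTED$lacO_top, PRINTED$lacO_bottom)
  expect_error(ligate(list(big, flipFragment(lacO)), circularize = TRUE),
               class = "ligationError")
  # with BglII/MluI ends the part fits in exactly one orientation; with a
  # BamHI x BglII backbone (identical GATC overhangs on both ends) a
  # GATC/GATC part fits both ways and is refused
  bb2 <- duplexFragment(
    paste0("GGATCCAAACCCAGATCT", "AAGGCACTGTCCAAGGTGCAAT"), "circular")
  symPart <- duplexFragment(
    "AAGGCACTGTCCAAGG", "linear",
    leftEnd = stickyEnd("five_prime", "GATC", "top"),
    rightEnd = stickyEnd("five_prime", "GATC", "bottom"))
  expect_error(insertPart(bb2, symPart, list("BamHI", "BglII")),
               class = "orientationError")
  # and a part fitting no orientation is refused too
  aattPart <- duplexFragment(
    "AAGGCACTGTCCAAGG", "linear",
    leftEnd = stickyEnd("five_prime", "AATT", "top"),
    rightEnd = stickyEnd("five_prime", "AATT", "bottom"))
  expect_error(insertPart(bb2, aattPart, list("BamHI", "BglII")),
               class = "orientationError")
})

test_that("insertion length arithmetic is exact", {
  bb <- compactBackbone(5)
  enz <- builtinEnzymes()
  part <- lacOperatorPart()
  frags <- digest(bb, list(enz$BglII, enz$MluI))
  small <- frags[[which.min(vapply(frags, fragmentLength, numeric(1)))]]
  product <- insertDownstream(bb, part)
  # product core = backbone core - stuffer(core + one overhang copy) + part
  expect_equal(nchar(product@core),
               nchar(bb@core) - nchar(small@core) - 4L +
                 nchar(part@fragment@core) + 4L)
  expect_equal(nchar(product@core), nchar(bb@core) - 14L + 42L)
})

test_that("insertion refuses a backbone with duplicated sites", {
  dup <- duplexFragment(
    paste0("AGATCTAAACCCAGATCTGGGTTTACGCGT",
           "AAACCCGGGTTTAAACCCGGGTTTAAACCCGGGTTT"),
    "circular")
  expect_error(insertPart(dup, lacOperatorPart(), list("BglII", "MluI")),
               class = "ambiguityError")
})

test_that("repeated downstream insertion regenerates BglII and MluI every time", {
  set.seed(314)
  plasmid <- compactBackbone(6)
  enz <- builtinEnzymes()
  for (i in 1:10) {
    part <- randomConformingPart(label = as.character(i))
    plasmid <- insertDownstream(plasmid, part)
    ds <- plasmid@features[plasmid@features$role == "downstream_region", ]
    expect_equal(nrow(ds), 1)
    span <- c(ds$start, ds$end)
    bgl <- findSites(plasmid, enz$BglII)$positions
    mlu <- findSites(plasmid, enz$MluI)$positions
    expect_length(bgl, 1); expect_length(mlu, 1)
    expect_true(bgl >= span[1] && bgl + 5 <= span[2])
    expect_true(mlu >= span[1] && mlu + 5 <= span[2])
  }
  # operators appear in insertion order, 5'->3'
  ops <- plasmid@features[plasmid@features$role == "operator", ]
  ops <- ops[order(ops$start), ]
  expect_identical(ops$regulator, paste0("R", 1:10))
})

test_that("digest of the ligation product is idempotent up to rotation", {
  bb <- compactBackbone(7)
  enz <- builtinEnzymes()
  frags <- digest(bb, list(enz$BglII, enz$MluI))
  back <- ligate(frags, circularize = TRUE)
  expect_true(isRotation(back@core, bb@core))
  again <- digest(back, list(enz$BglII, enz$MluI))
  expect_equal(sort(vapply(again, fragmentLength, numeric(1))),
               sort(vapply(frags, fragmentLength, numeric(1))))
})
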