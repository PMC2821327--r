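test_that("codon sets follow the standard genetic code", {
  expect_setequal(codonsOf("R"),
                  c("CGT", "CGC", "CGA", "CGG", "AGA", "AGG"))
  expect_identical(codonsOf("M"), "ATG")
  expect_identical(codonsOf("W"), "TGG")
  sizes <- vapply(AMINO_ACIDS <- sort(unique(unname(
    Biostrings::GENETIC_CODE[Biostrings::GENETIC_CODE != "*"]))),
    function(a) length(codonsOf(a)), integer(1))
  expect_equal(sum(sizes), 61)
  expect_setequal(names(sizes)[sizes == 1], c("M", "W"))
  expect_setequal(names(sizes)[sizes == 6], c("L", "S", "R"))
  expect_error(codonsOf("B"), "B")
  expect_error(codonsOf("U"), "U")
  expect_error(buildGraph("MSX*"), "X.*position 3")
})

test_that("triplet enumeration matches the combinatorics of the code", {
  full <- enumerateTriplets(FALSE)
  expect_equal(nrow(full), 99)
  expect_lt(nrow(full), 4 * 3 * 20)  # 240 hypothetical combinations
  cond <- enumerateTriplets(TRUE)
  expect_equal(nrow(cond), 69)
  ## branch-resolved: L, S, R contribute two branches of three symbols
  expect_equal(unname(table(cond$aa)[c("L", "S", "R")]), rep(6L, 3),
               ignore_attr = TRUE)
  expect_true(isValidTriplet("A", 1, "M"))   # ATG
  expect_true(isValidTriplet("A", 1, "I"))   # ATH
  expect_false(isValidTriplet("C", 1, "M"))
  expect_false(isValidTriplet("G", 1, "M"))
  ## validity = some codon carries the base at the position
  for (i in sample(nrow(full), 20))
    expect_true(isValidTriplet(full$symbol[i], full$pos[i], full$aa[i]))
})

test_that("full graphs have the worst-case node and arc structure", {
  gS <- buildGraph("S")
  expect_equal(nrow(graphNodes(gS)), 10)
  rc <- residueCounts(buildGraph("SSSS"))
  expect_equal(rc$arcs[2:3], c(20L, 20L))   # interior residues
  expect_equal(rc$units[1:3], rep(30L, 3))  # 10 nodes + 20 arcs
  ## second-position node splitting of serine: C after T, G after A
  nd <- graphNodes(gS)
  pos2 <- nd[nd$codonPos == 2, ]
  expect_setequal(paste0(pos2$prefix, pos2$symbol), c("TC", "AG"))
  ## no path spells a non-serine codon
  expect_setequal(enumeratePaths(gS), codonsOf("S"))
})

test_that("condensed graphs use one 3-node chain per branch", {
  expect_equal(nrow(graphNodes(buildGraph("R", TRUE))), 6)
  expect_equal(nrow(graphNodes(buildGraph("A", TRUE))), 3)
  expect_equal(nrow(graphNodes(buildGraph("YSH", TRUE))), 12)  # 3 + 6 + 3
  ## only R, Y, H, N ambiguity symbols ever arise
  cond <- enumerateTriplets(TRUE)
  expect_setequal(setdiff(unique(cond$symbol), c("A", "C", "G", "T")),
                  c("R", "Y", "H", "N"))
})

test_that("every path of the full graph translates back to the protein", {
  aas <- sort(unique(unname(
    Biostrings::GENETIC_CODE[Biostrings::GENETIC_CODE != "*"])))
  for (p in allProteins(aas, 1)) {
    paths <- enumeratePaths(buildGraph(p))
    expect_setequal(paths, codonsOf(p))
  }
  ## exhaustive 2-mers
  two <- allProteins(aas, 2)
  two <- two[nchar(two) == 2]
  for (p in two) {
    paths <- enumeratePaths(buildGraph(p))
    expect_equal(length(paths),
                 length(codonsOf(substr(p, 1, 1))) *
                   length(codonsOf(substr(p, 2, 2))))
    tr <- as.character(Biostrings::translate(Biostrings::DNAStringSet(paths),
                                             no.init.codon = TRUE))
    expect_true(all(tr == p))
  }
})

test_that("graph size stays within 30 units per residue", {
  set.seed(11)
  for (k in 1:20) {
    p <- randomProtein(30)
    rc <- residueCounts(buildGraph(p))
    expect_lte(max(rc$units), 30)
    expect_lte(sum(rc$units) / nchar(p), 30)
  }
})

test_that("condensed branches expand exactly to the codon sets", {
  aas <- sort(unique(unname(
    Biostrings::GENETIC_CODE[Biostrings::GENETIC_CODE != "*"])))
  for (a in aas) {
    branches <- aaBranches(a)
    expanded <- unlist(lapply(branches, function(br)
      expandAmbiguous(paste(br$symbols, collapse = ""))))
    expect_setequal(expanded, codonsOf(a))
    ## graph-level: condensed path expansion equals full path set
    p1 <- expandAmbiguous(enumeratePaths(buildGraph(a, TRUE)))
    expect_setequal(p1, enumeratePaths(buildGraph(a)))
  }
})

test_that("reverse complement is an involution preserving structure", {
  g <- buildGraph("GSH", TRUE)
  rr <- reverseComplement(reverseComplement(g))
  expect_equal(graphNodes(rr)$symbol, graphNodes(g)$symbol)
  expect_equal(graphNodes(rr)$layer, graphNodes(g)$layer)
  expect_setequal(apply(graphArcs(rr), 1, paste, collapse = ","),
                  apply(graphArcs(g), 1, paste, collapse = ","))
  expect_identical(enumeratePaths(reverseComplement(buildGraph("M"))), "CAT")
  ## path count is preserved
  for (p in c("R", "SS", "YLH")) {
    g <- buildGraph(p)
    expect_equal(length(enumeratePaths(reverseComplement(g))),
                 length(enumeratePaths(g)))
  }
})

test_that("path enumeration is guarded and DNA graphs are single paths", {
  expect_error(enumeratePaths(buildGraph("SSSSSS"), maxPaths = 100),
               "maxPaths")
  g <- dnaGraph("ACGTT")
  expect_identical(enumeratePaths(g), "ACGTT")
  expect_error(dnaGraph("ACGX"), "X")
})

test_that("graph dump renders layers and arcs as documented text", {
  f <- tempfile()
  dumpGraph(buildGraph("M"), f)
  lines <- readLines(f)
  expect_equal(lines[1], "layer 1: A/.")
  expect_true(any(grepl("^\\(1,1\\)->\\(2,1\\)$", lines)))
})
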