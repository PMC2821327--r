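test_that("single-codon self-alignment scores the three diagonal triplets", {
  tsm <- fxScoreMatrix(0.5)
  tt <- enumerateTriplets(FALSE)
  idx <- function(l) match(l, tt$label)
  expected <- tsm@scores[idx("A.1.M"), idx("A.1.M")] +
    tsm@scores[idx("T.2.M"), idx("T.2.M")] +
    tsm@scores[idx("G.3.M"), idx("G.3.M")]
  res <- align(buildGraph("M"), buildGraph("M"), tsm)
  expect_equal(res@score, expected)
  expect_equal(nrow(res@columns), 3)
  expect_equal(res@frameshifts, 0L)
})

test_that("all-negative scoring yields the empty alignment", {
  g <- dnaGraph("ACGT")
  S <- matrix(-1, 4, 4, dimnames = list(c("A","C","G","T"),
                                        c("A","C","G","T")))
  res <- align(g, dnaGraph("TTTT"), S)
  expect_equal(res@score, 0)
  expect_equal(nrow(res@columns), 0)
})

test_that("graph DP equals the enumeration oracle on sampled small pairs", {
  tsm <- fxScoreMatrix(0.5)
  asm <- fxCondensed(0.5)
  gaps <- fxGaps()
  prots <- allProteins(c("M", "R", "S", "H"), 2)
  set.seed(21)
  pick <- prots[sample(length(prots), 8)]
  for (pa in pick) for (pb in pick) {
    oracle <- oracleBestScore(pa, pb, tsm, gaps)
    expect_equal(alignScore(buildGraph(pa), buildGraph(pb), tsm, gaps),
                 oracle, tolerance = 1e-9)
    expect_equal(alignScore(buildGraph(pa, TRUE), buildGraph(pb, TRUE),
                            asm, gaps),
                 oracle, tolerance = 1e-9)
  }
})

test_that("score is invariant under swapping the inputs", {
  asm <- fxCondensed(0.5)
  set.seed(8)
  for (k in 1:5) {
    a <- buildGraph(randomProtein(15), TRUE)
    b <- buildGraph(randomProtein(15), TRUE)
    expect_equal(alignScore(a, b, asm), alignScore(b, a, asm))
  }
})

test_that("raising the frameshift budget never lowers the score", {
  asm <- fxCondensed(0.6)
  set.seed(9)
  for (k in 1:5) {
    sp <- simulateFrameshiftPair(25, 0.3, 0.3, 12, 1, seed = 400 + k)
    a <- buildGraph(sp@proteinA, TRUE); b <- buildGraph(sp@proteinB, TRUE)
    s0 <- alignScore(a, b, asm, maxFrameshifts = 0)
    s1 <- alignScore(a, b, asm, maxFrameshifts = 1)
    s3 <- alignScore(a, b, asm, maxFrameshifts = 3)
    expect_lte(s0, s1)
    expect_lte(s1, s3)
  }
})

test_that("with no frameshift budget all fragments stay in one frame", {
  asm <- fxCondensed(0.6)
  sp <- simulateFrameshiftPair(25, 0.3, 0.3, 12, 1, seed = 77)
  a <- buildGraph(sp@proteinA, TRUE); b <- buildGraph(sp@proteinB, TRUE)
  res <- align(a, b, asm, maxFrameshifts = 0)
  expect_equal(nrow(res@fragments), 1)
  expect_equal(length(unique(stats::na.omit(res@columns$d))), 1)
})

test_that("self-alignment yields one full-length in-frame fragment", {
  asm <- fxCondensed(0.5)
  p <- "MTEYKLVVVGAGGVGKSALT"
  res <- align(buildGraph(p, TRUE), buildGraph(p, TRUE), asm)
  expect_equal(nrow(res@fragments), 1)
  expect_equal(res@fragments$d, 0)
  expect_equal(res@spans, c(1L, 60L, 1L, 60L))
  ## the inferred DNA translates back to the protein
  expect_equal(backtralign:::translateDNA(res@dnaA), p)
  expect_equal(res@dnaA, res@dnaB)
})

test_that("fragment count is one more than the frameshift count", {
  asm <- fxCondensed(0.6)
  for (k in 1:5) {
    sp <- simulateFrameshiftPair(30, 0.2, 0.2, 15, 1, seed = 900 + k)
    res <- align(buildGraph(sp@proteinA, TRUE),
                 buildGraph(sp@proteinB, TRUE), asm)
    skipAmbiguity <- any(res@columns$move %in% c("skipA", "skipB"))
    if (!skipAmbiguity)
      expect_equal(nrow(res@fragments), res@frameshifts + 1)
  }
})

test_that("plain DNA graphs align full length against themselves", {
  dna <- "ATGGCTAGCAAGGGCGAGGAGCTG"
  res <- align(dnaGraph(dna), dnaGraph(dna), dnaScoreMatrix(),
               ungapped = TRUE)
  expect_equal(res@score, 5 * nchar(dna))
  expect_equal(res@dnaA, dna)
})

test_that("reduced-memory alignment reproduces the full DP exactly", {
  asm <- fxCondensed(0.6)
  gaps <- fxGaps()
  for (k in 1:10) {
    sp <- simulateFrameshiftPair(35, 0.3, 0.3, 18, 1, seed = 1200 + k)
    a <- buildGraph(sp@proteinA, TRUE); b <- buildGraph(sp@proteinB, TRUE)
    full <- align(a, b, asm, gaps)
    lin <- alignLinearSpace(a, b, asm, gaps, cutWidth = 16)
    expect_equal(lin@score, full@score)
    expect_identical(lin@columns[, c("posA", "posB", "move")],
                     full@columns[, c("posA", "posB", "move")])
  }
  expect_error(alignLinearSpace(a, b, asm, gaps, cutWidth = 3), "cutWidth")
})

test_that("orientations are tracked and reverse-complement is symmetric", {
  asm <- fxCondensed(0.5)
  a <- buildGraph("MKLHNSWRT", TRUE); b <- buildGraph("MKAHNSYRT", TRUE)
  both <- alignBothOrientations(a, b, asm)
  expect_equal(both$forward@orientation, "forward")
  expect_equal(both$reverse@orientation, "reverse-complement")
  expect_equal(alignScore(a, reverseComplement(b), asm),
               alignScore(reverseComplement(a), b, asm))
  ## a non-palindromic self-comparison favors the forward orientation
  m <- buildGraph("MMMMM", TRUE)
  bm <- alignBothOrientations(m, m, asm)
  expect_gte(bm$forward@score, bm$reverse@score)
})

test_that("representation mismatches are rejected", {
  tsm <- fxScoreMatrix(0.5)
  asm <- fxCondensed(0.5)
  expect_error(align(buildGraph("MS", TRUE), buildGraph("MS", TRUE), tsm),
               "full")
  expect_error(align(buildGraph("MS"), buildGraph("MS"), asm), "condensed")
  expect_error(align(buildGraph("MS"), buildGraph("MS"), tsm,
                     maxFrameshifts = -1), "maxFrameshifts")
})

test_that("alignment text rendering shows fragments and gap flags", {
  asm <- fxCondensed(0.6)
  sp <- simulateFrameshiftPair(20, 0.1, 0.1, 10, 1, seed = 55)
  res <- align(buildGraph(sp@proteinA, TRUE), buildGraph(sp@proteinB, TRUE),
               asm)
  txt <- formatAlignment(res)
  expect_true(any(grepl("^score:", txt)))
  expect_true(any(grepl("fragment", txt)))
  if (res@frameshifts > 0) expect_true(any(grepl("!", txt, fixed = TRUE)))
})
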