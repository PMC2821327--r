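test_that("the simulator honors zero divergence and determinism", {
  sp0 <- simulateFrameshiftPair(20, 0, 0, NA, seed = 1)
  expect_identical(sp0@proteinA, sp0@proteinB)
  expect_identical(sp0@dnaA, sp0@ancestorDNA)
  ## one +1 frameshift at zero divergence: identical up to the frameshift
  sp <- simulateFrameshiftPair(20, 0, 0, 10, 1, seed = 2)
  expect_identical(substr(sp@proteinA, 1, 9), substr(sp@proteinB, 1, 9))
  expect_false(identical(sp@proteinA, sp@proteinB))
  expect_equal(nchar(sp@proteinB), 19)  # one base lost, trailing codon dropped
  sp2 <- simulateFrameshiftPair(20, 0, 0, 10, 1, seed = 2)
  expect_identical(sp2@dnaB, sp@dnaB)
  ## translations recorded consistently
  expect_identical(backtralign:::translateDNA(sp@dnaA), sp@proteinA)
  expect_identical(backtralign:::translateDNA(sp@dnaB), sp@proteinB)
  expect_error(simulateFrameshiftPair(20, 0, 0, 10, 3, seed = 1),
               "1 or 2")
  expect_error(simulateFrameshiftPair(20, 0, 0, 25, 1, seed = 1), "inside")
  expect_error(simulateFrameshiftPair(3, 0, 0, NA, seed = 1), ">= 5")
})

test_that("the aligner recovers planted frameshift fragments", {
  asm <- fxCondensed(0.6)
  sp <- simulateFrameshiftPair(30, 0, 0, 15, 1, seed = 9)
  res <- align(buildGraph(sp@proteinA, TRUE), buildGraph(sp@proteinB, TRUE),
               asm)
  expect_gte(nrow(res@fragments), 2)
  ds <- stats::na.omit(res@fragments$d)
  expect_equal(ds[1], 0)        # in-frame before the frameshift
  expect_true(any(ds != 0))     # shifted after
  rec <- frameshiftRecovery(nSim = 10, theta = 0.2, lengthCodons = 30,
                            seed = 70, scores = asm)
  expect_true(all(is.finite(rec$error)))
  expect_lte(stats::median(rec$error), 1)
})

test_that("run configs round-trip through the key=value format", {
  cfg <- runConfig(theta = 0.35, maxFrameshifts = 2, orientation = "forward")
  f <- tempfile()
  writeRunConfig(cfg, f)
  back <- readRunConfig(f)
  expect_equal(back$theta, 0.35)
  expect_equal(back$maxFrameshifts, 2)
  expect_equal(back$orientation, "forward")
  expect_error(runConfig(bogus = 1), "unknown config key")
})

test_that("FASTA input is parsed with wrapping, multi-record and IDs", {
  f <- tempfile(fileext = ".fasta")
  writeLines(c(">p1 first protein", "MKLH", "NSWRT",
               ">p2 second", "MAAA"), f)
  r <- readFastaSequence(f)
  expect_equal(r$seq, "MKLHNSWRT")
  expect_equal(r$type, "protein")
  r2 <- readFastaSequence(f, id = "p2")
  expect_equal(r2$seq, "MAAA")
  expect_error(readFastaSequence(f, id = "p9"), "p9")
  d <- writeTempFasta(c(x = "acgtacgt"))
  rd <- readFastaSequence(d)
  expect_equal(rd$type, "dna")
  expect_equal(rd$seq, "ACGTACGT")
})

test_that("the pipeline aligns protein FASTA end to end", {
  p <- "MKLHNSWRTAGD"
  fa <- writeTempFasta(c(a = p)); fb <- writeTempFasta(c(b = p))
  out <- runPipeline(runConfig(theta = 0.3, orientation = "both"), fa, fb)
  expect_named(out$alignments, c("forward", "reverse"))
  fw <- out$alignments$forward
  expect_equal(nrow(fw@fragments), 1)
  expect_equal(fw@fragments$d, 0)
  expect_equal(fw@spans, c(1L, 36L, 1L, 36L))
  expect_true(any(grepl("score:", out$report)))
  expect_equal(out$record$idA, "a")
})

test_that("the pipeline accepts DNA input as single-path graphs", {
  dna <- "ATGGCTAGCAAGGGCGAGGAG"
  fa <- writeTempFasta(c(a = dna)); fb <- writeTempFasta(c(b = dna))
  out <- runPipeline(runConfig(orientation = "forward"), fa, fb)
  expect_equal(out$alignments$forward@score, 5 * nchar(dna))
  ## mixed input is refused
  fp <- writeTempFasta(c(p = "MKLH"))
  expect_error(runPipeline(runConfig(orientation = "forward"), fa, fp),
               "mixed")
})

test_that("a missing calibration file points at the calibrate step", {
  fa <- writeTempFasta(c(a = "MKLHNSWRT"))
  cfg <- runConfig(calibrationFile = tempfile())
  expect_error(runPipeline(cfg, fa, fa), "calibrate")
})

test_that("the CLI simulate subcommand writes FASTA plus a truth record", {
  cli <- system.file("cli", "backtralign.R", package = "backtralign")
  expect_true(nzchar(cli))
  prefix <- tempfile()
  out <- system2("Rscript", c(cli, "simulate", "--length", "20",
                              "--theta", "0.2", "--position", "10",
                              "--offset", "1", "--seed", "4",
                              "--out", prefix),
                 stdout = TRUE, stderr = TRUE)
  expect_true(file.exists(paste0(prefix, "_A.fasta")))
  truth <- readLines(paste0(prefix, "_truth.txt"))
  expect_true(any(grepl("frameshiftPosition=10", truth)))
  sp <- simulateFrameshiftPair(20, 0.2, 0.2, 10, 1, seed = 4)
  expect_equal(readFastaSequence(paste0(prefix, "_A.fasta"))$seq,
               sp@proteinA)
})
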