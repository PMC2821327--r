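## Shared fixtures, built once per test run.

.fx <- new.env(parent = emptyenv())

fxScoreMatrix <- function(theta = 0.5) {
  key <- paste0("tsm", theta)
  if (is.null(.fx[[key]])) .fx[[key]] <- buildScoreMatrix(theta)
  .fx[[key]]
}

fxCondensed <- function(theta = 0.5) {
  key <- paste0("asm", theta)
  if (is.null(.fx[[key]]))
    .fx[[key]] <- condenseScoreMatrix(fxScoreMatrix(theta))
  .fx[[key]]
}

fxGaps <- function() gapParams()

## Map a putative coding DNA sequence of `prot` to the triplet indices its
## bases occupy -- used to feed enumerated paths to the plain-sequence
## oracle DP.
tripletIdsOfDNA <- function(dna, prot) {
  tt <- enumerateTriplets(FALSE)
  n <- nchar(dna)
  vapply(seq_len(n), function(i) {
    p <- (i - 1L) %% 3L + 1L
    a <- substr(prot, (i - 1L) %/% 3L + 1L, (i - 1L) %/% 3L + 1L)
    which(tt$symbol == substr(dna, i, i) & tt$pos == p & tt$aa == a)
  }, integer(1))
}

## Best score over all enumerated putative DNA pairs under the same scoring
## and gap rules, via the independent plain-sequence DP (no graphs).
oracleBestScore <- function(protA, protB, tsm, gaps = fxGaps(),
                            maxFrameshifts = 3L) {
  seqsA <- lapply(enumeratePaths(buildGraph(protA)), tripletIdsOfDNA,
                  prot = protA)
  seqsB <- lapply(enumeratePaths(buildGraph(protB)), tripletIdsOfDNA,
                  prot = protB)
  backtralign:::cppOracleBest(seqsA, seqsB, tsm@scores, gaps@single,
                              gaps@triple, as.integer(maxFrameshifts),
                              TRUE, TRUE)
}

## All proteins over an alphabet up to a given length.
allProteins <- function(alphabet, maxLen) {
  unlist(lapply(seq_len(maxLen), function(L)
    apply(expand.grid(rep(list(alphabet), L)), 1, paste, collapse = "")))
}

writeTempFasta <- function(seqs, ids = names(seqs)) {
  f <- tempfile(fileext = ".fasta")
  writeLines(as.vector(rbind(paste0(">", ids), seqs)), f)
  f
}

## Synthetic 64x64 "empirical-style" codon matrix (NOT estimated from real
## alignments; for loader tests only): mechanistic P(0.5) padded with
## uniform stop-codon rows/columns.
writeSyntheticEmpirical <- function(file = tempfile(fileext = ".tsv")) {
  P <- fxCondensed()  # ensure cache warm; actual probs from the model below
  mod <- mechanisticModel(0.5)
  gc <- Biostrings::GENETIC_CODE
  all64 <- names(gc)
  m <- matrix(1 / 64, 64, 64, dimnames = list(all64, all64))
  m[rownames(mod@probs), colnames(mod@probs)] <- mod@probs
  writeCodonMatrix(m, file)
  file
}
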