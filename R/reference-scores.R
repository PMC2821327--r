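## Conditional codon weights within an amino acid: pi_c / sum(pi over codons
## of the amino acid).
.codonWeights <- function(aa, pi) {
  cs <- codonsOf(aa)
  w <- pi[cs]
  w / sum(w)
}

#' Expected amino-acid pair scores of a triplet matrix
#'
#' For each amino-acid pair, the expectation over codon pairs (weighted by
#' conditional codon frequencies within each amino acid) of the sum of the
#' three positionwise triplet substitution scores. This is how the
#' translation-dependent system behaves in a frameshift-free alignment, and
#' what is correlated against classic amino-acid and DNA scoring systems.
#'
#' @param tsm A \linkS4class{TripletScoreMatrix}.
#' @param pi Codon frequencies.
#' @return Symmetric 20x20 matrix (amino-acid dimnames).
#' @export
expectedAAScores <- function(tsm, pi = uniformCodonFrequencies()) {
  aas <- AMINO_ACIDS()
  tt <- enumerateTriplets(FALSE)
  tIdx <- .tripletIndex(FALSE)
  S <- tsm@scores
  E <- matrix(0, 20, 20, dimnames = list(aas, aas))
  for (ai in seq_along(aas)) for (aj in ai:length(aas)) {
    wi <- .codonWeights(aas[ai], pi); wj <- .codonWeights(aas[aj], pi)
    v <- 0
    for (ci in names(wi)) for (cj in names(wj)) {
      s3 <- sum(vapply(1:3, function(p)
        S[tIdx[paste(substr(ci, p, p), p, aas[ai], sep = ".")],
          tIdx[paste(substr(cj, p, p), p, aas[aj], sep = ".")]],
        numeric(1)))
      v <- v + wi[ci] * wj[cj] * s3
    }
    E[ai, aj] <- E[aj, ai] <- v
  }
  E
}

#' Expected amino-acid pair scores under classic DNA scoring
#'
#' Reference analogue of \code{\link{expectedAAScores}} where the positionwise
#' score is the classic match/transition/transversion value, independent of
#' the translation context.
#'
#' @param match,transition,transversion DNA scores (defaults +5/-3/-4).
#' @param pi Codon frequencies.
#' @return Symmetric 20x20 matrix.
#' @export
expectedAAScoresDNA <- function(match = 5, transition = -3,
                                transversion = -4,
                                pi = uniformCodonFrequencies()) {
  dna <- dnaScoreMatrix(match, transition, transversion)
  aas <- AMINO_ACIDS()
  E <- matrix(0, 20, 20, dimnames = list(aas, aas))
  for (ai in seq_along(aas)) for (aj in ai:length(aas)) {
    wi <- .codonWeights(aas[ai], pi); wj <- .codonWeights(aas[aj], pi)
    v <- 0
    for (ci in names(wi)) for (cj in names(wj)) {
      s3 <- sum(vapply(1:3, function(p)
        dna[substr(ci, p, p), substr(cj, p, p)], numeric(1)))
      v <- v + wi[ci] * wj[cj] * s3
    }
    E[ai, aj] <- E[aj, ai] <- v
  }
  E
}

#' Bundled BLOSUM62 reference matrix
#'
#' Standard published BLOSUM62 substitution scores (half-bit integers),
#' shipped as plain text and restricted to the 20 standard amino acids.
#'
#' @return Symmetric 20x20 integer matrix.
#' @export
blosum62 <- function() {
  file <- system.file("extdata", "BLOSUM62.txt", package = "backtralign",
                      mustWork = TRUE)
  m <- as.matrix(utils::read.table(file, header = TRUE, row.names = 1,
                                   check.names = FALSE, comment.char = "#"))
  aas <- AMINO_ACIDS()
  m[aas, aas]
}

#' Correlate expected scores with reference scoring systems
#'
#' Pearson correlation, over the 210 unordered amino-acid pairs, of an
#' expected amino-acid score table with (i) the classic DNA
#' match/transition/transversion reference and (ii) BLOSUM62.
#'
#' @param expected 20x20 expected-score matrix
#'   (\code{\link{expectedAAScores}}).
#' @param blosum Reference amino-acid matrix (defaults to the bundled
#'   BLOSUM62).
#' @param dnaParams Numeric length-3: match, transition, transversion scores.
#' @param pi Codon frequencies for the DNA reference expectation.
#' @return Named numeric vector \code{c(dna = ..., blosum = ...)}.
#' @export
correlateWithReferences <- function(expected, blosum = blosum62(),
                                    dnaParams = c(5, -3, -4),
                                    pi = uniformCodonFrequencies()) {
  aas <- AMINO_ACIDS()
  if (!all(dim(expected) == c(20, 20)) || !all(dim(blosum) == c(20, 20)))
    stop("expected and blosum must be 20x20 amino-acid matrices")
  expected <- expected[aas, aas]
  blosum <- blosum[aas, aas]
  dnaRef <- expectedAAScoresDNA(dnaParams[1], dnaParams[2], dnaParams[3], pi)
  ut <- upper.tri(expected, diag = TRUE)
  c(dna = stats::cor(expected[ut], dnaRef[ut]),
    blosum = stats::cor(expected[ut], blosum[ut]))
}

#' Reference-correlation table across evolutionary distances
#'
#' Builds mechanistic translation-dependent matrices over a grid of
#' evolutionary distances (and optionally an empirical one), computes their
#' expected amino-acid scores, and correlates each with the DNA reference and
#' BLOSUM62. With no empirical matrix file, the empirical row is skipped with
#' a warning.
#'
#' @param thetas Evolutionary distance grid.
#' @param empiricalFile Optional path to an empirical codon matrix.
#' @param omega,kappa Mechanistic parameters.
#' @param pi Codon frequencies.
#' @param dnaParams DNA reference scores.
#' @return data.frame with columns \code{matrix}, \code{dna}, \code{blosum}.
#' @export
referenceCorrelationTable <- function(thetas = c(0.1, 0.3, 0.5, 0.7, 1.0),
                                      empiricalFile = NULL,
                                      omega = 0.2, kappa = 4.0,
                                      pi = uniformCodonFrequencies(),
                                      dnaParams = c(5, -3, -4)) {
  rows <- lapply(thetas, function(th) {
    tsm <- buildScoreMatrix(th, pi = pi, omega = omega, kappa = kappa)
    cc <- correlateWithReferences(expectedAAScores(tsm, pi),
                                  dnaParams = dnaParams, pi = pi)
    data.frame(matrix = sprintf("mechanistic(%.1f)", th),
               theta = th, dna = cc["dna"], blosum = cc["blosum"],
               row.names = NULL)
  })
  out <- do.call(rbind, rows)
  if (is.null(empiricalFile)) {
    warning("no empirical codon matrix file supplied; ",
            "empirical correlation row skipped")
  } else {
    mod <- loadEmpiricalMatrix(empiricalFile, pi)
    tsm <- buildScoreMatrix(mod, pi = pi)
    cc <- correlateWithReferences(expectedAAScores(tsm, pi),
                                  dnaParams = dnaParams, pi = pi)
    out <- rbind(out, data.frame(matrix = "empirical", theta = NA,
                                 dna = cc["dna"], blosum = cc["blosum"],
                                 row.names = NULL))
  }
  rownames(out) <- NULL
  out
}
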