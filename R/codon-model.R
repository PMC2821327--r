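.isTransition <- function(a, b) {
  (a %in% c("A", "G") && b %in% c("A", "G")) ||
    (a %in% c("C", "T") && b %in% c("C", "T"))
}

#' Uniform codon frequencies
#'
#' Uniform distribution over the 61 sense codons, the default equilibrium
#' frequency vector when no codon-usage table is supplied.
#'
#' @return Named numeric vector of length 61 summing to 1.
#' @export
uniformCodonFrequencies <- function() {
  cs <- SENSE_CODONS()
  stats::setNames(rep(1 / length(cs), length(cs)), cs)
}

#' Read a codon frequency table
#'
#' Plain-text format: lines \code{CODON<TAB>frequency}; \code{#} comments.
#' Stop codons are dropped; frequencies are renormalized over the 61 sense
#' codons.
#'
#' @param file Path.
#' @return Named numeric vector over the sense codons, summing to 1.
#' @export
readCodonFrequencies <- function(file) {
  tab <- utils::read.table(file, comment.char = "#", header = FALSE,
                           col.names = c("codon", "freq"),
                           colClasses = c("character", "numeric"))
  tab$codon <- toupper(gsub("U", "T", tab$codon))
  if (any(tab$freq < 0))
    stop("negative frequency for codon ", tab$codon[which(tab$freq < 0)[1]])
  cs <- SENSE_CODONS()
  missing <- setdiff(cs, tab$codon)
  if (length(missing))
    stop("codon frequency table is missing codon ", missing[1])
  pi <- stats::setNames(tab$freq[match(cs, tab$codon)], cs)
  pi / sum(pi)
}

#' Build the mechanistic codon rate matrix
#'
#' Goldman-Yang-type Markov generator over the 61 sense codons: the rate from
#' codon i to codon j is zero if they differ at two or more positions, and
#' otherwise proportional to the target frequency pi_j, multiplied by kappa
#' for a transition and by omega for a nonsynonymous change. Diagonal entries
#' make rows sum to zero, and the matrix is rescaled so the mean substitution
#' rate at equilibrium is 1, making the evolutionary distance theta an
#' expected number of nucleotide substitutions per codon.
#'
#' @param omega Nonsynonymous/synonymous rate ratio (>= 0).
#' @param kappa Transition/transversion rate ratio (>= 0).
#' @param pi Equilibrium codon frequencies over the sense codons (sums to 1).
#' @return 61x61 rate matrix Q with codon dimnames.
#' @export
buildRateMatrix <- function(omega = 0.2, kappa = 4.0,
                            pi = uniformCodonFrequencies()) {
  stopifnot(omega >= 0, kappa >= 0, all(pi >= 0))
  if (abs(sum(pi) - 1) > 1e-6)
    stop("pi must sum to 1 (got ", format(sum(pi)), ")")
  cs <- SENSE_CODONS()
  pi <- pi[cs]
  nc <- length(cs)
  Q <- matrix(0, nc, nc, dimnames = list(cs, cs))
  aa <- aaOfCodon(cs)
  split1 <- strsplit(cs, "")
  for (i in seq_len(nc)) for (j in seq_len(nc)) {
    if (i == j) next
    diff <- which(split1[[i]] != split1[[j]])
    if (length(diff) != 1L) next
    r <- pi[j]
    if (.isTransition(split1[[i]][diff], split1[[j]][diff])) r <- r * kappa
    if (aa[i] != aa[j]) r <- r * omega
    Q[i, j] <- r
  }
  diag(Q) <- -rowSums(Q)
  scale <- -sum(pi * diag(Q))
  Q / scale
}

#' Codon substitution probabilities at distance theta
#'
#' Computes P(theta) = expm(theta * Q) for a valid generator Q.
#'
#' @param Q Rate matrix from \code{\link{buildRateMatrix}}.
#' @param theta Evolutionary distance (>= 0), expected nucleotide
#'   substitutions per codon.
#' @param pi Equilibrium frequencies used to build Q (stored for provenance).
#' @param params Optional list of model parameters (omega, kappa).
#' @return A \linkS4class{CodonSubstitutionModel}.
#' @export
transitionProbabilities <- function(Q, theta, pi = uniformCodonFrequencies(),
                                    params = list()) {
  if (theta < 0) stop("theta must be >= 0")
  P <- as.matrix(Matrix::expm(theta * Q))
  dimnames(P) <- dimnames(Q)
  P[P < 0] <- 0          # clip expm round-off
  P <- P / rowSums(P)
  new("CodonSubstitutionModel", probs = P, pi = pi[rownames(P)],
      theta = theta, source = "mechanistic", params = params)
}

#' Mechanistic codon substitution model in one step
#'
#' @inheritParams buildRateMatrix
#' @inheritParams transitionProbabilities
#' @return A \linkS4class{CodonSubstitutionModel}.
#' @export
mechanisticModel <- function(theta, omega = 0.2, kappa = 4.0,
                             pi = uniformCodonFrequencies()) {
  Q <- buildRateMatrix(omega, kappa, pi)
  transitionProbabilities(Q, theta, pi, params = list(omega = omega,
                                                      kappa = kappa))
}

#' Load an empirical codon substitution matrix
#'
#' Reads a tab-separated 64x64 (or 61x61) codon substitution probability
#' table with codon row/column labels (e.g. a "1-codon PAM" matrix estimated
#' from coding-sequence alignments). Stop-codon rows and columns are dropped
#' and the remaining rows renormalized over the 61 sense codons.
#'
#' @param file Path to the table.
#' @param pi Codon frequencies to associate with the model.
#' @return A \linkS4class{CodonSubstitutionModel} with
#'   \code{source = "empirical"}.
#' @export
loadEmpiricalMatrix <- function(file, pi = uniformCodonFrequencies()) {
  m <- as.matrix(utils::read.table(file, header = TRUE, row.names = 1,
                                   sep = "\t", check.names = FALSE,
                                   comment.char = "#"))
  rownames(m) <- toupper(gsub("U", "T", rownames(m)))
  colnames(m) <- toupper(gsub("U", "T", colnames(m)))
  cs <- SENSE_CODONS()
  missing <- setdiff(cs, rownames(m))
  if (length(missing))
    stop("empirical matrix is missing codon ", missing[1])
  missing <- setdiff(cs, colnames(m))
  if (length(missing))
    stop("empirical matrix is missing codon column ", missing[1])
  m <- m[cs, cs]
  if (any(m < 0)) {
    bad <- which(m < 0, arr.ind = TRUE)[1, ]
    stop("negative entry at ", cs[bad[1]], " -> ", cs[bad[2]])
  }
  if (any(rowSums(m) == 0)) stop("empirical matrix has an all-zero row")
  if (max(abs(rowSums(m) - 1)) > 1e-12)  # keep already-stochastic input bit-exact
    m <- m / rowSums(m)
  new("CodonSubstitutionModel", probs = m, pi = pi[cs], theta = NA_real_,
      source = "empirical", params = list())
}

#' Write a codon substitution matrix
#'
#' Tab-separated with codon labels; the bit-exact inverse of
#' \code{\link{loadEmpiricalMatrix}} up to renormalization.
#'
#' @param model A \linkS4class{CodonSubstitutionModel} (or plain matrix).
#' @param file Output path.
#' @export
writeCodonMatrix <- function(model, file) {
  m <- if (is(model, "CodonSubstitutionModel")) model@probs else model
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(paste(c("", colnames(m)), collapse = "\t"), con)
  for (i in seq_len(nrow(m)))
    writeLines(paste(c(rownames(m)[i], sprintf("%.17g", m[i, ])),
                     collapse = "\t"), con)
}

setMethod("show", "CodonSubstitutionModel", function(object) {
  cat("CodonSubstitutionModel (", object@source, ")\n", sep = "")
  if (!is.na(object@theta))
    cat("  theta =", object@theta, "substitutions/codon\n")
  if (length(object@params))
    cat("  omega =", object@params$omega, ", kappa =", object@params$kappa,
        "\n")
})
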