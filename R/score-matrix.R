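## Marginal probability of a codon fragment: sum of pi over codons carrying
## the given bases at the given codon positions.
.fragmentMarginal <- function(pi, positions, bases) {
  cs <- names(pi)
  keep <- rep(TRUE, length(cs))
  for (k in seq_along(positions))
    keep <- keep & substr(cs, positions[k], positions[k]) == bases[k]
  sum(pi[keep])
}

#' Probability of a merged word
#'
#' Two codons overlapping at a given offset merge into one DNA word of length
#' 3 + |offset| (the scenario of one ancestral segment read in two frames).
#' The word probability is computed in each of the two reading frames -- as
#' the product of the pi-probabilities of the codons and codon fragments
#' tiling the word in that frame -- and the two are combined by their
#' arithmetic mean, which keeps the function symmetric in the two codons.
#'
#' @param codonI,codonJ Sense codons.
#' @param offset Start of \code{codonJ} relative to \code{codonI}, in -2..2.
#' @param pi Codon frequencies.
#' @return The word probability; 0 if the codons are incompatible at this
#'   offset.
#' @export
wordProbability <- function(codonI, codonJ, offset, pi = uniformCodonFrequencies()) {
  stopifnot(offset %in% -2:2)
  if (offset < 0)
    return(wordProbability(codonJ, codonI, -offset, pi))
  ci <- strsplit(codonI, "")[[1]]; cj <- strsplit(codonJ, "")[[1]]
  if (offset == 0) {
    if (codonI != codonJ) return(0)
    return(unname(pi[codonI]))
  }
  ov <- 3 - offset  # overlap length
  if (!all(ci[(offset + 1):3] == cj[1:ov])) return(0)
  if (offset == 1) {
    f1 <- pi[codonI] * .fragmentMarginal(pi, 1, cj[3])
    f2 <- .fragmentMarginal(pi, 3, ci[1]) * pi[codonJ]
  } else {
    f1 <- pi[codonI] * .fragmentMarginal(pi, c(1, 2), cj[2:3])
    f2 <- .fragmentMarginal(pi, c(2, 3), ci[1:2]) * pi[codonJ]
  }
  unname((f1 + f2) / 2)
}

## Ancestral-pair weight matrix for one offset: W[ci', cj'] = word probability
## of the merged ancestral word, 0 for incompatible pairs.
.wordWeightMatrix <- function(offset, pi) {
  cs <- names(pi)
  n <- length(cs)
  W <- matrix(0, n, n, dimnames = list(cs, cs))
  if (offset == 0) {
    diag(W) <- pi
    return(W)
  }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    w <- wordProbability(cs[i], cs[j], offset, pi)
    if (w > 0) W[i, j] <- w
  }
  W
}

## 99x61 indicator: triplet t <- codon c at position p.
.tripletAggregator <- function(pos, pi) {
  tt <- enumerateTriplets(FALSE)
  cs <- names(pi)
  Tm <- matrix(0, nrow(tt), length(cs), dimnames = list(tt$label, cs))
  aa <- aaOfCodon(cs)
  for (c in seq_along(cs)) {
    t <- which(tt$pos == pos & tt$aa == aa[c] &
                 tt$symbol == substr(cs[c], pos, pos))
    Tm[t, c] <- 1
  }
  Tm
}

#' Foreground probabilities of triplet pairs
#'
#' Probability that two triplets (nucleotide, codon position, amino acid)
#' share a common ancestral origin under the duplication-and-divergence
#' scenario: an ancestral word merges two codons overlapping at offset
#' p_i - p_j, each codon then evolves independently under the codon
#' substitution model, and codons are marginalized to amino acids. The result
#' is globally renormalized to sum to 1 over all ordered valid triplet pairs.
#'
#' @param model A \linkS4class{CodonSubstitutionModel}.
#' @param pi Codon frequencies (defaults to the model's).
#' @return 99x99 symmetric matrix of probabilities (triplet-label dimnames).
#' @export
foregroundProbabilities <- function(model, pi = model@pi) {
  P <- model@probs
  cs <- rownames(P)
  pi <- pi[cs]
  aggr <- lapply(1:3, .tripletAggregator, pi = pi)
  Wcache <- list()
  tt <- enumerateTriplets(FALSE)
  f <- matrix(0, nrow(tt), nrow(tt), dimnames = list(tt$label, tt$label))
  for (pI in 1:3) for (pJ in 1:3) {
    k <- pI - pJ
    key <- as.character(k)
    if (is.null(Wcache[[key]])) Wcache[[key]] <- .wordWeightMatrix(k, pi)
    probc <- t(P) %*% Wcache[[key]] %*% P
    f <- f + aggr[[pI]] %*% probc %*% t(aggr[[pJ]])
  }
  f <- (f + t(f)) / 2
  f / sum(f)
}

#' Background probabilities of triplets and triplet pairs
#'
#' The probability of a triplet appearing independently in a putative coding
#' sequence: p(t) for t = (alpha, p, a) is one third of the total frequency
#' of codons of a with alpha at position p (the factor 1/3 makes p a proper
#' distribution over the 99 triplets). Pair background is the product
#' b(ti, tj) = p(ti) p(tj).
#'
#' @param pi Codon frequencies.
#' @return List with \code{p} (length-99 vector) and \code{b} (99x99 matrix).
#' @export
backgroundProbabilities <- function(pi = uniformCodonFrequencies()) {
  tt <- enumerateTriplets(FALSE)
  p <- vapply(seq_len(nrow(tt)), function(i) {
    cs <- codonsOf(tt$aa[i])
    sum(pi[cs[substr(cs, tt$pos[i], tt$pos[i]) == tt$symbol[i]]]) / 3
  }, numeric(1))
  names(p) <- tt$label
  list(p = p, b = outer(p, p))
}

#' Build the translation-dependent score matrix
#'
#' Log-odds scores over all pairs of valid triplets: score = log(f / b) in
#' natural-log units, with foreground f from
#' \code{\link{foregroundProbabilities}} and background b from
#' \code{\link{backgroundProbabilities}}. Pairs with zero foreground (only
#' possible at theta = 0) are floored at log((fmin/2) / b), below every
#' observed score.
#'
#' @param model A \linkS4class{CodonSubstitutionModel}, or a number, in which
#'   case a mechanistic model is built at that evolutionary distance theta.
#' @param pi Codon frequencies.
#' @param omega,kappa Mechanistic parameters, used when \code{model} is a
#'   distance.
#' @return A \linkS4class{TripletScoreMatrix}.
#' @examples
#' tsm <- buildScoreMatrix(0.3)
#' tsm@scores["A.1.M", "A.1.M"]
#' @export
buildScoreMatrix <- function(model, pi = NULL, omega = 0.2, kappa = 4.0) {
  if (is.numeric(model))
    model <- mechanisticModel(model, omega, kappa,
                              pi = if (is.null(pi)) uniformCodonFrequencies()
                              else pi)
  if (is.null(pi)) pi <- model@pi
  f <- foregroundProbabilities(model, pi)
  bg <- backgroundProbabilities(pi)
  if (any(bg$p == 0))
    stop("degenerate pi: background probability of triplet ",
         names(bg$p)[which(bg$p == 0)[1]], " is zero")
  fmin <- min(f[f > 0])
  f2 <- ifelse(f == 0, fmin / 2, f)
  scores <- log(f2 / bg$b)
  modelTag <- if (model@source == "mechanistic")
    sprintf("mechanistic(omega=%g,kappa=%g)", model@params$omega,
            model@params$kappa) else "empirical"
  new("TripletScoreMatrix", scores = scores, foreground = f,
      background = bg$b, theta = model@theta, model = modelTag)
}

setMethod("show", "TripletScoreMatrix", function(object) {
  cat("TripletScoreMatrix: 99x99 triplet pairs, model ", object@model,
      ", theta = ", object@theta, "\n", sep = "")
  cat("  score range [", format(min(object@scores), digits = 3), ", ",
      format(max(object@scores), digits = 3), "], expected background score ",
      format(sum(object@background * object@scores), digits = 4), "\n",
      sep = "")
})

#' Condense a score matrix to IUPAC triplets
#'
#' The condensed score of a pair of ambiguous triplets is the maximum
#' substitution score over all pairs of plain nucleotides from the respective
#' represented sets; the realizing pair is stored for traceback
#' reconstruction of the plain DNA sequences. Ties are broken by the fixed
#' nucleotide order A < C < G < T on the first, then second member.
#'
#' @param tsm A \linkS4class{TripletScoreMatrix}.
#' @return An \linkS4class{AmbiguousScoreMatrix} over the 69 condensed
#'   triplets.
#' @export
condenseScoreMatrix <- function(tsm) {
  ct <- enumerateTriplets(TRUE)
  full <- enumerateTriplets(FALSE)
  fullIdx <- lapply(seq_len(nrow(ct)), function(i) {
    bases <- IUPAC_SETS[[ct$symbol[i]]]  # already in A<C<G<T order
    match(paste(bases, ct$pos[i], ct$aa[i], sep = "."), full$label)
  })
  n <- nrow(ct)
  labs <- paste(ct$label, ct$branch, sep = ".")
  sc <- matrix(NA_real_, n, n, dimnames = list(labs, labs))
  aA <- matrix(NA_character_, n, n, dimnames = list(labs, labs))
  aB <- aA
  S <- tsm@scores
  for (i in seq_len(n)) for (j in seq_len(n)) {
    ii <- fullIdx[[i]]; jj <- fullIdx[[j]]
    sub <- S[ii, jj, drop = FALSE]
    ## rows/cols are in A<C<G<T order; pick the first maximum under
    ## (first member, then second member) to honor the fixed tie-break
    mx <- max(sub)
    cand <- which(sub == mx, arr.ind = TRUE)
    cand <- cand[order(cand[, 1], cand[, 2]), , drop = FALSE]
    bi <- cand[1, 1]; bj <- cand[1, 2]
    sc[i, j] <- mx
    aA[i, j] <- full$symbol[ii[bi]]
    aB[i, j] <- full$symbol[jj[bj]]
  }
  new("AmbiguousScoreMatrix", scores = sc, argmaxA = aA, argmaxB = aB,
      theta = tsm@theta, model = tsm@model)
}

setMethod("show", "AmbiguousScoreMatrix", function(object) {
  cat("AmbiguousScoreMatrix: 69x69 condensed triplet pairs, model ",
      object@model, ", theta = ", object@theta, "\n", sep = "")
})

#' Plain nucleotide score matrix
#'
#' Classic DNA scoring: one value for a match, one for a transition and one
#' for a transversion, for aligning plain DNA single-path graphs.
#'
#' @param match,transition,transversion Scores.
#' @return 4x4 numeric matrix over A, C, G, T.
#' @export
dnaScoreMatrix <- function(match = 5, transition = -3, transversion = -4) {
  m <- matrix(transversion, 4, 4, dimnames = list(BASES, BASES))
  m["A", "G"] <- m["G", "A"] <- m["C", "T"] <- m["T", "C"] <- transition
  diag(m) <- match
  m
}

#' Write a score matrix to a TSV file
#'
#' Tab-separated, triplet labels as header row/column, full-precision scores,
#' and provenance header lines prefixed \code{#} (model, theta). Bit-exact
#' round trip with \code{\link{readScoreMatrix}}.
#'
#' @param x A \linkS4class{TripletScoreMatrix} or
#'   \linkS4class{AmbiguousScoreMatrix}.
#' @param file Output path.
#' @export
writeScoreMatrix <- function(x, file) {
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(c(paste0("# backtralign score matrix"),
               paste0("# model\t", x@model),
               paste0("# theta\t", format(x@theta, digits = 17)),
               paste0("# condensed\t", is(x, "AmbiguousScoreMatrix"))), con)
  m <- x@scores
  writeLines(paste(c("triplet", colnames(m)), collapse = "\t"), con)
  for (i in seq_len(nrow(m)))
    writeLines(paste(c(rownames(m)[i], sprintf("%.17g", m[i, ])),
                     collapse = "\t"), con)
  if (is(x, "AmbiguousScoreMatrix")) {
    writeLines("# argmax", con)
    for (i in seq_len(nrow(m)))
      writeLines(paste(c(rownames(m)[i],
                         paste0(x@argmaxA[i, ], x@argmaxB[i, ])),
                       collapse = "\t"), con)
  }
}

#' Read a score matrix written by \code{\link{writeScoreMatrix}}
#'
#' @param file Path.
#' @return A \linkS4class{TripletScoreMatrix} or
#'   \linkS4class{AmbiguousScoreMatrix} (foreground/background slots empty).
#' @export
readScoreMatrix <- function(file) {
  lines <- readLines(file)
  hdr <- grep("^#", lines, value = TRUE)
  getHdr <- function(key) {
    ln <- grep(paste0("^# ", key, "\t"), hdr, value = TRUE)
    if (length(ln)) sub(paste0("^# ", key, "\t"), "", ln[1]) else NA
  }
  model <- getHdr("model")
  theta <- as.numeric(getHdr("theta"))
  condensed <- identical(getHdr("condensed"), "TRUE")
  body <- lines[!grepl("^#", lines)]
  cn <- strsplit(body[1], "\t")[[1]][-1]
  n <- length(cn)
  rows <- lapply(body[1 + seq_len(n)], function(l) strsplit(l, "\t")[[1]])
  m <- t(vapply(rows, function(r) as.numeric(r[-1]), numeric(n)))
  dimnames(m) <- list(vapply(rows, `[`, character(1), 1), cn)
  if (!condensed)
    return(new("TripletScoreMatrix", scores = m,
               foreground = matrix(numeric(), 0, 0),
               background = matrix(numeric(), 0, 0),
               theta = theta, model = model))
  amRows <- lapply(body[1 + n + seq_len(n)], function(l) strsplit(l, "\t")[[1]])
  am <- t(vapply(amRows, function(r) r[-1], character(n)))
  aA <- substr(am, 1, 1); aB <- substr(am, 2, 2)
  dim(aA) <- dim(aB) <- dim(m)
  dimnames(aA) <- dimnames(aB) <- dimnames(m)
  new("AmbiguousScoreMatrix", scores = m, argmaxA = aA, argmaxB = aB,
      theta = theta, model = model)
}
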