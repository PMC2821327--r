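#' Maximum-likelihood Gumbel fit of an optimal-score sample
#'
#' Fits the extreme-value law F(x) = exp(-exp(-lambda (x - mu))) to a sample
#' of optimal local alignment scores by maximum likelihood (profile solution
#' for the scale via a one-dimensional root, then the closed-form location),
#' and recovers the Karlin-Altschul prefactor K from the fitted location via
#' mu = ln(K m n) / lambda.
#'
#' @param scores Numeric vector of optimal scores (>= 100 finite values).
#' @param m,n Search-space dimensions (sequence lengths in bases).
#' @param class Alignment class label for the result.
#' @return A \linkS4class{GumbelParams}.
#' @export
fitGumbel <- function(scores, m, n, class = "FW") {
  x <- scores[is.finite(scores)]
  if (length(x) < 100)
    stop("unstable fit: only ", length(x),
         " finite scores (at least 100 required)")
  s <- stats::sd(x)
  if (s == 0) stop("degenerate score sample (zero variance)")
  ## profile ML: beta solves beta = mean(x) - sum(x e^{-x/b})/sum(e^{-x/b})
  g <- function(b) {
    w <- exp(-(x - max(x)) / b)  # stabilized
    mean(x) - sum(x * w) / sum(w) - b
  }
  beta <- stats::uniroot(g, c(s / 50, s * 50), tol = 1e-10)$root
  ## closed-form location, stabilized around max(x)
  mu <- max(x) - beta * log(mean(exp(-(x - max(x)) / beta)))
  lambda <- 1 / beta
  K <- exp(lambda * mu) / (m * n)
  ks <- suppressWarnings(  # integer-valued scores tie; stat still informative
    stats::ks.test(x, function(q) exp(-exp(-lambda * (q - mu)))))
  new("GumbelParams", lambda = lambda, K = K, alignClass = class,
      meta = list(location = mu, sampleSize = length(x), m = m, n = n,
                  ksStatistic = unname(ks$statistic)))
}

#' Analytic ungapped Karlin-Altschul lambda
#'
#' The unique positive root of sum_ij p_i p_j exp(lambda s_ij) = 1 for an
#' ungapped scoring system with negative expected score; the closed-form
#' oracle against which simulation-based fits are checked.
#'
#' @param S Score matrix.
#' @param p Symbol frequencies for rows (and columns if \code{q} missing).
#' @param q Column symbol frequencies.
#' @return lambda.
#' @export
karlinAltschulLambda <- function(S, p, q = p) {
  es <- sum(outer(p, q) * S)
  if (es >= 0) stop("expected score must be negative")
  f <- function(l) sum(outer(p, q) * exp(l * S)) - 1
  upper <- 1
  while (f(upper) < 0) upper <- upper * 2
  stats::uniroot(f, c(1e-8, upper), tol = 1e-12)$root
}

#' Simulate random proteins
#'
#' @param n Length in residues.
#' @param aaFrequencies Named residue frequencies (default uniform over the
#'   20 standard amino acids).
#' @return Protein string.
#' @export
randomProtein <- function(n, aaFrequencies = NULL) {
  aas <- AMINO_ACIDS()
  p <- if (is.null(aaFrequencies)) rep(1 / 20, 20) else
    aaFrequencies[aas] / sum(aaFrequencies[aas])
  paste(sample(aas, n, replace = TRUE, prob = p), collapse = "")
}

#' Calibrate Gumbel parameters for one alignment class
#'
#' Simulates pairs of i.i.d. random proteins, aligns each pair under the
#' class constraints -- whole-alignment classes FW/RC use the frameshift
#' budget; per-frame classes +0,+1,+2 / -0,-1,-2 restrict the alignment to
#' the respective reading-frame difference with frameshifts disallowed; the
#' RC-side classes align against the reverse-complemented second graph --
#' and fits the Gumbel law to the optimal-score sample.
#'
#' @param class One of \code{"FW"}, \code{"RC"}, \code{"+0"}, \code{"+1"},
#'   \code{"+2"}, \code{"-0"}, \code{"-1"}, \code{"-2"}.
#' @param scores An \linkS4class{AmbiguousScoreMatrix} (condensed graphs are
#'   used for the simulation).
#' @param gaps \linkS4class{GapParams}.
#' @param maxFrameshifts Budget for the FW/RC classes.
#' @param numPairs Number of simulated protein pairs.
#' @param proteinLength Length of each simulated protein (residues).
#' @param aaFrequencies Residue frequencies (default uniform).
#' @param seed Mandatory RNG seed.
#' @return A \linkS4class{GumbelParams} with fit metadata.
#' @export
calibrateGumbel <- function(class, scores, gaps = gapParams(),
                            maxFrameshifts = 3L, numPairs = 500L,
                            proteinLength = 200L, aaFrequencies = NULL,
                            seed) {
  if (missing(seed)) stop("seed is mandatory for calibration")
  stopifnot(class %in% c("FW", "RC", "+0", "+1", "+2", "-0", "-1", "-2"))
  set.seed(seed)
  rc <- substr(class, 1, 1) %in% c("R", "-")
  d <- if (class %in% c("+0", "+1", "+2", "-0", "-1", "-2"))
    as.integer(substr(class, 2, 2)) else NULL
  vals <- numeric(numPairs)
  for (k in seq_len(numPairs)) {
    gA <- buildGraph(randomProtein(proteinLength, aaFrequencies), TRUE)
    gB <- buildGraph(randomProtein(proteinLength, aaFrequencies), TRUE)
    if (rc) gB <- reverseComplement(gB)
    vals[k] <- alignScore(gA, gB, scores, gaps, maxFrameshifts,
                          frameDifference = d)
  }
  gp <- fitGumbel(vals, 3 * proteinLength, 3 * proteinLength, class)
  gp@meta$numPairs <- numPairs
  gp@meta$proteinLength <- proteinLength
  gp@meta$seed <- seed
  gp
}

#' Calibrate all eight alignment classes
#'
#' @inheritParams calibrateGumbel
#' @param classes Character vector of classes to calibrate.
#' @return Named list of \linkS4class{GumbelParams}.
#' @export
calibrateAll <- function(scores, gaps = gapParams(), maxFrameshifts = 3L,
                         numPairs = 500L, proteinLength = 200L,
                         aaFrequencies = NULL, seed,
                         classes = c("FW", "RC", "+0", "+1", "+2",
                                     "-0", "-1", "-2")) {
  out <- lapply(seq_along(classes), function(k)
    calibrateGumbel(classes[k], scores, gaps, maxFrameshifts, numPairs,
                    proteinLength, aaFrequencies, seed = seed + k))
  names(out) <- classes
  out
}

#' E-value of an alignment score
#'
#' Karlin-Altschul conversion E = K (3 nA) (3 nB) exp(-lambda S) for the
#' matching alignment class.
#'
#' @param score Alignment (or fragment) score.
#' @param params \linkS4class{GumbelParams} of the matching class.
#' @param nA,nB Protein lengths in residues.
#' @return Expected number of chance alignments at or above the score.
#' @export
evalue <- function(score, params, nA, nB) {
  if (!is(params, "GumbelParams"))
    stop("uncalibrated class: supply GumbelParams")
  params@K * (3 * nA) * (3 * nB) * exp(-params@lambda * score)
}

#' Attach E-values to an alignment
#'
#' Whole-alignment E-value from the FW or RC class; per-fragment E-values
#' from the fragment's frame-difference class (+d forward, -d reverse),
#' using the fragment's own score contribution and the whole-sequence
#' lengths.
#'
#' @param result An \linkS4class{AlignmentResult}.
#' @param calibration Named list of \linkS4class{GumbelParams}.
#' @return The result with \code{evalue} slots filled.
#' @export
applyCalibration <- function(result, calibration) {
  fwd <- result@orientation == "forward"
  whole <- if (fwd) "FW" else "RC"
  nA <- result@lengths[1]; nB <- result@lengths[2]
  if (is.null(calibration[[whole]]))
    stop("uncalibrated class '", whole, "'")
  result@evalue <- evalue(result@score, calibration[[whole]], nA, nB)
  fr <- result@fragments
  if (nrow(fr)) {
    for (k in seq_len(nrow(fr))) {
      if (is.na(fr$d[k])) next
      cls <- paste0(if (fwd) "+" else "-", fr$d[k])
      if (is.null(calibration[[cls]]))
        stop("uncalibrated class '", cls, "'")
      fr$evalue[k] <- evalue(fr$score[k], calibration[[cls]], nA, nB)
    }
    result@fragments <- fr
  }
  result
}

setMethod("show", "GumbelParams", function(object) {
  cat("GumbelParams [", object@alignClass, "]: lambda = ",
      format(object@lambda, digits = 5), ", K = ",
      format(object@K, digits = 5), "\n", sep = "")
})

#' Write a Gumbel calibration file
#'
#' Plain text, one line per class: class, lambda, K, numPairs, length, seed;
#' \code{#} comments.
#'
#' @param calibration Named list of \linkS4class{GumbelParams}.
#' @param file Output path.
#' @export
writeCalibration <- function(calibration, file) {
  con <- file(file, "w")
  on.exit(close(con))
  writeLines("# backtralign Gumbel calibration: class lambda K numPairs length seed",
             con)
  for (gp in calibration)
    writeLines(sprintf("%s\t%.17g\t%.17g\t%d\t%d\t%d", gp@alignClass, gp@lambda,
                       gp@K,
                       as.integer(gp@meta$numPairs %||% NA),
                       as.integer(gp@meta$proteinLength %||% NA),
                       as.integer(gp@meta$seed %||% NA)), con)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a Gumbel calibration file
#'
#' @param file Path written by \code{\link{writeCalibration}}.
#' @return Named list of \linkS4class{GumbelParams}.
#' @export
readCalibration <- function(file) {
  lines <- grep("^#", readLines(file), value = TRUE, invert = TRUE)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (l in lines) {
    f <- strsplit(l, "\t")[[1]]
    out[[f[1]]] <- new("GumbelParams", lambda = as.numeric(f[2]),
                       K = as.numeric(f[3]), alignClass = f[1],
                       meta = list(numPairs = as.integer(f[4]),
                                   proteinLength = as.integer(f[5]),
                                   seed = as.integer(f[6])))
  }
  out
}
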