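test_that("the mechanistic rate matrix is a normalized reversible generator", {
  Q <- buildRateMatrix()
  pi <- uniformCodonFrequencies()
  expect_lt(max(abs(rowSums(Q))), 1e-12)
  expect_equal(-sum(pi * diag(Q)), 1, tolerance = 1e-12)
  ## omega = kappa = 1, uniform pi: all single-base neighbor rates equal
  Q1 <- buildRateMatrix(omega = 1, kappa = 1)
  off <- Q1[Q1 != 0 & row(Q1) != col(Q1)]
  expect_lt(diff(range(off)), 1e-12)
  badPi <- pi; badPi[1] <- badPi[1] + 0.1
  expect_error(buildRateMatrix(pi = badPi), "sum to 1")
})

test_that("transition probabilities are stochastic and reversible", {
  Q <- buildRateMatrix()
  pi <- uniformCodonFrequencies()
  expect_equal(transitionProbabilities(Q, 0)@probs, diag(61),
               ignore_attr = TRUE, tolerance = 1e-12)
  for (th in c(0.1, 0.5, 1.0)) {
    P <- transitionProbabilities(Q, th)@probs
    expect_lt(max(abs(rowSums(P) - 1)), 1e-9)
    ## GY94 is time-reversible: pi_i P_ij = pi_j P_ji
    expect_lt(max(abs(pi * P - t(pi * P))), 1e-9)
  }
  expect_error(transitionProbabilities(Q, -0.1), ">= 0")
})

test_that("empirical matrix loading drops stops and renormalizes", {
  f <- writeSyntheticEmpirical()
  mod <- loadEmpiricalMatrix(f)
  expect_equal(dim(mod@probs), c(61L, 61L))
  expect_lt(max(abs(rowSums(mod@probs) - 1)), 1e-9)
  expect_identical(mod@source, "empirical")
  ## identity matrix reproduces theta=0 behavior downstream
  f2 <- tempfile()
  I61 <- diag(61)
  dimnames(I61) <- dimnames(mod@probs)
  writeCodonMatrix(I61, f2)
  modI <- loadEmpiricalMatrix(f2)
  fg <- foregroundProbabilities(modI, uniformCodonFrequencies())
  ## identical to the mechanistic model at theta = 0 (P(0) = I)
  fg0 <- foregroundProbabilities(mechanisticModel(0))
  expect_equal(fg, fg0, tolerance = 1e-12)
  ## foreground concentrates on self-pairs relative to background
  expect_gt(sum(diag(fg)), 10 * sum(diag(backgroundProbabilities()$b)))
  ## round-trip of a model matrix is bit-exact
  f3 <- tempfile()
  writeCodonMatrix(mod, f3)
  expect_identical(loadEmpiricalMatrix(f3)@probs, mod@probs)
  ## malformed inputs are rejected with the offending label
  m <- as.matrix(utils::read.table(f, sep = "\t", header = TRUE,
                                   row.names = 1, check.names = FALSE))
  m2 <- m[-1, ]
  f4 <- tempfile()
  utils::write.table(m2, f4, sep = "\t", quote = FALSE, col.names = NA)
  expect_error(loadEmpiricalMatrix(f4), rownames(m)[1])
  m3 <- m; m3[2, 3] <- -1
  utils::write.table(m3, f4, sep = "\t", quote = FALSE, col.names = NA)
  expect_error(loadEmpiricalMatrix(f4), "negative")
})

test_that("merged-word probabilities follow the two-frame construction", {
  pi <- uniformCodonFrequencies()
  ## brute-force marginals by codon enumeration
  m1 <- function(x) sum(pi[substr(names(pi), 1, 1) == x])
  m3 <- function(x) sum(pi[substr(names(pi), 3, 3) == x])
  ## w = CATG from CAT + ATG at offset +1
  expect_equal(wordProbability("CAT", "ATG", 1, pi),
               (pi[["CAT"]] * m1("G") + m3("C") * pi[["ATG"]]) / 2)
  ## offset 0 requires identical codons and returns pi
  expect_equal(wordProbability("CAT", "CAT", 0, pi), pi[["CAT"]])
  expect_equal(wordProbability("CAT", "ATG", 0, pi), 0)
  ## symmetry under swapping codons and negating the offset
  for (k in c(1, 2)) {
    expect_equal(wordProbability("TCA", "CAA", k, pi),
                 wordProbability("CAA", "TCA", -k, pi))
  }
  ## incompatible overlap
  expect_equal(wordProbability("AAA", "GGG", 1, pi), 0)
})

test_that("foreground probabilities are a symmetric distribution", {
  tsm <- fxScoreMatrix(0.5)
  f <- tsm@foreground
  expect_equal(sum(f), 1, tolerance = 1e-12)
  expect_lt(max(abs(f - t(f))), 1e-12)
  ## theta = 0: same-position pairs are nonzero only for identical triplets
  mod0 <- mechanisticModel(0)
  f0 <- foregroundProbabilities(mod0)
  tt <- enumerateTriplets(FALSE)
  samePos <- outer(tt$pos, tt$pos, "==")
  ## P(0) = I: equal-position pairs need a single codon aligned to itself,
  ## so only identical triplets carry mass there
  expect_true(all(f0[samePos & row(f0) != col(f0)] < 1e-15))
})

test_that("Monte-Carlo simulation reproduces computed foreground cells", {
  ## offset +1 block (positions 2 x 1): sample ancestral codon pairs from
  ## the merged-word weights, evolve both codons under P(theta), tally
  ## triplet pairs, and compare with the closed-form computation.
  set.seed(31)
  pi <- uniformCodonFrequencies()
  mod <- mechanisticModel(0.5)
  P <- mod@probs
  cs <- rownames(P)
  W <- outer(seq_along(cs), seq_along(cs), Vectorize(function(i, j)
    wordProbability(cs[i], cs[j], 1, pi)))
  w0 <- sum(W)
  nDraw <- 200000L
  pairIdx <- sample.int(length(W), nDraw, replace = TRUE, prob = as.vector(W))
  ai <- (pairIdx - 1L) %% length(cs) + 1L
  aj <- (pairIdx - 1L) %/% length(cs) + 1L
  evolve <- function(anc) {
    out <- integer(length(anc))
    for (u in unique(anc)) {
      sel <- anc == u
      out[sel] <- sample.int(length(cs), sum(sel), replace = TRUE,
                             prob = P[u, ])
    }
    out
  }
  ci <- evolve(ai); cj <- evolve(aj)
  gc <- Biostrings::GENETIC_CODE
  labI <- paste(substr(cs[ci], 2, 2), 2, unname(gc[cs[ci]]), sep = ".")
  labJ <- paste(substr(cs[cj], 1, 1), 1, unname(gc[cs[cj]]), sep = ".")
  tt <- enumerateTriplets(FALSE)
  counts <- table(factor(labI, tt$label), factor(labJ, tt$label))
  ## closed form for this block, normalized by the block mass
  probc <- t(P) %*% W %*% P
  aggr2 <- backtralign:::.tripletAggregator(2, pi)
  aggr1 <- backtralign:::.tripletAggregator(1, pi)
  expected <- (aggr2 %*% probc %*% t(aggr1)) / w0
  big <- which(expected > 20 / nDraw, arr.ind = TRUE)
  pObs <- counts / nDraw
  se <- sqrt(expected * (1 - expected) / nDraw)
  dev <- abs(pObs[big] - expected[big]) / se[big]
  expect_lt(mean(dev > 3), 0.02)   # ~99.7% within 3 SE
  expect_true(all(dev < 6))
})

test_that("background probabilities sum to one with product pairs", {
  bg <- backgroundProbabilities()
  expect_equal(sum(bg$p), 1, tolerance = 1e-12)
  expect_equal(bg$b, t(bg$b))
  expect_equal(unname(bg$p["A.1.M"]), 1 / 3 / 61)
  expect_false("G.1.M" %in% names(bg$p))  # ATG has no G at position 1
})

test_that("log-odds scores are symmetric with negative expectation", {
  for (th in c(0.1, 0.5, 1.0)) {
    tsm <- fxScoreMatrix(th)
    expect_lt(max(abs(tsm@scores - t(tsm@scores))), 1e-12)
    expect_lt(sum(tsm@background * tsm@scores), 0)
  }
  ## self-similarity decays with evolutionary distance
  d01 <- diag(fxScoreMatrix(0.1)@scores)
  d10 <- diag(fxScoreMatrix(1.0)@scores)
  expect_true(all(d01 > d10))
})

test_that("condensation takes maxima with recoverable argmax pairs", {
  asm <- fxCondensed(0.5)
  tsm <- fxScoreMatrix(0.5)
  expect_equal(dim(asm@scores), c(69L, 69L))
  ct <- enumerateTriplets(TRUE)
  full <- enumerateTriplets(FALSE)
  set.seed(5)
  for (k in 1:40) {
    i <- sample(69, 1); j <- sample(69, 1)
    basesI <- backtralign:::IUPAC_SETS[[ct$symbol[i]]]
    basesJ <- backtralign:::IUPAC_SETS[[ct$symbol[j]]]
    ii <- match(paste(basesI, ct$pos[i], ct$aa[i], sep = "."), full$label)
    jj <- match(paste(basesJ, ct$pos[j], ct$aa[j], sep = "."), full$label)
    sub <- tsm@scores[ii, jj, drop = FALSE]
    expect_equal(asm@scores[i, j], max(sub))
    expect_true(all(asm@scores[i, j] >= sub))
    ## the stored pair realizes the maximum
    ia <- match(paste(asm@argmaxA[i, j], ct$pos[i], ct$aa[i], sep = "."),
                full$label)
    ja <- match(paste(asm@argmaxB[i, j], ct$pos[j], ct$aa[j], sep = "."),
                full$label)
    expect_equal(tsm@scores[ia, ja], max(sub))
  }
  ## singleton sets condense to the unique constituent score
  iM <- which(ct$aa == "M" & ct$pos == 1)
  jM <- which(ct$aa == "W" & ct$pos == 1)
  expect_equal(asm@scores[iM, jM],
               tsm@scores[match("A.1.M", full$label),
                          match("T.1.W", full$label)])
})

test_that("score matrices round-trip through the TSV format bit-exactly", {
  tsm <- fxScoreMatrix(0.5)
  f <- tempfile()
  writeScoreMatrix(tsm, f)
  back <- readScoreMatrix(f)
  expect_identical(back@scores, tsm@scores)
  expect_identical(back@theta, tsm@theta)
  asm <- fxCondensed(0.5)
  f2 <- tempfile()
  writeScoreMatrix(asm, f2)
  back2 <- readScoreMatrix(f2)
  expect_identical(back2@scores, asm@scores)
  expect_identical(back2@argmaxA, asm@argmaxA)
  expect_identical(back2@argmaxB, asm@argmaxB)
})

test_that("expected amino-acid scores reduce to weighted codon-pair sums", {
  tsm <- fxScoreMatrix(0.5)
  E <- expectedAAScores(tsm)
  expect_equal(E, t(E))
  ## M x M: single codon pair, plain 3-position sum
  tt <- enumerateTriplets(FALSE)
  idx <- function(l) match(l, tt$label)
  direct <- tsm@scores[idx("A.1.M"), idx("A.1.M")] +
    tsm@scores[idx("T.2.M"), idx("T.2.M")] +
    tsm@scores[idx("G.3.M"), idx("G.3.M")]
  expect_equal(E["M", "M"], direct)
  ## brute-force enumeration for (L, L) under uniform weights
  csL <- codonsOf("L")
  acc <- 0
  for (ci in csL) for (cj in csL) {
    s3 <- sum(vapply(1:3, function(p)
      tsm@scores[idx(paste(substr(ci, p, p), p, "L", sep = ".")),
                 idx(paste(substr(cj, p, p), p, "L", sep = "."))],
      numeric(1)))
    acc <- acc + s3 / 36
  }
  expect_equal(E["L", "L"], acc)
})

test_that("reference correlations behave as correlations", {
  E <- expectedAAScoresDNA()
  cc <- correlateWithReferences(E)
  expect_equal(unname(cc["dna"]), 1)  # table against itself
  expect_error(correlateWithReferences(E[1:5, 1:5]), "20x20")
})
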