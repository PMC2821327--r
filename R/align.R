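## Encode a graph for the C++ DP: CSR layers, per-node score indices,
## predecessor lists and 3-step predecessor lists with canonical
## intermediates (all in canonical node order for deterministic tie-breaks).
.encodeGraph <- function(graph) {
  nd <- graph@nodes
  L <- nLayers(graph)
  nPerLayer <- tabulate(nd$layer, L)
  layerStart <- c(0L, cumsum(nPerLayer))
  n <- nrow(nd)
  preds <- vector("list", n)
  if (nrow(graph@arcs))
    preds <- split(graph@arcs[, 1],
                   factor(graph@arcs[, 2], levels = seq_len(n)))
  preds <- lapply(preds, function(p) sort(as.integer(p)))
  p3 <- vector("list", n)
  mid <- vector("list", n)
  for (v in seq_len(n)) {
    seen <- integer(0)
    m1 <- integer(0); m2 <- integer(0)
    for (u in preds[[v]]) for (w in preds[[u]]) for (x in preds[[w]]) {
      if (!(x %in% seen)) {
        seen <- c(seen, x); m1 <- c(m1, w); m2 <- c(m2, u)
      }
    }
    ord <- order(seen)
    p3[[v]] <- seen[ord]; mid[[v]] <- cbind(m1[ord], m2[ord])
  }
  predLen <- lengths(preds)
  p3Len <- lengths(p3)
  midMat <- do.call(rbind, mid[p3Len > 0])
  if (is.null(midMat)) midMat <- matrix(integer(), 0, 2)
  list(layerStart = as.integer(layerStart),
       sym = as.integer(nd$tripletId),
       predPtr = as.integer(c(0L, cumsum(predLen))),
       predIdx = as.integer(unlist(preds, use.names = FALSE)),
       pred3Ptr = as.integer(c(0L, cumsum(p3Len))),
       pred3Idx = as.integer(unlist(p3, use.names = FALSE)),
       pred3Mid1 = as.integer(midMat[, 1]),
       pred3Mid2 = as.integer(midMat[, 2]))
}

.scoreMatrixFor <- function(graphA, graphB, scores) {
  if (is(scores, "AmbiguousScoreMatrix")) {
    for (g in list(graphA, graphB))
      if (g@type == "protein" && !g@condensed)
        stop("condensed score matrix requires condensed graphs")
    S <- scores@scores
  } else if (is(scores, "TripletScoreMatrix")) {
    for (g in list(graphA, graphB))
      if (g@type == "protein" && g@condensed)
        stop("full score matrix requires full (non-condensed) graphs")
    S <- scores@scores
  } else if (is.matrix(scores)) {
    S <- scores
  } else stop("unsupported score object of class ", class(scores))
  maxIdA <- max(graphA@nodes$tripletId)
  maxIdB <- max(graphB@nodes$tripletId)
  if (maxIdA > nrow(S) || maxIdB > ncol(S))
    stop("score matrix does not cover the graphs' symbol indices ",
         "(representation mismatch?)")
  S
}

.resolveColumns <- function(cols, graphA, graphB, scores) {
  ndA <- graphA@nodes; ndB <- graphB@nodes
  n <- nrow(cols)
  symA <- ifelse(cols[, "a"] > 0, ndA$symbol[cols[, "a"]], NA)
  symB <- ifelse(cols[, "b"] > 0, ndB$symbol[cols[, "b"]], NA)
  baseA <- symA; baseB <- symB
  condensed <- is(scores, "AmbiguousScoreMatrix")
  if (condensed) {
    for (r in seq_len(n)) {
      ta <- if (cols[r, "a"] > 0) ndA$tripletId[cols[r, "a"]] else NA
      tb <- if (cols[r, "b"] > 0) ndB$tripletId[cols[r, "b"]] else NA
      if (!is.na(ta) && !is.na(tb)) {
        baseA[r] <- scores@argmaxA[ta, tb]
        baseB[r] <- scores@argmaxB[ta, tb]
      } else {
        ## unpaired condensed symbol: lexicographically smallest constituent
        if (!is.na(ta)) baseA[r] <- IUPAC_SETS[[symA[r]]][1]
        if (!is.na(tb)) baseB[r] <- IUPAC_SETS[[symB[r]]][1]
      }
    }
  }
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  if (graphA@reversed) baseA <- ifelse(is.na(baseA), NA, comp[baseA])
  if (graphB@reversed) baseB <- ifelse(is.na(baseB), NA, comp[baseB])
  data.frame(posA = cols[, "i"], posB = cols[, "j"],
             symbolA = unname(symA), symbolB = unname(symB),
             baseA = unname(baseA), baseB = unname(baseB),
             move = c("start", "match", "skipA", "skipB", "gapA",
                      "gapB")[cols[, "move"] + 1L],
             stringsAsFactors = FALSE)
}

.assembleResult <- function(raw, graphA, graphB, scores, gaps, orientation) {
  S <- .scoreMatrixFor(graphA, graphB, scores)
  cols <- raw$columns
  lengths <- c(nA = if (graphA@type == "protein") nchar(graphA@protein)
               else nLayers(graphA),
               nB = if (graphB@type == "protein") nchar(graphB@protein)
               else nLayers(graphB))
  if (nrow(cols) == 0) {
    return(new("AlignmentResult", score = raw$score, dnaA = "", dnaB = "",
               columns = .resolveColumns(cols, graphA, graphB, scores),
               fragments = data.frame(), orientation = orientation,
               evalue = NA_real_, frameshifts = 0L,
               spans = integer(4), lengths = as.integer(lengths)))
  }
  df <- .resolveColumns(cols, graphA, graphB, scores)
  df$d <- ifelse(df$move == "match",
                 ((cols[, "i"] - cols[, "j"]) %% 3L), NA)

  ## fragments: maximal runs between frameshift gap columns
  isFS <- df$move %in% c("gapA", "gapB")
  fragId <- cumsum(isFS)
  fragId[isFS] <- NA
  frag <- data.frame()
  for (fid in unique(stats::na.omit(fragId))) {
    idx <- which(!is.na(fragId) & fragId == fid)
    sub <- df[idx, ]
    mcols <- which(sub$move == "match")
    subScore <- 0
    if (length(mcols)) {
      ta <- graphA@nodes$tripletId[cols[idx[mcols], "a"]]
      tb <- graphB@nodes$tripletId[cols[idx[mcols], "b"]]
      subScore <- sum(S[cbind(ta, tb)])
    }
    nSkipCols <- sum(sub$move %in% c("skipA", "skipB"))
    subScore <- subScore + gaps@triple * (nSkipCols / 3)
    frag <- rbind(frag, data.frame(
      start = idx[1], end = idx[length(idx)],
      d = if (length(mcols)) sub$d[mcols[1]] else NA,
      score = subScore, evalue = NA_real_))
  }

  dnaA <- paste(ifelse(!is.na(df$baseA), df$baseA,
                       ifelse(df$move == "gapA", "!", "-")), collapse = "")
  dnaB <- paste(ifelse(!is.na(df$baseB), df$baseB,
                       ifelse(df$move == "gapB", "!", "-")), collapse = "")

  new("AlignmentResult", score = raw$score, dnaA = dnaA, dnaB = dnaB,
      columns = df, fragments = frag, orientation = orientation,
      evalue = NA_real_, frameshifts = as.integer(raw$frameshifts),
      spans = as.integer(c(raw$startI, raw$endI, raw$startJ, raw$endJ)),
      lengths = as.integer(lengths))
}

#' Align two back-translation graphs
#'
#' Local alignment by dynamic programming over all pairs of putative coding
#' DNA sequences of the two graphs, with the non-monotonic gap model: size-1
#' frameshift gaps (extendable once to size 2) charged
#' \code{gaps@single} each and limited to \code{maxFrameshifts} events per
#' alignment, and whole-codon skips charged \code{gaps@triple}, uncounted
#' and chainable.
#'
#' @param graphA,graphB \linkS4class{BackTranslationGraph}s (condensed with a
#'   condensed matrix, full with a full matrix; DNA graphs with a 4x4
#'   nucleotide matrix).
#' @param scores An \linkS4class{AmbiguousScoreMatrix},
#'   \linkS4class{TripletScoreMatrix}, or plain numeric matrix indexed by the
#'   graphs' symbol indices.
#' @param gaps A \linkS4class{GapParams}.
#' @param maxFrameshifts Frameshift budget (>= 0).
#' @param frameDifference If non-NULL (0, 1 or 2), restrict the alignment to
#'   a fixed reading-frame difference d = (i - j) mod 3 and disallow
#'   frameshift gaps (used for per-frame significance calibration).
#' @param ungapped Disallow all gaps (overrides the gap model).
#' @return An \linkS4class{AlignmentResult}.
#' @examples
#' asm <- condenseScoreMatrix(buildScoreMatrix(0.3))
#' res <- align(buildGraph("MSHRW", TRUE), buildGraph("MSHRW", TRUE), asm)
#' alignmentScore(res)
#' @export
align <- function(graphA, graphB, scores, gaps = gapParams(),
                  maxFrameshifts = 3L, frameDifference = NULL,
                  ungapped = FALSE) {
  if (maxFrameshifts < 0) stop("maxFrameshifts must be >= 0")
  S <- .scoreMatrixFor(graphA, graphB, scores)
  mode <- 0L; d <- 0L
  allowSingle <- !ungapped && maxFrameshifts > 0
  allowTriple <- !ungapped
  if (!is.null(frameDifference)) {
    stopifnot(frameDifference %in% 0:2)
    mode <- 1L; d <- as.integer(frameDifference)
    allowSingle <- FALSE
  }
  raw <- cppAlignGraphs(.encodeGraph(graphA), .encodeGraph(graphB), S,
                        gaps@single, gaps@triple, as.integer(maxFrameshifts),
                        allowSingle, allowTriple, mode, d, list())
  orientation <- if (graphA@reversed || graphB@reversed)
    "reverse-complement" else "forward"
  .assembleResult(raw, graphA, graphB, scores, gaps, orientation)
}

#' Optimal alignment score only
#'
#' @inheritParams align
#' @return Numeric score.
#' @export
alignScore <- function(graphA, graphB, scores, gaps = gapParams(),
                       maxFrameshifts = 3L, frameDifference = NULL,
                       ungapped = FALSE) {
  align(graphA, graphB, scores, gaps, maxFrameshifts, frameDifference,
        ungapped)@score
}

#' Reduced-memory cut-point alignment
#'
#' Two-pass variant for large inputs: pass 1 computes the optimal local score
#' with a 4-column sliding window (the recurrence reaches 3 cells left/up),
#' propagating per entry the alignment start and its intersections with
#' cut-point columns spaced \code{cutWidth} apart; pass 2 re-fills only the
#' submatrices between consecutive recorded cut-points, pinned at the
#' recorded entries, and concatenates the fragment tracebacks. The result is
#' identical (score and columns) to \code{\link{align}} under the same
#' deterministic tie-breaking.
#'
#' @inheritParams align
#' @param cutWidth Cut-point spacing in columns (>= 4; default 128).
#' @return An \linkS4class{AlignmentResult}.
#' @export
alignLinearSpace <- function(graphA, graphB, scores, gaps = gapParams(),
                             maxFrameshifts = 3L, cutWidth = 128L) {
  if (cutWidth < 4) stop("cutWidth must be >= 4 (window dependency)")
  S <- .scoreMatrixFor(graphA, graphB, scores)
  eA <- .encodeGraph(graphA); eB <- .encodeGraph(graphB)
  allowSingle <- maxFrameshifts > 0
  p1 <- cppAlignWindow(eA, eB, S, gaps@single, gaps@triple,
                       as.integer(maxFrameshifts), allowSingle, TRUE,
                       as.integer(cutWidth))
  orientation <- if (graphA@reversed || graphB@reversed)
    "reverse-complement" else "forward"
  if (p1$score <= 0 || p1$startI < 0) {
    raw <- list(score = 0, columns = matrix(integer(), 0, 5,
                  dimnames = list(NULL, c("i", "j", "a", "b", "move"))),
                frameshifts = 0L, startI = 0L, endI = 0L, startJ = 0L,
                endJ = 0L)
    return(.assembleResult(raw, graphA, graphB, scores, gaps, orientation))
  }

  ## pins along the path: fresh start, recorded cut intersections, end
  pins <- list(list(i = p1$startI, j = p1$startJ, a = p1$startA,
                    b = p1$startB, fs = 0L, move = 0L, run = 0L))
  cuts <- p1$cuts
  if (nrow(cuts)) {
    for (r in seq_len(nrow(cuts))) {
      rec <- list(i = cuts[r, "i"], j = cuts[r, "cut"] * cutWidth,
                  a = cuts[r, "a"], b = cuts[r, "b"], fs = cuts[r, "fs"],
                  move = cuts[r, "move"], run = cuts[r, "run"])
      if (rec$i == p1$endI && rec$j == p1$endJ && rec$a == p1$endA &&
          rec$b == p1$endB) next  # the end itself sits on a cut column
      if (rec$j <= p1$startJ) next  # cut at/before the fresh start column
      pins[[length(pins) + 1L]] <- rec
    }
  }
  pins[[length(pins) + 1L]] <- list(i = p1$endI, j = p1$endJ, a = p1$endA,
                                    b = p1$endB, fs = p1$endFS,
                                    move = p1$endMove, run = p1$endRun)

  allCols <- list(matrix(c(p1$startI, p1$startJ, p1$startA, p1$startB, 1L),
                         1, 5, dimnames = list(NULL,
                                               c("i", "j", "a", "b", "move"))))
  for (k in seq_len(length(pins) - 1L)) {
    p <- pins[[k]]; q <- pins[[k + 1L]]
    pin <- list(i1 = p$i, j1 = p$j, a1 = p$a, b1 = p$b, fs = p$fs,
                move = p$move, run = p$run, i2 = q$i, j2 = q$j, a2 = q$a,
                b2 = q$b)
    seg <- cppAlignGraphs(eA, eB, S, gaps@single, gaps@triple,
                          as.integer(maxFrameshifts), allowSingle, TRUE,
                          2L, 0L, pin)
    allCols[[length(allCols) + 1L]] <- seg$columns
  }
  colMat <- do.call(rbind, allCols)
  raw <- list(score = p1$score, columns = colMat,
              frameshifts = p1$endFS, startI = p1$startI, endI = p1$endI,
              startJ = p1$startJ, endJ = p1$endJ)
  res <- .assembleResult(raw, graphA, graphB, scores, gaps, orientation)
  res
}

#' Align in both orientations
#'
#' Runs the forward alignment (A vs B) and the reverse-complement alignment
#' (A vs RC(B)); each is evaluated against its own Gumbel parameter class
#' (FW / RC, and +d / -d for fragments) when a calibration is supplied.
#'
#' @inheritParams align
#' @param calibration Optional named list of \linkS4class{GumbelParams}
#'   (classes FW, RC, +0..+2, -0..-2), as from
#'   \code{\link{calibrateGumbel}} / \code{\link{readCalibration}}.
#' @return List with elements \code{forward} and \code{reverse}, both
#'   \linkS4class{AlignmentResult}s.
#' @export
alignBothOrientations <- function(graphA, graphB, scores,
                                  gaps = gapParams(), maxFrameshifts = 3L,
                                  calibration = NULL) {
  fw <- align(graphA, graphB, scores, gaps, maxFrameshifts)
  rc <- align(graphA, reverseComplement(graphB), scores, gaps,
              maxFrameshifts)
  if (!is.null(calibration)) {
    fw <- applyCalibration(fw, calibration)
    rc <- applyCalibration(rc, calibration)
  }
  list(forward = fw, reverse = rc)
}

#' @describeIn AlignmentResult-class Optimal score accessor.
#' @param x,object An \code{AlignmentResult}.
#' @export
alignmentScore <- function(x) x@score

#' @describeIn AlignmentResult-class Alignment column table accessor.
#' @export
alignmentColumns <- function(x) x@columns

#' @describeIn AlignmentResult-class Frame-difference fragment table.
#' @export
alignmentFragments <- function(x) x@fragments

#' @describeIn AlignmentResult-class Inferred DNA sequence pair.
#' @export
alignedDNA <- function(x) c(A = x@dnaA, B = x@dnaB)

setMethod("show", "AlignmentResult", function(object) {
  cat("AlignmentResult (", object@orientation, ")\n", sep = "")
  cat("  score ", format(object@score, digits = 6),
      if (!is.na(object@evalue))
        paste0(", E-value ", format(object@evalue, digits = 3)),
      ", ", object@frameshifts, " frameshift(s), ",
      nrow(object@fragments), " fragment(s)\n", sep = "")
  if (nrow(object@columns)) {
    cat("  A[", object@spans[1], "..", object@spans[2], "] x B[",
        object@spans[3], "..", object@spans[4], "]\n", sep = "")
  }
})

#' Render an alignment as text
#'
#' Three-row blocks (DNA A, match line, DNA B) with codon boundaries marked
#' every three consumed bases, frameshift gaps flagged \code{!}, codon skips
#' \code{-}, and fragment separators annotated with the frame difference d
#' and the per-fragment score/E-value.
#'
#' @param result An \linkS4class{AlignmentResult}.
#' @param width Block width in columns.
#' @return Character vector of report lines (invisibly printed with
#'   \code{cat} if assigned to nothing).
#' @export
formatAlignment <- function(result, width = 60L) {
  df <- result@columns
  out <- c(sprintf("score: %.4f  orientation: %s  frameshifts: %d",
                   result@score, result@orientation, result@frameshifts),
           if (!is.na(result@evalue))
             sprintf("E-value: %.3g", result@evalue))
  if (!nrow(df)) return(c(out, "(empty alignment)"))
  fr <- result@fragments
  for (k in seq_len(nrow(fr)))
    out <- c(out, sprintf("fragment %d: columns %d..%d, d=%s, score %.4f%s",
                          k, fr$start[k], fr$end[k],
                          ifelse(is.na(fr$d[k]), "?", fr$d[k]), fr$score[k],
                          ifelse(is.na(fr$evalue[k]), "",
                                 sprintf(", E=%.3g", fr$evalue[k]))))
  chA <- ifelse(!is.na(df$baseA), df$baseA,
                ifelse(df$move == "gapA", "!", "-"))
  chB <- ifelse(!is.na(df$baseB), df$baseB,
                ifelse(df$move == "gapB", "!", "-"))
  mid <- ifelse(df$move == "match" & chA == chB, "|",
                ifelse(df$move == "match", ".", " "))
  ## codon boundary markers every 3 consumed bases of A
  consumed <- cumsum(!is.na(df$baseA))
  mark <- ifelse(!is.na(df$baseA) & consumed %% 3 == 0 & consumed > 0,
                 "^", " ")
  for (s in seq(1, nrow(df), by = width)) {
    e <- min(s + width - 1L, nrow(df))
    out <- c(out, "",
             paste0("A ", paste(chA[s:e], collapse = "")),
             paste0("  ", paste(mid[s:e], collapse = "")),
             paste0("B ", paste(chB[s:e], collapse = "")),
             paste0("  ", paste(mark[s:e], collapse = "")))
  }
  out
}
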