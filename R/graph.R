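#' Build the back-translation graph of a protein
#'
#' Constructs the layered DAG of all putative coding DNA sequences of a
#' protein. The full (non-ambiguous) variant keeps one node per distinct
#' (nucleotide, within-codon prefix) pair at each layer, so that no
#' root-to-sink path spells a sequence that fails to translate back to the
#' protein (this splits e.g. the second-position C/T of serine/leucine and the
#' third positions of L, S, R). The condensed variant represents each amino
#' acid as one chain of three IUPAC symbols per codon-prefix branch (two
#' branches for L, S, R; one for all others).
#'
#' @param protein Amino-acid string (standard 20-letter alphabet).
#' @param condensed Logical; build the IUPAC-condensed graph.
#' @return A \linkS4class{BackTranslationGraph}.
#' @examples
#' g <- buildGraph("YSH", condensed = TRUE)
#' nrow(graphNodes(g))  # 12 nodes: 3 + 6 + 3
#' @export
## Per-amino-acid node/arc template, memoized: nodes in canonical order
## (codon position, then symbol order, then prefix), intra-codon arcs as
## local index pairs, and the local indices of first/third-position nodes.
.aaTemplate <- local({
  cache <- new.env(parent = emptyenv())
  function(a, condensed) {
    key <- paste0(a, if (condensed) "c" else "f")
    if (!is.null(cache[[key]])) return(cache[[key]])
    tidx <- .tripletIndex(condensed)
    if (condensed) {
      brs <- aaBranches(a)
      rows <- do.call(rbind, lapply(seq_along(brs), function(bi) {
        br <- brs[[bi]]
        data.frame(pos = 1:3, symbol = br$symbols,
                   prefix = c("", substr(br$prefix, 1, 1), br$prefix),
                   branch = bi, stringsAsFactors = FALSE)
      }))
      rows <- rows[!duplicated(rows[, c("pos", "symbol", "prefix")]), ,
                   drop = FALSE]
      rows$tripletId <- unname(tidx[paste(rows$symbol, rows$pos, a,
                                          rows$branch, sep = ".")])
    } else {
      cs <- codonsOf(a)
      rows <- unique(do.call(rbind, lapply(1:3, function(p)
        data.frame(pos = p, symbol = substr(cs, p, p),
                   prefix = substr(cs, 1, p - 1), branch = NA_integer_,
                   stringsAsFactors = FALSE))))
      rows$tripletId <- unname(tidx[paste(rows$symbol, rows$pos, a,
                                          sep = ".")])
    }
    ord <- order(rows$pos, match(rows$symbol, SYMBOL_ORDER), rows$prefix)
    rows <- rows[ord, , drop = FALSE]
    rownames(rows) <- NULL
    ## intra-codon arcs: target prefix extends (source prefix, source symbol)
    arcs <- NULL
    for (p in 1:2) {
      from <- which(rows$pos == p); to <- which(rows$pos == p + 1L)
      grid <- expand.grid(f = from, t = to)
      keep <- paste0(rows$prefix[grid$f], rows$symbol[grid$f]) ==
        rows$prefix[grid$t]
      arcs <- rbind(arcs, cbind(grid$f[keep], grid$t[keep]))
    }
    tpl <- list(nodes = rows, arcs = arcs,
                first = which(rows$pos == 1L), third = which(rows$pos == 3L))
    cache[[key]] <- tpl
    tpl
  }
})

buildGraph <- function(protein, condensed = FALSE) {
  letters <- .checkProtein(protein)
  n <- length(letters)
  tpls <- lapply(letters, .aaTemplate, condensed = condensed)
  sizes <- vapply(tpls, function(t) nrow(t$nodes), integer(1))
  offset <- c(0L, cumsum(sizes))
  nodes <- do.call(rbind, lapply(tpls, `[[`, "nodes"))
  nodes <- data.frame(
    layer = unlist(lapply(seq_len(n), function(k)
      3L * (k - 1L) + tpls[[k]]$nodes$pos)),
    symbol = nodes$symbol, prefix = nodes$prefix,
    aa = rep(letters, sizes), codonPos = nodes$pos, branch = nodes$branch,
    tripletId = nodes$tripletId, stringsAsFactors = FALSE)
  intra <- do.call(rbind, lapply(seq_len(n), function(k)
    tpls[[k]]$arcs + offset[k]))
  inter <- if (n > 1L) do.call(rbind, lapply(seq_len(n - 1L), function(k) {
    from <- tpls[[k]]$third + offset[k]
    to <- tpls[[k + 1L]]$first + offset[k + 1L]
    cbind(rep(from, each = length(to)), rep(to, length(from)))
  })) else NULL
  arcs <- rbind(intra, inter)
  if (is.null(arcs)) arcs <- matrix(integer(), 0, 2)
  ## restore layer-major arc/node consistency: nodes are already grouped by
  ## residue and position, i.e. sorted by layer with canonical within-layer
  ## order inherited from the templates
  colnames(arcs) <- c("from", "to")
  storage.mode(arcs) <- "integer"
  rownames(nodes) <- NULL
  new("BackTranslationGraph", protein = protein, nodes = nodes, arcs = arcs,
      condensed = condensed, type = "protein", reversed = FALSE)
}

#' Represent a plain DNA sequence as a single-path graph
#'
#' Degenerate back-translation graph with one node per base, enabling
#' DNA-vs-DNA (or DNA-vs-graph) alignment with the same machinery. The
#' \code{tripletId} of each node is its base index (A=1, C=2, G=3, T=4), for
#' use with a 4x4 nucleotide score matrix such as \code{\link{dnaScoreMatrix}}.
#'
#' @param dna DNA string over ACGT.
#' @return A \linkS4class{BackTranslationGraph} with \code{type = "dna"}.
#' @export
dnaGraph <- function(dna) {
  b <- strsplit(toupper(dna), "")[[1]]
  bad <- which(!b %in% BASES)
  if (length(bad))
    stop("invalid base '", b[bad[1]], "' at position ", bad[1])
  n <- length(b)
  nodes <- data.frame(layer = seq_len(n), symbol = b, prefix = "",
                      aa = NA_character_, codonPos = ((seq_len(n) - 1L) %% 3L) + 1L,
                      branch = NA_integer_, tripletId = match(b, BASES),
                      stringsAsFactors = FALSE)
  arcs <- if (n > 1L) cbind(from = 1:(n - 1L), to = 2:n) else
    matrix(integer(), 0, 2, dimnames = list(NULL, c("from", "to")))
  storage.mode(arcs) <- "integer"
  new("BackTranslationGraph", protein = NA_character_, nodes = nodes,
      arcs = arcs, condensed = FALSE, type = "dna", reversed = FALSE)
}

#' @describeIn BackTranslationGraph-class Number of layers (3n).
#' @param x,object A \code{BackTranslationGraph}.
#' @export
nLayers <- function(x) max(x@nodes$layer)

#' @describeIn BackTranslationGraph-class Node table accessor.
#' @export
graphNodes <- function(x) x@nodes

#' @describeIn BackTranslationGraph-class Arc matrix accessor.
#' @export
graphArcs <- function(x) x@arcs

#' @describeIn BackTranslationGraph-class Protein sequence accessor.
#' @export
graphProtein <- function(x) x@protein

#' @describeIn BackTranslationGraph-class Condensed-representation flag.
#' @export
isCondensed <- function(x) x@condensed

setMethod("show", "BackTranslationGraph", function(object) {
  what <- if (object@type == "dna") "single-path DNA graph" else
    paste0(if (object@condensed) "condensed " else "full ",
           "back-translation graph")
  cat("BackTranslationGraph: ", what,
      if (object@reversed) " (reverse-complemented)", "\n", sep = "")
  if (object@type == "protein")
    cat("  protein: ", object@protein, " (", nchar(object@protein),
        " aa)\n", sep = "")
  cat("  ", nLayers(object), " layers, ", nrow(object@nodes), " nodes, ",
      nrow(object@arcs), " arcs\n", sep = "")
})

#' Reverse-complement a back-translation graph
#'
#' Reverses all arcs, mirrors the layer order and complements every node
#' symbol (IUPAC-aware, by complementing the underlying nucleotide set:
#' R<->Y, N<->N, H<->D). Node \code{tripletId}s keep the source-strand
#' scoring context; the complemented symbols are what reverse-complement
#' alignments display.
#'
#' @param x A \linkS4class{BackTranslationGraph}.
#' @param ... Ignored.
#' @return The reverse-complemented graph.
#' @importFrom Biostrings reverseComplement
#' @aliases reverseComplement,BackTranslationGraph-method
#' @name reverseComplement
#' @export reverseComplement
#' @exportMethod reverseComplement
setMethod("reverseComplement", "BackTranslationGraph", function(x, ...) {
  nd <- x@nodes
  L <- nLayers(x)
  nd$layer <- L + 1L - nd$layer
  nd$symbol <- .complementSymbol(nd$symbol)
  ord <- order(nd$layer, match(nd$symbol, SYMBOL_ORDER), nd$prefix)
  perm <- order(ord)  # old index -> new index
  arcs <- x@arcs
  newArcs <- cbind(from = perm[arcs[, 2]], to = perm[arcs[, 1]])
  nd <- nd[ord, , drop = FALSE]
  rownames(nd) <- NULL
  storage.mode(newArcs) <- "integer"
  new("BackTranslationGraph", protein = x@protein, nodes = nd, arcs = newArcs,
      condensed = x@condensed, type = x@type, reversed = !x@reversed)
})

#' Enumerate all root-to-sink paths of a graph
#'
#' Spells the exact set of DNA sequences represented by a back-translation
#' graph. For condensed graphs the sequences are over IUPAC symbols; use
#' \code{\link{expandAmbiguous}} to expand them. Guarded against exponential
#' blowup by \code{maxPaths}.
#'
#' @param graph A \linkS4class{BackTranslationGraph}.
#' @param maxPaths Maximum admissible number of paths.
#' @return Character vector of spelled sequences.
#' @export
enumeratePaths <- function(graph, maxPaths = 100000L) {
  nd <- graph@nodes
  L <- nLayers(graph)
  succ <- split(graph@arcs[, 2], factor(graph@arcs[, 1],
                                        levels = seq_len(nrow(nd))))
  ## count paths from each node to the sink layer
  cnt <- numeric(nrow(nd))
  for (l in L:1) {
    idx <- which(nd$layer == l)
    for (v in idx)
      cnt[v] <- if (l == L) 1 else sum(cnt[succ[[v]]])
  }
  total <- sum(cnt[nd$layer == 1L])
  if (total > maxPaths)
    stop("graph spells ", total, " paths, exceeding maxPaths = ", maxPaths)
  out <- character(0)
  walk <- function(v, acc) {
    acc <- paste0(acc, nd$symbol[v])
    if (nd$layer[v] == L) out[[length(out) + 1L]] <<- acc
    else for (w in succ[[v]]) walk(w, acc)
  }
  for (v in which(nd$layer == 1L)) walk(v, "")
  out
}

#' Expand IUPAC-ambiguous sequences to plain DNA
#'
#' @param seqs Character vector of sequences over the back-translation
#'   alphabet (ACGT plus R, Y, H, N, D).
#' @return Character vector of all plain expansions (unique, sorted).
#' @export
expandAmbiguous <- function(seqs) {
  one <- function(s) {
    sets <- IUPAC_SETS[strsplit(s, "")[[1]]]
    apply(do.call(expand.grid, c(rev(sets), stringsAsFactors = FALSE)),
          1, function(r) paste(rev(r), collapse = ""))
  }
  sort(unique(unlist(lapply(seqs, one))))
}

#' Per-residue node and arc counts
#'
#' Attributes each arc to its source residue (so arcs into the next codon's
#' first position count toward the residue they leave), matching the
#' convention under which an interior worst-case (L/S/R) residue of the full
#' graph costs 10 nodes and 20 arcs, at most 30 memory units per residue.
#'
#' @param graph A protein \linkS4class{BackTranslationGraph}.
#' @return data.frame with one row per residue: \code{nodes}, \code{arcs},
#'   \code{units}.
#' @export
residueCounts <- function(graph) {
  stopifnot(graph@type == "protein")
  nd <- graph@nodes
  res <- (nd$layer - 1L) %/% 3L + 1L
  n <- max(res)
  nodes <- tabulate(res, n)
  arcRes <- (nd$layer[graph@arcs[, 1]] - 1L) %/% 3L + 1L
  arcs <- tabulate(arcRes, n)
  data.frame(residue = seq_len(n), nodes = nodes, arcs = arcs,
             units = nodes + arcs)
}

#' Dump a graph as plain text
#'
#' Debug/test format: one line per layer listing \code{symbol/prefix} tokens,
#' then the arc list as \code{(layer,i)->(layer+1,j)} with i, j the within-
#' layer node ranks.
#'
#' @param graph A \linkS4class{BackTranslationGraph}.
#' @param file Connection or path; \code{""} prints to stdout.
#' @export
dumpGraph <- function(graph, file = "") {
  nd <- graph@nodes
  lines <- vapply(split(seq_len(nrow(nd)), nd$layer), function(idx) {
    paste(paste0(nd$symbol[idx], "/", ifelse(nd$prefix[idx] == "", ".",
                                             nd$prefix[idx])),
          collapse = " ")
  }, character(1))
  rank <- unlist(lapply(split(seq_len(nrow(nd)), nd$layer), seq_along))
  rank <- rank[order(unlist(split(seq_len(nrow(nd)), nd$layer)))]
  arcLines <- apply(graph@arcs, 1, function(a)
    sprintf("(%d,%d)->(%d,%d)", nd$layer[a[1]], rank[a[1]],
            nd$layer[a[2]], rank[a[2]]))
  writeLines(c(paste0("layer ", names(lines), ": ", lines), arcLines), file)
}
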