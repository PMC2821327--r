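#' Back-translation graph of a protein
#'
#' A layered DAG over 3n positions (n = protein length) whose root-to-sink
#' paths spell exactly the putative coding DNA sequences of the protein.
#' Nodes live in \code{nodes} (one row per node: \code{layer}, \code{symbol},
#' \code{prefix} -- the 0-2 preceding bases within the codon, used to split
#' nodes so that no path spells a non-coding sequence --, \code{aa},
#' \code{codonPos}, \code{tripletId} into the canonical triplet table);
#' \code{arcs} is a 2-column integer matrix of node-index pairs between
#' consecutive layers. Condensed graphs use IUPAC ambiguity symbols (R, Y, H,
#' N) with L/S/R represented as two 3-node branches. Plain DNA sequences are
#' represented as degenerate single-path graphs (\code{type = "dna"}).
#'
#' @slot protein Amino-acid sequence (NA for DNA graphs).
#' @slot nodes data.frame of nodes, ordered by (layer, symbol, prefix).
#' @slot arcs Integer matrix, columns \code{from}, \code{to}.
#' @slot condensed Logical.
#' @slot type \code{"protein"} or \code{"dna"}.
#' @slot reversed Logical; TRUE for reverse-complemented graphs (node symbols
#'   complemented, layers mirrored; \code{tripletId} keeps the source-strand
#'   scoring context).
#' @export
setClass("BackTranslationGraph",
  representation(protein = "character", nodes = "data.frame",
                 arcs = "matrix", condensed = "logical",
                 type = "character", reversed = "logical"))

setValidity("BackTranslationGraph", function(object) {
  nd <- object@nodes
  ar <- object@arcs
  msg <- character()
  if (nrow(ar)) {
    dl <- nd$layer[ar[, 2]] - nd$layer[ar[, 1]]
    if (any(dl != 1L)) msg <- c(msg, "arcs must connect consecutive layers")
  }
  if (object@type == "protein" && !is.na(object@protein) &&
      max(nd$layer) != 3L * nchar(object@protein))
    msg <- c(msg, "protein graph must have 3n layers")
  if (length(msg)) msg else TRUE
})

#' Codon substitution model
#'
#' Holds a 61x61 codon-to-codon substitution probability matrix P(theta) over
#' the sense codons, either from the mechanistic Goldman-Yang-type rate matrix
#' (P(theta) = expm(theta * Q)) or loaded from an empirical table, together
#' with the equilibrium codon frequencies used to build it.
#'
#' @slot probs 61x61 row-stochastic matrix, dimnames = sense codons.
#' @slot pi Equilibrium codon frequencies (sums to 1).
#' @slot theta Evolutionary distance (expected nucleotide substitutions per
#'   codon; NA for empirical models).
#' @slot source \code{"mechanistic"} or \code{"empirical"}.
#' @slot params List of model parameters (omega, kappa) when mechanistic.
#' @export
setClass("CodonSubstitutionModel",
  representation(probs = "matrix", pi = "numeric", theta = "numeric",
                 source = "character", params = "list"))

setValidity("CodonSubstitutionModel", function(object) {
  p <- object@probs
  if (!all(dim(p) == c(61L, 61L))) return("probs must be 61x61")
  if (any(abs(rowSums(p) - 1) > 1e-9)) return("rows of probs must sum to 1")
  if (abs(sum(object@pi) - 1) > 1e-6) return("pi must sum to 1")
  TRUE
})

#' Translation-dependent triplet score matrix
#'
#' Log-odds scores log(f/b) over all pairs of valid (nucleotide, position,
#' amino-acid) triplets, where f is the foreground probability of the pair
#' under common ancestry (merged-word scenario plus codon divergence) and b
#' the background product of independent triplet probabilities. Scores are in
#' natural-log units.
#'
#' @slot scores 99x99 symmetric numeric matrix (triplet-label dimnames).
#' @slot foreground,background Matching probability matrices.
#' @slot theta Evolutionary distance the matrix was built at.
#' @slot model Provenance string.
#' @export
setClass("TripletScoreMatrix",
  representation(scores = "matrix", foreground = "matrix",
                 background = "matrix", theta = "numeric", model = "character"))

#' IUPAC-condensed triplet score matrix
#'
#' The condensed form of a \linkS4class{TripletScoreMatrix}: scores over the
#' 69 branch-resolved condensed triplets, each equal to the maximum over the
#' cartesian product of the represented nucleotide sets, together with the
#' realizing plain nucleotide pair for traceback.
#'
#' @slot scores 69x69 numeric matrix.
#' @slot argmaxA,argmaxB 69x69 character matrices: the plain nucleotides of
#'   the (row, column) triplet realizing each maximum.
#' @slot theta,model Provenance.
#' @export
setClass("AmbiguousScoreMatrix",
  representation(scores = "matrix", argmaxA = "matrix", argmaxB = "matrix",
                 theta = "numeric", model = "character"))

#' Gap model parameters
#'
#' Non-monotonic gap model: frameshift gaps (size 1, or extension of a size-1
#' gap to size 2) cost \code{single} each and are counted against a per-
#' alignment frameshift budget; whole-codon skips (size 3) cost \code{triple},
#' do not count as frameshifts, and may chain. Codon indels must be cheaper
#' than frame-disruptive gaps: |triple| < |single|.
#'
#' @slot single Negative score; frameshift gap penalty.
#' @slot triple Negative score; codon-skip penalty.
#' @export
setClass("GapParams", representation(single = "numeric", triple = "numeric"))

setValidity("GapParams", function(object) {
  if (object@single >= 0 || object@triple >= 0)
    return("gap penalties must be negative")
  if (abs(object@triple) >= abs(object@single))
    return("|triple| must be < |single| (codon skips are cheaper than frameshifts)")
  TRUE
})

#' @describeIn GapParams-class Constructor.
#' @param single,triple Gap penalties (negative).
#' @export
gapParams <- function(single = -12, triple = -5) {
  new("GapParams", single = single, triple = triple)
}

#' Result of a back-translation graph alignment
#'
#' @slot score Optimal local alignment score.
#' @slot dnaA,dnaB Inferred plain (non-ambiguous) DNA sequences, gap-annotated
#'   with \code{-} (codon skip) and \code{!} (frameshift gap).
#' @slot columns data.frame of alignment columns: graph positions
#'   \code{posA}/\code{posB} (0 for a gap), symbols, resolved plain bases,
#'   \code{move} (match, frameshift gap, codon skip) and reading-frame
#'   difference \code{d}.
#' @slot fragments data.frame of maximal constant-frame-difference runs:
#'   start/end column, d, score contribution, optional E-value.
#' @slot orientation \code{"forward"} or \code{"reverse-complement"}.
#' @slot evalue Whole-alignment E-value (NA when uncalibrated).
#' @slot frameshifts Number of frameshift gap events used.
#' @slot spans Integer vector (startA, endA, startB, endB) of graph positions.
#' @slot lengths Protein/sequence lengths (nA, nB) in residues or bases.
#' @export
setClass("AlignmentResult",
  representation(score = "numeric", dnaA = "character", dnaB = "character",
                 columns = "data.frame", fragments = "data.frame",
                 orientation = "character", evalue = "numeric",
                 frameshifts = "integer", spans = "integer",
                 lengths = "integer"))

#' Gumbel parameters for one alignment class
#'
#' Extreme-value parameters (lambda, K) calibrated by simulation for one of
#' the eight alignment classes: whole-alignment forward (FW) / reverse-
#' complement (RC), and the per-reading-frame-difference classes +0,+1,+2
#' (forward) and -0,-1,-2 (reverse-complement), the latter fitted on
#' alignments restricted to a fixed frame difference with no frameshifts.
#'
#' @slot lambda Gumbel scale parameter (> 0, per score unit).
#' @slot K Gumbel prefactor (> 0).
#' @slot alignClass One of FW, RC, +0, +1, +2, -0, -1, -2.
#' @slot meta List: numPairs, proteinLength, seed, location, ksStatistic.
#' @export
setClass("GumbelParams",
  representation(lambda = "numeric", K = "numeric", alignClass = "character",
                 meta = "list"))

setValidity("GumbelParams", function(object) {
  if (!(object@lambda > 0) || !(object@K > 0))
    return("lambda and K must be strictly positive")
  TRUE
})
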