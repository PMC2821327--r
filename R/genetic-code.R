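#' @useDynLib backtralign, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
NULL

## Nucleotide symbols, in the fixed order used for deterministic tie-breaking
## throughout the package (plain bases first, then the ambiguity codes that can
## arise in condensed graphs and their reverse complements).
BASES <- c("A", "C", "G", "T")
AMBIG_SYMBOLS <- c("R", "Y", "H", "N", "D")
SYMBOL_ORDER <- c(BASES, AMBIG_SYMBOLS)

## IUPAC ambiguity sets actually needed for back-translation: R, Y, H, N.
## D = {A,G,T} is admitted only as the complement image of H in
## reverse-complemented graphs.
IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"),
  H = c("A", "C", "T"), N = c("A", "C", "G", "T"),
  D = c("A", "G", "T")
)

.setToSymbol <- function(bases) {
  key <- paste(sort(unique(bases)), collapse = "")
  hit <- vapply(IUPAC_SETS, function(s) paste(sort(s), collapse = "") == key,
                logical(1))
  if (!any(hit))
    stop("no IUPAC symbol for nucleotide set {", key, "}")
  names(IUPAC_SETS)[which(hit)[1]]
}

.complementSymbol <- function(sym) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  vapply(sym, function(s) .setToSymbol(unname(comp[IUPAC_SETS[[s]]])),
         character(1), USE.NAMES = FALSE)
}

## Standard genetic code, keyed by amino acid: list of sense codons.
.geneticCodeTable <- local({
  tab <- NULL
  function() {
    if (is.null(tab)) {
      gc <- Biostrings::GENETIC_CODE
      sense <- gc[gc != "*"]
      byAA <- split(names(sense), unname(sense))
      ## canonical codon order: lexicographic over A<C<G<T
      tab <<- lapply(byAA, function(x) sort(x))
    }
    tab
  }
})

AMINO_ACIDS <- function() sort(names(.geneticCodeTable()))

#' Sense codons of an amino acid
#'
#' Returns the codons of the standard genetic code encoding a given amino
#' acid. The standard 20-letter alphabet only; ambiguity letters (B, Z, X),
#' selenocysteine (U) and stops are rejected.
#'
#' @param aminoAcid A single one-letter amino-acid code.
#' @return Character vector of codons (3-letter strings over ACGT).
#' @examples
#' codonsOf("R")  # six codons
#' codonsOf("M")  # single codon ATG
#' @export
codonsOf <- function(aminoAcid) {
  tab <- .geneticCodeTable()
  if (length(aminoAcid) != 1L || !aminoAcid %in% names(tab))
    stop("unknown amino-acid letter '", aminoAcid,
         "': only the 20 standard one-letter codes are supported")
  tab[[aminoAcid]]
}

.checkProtein <- function(protein) {
  letters <- strsplit(protein, "")[[1]]
  bad <- which(!letters %in% AMINO_ACIDS())
  if (length(bad))
    stop("invalid amino-acid letter '", letters[bad[1]], "' at position ",
         bad[1], ": only the 20 standard one-letter codes are supported")
  letters
}

SENSE_CODONS <- function() sort(unlist(.geneticCodeTable(), use.names = FALSE))

aaOfCodon <- function(codon) {
  gc <- Biostrings::GENETIC_CODE
  unname(gc[codon])
}

#' Condensed back-translation branches of an amino acid
#'
#' Codons are grouped by their 2-base prefix; each group condenses to a chain
#' of three (possibly ambiguous) symbols. L, S and R yield two branches; all
#' other amino acids a single one.
#'
#' @param aminoAcid One-letter amino-acid code.
#' @return A list of branches; each branch is a list with elements
#'   \code{symbols} (3 IUPAC symbols), \code{prefix} (the defining 2-base
#'   prefix) and \code{codons}.
#' @export
aaBranches <- function(aminoAcid) {
  codons <- codonsOf(aminoAcid)
  pref <- substr(codons, 1, 2)
  groups <- split(codons, pref)
  lapply(names(groups), function(p) {
    cs <- groups[[p]]
    thirds <- unique(substr(cs, 3, 3))
    list(symbols = c(substr(p, 1, 1), substr(p, 2, 2), .setToSymbol(thirds)),
         prefix = p, codons = cs)
  })
}

#' Enumerate valid scoring triplets
#'
#' A triplet (alpha, p, a) is a nucleotide \code{alpha} at codon position
#' \code{p} of a codon encoding amino acid \code{a}. In the plain form there
#' are 99 valid triplets (out of 240 hypothetical base/position/amino-acid
#' combinations). In the condensed form, triplets are the branch-resolved
#' condensed symbols: one per position of each condensed branch, 69 in total
#' (L, S and R contribute two branches each).
#'
#' @param condensed Logical; enumerate condensed (IUPAC) triplets instead of
#'   plain ones.
#' @return A data.frame with columns \code{symbol}, \code{pos}, \code{aa},
#'   plus \code{branch} and \code{set} for the condensed form. Row order is
#'   the canonical triplet index used by score matrices.
#' @examples
#' nrow(enumerateTriplets())          # 99
#' nrow(enumerateTriplets(TRUE))      # 69
#' @export
enumerateTriplets <- function(condensed = FALSE) {
  aas <- AMINO_ACIDS()
  if (!condensed) {
    rows <- do.call(rbind, lapply(aas, function(a) {
      cs <- codonsOf(a)
      do.call(rbind, lapply(1:3, function(p) {
        b <- sort(unique(substr(cs, p, p)))
        data.frame(symbol = b, pos = p, aa = a, stringsAsFactors = FALSE)
      }))
    }))
  } else {
    rows <- do.call(rbind, lapply(aas, function(a) {
      brs <- aaBranches(a)
      do.call(rbind, lapply(seq_along(brs), function(k) {
        br <- brs[[k]]
        data.frame(symbol = br$symbols, pos = 1:3, aa = a, branch = k,
                   set = vapply(br$symbols,
                                function(s) paste(IUPAC_SETS[[s]],
                                                  collapse = ""),
                                character(1)),
                   stringsAsFactors = FALSE)
      }))
    }))
  }
  rownames(rows) <- NULL
  rows$label <- paste(rows$symbol, rows$pos, rows$aa, sep = ".")
  rows
}

## Fast triplet index lookup: maps "symbol.pos.aa" (plain) or
## "symbol.pos.aa.branch" (condensed) to the row index of enumerateTriplets().
.tripletIndex <- local({
  cache <- list()
  function(condensed = FALSE) {
    key <- if (condensed) "c" else "f"
    if (is.null(cache[[key]])) {
      tt <- enumerateTriplets(condensed)
      keys <- if (condensed) paste(tt$label, tt$branch, sep = ".") else tt$label
      idx <- seq_len(nrow(tt))
      names(idx) <- keys
      cache[[key]] <<- idx
    }
    cache[[key]]
  }
})

#' Check whether a triplet is valid
#'
#' @param symbol Nucleotide symbol.
#' @param pos Codon position (1-3).
#' @param aa Amino-acid letter.
#' @return Logical.
#' @export
isValidTriplet <- function(symbol, pos, aa) {
  any(substr(codonsOf(aa), pos, pos) == symbol)
}

translateDNA <- function(dna) {
  as.character(Biostrings::translate(Biostrings::DNAStringSet(dna),
                                     no.init.codon = TRUE))
}
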