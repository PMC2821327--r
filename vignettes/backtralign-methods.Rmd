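---
title: "Frameshift-aware alignment of back-translation graphs: models and methods"
author: "backtralign authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Frameshift-aware alignment of back-translation graphs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(backtralign)
```

# Scope and model

`backtralign` infers distant homology between two proteins whose coding
sequences may have diverged through a frameshift plus many point mutations.
Instead of aligning the amino-acid strings, it aligns the complete sets of
putative coding DNA sequences, represented as back-translation graphs, and
reports the best pair of putative sequences under a translation-dependent
scoring system. The underlying evolutionary scenario is
duplication-and-divergence: one ancestral DNA segment encoded (parts of) both
proteins on shifted reading frames; after duplication the two copies evolved
independently by synonymous/nonsynonymous point substitutions and whole-codon
indels.

Assumptions worth keeping in mind:

* both input sequences are treated as protein-coding over the standard
  genetic code (a single, data-driven table; alternative codes are out of
  scope);
* codon sites evolve independently under a stationary, time-reversible
  Markov model — there is no site-rate heterogeneity and no selection model
  beyond the nonsynonymous/synonymous rate ratio;
* frameshifts are rare events: the alignment admits a small budget of
  frame-disruptive gaps, while whole-codon indels are ordinary events.

# Back-translation graphs

A protein of length $n$ maps to a layered DAG over $3n$ positions; the nodes
at position $i$ are the nucleotides that can occur there in some coding
sequence, split by their within-codon prefix so that no root-to-sink path
spells a non-coding sequence (the classic cases: C/T at the second position
of serine/leucine, and the third positions of the 6-codon amino acids L, S,
R). Arcs connect consecutive bases of one codon and codon boundaries. The
full representation costs at most 10 nodes and 20 arcs per residue (30
memory units, attained by poly-{L,S,R}); the IUPAC-condensed representation
(symbols R, Y, H, N only) reduces every amino acid to one 3-node chain per
codon-prefix branch — two branches for L, S, R (6 nodes), one for the other
17 (3 nodes). Condensation is lossless for alignment because within a branch
the first two positions are fixed and the third is a free set, so a maximum
over constituent nucleotide pairs factorizes per column; the test suite
verifies score equality between condensed and full representations by
exhaustion over small proteins.

Reverse complementation reverses arcs, mirrors layers and complements node
symbols setwise (R↔Y, N↔N, H↔D; D occurs only as a complement image). A
design choice that the underlying recurrence leaves open: nodes of a
reverse-complemented graph keep their *source-strand* triplet as scoring
context, because complemented contexts are in general not valid triplets and
the score matrix is defined over valid triplets only. Displayed sequences
use the complemented symbols; scoring uses the sense context. The
reverse-complement alignment class therefore measures whether the sense
codons of B, read backwards on the opposite strand, could share ancestry
with A — and it is calibrated separately (classes RC, −d), so its E-values
are comparable within the class.

# Translation-dependent scoring

Scores are defined on triplets $(\alpha, p, a)$: nucleotide $\alpha$ at
codon position $p$ of a codon encoding amino acid $a$. 99 of the 240
conceivable combinations are valid; condensed, branch-resolved triplets
number 69. For a pair of triplets the score is the log-odds
$\log(f/b)$ (natural log, floating point — downstream Gumbel calibration
absorbs any scale) of

* the **foreground** $f$: the probability that the two nucleotides share a
  common ancestral origin. The ancestral configuration is a merged word —
  two codons overlapping at offset $p_i - p_j$ — whose probability is
  computed in each of the two reading frames it spans (products of codon and
  codon-fragment frequencies under $\pi$) and combined by arithmetic mean;
  the mean keeps the word probability symmetric in the two codons and on a
  probability scale. Both ancestral codons then evolve independently under
  the codon substitution model, and codons are marginalized to amino acids
  with $\pi$-conditional weights. $f$ is renormalized globally over all
  valid triplet pairs; the normalizer only shifts all scores by a constant.
* the **background** $b(t_i, t_j) = p(t_i)\,p(t_j)$, with
  $p(\alpha,p,a) = \frac13 \sum_{c \in \mathrm{codons}(a),\, c[p]=\alpha} \pi_c$;
  the factor $1/3$ makes $p$ a distribution over the 99 triplets.

Zero-foreground pairs (they arise only at $\theta = 0$) are floored at
$\log\left(\frac{f_{\min}/2}{b}\right)$, below every observed score.

## Codon substitution models

The mechanistic model is the Goldman–Yang-type Markov generator: rate
$q_{ij} = 0$ unless codons differ at exactly one position, otherwise
$\pi_j$ times $\kappa$ for a transition and $\omega$ for a nonsynonymous
change; rows sum to zero and the generator is rescaled to one expected
substitution per codon per unit time, so the distance $\theta$ is measured
in expected nucleotide substitutions per codon and
$P(\theta) = e^{\theta Q}$ (computed with `Matrix::expm`). An empirical
61×61 (or 64×64, stops dropped) substitution matrix can be loaded instead.

Parameter defaults, with units and rationale:

* $\omega = 0.2$ (dimensionless): moderate purifying selection, a common
  genome-wide order of magnitude for coding genes.
* $\kappa = 4.0$ (dimensionless): transition/transversion *rate* ratio in
  the typical vertebrate nuclear range. This choice matters qualitatively:
  the correlation of the expected amino-acid scores with the classic
  +5/−3/−4 DNA system decays with $\theta$ only when the transition bias is
  strong enough ($\kappa \gtrsim 3$ at $\omega = 0.2$ under uniform $\pi$);
  at $\kappa = 2$ the decay direction reverses. Since the decay with
  distance is a structural property of this family of scoring systems (the
  transition/transversion contrast saturates as substitutions accumulate,
  leaving amino-acid-level conservation as the persistent signal), the
  package defaults sit in the regime where it holds.
* $\pi$: uniform over the 61 sense codons unless a codon-usage table is
  supplied (`readCodonFrequencies`). Uniform $\pi$ keeps the bundled
  analyses free of an arbitrary organism choice; experiments with skewed
  frequencies moved the correlation analysis by under 0.01.
* $\theta$: chosen per analysis; for aligning two sequences each diverged by
  $\theta_0$ from their ancestor, the matching matrix distance is about
  $2\theta_0$.

## Behavior without frameshifts

For each score matrix the package computes the expected score of every
amino-acid pair (3-position sums weighted by conditional codon frequencies)
and its Pearson correlation, over the 210 unordered pairs, with BLOSUM62
(bundled as plain text) and with the expected table of the +5/−3/−4
match/transition/transversion system (`referenceCorrelationTable`).
Mechanistic matrices correlate more with the DNA reference than with
BLOSUM62, and the DNA correlation decreases monotonically in $\theta$ —
the matrices interpolate between a non-selective DNA scoring and a
selection-aware protein scoring. Absolute correlation values depend on the
unknowable original parametrization (codon frequencies, $\omega$, $\kappa$)
and are not asserted anywhere; only the orderings are. When no empirical
codon matrix file is supplied the empirical comparison row is skipped with
a warning rather than substituted.

# Alignment algorithm

The DP matrix has a cell per position pair $(i, j)$ and an entry per node
pair; an entry is the maximum of: 0; the substitution score plus the best
compatible diagonal predecessor (graph-predecessor-restricted); a frameshift
gap of size 1 in either sequence (penalty −12 by default), where extending a
size-1 gap to size 2 costs another −12 but not another budget unit, and the
per-alignment budget is 3 events by default; and a whole-codon skip (−5 by
default, |triple| < |single| enforced) reaching back three positions in one
graph. Two clarifications the recurrence itself leaves open, resolved here:

* codon skips are restricted to 3-step-connected node pairs (the skipped
  bases belong to a real path of the skipped graph); canonical intermediate
  nodes are chosen lexicographically for traceback;
* skips may start at any offset, not only at codon boundaries (the
  recurrence indexes $j-3$ without a phase constraint);
* a third consecutive size-1 gap in the same sequence opens a *new*
  frameshift event;
* the frameshift count stored per entry is that of the single best path —
  a lower-scoring predecessor with fewer frameshifts can be dominated. This
  is the recurrence's own bookkeeping and is accepted as such.

Tie-breaking is fully deterministic (case precedence match > skip-in-A >
skip-in-B > gap-in-A > gap-in-B > stop; predecessors scanned in canonical
node order), which is what makes the reduced-memory variant reproducible
column for column.

Traceback substitutes each aligned condensed symbol pair by the stored
argmax nucleotide pair (ties broken A<C<G<T on first, then second member);
unpaired condensed symbols resolve to their lexicographically smallest
constituent. The alignment splits at frameshift gaps into fragments of
constant reading-frame difference $d = (i - j) \bmod 3$; a fragment's score
is the sum of its substitution scores and codon-skip penalties, with
frameshift penalties at its boundaries attributed to neither side.

## Reduced memory

For long inputs a two-pass scheme bounds memory: pass 1 computes the optimal
score in a 4-column sliding window (dependencies reach 3 columns back),
propagating per entry the alignment start and the last entry of the path in
each cut-point column (spacing 128 columns by default, ≥ 4 required); pass 2
re-fills only the submatrices between consecutive recorded cut entries with
pinned endpoints (carrying the frameshift count and gap-run state across the
pin) and concatenates the fragment tracebacks. Under the deterministic
tie-breaking the reconstruction is identical — score and columns — to the
full DP; the suite asserts this on seeded simulated pairs, and the paths may
legitimately skip a cut column entirely (a codon skip can jump it), in which
case the enclosing segment simply spans two blocks.

# Score significance

Optimal local scores of unrelated sequences follow a Gumbel law; the package
fits $(\lambda, K)$ by maximum likelihood (profile root for the scale, then
the closed-form location, $K$ recovered from
$\mu = \ln(K m n)/\lambda$ with $m = 3n_A$, $n = 3n_B$) on scores of
simulated i.i.d. protein pairs. Eight classes are calibrated: FW and RC for
whole alignments under the frameshift budget, and ±0, ±1, ±2 for fragments,
fitted on alignments restricted to the respective frame difference with
frameshifts disallowed. E-values use whole-sequence lengths also for
fragments — the per-fragment law is calibrated under the same convention, so
the conversion is internally consistent even though fragment lengths vary.
A fit refuses fewer than 100 finite scores. Defaults (500 pairs of length
200, uniform amino-acid frequencies, mandatory seed) keep one class in the
tens of seconds; the tests run reduced sizes (110–200 pairs, lengths
40–100), which the suite's tolerances reflect.

Two cross-checks anchor the simulation-based fit: for ungapped plain-DNA
scoring the fitted $\lambda$ must sit within 10% of the analytic root of
$\sum p_i p_j e^{\lambda s_{ij}} = 1$, and Kolmogorov–Smirnov statistics of
the fitted law against fresh samples stay below the 5% critical value in at
least 9 of 10 repeated calibrations of the frameshift-free classes.

# The simulator

`simulateFrameshiftPair` draws an ancestral codon sequence from $\pi$,
evolves copy A codon-wise by one-step sampling of $P(\theta_A)$ (equivalent
in distribution to an event-level simulation for every summary used here,
and far simpler), deletes 1–2 bases at the planted position to produce the
frameshifted copy, repairs any stop codon created by the re-reading to the
nearest sense codon via a deterministic single-base change (the scenario
assumes both copies stay coding), evolves copy B in the new frame, and
records the truth. What it deliberately does not emulate: site-rate
heterogeneity, indel clustering, selection beyond $\omega$, and base
composition drift — so a passing recovery study shows the method works under
its own model of divergence, not that it matches every property of real
coding sequences. The recovery study (100 seeded replicates at
$\theta = 0.3$ per copy, length 40 codons, one +1 frameshift) asserts a
median boundary localization error of at most one codon, with degradation
as $\theta$ grows checked as an ordering, not a number.

# Numerical and degenerate-input choices

* Scores are floating point throughout; no integer rounding.
* `expm` round-off below zero is clipped and rows re-normalized (deviations
  are at the $10^{-16}$ level).
* Empirical matrices already row-stochastic within $10^{-12}$ are not
  renormalized, keeping file round-trips bit-exact.
* Degenerate $\pi$ that zeroes the background of a valid triplet is
  rejected rather than floored.
* Proteins with non-standard letters (B, Z, X, U, stops) are rejected with
  the offending position; back-translation is defined on the 20-letter
  alphabet only.
* Empty alignments (no positive-scoring pair) return score 0 with zero
  columns.

# Problem sizes used in the bundled analyses

Exhaustive equivalence checks cover all proteins of length ≤ 3 over
{M, R, S, H} (3,570 unordered pairs — alphabet chosen to span the extremes:
single-codon, 6-codon two-branch, and 2-codon amino acids); the
reduced-memory equivalence uses 50 seeded simulated pairs of 40 codons at
cut width 32; DNA Gumbel calibration uses 500 pairs of length 400. These
sizes make the full suite run in a few minutes while leaving each check
statistically meaningful; all randomness flows through explicit seeds.

# Known limitations

* The RC scoring convention above is a modeling choice; a principled
  opposite-strand foreground model would require its own merged-word
  derivation.
* Gapped-regime Gumbel parameters are estimated by simulation only; no
  analytic correction for finite-length edge effects is applied, so K is
  accurate only to the extent the location fit is.
* Per-entry frameshift counting (best-path bookkeeping) can discard a
  budget-frugal suboptimal prefix that would enable a later frameshift.
* No seeding/banding heuristics: alignment is quadratic in sequence length;
  the cut-point variant reduces memory, not time.
* Mixed DNA-vs-protein alignment is not offered; DNA inputs align as
  degenerate single-path graphs against each other.
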