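// Dynamic programming core for back-translation graph alignment.
//
// The DP matrix M has one cell per (position i of graph A, position j of
// graph B); each cell holds one entry per pair of nodes at those positions.
// An entry value is the max of: (a) 0; (b) substitution score + best
// compatible entry at (i-1, j-1); (c)/(d) a frameshift gap of size 1 (or an
// extension of a size-1 gap to size 2) in either sequence, budget-limited;
// (e)/(f) a whole-codon skip (gap of size 3), not counted as a frameshift.
// Codon skips require the three skipped positions to be connected in the
// graph (3-step predecessors); canonical intermediate nodes are recorded for
// traceback.
//
// Tie-breaking is fixed for determinism: case precedence
// match > skipA > skipB > gapA > gapB > stop, and predecessor candidates are
// scanned in canonical node order (nucleotide symbol order, then prefix).

#include <Rcpp.h>
#include <vector>
#include <cstdint>
using namespace Rcpp;

static const double NEG_INF = -1e300;

enum Move : int8_t { START = 0, MATCH = 1, SKIPA = 2, SKIPB = 3,
                     GAPA = 4, GAPB = 5 };

struct EntryCore {
  double score;
  int16_t fs;
  int8_t move;
  int8_t run;  // trailing same-direction size-1 gap run (only for GAPA/GAPB)
};

struct Graph {
  int L;                       // layers
  int n;                       // nodes
  std::vector<int> layerStart; // L+1 CSR into nodes (sorted by layer)
  std::vector<int> sym;        // 0-based score index per node
  std::vector<int> layerOf;
  std::vector<int> predPtr, predIdx;
  std::vector<int> p3Ptr, p3Idx, p3Mid1, p3Mid2;
};

static Graph makeGraph(const List &g) {
  Graph G;
  IntegerVector ls = g["layerStart"], sym = g["sym"],
    pp = g["predPtr"], pi = g["predIdx"],
    qp = g["pred3Ptr"], qi = g["pred3Idx"],
    m1 = g["pred3Mid1"], m2 = g["pred3Mid2"];
  G.L = ls.size() - 1;
  G.layerStart.assign(ls.begin(), ls.end());
  G.n = G.layerStart[G.L];
  G.sym.resize(G.n);
  for (int k = 0; k < G.n; ++k) G.sym[k] = sym[k] - 1;
  G.layerOf.resize(G.n);
  for (int l = 0; l < G.L; ++l)
    for (int k = G.layerStart[l]; k < G.layerStart[l + 1]; ++k)
      G.layerOf[k] = l + 1;  // 1-based layer
  G.predPtr.assign(pp.begin(), pp.end());
  G.predIdx.resize(pi.size());
  for (int k = 0; k < pi.size(); ++k) G.predIdx[k] = pi[k] - 1;
  G.p3Ptr.assign(qp.begin(), qp.end());
  G.p3Idx.resize(qi.size());
  G.p3Mid1.resize(m1.size());
  G.p3Mid2.resize(m2.size());
  for (int k = 0; k < qi.size(); ++k) {
    G.p3Idx[k] = qi[k] - 1;
    G.p3Mid1[k] = m1[k] - 1;
    G.p3Mid2[k] = m2[k] - 1;
  }
  return G;
}

struct Params {
  double singleGap, tripleGap;
  int maxFS;
  bool allowSingle, allowTriple;
  int mode;        // 0 local, 1 frame-restricted local, 2 pinned global
  int dRestrict;   // mode 1: required (i - j) mod 3
};

struct Chosen {
  double score;
  int8_t move, run;
  int16_t fs;
  int prevA, prevB;  // node indices of predecessor entry (-1 = fresh start)
  int aux;           // pred3 CSR slot for skips
};

// Evaluate all candidates for entry (i, j, a, b). getE(a,b) returns the
// already-computed entry for nodes (a,b) or NULL if unavailable/invalid.
template <typename Getter>
static inline Chosen evalEntry(int i, int j, int a, int b,
                               const Graph &A, const Graph &B,
                               const NumericMatrix &S, const Params &par,
                               const Getter &getE) {
  Chosen best;
  best.score = NEG_INF; best.move = START; best.run = 0; best.fs = 0;
  best.prevA = -1; best.prevB = -1; best.aux = -1;

  const double sub = S(A.sym[a], B.sym[b]);

  // (b) match
  if (i == 1 || j == 1) {
    if (par.mode != 2) {  // fresh start at the matrix border
      best.score = sub; best.move = MATCH; best.fs = 0; best.run = 0;
      best.prevA = -1; best.prevB = -1;
    }
    if (i > 1 || j > 1) {
      // border in one graph only: no predecessors on that side
    }
  }
  if (i > 1 && j > 1) {
    for (int pa = A.predPtr[a]; pa < A.predPtr[a + 1]; ++pa) {
      int a1 = A.predIdx[pa];
      for (int pb = B.predPtr[b]; pb < B.predPtr[b + 1]; ++pb) {
        int b1 = B.predIdx[pb];
        const EntryCore *e = getE(a1, b1);
        if (!e || e->score <= NEG_INF / 2) continue;
        double cand = e->score + sub;
        if (cand > best.score) {
          best.score = cand; best.move = MATCH; best.fs = e->fs; best.run = 0;
          best.prevA = a1; best.prevB = b1; best.aux = -1;
        }
      }
    }
  }

  // (e) codon skip in A: consumes B positions j-2..j, same A node
  if (par.allowTriple && j > 3) {
    for (int q = B.p3Ptr[b]; q < B.p3Ptr[b + 1]; ++q) {
      int b3 = B.p3Idx[q];
      const EntryCore *e = getE(a, b3);
      if (!e || e->score <= NEG_INF / 2) continue;
      double cand = e->score + par.tripleGap;
      if (cand > best.score) {
        best.score = cand; best.move = SKIPA; best.fs = e->fs; best.run = 0;
        best.prevA = a; best.prevB = b3; best.aux = q;
      }
    }
  }

  // (f) codon skip in B
  if (par.allowTriple && i > 3) {
    for (int q = A.p3Ptr[a]; q < A.p3Ptr[a + 1]; ++q) {
      int a3 = A.p3Idx[q];
      const EntryCore *e = getE(a3, b);
      if (!e || e->score <= NEG_INF / 2) continue;
      double cand = e->score + par.tripleGap;
      if (cand > best.score) {
        best.score = cand; best.move = SKIPB; best.fs = e->fs; best.run = 0;
        best.prevA = a3; best.prevB = b; best.aux = q;
      }
    }
  }

  // (c) frameshift gap in A (consumes one B position)
  if (par.allowSingle && j > 1) {
    for (int pb = B.predPtr[b]; pb < B.predPtr[b + 1]; ++pb) {
      int b1 = B.predIdx[pb];
      const EntryCore *e = getE(a, b1);
      if (!e || e->score <= NEG_INF / 2) continue;
      bool ext = (e->move == GAPA && e->run == 1);
      if (!ext && e->fs >= par.maxFS) continue;
      double cand = e->score + par.singleGap;
      if (cand > best.score) {
        best.score = cand; best.move = GAPA;
        best.fs = ext ? e->fs : e->fs + 1;
        best.run = ext ? 2 : 1;
        best.prevA = a; best.prevB = b1; best.aux = -1;
      }
    }
  }

  // (d) frameshift gap in B
  if (par.allowSingle && i > 1) {
    for (int pa = A.predPtr[a]; pa < A.predPtr[a + 1]; ++pa) {
      int a1 = A.predIdx[pa];
      const EntryCore *e = getE(a1, b);
      if (!e || e->score <= NEG_INF / 2) continue;
      bool ext = (e->move == GAPB && e->run == 1);
      if (!ext && e->fs >= par.maxFS) continue;
      double cand = e->score + par.singleGap;
      if (cand > best.score) {
        best.score = cand; best.move = GAPB;
        best.fs = ext ? e->fs : e->fs + 1;
        best.run = ext ? 2 : 1;
        best.prevA = a1; best.prevB = b; best.aux = -1;
      }
    }
  }

  // (a) 0 floor (local modes only)
  if (par.mode != 2 && best.score < 0) {
    best.score = 0; best.move = START; best.fs = 0; best.run = 0;
    best.prevA = -1; best.prevB = -1; best.aux = -1;
  }
  return best;
}

static Params readParams(double singleGap, double tripleGap, int maxFS,
                         bool allowSingle, bool allowTriple, int mode,
                         int dRestrict) {
  Params p;
  p.singleGap = singleGap; p.tripleGap = tripleGap; p.maxFS = maxFS;
  p.allowSingle = allowSingle; p.allowTriple = allowTriple;
  p.mode = mode; p.dRestrict = dRestrict;
  return p;
}

// Full-matrix fill with backpointers and traceback.
// mode 2 (pinned): pin = list(i1,j1,a1,b1,fs,move,run,i2,j2,a2,b2), all
// node indices 1-based; fill restricted to [i1..i2] x [j1..j2].
// [[Rcpp::export]]
List cppAlignGraphs(List gA, List gB, NumericMatrix S,
                    double singleGap, double tripleGap, int maxFS,
                    bool allowSingle, bool allowTriple,
                    int mode, int dRestrict, List pin) {
  Graph A = makeGraph(gA), B = makeGraph(gB);
  Params par = readParams(singleGap, tripleGap, maxFS, allowSingle,
                          allowTriple, mode, dRestrict);

  long long total = (long long)A.n * B.n;
  if (total > 300000000LL)
    stop("DP matrix too large (%lld entries); use the cut-point variant",
         total);

  std::vector<EntryCore> E(A.n * B.n);
  std::vector<int32_t> bpA(A.n * B.n, -1), bpB(A.n * B.n, -1),
    aux(A.n * B.n, -1);
  for (auto &e : E) { e.score = NEG_INF; e.fs = 0; e.move = START; e.run = 0; }

  int i1 = 1, i2 = A.L, j1 = 1, j2 = B.L;
  int pinA = -1, pinB = -1, endA = -1, endB = -1, endI = -1, endJ = -1;
  if (mode == 2) {
    i1 = as<int>(pin["i1"]); j1 = as<int>(pin["j1"]);
    i2 = as<int>(pin["i2"]); j2 = as<int>(pin["j2"]);
    pinA = as<int>(pin["a1"]) - 1; pinB = as<int>(pin["b1"]) - 1;
    endA = as<int>(pin["a2"]) - 1; endB = as<int>(pin["b2"]) - 1;
    endI = i2; endJ = j2;
    EntryCore &s = E[pinA * B.n + pinB];
    s.score = 0;
    s.fs = as<int>(pin["fs"]);
    s.move = (int8_t)as<int>(pin["move"]);
    s.run = (int8_t)as<int>(pin["run"]);
  }

  double bestScore = (mode == 2) ? NEG_INF : 0;
  int bestA = -1, bestB = -1, bestI = -1, bestJ = -1;

  auto getE = [&](int a, int b) -> const EntryCore * {
    return &E[a * B.n + b];
  };

  for (int j = j1; j <= j2; ++j) {
    for (int i = i1; i <= i2; ++i) {
      if (mode == 1 && (((i - j) % 3) + 3) % 3 != par.dRestrict) continue;
      for (int a = A.layerStart[i - 1]; a < A.layerStart[i]; ++a) {
        for (int b = B.layerStart[j - 1]; b < B.layerStart[j]; ++b) {
          if (mode == 2 && a == pinA && b == pinB && i == i1 && j == j1)
            continue;  // keep the pinned start
          Chosen c = evalEntry(i, j, a, b, A, B, S, par, getE);
          EntryCore &e = E[a * B.n + b];
          e.score = c.score; e.fs = c.fs; e.move = c.move; e.run = c.run;
          bpA[a * B.n + b] = c.prevA; bpB[a * B.n + b] = c.prevB;
          aux[a * B.n + b] = c.aux;
          if (mode != 2 && c.score > bestScore) {
            bestScore = c.score; bestA = a; bestB = b; bestI = i; bestJ = j;
          }
        }
      }
    }
  }

  if (mode == 2) {
    bestA = endA; bestB = endB; bestI = endI; bestJ = endJ;
    bestScore = E[endA * B.n + endB].score;
    if (bestScore <= NEG_INF / 2)
      stop("pinned end entry is unreachable");
  }

  // traceback
  std::vector<std::array<int, 5>> cols;  // i, j, a, b, move (1-based nodes)
  int fsUsed = 0;
  int sI = bestI, sJ = bestJ, sA = bestA, sB = bestB;
  // pinned segment scores are relative to the pin and may be negative
  bool doTrace = (mode == 2) ? (bestScore > NEG_INF / 2)
                             : (bestA >= 0 && bestScore > 0);
  if (doTrace) {
    int a = bestA, b = bestB, i = bestI, j = bestJ;
    fsUsed = E[a * B.n + b].fs;
    while (true) {
      EntryCore &e = E[a * B.n + b];
      if (e.move == START) break;
      int pa = bpA[a * B.n + b], pb = bpB[a * B.n + b];
      switch (e.move) {
      case MATCH:
        cols.push_back({i, j, a + 1, b + 1, MATCH});
        sI = i; sJ = j; sA = a; sB = b;
        if (pa < 0) { a = -1; b = -1; }
        else { a = pa; b = pb; }
        i -= 1; j -= 1;
        break;
      case GAPA:
        cols.push_back({0, j, 0, b + 1, GAPA});
        b = pb; j -= 1;
        break;
      case GAPB:
        cols.push_back({i, 0, a + 1, 0, GAPB});
        a = pa; i -= 1;
        break;
      case SKIPA: {
        int q = aux[a * B.n + b];
        cols.push_back({0, j, 0, b + 1, SKIPA});
        cols.push_back({0, j - 1, 0, B.p3Mid2[q] + 1, SKIPA});
        cols.push_back({0, j - 2, 0, B.p3Mid1[q] + 1, SKIPA});
        b = pb; j -= 3;
        break;
      }
      case SKIPB: {
        int q = aux[a * B.n + b];
        cols.push_back({i, 0, a + 1, 0, SKIPB});
        cols.push_back({i - 1, 0, A.p3Mid2[q] + 1, 0, SKIPB});
        cols.push_back({i - 2, 0, A.p3Mid1[q] + 1, 0, SKIPB});
        a = pa; i -= 3;
        break;
      }
      default: stop("dangling backpointer in traceback");
      }
      if (a < 0) break;  // fresh start at matrix border
      if (mode == 2 && a == pinA && b == pinB && i == i1 && j == j1) {
        sI = i; sJ = j; sA = a; sB = b;
        break;
      }
    }
  }

  IntegerMatrix colMat(cols.size(), 5);
  for (size_t r = 0; r < cols.size(); ++r) {
    size_t rr = cols.size() - 1 - r;  // forward order
    for (int c = 0; c < 5; ++c) colMat(r, c) = cols[rr][c];
  }
  colnames(colMat) = CharacterVector::create("i", "j", "a", "b", "move");

  return List::create(_["score"] = bestScore,
                      _["endI"] = bestI, _["endJ"] = bestJ,
                      _["endA"] = bestA + 1, _["endB"] = bestB + 1,
                      _["startI"] = sI, _["startJ"] = sJ,
                      _["startA"] = sA + 1, _["startB"] = sB + 1,
                      _["frameshifts"] = fsUsed,
                      _["columns"] = colMat);
}

// Pass 1 of the reduced-memory variant: sliding window of `window` columns
// (>= 4: dependencies reach 3 columns left), propagating per entry the
// alignment start and the recorded intersections with cut-point columns
// (every cutWidth-th column). Returns score, end/start entries and the cut
// records of the best path.
struct CutRec { int cut, i, a, b, fs; int8_t move, run; };

struct WEntry {
  EntryCore core;
  int sI, sJ, sA, sB;
  std::vector<CutRec> cuts;
};

// [[Rcpp::export]]
List cppAlignWindow(List gA, List gB, NumericMatrix S,
                    double singleGap, double tripleGap, int maxFS,
                    bool allowSingle, bool allowTriple,
                    int cutWidth) {
  if (cutWidth < 4)
    stop("cutWidth must be >= 4 (the sliding window spans 4 columns)");
  Graph A = makeGraph(gA), B = makeGraph(gB);
  Params par = readParams(singleGap, tripleGap, maxFS, allowSingle,
                          allowTriple, 0, 0);

  // ring buffer over the last 4 columns; col j stores entries for all
  // (node a of A, node b at layer j of B)
  std::array<std::vector<WEntry>, 4> ring;
  std::array<int, 4> ringJ = {-1, -1, -1, -1};
  std::array<int, 4> ringOff = {0, 0, 0, 0};  // layerStart of that column

  double bestScore = 0;
  WEntry bestE; bestE.core.score = 0;
  int bestI = -1, bestJ = -1, bestA = -1, bestB = -1;

  for (int j = 1; j <= B.L; ++j) {
    int slot = j % 4;
    int bOff = B.layerStart[j - 1];
    int nBj = B.layerStart[j] - bOff;
    ring[slot].assign((size_t)A.n * nBj, WEntry());
    for (auto &w : ring[slot]) {
      w.core.score = NEG_INF; w.core.move = START; w.core.fs = 0;
      w.core.run = 0;
    }
    ringJ[slot] = j; ringOff[slot] = bOff;

    auto entryAt = [&](int jj, int a, int b) -> WEntry * {
      int s = jj % 4;
      if (ringJ[s] != jj) return nullptr;
      return &ring[s][(size_t)a * (B.layerStart[jj] - ringOff[s]) +
                      (b - ringOff[s])];
    };

    for (int i = 1; i <= A.L; ++i) {
      for (int a = A.layerStart[i - 1]; a < A.layerStart[i]; ++a) {
        for (int b = bOff; b < B.layerStart[j]; ++b) {
          auto getE = [&](int aa, int bb) -> const EntryCore * {
            int jj = B.layerOf[bb];
            WEntry *w = entryAt(jj, aa, bb);
            return w ? &w->core : nullptr;
          };
          Chosen c = evalEntry(i, j, a, b, A, B, S, par, getE);
          WEntry &w = *entryAt(j, a, b);
          w.core.score = c.score; w.core.fs = c.fs; w.core.move = c.move;
          w.core.run = c.run;
          if (c.move == START) {
            w.sI = w.sJ = w.sA = w.sB = -1;
            w.cuts.clear();
          } else if (c.move == MATCH && c.prevA < 0) {
            w.sI = i; w.sJ = j; w.sA = a; w.sB = b;  // fresh start here
            w.cuts.clear();
          } else {
            int pj = (c.move == MATCH || c.move == GAPA) ? j - 1 :
                     (c.move == SKIPA) ? j - 3 : j;
            WEntry *prev = entryAt(pj, c.prevA, c.prevB);
            if (prev->core.move == START) {
              // path starts at this entry (prev carries no alignment)
              w.sI = i; w.sJ = j; w.sA = a; w.sB = b;
              w.cuts.clear();
            } else {
              w.sI = prev->sI; w.sJ = prev->sJ;
              w.sA = prev->sA; w.sB = prev->sB;
              w.cuts = prev->cuts;
            }
          }
          if (c.move != START && j % cutWidth == 0) {
            CutRec r;
            r.cut = j / cutWidth; r.i = i; r.a = a; r.b = b;
            r.fs = c.fs; r.move = c.move; r.run = c.run;
            if (!w.cuts.empty() && w.cuts.back().cut == r.cut)
              w.cuts.back() = r;  // later visit to the same cut column wins
            else
              w.cuts.push_back(r);
          }
          if (c.score > bestScore) {
            bestScore = c.score; bestE = w;
            bestI = i; bestJ = j; bestA = a; bestB = b;
          }
        }
      }
    }
  }

  IntegerMatrix cutMat(bestE.cuts.size(), 7);
  for (size_t r = 0; r < bestE.cuts.size(); ++r) {
    const CutRec &c = bestE.cuts[r];
    cutMat(r, 0) = c.cut; cutMat(r, 1) = c.i; cutMat(r, 2) = c.a + 1;
    cutMat(r, 3) = c.b + 1; cutMat(r, 4) = c.fs; cutMat(r, 5) = c.move;
    cutMat(r, 6) = c.run;
  }
  colnames(cutMat) = CharacterVector::create("cut", "i", "a", "b", "fs",
                                             "move", "run");
  return List::create(_["score"] = bestScore,
                      _["endI"] = bestI, _["endJ"] = bestJ,
                      _["endA"] = bestA + 1, _["endB"] = bestB + 1,
                      _["endFS"] = (int)bestE.core.fs,
                      _["endMove"] = (int)bestE.core.move,
                      _["endRun"] = (int)bestE.core.run,
                      _["startI"] = bestE.sI, _["startJ"] = bestE.sJ,
                      _["startA"] = bestE.sA + 1, _["startB"] = bestE.sB + 1,
                      _["cuts"] = cutMat,
                      _["windowColumns"] = 4);
}

// Independent oracle: local alignment of two plain symbol sequences under
// the same gap rules, no graphs. Returns the best score over all pairs
// (seqsA x seqsB). Used by tests to cross-check the graph DP against
// exhaustive path enumeration.
// [[Rcpp::export]]
double cppOracleBest(List seqsA, List seqsB, NumericMatrix S,
                     double singleGap, double tripleGap, int maxFS,
                     bool allowSingle, bool allowTriple) {
  double best = 0;
  struct PE { double score; int16_t fs; int8_t move; int8_t run; };
  for (int ia = 0; ia < seqsA.size(); ++ia) {
    IntegerVector sa = seqsA[ia];
    int n = sa.size();
    for (int ib = 0; ib < seqsB.size(); ++ib) {
      IntegerVector sb = seqsB[ib];
      int m = sb.size();
      // (n+1) x (m+1) cells, row 0 / col 0 virtual zeros
      std::vector<PE> M((n + 1) * (m + 1));
      for (auto &e : M) { e.score = 0; e.fs = 0; e.move = START; e.run = 0; }
      for (int j = 1; j <= m; ++j) {
        for (int i = 1; i <= n; ++i) {
          PE cur; cur.score = NEG_INF; cur.move = START; cur.fs = 0;
          cur.run = 0;
          double sub = S(sa[i - 1] - 1, sb[j - 1] - 1);
          { // match
            PE &p = M[(i - 1) * (m + 1) + (j - 1)];
            double cand = p.score + sub;
            if (cand > cur.score) {
              cur.score = cand; cur.move = MATCH; cur.fs = p.fs; cur.run = 0;
            }
          }
          if (allowTriple && j > 3) {
            PE &p = M[i * (m + 1) + (j - 3)];
            // skipped prefix of length 3 cannot start an alignment:
            // p at column j-3 >= 1 always holds here
            double cand = p.score + tripleGap;
            if (cand > cur.score) {
              cur.score = cand; cur.move = SKIPA; cur.fs = p.fs; cur.run = 0;
            }
          }
          if (allowTriple && i > 3) {
            PE &p = M[(i - 3) * (m + 1) + j];
            double cand = p.score + tripleGap;
            if (cand > cur.score) {
              cur.score = cand; cur.move = SKIPB; cur.fs = p.fs; cur.run = 0;
            }
          }
          if (allowSingle && j > 1) {
            PE &p = M[i * (m + 1) + (j - 1)];
            bool ext = (p.move == GAPA && p.run == 1);
            if (ext || p.fs < maxFS) {
              double cand = p.score + singleGap;
              if (cand > cur.score) {
                cur.score = cand; cur.move = GAPA;
                cur.fs = ext ? p.fs : p.fs + 1;
                cur.run = ext ? 2 : 1;
              }
            }
          }
          if (allowSingle && i > 1) {
            PE &p = M[(i - 1) * (m + 1) + j];
            bool ext = (p.move == GAPB && p.run == 1);
            if (ext || p.fs < maxFS) {
              double cand = p.score + singleGap;
              if (cand > cur.score) {
                cur.score = cand; cur.move = GAPB;
                cur.fs = ext ? p.fs : p.fs + 1;
                cur.run = ext ? 2 : 1;
              }
            }
          }
          if (cur.score < 0) {
            cur.score = 0; cur.move = START; cur.fs = 0; cur.run = 0;
          }
          M[i * (m + 1) + j] = cur;
          if (cur.score > best) best = cur.score;
        }
      }
    }
  }
  return best;
}
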