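#include <Rcpp.h>
#include <vector>
#include <limits>
#include <cmath>
using namespace Rcpp;

// Local Viterbi over a plan7-like profile: uniform entry into any match
// state (cost -log2(M) bits), free exit after any match state, unaligned
// flanking residues cost nothing.  All scores are log2-odds against the
// background, precomputed per (node, residue) in R and passed as matrices:
//   sm: M x n  match-state log-odds for residue i at node k
//   si: M x n  insert-state log-odds
//   tl: (M+1) x 7  log2 transition probabilities, rows = nodes 0..M,
//       columns MM, MI, MD, IM, II, DM, DD
// Ties between equal-scoring alignments are broken toward the smallest
// seq_start, then the smallest node_start (and, both equal, the earliest
// end cell visited, i.e. smallest seq_end then node_end).

struct Cell {
  double s;
  int si_, sk_;  // 1-based start residue / start node of the best path
};

static inline bool beats(double s, int si_, int sk_, const Cell &b) {
  if (s > b.s) return true;
  if (s < b.s) return false;
  if (si_ < b.si_) return true;
  if (si_ > b.si_) return false;
  return sk_ < b.sk_;
}

// [[Rcpp::export]]
List viterbi_local_cpp(NumericMatrix sm, NumericMatrix si, NumericMatrix tl) {
  const int M = sm.nrow(), n = sm.ncol();
  const double NEG = -std::numeric_limits<double>::infinity();
  const double entry = -std::log2((double) M);
  const int MM = 0, MI = 1, MD = 2, IM = 3, II = 4, DM = 5, DD = 6;

  std::vector<Cell> vmPrev(M + 1, {NEG, 0, 0}), vmCur(M + 1, {NEG, 0, 0});
  std::vector<Cell> viPrev(M + 1, {NEG, 0, 0}), viCur(M + 1, {NEG, 0, 0});
  std::vector<Cell> vdPrev(M + 1, {NEG, 0, 0}), vdCur(M + 1, {NEG, 0, 0});

  Cell best = {NEG, 0, 0};
  int bestEndI = 0, bestEndK = 0;

  for (int i = 1; i <= n; ++i) {
    vmCur[0] = viCur[0] = vdCur[0] = {NEG, 0, 0};
    for (int k = 1; k <= M; ++k) {
      // match
      Cell m = {entry, i, k};
      if (vmPrev[k - 1].s > NEG) {
        double s = vmPrev[k - 1].s + tl(k - 1, MM);
        if (beats(s, vmPrev[k - 1].si_, vmPrev[k - 1].sk_, m))
          m = {s, vmPrev[k - 1].si_, vmPrev[k - 1].sk_};
      }
      if (viPrev[k - 1].s > NEG) {
        double s = viPrev[k - 1].s + tl(k - 1, IM);
        if (beats(s, viPrev[k - 1].si_, viPrev[k - 1].sk_, m))
          m = {s, viPrev[k - 1].si_, viPrev[k - 1].sk_};
      }
      if (vdPrev[k - 1].s > NEG) {
        double s = vdPrev[k - 1].s + tl(k - 1, DM);
        if (beats(s, vdPrev[k - 1].si_, vdPrev[k - 1].sk_, m))
          m = {s, vdPrev[k - 1].si_, vdPrev[k - 1].sk_};
      }
      m.s += sm(k - 1, i - 1);
      vmCur[k] = m;

      // insert after node k (never before entry, never useful past node M
      // for a single hit, but kept general: I_M -> E is free-exit-less so
      // inserts at M can only precede nothing; they are still computed)
      Cell ins = {NEG, 0, 0};
      if (vmPrev[k].s > NEG) {
        double s = vmPrev[k].s + tl(k, MI);
        if (beats(s, vmPrev[k].si_, vmPrev[k].sk_, ins))
          ins = {s, vmPrev[k].si_, vmPrev[k].sk_};
      }
      if (viPrev[k].s > NEG) {
        double s = viPrev[k].s + tl(k, II);
        if (beats(s, viPrev[k].si_, viPrev[k].sk_, ins))
          ins = {s, viPrev[k].si_, viPrev[k].sk_};
      }
      if (ins.s > NEG) ins.s += si(k - 1, i - 1);
      viCur[k] = ins;

      // delete (no emission; depends on current column at k-1)
      Cell d = {NEG, 0, 0};
      if (k >= 2) {
        if (vmCur[k - 1].s > NEG) {
          double s = vmCur[k - 1].s + tl(k - 1, MD);
          if (beats(s, vmCur[k - 1].si_, vmCur[k - 1].sk_, d))
            d = {s, vmCur[k - 1].si_, vmCur[k - 1].sk_};
        }
        if (vdCur[k - 1].s > NEG) {
          double s = vdCur[k - 1].s + tl(k - 1, DD);
          if (beats(s, vdCur[k - 1].si_, vdCur[k - 1].sk_, d))
            d = {s, vdCur[k - 1].si_, vdCur[k - 1].sk_};
        }
      }
      vdCur[k] = d;

      if (beats(vmCur[k].s, vmCur[k].si_, vmCur[k].sk_, best)) {
        best = vmCur[k];
        bestEndI = i;
        bestEndK = k;
      }
    }
    std::swap(vmPrev, vmCur);
    std::swap(viPrev, viCur);
    std::swap(vdPrev, vdCur);
  }

  if (best.s == NEG)
    return List::create(_["score"] = NEG);
  return List::create(
    _["score"] = best.s,
    _["seq_start"] = best.si_ - 1,   // 0-based half-open
    _["seq_end"] = bestEndI,
    _["node_start"] = best.sk_ - 1,  // 0-based half-open
    _["node_end"] = bestEndK);
}
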