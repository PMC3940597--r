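#include <Rcpp.h>
#include <vector>
#include <string>
#include <limits>
using namespace Rcpp;

static const double NEG_INF = -std::numeric_limits<double>::infinity();

// ---------------------------------------------------------------------------
// Local ("glocal" entry/exit) Viterbi over a match/insert/delete profile.
//
// Model conventions (shared with the R-side brute-force oracle):
//  * match emissions me[L][4] and insert emissions ie[L+1][4] are log2-odds
//    against the background; residue code 4 (N) emits 0 in any state;
//  * transition matrices trM/trI/trD have L+1 rows (source position
//    j = 0..L) and columns (->M, ->I, ->D) in log2 probability;
//  * local entry B->M_j and exit M_j->E are free (score 0), so every local
//    alignment starts and ends in a match state and flanking read residues
//    are unpenalized.
// ---------------------------------------------------------------------------

struct ViterbiResult {
  double score;
  int qstart, qend;   // 0-based half-open emitted interval
  int mstart, mend;   // 1-based match-state interval (inclusive)
  std::vector<int> path_state; // 1=M,2=I,3=D (alignment order)
  std::vector<int> path_mpos;
  std::vector<int> path_qpos; // 1-based emitted residue, 0 for D
};

static ViterbiResult viterbi_core(const std::vector<int>& x,
                                  const NumericMatrix& me,
                                  const NumericMatrix& ie,
                                  const NumericMatrix& trM,
                                  const NumericMatrix& trI,
                                  const NumericMatrix& trD,
                                  bool want_path) {
  const int n = (int)x.size();
  const int L = me.nrow();
  ViterbiResult res;
  res.score = NEG_INF;
  res.qstart = res.qend = res.mstart = res.mend = 0;
  if (n == 0 || L == 0) return res;

  const int W = L + 1;
  std::vector<double> VM((n + 1) * W, NEG_INF), VI((n + 1) * W, NEG_INF),
      VD((n + 1) * W, NEG_INF);
  // traceback codes: 0 = fresh local entry, 1 = M, 2 = I, 3 = D
  std::vector<signed char> PM, PI, PD;
  if (want_path) {
    PM.assign((n + 1) * W, -1);
    PI.assign((n + 1) * W, -1);
    PD.assign((n + 1) * W, -1);
  }
  auto at = [W](int i, int j) { return i * W + j; };

  double best = NEG_INF;
  int bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    const int xi = x[i - 1];
    for (int j = 1; j <= L; ++j) {
      // M_j: emit x_i
      double em = (xi < 4) ? me(j - 1, xi) : 0.0;
      double sM = 0.0; // fresh entry
      signed char pM = 0;
      double c;
      c = VM[at(i - 1, j - 1)] + trM(j - 1, 0);
      if (c > sM) { sM = c; pM = 1; }
      c = VI[at(i - 1, j - 1)] + trI(j - 1, 0);
      if (c > sM) { sM = c; pM = 2; }
      c = VD[at(i - 1, j - 1)] + trD(j - 1, 0);
      if (c > sM) { sM = c; pM = 3; }
      VM[at(i, j)] = em + sM;
      if (want_path) PM[at(i, j)] = pM;
      if (VM[at(i, j)] > best) { best = VM[at(i, j)]; bi = i; bj = j; }

      // I_j: emit x_i
      double ei = (xi < 4) ? ie(j, xi) : 0.0;
      double sI = VM[at(i - 1, j)] + trM(j, 1);
      signed char pI = 1;
      c = VI[at(i - 1, j)] + trI(j, 1);
      if (c > sI) { sI = c; pI = 2; }
      c = VD[at(i - 1, j)] + trD(j, 1);
      if (c > sI) { sI = c; pI = 3; }
      VI[at(i, j)] = ei + sI;
      if (want_path) PI[at(i, j)] = pI;

      // D_j: silent
      double sD = VM[at(i, j - 1)] + trM(j - 1, 2);
      signed char pD = 1;
      c = VD[at(i, j - 1)] + trD(j - 1, 2);
      if (c > sD) { sD = c; pD = 3; }
      c = VI[at(i, j - 1)] + trI(j - 1, 2);
      if (c > sD) { sD = c; pD = 2; }
      VD[at(i, j)] = sD;
      if (want_path) PD[at(i, j)] = pD;
    }
  }

  res.score = best;
  if (best == NEG_INF) return res;
  res.qend = bi;          // half-open end (1-based bi == 0-based half-open)
  res.mend = bj;

  // walk back to the entry cell
  int i = bi, j = bj, state = 1;
  while (true) {
    signed char p;
    if (state == 1) {
      p = want_path ? PM[at(i, j)] : 0;
      if (want_path) {
        res.path_state.push_back(1);
        res.path_mpos.push_back(j);
        res.path_qpos.push_back(i);
      }
      if (!want_path) break;
      if (p == 0) break;
      i -= 1; j -= 1; state = p;
    } else if (state == 2) {
      p = PI[at(i, j)];
      res.path_state.push_back(2);
      res.path_mpos.push_back(j);
      res.path_qpos.push_back(i);
      i -= 1; state = p;
    } else {
      p = PD[at(i, j)];
      res.path_state.push_back(3);
      res.path_mpos.push_back(j);
      res.path_qpos.push_back(0);
      j -= 1; state = p;
    }
  }
  if (want_path) {
    std::reverse(res.path_state.begin(), res.path_state.end());
    std::reverse(res.path_mpos.begin(), res.path_mpos.end());
    std::reverse(res.path_qpos.begin(), res.path_qpos.end());
    res.qstart = i - 1; // 0-based start of emitted interval
    res.mstart = j;
  } else {
    // without pointers we cannot recover the start; rerun cheaply with
    // pointers is avoided by always recording them when interval is needed.
    res.qstart = 0;
    res.mstart = 1;
  }
  return res;
}

// [[Rcpp::export(name = ".viterbi_cpp")]]
List viterbi_cpp(IntegerVector seq, NumericMatrix me, NumericMatrix ie,
                 NumericMatrix trM, NumericMatrix trI, NumericMatrix trD,
                 bool want_path) {
  std::vector<int> x(seq.begin(), seq.end());
  ViterbiResult r = viterbi_core(x, me, ie, trM, trI, trD, true);
  List out = List::create(
      _["score"] = r.score, _["qstart"] = r.qstart, _["qend"] = r.qend,
      _["mstart"] = r.mstart, _["mend"] = r.mend);
  if (want_path) {
    out["path_state"] = IntegerVector(r.path_state.begin(), r.path_state.end());
    out["path_mpos"] = IntegerVector(r.path_mpos.begin(), r.path_mpos.end());
    out["path_qpos"] = IntegerVector(r.path_qpos.begin(), r.path_qpos.end());
  }
  return out;
}

// Batch scan used by fragment extraction: one row (score, qstart, qend) per
// input sequence.
// [[Rcpp::export(name = ".viterbi_batch_cpp")]]
NumericMatrix viterbi_batch_cpp(List seqs, NumericMatrix me, NumericMatrix ie,
                                NumericMatrix trM, NumericMatrix trI,
                                NumericMatrix trD) {
  const int n = seqs.size();
  NumericMatrix out(n, 3);
  for (int i = 0; i < n; ++i) {
    IntegerVector s = seqs[i];
    std::vector<int> x(s.begin(), s.end());
    ViterbiResult r = viterbi_core(x, me, ie, trM, trI, trD, true);
    out(i, 0) = r.score;
    out(i, 1) = r.qstart;
    out(i, 2) = r.qend;
  }
  return out;
}

// ---------------------------------------------------------------------------
// Affine-gap pairwise alignment (Smith-Waterman local / Needleman-Wunsch
// global). Unit identity scoring; a gap of length g costs
// gap_open + g * gap_ext. Returns alignment statistics needed for percent
// identity and p-distance: matches, aligned residue pairs, total columns.
// ---------------------------------------------------------------------------

// [[Rcpp::export(name = ".align_pair_cpp")]]
List align_pair_cpp(std::string q, std::string r, double match,
                    double mismatch, double gap_open, double gap_ext,
                    bool global) {
  const int n = (int)q.size(), m = (int)r.size();
  if (n == 0 || m == 0) {
    return List::create(_["score"] = NA_REAL, _["qstart"] = 0, _["qend"] = 0,
                        _["rstart"] = 0, _["rend"] = 0, _["matches"] = 0,
                        _["aligned_pairs"] = 0, _["aln_len"] = 0);
  }
  const double gfirst = gap_open + gap_ext;
  const int W = m + 1;
  std::vector<double> M((n + 1) * W, NEG_INF), X((n + 1) * W, NEG_INF),
      Y((n + 1) * W, NEG_INF);
  // pointers: M: 0 local-start, 1 M, 2 X, 3 Y ; X: 1 M, 2 X ; Y: 1 M, 3 Y
  std::vector<signed char> PM((n + 1) * W, -1), PX((n + 1) * W, -1),
      PY((n + 1) * W, -1);
  auto at = [W](int i, int j) { return i * W + j; };

  M[at(0, 0)] = 0.0;
  if (global) {
    for (int i = 1; i <= n; ++i) {
      X[at(i, 0)] = -(gap_open + i * gap_ext);
      PX[at(i, 0)] = (i == 1) ? 1 : 2;
    }
    for (int j = 1; j <= m; ++j) {
      Y[at(0, j)] = -(gap_open + j * gap_ext);
      PY[at(0, j)] = (j == 1) ? 1 : 3;
    }
  }

  double best = NEG_INF;
  int bi = 0, bj = 0, bstate = 1;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      const double s = (q[i - 1] == r[j - 1]) ? match : mismatch;
      double vM;
      signed char pM;
      if (global) {
        vM = M[at(i - 1, j - 1)];
        pM = 1;
      } else {
        vM = 0.0;
        pM = 0;
        if (M[at(i - 1, j - 1)] > vM) { vM = M[at(i - 1, j - 1)]; pM = 1; }
      }
      if (X[at(i - 1, j - 1)] > vM) { vM = X[at(i - 1, j - 1)]; pM = 2; }
      if (Y[at(i - 1, j - 1)] > vM) { vM = Y[at(i - 1, j - 1)]; pM = 3; }
      M[at(i, j)] = vM + s;
      PM[at(i, j)] = pM;

      double vX = M[at(i - 1, j)] - gfirst;
      signed char pX = 1;
      if (X[at(i - 1, j)] - gap_ext > vX) {
        vX = X[at(i - 1, j)] - gap_ext;
        pX = 2;
      }
      X[at(i, j)] = vX;
      PX[at(i, j)] = pX;

      double vY = M[at(i, j - 1)] - gfirst;
      signed char pY = 1;
      if (Y[at(i, j - 1)] - gap_ext > vY) {
        vY = Y[at(i, j - 1)] - gap_ext;
        pY = 3;
      }
      Y[at(i, j)] = vY;
      PY[at(i, j)] = pY;

      if (!global && M[at(i, j)] > best) {
        best = M[at(i, j)];
        bi = i; bj = j; bstate = 1;
      }
    }
  }
  if (global) {
    best = M[at(n, m)]; bi = n; bj = m; bstate = 1;
    if (X[at(n, m)] > best) { best = X[at(n, m)]; bstate = 2; }
    if (Y[at(n, m)] > best) { best = Y[at(n, m)]; bstate = 3; }
  }
  if (best == NEG_INF || (!global && best <= 0.0)) {
    return List::create(_["score"] = (global ? best : 0.0), _["qstart"] = 0,
                        _["qend"] = 0, _["rstart"] = 0, _["rend"] = 0,
                        _["matches"] = 0, _["aligned_pairs"] = 0,
                        _["aln_len"] = 0);
  }

  int i = bi, j = bj, state = bstate;
  int matches = 0, pairs = 0, cols = 0;
  while (true) {
    if (state == 1) {
      signed char p = PM[at(i, j)];
      if (i == 0 && j == 0) break;
      cols += 1;
      pairs += 1;
      if (q[i - 1] == r[j - 1]) matches += 1;
      i -= 1; j -= 1;
      if (p == 0) break;
      state = p;
      if (!global && i == 0 && j == 0) break;
      if (global && i == 0 && j == 0) break;
    } else if (state == 2) {
      signed char p = PX[at(i, j)];
      cols += 1;
      i -= 1;
      state = p;
      if (i == 0 && j == 0) break;
    } else {
      signed char p = PY[at(i, j)];
      cols += 1;
      j -= 1;
      state = p;
      if (i == 0 && j == 0) break;
    }
  }
  return List::create(_["score"] = best, _["qstart"] = i, _["qend"] = bi,
                      _["rstart"] = j, _["rend"] = bj, _["matches"] = matches,
                      _["aligned_pairs"] = pairs, _["aln_len"] = cols);
}
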