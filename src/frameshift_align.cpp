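// Frameshift-tolerant local alignment of a translated nucleotide query
// against a protein subject (modified Smith-Waterman).
//
// DP lattice over (nt consumed i, subject residues consumed j) with affine
// gaps.  Column transitions:
//   - codon column: consume 3 nt + 1 aa, scored by the substitution matrix,
//     or by stop_score when the codon is a stop;
//   - frame-slip columns: consume {1,2,4,5} nt + 1 aa, charged the
//     frameshift penalty (plus the trailing codon's substitution score when
//     a full codon is consumed, i.e. 4 or 5 nt);
//   - gap in subject: consume 3 nt (one codon) against '-', affine;
//   - gap in query: consume 1 aa against '-', affine.
// Local alignments start and end on a codon/slip column.  Ties are broken
// deterministically: transitions are evaluated in a fixed order (codon
// diagonal first, then slips by increasing nt, then gaps) and the first
// maximum wins; the best cell is the first maximum in (i, j) row-major scan.

#include <Rcpp.h>
#include <limits>
using namespace Rcpp;

static const double NEG_INF = -std::numeric_limits<double>::infinity();

// [[Rcpp::export(name = ".align_frameshift_cpp")]]
List align_frameshift_cpp(int n,
                          CharacterVector aa_at,
                          LogicalVector is_stop,
                          std::string subject,
                          NumericMatrix submat,
                          double gap_open,
                          double gap_extend,
                          double frameshift_penalty,
                          double stop_score) {
  const int m = (int) subject.size();
  if (m == 0) stop("subject protein must be non-empty");
  if (n < 3) stop("query must be at least 3 nt");

  // map residue characters to substitution-matrix indices
  List dn = submat.attr("dimnames");
  CharacterVector rn = dn[0];
  int idx[256];
  for (int c = 0; c < 256; ++c) idx[c] = -1;
  for (int k = 0; k < rn.size(); ++k) {
    std::string s = as<std::string>(rn[k]);
    if (s.size() == 1) idx[(unsigned char) s[0]] = k;
  }
  int xrow = idx[(unsigned char) 'X'];

  std::vector<int> sidx(m);
  for (int j = 0; j < m; ++j) {
    int r = idx[(unsigned char) subject[j]];
    if (r < 0) r = xrow;
    if (r < 0) stop("subject residue not in substitution matrix");
    sidx[j] = r;
  }

  // substitution score of the codon starting at 0-based nt position p
  // against subject residue j (0-based)
  std::vector<int> qrow(n, -1);           // matrix row of codon at p
  std::vector<bool> qstop(n, false);
  for (int p = 0; p + 3 <= n; ++p) {
    std::string a = as<std::string>(aa_at[p]);
    qstop[p] = is_stop[p];
    if (!a.empty()) {
      int r = idx[(unsigned char) a[0]];
      qrow[p] = (r >= 0) ? r : xrow;
    } else {
      qrow[p] = xrow;
    }
  }
  auto colscore = [&](int p, int j) -> double {
    if (qstop[p]) return stop_score;
    int r = qrow[p];
    if (r < 0) return 0.0;
    return submat(r, sidx[j]);
  };

  const int W = m + 1;
  std::vector<double> M((n + 1) * W, NEG_INF),
                      Ix((n + 1) * W, NEG_INF),
                      Iy((n + 1) * W, NEG_INF);
  // pointers: for M, transition (0=codon,1..4=slip{1,2,4,5}) and source
  // state (0=fresh start, 1=M, 2=Ix, 3=Iy); for Ix/Iy, source (1=M, self=2/3)
  std::vector<signed char> ptrM_tr((n + 1) * W, -1),
                           ptrM_src((n + 1) * W, -1),
                           ptrIx((n + 1) * W, -1),
                           ptrIy((n + 1) * W, -1);
  const int slip_nt[4] = {1, 2, 4, 5};

  double best = 0.0;
  int best_i = -1, best_j = -1;

  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      const int at = i * W + j;
      // --- M: codon column then slips, fixed order, strict > keeps first
      double bm = NEG_INF;
      signed char btr = -1, bsrc = -1;
      // transition list: {nt consumed, transition code}
      for (int t = 0; t < 5; ++t) {
        int k = (t == 0) ? 3 : slip_nt[t - 1];
        if (i - k < 0) continue;
        int from = (i - k) * W + (j - 1);
        double add;
        if (t == 0) add = colscore(i - 3, j - 1);
        else add = frameshift_penalty +
                   ((k >= 4) ? colscore(i - 3, j - 1) : 0.0);
        // source preference: fresh start, then M, Ix, Iy — fresh start
        // first so zero-start locality is preferred on equal score
        double cands[4] = {0.0, M[from], Ix[from], Iy[from]};
        for (int s = 0; s < 4; ++s) {
          if (cands[s] == NEG_INF) continue;
          double v = cands[s] + add;
          if (v > bm) { bm = v; btr = (signed char) t; bsrc = (signed char) s; }
        }
      }
      M[at] = bm; ptrM_tr[at] = btr; ptrM_src[at] = bsrc;
      // --- Ix: gap in subject, consumes one query codon
      if (i - 3 >= 0) {
        int from = (i - 3) * W + j;
        double vo = (M[from] == NEG_INF) ? NEG_INF : M[from] + gap_open;
        double ve = (Ix[from] == NEG_INF) ? NEG_INF : Ix[from] + gap_extend;
        if (vo >= ve) { Ix[at] = vo; ptrIx[at] = 1; }
        else          { Ix[at] = ve; ptrIx[at] = 2; }
      }
      // --- Iy: gap in query, consumes one subject residue
      {
        int from = i * W + (j - 1);
        double vo = (M[from] == NEG_INF) ? NEG_INF : M[from] + gap_open;
        double ve = (Iy[from] == NEG_INF) ? NEG_INF : Iy[from] + gap_extend;
        if (vo >= ve) { Iy[at] = vo; ptrIy[at] = 1; }
        else          { Iy[at] = ve; ptrIy[at] = 3; }
      }
      if (M[at] > best) { best = M[at]; best_i = i; best_j = j; }
    }
  }

  // empty alignment
  if (best_i < 0) {
    return List::create(_["score"] = 0.0,
                        _["ops"] = IntegerMatrix(0, 3));
  }

  // traceback
  std::vector<int> op_v, qi_v, sj_v;    // op, nt consumed after col, aa idx
  int i = best_i, j = best_j, state = 1; // 1=M, 2=Ix, 3=Iy
  while (true) {
    const int at = i * W + j;
    if (state == 1) {
      int t = ptrM_tr[at], src = ptrM_src[at];
      int k = (t == 0) ? 3 : slip_nt[t - 1];
      // ops: 0 codon, 1..4 slips, 5 gap-in-subject, 6 gap-in-query
      op_v.push_back(t == 0 ? 0 : t);
      qi_v.push_back(i);
      sj_v.push_back(j);
      i -= k; j -= 1;
      if (src == 0) break;
      state = src;
    } else if (state == 2) {
      op_v.push_back(5); qi_v.push_back(i); sj_v.push_back(j);
      int src = ptrIx[at];
      i -= 3;
      state = (src == 1) ? 1 : 2;
    } else {
      op_v.push_back(6); qi_v.push_back(i); sj_v.push_back(j);
      int src = ptrIy[at];
      j -= 1;
      state = (src == 1) ? 1 : 3;
    }
  }

  const int L = (int) op_v.size();
  IntegerMatrix ops(L, 3);
  for (int r = 0; r < L; ++r) {
    ops(L - 1 - r, 0) = op_v[r];
    ops(L - 1 - r, 1) = qi_v[r];
    ops(L - 1 - r, 2) = sj_v[r];
  }
  colnames(ops) = CharacterVector::create("op", "q_nt_end", "s_pos");
  return List::create(_["score"] = best, _["ops"] = ops);
}
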