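#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Affine-gap pairwise alignment (Gotoh) with full traceback.
// Codes in `a`/`b` are 1-based row/column indices into `submat`.
// Gap of length g costs gapOpen + g * gapExt.
// Tie-break among predecessors: diagonal (M) > up (gap in b) > left (gap in a).
// local = true gives Smith-Waterman (alignments start and end in M).
// [[Rcpp::export]]
List cpp_align_affine(IntegerVector a, IntegerVector b, NumericMatrix submat,
                      double gapOpen, double gapExt, bool local) {
  const int n = a.size(), m = b.size();
  const double NEG = -1e18;
  const int W = m + 1;
  std::vector<double> M((n + 1) * W, NEG), X((n + 1) * W, NEG),
      Y((n + 1) * W, NEG);
  // traceback: M: 0 = start, 1 = from M, 2 = from X, 3 = from Y
  //            X: 1 = opened from M, 2 = extended; Y likewise
  std::vector<unsigned char> tM((n + 1) * W, 0), tX((n + 1) * W, 0),
      tY((n + 1) * W, 0);

  M[0] = 0.0;
  if (local) {
    for (int i = 1; i <= n; ++i) M[i * W] = 0.0;
    for (int j = 1; j <= m; ++j) M[j] = 0.0;
  } else {
    for (int i = 1; i <= n; ++i) { X[i * W] = -(gapOpen + i * gapExt); tX[i * W] = 2; }
    tX[W] = 1;
    for (int j = 1; j <= m; ++j) { Y[j] = -(gapOpen + j * gapExt); tY[j] = 2; }
    tY[1] = 1;
  }

  double best = local ? 0.0 : NEG;
  int bi = 0, bj = 0;

  for (int i = 1; i <= n; ++i) {
    const int ai = a[i - 1] - 1;
    for (int j = 1; j <= m; ++j) {
      const int idx = i * W + j, up = (i - 1) * W + j, lf = idx - 1,
                dg = up - 1;
      // X: consume a_i (gap in b)
      double xo = M[up] - (gapOpen + gapExt), xe = X[up] - gapExt;
      if (xo >= xe) { X[idx] = xo; tX[idx] = 1; } else { X[idx] = xe; tX[idx] = 2; }
      // Y: consume b_j (gap in a)
      double yo = M[lf] - (gapOpen + gapExt), ye = Y[lf] - gapExt;
      if (yo >= ye) { Y[idx] = yo; tY[idx] = 1; } else { Y[idx] = ye; tY[idx] = 2; }
      // M: diagonal
      double pm = M[dg], px = X[dg], py = Y[dg];
      double bestPrev = pm; unsigned char tb = 1;
      if (px > bestPrev) { bestPrev = px; tb = 2; }
      if (py > bestPrev) { bestPrev = py; tb = 3; }
      double sc = bestPrev + submat(ai, b[j - 1] - 1);
      if (local && sc < 0.0) { M[idx] = 0.0; tM[idx] = 0; }
      else {
        M[idx] = sc;
        tM[idx] = (bestPrev <= NEG / 2) ? 0 : tb;
      }
      if (local && M[idx] > best) { best = M[idx]; bi = i; bj = j; }
    }
  }

  int mat = 1;  // 1 = M, 2 = X, 3 = Y
  if (!local) {
    bi = n; bj = m;
    best = M[bi * W + bj]; mat = 1;
    if (X[bi * W + bj] > best) { best = X[bi * W + bj]; mat = 2; }
    if (Y[bi * W + bj] > best) { best = Y[bi * W + bj]; mat = 3; }
  }

  std::vector<int> aIdx, bIdx;
  int i = bi, j = bj;
  if (local && best <= 0.0) { i = 0; j = 0; }
  while (i > 0 || j > 0) {
    const int idx = i * W + j;
    if (mat == 1) {
      unsigned char t = tM[idx];
      if (t == 0 && M[idx] <= 0.0) break;  // local restart / border, not a column
      aIdx.push_back(i); bIdx.push_back(j);
      --i; --j;
      if (t == 0) break;  // alignment starts with this column
      mat = t;
    } else if (mat == 2) {
      unsigned char t = tX[idx];
      aIdx.push_back(i); bIdx.push_back(0);
      --i;
      mat = (t == 1) ? 1 : 2;
    } else {
      unsigned char t = tY[idx];
      aIdx.push_back(0); bIdx.push_back(j);
      --j;
      mat = (t == 1) ? 1 : 3;
    }
  }
  std::reverse(aIdx.begin(), aIdx.end());
  std::reverse(bIdx.begin(), bIdx.end());

  return List::create(_["score"] = best, _["a_idx"] = wrap(aIdx),
                      _["b_idx"] = wrap(bIdx));
}

// Ungapped X-drop extension of exact word seeds.
// Seeds must be sorted by (diagonal, qpos); seeds starting inside the
// previously extended hit on the same diagonal are skipped.
// 'N' never matches. Returns one row per extended hit:
// qstart, qend, sstart, send, score, matches.
// [[Rcpp::export]]
NumericMatrix cpp_ungapped_extend(std::string q, std::string s,
                                  IntegerVector qpos, IntegerVector spos,
                                  int k, double match, double mismatch,
                                  double xdrop) {
  const int nq = q.size(), ns = s.size(), nseed = qpos.size();
  std::vector<double> out;
  long lastDiag = -2147483647; int lastQEnd = -1;
  for (int t = 0; t < nseed; ++t) {
    const int q0 = qpos[t], s0 = spos[t];   // 1-based
    const long diag = (long)q0 - (long)s0;
    if (diag == lastDiag && q0 <= lastQEnd) continue;
    double seedScore = k * match;
    // left extension
    double cur = seedScore, bestL = 0.0; int extL = 0, matL = 0, curMatL = 0;
    {
      int i = q0 - 1, j = s0 - 1, ext = 0;
      double base = seedScore;
      while (i >= 1 && j >= 1) {
        const char ci = q[i - 1], cj = s[j - 1];
        const bool isM = (ci == cj && ci != 'N');
        cur += isM ? match : mismatch;
        if (isM) ++curMatL;
        ++ext;
        if (cur - base > bestL) { bestL = cur - base; extL = ext; matL = curMatL; }
        if (cur < base + bestL - xdrop) break;
        --i; --j;
      }
    }
    // right extension
    double bestR = 0.0; int extR = 0, matR = 0, curMatR = 0;
    {
      int i = q0 + k, j = s0 + k, ext = 0;
      double cur2 = seedScore, base = seedScore;
      while (i <= nq && j <= ns) {
        const char ci = q[i - 1], cj = s[j - 1];
        const bool isM = (ci == cj && ci != 'N');
        cur2 += isM ? match : mismatch;
        if (isM) ++curMatR;
        ++ext;
        if (cur2 - base > bestR) { bestR = cur2 - base; extR = ext; matR = curMatR; }
        if (cur2 < base + bestR - xdrop) break;
        ++i; ++j;
      }
    }
    const int qs = q0 - extL, qe = q0 + k - 1 + extR;
    const int ss = s0 - extL, se = s0 + k - 1 + extR;
    const double score = seedScore + bestL + bestR;
    const int matches = k + matL + matR;
    out.push_back(qs); out.push_back(qe); out.push_back(ss); out.push_back(se);
    out.push_back(score); out.push_back(matches);
    lastDiag = diag; lastQEnd = qe;
  }
  const int nh = out.size() / 6;
  NumericMatrix res(nh, 6);
  for (int r = 0; r < nh; ++r)
    for (int c = 0; c < 6; ++c) res(r, c) = out[r * 6 + c];
  colnames(res) = CharacterVector::create("qstart", "qend", "sstart", "send",
                                          "score", "matches");
  return res;
}

// Maximal equal runs between x[i] and y[i + off] (0-based offset), 'N'
// never matches. Returns runs of length >= minLen as rows (start_x, len),
// 1-based start in x.
// [[Rcpp::export]]
IntegerMatrix cpp_diag_runs(std::string x, std::string y, int off,
                            int minLen) {
  const int nx = x.size(), ny = y.size();
  std::vector<int> starts, lens;
  int i = (off < 0) ? -off : 0;  // need i + off >= 0
  const int iMax = std::min(nx, ny - off);
  int runStart = -1;
  for (; i < iMax; ++i) {
    const char a = x[i], b = y[i + off];
    const bool eq = (a == b && a != 'N');
    if (eq) { if (runStart < 0) runStart = i; }
    else if (runStart >= 0) {
      const int len = i - runStart;
      if (len >= minLen) { starts.push_back(runStart + 1); lens.push_back(len); }
      runStart = -1;
    }
  }
  if (runStart >= 0) {
    const int len = iMax - runStart;
    if (len >= minLen) { starts.push_back(runStart + 1); lens.push_back(len); }
  }
  IntegerMatrix res(starts.size(), 2);
  for (int r = 0; r < (int)starts.size(); ++r) {
    res(r, 0) = starts[r]; res(r, 1) = lens[r];
  }
  colnames(res) = CharacterVector::create("start", "len");
  return res;
}
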