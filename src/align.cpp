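#include <Rcpp.h>
#include <string>
#include <vector>
using namespace Rcpp;

// Needleman-Wunsch global alignment with affine (Gotoh) or linear gaps.
// A gap of length L costs gap_open + L * gap_extend in affine mode and
// L * gap_extend in linear mode. Traceback is deterministic: at score ties
// the diagonal move wins over up (gap in b), which wins over left (gap in a).
// `sub` is a 26x26 matrix indexed by uppercase letter - 'A'.

static const double NEG_INF = -1e18;

// [[Rcpp::export(name = ".nw_align_cpp")]]
List nw_align_cpp(std::string a, std::string b, NumericMatrix sub,
                  double gap_open, double gap_extend, bool affine) {
  const int n = a.size(), m = b.size();
  if (n == 0 || m == 0) stop("sequences must be non-empty");
  std::vector<int> ai(n), bi(m);
  for (int i = 0; i < n; ++i) {
    int c = a[i] - 'A';
    if (c < 0 || c >= 26) stop("invalid residue '%s' in sequence", std::string(1, a[i]));
    ai[i] = c;
  }
  for (int j = 0; j < m; ++j) {
    int c = b[j] - 'A';
    if (c < 0 || c >= 26) stop("invalid residue '%s' in sequence", std::string(1, b[j]));
    bi[j] = c;
  }

  // states: 0 = M (diagonal), 1 = Ix (up, gap in b), 2 = Iy (left, gap in a)
  const int NM = (n + 1) * (m + 1);
  std::vector<double> M(NM, NEG_INF), Ix(NM, NEG_INF), Iy(NM, NEG_INF);
  // ptr[state][cell]: predecessor state, -1 at origin
  std::vector<signed char> pM(NM, -1), pIx(NM, -1), pIy(NM, -1);
  const double open_cost = affine ? (gap_open + gap_extend) : gap_extend;
  const double ext_cost = gap_extend;
  #define IDX(i, j) ((i) * (m + 1) + (j))

  M[IDX(0, 0)] = 0.0;
  for (int i = 1; i <= n; ++i) {
    Ix[IDX(i, 0)] = affine ? -(gap_open + i * gap_extend) : -(i * gap_extend);
    pIx[IDX(i, 0)] = (i == 1) ? 0 : 1;
  }
  for (int j = 1; j <= m; ++j) {
    Iy[IDX(0, j)] = affine ? -(gap_open + j * gap_extend) : -(j * gap_extend);
    pIy[IDX(0, j)] = (j == 1) ? 0 : 2;
  }

  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      const int c = IDX(i, j), d = IDX(i - 1, j - 1), u = IDX(i - 1, j), l = IDX(i, j - 1);
      const double s = sub(ai[i - 1], bi[j - 1]);
      // M: tie-break prefers M > Ix > Iy predecessors
      double best = M[d]; signed char ps = 0;
      if (Ix[d] > best) { best = Ix[d]; ps = 1; }
      if (Iy[d] > best) { best = Iy[d]; ps = 2; }
      if (best > NEG_INF / 2) { M[c] = best + s; pM[c] = ps; }
      // Ix: gap in b (consume a[i]); open from M, extend from Ix
      double vo = M[u] - open_cost, ve = Ix[u] - ext_cost;
      if (!affine) { // linear: every gap symbol costs ext; Iy->Ix switches allowed
        double vy = Iy[u] - ext_cost;
        if (vo >= ve && vo >= vy) { Ix[c] = vo; pIx[c] = 0; }
        else if (ve >= vy)        { Ix[c] = ve; pIx[c] = 1; }
        else                      { Ix[c] = vy; pIx[c] = 2; }
      } else {
        if (vo >= ve) { Ix[c] = vo; pIx[c] = 0; } else { Ix[c] = ve; pIx[c] = 1; }
      }
      // Iy: gap in a (consume b[j])
      vo = M[l] - open_cost; ve = Iy[l] - ext_cost;
      if (!affine) {
        double vx = Ix[l] - ext_cost;
        if (vo >= vx && vo >= ve) { Iy[c] = vo; pIy[c] = 0; }
        else if (vx >= ve)        { Iy[c] = vx; pIy[c] = 1; }
        else                      { Iy[c] = ve; pIy[c] = 2; }
      } else {
        if (vo >= ve) { Iy[c] = vo; pIy[c] = 0; } else { Iy[c] = ve; pIy[c] = 2; }
      }
    }
  }

  const int e = IDX(n, m);
  double score = M[e]; int state = 0;
  if (Ix[e] > score) { score = Ix[e]; state = 1; }
  if (Iy[e] > score) { score = Iy[e]; state = 2; }

  std::string ga, gb;
  ga.reserve(n + m); gb.reserve(n + m);
  int i = n, j = m;
  while (i > 0 || j > 0) {
    const int c = IDX(i, j);
    if (state == 0) {
      signed char ps = pM[c];
      ga.push_back(a[i - 1]); gb.push_back(b[j - 1]);
      --i; --j; state = ps;
    } else if (state == 1) {
      signed char ps = pIx[c];
      ga.push_back(a[i - 1]); gb.push_back('-');
      --i; state = ps;
    } else {
      signed char ps = pIy[c];
      ga.push_back('-'); gb.push_back(b[j - 1]);
      --j; state = ps;
    }
  }
  std::reverse(ga.begin(), ga.end());
  std::reverse(gb.begin(), gb.end());
  return List::create(_["a"] = ga, _["b"] = gb, _["score"] = score);
}

// Dynamic-programming core of profile-profile alignment. `colscore` holds
// the pre-computed mean pairwise score of column i of profile A vs column j
// of profile B; `gap_a` / `gap_b` the score of aligning a column of A (resp.
// B) against an all-gap column. Gotoh over profile columns: each run of
// inserted gap columns additionally pays `gap_open` once (0 for linear
// schemes). Tie-break diagonal > up (consume A) > left (consume B).
// Returns merge operations as two logical vectors over output columns.

// [[Rcpp::export(name = ".profile_dp_cpp")]]
List profile_dp_cpp(NumericMatrix colscore, NumericVector gap_a,
                    NumericVector gap_b, double gap_open) {
  const int n = colscore.nrow(), m = colscore.ncol();
  #define ID2(i, j) ((i) * (m + 1) + (j))
  const int NC = (n + 1) * (m + 1);
  // states: 0 = M (diag), 1 = GA (gap column in B, consume A), 2 = GB
  std::vector<double> M(NC, NEG_INF), GA(NC, NEG_INF), GB(NC, NEG_INF);
  std::vector<signed char> pM(NC, -1), pGA(NC, -1), pGB(NC, -1);
  M[0] = 0.0;
  for (int i = 1; i <= n; ++i) {
    GA[ID2(i, 0)] = (i == 1 ? -gap_open : GA[ID2(i - 1, 0)]) + gap_a[i - 1];
    pGA[ID2(i, 0)] = (i == 1) ? 0 : 1;
  }
  for (int j = 1; j <= m; ++j) {
    GB[ID2(0, j)] = (j == 1 ? -gap_open : GB[ID2(0, j - 1)]) + gap_b[j - 1];
    pGB[ID2(0, j)] = (j == 1) ? 0 : 2;
  }
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      const int c = ID2(i, j), d = ID2(i - 1, j - 1), u = ID2(i - 1, j),
                l = ID2(i, j - 1);
      double best = M[d]; signed char ps = 0;
      if (GA[d] > best) { best = GA[d]; ps = 1; }
      if (GB[d] > best) { best = GB[d]; ps = 2; }
      if (best > NEG_INF / 2) { M[c] = best + colscore(i - 1, j - 1); pM[c] = ps; }
      double vo = std::max(M[u], GB[u]) - gap_open, ve = GA[u];
      signed char po = (M[u] >= GB[u]) ? 0 : 2;
      if (vo >= ve) { GA[c] = vo + gap_a[i - 1]; pGA[c] = po; }
      else          { GA[c] = ve + gap_a[i - 1]; pGA[c] = 1; }
      vo = std::max(M[l], GA[l]) - gap_open; ve = GB[l];
      po = (M[l] >= GA[l]) ? 0 : 1;
      if (vo >= ve) { GB[c] = vo + gap_b[j - 1]; pGB[c] = po; }
      else          { GB[c] = ve + gap_b[j - 1]; pGB[c] = 2; }
    }
  }
  const int e = ID2(n, m);
  double score = M[e]; int state = 0;
  if (GA[e] > score) { score = GA[e]; state = 1; }
  if (GB[e] > score) { score = GB[e]; state = 2; }
  std::vector<int> ops; // 0 diag, 1 up, 2 left (reversed)
  int i = n, j = m;
  while (i > 0 || j > 0) {
    const int c = ID2(i, j);
    ops.push_back(state);
    if (state == 0)      { state = pM[c];  --i; --j; }
    else if (state == 1) { state = pGA[c]; --i; }
    else                 { state = pGB[c]; --j; }
  }
  std::reverse(ops.begin(), ops.end());
  const int L = ops.size();
  LogicalVector takeA(L), takeB(L);
  for (int k = 0; k < L; ++k) {
    takeA[k] = (ops[k] != 2);
    takeB[k] = (ops[k] != 1);
  }
  return List::create(_["take_a"] = takeA, _["take_b"] = takeB,
                      _["score"] = score);
}
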