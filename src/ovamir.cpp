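#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

static const double BIG = 1e9;
static const double EPS = 1e-7;

static inline int baseCode(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': case 'U': case 'u': return 3;
    default: return -1;
  }
}

// pair type index into the 6x6 stack table; -1 if not a legal pair
// order: CG GC GU UG AU UA (first base is the 5'-most base of the pair)
static inline int pairType(int a, int b) {
  if (a == 1 && b == 2) return 0;
  if (a == 2 && b == 1) return 1;
  if (a == 2 && b == 3) return 2;
  if (a == 3 && b == 2) return 3;
  if (a == 0 && b == 3) return 4;
  if (a == 3 && b == 0) return 5;
  return -1;
}

// Single-optimal nested-structure fold under the package's nearest-neighbor
// style model: stacking energies for adjacent pairs, linear hairpin and
// interior/bulge loop penalties (interior loops capped), affine multiloop
// cost. forbid[i] = TRUE excludes position i from pairing (accessibility
// constraint mode). Exact DP; deterministic traceback.
// [[Rcpp::export(name = ".fold_engine")]]
List fold_engine(std::string seq, LogicalVector forbid, NumericMatrix stacks,
                 double hairpin_a, double hairpin_b, double loop_a,
                 double loop_b, double multi_a, double multi_b,
                 double multi_c, int max_interior, int min_loop) {
  int n = seq.size();
  std::vector<int> s(n);
  for (int i = 0; i < n; ++i) s[i] = baseCode(seq[i]);

  if (n < 2) {
    return List::create(_["energy"] = 0.0,
                        _["partner"] = IntegerVector(n, 0),
                        _["dot_bracket"] = std::string(n, '.'));
  }

  // V(i,j): best energy with (i,j) paired; WM: multiloop segment, >=1 branch
  std::vector<std::vector<double> > V(n, std::vector<double>(n, BIG));
  std::vector<std::vector<double> > WM(n, std::vector<double>(n, BIG));
  // backpointers: VK/VL: (-1,-1) hairpin; (k,l) interior; (-2,k) multi split
  std::vector<std::vector<int> > VK(n, std::vector<int>(n, 0));
  std::vector<std::vector<int> > VL(n, std::vector<int>(n, 0));
  // WMC: 0 V-branch; 1 left unpaired; 2 right unpaired; 3 split at WMK
  std::vector<std::vector<int> > WMC(n, std::vector<int>(n, -1));
  std::vector<std::vector<int> > WMK(n, std::vector<int>(n, 0));

  for (int d = 1; d < n; ++d) {
    for (int i = 0; i + d < n; ++i) {
      int j = i + d;
      // --- V(i,j) ---
      int pt = pairType(s[i], s[j]);
      if (pt >= 0 && !forbid[i] && !forbid[j] && (j - i - 1) >= min_loop) {
        double best = hairpin_a + hairpin_b * (j - i - 1);
        int bk = -1, bl = -1;
        // stack / interior / bulge with one interior pair (k,l)
        for (int k = i + 1; k < j - 1 && (k - i - 1) <= max_interior; ++k) {
          for (int l = j - 1; l > k; --l) {
            int u = (k - i - 1) + (j - 1 - l);
            if (u > max_interior) break;
            if (V[k][l] >= BIG / 2) continue;
            double e;
            if (u == 0)
              e = stacks(pt, pairType(s[k], s[l])) + V[k][l];
            else
              e = loop_a + loop_b * u + V[k][l];
            if (e < best - EPS) { best = e; bk = k; bl = l; }
          }
        }
        // multiloop closed by (i,j): >=2 branches inside
        for (int k = i + 2; k <= j - 1; ++k) {
          if (WM[i + 1][k - 1] >= BIG / 2 || WM[k][j - 1] >= BIG / 2) continue;
          double e = multi_a + WM[i + 1][k - 1] + WM[k][j - 1];
          if (e < best - EPS) { best = e; bk = -2; bl = k; }
        }
        V[i][j] = best;
        VK[i][j] = bk;
        VL[i][j] = bl;
      }
      // --- WM(i,j) ---
      double best = BIG;
      int bc = -1, bk = 0;
      if (V[i][j] < BIG / 2 && V[i][j] + multi_b < best - EPS) {
        best = V[i][j] + multi_b; bc = 0;
      }
      if (WM[i + 1][j] < BIG / 2 && WM[i + 1][j] + multi_c < best - EPS) {
        best = WM[i + 1][j] + multi_c; bc = 1;
      }
      if (WM[i][j - 1] < BIG / 2 && WM[i][j - 1] + multi_c < best - EPS) {
        best = WM[i][j - 1] + multi_c; bc = 2;
      }
      for (int k = i + 1; k <= j; ++k) {
        if (WM[i][k - 1] >= BIG / 2 || WM[k][j] >= BIG / 2) continue;
        double e = WM[i][k - 1] + WM[k][j];
        if (e < best - EPS) { best = e; bc = 3; bk = k; }
      }
      WM[i][j] = best;
      WMC[i][j] = bc;
      WMK[i][j] = bk;
    }
  }

  // external loop
  std::vector<double> W(n + 1, 0.0);
  for (int j = 0; j < n; ++j) {
    W[j + 1] = W[j];
    for (int i = 0; i <= j; ++i) {
      if (V[i][j] >= BIG / 2) continue;
      double e = W[i] + V[i][j];
      if (e < W[j + 1] - EPS) W[j + 1] = e;
    }
  }
  double mfe = W[n];

  // traceback
  std::vector<int> partner(n, -1);
  std::vector<std::pair<std::pair<int, int>, int> > stk; // ((i,j), state 0=V 1=WM)
  int j = n;
  while (j > 0) {
    if (std::fabs(W[j] - W[j - 1]) < EPS) { --j; continue; }
    int found = -1;
    for (int i = 0; i < j; ++i) {
      if (V[i][j - 1] < BIG / 2 && std::fabs(W[i] + V[i][j - 1] - W[j]) < EPS) {
        found = i; break;
      }
    }
    if (found < 0) { --j; continue; } // defensive; should not happen
    stk.push_back(std::make_pair(std::make_pair(found, j - 1), 0));
    j = found;
  }
  while (!stk.empty()) {
    int i = stk.back().first.first;
    int jj = stk.back().first.second;
    int state = stk.back().second;
    stk.pop_back();
    if (state == 0) {
      partner[i] = jj; partner[jj] = i;
      int bk = VK[i][jj], bl = VL[i][jj];
      if (bk == -1) continue; // hairpin
      if (bk == -2) {         // multi split at bl
        stk.push_back(std::make_pair(std::make_pair(i + 1, bl - 1), 1));
        stk.push_back(std::make_pair(std::make_pair(bl, jj - 1), 1));
      } else {
        stk.push_back(std::make_pair(std::make_pair(bk, bl), 0));
      }
    } else {
      int bc = WMC[i][jj];
      if (bc == 0) stk.push_back(std::make_pair(std::make_pair(i, jj), 0));
      else if (bc == 1) stk.push_back(std::make_pair(std::make_pair(i + 1, jj), 1));
      else if (bc == 2) stk.push_back(std::make_pair(std::make_pair(i, jj - 1), 1));
      else if (bc == 3) {
        int k = WMK[i][jj];
        stk.push_back(std::make_pair(std::make_pair(i, k - 1), 1));
        stk.push_back(std::make_pair(std::make_pair(k, jj), 1));
      }
    }
  }

  std::string db(n, '.');
  IntegerVector part(n, 0);
  for (int i = 0; i < n; ++i) {
    if (partner[i] >= 0) {
      part[i] = partner[i] + 1; // 1-based, 0 = unpaired
      db[i] = (partner[i] > i) ? '(' : ')';
    }
  }
  return List::create(_["energy"] = mfe, _["partner"] = part,
                      _["dot_bracket"] = db);
}

// Local (Smith-Waterman) complementarity alignment of a miRNA (given 5'->3',
// aligned antiparallel) against a target window (5'->3'), affine gaps.
// Pair scores: Watson-Crick wc_score, G:U wobble gu_score, mismatch
// mm_score; scores doubled at miRNA positions w5_from..w5_to (1-based from
// the miRNA 5' end). Gap penalties are not weighted.
// [[Rcpp::export(name = ".sw_duplex")]]
List sw_duplex(std::string mirna, std::string window, double wc_score,
               double gu_score, double mm_score, double gap_open,
               double gap_extend, double w5_factor, int w5_from, int w5_to) {
  int m = mirna.size(), w = window.size();
  std::vector<int> mr(m), wn(w);
  for (int i = 0; i < m; ++i) mr[i] = baseCode(mirna[m - 1 - i]); // reversed
  for (int j = 0; j < w; ++j) wn[j] = baseCode(window[j]);

  std::vector<std::vector<double> > H(m + 1, std::vector<double>(w + 1, 0)),
      E(m + 1, std::vector<double>(w + 1, -BIG)),
      F(m + 1, std::vector<double>(w + 1, -BIG));
  std::vector<std::vector<char> > P(m + 1, std::vector<char>(w + 1, 0));
  // P: 0 stop, 1 diag, 2 up(gap in window), 3 left(gap in miRNA)
  double best = 0; int bi = 0, bj = 0;
  for (int i = 1; i <= m; ++i) {
    int pos5 = m - (i - 1); // miRNA position (1-based from 5' end) of mr[i-1]
    double wgt = (pos5 >= w5_from && pos5 <= w5_to) ? w5_factor : 1.0;
    for (int jj = 1; jj <= w; ++jj) {
      int a = mr[i - 1], b = wn[jj - 1];
      double sc;
      int pt = (a >= 0 && b >= 0) ? pairType(b, a) : -1;
      if (pt == 0 || pt == 1 || pt == 4 || pt == 5) sc = wc_score;
      else if (pt == 2 || pt == 3) sc = gu_score;
      else sc = mm_score;
      sc *= wgt;
      E[i][jj] = std::max(H[i][jj - 1] + gap_open, E[i][jj - 1] + gap_extend);
      F[i][jj] = std::max(H[i - 1][jj] + gap_open, F[i - 1][jj] + gap_extend);
      double h = H[i - 1][jj - 1] + sc;
      double v = 0; char p = 0;
      if (h > v) { v = h; p = 1; }
      if (F[i][jj] > v) { v = F[i][jj]; p = 2; }
      if (E[i][jj] > v) { v = E[i][jj]; p = 3; }
      H[i][jj] = v; P[i][jj] = p;
      if (v > best + EPS) { best = v; bi = i; bj = jj; }
    }
  }

  std::vector<int> col_m, col_w; // per alignment column, 0-based; -1 = gap
  int i = bi, jj = bj;
  while (i > 0 && jj > 0 && H[i][jj] > EPS && P[i][jj] != 0) {
    char p = P[i][jj];
    if (p == 1) { col_m.push_back(i - 1); col_w.push_back(jj - 1); --i; --jj; }
    else if (p == 2) { // gap in window: consume miRNA rows along F
      while (i > 0) {
        col_m.push_back(i - 1); col_w.push_back(-1); --i;
        if (std::fabs(F[i + 1][jj] - (H[i][jj] + gap_open)) < EPS) break;
      }
    } else { // gap in miRNA: consume window cols along E
      while (jj > 0) {
        col_m.push_back(-1); col_w.push_back(jj - 1); --jj;
        if (std::fabs(E[i][jj + 1] - (H[i][jj] + gap_open)) < EPS) break;
      }
    }
  }
  std::reverse(col_m.begin(), col_m.end());
  std::reverse(col_w.begin(), col_w.end());
  int ncol = col_m.size();
  IntegerVector mcol(ncol), wcol(ncol);
  for (int k = 0; k < ncol; ++k) {
    // convert reversed-miRNA index back to original 5'->3' 0-based index
    mcol[k] = (col_m[k] < 0) ? NA_INTEGER : (m - 1 - col_m[k]);
    wcol[k] = (col_w[k] < 0) ? NA_INTEGER : col_w[k];
  }
  return List::create(_["score"] = best, _["mirna_col"] = mcol,
                      _["window_col"] = wcol);
}

// Ungapped tag-vs-mature matching with soft terminal offsets.
// offset = start of tag on the mature (may be negative); overhanging tag
// bases are allowed up to max_offset at each end and are not counted as
// mismatches. matures must be supplied in name-sorted order (tie-break).
// [[Rcpp::export(name = ".match_tags")]]
List match_tags(CharacterVector tags, CharacterVector matures, int max_mm,
                int max_offset) {
  int nt = tags.size(), nm = matures.size();
  std::vector<std::string> T(nt), M(nm);
  for (int i = 0; i < nt; ++i) T[i] = as<std::string>(tags[i]);
  for (int i = 0; i < nm; ++i) M[i] = as<std::string>(matures[i]);
  IntegerVector best_idx(nt, NA_INTEGER), best_mm(nt, NA_INTEGER),
      best_off(nt, NA_INTEGER);
  // offset scan order fixes ties at equal |offset|: 0,-1,1,-2,2,...
  std::vector<int> offs;
  offs.push_back(0);
  for (int o = 1; o <= max_offset; ++o) { offs.push_back(-o); offs.push_back(o); }
  for (int t = 0; t < nt; ++t) {
    int lt = T[t].size();
    int bmm = max_mm + 1, boff = 0, bidx = -1;
    for (int mi = 0; mi < nm; ++mi) {
      int lm = M[mi].size();
      for (size_t oi = 0; oi < offs.size(); ++oi) {
        int o = offs[oi];
        int right_over = (o + lt) - lm;
        if (right_over > max_offset) continue;
        int from = std::max(0, -o), to = std::min(lt, lm - o);
        if (to - from < 1) continue;
        int mm = 0;
        for (int p = from; p < to && mm <= max_mm; ++p)
          if (T[t][p] != M[mi][o + p]) ++mm;
        if (mm > max_mm) continue;
        if (mm < bmm || (mm == bmm && std::abs(o) < std::abs(boff))) {
          bmm = mm; boff = o; bidx = mi;
        }
      }
    }
    if (bidx >= 0) {
      best_idx[t] = bidx + 1; best_mm[t] = bmm; best_off[t] = boff;
    }
  }
  return List::create(_["index"] = best_idx, _["mismatches"] = best_mm,
                      _["offset"] = best_off);
}
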