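// Dynamic-programming alignment kernels.
//
// Two routines back the classification and HGT modules:
//  * glocal_profile_align: profile-global / sequence-local affine-gap
//    alignment of a position-specific score matrix against a protein, with
//    traceback (needed to read off the residues sitting in the catalytic
//    triad columns and the covered sequence interval);
//  * pairwise_identity_matrix: global (Needleman-Wunsch, affine) alignment
//    identity over all sequence pairs. Identity is matches over aligned
//    residue pairs, gap columns excluded.
// Scores are simple match/mismatch: the synthetic sequences these run on
// evolve under an equal-exchangeability substitution model, so a BLOSUM-type
// matrix would add nothing but runtime.

#include <Rcpp.h>
#include <vector>
#include <string>
#include <algorithm>
using namespace Rcpp;

static const double NEG = -1e30;

// seq encoded 0..19 (alphabet order supplied by caller), -1 for X/unknown.
// prof: L x 20 score matrix. Unknown residues score 0 in any column.
// [[Rcpp::export(name = ".glocal_profile_align")]]
List glocal_profile_align(NumericMatrix prof, IntegerVector seq,
                          double gap_open, double gap_ext,
                          IntegerVector cat_cols) {
  const int L = prof.nrow();
  const int n = seq.size();
  // reusable DP buffers, (L+1) x (n+1)
  static std::vector<double> M, X, Y;
  static std::vector<signed char> tbM, tbX, tbY;
  const size_t need = (size_t)(L + 1) * (n + 1);
  if (M.size() < need) {
    M.resize(need); X.resize(need); Y.resize(need);
    tbM.resize(need); tbX.resize(need); tbY.resize(need);
  }
  auto at = [n](int i, int j) { return (size_t)i * (n + 1) + j; };
  // flat, column-major copy of the profile for pointer access
  std::vector<double> P((size_t)L * 20);
  for (int c = 0; c < 20; ++c)
    for (int i = 0; i < L; ++i) P[(size_t)c * L + i] = prof(i, c);

  for (int j = 0; j <= n; ++j) {           // free start in sequence
    M[at(0, j)] = 0.0; X[at(0, j)] = NEG; Y[at(0, j)] = NEG;
  }
  for (int i = 1; i <= L; ++i) {
    // profile rows may start with deletions (profile must be consumed)
    double fromM = M[at(i - 1, 0)] - gap_open;
    double fromX = X[at(i - 1, 0)] - gap_ext;
    M[at(i, 0)] = NEG; Y[at(i, 0)] = NEG;
    X[at(i, 0)] = std::max(fromM, fromX);
    tbX[at(i, 0)] = (fromM >= fromX) ? 1 : 2;
    const double *Mp = &M[at(i - 1, 0)], *Xp = &X[at(i - 1, 0)],
                 *Yp = &Y[at(i - 1, 0)];
    double *Mc = &M[at(i, 0)], *Xc = &X[at(i, 0)], *Yc = &Y[at(i, 0)];
    signed char *tMc = &tbM[at(i, 0)], *tXc = &tbX[at(i, 0)],
                *tYc = &tbY[at(i, 0)];
    for (int j = 1; j <= n; ++j) {
      const int a = seq[j - 1];
      const double s = (a < 0) ? 0.0 : P[(size_t)a * L + (i - 1)];
      // M: align profile row i with sequence residue j
      double m1 = Mp[j - 1], m2 = Xp[j - 1], m3 = Yp[j - 1];
      double best = m1; signed char tb = 1;
      if (m2 > best) { best = m2; tb = 2; }
      if (m3 > best) { best = m3; tb = 3; }
      Mc[j] = best + s; tMc[j] = tb;
      // X: profile row i against a gap
      double x1 = Mp[j] - gap_open, x2 = Xp[j] - gap_ext;
      Xc[j] = std::max(x1, x2); tXc[j] = (x1 >= x2) ? 1 : 2;
      // Y: sequence residue j against a gap in the profile
      double y1 = Mc[j - 1] - gap_open, y2 = Yc[j - 1] - gap_ext;
      Yc[j] = std::max(y1, y2); tYc[j] = (y1 >= y2) ? 1 : 3;
    }
  }
  // free end in sequence: best over j of M/X at row L
  double score = NEG; int bj = 0; int bstate = 1;
  for (int j = 0; j <= n; ++j) {
    if (M[at(L, j)] > score) { score = M[at(L, j)]; bj = j; bstate = 1; }
    if (X[at(L, j)] > score) { score = X[at(L, j)]; bj = j; bstate = 2; }
  }
  // traceback: record sequence position aligned to each profile row (0 = gap)
  std::vector<int> rowpos(L + 1, 0);
  int i = L, j = bj, state = bstate;
  int endpos = 0, startpos = 0;
  while (i > 0) {
    if (state == 1) {               // M
      rowpos[i] = j;
      if (endpos == 0) endpos = j;
      startpos = j;
      signed char tb = tbM[at(i, j)];
      --i; --j; state = tb;
    } else if (state == 2) {        // X (gap in sequence)
      signed char tb = tbX[at(i, j)];
      --i; state = tb;
    } else {                        // Y (gap in profile)
      signed char tb = tbY[at(i, j)];
      --j; state = tb;
    }
  }
  IntegerVector catpos(cat_cols.size());
  for (int k = 0; k < cat_cols.size(); ++k) {
    int row = cat_cols[k];          // 1-based profile row
    catpos[k] = (row >= 1 && row <= L) ? rowpos[row] : 0;
  }
  return List::create(_["score"] = score,
                      _["cat_seq_pos"] = catpos,
                      _["start"] = startpos,
                      _["end"] = endpos);
}

struct AlnCounts { int match; int mismatch; };

// Banded global alignment in band storage: cell (i, j) lives at column
// c = j - i + band, so diagonal (match) moves keep c, a gap in b moves to
// c + 1 and a gap in a to c - 1. The band is widened by the length
// difference, which keeps the global end cell inside it.
struct BandedAligner {
  std::vector<double> M, X, Y;
  std::vector<signed char> tbM, tbX, tbY;

  AlnCounts align(const std::string &a, const std::string &b,
                  double match, double mismatch,
                  double gap_open, double gap_ext, int base_band) {
    const int n = (int)a.size(), m = (int)b.size();
    const int band = base_band + std::abs(n - m);
    const int W = 2 * band + 1;
    const size_t need = (size_t)(n + 1) * W;
    if (M.size() < need) {
      M.resize(need); X.resize(need); Y.resize(need);
      tbM.resize(need); tbX.resize(need); tbY.resize(need);
    }
    auto at = [W](int i, int c) { return (size_t)i * W + c; };
    for (int i = 0; i <= n; ++i) {
      int jlo = std::max(0, i - band), jhi = std::min(m, i + band);
      for (int j = jlo; j <= jhi; ++j) {
        const int c = j - i + band;
        const size_t k = at(i, c);
        M[k] = X[k] = Y[k] = NEG;
        if (i == 0 && j == 0) { M[k] = 0.0; continue; }
        if (i > 0) {       // X: a[i-1] against a gap; predecessor (i-1, j)
          const int cp = c + 1;
          if (cp < W && j <= (i - 1) + band) {
            double x1 = M[at(i - 1, cp)] - gap_open;
            double x2 = X[at(i - 1, cp)] - gap_ext;
            X[k] = std::max(x1, x2); tbX[k] = (x1 >= x2) ? 1 : 2;
          }
        }
        if (j > 0) {       // Y: b[j-1] against a gap; predecessor (i, j-1)
          const int cp = c - 1;
          if (cp >= 0) {
            double y1 = M[at(i, cp)] - gap_open;
            double y2 = Y[at(i, cp)] - gap_ext;
            Y[k] = std::max(y1, y2); tbY[k] = (y1 >= y2) ? 1 : 3;
          }
        }
        if (i > 0 && j > 0) {
          const size_t kp = at(i - 1, c);   // (i-1, j-1): same band column
          double s = (a[i - 1] == b[j - 1] && a[i - 1] != 'X')
                         ? match : mismatch;
          double m1 = M[kp], m2 = X[kp], m3 = Y[kp];
          double best = m1; signed char tb = 1;
          if (m2 > best) { best = m2; tb = 2; }
          if (m3 > best) { best = m3; tb = 3; }
          M[k] = best + s; tbM[k] = tb;
        }
      }
    }
    int i = n, c = m - n + band, state = 1;
    double best = M[at(n, c)];
    if (X[at(n, c)] > best) { best = X[at(n, c)]; state = 2; }
    if (Y[at(n, c)] > best) { best = Y[at(n, c)]; state = 3; }
    AlnCounts cnt = {0, 0};
    while (true) {
      const int j = c - band + i;
      if (i == 0 && j == 0) break;
      if (state == 1) {
        if (a[i - 1] == b[j - 1]) cnt.match++; else cnt.mismatch++;
        signed char tb = tbM[at(i, c)]; --i; state = tb;
      } else if (state == 2) {
        signed char tb = tbX[at(i, c)]; --i; ++c; state = tb;
      } else {
        signed char tb = tbY[at(i, c)]; --c; state = tb;
      }
    }
    return cnt;
  }
};

// [[Rcpp::export(name = ".pairwise_identity_matrix")]]
NumericMatrix pairwise_identity_matrix(CharacterVector seqs,
                                       double match = 2.0,
                                       double mismatch = -1.0,
                                       double gap_open = 11.0,
                                       double gap_ext = 1.0,
                                       int band = 16) {
  const int n = seqs.size();
  NumericMatrix out(n, n);
  std::vector<std::string> s(n);
  for (int i = 0; i < n; ++i) s[i] = as<std::string>(seqs[i]);
  BandedAligner al;
  for (int i = 0; i < n; ++i) {
    out(i, i) = 1.0;
    for (int j = 0; j < i; ++j) {
      AlnCounts c = al.align(s[i], s[j], match, mismatch,
                             gap_open, gap_ext, band);
      double id = (c.match + c.mismatch > 0)
                      ? (double)c.match / (c.match + c.mismatch)
                      : 0.0;
      out(i, j) = out(j, i) = id;
    }
  }
  return out;
}
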