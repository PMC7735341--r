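#include <Rcpp.h>
#include <vector>
#include <algorithm>

using namespace Rcpp;

// Unit-cost Levenshtein distance between two integer-encoded symbol
// sequences. Two-row dynamic programme; O(|a|*|b|) time, O(min) space.
static int lev_core(const int* a, int na, const int* b, int nb) {
  if (na == 0) return nb;
  if (nb == 0) return na;
  if (na < nb) { std::swap(a, b); std::swap(na, nb); }
  std::vector<int> prev(nb + 1), cur(nb + 1);
  for (int j = 0; j <= nb; ++j) prev[j] = j;
  for (int i = 1; i <= na; ++i) {
    cur[0] = i;
    const int ai = a[i - 1];
    for (int j = 1; j <= nb; ++j) {
      int sub = prev[j - 1] + (ai == b[j - 1] ? 0 : 1);
      int del = prev[j] + 1;
      int ins = cur[j - 1] + 1;
      cur[j] = std::min(sub, std::min(del, ins));
    }
    std::swap(prev, cur);
  }
  return prev[nb];
}

// [[Rcpp::export]]
int lev_dist_cpp(IntegerVector a, IntegerVector b) {
  return lev_core(INTEGER(a), a.size(), INTEGER(b), b.size());
}

// Pairwise LSI matrix over a list of integer-encoded sequences:
// entry (i, j) = 1 - LD(i, j) / max(len_i, len_j); diagonal 1.
// [[Rcpp::export]]
NumericMatrix lsi_matrix_cpp(List seqs) {
  int n = seqs.size();
  std::vector<IntegerVector> v(n);
  for (int i = 0; i < n; ++i) v[i] = as<IntegerVector>(seqs[i]);
  NumericMatrix out(n, n);
  for (int i = 0; i < n; ++i) {
    out(i, i) = 1.0;
    for (int j = i + 1; j < n; ++j) {
      int na = v[i].size(), nb = v[j].size();
      int m = std::max(na, nb);
      double s = (m == 0) ? 1.0
                          : 1.0 - (double)lev_core(INTEGER(v[i]), na,
                                                   INTEGER(v[j]), nb) / m;
      out(i, j) = s;
      out(j, i) = s;
    }
  }
  return out;
}

static double lsi_pair(const IntegerVector& a, const IntegerVector& b) {
  int na = a.size(), nb = b.size();
  int m = std::max(na, nb);
  if (m == 0) return 1.0;
  return 1.0 - (double)lev_core(INTEGER(a), na, INTEGER(b), nb) / m;
}

// Group-level similarity matrix for one bootstrap replicate.
// groups: list of lists of integer-encoded sequences (shared alphabet);
// idx: per group, 1-based indices of the resampled members.
// target = 0: LSI between per-group median strings (argmax of summed
//             pairwise LSI within the resampled group, first index wins);
// target = 1: mean cross-group pairwise LSI; diagonal 1.
// [[Rcpp::export]]
NumericMatrix group_sim_matrix_cpp(List groups, List idx, int target) {
  int g = groups.size();
  std::vector< std::vector<IntegerVector> > mem(g);
  for (int k = 0; k < g; ++k) {
    List gk = groups[k];
    IntegerVector ik = idx[k];
    mem[k].reserve(ik.size());
    for (int t = 0; t < ik.size(); ++t)
      mem[k].push_back(as<IntegerVector>(gk[ik[t] - 1]));
  }
  NumericMatrix out(g, g);
  if (target == 0) {
    std::vector<IntegerVector> med(g);
    for (int k = 0; k < g; ++k) {
      int n = mem[k].size();
      if (n == 1) { med[k] = mem[k][0]; continue; }
      std::vector<double> score(n, 0.0);
      for (int i = 0; i < n; ++i)
        for (int j = i + 1; j < n; ++j) {
          double s = lsi_pair(mem[k][i], mem[k][j]);
          score[i] += s;
          score[j] += s;
        }
      int best = 0;
      for (int i = 1; i < n; ++i) if (score[i] > score[best]) best = i;
      med[k] = mem[k][best];
    }
    for (int i = 0; i < g; ++i) {
      out(i, i) = 1.0;
      for (int j = i + 1; j < g; ++j) {
        double s = lsi_pair(med[i], med[j]);
        out(i, j) = s;
        out(j, i) = s;
      }
    }
  } else {
    for (int i = 0; i < g; ++i) {
      out(i, i) = 1.0;
      for (int j = i + 1; j < g; ++j) {
        double acc = 0.0;
        int cnt = 0;
        for (size_t a = 0; a < mem[i].size(); ++a)
          for (size_t b = 0; b < mem[j].size(); ++b) {
            acc += lsi_pair(mem[i][a], mem[j][b]);
            ++cnt;
          }
        double s = cnt ? acc / cnt : 0.0;
        out(i, j) = s;
        out(j, i) = s;
      }
    }
  }
  return out;
}

// Cross LSI matrix between two sequence lists (rows = xs, cols = ys).
// [[Rcpp::export]]
NumericMatrix lsi_cross_cpp(List xs, List ys) {
  int nx = xs.size(), ny = ys.size();
  std::vector<IntegerVector> vx(nx), vy(ny);
  for (int i = 0; i < nx; ++i) vx[i] = as<IntegerVector>(xs[i]);
  for (int j = 0; j < ny; ++j) vy[j] = as<IntegerVector>(ys[j]);
  NumericMatrix out(nx, ny);
  for (int i = 0; i < nx; ++i) {
    for (int j = 0; j < ny; ++j) {
      int na = vx[i].size(), nb = vy[j].size();
      int m = std::max(na, nb);
      out(i, j) = (m == 0) ? 1.0
                           : 1.0 - (double)lev_core(INTEGER(vx[i]), na,
                                                    INTEGER(vy[j]), nb) / m;
    }
  }
  return out;
}
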