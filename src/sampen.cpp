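#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <numeric>
using namespace Rcpp;

// Template match counts for sample entropy on a single series.
//
// Convention (Richman & Moorman): templates of length m taken at
// i = 1..L-m so that every m-template extends to an (m+1)-template;
// pairs i < j only (self-matches excluded); Chebyshev distance;
// strict inequality d < r. B counts m-matches, A counts (m+1)-matches,
// so SampEn = -ln(A/B) is a proper conditional probability.
//
// Two exact algorithms produce identical counts:
//  - "direct": all-pairs enumeration, all tolerances binned in one pass
//    (binary search into the sorted r grid); right choice for short
//    series and m >= 2.
//  - "sweep" (m = 1 only): series sorted by value, a two-pointer window
//    bounds |y_i - y_j| < r, and a Fenwick tree over the ranks of the
//    successor values counts extensions; O(n log n) per tolerance, which
//    makes 1e5-point series routine.

namespace {

struct Fenwick {
  std::vector<double> t;
  explicit Fenwick(int n) : t(n + 1, 0.0) {}
  void add(int i) { for (++i; i < (int)t.size(); i += i & (-i)) t[i] += 1.0; }
  void remove(int i) { for (++i; i < (int)t.size(); i += i & (-i)) t[i] -= 1.0; }
  // sum of counts with index < i
  double prefix(int i) const {
    double s = 0.0;
    for (; i > 0; i -= i & (-i)) s += t[i];
    return s;
  }
};

void direct_counts(const double *x, int nt, int m, const std::vector<double> &rs,
                   std::vector<double> &Ah, std::vector<double> &Bh) {
  const int nr = (int)rs.size();
  const double rmax = rs[nr - 1];
  for (int i = 0; i < nt - 1; ++i) {
    for (int j = i + 1; j < nt; ++j) {
      double dm = 0.0;
      for (int k = 0; k < m; ++k) {
        double d = std::fabs(x[i + k] - x[j + k]);
        if (d > dm) dm = d;
        if (dm >= rmax) break;
      }
      if (dm >= rmax) continue;
      int bi = (int)(std::upper_bound(rs.begin(), rs.end(), dm) - rs.begin());
      Bh[bi] += 1.0;
      double d1 = std::fabs(x[i + m] - x[j + m]);
      double dm1 = dm > d1 ? dm : d1;   // dm1 < r implies dm < r
      if (dm1 < rmax) {
        int ai = (int)(std::upper_bound(rs.begin(), rs.end(), dm1) - rs.begin());
        Ah[ai] += 1.0;
      }
    }
  }
  // histogram -> cumulative counts per sorted tolerance
  for (int s = 1; s < nr; ++s) { Ah[s] += Ah[s - 1]; Bh[s] += Bh[s - 1]; }
}

// m = 1: one sweep per tolerance, exact counts.
void sweep_counts_one(const double *x, int nt, double r,
                      double &A, double &B) {
  std::vector<int> ord(nt);
  std::iota(ord.begin(), ord.end(), 0);
  std::sort(ord.begin(), ord.end(),
            [&](int a, int b) { return x[a] < x[b]; });
  // compress successor values x[i + 1]
  std::vector<double> srt(nt);
  for (int i = 0; i < nt; ++i) srt[i] = x[i + 1];
  std::sort(srt.begin(), srt.end());
  Fenwick bit(nt);
  A = 0.0; B = 0.0;
  int l = 0;
  for (int k = 0; k < nt; ++k) {
    int i = ord[k];
    while (x[i] - x[ord[l]] >= r) {
      int q = ord[l];
      int rq = (int)(std::lower_bound(srt.begin(), srt.end(), x[q + 1]) -
                     srt.begin());
      bit.remove(rq);
      ++l;
    }
    B += (double)(k - l);
    double v = x[i + 1];
    int hi = (int)(std::lower_bound(srt.begin(), srt.end(), v + r) -
                   srt.begin());        // values < v + r
    int lo = (int)(std::upper_bound(srt.begin(), srt.end(), v - r) -
                   srt.begin());        // values <= v - r
    A += bit.prefix(hi) - bit.prefix(lo);
    int ri = (int)(std::lower_bound(srt.begin(), srt.end(), v) - srt.begin());
    bit.add(ri);
  }
}

} // namespace

// [[Rcpp::export]]
List sampen_counts(NumericVector y, int m, NumericVector r,
                   std::string method = "auto") {
  const int n = y.size();
  const int nt = n - m;  // number of usable templates
  const int nr = r.size();
  if (m < 1) stop("m must be >= 1");
  if (nt < 2) stop("series too short: need length - m >= 2 template pairs");
  for (int s = 0; s < nr; ++s)
    if (!(r[s] > 0)) stop("all tolerances r must be > 0");
  for (int i = 0; i < n; ++i)
    if (NumericVector::is_na(y[i])) stop("NA in input series");

  std::vector<int> ordr(nr);
  std::iota(ordr.begin(), ordr.end(), 0);
  std::sort(ordr.begin(), ordr.end(),
            [&](int a, int b) { return r[a] < r[b]; });
  std::vector<double> rs(nr);
  for (int s = 0; s < nr; ++s) rs[s] = r[ordr[s]];

  bool use_sweep;
  if (method == "direct") use_sweep = false;
  else if (method == "sweep") {
    if (m != 1) stop("sweep method requires m = 1");
    use_sweep = true;
  } else if (method == "auto") {
    use_sweep = (m == 1 && nt > 1500);
  } else stop("unknown method");

  std::vector<double> As(nr, 0.0), Bs(nr, 0.0);
  const double *x = REAL(y);
  if (use_sweep) {
    for (int s = 0; s < nr; ++s) sweep_counts_one(x, nt, rs[s], As[s], Bs[s]);
  } else {
    direct_counts(x, nt, m, rs, As, Bs);
  }

  NumericVector A(nr), B(nr);
  for (int s = 0; s < nr; ++s) { A[ordr[s]] = As[s]; B[ordr[s]] = Bs[s]; }
  double npairs = (double)nt * (nt - 1) / 2.0;
  return List::create(_["A"] = A, _["B"] = B,
                      _["n_templates"] = nt,
                      _["n_pairs"] = npairs);
}
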