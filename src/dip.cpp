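// Hartigan's dip statistic for unimodality.
//
// The dip of an empirical cdf F_n is the smallest sup-norm distance from F_n
// to any unimodal cdf. A unimodal cdf G (convex up to its mode, concave
// after, with at most one atom at the mode) fits within a band of half-width
// d around F_n iff, for some mode placed at a sample point x_j,
//   * a convex nondecreasing function passes under the upper step corners
//     (x_i, c_{i-1}/n) for i <= j while staying above the lower corners
//     c_i/n for i < j, and
//   * a concave function passes over the lower corners (x_i, c_i/n) for
//     i >= j while staying below the upper corners for i > j,
// where c_i are cumulative tie counts. The mode point itself escapes the
// band through the atom. The minimal feasible 2d on each side equals the
// maximal gap between the step corners and the greatest convex minorant
// (resp. least concave majorant) of the opposite corners, so
//   dip = 1/2 * min_j max(devL(j), devR(j)).
// devL is nondecreasing and devR nonincreasing in j, so the minimising mode
// is found by binary search; each evaluation is a single monotone-chain hull
// pass, giving O(n log n) per dip.

#include <Rcpp.h>
#include <algorithm>
#include <vector>

using namespace Rcpp;

namespace {

// Reusable scratch space so bootstrap loops do not allocate per evaluation.
struct DipWork {
  std::vector<double> ux, lo, hi;
  std::vector<int> hull;
  void reserve(std::size_t n) {
    ux.reserve(n);
    lo.reserve(n);
    hi.reserve(n);
    hull.reserve(n);
  }
};

inline double cross(double ax, double ay, double bx, double by, double cx,
                    double cy) {
  return (bx - ax) * (cy - ay) - (by - ay) * (cx - ax);
}

// Max gap c_i/n - gcm(x_i) over i < j, where the greatest convex minorant is
// taken over the upper corners (x_i, c_{i-1}/n), i <= j. Indices are 0-based
// into the unique-value arrays; j1 is the 1-based mode index.
double dev_left(DipWork& w, int j1) {
  if (j1 <= 1) return 0.0;
  const std::vector<double>& ux = w.ux;
  const std::vector<double>& hi = w.hi;
  std::vector<int>& h = w.hull;
  h.clear();
  for (int i = 0; i < j1; ++i) {
    while (h.size() >= 2 &&
           cross(ux[h[h.size() - 2]], hi[h[h.size() - 2]], ux[h.back()],
                 hi[h.back()], ux[i], hi[i]) <= 0.0)
      h.pop_back();
    h.push_back(i);
  }
  // Walk check points i < j1 - 1 alongside hull segments.
  double dev = 0.0;
  std::size_t seg = 0;
  for (int i = 0; i < j1 - 1; ++i) {
    while (seg + 1 < h.size() && h[seg + 1] < i) ++seg;
    double hv;
    if (seg + 1 >= h.size()) {
      hv = hi[h.back()];
    } else {
      const int a = h[seg], b = h[seg + 1];
      const double dx = ux[b] - ux[a];
      hv = (dx <= 0.0) ? hi[a]
                       : hi[a] + (ux[i] - ux[a]) / dx * (hi[b] - hi[a]);
    }
    const double d = w.lo[i] - hv;
    if (d > dev) dev = d;
  }
  return dev;
}

// Max gap lcm(x_i) - c_{i-1}/n over i > j, least concave majorant over the
// lower corners (x_i, c_i/n), i >= j.
double dev_right(DipWork& w, int j1, int u) {
  if (j1 >= u) return 0.0;
  const std::vector<double>& ux = w.ux;
  const std::vector<double>& lo = w.lo;
  std::vector<int>& h = w.hull;
  h.clear();
  for (int i = j1 - 1; i < u; ++i) {
    while (h.size() >= 2 &&
           cross(ux[h[h.size() - 2]], lo[h[h.size() - 2]], ux[h.back()],
                 lo[h.back()], ux[i], lo[i]) >= 0.0)
      h.pop_back();
    h.push_back(i);
  }
  double dev = 0.0;
  std::size_t seg = 0;
  for (int i = j1; i < u; ++i) {
    while (seg + 1 < h.size() && h[seg + 1] < i) ++seg;
    double hv;
    if (seg + 1 >= h.size()) {
      hv = lo[h.back()];
    } else {
      const int a = h[seg], b = h[seg + 1];
      const double dx = ux[b] - ux[a];
      hv = (dx <= 0.0) ? lo[a]
                       : lo[a] + (ux[i] - ux[a]) / dx * (lo[b] - lo[a]);
    }
    const double d = hv - w.hi[i];
    if (d > dev) dev = d;
  }
  return dev;
}

double dip_sorted(const std::vector<double>& xs, DipWork& w) {
  const std::size_t n = xs.size();
  if (n < 2) return 0.0;

  // Collapse ties: unique values with cumulative counts.
  w.ux.clear();
  w.lo.clear();
  w.hi.clear();
  std::size_t i = 0;
  double prev_cum = 0.0;
  while (i < n) {
    std::size_t k = i;
    while (k + 1 < n && xs[k + 1] == xs[i]) ++k;
    w.ux.push_back(xs[i]);
    w.hi.push_back(prev_cum);
    prev_cum = static_cast<double>(k + 1) / static_cast<double>(n);
    w.lo.push_back(prev_cum);
    i = k + 1;
  }
  const int u = static_cast<int>(w.ux.size());
  if (u < 2) return 0.0;

  // Binary search for the smallest mode index with devL >= devR; devL is
  // nondecreasing and devR nonincreasing in the mode index.
  int loj = 1, hij = u;
  while (loj < hij) {
    const int mid = loj + (hij - loj) / 2;
    if (dev_left(w, mid) >= dev_right(w, mid, u))
      hij = mid;
    else
      loj = mid + 1;
  }
  const int jstar = loj;
  double best = std::max(dev_left(w, jstar), dev_right(w, jstar, u));
  if (jstar > 1) {
    const double alt =
        std::max(dev_left(w, jstar - 1), dev_right(w, jstar - 1, u));
    best = std::min(best, alt);
  }
  return 0.5 * best;
}

}  // namespace

//' @noRd
// [[Rcpp::export(name = ".dip_statistic")]]
double dip_statistic_cpp(NumericVector x) {
  std::vector<double> xs(x.begin(), x.end());
  std::sort(xs.begin(), xs.end());
  DipWork w;
  w.reserve(xs.size());
  return dip_sorted(xs, w);
}

// Bootstrap p-value against the uniform null (the least favourable unimodal
// distribution). Uses R's RNG so set.seed() governs reproducibility.
//' @noRd
// [[Rcpp::export(name = ".dip_pvalue_boot")]]
double dip_pvalue_boot_cpp(double observed, int n, int n_boot) {
  int ge = 0;
  std::vector<double> xs(static_cast<std::size_t>(n));
  DipWork w;
  w.reserve(xs.size());
  for (int b = 0; b < n_boot; ++b) {
    for (int i = 0; i < n; ++i) xs[static_cast<std::size_t>(i)] = unif_rand();
    std::sort(xs.begin(), xs.end());
    if (dip_sorted(xs, w) >= observed) ++ge;
  }
  return (1.0 + ge) / (1.0 + n_boot);
}
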