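#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

// Felzenszwalb & Huttenlocher exact 1D squared distance transform.
// f: input costs, d: output, n: length. Work arrays v (parabola sites)
// and z (boundaries) are caller-allocated. "No source" is encoded as
// the large finite BIG (not IEEE Inf) so the parabola arithmetic stays
// well-defined; callers translate values >= BIG/2 back to Inf.
static const double BIG = 1e15;

static void dt1d(const std::vector<double>& f, std::vector<double>& d,
                 std::vector<int>& v, std::vector<double>& z, int n) {
  const double INF = std::numeric_limits<double>::infinity();
  int k = 0;
  v[0] = 0;
  z[0] = -INF;
  z[1] = INF;
  for (int q = 1; q < n; ++q) {
    double s = ((f[q] + q * (double)q) - (f[v[k]] + v[k] * (double)v[k])) /
               (2.0 * q - 2.0 * v[k]);
    while (s <= z[k]) {
      --k;
      s = ((f[q] + q * (double)q) - (f[v[k]] + v[k] * (double)v[k])) /
          (2.0 * q - 2.0 * v[k]);
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = INF;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    double dq = q - (double)v[k];
    d[q] = dq * dq + f[v[k]];
  }
}

//' @title Squared Euclidean distance transform
//' @description For every pixel, the squared Euclidean distance (in pixel
//'   units) to the nearest TRUE pixel of \code{feature}. Pixels that are
//'   themselves TRUE get 0. If no pixel is TRUE, all entries are Inf.
//' @param feature logical matrix of feature (source) pixels
//' @return numeric matrix of squared distances
//' @keywords internal
// [[Rcpp::export]]
NumericMatrix edt_sq(LogicalMatrix feature) {
  const double INF = std::numeric_limits<double>::infinity();
  int nr = feature.nrow(), nc = feature.ncol();
  NumericMatrix out(nr, nc);
  int nmax = std::max(nr, nc);
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);

  // columns first
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) f[i] = feature(i, j) ? 0.0 : BIG;
    dt1d(f, d, v, z, nr);
    for (int i = 0; i < nr; ++i) out(i, j) = d[i];
  }
  // then rows
  for (int i = 0; i < nr; ++i) {
    for (int j = 0; j < nc; ++j) f[j] = out(i, j);
    dt1d(f, d, v, z, nc);
    for (int j = 0; j < nc; ++j) out(i, j) = d[j] >= BIG / 2 ? INF : d[j];
  }
  return out;
}

//' @title Connected-component labelling
//' @description Labels connected TRUE regions of a logical matrix with
//'   consecutive integers starting at 1 (0 = background), using 4- or
//'   8-connectivity. Deterministic: components are numbered in
//'   column-major scan order of their first pixel.
//' @param mask logical matrix
//' @param connectivity 4 or 8
//' @return integer matrix of component labels
//' @keywords internal
// [[Rcpp::export]]
IntegerMatrix label_components(LogicalMatrix mask, int connectivity = 8) {
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  std::fill(lab.begin(), lab.end(), 0);
  std::vector<int> stack;
  int next = 0;
  const int dx4[4] = {1, -1, 0, 0}, dy4[4] = {0, 0, 1, -1};
  const int dx8[8] = {1, -1, 0, 0, 1, 1, -1, -1},
            dy8[8] = {0, 0, 1, -1, 1, -1, 1, -1};
  const int *dx = connectivity == 4 ? dx4 : dx8;
  const int *dy = connectivity == 4 ? dy4 : dy8;
  int nd = connectivity == 4 ? 4 : 8;
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (!mask(i, j) || lab(i, j)) continue;
      ++next;
      stack.clear();
      stack.push_back(i + j * nr);
      lab(i, j) = next;
      while (!stack.empty()) {
        int p = stack.back();
        stack.pop_back();
        int pi = p % nr, pj = p / nr;
        for (int k = 0; k < nd; ++k) {
          int qi = pi + dx[k], qj = pj + dy[k];
          if (qi < 0 || qi >= nr || qj < 0 || qj >= nc) continue;
          if (mask(qi, qj) && !lab(qi, qj)) {
            lab(qi, qj) = next;
            stack.push_back(qi + qj * nr);
          }
        }
      }
    }
  }
  lab.attr("n") = next;
  return lab;
}
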