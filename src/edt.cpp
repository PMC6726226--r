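#include <Rcpp.h>
#include <vector>
#include <limits>

// Squared Euclidean distance transform of a 3D binary array:
// for each voxel, squared distance to the nearest zero (background) voxel.
// Separable lower-envelope algorithm (Felzenszwalb & Huttenlocher 2012),
// one 1D pass per axis.

static void dt1d(const std::vector<double>& f, std::vector<double>& d) {
  const int n = (int)f.size();
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0;
  z[0] = -std::numeric_limits<double>::infinity();
  z[1] = std::numeric_limits<double>::infinity();
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
    z[k + 1] = std::numeric_limits<double>::infinity();
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    d[q] = (q - v[k]) * (double)(q - v[k]) + f[v[k]];
  }
}

// [[Rcpp::export(name = ".edt_sq_3d")]]
Rcpp::NumericVector edt_sq_3d(Rcpp::LogicalVector mask,
                              Rcpp::IntegerVector dims) {
  const int d1 = dims[0], d2 = dims[1], d3 = dims[2];
  const double INF = 1e18;
  std::vector<double> D((size_t)d1 * d2 * d3);
  for (size_t i = 0; i < D.size(); ++i) D[i] = mask[i] ? INF : 0.0;

  std::vector<double> f, d;
  // axis 1 (fastest)
  f.resize(d1); d.resize(d1);
  for (int k = 0; k < d3; ++k)
    for (int j = 0; j < d2; ++j) {
      size_t base = (size_t)d1 * (j + (size_t)d2 * k);
      for (int i = 0; i < d1; ++i) f[i] = D[base + i];
      dt1d(f, d);
      for (int i = 0; i < d1; ++i) D[base + i] = d[i];
    }
  // axis 2
  f.resize(d2); d.resize(d2);
  for (int k = 0; k < d3; ++k)
    for (int i = 0; i < d1; ++i) {
      for (int j = 0; j < d2; ++j) f[j] = D[i + (size_t)d1 * (j + (size_t)d2 * k)];
      dt1d(f, d);
      for (int j = 0; j < d2; ++j) D[i + (size_t)d1 * (j + (size_t)d2 * k)] = d[j];
    }
  // axis 3
  f.resize(d3); d.resize(d3);
  for (int j = 0; j < d2; ++j)
    for (int i = 0; i < d1; ++i) {
      for (int k = 0; k < d3; ++k) f[k] = D[i + (size_t)d1 * (j + (size_t)d2 * k)];
      dt1d(f, d);
      for (int k = 0; k < d3; ++k) D[i + (size_t)d1 * (j + (size_t)d2 * k)] = d[k];
    }
  Rcpp::NumericVector out(D.size());
  std::copy(D.begin(), D.end(), out.begin());
  out.attr("dim") = dims;
  return out;
}
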