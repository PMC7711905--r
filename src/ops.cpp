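#include <Rcpp.h>
using namespace Rcpp;

// Separable filtering with edge replication: 1D kernel kx along columns
// (x), then ky along rows (y). Kernels are centered (odd length).
// [[Rcpp::export]]
NumericMatrix cpp_sep_filter(const NumericMatrix& m, const NumericVector& kx,
                             const NumericVector& ky) {
  const int h = m.nrow(), w = m.ncol();
  const int nx = kx.size(), ny = ky.size();
  const int rx = (nx - 1) / 2, ry = (ny - 1) / 2;
  NumericMatrix tmp(h, w), out(h, w);
  const double* mp = &m(0, 0);
  double* tp = &tmp(0, 0);
  // x pass: each output column is a kernel-weighted sum of input columns
  for (int c = 0; c < w; ++c) {
    double* tcol = tp + (size_t)c * h;
    for (int i = 0; i < nx; ++i) {
      const double kv = kx[i];
      if (kv == 0.0) continue;
      int cc = c + i - rx;
      if (cc < 0) cc = 0; else if (cc >= w) cc = w - 1;
      const double* mcol = mp + (size_t)cc * h;
      for (int r = 0; r < h; ++r) tcol[r] += kv * mcol[r];
    }
  }
  // y pass: clamp-free in the interior rows
  double* op = &out(0, 0);
  for (int c = 0; c < w; ++c) {
    const double* tcol = tp + (size_t)c * h;
    double* ocol = op + (size_t)c * h;
    for (int i = 0; i < ny; ++i) {
      const double kv = ky[i];
      if (kv == 0.0) continue;
      const int off = i - ry;
      int r0 = std::max(0, -off), r1 = std::min(h, h - off);
      for (int r = 0; r < r0; ++r) ocol[r] += kv * tcol[0];
      const double* src = tcol + off;
      for (int r = r0; r < r1; ++r) ocol[r] += kv * src[r];
      for (int r = r1; r < h; ++r) ocol[r] += kv * tcol[h - 1];
    }
  }
  return out;
}

// Maximum over a (2*radius+1)^2 neighborhood, edge replicated
// (separable two-pass max filter).
// [[Rcpp::export]]
NumericMatrix cpp_neigh_max(const NumericMatrix& m, const int radius) {
  const int h = m.nrow(), w = m.ncol();
  NumericMatrix tmp(h, w), out(h, w);
  const double* mp = &m(0, 0);
  double* tp = &tmp(0, 0);
  for (int c = 0; c < w; ++c) {
    const double* mcol = mp + (size_t)c * h;
    double* tcol = tp + (size_t)c * h;
    for (int r = 0; r < h; ++r) {
      const int a = std::max(0, r - radius), b = std::min(h - 1, r + radius);
      double v = mcol[a];
      for (int rr = a + 1; rr <= b; ++rr) if (mcol[rr] > v) v = mcol[rr];
      tcol[r] = v;
    }
  }
  double* op = &out(0, 0);
  for (int c = 0; c < w; ++c) {
    const int a = std::max(0, c - radius), b = std::min(w - 1, c + radius);
    double* ocol = op + (size_t)c * h;
    const double* first = tp + (size_t)a * h;
    for (int r = 0; r < h; ++r) ocol[r] = first[r];
    for (int cc = a + 1; cc <= b; ++cc) {
      const double* tcol = tp + (size_t)cc * h;
      for (int r = 0; r < h; ++r) if (tcol[r] > ocol[r]) ocol[r] = tcol[r];
    }
  }
  return out;
}

// Bilinear sampling at 0-based (x = col, y = row) locations; zero outside.
// [[Rcpp::export]]
NumericVector cpp_bilinear(const NumericMatrix& px, const NumericVector& sx,
                           const NumericVector& sy) {
  const int h = px.nrow(), w = px.ncol();
  const R_xlen_t n = sx.size();
  NumericVector out(n);
  const double* pp = &px(0, 0);
  for (R_xlen_t i = 0; i < n; ++i) {
    const double x = sx[i], y = sy[i];
    const double fx0 = std::floor(x), fy0 = std::floor(y);
    const int x0 = (int)fx0, y0 = (int)fy0;
    const double ax = x - fx0, ay = y - fy0;
    double v = 0.0;
    const bool x0ok = x0 >= 0 && x0 < w, x1ok = x0 + 1 >= 0 && x0 + 1 < w;
    const bool y0ok = y0 >= 0 && y0 < h, y1ok = y0 + 1 >= 0 && y0 + 1 < h;
    if (x0ok && y0ok) v += pp[(size_t)x0 * h + y0] * (1 - ax) * (1 - ay);
    if (x1ok && y0ok) v += pp[(size_t)(x0 + 1) * h + y0] * ax * (1 - ay);
    if (x0ok && y1ok) v += pp[(size_t)x0 * h + y0 + 1] * (1 - ax) * ay;
    if (x1ok && y1ok) v += pp[(size_t)(x0 + 1) * h + y0 + 1] * ax * ay;
    out[i] = v;
  }
  return out;
}

// Magnitude-weighted orientation-cell histogram accumulation: each pixel
// splits its vote between the two nearest orientation bins. Indices are
// 0-based; returns a vector of length n_cells * nbin, bins fastest.
// [[Rcpp::export]]
NumericVector cpp_cell_hist(const IntegerVector& cell_id,
                            const IntegerVector& b0, const IntegerVector& b1,
                            const NumericVector& w0, const NumericVector& w1,
                            const int n_cells, const int nbin) {
  NumericVector hist(n_cells * nbin);
  double* hp = &hist[0];
  const R_xlen_t n = cell_id.size();
  for (R_xlen_t i = 0; i < n; ++i) {
    const int base = cell_id[i] * nbin;
    hp[base + b0[i]] += w0[i];
    hp[base + b1[i]] += w1[i];
  }
  return hist;
}
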