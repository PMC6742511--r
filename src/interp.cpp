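#include <Rcpp.h>
using namespace Rcpp;

// Bilinear sampling on a matrix M[row, col] at (x = col coord, y = row coord),
// 0-based pixel units. Out-of-bounds samples return 0 with ok = false.
static inline double bilin(const NumericMatrix& M, double x, double y,
                           int H, int W, bool& ok) {
  if (!(x >= 0.0) || !(y >= 0.0) || x > W - 1.0 || y > H - 1.0) {
    ok = false;
    return 0.0;
  }
  ok = true;
  int x0 = (int)std::floor(x);
  int y0 = (int)std::floor(y);
  if (x0 > W - 2) x0 = W - 2;
  if (y0 > H - 2) y0 = H - 2;
  if (x0 < 0) x0 = 0;  // W == 1 case
  if (y0 < 0) y0 = 0;
  int x1 = (W == 1) ? x0 : x0 + 1;
  int y1 = (H == 1) ? y0 : y0 + 1;
  double fx = x - x0, fy = y - y0;
  return (1 - fx) * (1 - fy) * M(y0, x0) + fx * (1 - fy) * M(y0, x1) +
         (1 - fx) * fy * M(y1, x0) + fx * fy * M(y1, x1);
}

// [[Rcpp::export]]
List cpp_bilinear(NumericMatrix M, NumericVector xs, NumericVector ys) {
  int H = M.nrow(), W = M.ncol(), n = xs.size();
  NumericVector out(n);
  LogicalVector valid(n);
  for (int i = 0; i < n; i++) {
    bool ok;
    out[i] = bilin(M, xs[i], ys[i], H, W, ok);
    valid[i] = ok;
  }
  return List::create(_["value"] = out, _["valid"] = valid);
}

// Value and spatial gradient (per pixel unit) of the bilinear interpolant.
// [[Rcpp::export]]
List cpp_bilinear_grad(NumericMatrix M, NumericVector xs, NumericVector ys) {
  int H = M.nrow(), W = M.ncol(), n = xs.size();
  NumericVector val(n), gx(n), gy(n);
  LogicalVector valid(n);
  for (int i = 0; i < n; i++) {
    double x = xs[i], y = ys[i];
    if (!(x >= 0.0) || !(y >= 0.0) || x > W - 1.0 || y > H - 1.0) {
      valid[i] = false;
      val[i] = gx[i] = gy[i] = 0.0;
      continue;
    }
    valid[i] = true;
    int x0 = (int)std::floor(x);
    int y0 = (int)std::floor(y);
    if (x0 > W - 2) x0 = W - 2;
    if (y0 > H - 2) y0 = H - 2;
    if (x0 < 0) x0 = 0;
    if (y0 < 0) y0 = 0;
    int x1 = (W == 1) ? x0 : x0 + 1;
    int y1 = (H == 1) ? y0 : y0 + 1;
    double fx = x - x0, fy = y - y0;
    double m00 = M(y0, x0), m01 = M(y0, x1), m10 = M(y1, x0), m11 = M(y1, x1);
    val[i] = (1 - fx) * (1 - fy) * m00 + fx * (1 - fy) * m01 +
             (1 - fx) * fy * m10 + fx * fy * m11;
    gx[i] = (1 - fy) * (m01 - m00) + fy * (m11 - m10);
    gy[i] = (1 - fx) * (m10 - m00) + fx * (m11 - m01);
  }
  return List::create(_["value"] = val, _["gx"] = gx, _["gy"] = gy,
                      _["valid"] = valid);
}

// For every pixel p (column-major order) and displacement label s, sample
// M at (col_p + dx_px[s], row_p + dy_px[s]). Returns npix x S value matrix
// and out-of-bounds indicator.
// [[Rcpp::export]]
List cpp_warp_matrix(NumericMatrix M, NumericVector dx_px, NumericVector dy_px) {
  int H = M.nrow(), W = M.ncol(), S = dx_px.size();
  int npix = H * W;
  NumericMatrix val(npix, S);
  LogicalMatrix oob(npix, S);
  for (int s = 0; s < S; s++) {
    double dx = dx_px[s], dy = dy_px[s];
    int p = 0;
    for (int c = 0; c < W; c++) {
      for (int r = 0; r < H; r++, p++) {
        bool ok;
        val(p, s) = bilin(M, c + dx, r + dy, H, W, ok);
        oob(p, s) = !ok;
      }
    }
  }
  return List::create(_["value"] = val, _["oob"] = oob);
}

// Separable correlation with a 1-D kernel, replicate boundary handling.
// [[Rcpp::export]]
NumericMatrix cpp_sepconv(NumericMatrix M, NumericVector k) {
  int H = M.nrow(), W = M.ncol(), K = k.size();
  int half = K / 2;
  NumericMatrix tmp(H, W), out(H, W);
  // along rows (y direction)
  for (int c = 0; c < W; c++) {
    for (int r = 0; r < H; r++) {
      double acc = 0.0;
      for (int j = 0; j < K; j++) {
        int rr = r + j - half;
        if (rr < 0) rr = 0;
        if (rr > H - 1) rr = H - 1;
        acc += k[j] * M(rr, c);
      }
      tmp(r, c) = acc;
    }
  }
  // along columns (x direction)
  for (int c = 0; c < W; c++) {
    for (int r = 0; r < H; r++) {
      double acc = 0.0;
      for (int j = 0; j < K; j++) {
        int cc = c + j - half;
        if (cc < 0) cc = 0;
        if (cc > W - 1) cc = W - 1;
        acc += k[j] * tmp(r, cc);
      }
      out(r, c) = acc;
    }
  }
  return out;
}

// Draw one label index (1-based) per row of q (npix x S, possibly a
// subset given by rows) via inverse-CDF with the supplied uniforms.
// Scans label-by-label in column-major order for cache efficiency.
// [[Rcpp::export]]
IntegerVector cpp_sample_labels(NumericMatrix q, IntegerVector rows,
                                NumericVector u) {
  int n = rows.size(), S = q.ncol();
  IntegerVector out(n);
  std::vector<double> acc(n, 0.0);
  std::vector<char> done(n, 0);
  int remaining = n;
  for (int s = 0; s < S && remaining > 0; s++) {
    const double* col = &q(0, s);
    for (int i = 0; i < n; i++) {
      if (done[i]) continue;
      acc[i] += col[rows[i] - 1];
      if (acc[i] >= u[i]) {
        out[i] = s + 1;
        done[i] = 1;
        remaining--;
      }
    }
  }
  for (int i = 0; i < n; i++) if (!done[i]) out[i] = S;
  return out;
}
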