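#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Mean-field fixed-point sweeps for the per-pixel belief q over displacement
// labels. logunary holds, per pixel and label, the sum of the image
// log-likelihood, the -beta1*||Delta||^2 unary prior and any landmark
// log-factor. The pairwise coupling enters through the first and second
// moments of the neighbouring beliefs:
//   E||Delta_s - Delta'||^2 = ||Delta_s||^2 - 2 Delta_s . E[Delta'] + E||Delta'||^2
// so each sweep costs O(npix * S). Pixels are updated in red-black
// (checkerboard) order, Gauss-Seidel style: each pixel's moments are
// refreshed immediately after its update. Internally the npix x S inputs
// are transposed to label-contiguous buffers for cache efficiency.
// [[Rcpp::export]]
List cpp_estep_sweeps(NumericMatrix logunary, NumericMatrix q_init,
                      NumericVector dxs, NumericVector dys,
                      double beta2, int H, int W,
                      int max_inner, double tol) {
  int npix = H * W, S = dxs.size();
  std::vector<double> Lt((size_t)npix * S), qt((size_t)npix * S);
  for (int s = 0; s < S; s++)
    for (int p = 0; p < npix; p++) {
      Lt[(size_t)p * S + s] = logunary(p, s);
      qt[(size_t)p * S + s] = q_init(p, s);
    }
  std::vector<double> d2(S);
  for (int s = 0; s < S; s++) d2[s] = dxs[s] * dxs[s] + dys[s] * dys[s];

  std::vector<double> m1x(npix), m1y(npix), m2(npix), lq(S);
  for (int p = 0; p < npix; p++) {
    double ax = 0.0, ay = 0.0, a2 = 0.0;
    const double* qp = &qt[(size_t)p * S];
    for (int s = 0; s < S; s++) {
      ax += qp[s] * dxs[s];
      ay += qp[s] * dys[s];
      a2 += qp[s] * d2[s];
    }
    m1x[p] = ax; m1y[p] = ay; m2[p] = a2;
  }

  double max_change = R_PosInf;
  int sweep = 0;
  bool converged = false;

  while (sweep < max_inner) {
    sweep++;
    max_change = 0.0;
    for (int parity = 0; parity < 2; parity++) {
      for (int c = 0; c < W; c++) {
        for (int r = (c + parity) % 2; r < H; r += 2) {
          int p = c * H + r;
          double sm1x = 0.0, sm1y = 0.0, sm2 = 0.0;
          int nnb = 0;
          if (r > 0)     { int q0 = p - 1; sm1x += m1x[q0]; sm1y += m1y[q0]; sm2 += m2[q0]; nnb++; }
          if (r < H - 1) { int q0 = p + 1; sm1x += m1x[q0]; sm1y += m1y[q0]; sm2 += m2[q0]; nnb++; }
          if (c > 0)     { int q0 = p - H; sm1x += m1x[q0]; sm1y += m1y[q0]; sm2 += m2[q0]; nnb++; }
          if (c < W - 1) { int q0 = p + H; sm1x += m1x[q0]; sm1y += m1y[q0]; sm2 += m2[q0]; nnb++; }
          const double* Lp = &Lt[(size_t)p * S];
          double* qp = &qt[(size_t)p * S];
          double best = R_NegInf;
          for (int s = 0; s < S; s++) {
            double pairterm = nnb * d2[s] -
              2.0 * (dxs[s] * sm1x + dys[s] * sm1y) + sm2;
            double v = Lp[s] - beta2 * pairterm;
            lq[s] = v;
            if (v > best) best = v;
          }
          double Z = 0.0;
          if (R_FINITE(best)) {
            for (int s = 0; s < S; s++) {
              lq[s] = std::exp(lq[s] - best);
              Z += lq[s];
            }
          }
          double change = 0.0, ax = 0.0, ay = 0.0, a2 = 0.0;
          if (Z <= 0.0 || !R_FINITE(Z)) {
            // total underflow: reset to uniform
            double u = 1.0 / S;
            for (int s = 0; s < S; s++) {
              change += std::fabs(qp[s] - u);
              qp[s] = u;
              ax += u * dxs[s]; ay += u * dys[s]; a2 += u * d2[s];
            }
          } else {
            for (int s = 0; s < S; s++) {
              double qnew = lq[s] / Z;
              change += std::fabs(qp[s] - qnew);
              qp[s] = qnew;
              ax += qnew * dxs[s]; ay += qnew * dys[s]; a2 += qnew * d2[s];
            }
          }
          m1x[p] = ax; m1y[p] = ay; m2[p] = a2;
          if (change > max_change) max_change = change;
        }
      }
    }
    if (max_change < tol) { converged = true; break; }
  }
  NumericMatrix q(npix, S);
  for (int s = 0; s < S; s++)
    for (int p = 0; p < npix; p++) q(p, s) = qt[(size_t)p * S + s];
  return List::create(_["q"] = q, _["n_sweeps"] = sweep,
                      _["max_change"] = max_change,
                      _["converged"] = converged);
}
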