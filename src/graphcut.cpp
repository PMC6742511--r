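#include <Rcpp.h>
#include <vector>
#include <queue>
using namespace Rcpp;

// Dinic max-flow on an explicit residual graph.
struct Dinic {
  int n;
  std::vector<int> to, nxt;
  std::vector<double> cap;
  std::vector<int> head, level, iter;

  void init(int n_) {
    n = n_;
    head.assign(n, -1);
    to.clear(); nxt.clear(); cap.clear();
  }
  void add_edge(int u, int v, double c) {
    to.push_back(v); cap.push_back(c); nxt.push_back(head[u]); head[u] = to.size() - 1;
    to.push_back(u); cap.push_back(0.0); nxt.push_back(head[v]); head[v] = to.size() - 1;
  }
  bool bfs(int s, int t) {
    level.assign(n, -1);
    std::queue<int> q;
    level[s] = 0; q.push(s);
    while (!q.empty()) {
      int u = q.front(); q.pop();
      for (int e = head[u]; e != -1; e = nxt[e]) {
        if (cap[e] > 1e-12 && level[to[e]] < 0) {
          level[to[e]] = level[u] + 1;
          q.push(to[e]);
        }
      }
    }
    return level[t] >= 0;
  }
  double dfs(int u, int t, double f) {
    if (u == t) return f;
    for (int& e = iter[u]; e != -1; e = nxt[e]) {
      int v = to[e];
      if (cap[e] > 1e-12 && level[v] == level[u] + 1) {
        double d = dfs(v, t, std::min(f, cap[e]));
        if (d > 0) {
          cap[e] -= d;
          cap[e ^ 1] += d;
          return d;
        }
      }
    }
    return 0.0;
  }
  double maxflow(int s, int t) {
    double flow = 0.0;
    while (bfs(s, t)) {
      iter = head;
      double f;
      while ((f = dfs(s, t, R_PosInf)) > 0) flow += f;
    }
    return flow;
  }
  // source side of the min cut (reachable in residual graph)
  std::vector<char> min_cut_source_side(int s) {
    std::vector<char> side(n, 0);
    std::queue<int> q;
    side[s] = 1; q.push(s);
    while (!q.empty()) {
      int u = q.front(); q.pop();
      for (int e = head[u]; e != -1; e = nxt[e]) {
        if (cap[e] > 1e-12 && !side[to[e]]) {
          side[to[e]] = 1;
          q.push(to[e]);
        }
      }
    }
    return side;
  }
};

static double labeling_energy_cpp(const NumericMatrix& unary,
                                  const std::vector<int>& lab,
                                  const NumericMatrix& V, int H, int W) {
  double E = 0.0;
  int npix = H * W;
  for (int p = 0; p < npix; p++) E += unary(p, lab[p]);
  for (int c = 0; c < W; c++) {
    for (int r = 0; r < H; r++) {
      int p = c * H + r;
      if (r < H - 1) E += V(lab[p], lab[p + 1]);
      if (c < W - 1) E += V(lab[p], lab[p + H]);
    }
  }
  return E;
}

// Solve one expansion move for label alpha by min-cut on the (truncated)
// binary move energy. Returns the candidate labeling.
static void expansion_move(const NumericMatrix& unary, const NumericMatrix& V,
                           const std::vector<std::pair<int, int> >& edges,
                           const std::vector<int>& lab, int alpha, int npix,
                           Dinic& g, std::vector<double>& th0,
                           std::vector<double>& th1, std::vector<int>& cand) {
  int src = npix, snk = npix + 1;
  for (int p = 0; p < npix; p++) {
    th0[p] = unary(p, lab[p]);
    th1[p] = unary(p, alpha);
  }
  g.init(npix + 2);
  // Binary move energy per edge, with y = 1 meaning "switch to alpha":
  //   E(0,0) = At, E(0,1) = B, E(1,0) = C, E(1,1) = 0,
  // decomposed as At + (C - At) yp + (0 - C) yq + lam [yp = 0, yq = 1]
  // with lam = B + C - At >= 0 after truncating At = min(A, B + C).
  for (size_t e = 0; e < edges.size(); e++) {
    int p = edges[e].first, q = edges[e].second;
    double A = V(lab[p], lab[q]);
    double B = V(lab[p], alpha);
    double C = V(alpha, lab[q]);
    double At = std::min(A, B + C);
    th1[p] += C - At;
    th1[q] += -C;
    double lam = B + C - At;
    if (lam > 0) g.add_edge(p, q, lam);
  }
  for (int p = 0; p < npix; p++) {
    double m = std::min(th0[p], th1[p]);
    double c0 = th0[p] - m, c1 = th1[p] - m;
    if (c0 > 0) g.add_edge(p, snk, c0);  // cut iff y_p = 0 (keep)
    if (c1 > 0) g.add_edge(src, p, c1);  // cut iff y_p = 1 (switch)
  }
  g.maxflow(src, snk);
  std::vector<char> side = g.min_cut_source_side(src);
  for (int p = 0; p < npix; p++)
    cand[p] = side[p] ? lab[p] : alpha;  // sink side: switch to alpha
}

// Alpha-expansion over the displacement label set. unary is npix x S
// (column-major pixels); the pairwise cost between labels a, b is
// beta2 * ||Delta_a - Delta_b||^2 on every 4-neighbour edge. Squared
// Euclidean label distance is a semi-metric, so non-submodular move terms
// are truncated in the move graph; a move is only accepted if it strictly
// lowers the true (untruncated) energy. Labels are visited in fixed order
// until a full cycle yields no accepted move.
// [[Rcpp::export]]
List cpp_alpha_expansion(NumericMatrix unary, int H, int W, double beta2,
                         NumericVector dxs, NumericVector dys,
                         IntegerVector init, int max_cycles) {
  int npix = H * W, S = dxs.size();
  NumericMatrix V(S, S);
  for (int a = 0; a < S; a++)
    for (int b = 0; b < S; b++) {
      double dx = dxs[a] - dxs[b], dy = dys[a] - dys[b];
      V(a, b) = beta2 * (dx * dx + dy * dy);
    }

  std::vector<int> lab(npix);
  for (int p = 0; p < npix; p++) lab[p] = init[p];
  double E = labeling_energy_cpp(unary, lab, V, H, W);
  std::vector<double> trace;
  trace.push_back(E);
  int n_moves = 0;

  // collect grid edges once
  std::vector<std::pair<int, int> > edges;
  edges.reserve(2 * npix);
  for (int c = 0; c < W; c++)
    for (int r = 0; r < H; r++) {
      int p = c * H + r;
      if (r < H - 1) edges.push_back(std::make_pair(p, p + 1));
      if (c < W - 1) edges.push_back(std::make_pair(p, p + H));
    }

  Dinic g;
  std::vector<double> th0(npix), th1(npix);
  std::vector<int> cand(npix);

  bool done = false;
  for (int cycle = 0; cycle < max_cycles && !done; cycle++) {
    bool improved = false;
    for (int alpha = 0; alpha < S; alpha++) {
      expansion_move(unary, V, edges, lab, alpha, npix, g, th0, th1, cand);
      bool any = false;
      for (int p = 0; p < npix; p++)
        if (cand[p] != lab[p]) { any = true; break; }
      if (!any) continue;
      double Ecand = labeling_energy_cpp(unary, cand, V, H, W);
      if (Ecand < E - 1e-12) {
        lab = cand;
        E = Ecand;
        trace.push_back(E);
        n_moves++;
        improved = true;
      }
    }
    // Alpha-beta swap phase (submodular without truncation for squared
    // Euclidean label costs, since V(a,a) + V(b,b) = 0 <= 2 V(a,b));
    // quadratic in S, so only run for small label sets.
    if (S <= 60) {
      for (int a = 0; a < S; a++) {
        for (int b = a + 1; b < S; b++) {
          // collect pixels labeled a or b
          std::vector<int> sub;
          for (int p = 0; p < npix; p++)
            if (lab[p] == a || lab[p] == b) sub.push_back(p);
          if (sub.empty()) continue;
          std::vector<int> subidx(npix, -1);
          for (size_t k = 0; k < sub.size(); k++) subidx[sub[k]] = k;
          int ns = sub.size();
          int ssrc = ns, ssnk = ns + 1;
          g.init(ns + 2);
          std::vector<double> t0v(ns), t1v(ns);  // y=0 -> a, y=1 -> b
          for (int k = 0; k < ns; k++) {
            int p = sub[k];
            t0v[k] = unary(p, a);
            t1v[k] = unary(p, b);
            int r = p % H, c = p / H;
            int nb[4]; int nn = 0;
            if (r > 0) nb[nn++] = p - 1;
            if (r < H - 1) nb[nn++] = p + 1;
            if (c > 0) nb[nn++] = p - H;
            if (c < W - 1) nb[nn++] = p + H;
            for (int j = 0; j < nn; j++) {
              int q = nb[j];
              if (subidx[q] < 0) {  // fixed neighbour
                t0v[k] += V(a, lab[q]);
                t1v[k] += V(b, lab[q]);
              }
            }
          }
          // pair terms between swap pixels: E(0,0)=E(1,1)=0, E(0,1)=E(1,0)=V(a,b)
          double vab = V(a, b);
          if (vab > 0) {
            for (size_t e = 0; e < edges.size(); e++) {
              int p = edges[e].first, q = edges[e].second;
              if (subidx[p] >= 0 && subidx[q] >= 0) {
                // symmetric Potts-like term: split across both cut directions
                g.add_edge(subidx[p], subidx[q], vab);
                g.add_edge(subidx[q], subidx[p], vab);
              }
            }
          }
          for (int k = 0; k < ns; k++) {
            double m = std::min(t0v[k], t1v[k]);
            double c0 = t0v[k] - m, c1 = t1v[k] - m;
            if (c0 > 0) g.add_edge(k, ssnk, c0);  // cut iff y=0 (label a)
            if (c1 > 0) g.add_edge(ssrc, k, c1);  // cut iff y=1 (label b)
          }
          g.maxflow(ssrc, ssnk);
          std::vector<char> side = g.min_cut_source_side(ssrc);
          std::vector<int> cnd(lab);
          for (int k = 0; k < ns; k++) cnd[sub[k]] = side[k] ? a : b;
          double Ec = labeling_energy_cpp(unary, cnd, V, H, W);
          if (Ec < E - 1e-12) {
            lab = cnd;
            E = Ec;
            trace.push_back(E);
            n_moves++;
            improved = true;
          }
        }
      }
    }
    // ICM polish: per-pixel best-label sweeps (strict descent) to clean up
    // residual suboptimality left by the truncated expansion moves
    bool icm_improved = true;
    while (icm_improved) {
      icm_improved = false;
      for (int p = 0; p < npix; p++) {
        int r = p % H, c = p / H;
        int best = lab[p];
        double base = R_PosInf;
        for (int s = 0; s < S; s++) {
          double e = unary(p, s);
          if (r > 0)     e += V(s, lab[p - 1]);
          if (r < H - 1) e += V(s, lab[p + 1]);
          if (c > 0)     e += V(s, lab[p - H]);
          if (c < W - 1) e += V(s, lab[p + H]);
          if (e < base - 1e-12) { base = e; best = s; }
        }
        if (best != lab[p]) {
          lab[p] = best;
          icm_improved = true;
          improved = true;
        }
      }
    }
    double Enew = labeling_energy_cpp(unary, lab, V, H, W);
    if (Enew < E - 1e-12) { E = Enew; trace.push_back(E); }
    if (!improved) done = true;
  }

  IntegerVector out(npix);
  for (int p = 0; p < npix; p++) out[p] = lab[p];
  return List::create(_["labels"] = out, _["energy"] = E,
                      _["trace"] = trace, _["n_moves"] = n_moves);
}

// Single expansion move (for validation): returns the candidate labeling
// (0-based) that minimises the truncated binary move energy.
// [[Rcpp::export]]
IntegerVector cpp_expansion_move(NumericMatrix unary, int H, int W,
                                 double beta2, NumericVector dxs,
                                 NumericVector dys, IntegerVector init,
                                 int alpha) {
  int npix = H * W, S = dxs.size();
  NumericMatrix V(S, S);
  for (int a = 0; a < S; a++)
    for (int b = 0; b < S; b++) {
      double dx = dxs[a] - dxs[b], dy = dys[a] - dys[b];
      V(a, b) = beta2 * (dx * dx + dy * dy);
    }
  std::vector<std::pair<int, int> > edges;
  for (int c = 0; c < W; c++)
    for (int r = 0; r < H; r++) {
      int p = c * H + r;
      if (r < H - 1) edges.push_back(std::make_pair(p, p + 1));
      if (c < W - 1) edges.push_back(std::make_pair(p, p + H));
    }
  std::vector<int> lab(npix);
  for (int p = 0; p < npix; p++) lab[p] = init[p];
  Dinic g;
  std::vector<double> th0(npix), th1(npix);
  std::vector<int> cand(npix);
  expansion_move(unary, V, edges, lab, alpha, npix, g, th0, th1, cand);
  IntegerVector out(npix);
  for (int p = 0; p < npix; p++) out[p] = cand[p];
  return out;
}
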