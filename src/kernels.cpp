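// Hot kernels of the reactive spreading process:
//  - one synchronous stochastic step (reads only the step-start state);
//  - exact and approximate one-step adoption probabilities per node;
//  - the deterministic (expected-value) step and its fixed-point iteration.
//
// The exact adoption backend economises the configuration-by-event sum by a
// dynamic program over per-(layer, sender-state) link categories with
// memoised exact tie-breaking sums; its cost is still exponential in the
// degree and is guarded.  The approximate backend is the closed-form O(m k)
// path.
#include <Rcpp.h>
#include <vector>
#include <map>
#include <cmath>
using namespace Rcpp;

// gammaCube is m x m x L, column-major: g(k, r, a) = gammaCube[k + m*r + m*m*a]

// [[Rcpp::export]]
IntegerVector cpp_stoch_step(IntegerVector state, List nbrs, List lays,
                             NumericVector gammaCube, NumericMatrix delta,
                             IntegerMatrix thetaT, int m) {
  int N = state.size();
  IntegerVector out(N);
  for (int i = 0; i < N; i++) {
    int k = state[i] - 1;
    // spontaneous loaded-dice draw over the full row (diagonal = stay)
    double u = unif_rand(), acc = 0.0;
    int dest = k;
    for (int l = 0; l < m; l++) {
      acc += delta(k, l);
      if (u < acc) { dest = l; break; }
    }
    if (dest != k) { out[i] = dest + 1; continue; }
    // contact mechanism: each link transmits independently; one successful
    // link is chosen uniformly (reservoir sampling)
    IntegerVector nb = nbrs[i];
    IntegerVector la = lays[i];
    int deg = nb.size();
    int cnt = 0, chosen = -1;
    for (int t = 0; t < deg; t++) {
      int r = state[nb[t] - 1] - 1;
      int a = la[t] - 1;
      double g = gammaCube[k + m * r + m * m * a];
      if (g > 0.0 && unif_rand() < g) {
        cnt++;
        if (cnt == 1 || unif_rand() * cnt < 1.0) chosen = r;
      }
    }
    if (cnt > 0) out[i] = thetaT(k, chosen);
    else out[i] = k + 1;
  }
  return out;
}

// Approximated stochastic step: instead of simulating every link event, each
// node samples its next state from the closed-form approximate adoption
// distribution given its neighbors' current states (the no-adoption
// probability stays exact).
// [[Rcpp::export]]
IntegerVector cpp_stoch_step_approx(IntegerVector state, List nbrs, List lays,
                                    NumericVector gammaCube,
                                    NumericMatrix delta,
                                    IntegerMatrix thetaT, int m, int L) {
  int N = state.size();
  IntegerVector out(N);
  std::vector<int> n(m * L);
  for (int i = 0; i < N; i++) {
    int k = state[i] - 1;
    double u = unif_rand(), acc = 0.0;
    int dest = k;
    for (int l = 0; l < m; l++) {
      acc += delta(k, l);
      if (u < acc) { dest = l; break; }
    }
    if (dest != k) { out[i] = dest + 1; continue; }
    IntegerVector nb = nbrs[i];
    IntegerVector la = lays[i];
    int deg = nb.size();
    std::fill(n.begin(), n.end(), 0);
    for (int t = 0; t < deg; t++)
      n[(la[t] - 1) * m + (state[nb[t] - 1] - 1)]++;
    double h = 1.0, tot = 0.0;
    std::vector<double> w(m * L, 0.0);
    for (int a = 0; a < L; a++)
      for (int r = 0; r < m; r++) {
        int c = a * m + r;
        if (n[c] == 0) continue;
        double g = gammaCube[k + m * r + m * m * a];
        if (g <= 0.0) continue;
        h *= std::pow(1.0 - g, (double)n[c]);
        w[c] = n[c] * g / (1.0 - 0.5 * g);
        tot += w[c];
      }
    if (tot <= 0.0) { out[i] = k + 1; continue; }
    double u2 = unif_rand();
    if (u2 < h) { out[i] = k + 1; continue; }
    double accq = h;
    int adopted = k + 1;
    bool found = false;
    for (int a = 0; a < L && !found; a++)
      for (int r = 0; r < m; r++) {
        int c = a * m + r;
        if (w[c] <= 0.0) continue;
        accq += (1.0 - h) * w[c] / tot;
        if (u2 < accq) { adopted = thetaT(k, r); found = true; break; }
      }
    out[i] = adopted;
  }
  return out;
}

// Exact E[s_c / S; S >= 1] sums for one category count vector, enumerated
// over the joint per-category success counts (product of (n_c + 1) terms).
static void exactCategoryQ(const std::vector<int>& n,
                           const std::vector<double>& g,
                           std::vector<double>& qc) {
  int C = (int)n.size();
  qc.assign(C, 0.0);
  std::vector<std::vector<double>> pmf(C);
  for (int c = 0; c < C; c++) {
    pmf[c].assign(n[c] + 1, 0.0);
    for (int s = 0; s <= n[c]; s++)
      pmf[c][s] = ::Rf_dbinom((double)s, (double)n[c], g[c], 0);
  }
  std::vector<int> s(C, 0);
  while (true) {
    int S = 0;
    double p = 1.0;
    for (int c = 0; c < C; c++) { S += s[c]; p *= pmf[c][s[c]]; }
    if (S > 0 && p > 0) {
      for (int c = 0; c < C; c++)
        if (s[c] > 0) qc[c] += p * (double)s[c] / (double)S;
    }
    int c = 0;
    while (c < C && s[c] == n[c]) { s[c] = 0; c++; }
    if (c == C) break;
    s[c]++;
  }
}

// Per-receiver-state context for the exact backend: the active (positive
// success probability) categories, a mixed-radix encoding of their count
// vectors (radix = max degree + 1, shared across nodes), dense DP scratch
// buffers and a memo of the exact tie-breaking sums per encoded count
// vector.
struct ExactCtx {
  std::vector<int> actLayer, actState;
  std::vector<double> actG;
  int C;
  int radix = 0;             // maxDeg + 1; 0 = not yet built
  size_t span;               // radix^C (dense table size)
  std::vector<double> cur, nxt;            // DP buffers over encoded counts
  std::vector<std::vector<double>> memo;   // memo[idx] = q per category
};

static void buildExactCtx(ExactCtx& ctx, int m, int L, const double* gcube,
                          int k, int maxDeg) {
  ctx.actLayer.clear(); ctx.actState.clear(); ctx.actG.clear();
  for (int a = 0; a < L; a++)
    for (int r = 0; r < m; r++) {
      double g = gcube[k + m * r + m * m * a];
      if (g > 0.0) {
        ctx.actLayer.push_back(a);
        ctx.actState.push_back(r);
        ctx.actG.push_back(g);
      }
    }
  ctx.C = (int)ctx.actG.size();
  ctx.radix = maxDeg + 1;
  ctx.span = 1;
  for (int c = 0; c < ctx.C; c++) ctx.span *= (size_t)ctx.radix;
  ctx.cur.assign(ctx.span, 0.0);
  ctx.nxt.assign(ctx.span, 0.0);
  ctx.memo.assign(ctx.span, std::vector<double>());
}

// Exact chosen-transmission distribution for one node and one receiver
// state k: a dense DP over the node's links yields the distribution of
// category count vectors (category = active (layer, sender state) pair),
// each resolved by the memoised exact tie-breaking sum.  Links on
// zero-gamma categories are inert and not tracked.
static void exactNodeState(const std::vector<int>& links,
                           const std::vector<int>& linkLayer,
                           const NumericMatrix& P, int m,
                           int k, double hk,
                           std::vector<double>& q, ExactCtx& ctx) {
  int deg = (int)links.size();
  q.assign(m, 0.0);
  int C = ctx.C;
  if (C == 0 || deg == 0) return;
  if (C == 1) {
    // single transmissible category: the chosen transmission is certain
    q[ctx.actState[0]] = 1.0 - hk;
    return;
  }
  // strides of each category digit in the encoded index
  std::vector<size_t> stride(C);
  size_t s = 1;
  for (int c = 0; c < C; c++) { stride[c] = s; s *= (size_t)ctx.radix; }
  std::fill(ctx.cur.begin(), ctx.cur.end(), 0.0);
  ctx.cur[0] = 1.0;
  size_t hi = 1;   // one past the largest index that can be occupied
  for (int t = 0; t < deg; t++) {
    int j = links[t], a = linkLayer[t];
    size_t fillEnd = hi + stride[C - 1];
    if (fillEnd > ctx.span) fillEnd = ctx.span;
    std::fill(ctx.nxt.begin(), ctx.nxt.begin() + fillEnd, 0.0);
    size_t newHi = hi;
    for (size_t idx = 0; idx < hi; idx++) {
      double w = ctx.cur[idx];
      if (w == 0.0) continue;
      double inert = 1.0;
      for (int c = 0; c < C; c++) {
        if (ctx.actLayer[c] != a) continue;
        double pr = P(j, ctx.actState[c]);
        inert -= pr;
        if (pr <= 0.0) continue;
        size_t nidx = idx + stride[c];
        ctx.nxt[nidx] += w * pr;
        if (nidx + 1 > newHi) newHi = nidx + 1;
      }
      if (inert > 0.0) ctx.nxt[idx] += w * inert;
    }
    ctx.cur.swap(ctx.nxt);
    hi = newHi;
  }
  std::vector<int> cnt(C);
  for (size_t idx = 0; idx < hi; idx++) {
    double w = ctx.cur[idx];
    if (w == 0.0) continue;
    std::vector<double>& qc = ctx.memo[idx];
    if (qc.empty()) {
      size_t rest = idx;
      for (int c = 0; c < C; c++) {
        cnt[c] = (int)(rest % (size_t)ctx.radix);
        rest /= (size_t)ctx.radix;
      }
      exactCategoryQ(cnt, ctx.actG, qc);
      if (qc.empty()) qc.assign(C, 0.0);  // all-zero counts
    }
    for (int c = 0; c < C; c++) q[ctx.actState[c]] += w * qc[c];
  }
}

struct Links {
  std::vector<std::vector<int>> nb;   // 0-based neighbor ids
  std::vector<std::vector<int>> la;   // 0-based layer ids
};

static Links buildLinks(const List& nbrs, const List& lays) {
  int N = nbrs.size();
  Links lk;
  lk.nb.resize(N);
  lk.la.resize(N);
  for (int i = 0; i < N; i++) {
    IntegerVector nb = nbrs[i], la = lays[i];
    lk.nb[i].resize(nb.size());
    lk.la[i].resize(nb.size());
    for (int t = 0; t < nb.size(); t++) {
      lk.nb[i][t] = nb[t] - 1;
      lk.la[i][t] = la[t] - 1;
    }
  }
  return lk;
}

// qhat[i][k][l] (receiver state k adopts l) and h[i][k] for every node i.
static void adoptionAll(const NumericMatrix& P, const Links& lk,
                        const double* gcube, const IntegerMatrix& thetaT,
                        int m, int L, bool exact, double budget,
                        std::vector<double>& qhat, std::vector<double>& h,
                        std::vector<ExactCtx>* ctxs) {
  int N = P.nrow();
  std::fill(qhat.begin(), qhat.end(), 0.0);
  std::vector<double> q(m), u(m);
  if (exact) {
    int maxDeg = 0;
    for (int i = 0; i < N; i++) {
      int deg = (int)lk.nb[i].size();
      if (deg > maxDeg) maxDeg = deg;
      double cost = pow((double)(m * L), (double)deg) * pow(2.0, (double)deg);
      if (cost > budget)
        stop("exact backend needs ~%g elementary terms for a node of degree "
             "%d (budget %g); use the approximate backend", cost, deg, budget);
    }
    for (int k = 0; k < m; k++)
      if ((*ctxs)[k].radix == 0)
        buildExactCtx((*ctxs)[k], m, L, gcube, k, maxDeg);
  }
  for (int i = 0; i < N; i++) {
    int deg = (int)lk.nb[i].size();
    for (int k = 0; k < m; k++) {
      double hk = 1.0;
      for (int t = 0; t < deg; t++) {
        double v = 0.0;
        for (int r = 0; r < m; r++)
          v += gcube[k + m * r + m * m * lk.la[i][t]] * P(lk.nb[i][t], r);
        hk *= (1.0 - v);
      }
      h[i + N * k] = hk;
      if (exact) {
        exactNodeState(lk.nb[i], lk.la[i], P, m, k, hk, q, (*ctxs)[k]);
      } else {
        // one-point-quadrature closed form: u_r = sum over links of
        // gamma[k, r] p_j^r / (1 - v_j / 2), scaled to total 1 - h
        double tot = 0.0;
        for (int r = 0; r < m; r++) u[r] = 0.0;
        for (int t = 0; t < deg; t++) {
          int j = lk.nb[i][t], a = lk.la[i][t];
          double v = 0.0;
          for (int r = 0; r < m; r++)
            v += gcube[k + m * r + m * m * a] * P(j, r);
          double denom = 1.0 - 0.5 * v;
          for (int r = 0; r < m; r++)
            u[r] += gcube[k + m * r + m * m * a] * P(j, r) / denom;
        }
        for (int r = 0; r < m; r++) tot += u[r];
        for (int r = 0; r < m; r++)
          q[r] = tot > 0.0 ? u[r] / tot * (1.0 - hk) : 0.0;
      }
      for (int r = 0; r < m; r++) {
        int l = thetaT(k, r) - 1;
        qhat[i + N * (k + m * l)] += q[r];
      }
    }
  }
}

// One deterministic step: the three-term composition of spontaneous-in,
// contact-in (given no spontaneous move) and stay.
static void composeStep(const NumericMatrix& P, const NumericMatrix& delta,
                        const std::vector<double>& qhat,
                        const std::vector<double>& h, int m,
                        NumericMatrix& out) {
  int N = P.nrow();
  for (int i = 0; i < N; i++) {
    for (int k = 0; k < m; k++) {
      double acc = 0.0;
      for (int l = 0; l < m; l++) {
        if (l != k) acc += P(i, l) * delta(l, k);
        acc += P(i, l) * delta(l, l) * qhat[i + N * (l + m * k)];
      }
      acc += P(i, k) * delta(k, k) * h[i + N * k];
      out(i, k) = acc;
    }
  }
}

// [[Rcpp::export]]
List cpp_adoption_field(NumericMatrix P, List nbrs, List lays,
                        NumericVector gammaCube, IntegerMatrix thetaT,
                        int m, int L, bool exact, double budget) {
  int N = P.nrow();
  Links lk = buildLinks(nbrs, lays);
  std::vector<double> qhat((size_t)N * m * m), h((size_t)N * m);
  std::vector<ExactCtx> ctxs(m);
  adoptionAll(P, lk, REAL(gammaCube), thetaT, m, L, exact, budget,
              qhat, h, &ctxs);
  NumericVector qh(qhat.begin(), qhat.end());
  qh.attr("dim") = IntegerVector::create(N, m, m);
  NumericMatrix hh(N, m);
  std::copy(h.begin(), h.end(), hh.begin());
  return List::create(_["qhat"] = qh, _["h"] = hh);
}

// [[Rcpp::export]]
NumericMatrix cpp_step_field(NumericMatrix P, List nbrs, List lays,
                             NumericVector gammaCube, NumericMatrix delta,
                             IntegerMatrix thetaT, int m, int L,
                             bool exact, double budget) {
  int N = P.nrow();
  Links lk = buildLinks(nbrs, lays);
  std::vector<double> qhat((size_t)N * m * m), h((size_t)N * m);
  std::vector<ExactCtx> ctxs(m);
  adoptionAll(P, lk, REAL(gammaCube), thetaT, m, L, exact, budget,
              qhat, h, &ctxs);
  NumericMatrix out(N, m);
  composeStep(P, delta, qhat, h, m, out);
  return out;
}

// [[Rcpp::export]]
List cpp_iterate_fixed_point(NumericMatrix P0, List nbrs, List lays,
                             NumericVector gammaCube, NumericMatrix delta,
                             IntegerMatrix thetaT, int m, int L,
                             bool exact, double budget,
                             double tol, int maxIter, int histLen) {
  int N = P0.nrow();
  Links lk = buildLinks(nbrs, lays);
  std::vector<double> qhat((size_t)N * m * m), h((size_t)N * m);
  std::vector<ExactCtx> ctxs(m);
  NumericMatrix P = clone(P0), Q(N, m);
  std::vector<double> hist;
  double resid = R_PosInf;
  int it = 0;
  bool converged = false;
  const double* gcube = REAL(gammaCube);
  while (it < maxIter) {
    adoptionAll(P, lk, gcube, thetaT, m, L, exact, budget, qhat, h, &ctxs);
    composeStep(P, delta, qhat, h, m, Q);
    resid = 0.0;
    for (int idx = 0; idx < N * m; idx++) {
      double d = std::fabs(Q[idx] - P[idx]);
      if (d > resid) resid = d;
    }
    std::copy(Q.begin(), Q.end(), P.begin());
    it++;
    hist.push_back(resid);
    if ((int)hist.size() > histLen) hist.erase(hist.begin());
    if (resid < tol) { converged = true; break; }
  }
  return List::create(_["field"] = P, _["iterations"] = it,
                      _["converged"] = converged, _["residual"] = resid,
                      _["residualHistory"] = NumericVector(hist.begin(),
                                                           hist.end()));
}
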