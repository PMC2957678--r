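#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Propensity of one reaction channel under the stochastic (combinatorial)
// counting convention: k*c1*c2 for distinct reactants, k*c*(c-1)/2 for a
// homodimer pair, Hill kinetics read only their regulator.
static inline double propensity(int j, const std::vector<double>& y,
                                const IntegerVector& type, const NumericVector& k,
                                const IntegerVector& r1, const IntegerVector& r2,
                                const IntegerVector& same2,
                                const NumericVector& vmax, const NumericVector& K,
                                const NumericVector& nhill, const NumericVector& basal,
                                const IntegerVector& reg) {
  if (type[j] == 1) {
    double R = y[reg[j] - 1];
    if (R <= 0.0) return basal[j];
    double n = nhill[j];
    double Rn, Kn;
    int ni = (int) n;
    if (n == (double) ni && ni > 0 && ni <= 16) {
      // integer Hill coefficients: repeated multiplication beats pow()
      double r = R / K[j], acc = 1.0;
      for (int q = 0; q < ni; ++q) acc *= r;
      Rn = acc; Kn = 1.0;
    } else {
      Rn = std::pow(R, n); Kn = std::pow(K[j], n);
    }
    return basal[j] + vmax[j] * Rn / (Kn + Rn);
  }
  double a = k[j];
  if (r1[j] > 0) {
    if (same2[j] == 1) {
      double c = y[r1[j] - 1];
      a *= c * (c - 1.0) / 2.0;
    } else {
      a *= y[r1[j] - 1];
      if (r2[j] > 0) a *= y[r2[j] - 1];
    }
  }
  return a > 0.0 ? a : 0.0;
}

// [[Rcpp::export]]
List ssa_core(NumericVector init, List comp, double t_end,
              IntegerVector rec_idx, double grid_dt) {
  const int ns = as<int>(comp["ns"]);
  const int nr = as<int>(comp["nr"]);
  const IntegerVector type = comp["type"];
  const NumericVector k = comp["k"];
  const IntegerVector r1 = comp["r1"], r2 = comp["r2"], same2 = comp["same2"];
  const NumericVector vmax = comp["vmax"], K = comp["K"], nhill = comp["nhill"],
                      basal = comp["basal"];
  const IntegerVector reg = comp["reg"];
  const IntegerVector ch_ptr = comp["ch_ptr"], ch_idx = comp["ch_idx"];
  const NumericVector ch_delta = comp["ch_delta"];
  const IntegerVector dep_ptr = comp["dep_ptr"], dep_idx = comp["dep_idx"];

  std::vector<double> y(init.begin(), init.end());
  const int nrec = rec_idx.size();

  // does reaction j change any recorded species?
  std::vector<bool> recorded(ns, false);
  for (int i = 0; i < nrec; ++i) recorded[rec_idx[i] - 1] = true;
  std::vector<bool> touches(nr, false);
  for (int j = 0; j < nr; ++j)
    for (int q = ch_ptr[j]; q < ch_ptr[j + 1]; ++q)
      if (recorded[ch_idx[q] - 1]) { touches[j] = true; break; }

  std::vector<double> a(nr);
  double A = 0.0;
  for (int j = 0; j < nr; ++j) {
    a[j] = propensity(j, y, type, k, r1, r2, same2, vmax, K, nhill, basal, reg);
    A += a[j];
  }
  // scan channels in (periodically refreshed) descending-propensity order so
  // the linear selection search terminates early for the dominant channels
  std::vector<int> order(nr);
  for (int j = 0; j < nr; ++j) order[j] = j;
  auto reorder = [&]() {
    std::sort(order.begin(), order.end(),
              [&](int p, int q) { return a[p] > a[q]; });
  };
  reorder();

  std::vector<double> out_t;
  std::vector<double> out_s;
  const bool grid = grid_dt > 0.0;
  double next_grid = 0.0;

  auto push_state = [&](double t) {
    out_t.push_back(t);
    for (int i = 0; i < nrec; ++i) out_s.push_back(y[rec_idx[i] - 1]);
  };

  if (!grid) push_state(0.0);

  double t = 0.0;
  long steps = 0;
  RNGScope rng;
  while (true) {
    if (A <= 0.0) {
      // absorbing state: refresh to rule out accumulated round-off
      A = 0.0;
      for (int j = 0; j < nr; ++j) {
        a[j] = propensity(j, y, type, k, r1, r2, same2, vmax, K, nhill, basal, reg);
        A += a[j];
      }
      if (A <= 0.0) break;
    }
    double tau = exp_rand() / A;
    double t_next = t + tau;
    if (grid) {
      while (next_grid <= t_end && next_grid < t_next) {
        push_state(next_grid);
        next_grid += grid_dt;
      }
    }
    if (t_next >= t_end) break;
    t = t_next;

    // select channel proportionally to propensity
    double u = unif_rand() * A;
    double acc = 0.0;
    int j = -1;
    for (int q = 0; q < nr; ++q) {
      int c = order[q];
      acc += a[c];
      if (u <= acc) { j = c; break; }
    }
    if (j < 0) {  // numerical slack: take the last non-zero channel
      for (int q = nr - 1; q >= 0; --q) if (a[q] > 0.0) { j = q; break; }
      if (j < 0) break;
    }

    for (int q = ch_ptr[j]; q < ch_ptr[j + 1]; ++q)
      y[ch_idx[q] - 1] += ch_delta[q];
    for (int q = dep_ptr[j]; q < dep_ptr[j + 1]; ++q) {
      int d = dep_idx[q] - 1;
      A -= a[d];
      a[d] = propensity(d, y, type, k, r1, r2, same2, vmax, K, nhill, basal, reg);
      A += a[d];
    }
    if ((++steps & 0xFFFFF) == 0) {  // periodic exact refresh of the total
      A = 0.0;
      for (int q = 0; q < nr; ++q) A += a[q];
      reorder();
      if (steps % 10485760 == 0) Rcpp::checkUserInterrupt();
    } else if (steps == 4096) {
      reorder();  // early refresh once the transient propensities settle
    }
    if (!grid && touches[j]) push_state(t);
  }

  if (grid) {
    while (next_grid <= t_end) { push_state(next_grid); next_grid += grid_dt; }
    if (out_t.empty()) push_state(0.0);
  }

  const int n = (int) out_t.size();
  NumericMatrix state(n, nrec);
  for (int i = 0; i < n; ++i)
    for (int c = 0; c < nrec; ++c)
      state(i, c) = out_s[(size_t) i * nrec + c];
  return List::create(_["time"] = NumericVector(out_t.begin(), out_t.end()),
                      _["state"] = state);
}

// First index m >= k (1-based) with b[m] true, as doubles with Inf when none:
// the backward scan used by the BLTL checker's until evaluation.
// [[Rcpp::export]]
NumericVector first_true_scan(LogicalVector b) {
  const int n = b.size();
  NumericVector res(n);
  double cur = R_PosInf;
  for (int i = n - 1; i >= 0; --i) {
    if (b[i] == TRUE) cur = i + 1;
    res[i] = cur;
  }
  return res;
}
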