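#include <Rcpp.h>
using namespace Rcpp;

// Simulated-annealing inner loop over single-unit flips, with the
// normal-approximation probability engine evaluated incrementally.
// Mirrors the R objective exactly: same tie tolerances, same degenerate
// variance rule. Uses R's RNG so runs are reproducible under set.seed().

static const double VAR_EPS = 1e-12;
static const double TIE_EPS = 1e-9;

struct Penalty {
  const NumericVector &target, &frw, &ptarget;
  double y, w;
  bool shortfall_norm, pen_step;

  // representation + probability penalty of one feature given its state
  double operator()(int f, double held, double mu, double var) const {
    double t = target[f];
    double pen = 0.0;
    bool met = held >= t - TIE_EPS;
    if (!met) {
      if (pen_step) pen += y * frw[f];
      else if (t > 0) pen += y * frw[f] * std::max(0.0, 1.0 - held / t);
    }
    double P = ptarget[f];
    if (P > 0) {
      double p;
      if (var <= VAR_EPS) {
        p = (mu >= t - TIE_EPS) ? 1.0 : 0.0;
      } else {
        double z = (t - mu) / std::sqrt(var);
        p = 0.5 * std::erfc(z / M_SQRT2);
      }
      double s = P - p;
      if (s > TIE_EPS) pen += w * frw[f] * (shortfall_norm ? s / P : s);
    }
    return pen;
  }
};

// [[Rcpp::export(name = ".anneal_core")]]
List anneal_core(NumericVector cost, IntegerVector status, NumericVector selfv,
                 IntegerVector adj_ptr, IntegerVector adj_idx,
                 NumericVector adj_len,
                 IntegerVector uo_ptr, IntegerVector uo_feat,
                 NumericVector uo_r, NumericVector uo_q,
                 NumericVector target, NumericVector frw, NumericVector ptarget,
                 double blm, double y, double w,
                 bool shortfall_norm, bool pen_step,
                 IntegerVector x0, int iterations, int temp_steps,
                 double t0, double decay) {
  const int n = cost.size();
  const int m = target.size();
  Penalty pen{target, frw, ptarget, y, w, shortfall_norm, pen_step};

  std::vector<int> x(x0.begin(), x0.end());
  std::vector<int> free_units;
  for (int i = 0; i < n; ++i)
    if (status[i] != 2 && status[i] != 3) free_units.push_back(i);
  const int nfree = (int)free_units.size();

  std::vector<double> held(m), mu(m), var(m);
  double cur = 0.0;

  // full recomputation of feature states and the total (drift control)
  auto recompute = [&]() {
    std::fill(held.begin(), held.end(), 0.0);
    std::fill(mu.begin(), mu.end(), 0.0);
    std::fill(var.begin(), var.end(), 0.0);
    double cst = 0.0, blen = 0.0;
    for (int i = 0; i < n; ++i) {
      if (x[i]) {
        cst += cost[i];
        blen += selfv[i];
        for (int k = uo_ptr[i]; k < uo_ptr[i + 1]; ++k) {
          int f = uo_feat[k];
          double r = uo_r[k], q = uo_q[k];
          held[f] += r;
          mu[f] += r * (1.0 - q);
          var[f] += r * r * q * (1.0 - q);
        }
      }
      for (int k = adj_ptr[i]; k < adj_ptr[i + 1]; ++k) {
        int h = adj_idx[k];
        if (h > i && x[i] != x[h]) blen += adj_len[k];
      }
    }
    double p = 0.0;
    for (int f = 0; f < m; ++f) p += pen(f, held[f], mu[f], var[f]);
    cur = cst + blm * blen + p;
  };
  recompute();

  std::vector<int> best_x(x);
  double best = cur;
  double temp = t0;
  int step_len = std::max(1, iterations / std::max(1, temp_steps));

  if (nfree > 0) {
    for (int it = 0; it < iterations; ++it) {
      if (it > 0 && it % step_len == 0) {
        temp *= decay;
        recompute();  // cap accumulated floating drift
      }
      int u = free_units[(int)(unif_rand() * nfree) % nfree];
      int s = 1 - 2 * x[u];

      double delta = s * cost[u];
      double dlen = s * selfv[u];
      for (int k = adj_ptr[u]; k < adj_ptr[u + 1]; ++k) {
        int h = adj_idx[k];
        // edge goes from matched to cut or back
        dlen += adj_len[k] * ((x[u] == x[h]) ? 1.0 : -1.0);
      }
      delta += blm * dlen;

      for (int k = uo_ptr[u]; k < uo_ptr[u + 1]; ++k) {
        int f = uo_feat[k];
        double r = uo_r[k], q = uo_q[k];
        double nh = held[f] + s * r;
        double nm = mu[f] + s * r * (1.0 - q);
        double nv = std::max(0.0, var[f] + s * r * r * q * (1.0 - q));
        delta += pen(f, nh, nm, nv) - pen(f, held[f], mu[f], var[f]);
      }

      bool accept = delta < 0.0;
      if (!accept && temp > 0.0) accept = unif_rand() < std::exp(-delta / temp);
      if (accept) {
        x[u] += s;
        for (int k = uo_ptr[u]; k < uo_ptr[u + 1]; ++k) {
          int f = uo_feat[k];
          double r = uo_r[k], q = uo_q[k];
          held[f] += s * r;
          mu[f] += s * r * (1.0 - q);
          var[f] = std::max(0.0, var[f] + s * r * r * q * (1.0 - q));
        }
        cur += delta;
        if (cur < best - 1e-12) {
          best = cur;
          best_x = x;
        }
      }
    }
  }

  return List::create(_["x"] = IntegerVector(best_x.begin(), best_x.end()),
                      _["total"] = best);
}
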