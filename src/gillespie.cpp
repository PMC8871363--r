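#include <Rcpp.h>
using namespace Rcpp;

// Hill terms of the production propensity.  Activation: k * x^h/(x^h+K^h);
// repression: k_rep * K^h/(x^h+K^h).  h == 2 is the common case and avoids
// pow().
static inline double hill_pow(double x, double h) {
  if (x <= 0.0) return 0.0;
  if (h == 2.0) return x * x;
  if (h == 1.0) return x;
  return std::pow(x, h);
}

struct GrnModel {
  int n;
  IntegerMatrix J;
  NumericMatrix k, krep, Kh, h;   // Kh = K^h, precomputed
  NumericVector decay, basal, prod_cap;
  bool has_ext;
  NumericVector ext_k;            // per-gene driver coupling
  double ext_amp, ext_period, ext_phase, ext_h, ext_Kh;
  std::vector<std::vector<int> > regulators;  // j indices with J[i][j] != 0
  std::vector<std::vector<int> > targets;     // i indices regulated by j

  double driver(double t) const {
    // nonnegative sinusoid, peak = amplitude
    return 0.5 * ext_amp * (1.0 + std::sin(2.0 * M_PI * t / ext_period + ext_phase));
  }

  // production propensity of gene i at state x, time t
  double production(int i, const std::vector<double>& x, double t) const {
    double prop = basal[i];
    bool any = !regulators[i].empty();
    bool drv = has_ext && ext_k[i] > 0.0;
    if (any || drv) {
      double prod = 1.0;
      for (size_t r = 0; r < regulators[i].size(); ++r) {
        int j = regulators[i][r];
        double xh = hill_pow(x[j], h(i, j));
        double den = xh + Kh(i, j);
        if (J(i, j) > 0) {
          prod *= k(i, j) * xh / den;
        } else {
          prod *= krep(i, j) * Kh(i, j) / den;
        }
        if (prod == 0.0) break;
      }
      if (drv) {
        double xh = hill_pow(driver(t), ext_h);
        prod *= ext_k[i] * xh / (xh + ext_Kh);
      }
      prop += std::min(prod, prod_cap[i]);
    }
    return prop;
  }
};

// [[Rcpp::export]]
NumericMatrix gillespie_cpp(IntegerMatrix J, NumericMatrix k, NumericMatrix krep,
                            NumericMatrix h, NumericMatrix K,
                            NumericVector decay, NumericVector basal,
                            NumericVector prod_cap,
                            NumericVector x0, double t_max, double grid_step,
                            bool has_ext, NumericVector ext_k, double ext_amp,
                            double ext_period, double ext_phase, double ext_h,
                            double ext_K, double dt_max) {
  GrnModel mod;
  mod.n = J.nrow();
  mod.J = J; mod.k = k; mod.krep = krep; mod.h = h;
  mod.decay = decay; mod.basal = basal; mod.prod_cap = prod_cap;
  mod.has_ext = has_ext; mod.ext_k = ext_k;
  mod.ext_amp = ext_amp; mod.ext_period = ext_period; mod.ext_phase = ext_phase;
  mod.ext_h = ext_h;
  mod.ext_Kh = hill_pow(ext_K, ext_h);
  int n = mod.n;

  NumericMatrix Kh(n, n);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j)
      Kh(i, j) = hill_pow(K(i, j), h(i, j));
  mod.Kh = Kh;

  mod.regulators.resize(n);
  mod.targets.resize(n);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j)
      if (J(i, j) != 0) {
        mod.regulators[i].push_back(j);
        mod.targets[j].push_back(i);
      }

  int n_grid = (int) std::floor(t_max / grid_step + 1e-9) + 1;
  NumericMatrix out(n, n_grid);

  std::vector<double> x(n), prod(n);
  for (int i = 0; i < n; ++i) x[i] = x0[i];
  for (int i = 0; i < n; ++i) prod[i] = mod.production(i, x, 0.0);

  // with a time-dependent driver the propensities drift between events, so
  // cap the jump and re-evaluate (documented approximation knob)
  bool cap = has_ext && dt_max > 0.0;

  double t = 0.0;
  int g = 0;           // next grid index to fill
  RNGScope rng;

  while (t < t_max) {
    double a_prod = 0.0, a_dec = 0.0;
    for (int i = 0; i < n; ++i) { a_prod += prod[i]; a_dec += mod.decay[i] * x[i]; }
    double a0 = a_prod + a_dec;

    double dt;
    bool fire = true;
    if (a0 <= 0.0) {
      if (!cap) {
        break;  // frozen system: hold state to the end of the grid
      }
      dt = dt_max; fire = false;
    } else {
      dt = -std::log(unif_rand()) / a0;
      if (cap && dt > dt_max) { dt = dt_max; fire = false; }
    }
    double t_new = std::min(t + dt, t_max);

    // zero-order hold: grid points strictly before the jump keep the old state
    while (g < n_grid && g * grid_step < t_new) {
      for (int i = 0; i < n; ++i) out(i, g) = x[i];
      ++g;
    }
    t = t_new;
    if (!fire || t >= t_max) {
      if (cap) for (int i = 0; i < n; ++i) prod[i] = mod.production(i, x, t);
      continue;
    }

    // choose reaction: production channels then decay channels
    double u = unif_rand() * a0;
    int gene = -1; bool is_prod = true;
    double acc = 0.0;
    for (int i = 0; i < n; ++i) {
      acc += prod[i];
      if (u <= acc) { gene = i; break; }
    }
    if (gene < 0) {
      is_prod = false;
      for (int i = 0; i < n; ++i) {
        acc += mod.decay[i] * x[i];
        if (u <= acc) { gene = i; break; }
      }
      if (gene < 0) gene = n - 1;
    }
    x[gene] += is_prod ? 1.0 : -1.0;
    if (x[gene] < 0.0) x[gene] = 0.0;

    if (cap) {
      // driver terms drift with t: refresh everything
      for (int i = 0; i < n; ++i) prod[i] = mod.production(i, x, t);
    } else {
      // only propensities that depend on the changed gene need refreshing
      prod[gene] = mod.production(gene, x, t);
      const std::vector<int>& tg = mod.targets[gene];
      for (size_t r = 0; r < tg.size(); ++r)
        prod[tg[r]] = mod.production(tg[r], x, t);
    }
  }

  // fill any remaining grid points with the final state
  while (g < n_grid) {
    for (int i = 0; i < n; ++i) out(i, g) = x[i];
    ++g;
  }
  return out;
}
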