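#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Model potentials evaluated in compiled code so the Langevin/ABF inner loops
// stay cheap. Forms mirror the R-side constructors exactly; a unit test
// asserts R and C++ evaluations agree.

enum PotForm { FLAT, HARMONIC, DOUBLE_WELL, TWO_CHANNEL, GRID1D };

struct Potential {
  PotForm form;
  int dim;
  // double_well
  double barrier, half_sep, tilt;
  // harmonic
  std::vector<double> kspring, center;
  // two_channel
  double ba, bb, sep, sigma_s, ridge;
  // grid1d
  std::vector<double> xg, Ug;
  // domain (reflecting walls)
  std::vector<double> lo, hi;
};

static Potential parse_potential(const List& pot) {
  Potential p;
  std::string form = as<std::string>(pot["form"]);
  p.dim = as<int>(pot["dim"]);
  List params = pot["params"];
  NumericMatrix dom = pot["domain"];
  for (int d = 0; d < p.dim; ++d) {
    p.lo.push_back(dom(0, d));
    p.hi.push_back(dom(1, d));
  }
  if (form == "flat") {
    p.form = FLAT;
  } else if (form == "harmonic") {
    p.form = HARMONIC;
    NumericVector k = params["k"], c = params["center"];
    p.kspring = std::vector<double>(k.begin(), k.end());
    p.center = std::vector<double>(c.begin(), c.end());
  } else if (form == "double_well") {
    p.form = DOUBLE_WELL;
    p.barrier = as<double>(params["barrier"]);
    p.half_sep = as<double>(params["half_separation"]);
    p.tilt = as<double>(params["tilt"]);
  } else if (form == "two_channel") {
    p.form = TWO_CHANNEL;
    p.ba = as<double>(params["barrier_a"]);
    p.bb = as<double>(params["barrier_b"]);
    p.sep = as<double>(params["channel_sep"]);
    p.sigma_s = as<double>(params["sigma_s"]);
    p.ridge = as<double>(params["ridge"]);
  } else if (form == "custom_grid") {
    p.form = GRID1D;
    NumericVector xg = params["x"], Ug = params["U"];
    p.xg = std::vector<double>(xg.begin(), xg.end());
    p.Ug = std::vector<double>(Ug.begin(), Ug.end());
  } else {
    stop("unknown potential form: " + form);
  }
  return p;
}

static inline double clamp01(double t) {
  return t < 0.0 ? 0.0 : (t > 1.0 ? 1.0 : t);
}

static double pot_energy(const Potential& p, const double* x) {
  switch (p.form) {
  case FLAT:
    return 0.0;
  case HARMONIC: {
    double u = 0.0;
    for (int d = 0; d < p.dim; ++d) {
      double dx = x[d] - p.center[d];
      u += 0.5 * p.kspring[d] * dx * dx;
    }
    return u;
  }
  case DOUBLE_WELL: {
    double r = x[0] / p.half_sep;
    double q = r * r - 1.0;
    return p.barrier * q * q - p.tilt * (x[0] + p.half_sep) / (2.0 * p.half_sep);
  }
  case TWO_CHANNEL: {
    // channel structure (inter-channel ridge + per-channel saddle height)
    // lives under a Gaussian envelope in s, so the start and end basins
    // are common to both channels
    double s = x[0];
    double u = 2.0 * x[1] / p.sep;
    double t = clamp01((u + 1.0) / 2.0);
    double h = t * t * (3.0 - 2.0 * t);
    double A = p.bb + (p.ba - p.bb) * h;
    double q = u * u - 1.0;
    double s2 = s * s, sg2 = p.sigma_s * p.sigma_s;
    double g = std::exp(-s2 * s2 / (2.0 * sg2 * sg2)); // flat-topped envelope
    return (p.ridge * q * q + A) * g;
  }
  case GRID1D: {
    double xv = x[0];
    const std::vector<double>& xg = p.xg;
    size_t n = xg.size();
    if (xv <= xg[0]) return p.Ug[0];
    if (xv >= xg[n - 1]) return p.Ug[n - 1];
    size_t j = std::upper_bound(xg.begin(), xg.end(), xv) - xg.begin();
    double f = (xv - xg[j - 1]) / (xg[j] - xg[j - 1]);
    return p.Ug[j - 1] * (1.0 - f) + p.Ug[j] * f;
  }
  }
  return NA_REAL;
}

static void pot_grad(const Potential& p, const double* x, double* g) {
  switch (p.form) {
  case FLAT:
    for (int d = 0; d < p.dim; ++d) g[d] = 0.0;
    return;
  case HARMONIC:
    for (int d = 0; d < p.dim; ++d) g[d] = p.kspring[d] * (x[d] - p.center[d]);
    return;
  case DOUBLE_WELL: {
    double a = p.half_sep, r = x[0] / a;
    g[0] = 4.0 * p.barrier * r * (r * r - 1.0) / a - p.tilt / (2.0 * a);
    return;
  }
  case TWO_CHANNEL: {
    double s = x[0];
    double u = 2.0 * x[1] / p.sep;
    double t = clamp01((u + 1.0) / 2.0);
    double h = t * t * (3.0 - 2.0 * t);
    double A = p.bb + (p.ba - p.bb) * h;
    double sg2 = p.sigma_s * p.sigma_s;
    double gaus = std::exp(-s * s * s * s / (2.0 * sg2 * sg2));
    double q = u * u - 1.0;
    double core = p.ridge * q * q + A;
    g[0] = core * gaus * (-2.0 * s * s * s / (sg2 * sg2));
    double dhdu = (t <= 0.0 || t >= 1.0) ? 0.0 : 6.0 * t * (1.0 - t) * 0.5;
    double dAdu = (p.ba - p.bb) * dhdu;
    double dUdu = (4.0 * p.ridge * q * u + dAdu) * gaus;
    g[1] = dUdu * 2.0 / p.sep;
    return;
  }
  case GRID1D: {
    double xv = x[0];
    const std::vector<double>& xg = p.xg;
    size_t n = xg.size();
    if (xv <= xg[0] || xv >= xg[n - 1]) { g[0] = 0.0; return; }
    size_t j = std::upper_bound(xg.begin(), xg.end(), xv) - xg.begin();
    g[0] = (p.Ug[j] - p.Ug[j - 1]) / (xg[j] - xg[j - 1]);
    return;
  }
  }
}

static inline double reflect(double x, double lo, double hi) {
  // fold back into [lo, hi]; loop handles overshoot past both walls
  for (int it = 0; it < 64 && (x < lo || x > hi); ++it) {
    if (x < lo) x = 2.0 * lo - x;
    if (x > hi) x = 2.0 * hi - x;
  }
  return x;
}

// [[Rcpp::export]]
NumericVector eval_potential_cpp(List pot, NumericMatrix X) {
  Potential p = parse_potential(pot);
  int n = X.nrow();
  NumericVector out(n);
  std::vector<double> x(p.dim);
  for (int i = 0; i < n; ++i) {
    for (int d = 0; d < p.dim; ++d) x[d] = X(i, d);
    out[i] = pot_energy(p, x.data());
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix grad_potential_cpp(List pot, NumericMatrix X) {
  Potential p = parse_potential(pot);
  int n = X.nrow();
  NumericMatrix out(n, p.dim);
  std::vector<double> x(p.dim), g(p.dim);
  for (int i = 0; i < n; ++i) {
    for (int d = 0; d < p.dim; ++d) x[d] = X(i, d);
    pot_grad(p, x.data(), g.data());
    for (int d = 0; d < p.dim; ++d) out(i, d) = g[d];
  }
  return out;
}

// Euler-Maruyama overdamped Langevin: x <- x - (D/kT) grad(U) dt + sqrt(2 D dt) eta.
// Saves frame 0 and every `thin`-th step. Uses R's RNG (seed set in the wrapper).
// [[Rcpp::export]]
NumericMatrix simulate_langevin_cpp(List pot, NumericVector x0, int n_steps,
                                    double dt, double D, double kT, int thin) {
  Potential p = parse_potential(pot);
  int dim = p.dim;
  int n_save = n_steps / thin + 1;
  NumericMatrix out(n_save, dim);
  std::vector<double> x(x0.begin(), x0.end()), g(dim);
  double mob = D / kT * dt, sig = std::sqrt(2.0 * D * dt);
  for (int d = 0; d < dim; ++d) out(0, d) = x[d];
  int row = 1;
  for (int step = 1; step <= n_steps; ++step) {
    pot_grad(p, x.data(), g.data());
    for (int d = 0; d < dim; ++d) {
      if (!std::isfinite(g[d]))
        stop("non-finite gradient at step %d", step);
      x[d] += -mob * g[d] + sig * norm_rand();
      x[d] = reflect(x[d], p.lo[d], p.hi[d]);
      if (!std::isfinite(x[d]))
        stop("non-finite coordinate at step %d", step);
    }
    if (step % thin == 0) {
      for (int d = 0; d < dim; ++d) out(row, d) = x[d];
      ++row;
    }
  }
  return out;
}

// 1D adaptive biasing force sampler on a model potential.
// Per-bin running mean force M = sum(-U')/n; applied bias force = -ramp * M,
// ramp = min(1, n_bin / full_samples). Harmonic walls outside [lo, hi].
// [[Rcpp::export]]
List run_abf_cpp(List pot, double lo, double hi, int n_bins,
                 int full_samples, double wall_k, double n_samples,
                 double dt, double D, double kT, double x0) {
  Potential p = parse_potential(pot);
  if (p.dim != 1) stop("ABF sampler requires a 1D potential");
  double w = (hi - lo) / n_bins;
  std::vector<double> f_sum(n_bins, 0.0);
  std::vector<double> n_bin(n_bins, 0.0);
  double x = x0, g;
  double mob = D / kT * dt, sig = std::sqrt(2.0 * D * dt);
  double n_outside = 0.0, n_outside_half = 0.0;
  long long N = (long long) n_samples;
  for (long long step = 0; step < N; ++step) {
    pot_grad(p, &x, &g);
    double force = -g;
    double bias = 0.0;
    int b = (int) std::floor((x - lo) / w);
    if (b >= 0 && b < n_bins) {
      f_sum[b] += force;
      n_bin[b] += 1.0;
      double ramp = n_bin[b] < full_samples ? n_bin[b] / full_samples : 1.0;
      bias = -ramp * f_sum[b] / n_bin[b];
    } else {
      n_outside += 1.0;
      if (b < 0) bias = wall_k * (lo - x);
      else bias = -wall_k * (x - hi);
    }
    if (x < lo - 0.5 || x > hi + 0.5) n_outside_half += 1.0;
    x += mob * (force + bias) + sig * norm_rand();
    x = reflect(x, p.lo[0], p.hi[0]);
    if (!std::isfinite(x)) stop("non-finite coordinate at sample %lld", step);
  }
  return List::create(_["f_sum"] = f_sum, _["n_bin"] = n_bin,
                      _["n_outside"] = n_outside,
                      _["n_outside_half"] = n_outside_half);
}

// Discrete Markov chain sampler; states 0-based here, wrapper converts.
// [[Rcpp::export]]
IntegerVector sample_chain_cpp(NumericMatrix T, int n_steps, int start) {
  int k = T.nrow();
  IntegerVector out(n_steps + 1);
  int s = start;
  out[0] = s;
  for (int step = 1; step <= n_steps; ++step) {
    double u = unif_rand(), acc = 0.0;
    int next = k - 1;
    for (int j = 0; j < k; ++j) {
      acc += T(s, j);
      if (u <= acc) { next = j; break; }
    }
    s = next;
    out[step] = s;
  }
  return out;
}

// First-passage sampling: steps to first hit of set B from `start`, n_chains times.
// [[Rcpp::export]]
NumericVector first_passage_cpp(NumericMatrix T, int start, IntegerVector B,
                                int n_chains, int max_steps) {
  int k = T.nrow();
  std::vector<bool> inB(k, false);
  for (int i = 0; i < B.size(); ++i) inB[B[i]] = true;
  NumericVector out(n_chains);
  for (int c = 0; c < n_chains; ++c) {
    int s = start, step = 0;
    while (!inB[s] && step < max_steps) {
      double u = unif_rand(), acc = 0.0;
      int next = k - 1;
      for (int j = 0; j < k; ++j) {
        acc += T(s, j);
        if (u <= acc) { next = j; break; }
      }
      s = next;
      ++step;
    }
    out[c] = inB[s] ? step : NA_REAL;
  }
  return out;
}

// Reversible MLE fixed-point sweeps on symmetric auxiliary variables:
// x_ij <- csym_ij / (c_i/x_i + c_j/x_j), iterated until the max relative
// change drops below tol. Returns x plus convergence metadata.
// [[Rcpp::export]]
List reversible_mle_cpp(NumericMatrix csym, NumericVector ci, double tol,
                        double max_iter) {
  int k = csym.nrow();
  NumericMatrix x(k, k);
  double tot = 0.0;
  for (int i = 0; i < k; ++i)
    for (int j = 0; j < k; ++j) tot += csym(i, j);
  for (int i = 0; i < k; ++i)
    for (int j = 0; j < k; ++j) x(i, j) = csym(i, j) / tot;
  std::vector<double> xi(k);
  double res = R_PosInf;
  long long it = 0, cap = (long long) max_iter;
  while (it < cap) {
    ++it;
    for (int i = 0; i < k; ++i) {
      double s = 0.0;
      for (int j = 0; j < k; ++j) s += x(i, j);
      xi[i] = s;
    }
    res = 0.0;
    for (int i = 0; i < k; ++i) {
      double ri = ci[i] / xi[i];
      for (int j = i; j < k; ++j) {
        if (csym(i, j) == 0.0) continue;
        double xn = csym(i, j) / (ri + ci[j] / xi[j]);
        double rel = std::fabs(xn - x(i, j)) / std::max(x(i, j), 1e-300);
        if (rel > res) res = rel;
        x(i, j) = xn;
        x(j, i) = xn;
      }
    }
    if (res < tol) break;
  }
  return List::create(_["x"] = x, _["iterations"] = (double) it,
                      _["residual"] = res, _["converged"] = res < tol);
}

// Nearest-centre assignment, ties broken by lowest centre index.
// [[Rcpp::export]]
List assign_nearest_cpp(NumericMatrix X, NumericMatrix centers) {
  int n = X.nrow(), k = centers.nrow(), d = X.ncol();
  IntegerVector lab(n);
  NumericVector dist2(n);
  for (int i = 0; i < n; ++i) {
    double best = R_PosInf;
    int besti = 0;
    for (int c = 0; c < k; ++c) {
      double acc = 0.0;
      for (int j = 0; j < d; ++j) {
        double dx = X(i, j) - centers(c, j);
        acc += dx * dx;
      }
      // strict improvement only: ascending loop order makes the lowest
      // centre index win exact ties
      if (acc < best) { best = acc; besti = c; }
    }
    lab[i] = besti + 1;
    dist2[i] = best;
  }
  return List::create(_["labels"] = lab, _["dist2"] = dist2);
}

// Sliding-window transition pair counting for one discrete trajectory.
// [[Rcpp::export]]
NumericMatrix count_pairs_cpp(IntegerVector dtraj, int lag, int n_states) {
  NumericMatrix C(n_states, n_states);
  int n = dtraj.size();
  for (int t = 0; t + lag < n; ++t) {
    int i = dtraj[t] - 1, j = dtraj[t + lag] - 1;
    if (i >= 0 && j >= 0 && i < n_states && j < n_states) C(i, j) += 1.0;
  }
  return C;
}
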