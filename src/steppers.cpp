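#include <Rcpp.h>
using namespace Rcpp;

// Single-locus distorter recursion: wbar p' = (1-c)(p^2 + (1-p)p(t+1)),
// wbar = (1-c)(p^2 + 2p(1-p)) + (1-p)^2.
static inline double step_single(double p, double tv, double cv) {
  double wbar = (1.0 - cv) * (p * p + 2.0 * p * (1.0 - p)) +
                (1.0 - p) * (1.0 - p);
  if (wbar <= 0.0) stop("degenerate population: mean fitness is zero");
  return (1.0 - cv) * (p * p + (1.0 - p) * p * (tv + 1.0)) / wbar;
}

// [[Rcpp::export]]
List cpp_iterate_single(double p0, double tv, double cv, double n_gen,
                        double tol, double max_gen, bool record) {
  double p = p0;
  std::vector<double> series;
  bool converged = false;
  double gen = 0.0;
  if (n_gen > 0.5) {
    R_xlen_t n = (R_xlen_t)n_gen;
    if (record) series.reserve(n);
    for (R_xlen_t i = 0; i < n; ++i) {
      p = step_single(p, tv, cv);
      if (record) series.push_back(p);
    }
    gen = (double)n;
  } else {
    while (gen < max_gen) {
      double pn = step_single(p, tv, cv);
      gen += 1.0;
      if (record) series.push_back(pn);
      if (std::fabs(pn - p) < tol) { p = pn; converged = true; break; }
      p = pn;
    }
  }
  List out = List::create(_["p"] = p, _["generations"] = gen,
                          _["converged"] = converged);
  if (record) out["series"] = NumericVector(series.begin(), series.end());
  return out;
}

// Two-locus distorter-suppressor recursion, gametes (D0S0, D0S1, D1S0, D1S1).
// obligate: constitutive suppressor expression taxes S1 carriers without D1.
static inline void step_two(double *x, double tv, double cv, double cs,
                            bool obligate) {
  double x00 = x[0], x01 = x[1], x10 = x[2], x11 = x[3];
  double h = (1.0 - cs) / 2.0;
  double ob = obligate ? (1.0 - cs) : 1.0;
  double r00 = x00 * x00 + ob * x00 * x01 + (1.0 - tv) * (1.0 - cv) * x00 * x10 +
               h * x00 * x11 + h * x01 * x10;
  double r01 = ob * x00 * x01 + h * x00 * x11 + ob * x01 * x01 +
               h * x01 * x10 + (1.0 - cs) * x01 * x11;
  double r10 = (1.0 + tv) * (1.0 - cv) * x00 * x10 + h * x00 * x11 +
               h * x01 * x10 + (1.0 - cv) * x10 * x10 + (1.0 - cs) * x10 * x11;
  double r11 = h * x00 * x11 + h * x01 * x10 + (1.0 - cs) * x01 * x11 +
               (1.0 - cs) * x10 * x11 + (1.0 - cs) * x11 * x11;
  double w = r00 + r01 + r10 + r11;
  if (w <= 0.0) stop("degenerate population: mean fitness is zero");
  x[0] = r00 / w; x[1] = r01 / w; x[2] = r10 / w; x[3] = r11 / w;
  for (int i = 0; i < 4; ++i) if (x[i] < 0.0) x[i] = 0.0;
}

// Mean individual distortion k * P(carries >= 1 D1 and no S1) under random
// union of gametes.
static inline double mean_distortion(const double *x, double k) {
  // P(individual carries >= 1 D1 and no S1) = P(no S1) - P(no D1 and no S1)
  double noS = x[0] + x[2];
  double p = noS * noS - x[0] * x[0];
  if (p < 0.0) p = 0.0;
  return k * p;
}

// [[Rcpp::export]]
List cpp_iterate_two(NumericVector x0, double tv, double cv, double cs,
                     bool obligate, double tol, double max_gen,
                     double purge_tol, double k, bool record,
                     int record_every, double dist_tol) {
  double x[4] = {x0[0], x0[1], x0[2], x0[3]};
  std::vector<double> series;
  bool converged = false, purged = false;
  double gen = 0.0, peak = 0.0, trough = 1.0;
  if (record_every < 1) record_every = 1;
  long long step_i = 0;
  while (gen < max_gen) {
    double prev[4] = {x[0], x[1], x[2], x[3]};
    step_two(x, tv, cv, cs, obligate);
    gen += 1.0;
    ++step_i;
    double d = -1.0;
    if (record || purge_tol > 0.0 || dist_tol > 0.0) {
      d = mean_distortion(x, k);
      if (d > peak) peak = d;
      if (d < trough) trough = d;
      if (record && (step_i % record_every == 0)) series.push_back(d);
    }
    if (purge_tol > 0.0 && (x[2] + x[3]) < purge_tol) { purged = true; break; }
    if (dist_tol > 0.0 && d >= 0.0 && d < dist_tol) { purged = true; break; }
    if (tol > 0.0) {
      double mc = 0.0;
      for (int i = 0; i < 4; ++i) {
        double d = std::fabs(x[i] - prev[i]);
        if (d > mc) mc = d;
      }
      if (mc < tol) { converged = true; break; }
    }
  }
  List out = List::create(
    _["state"] = NumericVector::create(x[0], x[1], x[2], x[3]),
    _["generations"] = gen, _["converged"] = converged,
    _["purged"] = purged);
  if (record) {
    out["distortion"] = NumericVector(series.begin(), series.end());
    out["peak"] = peak;
    out["trough"] = trough;
  }
  return out;
}
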