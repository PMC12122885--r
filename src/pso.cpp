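// Particle swarm core for penalized sum-of-Gaussians decomposition.
//
// All randomness comes from std::mt19937 with explicit uint32 -> double
// conversion: the engine's output sequence is fixed by the C++ standard,
// so results are bit-reproducible across platforms for a given seed
// (std::uniform_real_distribution would not be).

#include <Rcpp.h>
#include <random>
#include <cmath>
using namespace Rcpp;

static inline double unif01(std::mt19937 &rng) {
  return (static_cast<double>(rng()) + 0.5) / 4294967296.0;
}

static inline double gauss_sum(double t, const double *a, const double *mu,
                               const double *sg, int N) {
  double s = 0.0;
  for (int j = 0; j < N; ++j) {
    double u = (t - mu[j]) / sg[j];
    s += a[j] * std::exp(-0.5 * u * u);
  }
  return s;
}

// [[Rcpp::export]]
NumericVector superpose_eval_cpp(NumericVector t, NumericVector a,
                                 NumericVector mu, NumericVector sigma) {
  const int n = t.size(), N = a.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i)
    out[i] = gauss_sum(t[i], a.begin(), mu.begin(), sigma.begin(), N);
  return out;
}

// Trapezoid of |z - model| over the samples falling inside [t0, t1],
// scaled by max(N,1)^alpha / (t1 - t0). par = (a_1..a_N, mu_1..mu_N,
// sigma_1..sigma_N).
static double fitness_par(const NumericVector &t, const NumericVector &z,
                          int i0, int i1, double dt, double span,
                          const double *par, int N, double alpha) {
  double integral = 0.0;
  double prev = 0.0;
  for (int i = i0; i <= i1; ++i) {
    double r = std::fabs(z[i] - gauss_sum(t[i], par, par + N, par + 2 * N, N));
    if (i > i0) integral += 0.5 * dt * (prev + r);
    prev = r;
  }
  double pen = std::pow(std::max(N, 1), alpha);
  return pen / span * integral;
}

static void window_index(const NumericVector &t, double t0, double t1,
                         int &i0, int &i1) {
  const double eps = 1e-9;
  const int n = t.size();
  i0 = 0;
  while (i0 < n && t[i0] < t0 - eps) ++i0;
  i1 = n - 1;
  while (i1 >= 0 && t[i1] > t1 + eps) --i1;
}

// [[Rcpp::export]]
double fitness_window_cpp(NumericVector t, NumericVector z, double t0,
                          double t1, NumericVector par, double alpha) {
  if (t1 <= t0) stop("empty window: t1 must exceed t0");
  int N = par.size() / 3;
  int i0, i1;
  window_index(t, t0, t1, i0, i1);
  if (i1 <= i0) stop("window contains fewer than two samples");
  double dt = t[1] - t[0];
  return fitness_par(t, z, i0, i1, dt, t1 - t0, par.begin(), N, alpha);
}

// [[Rcpp::export]]
List pso_fit_cpp(NumericVector t, NumericVector z, double t0, double t1,
                 int N, double alpha, NumericVector lower, NumericVector upper,
                 int swarm, int iters, double inertia, double cognitive,
                 double social, int patience, double tol, int seed,
                 Nullable<NumericMatrix> init = R_NilValue) {
  if (t1 <= t0) stop("empty window");
  int i0, i1;
  window_index(t, t0, t1, i0, i1);
  if (i1 <= i0) stop("window contains fewer than two samples");
  const double dt = t[1] - t[0], span = t1 - t0;

  if (N == 0) {
    double f0 = fitness_par(t, z, i0, i1, dt, span, nullptr, 0, alpha);
    return List::create(_["par"] = NumericVector(0), _["fitness"] = f0,
                        _["iterations"] = 0);
  }

  const int D = 3 * N;
  if (lower.size() != D || upper.size() != D) stop("bad bound vectors");
  std::mt19937 rng(static_cast<uint32_t>(seed));

  std::vector<double> x(swarm * D), v(swarm * D, 0.0), pb(swarm * D);
  std::vector<double> pbf(swarm), cur(D);
  std::vector<double> gb(D);
  double gbf = R_PosInf;

  NumericMatrix initm = init.isNotNull() ? NumericMatrix(init)
                                         : NumericMatrix(0, D);
  for (int p = 0; p < swarm; ++p) {
    if (p < initm.nrow() && initm.ncol() == D) {
      for (int d = 0; d < D; ++d) {
        double xi = initm(p, d);
        x[p * D + d] = std::min(std::max(xi, (double)lower[d]),
                                (double)upper[d]);
      }
    } else {
      for (int d = 0; d < D; ++d)
        x[p * D + d] = lower[d] + (upper[d] - lower[d]) * unif01(rng);
    }
    double f = fitness_par(t, z, i0, i1, dt, span, &x[p * D], N, alpha);
    for (int d = 0; d < D; ++d) pb[p * D + d] = x[p * D + d];
    pbf[p] = f;
    if (f < gbf) { gbf = f; std::copy(x.begin() + p * D, x.begin() + (p + 1) * D, gb.begin()); }
  }

  int stall = 0, it = 0;
  for (it = 0; it < iters; ++it) {
    double gbf_before = gbf;
    for (int p = 0; p < swarm; ++p) {
      for (int d = 0; d < D; ++d) {
        double r1 = unif01(rng), r2 = unif01(rng);
        double xi = x[p * D + d];
        double vi = inertia * v[p * D + d] +
                    cognitive * r1 * (pb[p * D + d] - xi) +
                    social * r2 * (gb[d] - xi);
        xi += vi;
        // reflecting bounds with velocity damping
        if (xi < lower[d]) { xi = lower[d] + (lower[d] - xi); vi = -0.5 * vi; }
        if (xi > upper[d]) { xi = upper[d] - (xi - upper[d]); vi = -0.5 * vi; }
        if (xi < lower[d]) xi = lower[d];
        if (xi > upper[d]) xi = upper[d];
        x[p * D + d] = xi;
        v[p * D + d] = vi;
      }
      double f = fitness_par(t, z, i0, i1, dt, span, &x[p * D], N, alpha);
      if (f < pbf[p]) {
        pbf[p] = f;
        std::copy(x.begin() + p * D, x.begin() + (p + 1) * D, pb.begin() + p * D);
        if (f < gbf) { gbf = f; std::copy(x.begin() + p * D, x.begin() + (p + 1) * D, gb.begin()); }
      }
    }
    if (gbf_before - gbf > tol) stall = 0; else ++stall;
    if (stall >= patience) { ++it; break; }
  }

  return List::create(_["par"] = NumericVector(gb.begin(), gb.end()),
                      _["fitness"] = gbf, _["iterations"] = it);
}
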