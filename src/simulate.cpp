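// Closed-loop intermittent-driver simulation: kinematic single-track
// vehicle on an S-track, evidence-accumulating trigger, Gaussian ballistic
// steering corrections with injected response latency. All randomness is
// pre-drawn in R and consumed sequentially, so the loop itself is pure.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// floor-based wrap (std::fmod would pull in a glibc>=2.38 symbol under the
// conda toolchain and fail to load on older system libm)
static inline double wrap_pi(double x) {
  double w = x + M_PI;
  w -= 2.0 * M_PI * std::floor(w / (2.0 * M_PI));
  w -= M_PI;
  if (w <= -M_PI) w = M_PI;
  return w;
}

// nearest-point projection onto the sectioned centerline
// sections: columns s0, len, curv, x0, y0, h0
static void project_pt(const NumericMatrix &sec, double px, double py,
                       double &station, double &lateral, double &heading,
                       double &curvature) {
  double best = R_PosInf;
  const int ns = sec.nrow();
  for (int i = 0; i < ns; ++i) {
    const double s0 = sec(i, 0), L = sec(i, 1), k = sec(i, 2);
    const double X = sec(i, 3), Y = sec(i, 4), H = sec(i, 5);
    double d, s_cl, lat, h_at;
    if (k == 0.0) {
      const double dx = px - X, dy = py - Y;
      const double along = dx * std::cos(H) + dy * std::sin(H);
      lat = -dx * std::sin(H) + dy * std::cos(H);
      s_cl = std::min(std::max(along, 0.0), L);
      const double fx = X + s_cl * std::cos(H), fy = Y + s_cl * std::sin(H);
      d = std::hypot(px - fx, py - fy);
      h_at = H;
    } else {
      const double cx = X - std::sin(H) / k, cy = Y + std::cos(H) / k;
      const double phi0 = std::atan2(Y - cy, X - cx);
      const double phi = std::atan2(py - cy, px - cx);
      double dphi = phi - phi0;
      dphi -= 2.0 * M_PI * std::floor(dphi / (2.0 * M_PI));
      double s_raw = (k > 0) ? dphi / k : (dphi - 2.0 * M_PI) / k;
      s_cl = std::min(std::max(s_raw, 0.0), L);
      h_at = H + k * s_cl;
      const double fx = cx + std::sin(h_at) / k, fy = cy - std::cos(h_at) / k;
      if (s_raw >= 0 && s_raw <= L) {
        const double dq = std::hypot(px - cx, py - cy);
        lat = (k > 0) ? (1.0 / k - dq) : (dq + 1.0 / k);
        d = std::fabs(lat);
      } else {
        const double dxe = px - fx, dye = py - fy;
        lat = -dxe * std::sin(h_at) + dye * std::cos(h_at);
        d = std::hypot(dxe, dye);
      }
    }
    if (d < best - 1e-12) {
      best = d; station = s0 + s_cl; lateral = lat; heading = h_at;
      curvature = k;
    }
  }
}

static double curvature_at(const NumericMatrix &sec, double s) {
  const int ns = sec.nrow();
  for (int i = 0; i < ns; ++i) {
    if (s < sec(i, 0) + sec(i, 1)) return sec(i, 2);
  }
  return sec(ns - 1, 2);
}

// [[Rcpp::export]]
List simulate_loop_cpp(NumericMatrix sections, double lane_offset,
                       double total_length, double speed, double dt,
                       double wheelbase, double steer_ratio,
                       double w_heading, double w_lateral, double w_rate,
                       double evidence_gain, double leak, double threshold,
                       double amplitude_gain, double tau_d,
                       double refractory, double preview,
                       double road_preview,
                       NumericVector sigma_draws, NumericVector noise,
                       double start_x, double start_y, double start_h,
                       int max_steps) {
  const int max_corr = sigma_draws.size();
  std::vector<double> ca, cmu, csig, ctrig, cerr;
  ca.reserve(256); cmu.reserve(256); csig.reserve(256);
  ctrig.reserve(256); cerr.reserve(256);

  NumericMatrix states(max_steps, 11);
  double x = start_x, y = start_y, psi = start_h;
  double delta = 0.0, E = 0.0, t = 0.0, last_trig = -1e9;
  bool truncated = false;
  int n = 0;
  const double sq2pi = std::sqrt(2.0 * M_PI);

  for (int i = 0; i < max_steps; ++i) {
    double station, lateral, h_road, k_road;
    project_pt(sections, x, y, station, lateral, h_road, k_road);
    const double theta_h = wrap_pi(h_road - psi);
    const double y_l = lane_offset - lateral;
    const double yaw = speed / wheelbase * std::tan(delta / steer_ratio);

    // internal forward model (efference copy): the driver knows the travel
    // still to come from corrections already scheduled/in flight and
    // predicts the heading state a short preview ahead, so errors that
    // in-flight movements will fix are not re-responded to
    double pending = 0.0;
    for (size_t j = 0; j < ca.size(); ++j) {
      pending += ca[j] * csig[j] * sq2pi * 0.5 *
                 std::erfc((t - cmu[j]) / (csig[j] * M_SQRT2));
    }
    const double delta_fin = delta + pending;
    const double yaw_fin = speed / wheelbase * std::tan(delta_fin / steer_ratio);
    // the driver aims for the curvature of the road a look-ahead distance
    // up the lane (gaze headway), not the curvature under the wheels
    const double k_ahead = curvature_at(sections,
                                        station + speed * road_preview);
    const double thdot_pred = speed * k_ahead - yaw_fin;
    const double th_pred = theta_h + preview * thdot_pred;
    const double yl_pred = y_l + preview * speed * std::sin(theta_h);
    // flow-angle proxy term (~ d(theta_h)/dt) gives anticipatory damping
    const double e = w_heading * th_pred + w_lateral * yl_pred +
                     w_rate * thdot_pred;

    E = E * (1.0 - leak * dt) + e * evidence_gain * dt;
    if (std::fabs(E) >= threshold && t - last_trig >= refractory &&
        (int)ca.size() < max_corr) {
      const double sg = sigma_draws[ca.size()];
      const double a = amplitude_gain * e / (sg * sq2pi);
      ca.push_back(a);
      cmu.push_back(t + tau_d + 2.0 * sg);
      csig.push_back(sg);
      ctrig.push_back(t);
      cerr.push_back(e);
      E = 0.0;
      last_trig = t;
    }

    double rate = (i < noise.size()) ? noise[i] : 0.0;
    for (size_t j = 0; j < ca.size(); ++j) {
      const double u = (t - cmu[j]) / csig[j];
      rate += ca[j] * std::exp(-0.5 * u * u);
    }

    states(n, 0) = t;       states(n, 1) = x;      states(n, 2) = y;
    states(n, 3) = psi;     states(n, 4) = delta;  states(n, 5) = rate;
    states(n, 6) = theta_h; states(n, 7) = y_l;    states(n, 8) = yaw;
    states(n, 9) = e;       states(n, 10) = station;
    ++n;

    delta += rate * dt;
    psi += yaw * dt;
    x += speed * std::cos(psi) * dt;
    y += speed * std::sin(psi) * dt;
    t += dt;

    if (station >= total_length - 0.5) break;
    if (std::fabs(y_l) > 30.0) { truncated = true; break; }
  }

  return List::create(
    _["states"] = states(Range(0, std::max(n - 1, 0)), _),
    _["n"] = n,
    _["a"] = NumericVector(ca.begin(), ca.end()),
    _["mu"] = NumericVector(cmu.begin(), cmu.end()),
    _["sigma"] = NumericVector(csig.begin(), csig.end()),
    _["t_trigger"] = NumericVector(ctrig.begin(), ctrig.end()),
    _["error"] = NumericVector(cerr.begin(), cerr.end()),
    _["truncated"] = truncated);
}
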