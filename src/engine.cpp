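#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Finite-horizon minimum-jerk feedback jerk for one axis.
static inline double mj_jerk(double x, double v, double a, double xf,
                             double delta) {
  double d2 = delta * delta, d3 = d2 * delta;
  return -60.0 / d3 * (x - xf) - 36.0 / d2 * v - 9.0 / delta * a;
}

static inline double binary_certainty(double p) {
  const double eps = 1e-12;
  if (p < eps) p = eps;
  if (p > 1.0 - eps) p = 1.0 - eps;
  double h = -(p * std::log(p) + (1.0 - p) * std::log(1.0 - p));
  double c = 1.0 - h / std::log(2.0);
  if (c < 0.0) c = 0.0;
  if (c > 1.0) c = 1.0;
  return c;
}

// Run one trial of the certainty-weighted minimum-jerk model in the
// correct-side-positive frame. Evidence samples are pre-drawn in R (one per
// R_ms interval from stimulus onset); the engine applies the EMA filter and
// updates the flat-prior Gaussian belief at sample times. The controller
// clock runs from stimulus onset over the whole movement horizon tf_s:
// before the first sample certainty is zero and the effector is still, so
// early ticks produce the pre-lift-off micro-motion the displacement-onset
// RT is built on. With a positive threshold, motor updates are blocked
// until the magnitude of the running sum of EMA samples reaches the
// threshold (a vanishing threshold is continuous with the threshold-free
// model: motion is gated by evidence alone either way); a gate never
// crossed within tf_s leaves the trial at rest, flagged.
//
// Returns the per-tick trajectory from onset, the displacement-onset time
// (first tick where the cumulative 2-D path length reaches rt_disp_cm),
// and the 101-point time normalization of the lift-off window
// [onset, tf] -- the span a motion-capture recording of the reach covers.
// [[Rcpp::export]]
List cpp_run_trial(NumericVector samples, double R_ms, double D, double W,
                   double threshold, bool satisficing, int dist_mode,
                   double tf_s, double dt, double x_f, double start_depth,
                   double delta_min, double rt_disp_cm = 0.028) {
  int n_steps = (int)std::llround(tf_s / dt);
  double dt_ms = dt * 1000.0;
  int n_avail = samples.size();

  NumericVector x(n_steps + 1), depth(n_steps + 1);
  int max_s = n_avail;
  NumericVector e_bar_s(max_s), p_s(max_s), cert_s(max_s), gate_sum_s(max_s);

  double hx = 0, hv = 0, ha = 0, zx = 0, zv = 0, za = 0;
  double ema = 0, sum_ema = 0, gate_sum = 0;
  int n = 0;
  bool gate_open = threshold <= 0.0;
  int gate_ms = 0;
  double next_sample_ms = R_ms;
  double p = 0.5, certainty = 0.0, target = x_f;
  double cum_disp = 0.0;
  int onset_tick = -1;

  x[0] = 0.0;
  depth[0] = start_depth;

  for (int k = 1; k <= n_steps; ++k) {
    double t = (k - 1) * dt;  // time since onset at tick start

    while (n < n_avail && (k - 1) * dt_ms + 1e-6 >= next_sample_ms) {
      double s = samples[n];
      if (n == 0) ema = s;  // EMA(0) = s(1)
      ema = D * s + (1.0 - D) * ema;
      ++n;
      sum_ema += ema;
      gate_sum += ema;
      double e_bar = sum_ema / n;
      p = R::pnorm(e_bar * std::sqrt((double)n / W), 0.0, 1.0, 1, 0);
      certainty = binary_certainty(p);
      e_bar_s[n - 1] = e_bar;
      p_s[n - 1] = p;
      cert_s[n - 1] = certainty;
      gate_sum_s[n - 1] = gate_sum;
      if (!gate_open && std::fabs(gate_sum) >= threshold) {
        gate_open = true;
        gate_ms = (int)std::llround(n * R_ms);
      }
      next_sample_ms += R_ms;
    }

    double w = 0.0;
    if (n > 0 && gate_open) {
      target = (p >= 0.5) ? x_f : -x_f;
      w = certainty;
      if (satisficing) {
        // dist_mode 0: normalized depth distance to the screen;
        // dist_mode 1: remaining movement-time fraction as a proxy
        double dist = (dist_mode == 0) ? (start_depth - zx) / start_depth
                                       : 1.0 - t / tf_s;
        if (dist < 0.0) dist = 0.0;
        if (dist > 1.0) dist = 1.0;
        w = (dist == 0.0) ? 1.0 : std::pow(certainty, dist);
      }
    }

    if (w > 0.0) {
      double delta = tf_s - t;
      if (delta < delta_min) delta = delta_min;
      double hj = mj_jerk(hx, hv, ha, target, delta);
      double zj = mj_jerk(zx, zv, za, start_depth, delta);
      double hx0 = hx, zx0 = zx;
      hx += w * hv * dt; hv += w * ha * dt; ha += w * hj * dt;
      zx += w * zv * dt; zv += w * za * dt; za += w * zj * dt;
      cum_disp += std::sqrt((hx - hx0) * (hx - hx0) +
                            (zx - zx0) * (zx - zx0));
      if (onset_tick < 0 && cum_disp >= rt_disp_cm - 1e-12) onset_tick = k;
    }
    x[k] = hx;
    depth[k] = start_depth - zx;
  }

  // 101-point time normalizations (linear interpolation on the uniform
  // grid): the full trial span from stimulus onset, and the lift-off
  // window from the displacement-onset tick (undefined if the effector
  // never reached the criterion)
  NumericVector norm101(101), norm101_lift(101, NA_REAL);
  for (int j = 0; j <= 100; ++j) {
    double pos = j * (double)n_steps / 100.0;
    int lo = (int)std::floor(pos);
    double frac = pos - lo;
    norm101[j] = (lo >= n_steps) ? x[n_steps]
                                 : x[lo] * (1.0 - frac) + x[lo + 1] * frac;
  }
  if (onset_tick >= 0 && onset_tick < n_steps) {
    int w0 = onset_tick;
    int m = n_steps - w0;
    for (int j = 0; j <= 100; ++j) {
      double pos = w0 + j * (double)m / 100.0;
      int lo = (int)std::floor(pos);
      double frac = pos - lo;
      norm101_lift[j] = (lo >= n_steps) ? x[n_steps]
                                        : x[lo] * (1.0 - frac) + x[lo + 1] * frac;
    }
  }

  return List::create(
    _["x"] = x, _["depth"] = depth,
    _["n_samples"] = n,
    _["norm101"] = norm101,
    _["norm101_liftoff"] = norm101_lift,
    _["onset_ms"] = (onset_tick < 0) ? NA_INTEGER
                                     : (int)std::llround(onset_tick * dt * 1000.0),
    _["gate_open"] = gate_open,
    _["gate_ms"] = gate_open ? gate_ms : NA_INTEGER,
    _["e_bar"] = head(e_bar_s, n), _["p_correct"] = head(p_s, n),
    _["certainty"] = head(cert_s, n), _["gate_sum"] = head(gate_sum_s, n));
}

// Traditional collapsing-bound accumulator with post-decision motor
// positioning. Samples (one per ms, correct-side-positive, pre-drawn in R)
// accumulate until |sum| crosses thr / (1 + t)^k; the controller then moves
// toward the crossing side for tf_s seconds, weighted by the certainty of
// the two-hypothesis posterior (which keeps updating as sampling continues
// in flight). Optional second threshold flips the target in flight; an
// optional deadline stops in-flight accumulation and locks the target with
// the highest posterior.
// [[Rcpp::export]]
List cpp_run_ddm(NumericVector samples, double thr, double k_collapse,
                 bool t_in_seconds, double dft_drift, double sig2,
                 double tf_s, double dt, double x_f, double start_depth,
                 double delta_min, int max_decision_ms, double second_thr,
                 double deadline_ms) {
  int n_avail = samples.size();
  double cum = 0.0;
  int cross_ms = -1;
  int side = 0;
  int m = 0;

  while (m < max_decision_ms && m < n_avail) {
    cum += samples[m];
    ++m;
    double tcol = t_in_seconds ? (m / 1000.0) : (double)m;
    double bound = thr / std::pow(1.0 + tcol, k_collapse);
    if (std::fabs(cum) >= bound) {
      cross_ms = m;
      side = (cum >= 0) ? 1 : -1;
      break;
    }
  }

  if (cross_ms < 0) {
    return List::create(_["crossed"] = false, _["cross_ms"] = NA_INTEGER,
                        _["x"] = NumericVector(0),
                        _["depth"] = NumericVector(0),
                        _["choice_sign"] = NA_INTEGER);
  }

  int n_steps = (int)std::llround(tf_s / dt);
  NumericVector x(n_steps + 1), depth(n_steps + 1);
  double hx = 0, hv = 0, ha = 0, zx = 0, zv = 0, za = 0;
  x[0] = 0.0; depth[0] = start_depth;

  int target_sign = side;
  bool locked = false;
  double p_corr = 1.0 / (1.0 + std::exp(-2.0 * dft_drift * cum / sig2));

  for (int k = 1; k <= n_steps; ++k) {
    double t = (k - 1) * dt;
    // in-flight sampling: one sample per ms tick
    if (!locked) {
      int idx = cross_ms + (k - 1);
      if (idx < n_avail) cum += samples[idx];
      p_corr = 1.0 / (1.0 + std::exp(-2.0 * dft_drift * cum / sig2));
      if (R_finite(second_thr)) {
        // opposing crossing of the second threshold flips the target
        if (target_sign > 0 && cum <= -second_thr) target_sign = -1;
        else if (target_sign < 0 && cum >= second_thr) target_sign = 1;
      }
      if (R_finite(deadline_ms) && (k - 1) * dt * 1000.0 >= deadline_ms) {
        target_sign = (p_corr >= 0.5) ? 1 : -1;
        locked = true;
      }
    }
    double w = binary_certainty(p_corr);
    double delta = tf_s - t;
    if (delta < delta_min) delta = delta_min;
    double hj = mj_jerk(hx, hv, ha, target_sign * x_f, delta);
    double zj = mj_jerk(zx, zv, za, start_depth, delta);
    hx += w * hv * dt; hv += w * ha * dt; ha += w * hj * dt;
    zx += w * zv * dt; zv += w * za * dt; za += w * zj * dt;
    x[k] = hx;
    depth[k] = start_depth - zx;
  }

  return List::create(
    _["crossed"] = true, _["cross_ms"] = cross_ms,
    _["cross_sign"] = side,
    _["x"] = x, _["depth"] = depth,
    _["choice_sign"] = (hx >= 0) ? 1 : -1,
    _["p_correct_final"] = p_corr,
    _["target_sign_final"] = target_sign);
}
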