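// [[Rcpp::depends(RcppArmadillo)]]
#include "glauber.h"
using namespace Rcpp;

// ---- Mountain Car -------------------------------------------------------
// x in [-1.5*pi, 0.5*pi]; v capped at +/- 0.045 (hard-task setting);
// v' = v + 0.001*a - 0.0025*cos(3x); height y = 0.55 + 0.45*sin(3x).

static const double MC_XMIN = -1.5 * M_PI;
static const double MC_XMAX = 0.5 * M_PI;
static const double MC_VMAX = 0.045;

struct MCState { double x, v; };

// Advances one step; returns true if the pre-clamp position reached the
// right bound (the success event; the bound itself is only absorbing for
// the success predicate).
static inline bool mc_step_cpp(MCState& st, int a) {
  double v = st.v + 0.001 * (double)a - 0.0025 * std::cos(3.0 * st.x);
  if (v > MC_VMAX) v = MC_VMAX;
  if (v < -MC_VMAX) v = -MC_VMAX;
  double x = st.x + v;
  bool reached = (x >= MC_XMAX);
  if (x >= MC_XMAX) x = MC_XMAX;
  if (x <= MC_XMIN) { x = MC_XMIN; v = 0.0; } // inelastic left wall
  st.x = x;
  st.v = v;
  return reached;
}

static inline double mc_height_cpp(double x) {
  return 0.55 + 0.45 * std::sin(3.0 * x);
}

// [[Rcpp::export]]
NumericVector cpp_mc_step(double x, double v, int a) {
  MCState st = {x, v};
  bool reached = mc_step_cpp(st, a);
  return NumericVector::create(st.x, st.v, reached ? 1.0 : 0.0);
}

// ---- Acrobot ------------------------------------------------------------
// Two-link underactuated pendulum, torque on the middle joint. Standard
// benchmark dynamics with l1 = l2 = 1, lc1 = lc2 = 0.5, I1 = I2 = 1,
// g = 9.8, and link mass m (hard-task setting m = 1.75). RK4, dt = 0.2,
// angles wrapped to (-pi, pi], angular velocities clamped to +/-4*pi and
// +/-9*pi (the benchmark's conventional bounds).

static const double AC_L1 = 1.0, AC_LC1 = 0.5, AC_LC2 = 0.5;
static const double AC_I1 = 1.0, AC_I2 = 1.0, AC_G = 9.8;
static const double AC_MAXV1 = 4.0 * M_PI, AC_MAXV2 = 9.0 * M_PI;

struct AcState { double th1, th2, dth1, dth2; };

static inline void acro_deriv(const double y[4], double tau, double m,
                              double dy[4]) {
  const double th1 = y[0], th2 = y[1], dth1 = y[2], dth2 = y[3];
  const double c2 = std::cos(th2), s2 = std::sin(th2);
  const double d1 = m * AC_LC1 * AC_LC1 +
                    m * (AC_L1 * AC_L1 + AC_LC2 * AC_LC2 +
                         2.0 * AC_L1 * AC_LC2 * c2) +
                    AC_I1 + AC_I2;
  const double d2 = m * (AC_LC2 * AC_LC2 + AC_L1 * AC_LC2 * c2) + AC_I2;
  const double phi2 = m * AC_LC2 * AC_G * std::cos(th1 + th2 - M_PI / 2.0);
  const double phi1 = -m * AC_L1 * AC_LC2 * dth2 * dth2 * s2 -
                      2.0 * m * AC_L1 * AC_LC2 * dth2 * dth1 * s2 +
                      (m * AC_LC1 + m * AC_L1) * AC_G *
                          std::cos(th1 - M_PI / 2.0) +
                      phi2;
  const double ddth2 =
      (tau + (d2 / d1) * phi1 - m * AC_L1 * AC_LC2 * dth1 * dth1 * s2 - phi2) /
      (m * AC_LC2 * AC_LC2 + AC_I2 - d2 * d2 / d1);
  const double ddth1 = -(d2 * ddth2 + phi1) / d1;
  dy[0] = dth1;
  dy[1] = dth2;
  dy[2] = ddth1;
  dy[3] = ddth2;
}

static inline double wrap_angle(double a) {
  // map to (-pi, pi] without fmod
  return a + 2.0 * M_PI * std::floor((M_PI - a) / (2.0 * M_PI));
}

static inline void acro_step_cpp(AcState& st, int tau, double dt, double m,
                                 bool clamp_wrap = true) {
  double y[4] = {st.th1, st.th2, st.dth1, st.dth2};
  double k1[4], k2[4], k3[4], k4[4], tmp[4];
  const double t = (double)tau;
  acro_deriv(y, t, m, k1);
  for (int i = 0; i < 4; ++i) tmp[i] = y[i] + 0.5 * dt * k1[i];
  acro_deriv(tmp, t, m, k2);
  for (int i = 0; i < 4; ++i) tmp[i] = y[i] + 0.5 * dt * k2[i];
  acro_deriv(tmp, t, m, k3);
  for (int i = 0; i < 4; ++i) tmp[i] = y[i] + dt * k3[i];
  acro_deriv(tmp, t, m, k4);
  for (int i = 0; i < 4; ++i)
    y[i] += dt / 6.0 * (k1[i] + 2.0 * k2[i] + 2.0 * k3[i] + k4[i]);
  if (clamp_wrap) {
    y[0] = wrap_angle(y[0]);
    y[1] = wrap_angle(y[1]);
    if (y[2] > AC_MAXV1) y[2] = AC_MAXV1;
    if (y[2] < -AC_MAXV1) y[2] = -AC_MAXV1;
    if (y[3] > AC_MAXV2) y[3] = AC_MAXV2;
    if (y[3] < -AC_MAXV2) y[3] = -AC_MAXV2;
  }
  st.th1 = y[0];
  st.th2 = y[1];
  st.dth1 = y[2];
  st.dth2 = y[3];
}

static inline double acro_tip_height_cpp(const AcState& st) {
  return -std::cos(st.th1) - std::cos(st.th1 + st.th2);
}

// [[Rcpp::export]]
NumericVector cpp_acrobot_deriv(double th1, double th2, double dth1,
                                double dth2, double tau, double mass) {
  double y[4] = {th1, th2, dth1, dth2};
  double dy[4];
  acro_deriv(y, tau, mass, dy);
  return NumericVector::create(dy[0], dy[1], dy[2], dy[3]);
}

// [[Rcpp::export]]
NumericVector cpp_acrobot_step(NumericVector state, int tau, double dt,
                               double mass, bool clamp_wrap) {
  AcState st = {state[0], state[1], state[2], state[3]};
  acro_step_cpp(st, tau, dt, mass, clamp_wrap);
  return NumericVector::create(st.th1, st.th2, st.dth1, st.dth2);
}

// ---- sensor/motor coding ------------------------------------------------
// 4-bit plain binary encoding of a bounded observation into 16 half-open
// bins; most significant bit first; bit values mapped {0 -> -1, 1 -> +1}.

static inline int encode_bin(double value, double lo, double hi) {
  int b = (int)std::floor((value - lo) / (hi - lo) * 16.0);
  if (b < 0) b = 0;
  if (b > 15) b = 15;
  return b;
}

static inline int decode_action_cpp(double s1, double s2) {
  if (s1 > 0 && s2 > 0) return 1;
  if (s1 < 0 && s2 < 0) return -1;
  return 0;
}

// ---- agent-environment loop ---------------------------------------------
// One simulation step: (1) encoded observation written into the sensor
// fields (h_i = I_i); (2) one sequential Glauber sweep; (3) motors decoded
// into the action; (4) environment advanced one step.
// roles: 0 = sensor, 1 = motor, 2 = hidden. env_kind: 0 = mountain car
// (observes v in +/-0.045), 1 = acrobot (observes dth1 in +/-4*pi).

// [[Rcpp::export]]
List cpp_run_trial(const arma::vec& h, const arma::mat& J, double beta,
                   arma::vec state, const IntegerVector& roles, int env_kind,
                   NumericVector env_state, int n_steps, double mass,
                   double dt, bool collect_moments,
                   const IntegerVector& subset0, bool record_heights) {
  const int n = (int)h.n_elem;
  std::vector<int> sensors, motors;
  for (int i = 0; i < n; ++i) {
    if (roles[i] == 0) sensors.push_back(i);
    if (roles[i] == 1) motors.push_back(i);
  }
  if (sensors.size() != 4) stop("exactly 4 sensor units required");
  if (motors.size() != 2) stop("exactly 2 motor units required");
  const int k = subset0.size();
  if (k > 24) stop("state histogram limited to subsets of <= 24 units");

  arma::vec heff = h;
  std::vector<int> perm(n);

  MCState mc = {0.0, 0.0};
  AcState ac = {0.0, 0.0, 0.0, 0.0};
  double obs_lo, obs_hi;
  if (env_kind == 0) {
    mc.x = env_state[0];
    mc.v = env_state[1];
    obs_lo = -MC_VMAX;
    obs_hi = MC_VMAX;
  } else {
    ac.th1 = env_state[0];
    ac.th2 = env_state[1];
    ac.dth1 = env_state[2];
    ac.dth2 = env_state[3];
    obs_lo = -AC_MAXV1;
    obs_hi = AC_MAXV1;
  }

  const int B = 256;
  arma::mat block(collect_moments ? B : 0, collect_moments ? n : 0);
  arma::vec msum(collect_moments ? n : 0, arma::fill::zeros);
  arma::mat csum(collect_moments ? n : 0, collect_moments ? n : 0,
                 arma::fill::zeros);
  int filled = 0;
  NumericVector counts(k > 0 ? (R_xlen_t)1 << k : 0);
  NumericVector heights(record_heights ? n_steps : 0);
  double hsum = 0.0;
  bool success = false;

  for (int t = 0; t < n_steps; ++t) {
    const double obs = (env_kind == 0) ? mc.v : ac.dth1;
    const int bin = encode_bin(obs, obs_lo, obs_hi);
    for (int j = 0; j < 4; ++j)
      heff[sensors[j]] = (((bin >> (3 - j)) & 1) ? 1.0 : -1.0);
    glauber_one_sweep(heff, J, beta, state, perm);
    const int action = decode_action_cpp(state[motors[0]], state[motors[1]]);
    double y;
    if (env_kind == 0) {
      if (mc_step_cpp(mc, action)) success = true;
      y = mc_height_cpp(mc.x);
      if (!std::isfinite(mc.x) || !std::isfinite(mc.v))
        stop("mountain car state diverged");
    } else {
      acro_step_cpp(ac, action, dt, mass);
      y = acro_tip_height_cpp(ac);
      if (!std::isfinite(ac.th1) || !std::isfinite(ac.dth1))
        stop("acrobot state diverged");
      if (y > 1.8) success = true;
    }
    hsum += y;
    if (record_heights) heights[t] = y;
    if (collect_moments) {
      block.row(filled++) = state.t();
      if (filled == B) {
        csum += block.t() * block;
        msum += arma::sum(block, 0).t();
        filled = 0;
      }
    }
    if (k > 0) {
      size_t code = 0;
      for (int j = 0; j < k; ++j)
        if (state[subset0[j]] > 0) code |= ((size_t)1 << j);
      counts[code] += 1.0;
    }
  }

  List out = List::create(
      _["state"] = state,
      _["env_state"] = (env_kind == 0)
                           ? NumericVector::create(mc.x, mc.v)
                           : NumericVector::create(ac.th1, ac.th2, ac.dth1,
                                                   ac.dth2),
      _["mean_height"] = hsum / (double)n_steps, _["success"] = success,
      _["counts"] = counts, _["heights"] = heights);
  if (collect_moments) {
    if (filled > 0) {
      arma::mat part = block.rows(0, filled - 1);
      csum += part.t() * part;
      msum += arma::sum(part, 0).t();
    }
    arma::vec m = msum / (double)n_steps;
    arma::mat c = csum / (double)n_steps;
    c.diag().ones();
    out["m"] = m;
    out["c"] = c;
  }
  return out;
}

// Random-controller baseline: n_controllers networks with biases and allowed
// couplings drawn uniformly from [lo, hi]; success fraction of the task.
// [[Rcpp::export]]
LogicalVector cpp_random_controllers(int env_kind, int n_controllers,
                                     int n_steps, int n_hidden, double lo,
                                     double hi, double mass, double dt) {
  const int n = 6 + n_hidden;
  IntegerVector roles(n);
  for (int i = 0; i < n; ++i) roles[i] = (i < 4) ? 0 : (i < 6 ? 1 : 2);
  LogicalVector success(n_controllers);
  IntegerVector empty(0);
  for (int r = 0; r < n_controllers; ++r) {
    arma::vec h(n);
    for (int i = 0; i < n; ++i) h[i] = lo + (hi - lo) * unif_rand();
    arma::mat J(n, n, arma::fill::zeros);
    for (int i = 0; i < n; ++i)
      for (int j = i + 1; j < n; ++j) {
        const bool allowed = (roles[i] == 2 || roles[j] == 2);
        if (allowed) {
          const double v = lo + (hi - lo) * unif_rand();
          J(i, j) = v;
          J(j, i) = v;
        }
      }
    arma::vec state(n);
    random_state(state);
    NumericVector env_state;
    if (env_kind == 0) {
      env_state = NumericVector::create(-0.6 + 0.2 * unif_rand(), 0.0);
    } else {
      env_state = NumericVector(4);
      for (int i = 0; i < 4; ++i) env_state[i] = -0.1 + 0.2 * unif_rand();
    }
    List tr = cpp_run_trial(h, J, 1.0, state, roles, env_kind, env_state,
                            n_steps, mass, dt, false, empty, false);
    success[r] = as<bool>(tr["success"]);
  }
  return success;
}
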