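// Closed-loop integrator for helical chemotaxis.
//
// State per step: position x (um), Frenet triad (t, n, b), signalling
// (a, p, q).  The triad is advanced by the exact rotation for piecewise
// constant curvature/torsion (Rodrigues rotation about the Darboux vector),
// and the position by the exact integral of the rotated tangent, so a
// perfect helix closes to machine precision.  Signalling uses
// exponential-Euler for the linear-in-a part and forward Euler for p;
// binding events enter as instantaneous jumps a += p/mu.
//
// Units throughout: um, s, pM.

#include <Rcpp.h>
using namespace Rcpp;

namespace {

struct Vec3 {
  double x, y, z;
};

inline Vec3 operator+(Vec3 a, Vec3 b) { return {a.x + b.x, a.y + b.y, a.z + b.z}; }
inline Vec3 operator-(Vec3 a, Vec3 b) { return {a.x - b.x, a.y - b.y, a.z - b.z}; }
inline Vec3 operator*(double s, Vec3 a) { return {s * a.x, s * a.y, s * a.z}; }
inline double dot(Vec3 a, Vec3 b) { return a.x * b.x + a.y * b.y + a.z * b.z; }
inline Vec3 cross(Vec3 a, Vec3 b) {
  return {a.y * b.z - a.z * b.y, a.z * b.x - a.x * b.z, a.x * b.y - a.y * b.x};
}
inline double norm(Vec3 a) { return std::sqrt(dot(a, a)); }

// Rotate v about unit axis u by angle th.
inline Vec3 rodrigues(Vec3 v, Vec3 u, double c, double s) {
  // c = cos(th), s = sin(th)
  Vec3 w = cross(u, v);
  double ud = dot(u, v);
  return c * v + s * w + ((1.0 - c) * ud) * u;
}

// Concentration field.  type: 0 radial (screened point source), 1 uniform,
// 2 linear gradient along a fixed axis.
struct Field {
  int type;
  double c_surf;   // concentration at source surface (radial)
  double R_src;    // source (egg) radius
  double ell;      // screening length; R_PosInf -> pure 1/R
  double shape;    // stretching exponent of the screening cut-off
  double c0;       // uniform / linear background
  double slope;    // linear gradient magnitude (pM/um)
  Vec3 dir;        // linear gradient direction (unit)
};

// Returns concentration, writes gradient vector.
inline double field_eval(const Field& f, Vec3 x, Vec3& grad) {
  switch (f.type) {
    case 0: {
      double R = norm(x);
      if (R < 1e-12) R = 1e-12;
      double c = f.c_surf * (f.R_src / R);
      double screen = 0.0;
      if (R_finite(f.ell)) {
        double z = (R - f.R_src) / f.ell;
        if (z < 0.0) z = 0.0;
        c *= std::exp(-std::pow(z, f.shape));
        screen = (z > 0.0) ? f.shape * std::pow(z, f.shape - 1.0) / f.ell
                           : (f.shape == 1.0 ? 1.0 / f.ell : 0.0);
      }
      double dcdR = -c * (1.0 / R + screen);
      grad = (dcdR / R) * x;  // points towards the source (dcdR < 0)
      return c;
    }
    case 1:
      grad = {0.0, 0.0, 0.0};
      return f.c0;
    default: {
      double c = f.c0 + f.slope * dot(f.dir, x);
      grad = f.slope * f.dir;
      return c > 0.0 ? c : 0.0;
    }
  }
}

Field as_field(const List& fl) {
  Field f;
  f.type = as<int>(fl["type_code"]);
  f.c_surf = fl.containsElementNamed("c_surf") ? as<double>(fl["c_surf"]) : 0.0;
  f.R_src = fl.containsElementNamed("source_radius") ? as<double>(fl["source_radius"]) : 0.0;
  f.ell = fl.containsElementNamed("ell") ? as<double>(fl["ell"]) : R_PosInf;
  f.shape = fl.containsElementNamed("shape") ? as<double>(fl["shape"]) : 1.0;
  f.c0 = fl.containsElementNamed("c0") ? as<double>(fl["c0"]) : 0.0;
  f.slope = fl.containsElementNamed("slope") ? as<double>(fl["slope"]) : 0.0;
  f.dir = {0.0, 0.0, 1.0};
  if (fl.containsElementNamed("direction")) {
    NumericVector d = fl["direction"];
    double nn = std::sqrt(d[0] * d[0] + d[1] * d[1] + d[2] * d[2]);
    f.dir = {d[0] / nn, d[1] / nn, d[2] / nn};
  }
  return f;
}

// Piecewise-linear decision boundary Theta(p); knots (p ascending, theta).
// Constant extrapolation below the first knot; rule inactive above p_valid.
inline double theta_eval(const NumericMatrix& knots, double p) {
  int n = knots.nrow();
  if (p <= knots(0, 0)) return knots(0, 1);
  if (p >= knots(n - 1, 0)) return knots(n - 1, 1);
  for (int i = 1; i < n; ++i) {
    if (p <= knots(i, 0)) {
      double w = (p - knots(i - 1, 0)) / (knots(i, 0) - knots(i - 1, 0));
      return (1.0 - w) * knots(i - 1, 1) + w * knots(i, 1);
    }
  }
  return knots(n - 1, 1);
}

}  // namespace

// Advance an orthonormal frame and position by one step of constant
// (kappa, tau) over arc length v*dt.  frame rows: tangent, normal, binormal.
// [[Rcpp::export(name = ".frenet_step_cpp")]]
List frenet_step_cpp(NumericMatrix frame, NumericVector position,
                     double kappa, double tau, double v, double dt) {
  Vec3 t = {frame(0, 0), frame(0, 1), frame(0, 2)};
  Vec3 n = {frame(1, 0), frame(1, 1), frame(1, 2)};
  Vec3 b = {frame(2, 0), frame(2, 1), frame(2, 2)};
  Vec3 x = {position[0], position[1], position[2]};

  double L = v * dt;
  double om = std::sqrt(kappa * kappa + tau * tau);
  Vec3 dx;
  if (om * L < 1e-14) {
    dx = L * t;
  } else {
    Vec3 u = (1.0 / om) * (tau * t + kappa * b);  // Darboux axis (unit)
    double th = om * L;
    double c = std::cos(th), s = std::sin(th);
    // exact integral of the rotating tangent over the step
    Vec3 w = cross(u, t);
    double ud = dot(u, t);
    dx = (s / om) * t + ((1.0 - c) / om) * w + (ud * (L - s / om)) * u;
    t = rodrigues(t, u, c, s);
    n = rodrigues(n, u, c, s);
    b = rodrigues(b, u, c, s);
    // re-orthonormalize (Gram-Schmidt), guards against drift over 1e6+ steps
    double tn = norm(t);
    t = (1.0 / tn) * t;
    n = n - dot(n, t) * t;
    double nn = norm(n);
    n = (1.0 / nn) * n;
    b = cross(t, n);
  }
  x = x + dx;

  NumericMatrix fr(3, 3);
  fr(0, 0) = t.x; fr(0, 1) = t.y; fr(0, 2) = t.z;
  fr(1, 0) = n.x; fr(1, 1) = n.y; fr(1, 2) = n.z;
  fr(2, 0) = b.x; fr(2, 1) = b.y; fr(2, 2) = b.z;
  return List::create(_["frame"] = fr,
                      _["position"] = NumericVector::create(x.x, x.y, x.z));
}

// Full closed-loop path simulation.
//
// par: v, kappa0, tau0, lambda, mu, eta, c_b, R_egg, R_th, t_max, dt,
//      rho_low, rho_high
// policy: 0 constant gain (rho_const), 1 decision rule (knots, p_valid)
// start: position (3), tangent (3), normal (3), binormal (3)
// noise: draw per-step Poisson binding events; otherwise drive with b(t)
// stride: record every `stride` steps
// [[Rcpp::export(name = ".sim_path_cpp")]]
List sim_path_cpp(List par, List fld, NumericVector start, int policy,
                  double rho_const, NumericMatrix knots, double p_valid,
                  bool noise, int stride, bool store_path) {
  const double v = as<double>(par["v"]);
  const double kappa0 = as<double>(par["kappa0"]);
  const double tau0 = as<double>(par["tau0"]);
  const double lambda = as<double>(par["lambda"]);
  const double mu = as<double>(par["mu"]);
  const double eta = as<double>(par["eta"]);
  const double c_b = as<double>(par["c_b"]);
  const double R_egg = as<double>(par["R_egg"]);
  const double R_th = as<double>(par["R_th"]);
  const double t_max = as<double>(par["t_max"]);
  const double dt = as<double>(par["dt"]);
  const double rho_low = as<double>(par["rho_low"]);
  const double rho_high = as<double>(par["rho_high"]);

  Field f = as_field(fld);

  Vec3 x = {start[0], start[1], start[2]};
  Vec3 t = {start[3], start[4], start[5]};
  Vec3 n = {start[6], start[7], start[8]};
  Vec3 b = {start[9], start[10], start[11]};

  // signalling at the constant-input fixed point of the local concentration
  Vec3 grad;
  double c = field_eval(f, x, grad);
  double a = 1.0;
  double p = 1.0 / (lambda * (c_b + c));
  double q = 1.0;

  const double ema = std::exp(-dt / mu);
  const double emq = std::exp(-dt / eta);

  const long n_steps = (long)std::ceil(t_max / dt);
  const long n_rec = n_steps / stride + 2;
  std::vector<double> rt, rx, ry, rz, ra, rp, rq, rrho, rev;
  rt.reserve(n_rec);
  if (store_path) { rx.reserve(n_rec); ry.reserve(n_rec); rz.reserve(n_rec); }
  ra.reserve(n_rec); rp.reserve(n_rec); rq.reserve(n_rec);
  rrho.reserve(n_rec); rev.reserve(n_rec);

  int outcome = 0;  // 0 timeout, 1 success, 2 failure
  long clip_count = 0;
  double min_dist = norm(x);
  double ev_window = 0.0;
  double t_now = 0.0, t_end = t_max;

  RNGScope rngscope;

  for (long k = 0; k <= n_steps; ++k) {
    t_now = k * dt;
    double R = norm(x);
    if (R < min_dist) min_dist = R;
    if (k % stride == 0) {
      rt.push_back(t_now);
      if (store_path) { rx.push_back(x.x); ry.push_back(x.y); rz.push_back(x.z); }
      ra.push_back(a); rp.push_back(p); rq.push_back(q);
      rev.push_back(ev_window);
      ev_window = 0.0;
    }
    if (R <= R_egg) { outcome = 1; t_end = t_now; if (k % stride == 0) rrho.push_back(NA_REAL); break; }
    if (R >= R_th) { outcome = 2; t_end = t_now; if (k % stride == 0) rrho.push_back(NA_REAL); break; }
    if (k == n_steps) { if (k % stride == 0) rrho.push_back(NA_REAL); break; }

    c = field_eval(f, x, grad);
    // midpoint concentration along the current tangent (2nd-order drive)
    double c_mid = c + 0.5 * v * dt * (grad.x * t.x + grad.y * t.y +
                                       grad.z * t.z);
    if (c_mid < 0.0) c_mid = 0.0;

    // action for this step
    double rho;
    if (policy == 0) {
      rho = rho_const;
    } else {
      rho = (p > p_valid || q >= theta_eval(knots, p)) ? rho_low : rho_high;
    }
    if (k % stride == 0) rrho.push_back(rho);

    // signalling update over dt: exponential integrator for a with the
    // sensitivity predicted at midstep, exponential-trapezoidal update
    // for p, exact relaxation of q under linearly interpolated a
    double a_old = a;
    if (noise) {
      double lam_ev = lambda * c_mid * dt;
      double nev = (lam_ev > 0.0) ? R::rpois(lam_ev) : 0.0;
      ev_window += nev;
      double p_mid = p * std::exp(0.5 * dt * (1.0 - a) / mu);
      double P0 = p_mid * lambda * c_b;
      a = P0 + (a - P0) * ema + nev * p / mu;
    } else {
      double p_mid = p * std::exp(0.5 * dt * (1.0 - a) / mu);
      double P0 = p_mid * lambda * (c_b + c_mid);
      a = P0 + (a - P0) * ema;
    }
    p *= std::exp(dt * (1.0 - 0.5 * (a_old + a)) / mu);
    if (p < 1e-300) p = 1e-300;
    {
      double r = (a - a_old) / dt;
      q = a - r * eta + (q - a_old + r * eta) * emq;
    }

    if (!R_finite(a) || !R_finite(p) || !R_finite(q))
      stop("non-finite signalling state at t = %f", t_now);

    // geometry modulation (curvature clipped at zero), midpoint output
    double da = 0.5 * (a_old + a) - 1.0;
    double kap = kappa0 * (1.0 - rho * da);
    if (kap < 0.0) { kap = 0.0; ++clip_count; }
    double tau = tau0 * (1.0 + rho * da);

    // Frenet step (exact rotation for constant kappa, tau over v*dt)
    double L = v * dt;
    double om = std::sqrt(kap * kap + tau * tau);
    if (om * L < 1e-14) {
      x = x + L * t;
    } else {
      Vec3 u = (1.0 / om) * (tau * t + kap * b);
      double th = om * L;
      double cth = std::cos(th), sth = std::sin(th);
      Vec3 w = cross(u, t);
      double ud = dot(u, t);
      x = x + (sth / om) * t + ((1.0 - cth) / om) * w + (ud * (L - sth / om)) * u;
      t = rodrigues(t, u, cth, sth);
      n = rodrigues(n, u, cth, sth);
      b = rodrigues(b, u, cth, sth);
      double tn = norm(t);
      t = (1.0 / tn) * t;
      n = n - dot(n, t) * t;
      double nn2 = norm(n);
      n = (1.0 / nn2) * n;
      b = cross(t, n);
    }
  }

  List rec = List::create(
      _["t"] = wrap(rt), _["a"] = wrap(ra), _["p"] = wrap(rp),
      _["q"] = wrap(rq), _["rho"] = wrap(rrho), _["events"] = wrap(rev));
  if (store_path) {
    rec["x"] = wrap(rx); rec["y"] = wrap(ry); rec["z"] = wrap(rz);
  }
  return List::create(
      _["outcome"] = outcome, _["t_end"] = t_end, _["min_dist"] = min_dist,
      _["clip_count"] = (double)clip_count, _["record"] = rec,
      _["final_frame"] = NumericVector::create(t.x, t.y, t.z, n.x, n.y, n.z,
                                               b.x, b.y, b.z),
      _["final_position"] = NumericVector::create(x.x, x.y, x.z),
      _["final_signal"] = NumericVector::create(a, p, q));
}
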