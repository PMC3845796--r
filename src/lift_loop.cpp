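#include <Rcpp.h>
using namespace Rcpp;

// Closed-loop grip/lift trial: second-order grip-force reference tracking
// (closed form), PID lift-force controller with exact first-order output
// smoothing, and a stick-slip two-body plant (finger assembly + object).
//
// Conventions (must stay in lock-step with the R reference implementation
// in R/plant.R / R/lift_sim.R, which the tests compare against):
//  * positions in m, forces in N, time in s; the table surface is at x = 0;
//  * the finger assembly's weight is borne by the arm, so gravity acts on
//    the object only; the finger contributes inertia m_fin;
//  * total friction capacity between fingers and object is mu * F_G;
//  * the controller's lift force is applied once per finger: the plant
//    receives n_fingers * F_L(PID, smoothed);
//  * semi-implicit Euler at fixed dt with explicit stick/slip/rest modes.

struct PlantP {
  double Mo, mfin, mu, g, cdamp;
};

struct StepOut {
  double xo, vo, ao, xf, vf, af, Ff, Fn;
  int mode; // 0 resting, 1 stick, 2 slip
};

static inline double sgn(double x) { return (x > 0) - (x < 0); }

// one plant step; state passed in xo..vf, returns updated state + forces
static inline StepOut plant_step(double xo, double vo, double xf, double vf,
                                 double FG, double FL, const PlantP &p,
                                 double dt) {
  const double vtol = 1e-9;
  double cap = p.mu * FG;
  double vrel = vf - vo;
  double vo0 = vo, vf0 = vf;
  StepOut o;
  o.Ff = 0.0; o.Fn = 0.0;
  bool done = false;
  double s = 0.0;

  if (std::fabs(vrel) <= vtol) {
    double mt = p.mfin + p.Mo;
    double Fcomb = FL - p.Mo * p.g - p.cdamp * vo;
    if (xo <= 0.0 && vo <= vtol && Fcomb <= 0.0) {
      // object resting on the table, fingers possibly held by friction
      double freq = FL; // friction needed to keep the finger static
      if (std::fabs(freq) <= cap) {
        o.ao = 0.0; o.af = 0.0;
        vo = 0.0; vf = 0.0; vo0 = 0.0; vf0 = 0.0;
        if (xo < 0.0) xo = 0.0;
        o.Ff = freq;
        o.Fn = p.Mo * p.g - o.Ff;
        o.mode = 0; done = true;
      } else s = sgn(freq);
    } else {
      // joint stick motion (lift-off or airborne)
      double a = Fcomb / mt;
      double Freq = p.Mo * (a + p.g); // friction needed on the object
      if (std::fabs(Freq) <= cap) {
        o.ao = a; o.af = a;
        vo += a * dt; vf = vo;
        o.Ff = Freq; o.Fn = 0.0;
        o.mode = 1; done = true;
      } else s = sgn(Freq);
    }
  } else s = sgn(vrel);

  if (!done) { // slip
    o.Ff = cap * s;
    double Fo = o.Ff - p.Mo * p.g - p.cdamp * vo;
    double ao;
    if (xo <= 0.0 && vo <= vtol && Fo <= 0.0) {
      vo = 0.0; vo0 = 0.0; xo = 0.0; ao = 0.0;
      o.Fn = p.Mo * p.g - o.Ff;
    } else { o.Fn = 0.0; ao = Fo / p.Mo; }
    double af = (FL - o.Ff - p.cdamp * vf) / p.mfin;
    double vf2 = vf + af * dt, vo2 = vo + ao * dt;
    if (std::fabs(vrel) > vtol && sgn(vf2 - vo2) != sgn(vrel)) {
      // relative velocity crossed zero: re-stick at the common
      // momentum-conserving velocity (table-supported if resting)
      double v = (p.mfin * vf2 + p.Mo * vo2) / (p.mfin + p.Mo);
      if (xo <= 0.0 && v < 0.0) v = 0.0;
      vf2 = v; vo2 = v;
    }
    o.ao = ao; o.af = af;
    vo = vo2; vf = vf2;
    o.mode = 2;
  }

  // locally exact constant-acceleration position update (trapezoid in v):
  // exact on smooth segments, leaving only O(dt^2) error per mode switch
  xo += 0.5 * (vo0 + vo) * dt; xf += 0.5 * (vf0 + vf) * dt;
  if (xo < 0.0) { xo = 0.0; if (vo < 0.0) vo = 0.0; }
  o.xo = xo; o.vo = vo; o.xf = xf; o.vf = vf;
  return o;
}

// closed-form step response of the underdamped second-order grip controller
static inline double grip_response(double t, double fgref, double wn,
                                   double zeta) {
  if (t <= 0.0) return 0.0;
  double wd = wn * std::sqrt(1.0 - zeta * zeta);
  double k = zeta / std::sqrt(1.0 - zeta * zeta);
  return fgref * (1.0 - std::exp(-zeta * wn * t) *
                            (std::cos(wd * t) + k * std::sin(wd * t)));
}

struct TrialSummary {
  double xf_bar, xo_bar, sgf, max_abs_x;
};

// core loop; if traj != nullptr, fills an (n x 12) trajectory matrix
static TrialSummary run_trial(double fgref, const PlantP &p, double wn,
                              double zeta, double Kp, double Ki, double Kd,
                              double tau_s, double nf, double xref,
                              double duration, double dt, double w0,
                              double w1, NumericMatrix *traj) {
  int n = (int)std::lround(duration / dt);
  double xo = 0, vo = 0, xf = 0, vf = 0;
  double I = 0, FLs = 0;
  double e_prev = xref; // error is constant before the first step: no kick
  double decay = std::exp(-dt / tau_s);
  double sx_f = 0, sx_o = 0, s_fg = 0, max_abs_x = 0;
  int nw = 0;
  for (int k = 0; k < n; ++k) {
    double t = k * dt;
    double FG = grip_response(t, fgref, wn, zeta);
    double e = xref - xo;
    I += e * dt;
    double D = (e - e_prev) / dt;
    e_prev = e;
    double pid = Kp * e + Ki * I + Kd * D;
    FLs = pid + (FLs - pid) * decay; // exact discretization of Eq-style filter
    double FL = nf * FLs;
    StepOut o = plant_step(xo, vo, xf, vf, FG, FL, p, dt);
    xo = o.xo; vo = o.vo; xf = o.xf; vf = o.vf;
    double tk = (k + 1) * dt;
    if (tk > w0 && tk <= w1 + 1e-12) {
      sx_f += xf; sx_o += xo; s_fg += FG; ++nw;
    }
    double ax = std::max(std::fabs(xo), std::fabs(xf));
    if (ax > max_abs_x) max_abs_x = ax;
    if (traj) {
      NumericMatrix &m = *traj;
      m(k, 0) = tk;   m(k, 1) = xo;   m(k, 2) = vo;    m(k, 3) = o.ao;
      m(k, 4) = xf;   m(k, 5) = vf;   m(k, 6) = o.af;  m(k, 7) = FG;
      m(k, 8) = FL;   m(k, 9) = o.Ff; m(k, 10) = o.Fn; m(k, 11) = o.mode;
    }
  }
  TrialSummary out;
  out.xf_bar = nw ? sx_f / nw : 0.0;
  out.xo_bar = nw ? sx_o / nw : 0.0;
  out.sgf = nw ? s_fg / nw : 0.0;
  out.max_abs_x = max_abs_x;
  return out;
}

// [[Rcpp::export(name = ".lift_trial_cpp")]]
List lift_trial_cpp(double fgref, double Mo, double mfin, double mu, double g,
                    double cdamp, double wn, double zeta, double Kp, double Ki,
                    double Kd, double tau_s, double n_fingers, double xref,
                    double duration, double dt, double w0, double w1,
                    bool keep_trajectory) {
  PlantP p; p.Mo = Mo; p.mfin = mfin; p.mu = mu; p.g = g; p.cdamp = cdamp;
  int n = (int)std::lround(duration / dt);
  NumericMatrix traj;
  NumericMatrix *tp = nullptr;
  if (keep_trajectory) { traj = NumericMatrix(n, 12); tp = &traj; }
  TrialSummary s = run_trial(fgref, p, wn, zeta, Kp, Ki, Kd, tau_s, n_fingers,
                             xref, duration, dt, w0, w1, tp);
  List out = List::create(
      _["xf_bar"] = s.xf_bar, _["xo_bar"] = s.xo_bar, _["sgf"] = s.sgf,
      _["max_abs_x"] = s.max_abs_x);
  if (keep_trajectory) out["trajectory"] = traj;
  return out;
}

// [[Rcpp::export(name = ".lift_batch_cpp")]]
List lift_batch_cpp(NumericVector fgrefs, double Mo, double mfin, double mu,
                    double g, double cdamp, double wn, double zeta, double Kp,
                    double Ki, double Kd, double tau_s, double n_fingers,
                    double xref, double duration, double dt, double w0,
                    double w1) {
  PlantP p; p.Mo = Mo; p.mfin = mfin; p.mu = mu; p.g = g; p.cdamp = cdamp;
  int m = fgrefs.size();
  NumericVector xfb(m), xob(m), sgf(m), maxx(m);
  for (int i = 0; i < m; ++i) {
    TrialSummary s = run_trial(fgrefs[i], p, wn, zeta, Kp, Ki, Kd, tau_s,
                               n_fingers, xref, duration, dt, w0, w1, nullptr);
    xfb[i] = s.xf_bar; xob[i] = s.xo_bar; sgf[i] = s.sgf;
    maxx[i] = s.max_abs_x;
  }
  return List::create(_["xf_bar"] = xfb, _["xo_bar"] = xob, _["sgf"] = sgf,
                      _["max_abs_x"] = maxx);
}
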