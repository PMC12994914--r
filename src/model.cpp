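#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Coupled sleep-wake / circadian / melatonin model.
// State vector layout: 0 Vv, 1 Vm, 2 H, 3 x, 4 y, 5 n, 6 Ms, 7 Mp
static const int NS = 8;

struct Pars {
  double Qmax, theta, sigma_v, tau_v, tau_m, nu_vm, nu_mv, nu_vh, nu_vc,
      A_v, D_m, F_w, theta_nat, chi_wake, chi_sleep, mu, tau_c, f_c,
      gamma_c, q_c, k_c,
      G_c, alpha0, beta_c, p_c, E0_mel, rho_c, phi_m, theta_m, s_m, r_m,
      k_syn, k_clr, E_i50, h_i;
};

static Pars unpack(const List& p) {
  Pars q;
  q.Qmax = p["Qmax"]; q.theta = p["theta"]; q.sigma_v = p["sigma_v"];
  q.tau_v = p["tau_v"]; q.tau_m = p["tau_m"];
  q.nu_vm = p["nu_vm"]; q.nu_mv = p["nu_mv"]; q.nu_vh = p["nu_vh"];
  q.nu_vc = p["nu_vc"]; q.A_v = p["A_v"]; q.D_m = p["D_m"];
  q.F_w = p["F_w"]; q.theta_nat = p["theta_nat"];
  q.chi_wake = p["chi_wake"]; q.chi_sleep = p["chi_sleep"];
  q.mu = p["mu"];
  q.tau_c = p["tau_c"]; q.f_c = p["f_c"]; q.gamma_c = p["gamma_c"];
  q.q_c = p["q_c"]; q.k_c = p["k_c"]; q.G_c = p["G_c"];
  q.alpha0 = p["alpha0"]; q.beta_c = p["beta_c"]; q.p_c = p["p_c"];
  q.E0_mel = p["E0_mel"]; q.rho_c = p["rho_c"];
  q.phi_m = p["phi_m"]; q.theta_m = p["theta_m"]; q.s_m = p["s_m"];
  q.r_m = p["r_m"]; q.k_syn = p["k_syn"]; q.k_clr = p["k_clr"];
  q.E_i50 = p["E_i50"]; q.h_i = p["h_i"];
  return q;
}

static inline double sigm(double V, const Pars& p) {
  return p.Qmax / (1.0 + std::exp(-(V - p.theta) / p.sigma_v));
}

// force acts on the sleep-active (VLPO) drive only: +F_w imposes scheduled
// sleep, -F_w suppresses the VLPO during scheduled wake, 0 in natural mode.
// The wake-active drive is untouched so awake firing (and hence the
// homeostat) stays in its physiological range.
// Retinal input is gated to zero while asleep (eyes closed): light then
// influences neither the pacemaker nor melatonin inhibition.
static void deriv(const double* s, double E, bool awake, double force,
                  const Pars& p, double* d) {
  double E_eff = awake ? std::max(E, 0.0) : 0.0;
  double Qv = sigm(s[0], p), Qm = sigm(s[1], p);
  double C = 0.5 * (1.0 + s[3]);
  double Dv = p.A_v + p.nu_vh * s[2] + p.nu_vc * C + force;
  double Dm = p.D_m;
  d[0] = (p.nu_vm * Qm + Dv - s[0]) / p.tau_v;
  d[1] = (p.nu_mv * Qv + Dm - s[1]) / p.tau_m;
  d[2] = (p.mu * Qm - s[2]) / (awake ? p.chi_wake : p.chi_sleep);

  double alpha = (E_eff > 0.0)
      ? p.alpha0 * std::pow(E_eff / p.E0_mel, p.p_c) : 0.0;
  // photic drive follows the published convention: the activation rate
  // enters B in per-minute units while dn/dt runs in per-second units
  double B = p.G_c * (alpha * 60.0) * (1.0 - s[5]) *
      (1.0 - 0.4 * s[3]) * (1.0 - 0.4 * s[4]);
  // nonphotic (behavioural) drive: sleep-wake state acts on the pacemaker
  // mainly over the low-x half of the cycle, so a repeating schedule can
  // hold the oscillator near 24 h even in darkness
  double Ns = p.rho_c * (1.0 / 3.0 - (awake ? 0.0 : 1.0)) *
      (1.0 - std::tanh(10.0 * s[3]));
  double omega = M_PI / 43200.0;  // pi / 12 h, in s^-1
  double x = s[3], y = s[4];
  double x3 = x * x * x, x7 = x3 * x3 * x;
  double kfac = std::pow(24.0 / (p.f_c * p.tau_c), 2.0);
  d[3] = omega * (y + p.gamma_c * (x / 3.0 + 4.0 * x3 / 3.0
                  - 256.0 * x7 / 105.0) + B + Ns);
  d[4] = omega * (p.q_c * B * y - x * (kfac + p.k_c * B));
  d[5] = alpha * (1.0 - s[5]) - p.beta_c * s[5];

  // circadian synthesis gate: rotate the oscillator plane so -u peaks in
  // the biological night, then apply a curved (power-shaped) activation so
  // synthesis has an interior maximum rather than a flat plateau
  double u = std::cos(p.phi_m) * x + std::sin(p.phi_m) * y;
  double g_lin = (-u - p.theta_m) / (1.0 - p.theta_m);
  if (g_lin < 0.0) g_lin = 0.0;
  if (g_lin > 1.0) g_lin = 1.0;
  double gate = std::pow(g_lin, p.s_m);
  double supp = 1.0 / (1.0 + std::pow(E_eff / p.E_i50, p.h_i));
  d[6] = p.r_m * gate * supp - p.k_syn * s[6];
  d[7] = p.k_syn * s[6] - p.k_clr * s[7];
}

// [[Rcpp::export]]
NumericVector insom_deriv_cpp(NumericVector state, double light, bool awake,
                              List params) {
  Pars p = unpack(params);
  for (int i = 0; i < NS; ++i) {
    if (!R_finite(state[i])) stop("non-finite state component %d", i + 1);
  }
  NumericVector d(NS);
  deriv(REAL(state), light, awake, 0.0, p, REAL(d));
  d.names() = CharacterVector::create("Vv", "Vm", "H", "x", "y", "n",
                                      "Ms", "Mp");
  return d;
}

// Fixed-step RK4 over macro steps of length dt. The neuronal voltage pair
// relaxes on a ~10 s timescale, far below dt = 20 s, so each macro step is
// integrated as `n_sub` RK4 substeps (light varies linearly across the
// macro step; schedule state is constant within it). `light_half` holds
// melanopic irradiance on a dt/2 grid (length 2 * n_steps + 1);
// `awake_sched` is per-step (length n_steps) and ignored when
// natural = true. Output is thinned to every `thin` macro steps, sampling
// states at step starts (row 0 = initial state).
// [[Rcpp::export]]
List insom_integrate_cpp(NumericVector y0, double dt, int n_steps,
                         NumericVector light_half, LogicalVector awake_sched,
                         bool natural, List params, int thin, int n_sub) {
  Pars p = unpack(params);
  if (light_half.size() < 2 * n_steps + 1)
    stop("light vector too short for horizon");
  if (!natural && awake_sched.size() < n_steps)
    stop("schedule vector too short for horizon");
  if (n_sub < 1) stop("n_sub must be >= 1");

  std::vector<double> s(NS), k1(NS), k2(NS), k3(NS), k4(NS), tmp(NS);
  for (int i = 0; i < NS; ++i) s[i] = y0[i];
  bool awake = natural ? (s[1] > p.theta_nat) : (awake_sched[0] != 0);

  int n_out = n_steps / thin + 1;
  NumericMatrix out(n_out, NS);
  LogicalVector awake_out(n_out);
  int row = 0;
  for (int i = 0; i < NS; ++i) out(0, i) = s[i];
  awake_out[0] = awake;

  double h = dt / n_sub;
  for (int step = 0; step < n_steps; ++step) {
    if (!natural) awake = awake_sched[step] != 0;
    double force = natural ? 0.0 : (awake ? -p.F_w : p.F_w);
    double E0 = light_half[2 * step], E1 = light_half[2 * step + 2];

    for (int sub = 0; sub < n_sub; ++sub) {
      double f0 = (double)sub / n_sub, f1 = (double)(sub + 1) / n_sub;
      double Ea = E0 + (E1 - E0) * f0;
      double Em = E0 + (E1 - E0) * 0.5 * (f0 + f1);
      double Eb = E0 + (E1 - E0) * f1;
      deriv(s.data(), Ea, awake, force, p, k1.data());
      for (int i = 0; i < NS; ++i) tmp[i] = s[i] + 0.5 * h * k1[i];
      deriv(tmp.data(), Em, awake, force, p, k2.data());
      for (int i = 0; i < NS; ++i) tmp[i] = s[i] + 0.5 * h * k2[i];
      deriv(tmp.data(), Em, awake, force, p, k3.data());
      for (int i = 0; i < NS; ++i) tmp[i] = s[i] + h * k3[i];
      deriv(tmp.data(), Eb, awake, force, p, k4.data());
      for (int i = 0; i < NS; ++i) {
        s[i] += h / 6.0 * (k1[i] + 2.0 * k2[i] + 2.0 * k3[i] + k4[i]);
      }
    }
    if (s[5] < 0.0) s[5] = 0.0;
    if (s[5] > 1.0) s[5] = 1.0;
    if (s[6] < 0.0) s[6] = 0.0;
    if (s[7] < 0.0) s[7] = 0.0;

    for (int i = 0; i < NS; ++i) {
      if (!R_finite(s[i])) {
        stop("integration diverged at step %d (state component %d)",
             step + 1, i + 1);
      }
    }
    if (natural) {
      // hysteretic switching on the wake-active voltage: fall asleep on a
      // downward crossing, wake on an upward crossing of a 1 mV-higher
      // threshold so the flag cannot chatter at the boundary
      if (awake && s[1] < p.theta_nat) awake = false;
      else if (!awake && s[1] > p.theta_nat + 1.0) awake = true;
    }
    if ((step + 1) % thin == 0) {
      ++row;
      for (int i = 0; i < NS; ++i) out(row, i) = s[i];
      awake_out[row] = awake;
    }
  }
  colnames(out) = CharacterVector::create("Vv", "Vm", "H", "x", "y", "n",
                                          "Ms", "Mp");
  return List::create(_["states"] = out, _["awake"] = awake_out);
}
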