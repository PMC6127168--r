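#include <Rcpp.h>
using namespace Rcpp;

// Squid-axon gating rate functions, modern convention (rest near -65 mV).
// Removable singularities of the alpha_m / alpha_n expressions are replaced
// by their analytic limits.
static inline double alpha_m(double u) {
  double x = u + 40.0;
  if (fabs(x) < 1e-7) return 1.0;
  return 0.1 * x / (1.0 - exp(-x / 10.0));
}
static inline double beta_m(double u) { return 4.0 * exp(-(u + 65.0) / 18.0); }
static inline double alpha_h(double u) { return 0.07 * exp(-(u + 65.0) / 20.0); }
static inline double beta_h(double u) { return 1.0 / (1.0 + exp(-(u + 35.0) / 10.0)); }
static inline double alpha_n(double u) {
  double x = u + 55.0;
  if (fabs(x) < 1e-7) return 0.1;
  return 0.01 * x / (1.0 - exp(-x / 10.0));
}
static inline double beta_n(double u) { return 0.125 * exp(-(u + 65.0) / 80.0); }

struct HHDeriv {
  double du, dm, dh, dn;
};

// Total synaptic current through the rectifying electrical junctions at
// within-cycle sample s. Column-major profile matrices hold presynaptic
// sensilla voltages (S rows = samples per stroke cycle).
static inline double syn_current(double u, int s, int S,
                                 const double* halt, int nh, double g_h,
                                 const double* wing, int nw, double g_w,
                                 double u_in, double g_ins) {
  double acc = 0.0;
  if (nh > 0 && g_h > 0.0) {
    double sh = 0.0;
    for (int i = 0; i < nh; ++i) {
      double d = halt[s + (size_t)S * i] - u;
      if (d > 0.0) sh += d;
    }
    acc += g_h * sh;
  }
  if (nw > 0 && g_w > 0.0) {
    double sw = 0.0;
    for (int i = 0; i < nw; ++i) {
      double d = wing[s + (size_t)S * i] - u;
      if (d > 0.0) sw += d;
    }
    acc += g_w * sw;
  }
  if (g_ins > 0.0) {
    double d = u_in - u;
    if (d > 0.0) acc += g_ins * d;
  }
  return acc;
}

static inline HHDeriv hh_deriv(double u, double m, double h, double n,
                               double i_ext,
                               double c_mn, double gna, double gk, double gl,
                               double ena, double ek, double el) {
  HHDeriv d;
  double ina = gna * m * m * m * h * (u - ena);
  double ik = gk * n * n * n * n * (u - ek);
  double il = gl * (u - el);
  d.du = (i_ext - ina - ik - il) / c_mn;
  d.dm = alpha_m(u) * (1.0 - m) - beta_m(u) * m;
  d.dh = alpha_h(u) * (1.0 - h) - beta_h(u) * h;
  d.dn = alpha_n(u) * (1.0 - n) - beta_n(u) * n;
  return d;
}

static inline double clamp01(double x) {
  if (x < 0.0) return 0.0;
  if (x > 1.0) return 1.0;
  return x;
}

//' @noRd
// [[Rcpp::export(name = ".hh_sim_cpp")]]
List hh_sim_cpp(List par, double dt, int n_steps,
                NumericMatrix halt_prof, NumericMatrix wing_prof,
                double g_h, double g_w,
                NumericVector u_in, double g_ins,
                NumericVector i_inj,
                double u0, double m0, double h0, double n0,
                double noise_sd, bool keep_gates) {
  const double c_mn = as<double>(par["C_MN"]);
  const double gna = as<double>(par["gbar_Na"]);
  const double gk = as<double>(par["gbar_K"]);
  const double gl = as<double>(par["g_L"]);
  const double ena = as<double>(par["E_Na"]);
  const double ek = as<double>(par["E_K"]);
  const double el = as<double>(par["E_L"]);

  const int S = halt_prof.nrow();
  const int nh = halt_prof.ncol();
  const int nw = wing_prof.ncol();
  if (nw > 0 && wing_prof.nrow() != S)
    stop("haltere and wing profiles must share the cycle grid");
  const double* halt = nh > 0 ? REAL(halt_prof) : NULL;
  const double* wing = nw > 0 ? REAL(wing_prof) : NULL;

  const bool has_uin = (u_in.size() > 1);
  if (has_uin && u_in.size() != n_steps + 1)
    stop("visual trace must have n_steps + 1 samples");
  const double uin_const = (u_in.size() == 1) ? u_in[0] : 0.0;
  const bool has_inj = (i_inj.size() > 1);
  if (has_inj && i_inj.size() != n_steps + 1)
    stop("injected-current trace must have n_steps + 1 samples");

  NumericVector u_out(n_steps + 1);
  NumericVector m_out, h_out, n_out;
  if (keep_gates) {
    m_out = NumericVector(n_steps + 1);
    h_out = NumericVector(n_steps + 1);
    n_out = NumericVector(n_steps + 1);
  }

  double u = u0, m = m0, h = h0, n = n0;
  u_out[0] = u;
  if (keep_gates) { m_out[0] = m; h_out[0] = h; n_out[0] = n; }

  RNGScope rng;

  for (int k = 0; k < n_steps; ++k) {
    const int s1 = (S > 0) ? (k % S) : 0;
    const int s2 = (S > 0) ? ((k + 1) % S) : 0;
    const double uin1 = has_uin ? u_in[k] : uin_const;
    const double uin2 = has_uin ? u_in[k + 1] : uin_const;
    const double inj1 = has_inj ? i_inj[k] : 0.0;
    const double inj2 = has_inj ? i_inj[k + 1] : 0.0;

    double ie1 = inj1 + syn_current(u, s1, S, halt, nh, g_h, wing, nw, g_w,
                                    uin1, g_ins);
    HHDeriv k1 = hh_deriv(u, m, h, n, ie1, c_mn, gna, gk, gl, ena, ek, el);

    double up = u + dt * k1.du;
    double mp = m + dt * k1.dm;
    double hp = h + dt * k1.dh;
    double np = n + dt * k1.dn;

    double ie2 = inj2 + syn_current(up, s2, S, halt, nh, g_h, wing, nw, g_w,
                                    uin2, g_ins);
    HHDeriv k2 = hh_deriv(up, mp, hp, np, ie2, c_mn, gna, gk, gl, ena, ek, el);

    u += 0.5 * dt * (k1.du + k2.du);
    m = clamp01(m + 0.5 * dt * (k1.dm + k2.dm));
    h = clamp01(h + 0.5 * dt * (k1.dh + k2.dh));
    n = clamp01(n + 0.5 * dt * (k1.dn + k2.dn));

    if (noise_sd > 0.0) u += norm_rand() * noise_sd;

    if (!R_finite(u))
      stop("membrane potential became non-finite at t = %f ms", (k + 1) * dt);

    u_out[k + 1] = u;
    if (keep_gates) { m_out[k + 1] = m; h_out[k + 1] = h; n_out[k + 1] = n; }
  }

  List out = List::create(_["U"] = u_out);
  if (keep_gates) {
    out["m"] = m_out;
    out["h"] = h_out;
    out["n"] = n_out;
  }
  return out;
}
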