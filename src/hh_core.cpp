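#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// x / (1 - exp(-x/k)): the (V+c)-type rate kernel. Removable singularity at
// x = 0 replaced by its analytic limit k + x/2 within |x| < 1e-6.
static inline double efun(double x, double k) {
  if (std::fabs(x) < 1e-6) return k + 0.5 * x;
  return x / (1.0 - std::exp(-x / k));
}

struct HHRates {
  double am, bm, ah, bh, an, bn;
};

static inline HHRates hh_rates_at(double V) {
  HHRates r;
  r.am = 0.1 * efun(V + 40.0, 10.0);
  r.bm = 4.0 * std::exp(-(V + 65.0) / 18.0);
  r.ah = 0.07 * std::exp(-(V + 65.0) / 20.0);
  r.bh = 1.0 / (1.0 + std::exp(-(V + 35.0) / 10.0));
  r.an = 0.01 * efun(V + 55.0, 10.0);
  r.bn = 0.125 * std::exp(-(V + 65.0) / 80.0);
  return r;
}

// [[Rcpp::export]]
NumericMatrix hh_rates_cpp(NumericVector V) {
  int n = V.size();
  NumericMatrix out(n, 6);
  for (int i = 0; i < n; ++i) {
    if (!R_finite(V[i])) stop("non-finite membrane voltage");
    HHRates r = hh_rates_at(V[i]);
    out(i, 0) = r.am; out(i, 1) = r.bm;
    out(i, 2) = r.ah; out(i, 3) = r.bh;
    out(i, 4) = r.an; out(i, 5) = r.bn;
  }
  return out;
}

// Draw a multinomial over (p_1..p_m, stay) from n trials via sequential
// conditional binomials; moves[] receives counts per transition.
// Returns 1 if the total exit probability had to be clamped below 1.
static inline int multinomial_moves(int n, const double *p, int m, int *moves) {
  double ptot = 0.0;
  for (int k = 0; k < m; ++k) ptot += p[k];
  int clamped = 0;
  double scale = 1.0;
  if (ptot >= 1.0) { scale = 0.999 / ptot; clamped = 1; }
  int remaining = n;
  double prem = 1.0;
  for (int k = 0; k < m; ++k) {
    double pk = p[k] * scale;
    if (remaining <= 0 || pk <= 0.0) { moves[k] = 0; prem -= pk; continue; }
    double pc = pk / prem;
    if (pc > 1.0) pc = 1.0;
    int x = (int) ::Rf_rbinom((double) remaining, pc);
    moves[k] = x;
    remaining -= x;
    prem -= pk;
  }
  return clamped;
}

// One fixed-step update of the 8-state Na / 5-state K ensembles. Counts are
// updated from a snapshot so conservation and non-negativity hold by
// construction. na is a 4x2 grid (i = open m-particles, j = h state 0/1)
// stored column-major as in R; k has 5 entries (i = open n-particles).
// Returns the number of clamped source states (0 normally).
static int ensemble_step_inplace(int *na, int *kc, double V, double dt) {
  HHRates r = hh_rates_at(V);
  if (!R_finite(r.am + r.bm + r.ah + r.bh + r.an + r.bn))
    stop("non-finite gating rates (voltage blow-up?)");
  int clamped = 0;
  int dna[8] = {0, 0, 0, 0, 0, 0, 0, 0};
  double p[3];
  int mv[3];
  // Na: transitions up ((3-i)*am), down (i*bm), h-flip (ah from j=0, bh from j=1)
  for (int j = 0; j < 2; ++j) {
    for (int i = 0; i < 4; ++i) {
      int idx = i + 4 * j;
      int n = na[idx];
      if (n == 0) continue;
      int m = 0;
      int tgt[3];
      if (i < 3) { p[m] = (3 - i) * r.am * dt; tgt[m] = (i + 1) + 4 * j; ++m; }
      if (i > 0) { p[m] = i * r.bm * dt;       tgt[m] = (i - 1) + 4 * j; ++m; }
      p[m] = (j == 0 ? r.ah : r.bh) * dt; tgt[m] = i + 4 * (1 - j); ++m;
      clamped += multinomial_moves(n, p, m, mv);
      for (int k = 0; k < m; ++k) {
        dna[idx] -= mv[k];
        dna[tgt[k]] += mv[k];
      }
    }
  }
  int dk[5] = {0, 0, 0, 0, 0};
  for (int i = 0; i < 5; ++i) {
    int n = kc[i];
    if (n == 0) continue;
    int m = 0;
    int tgt[2];
    if (i < 4) { p[m] = (4 - i) * r.an * dt; tgt[m] = i + 1; ++m; }
    if (i > 0) { p[m] = i * r.bn * dt;       tgt[m] = i - 1; ++m; }
    clamped += multinomial_moves(n, p, m, mv);
    for (int k = 0; k < m; ++k) {
      dk[i] -= mv[k];
      dk[tgt[k]] += mv[k];
    }
  }
  for (int s = 0; s < 8; ++s) na[s] += dna[s];
  for (int s = 0; s < 5; ++s) kc[s] += dk[s];
  return clamped;
}

// [[Rcpp::export]]
List ensemble_step_cpp(IntegerMatrix na, IntegerVector k, double V, double dt,
                       int n_steps) {
  if (na.nrow() != 4 || na.ncol() != 2 || k.size() != 5)
    stop("bad ensemble state shape");
  int nac[8], kc[5];
  for (int s = 0; s < 8; ++s) nac[s] = na[s];
  for (int s = 0; s < 5; ++s) kc[s] = k[s];
  int clamped = 0;
  for (int t = 0; t < n_steps; ++t)
    clamped += ensemble_step_inplace(nac, kc, V, dt);
  IntegerMatrix na_out(4, 2);
  IntegerVector k_out(5);
  for (int s = 0; s < 8; ++s) na_out[s] = nac[s];
  for (int s = 0; s < 5; ++s) k_out[s] = kc[s];
  return List::create(_["na"] = na_out, _["k"] = k_out,
                      _["clamped"] = clamped);
}

// Voltage-clamped ensemble run returning the open-channel counts at every
// step (used for stationarity checks against the binomial law).
// [[Rcpp::export]]
List ensemble_clamp_cpp(IntegerMatrix na, IntegerVector k, double V, double dt,
                        int n_steps) {
  int nac[8], kc[5];
  for (int s = 0; s < 8; ++s) nac[s] = na[s];
  for (int s = 0; s < 5; ++s) kc[s] = k[s];
  IntegerVector open_na(n_steps), open_k(n_steps);
  int clamped = 0;
  for (int t = 0; t < n_steps; ++t) {
    clamped += ensemble_step_inplace(nac, kc, V, dt);
    open_na[t] = nac[3 + 4 * 1];
    open_k[t] = kc[4];
  }
  IntegerMatrix na_out(4, 2);
  IntegerVector k_out(5);
  for (int s = 0; s < 8; ++s) na_out[s] = nac[s];
  for (int s = 0; s < 5; ++s) k_out[s] = kc[s];
  return List::create(_["open_na"] = open_na, _["open_k"] = open_k,
                      _["na"] = na_out, _["k"] = k_out,
                      _["clamped"] = clamped);
}

// Expected-value (deterministic-limit) update of the 13-state master
// equation: one forward-Euler step on fractional occupancies.
// [[Rcpp::export]]
List master_equation_step_cpp(NumericMatrix na, NumericVector k, double V,
                              double dt, int n_steps) {
  double nac[8], kc[5];
  for (int s = 0; s < 8; ++s) nac[s] = na[s];
  for (int s = 0; s < 5; ++s) kc[s] = k[s];
  for (int t = 0; t < n_steps; ++t) {
    HHRates r = hh_rates_at(V);
    double dna[8] = {0, 0, 0, 0, 0, 0, 0, 0};
    for (int j = 0; j < 2; ++j) {
      for (int i = 0; i < 4; ++i) {
        int idx = i + 4 * j;
        double n = nac[idx];
        if (i < 3) { double f = n * (3 - i) * r.am * dt; dna[idx] -= f; dna[idx + 1] += f; }
        if (i > 0) { double f = n * i * r.bm * dt;       dna[idx] -= f; dna[idx - 1] += f; }
        double fh = n * (j == 0 ? r.ah : r.bh) * dt;
        dna[idx] -= fh; dna[i + 4 * (1 - j)] += fh;
      }
    }
    double dk[5] = {0, 0, 0, 0, 0};
    for (int i = 0; i < 5; ++i) {
      double n = kc[i];
      if (i < 4) { double f = n * (4 - i) * r.an * dt; dk[i] -= f; dk[i + 1] += f; }
      if (i > 0) { double f = n * i * r.bn * dt;       dk[i] -= f; dk[i - 1] += f; }
    }
    for (int s = 0; s < 8; ++s) nac[s] += dna[s];
    for (int s = 0; s < 5; ++s) kc[s] += dk[s];
  }
  NumericMatrix na_out(4, 2);
  NumericVector k_out(5);
  for (int s = 0; s < 8; ++s) na_out[s] = nac[s];
  for (int s = 0; s < 5; ++s) k_out[s] = kc[s];
  return List::create(_["na"] = na_out, _["k"] = k_out);
}

// Gaussian noise with Lorentzian PSD: AR(1) x_t = a x_{t-1} + w_t with
// a = exp(-omega_c * dt_s) and innovation sd sqrt(D (1 - a^2)), so the
// stationary variance is exactly D. State starts from N(0, D) and a warm-up
// of 5/omega_c seconds is generated and discarded.
// [[Rcpp::export]]
NumericVector lorentzian_noise_cpp(int n_steps, double dt_ms, double D,
                                   double omega_c) {
  if (D < 0) stop("noise power D must be non-negative");
  NumericVector out(n_steps);
  if (D == 0.0) return out;
  double dt_s = dt_ms * 1e-3;
  double a = std::exp(-omega_c * dt_s);
  double sw = std::sqrt(D * (1.0 - a * a));
  double x = ::norm_rand() * std::sqrt(D);
  int warm = (int) std::ceil(5.0 / omega_c / dt_s);
  for (int t = 0; t < warm; ++t) x = a * x + sw * ::norm_rand();
  for (int t = 0; t < n_steps; ++t) {
    x = a * x + sw * ::norm_rand();
    out[t] = x;
  }
  return out;
}

// Stochastic membrane run: forward Euler on the physiological voltage V with
// the channel ensembles gated by V_tot = V + V_ES + V_noise. perturb[] holds
// V_ES + V_noise at each step (length n_steps; perturb[k] applies at step k).
// Conductance conversion: gamma (pS) * N_open / area (um^2) -> mS/cm^2 is
// gamma * N / (area * 10).
// [[Rcpp::export]]
List hh_run_cpp(int n_steps, double dt, double area,
                IntegerMatrix na0, IntegerVector k0,
                double V0, double I0, NumericVector perturb,
                double gamma_na, double gamma_k,
                double Cm, double gL, double VNa, double VK, double VL,
                bool keep_total, bool keep_open) {
  if (perturb.size() < n_steps) stop("perturbation series too short");
  int nac[8], kc[5];
  for (int s = 0; s < 8; ++s) nac[s] = na0[s];
  for (int s = 0; s < 5; ++s) kc[s] = k0[s];
  const double gconv_na = gamma_na * 1e-1 / area;  // pS/um^2 -> mS/cm^2
  const double gconv_k = gamma_k * 1e-1 / area;
  NumericVector V(n_steps + 1);
  NumericVector Vtot_out(keep_total ? n_steps + 1 : 0);
  IntegerVector open_na(keep_open ? n_steps + 1 : 0);
  IntegerVector open_k(keep_open ? n_steps + 1 : 0);
  double V_ = V0;
  V[0] = V_;
  if (keep_total) Vtot_out[0] = V_ + perturb[0];
  if (keep_open) { open_na[0] = nac[7]; open_k[0] = kc[4]; }
  int clamped = 0;
  bool diverged = false;
  int t = 0;
  for (t = 0; t < n_steps; ++t) {
    double Vtot = V_ + perturb[t];
    double gna = gconv_na * nac[7];   // open Na: state (3,1)
    double gk = gconv_k * kc[4];      // open K: state 4
    double dV = (-gna * (Vtot - VNa) - gk * (Vtot - VK) - gL * (Vtot - VL)
                 + I0) * dt / Cm;
    clamped += ensemble_step_inplace(nac, kc, Vtot, dt);
    V_ += dV;
    if (!R_finite(V_) || std::fabs(V_) > 200.0) { diverged = true; break; }
    V[t + 1] = V_;
    if (keep_total)
      Vtot_out[t + 1] = V_ + perturb[t + 1 < n_steps ? t + 1 : n_steps - 1];
    if (keep_open) { open_na[t + 1] = nac[7]; open_k[t + 1] = kc[4]; }
  }
  IntegerMatrix na_out(4, 2);
  IntegerVector k_out(5);
  for (int s = 0; s < 8; ++s) na_out[s] = nac[s];
  for (int s = 0; s < 5; ++s) k_out[s] = kc[s];
  return List::create(_["V"] = V, _["V_total"] = Vtot_out,
                      _["open_na"] = open_na, _["open_k"] = open_k,
                      _["na"] = na_out, _["k"] = k_out,
                      _["clamped"] = clamped, _["diverged"] = diverged,
                      _["steps_done"] = t);
}

// Deterministic HH run: gating variables m, h, n as ODEs, conductances
// gbar_na m^3 h and gbar_k n^4, same series perturbation convention.
// [[Rcpp::export]]
List hh_run_det_cpp(int n_steps, double dt,
                    double m0, double h0, double n0,
                    double V0, double I0, NumericVector perturb,
                    double gbar_na, double gbar_k,
                    double Cm, double gL, double VNa, double VK, double VL) {
  double V_ = V0, m = m0, h = h0, nn = n0;
  NumericVector V(n_steps + 1);
  V[0] = V_;
  bool diverged = false;
  int t;
  for (t = 0; t < n_steps; ++t) {
    double Vtot = V_ + (perturb.size() > 0 ? perturb[t] : 0.0);
    HHRates r = hh_rates_at(Vtot);
    double gna = gbar_na * m * m * m * h;
    double gk = gbar_k * nn * nn * nn * nn;
    double dV = (-gna * (Vtot - VNa) - gk * (Vtot - VK) - gL * (Vtot - VL)
                 + I0) * dt / Cm;
    m += (r.am * (1.0 - m) - r.bm * m) * dt;
    h += (r.ah * (1.0 - h) - r.bh * h) * dt;
    nn += (r.an * (1.0 - nn) - r.bn * nn) * dt;
    V_ += dV;
    if (!R_finite(V_) || std::fabs(V_) > 200.0) { diverged = true; break; }
    V[t + 1] = V_;
  }
  return List::create(_["V"] = V, _["m"] = m, _["h"] = h, _["n"] = nn,
                      _["diverged"] = diverged, _["steps_done"] = t);
}
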