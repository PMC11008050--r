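#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Sigmoidal f-I curve shared by both populations. The removable singularity
// at the threshold current is handled by its first-order expansion
// (limit 1/d), keeping the function continuous and strictly increasing.
static inline double fi_curve(double I, double g, double Ithr, double d) {
  double y = g * (I - Ithr);
  double dy = d * y;
  if (std::fabs(dy) < 1e-8) return 1.0 / d + 0.5 * y;
  return y / (1.0 - std::exp(-dy));
}

// [[Rcpp::export]]
double transfer_rate_cpp(double I, double g, double Ithr, double d) {
  return fi_curve(I, g, Ithr, d);
}

// Euler-Maruyama integration of the coupled excitatory/inhibitory
// neural-mass equations. Gating variables are clipped to [0,1] after every
// step; the burn-in is discarded. Uses R's RNG (two standard-normal draws
// per node per step), so results are reproducible under set.seed().
//
// Returns mean post-burn excitatory rate per node (computed at full
// resolution) plus rate/gating series stored every `store_every` steps.
// [[Rcpp::export]]
List dmf_integrate_cpp(NumericMatrix C, NumericVector J, List par,
                       bool store_rates = true, bool store_gating = false,
                       int store_every = 1,
                       Nullable<NumericVector> S_E0 = R_NilValue,
                       Nullable<NumericVector> S_I0 = R_NilValue) {
  const int N = C.nrow();
  if (C.ncol() != N) stop("connectome must be square");
  if (J.size() != N) stop("FIC vector length does not match connectome");

  const double I0      = par["I0"];
  const double W_E     = par["W_E"];
  const double W_I     = par["W_I"];
  const double W_plus  = par["W_plus"];
  const double J_NMDA  = par["J_NMDA"];
  const double G       = par["G"];
  const double g_E     = par["g_E"];
  const double g_I     = par["g_I"];
  const double Ithr_E  = par["I_thr_E"];
  const double Ithr_I  = par["I_thr_I"];
  const double d_E     = par["d_E"];
  const double d_I     = par["d_I"];
  const double tau_N   = par["tau_NMDA"];
  const double tau_G   = par["tau_GABA"];
  const double gamma_k = par["gamma"];
  const double sigma_g = par["sigma_g"];
  const double dt      = par["dt"];
  const double t_total = par["t_total"];
  const double t_burn  = par["t_burn"];

  const int n_steps = (int) std::lround(t_total / dt);
  const int n_burn  = (int) std::lround(t_burn / dt);
  if (n_steps <= n_burn) stop("t_total must exceed t_burn");
  const int n_keep  = n_steps - n_burn;
  const int n_store = store_every > 0 ? n_keep / store_every : 0;
  const double sq_noise = sigma_g * std::sqrt(dt);

  std::vector<double> S_E(N, 0.1), S_I(N, 0.1), lr(N), rate_sum(N, 0.0);
  if (S_E0.isNotNull()) {
    NumericVector s0(S_E0);
    if (s0.size() != N) stop("S_E0 length mismatch");
    for (int n = 0; n < N; ++n) S_E[n] = s0[n];
  }
  if (S_I0.isNotNull()) {
    NumericVector s0(S_I0);
    if (s0.size() != N) stop("S_I0 length mismatch");
    for (int n = 0; n < N; ++n) S_I[n] = s0[n];
  }
  NumericMatrix r_store(store_rates ? n_store : 0, store_rates ? N : 0);
  NumericMatrix s_store(store_gating ? n_store : 0, store_gating ? N : 0);
  const double *cp = REAL(C);       // column-major; symmetric, so columns
  const double *Jp = REAL(J);       // double as rows in the afferent sum
  double *rsp = store_rates ? REAL(r_store) : nullptr;
  double *ssp = store_gating ? REAL(s_store) : nullptr;
  const double ext_E = W_E * I0, ext_I = W_I * I0;

  for (int t = 0; t < n_steps; ++t) {
    bool kept = t >= n_burn;
    int k = kept ? t - n_burn : -1;
    bool stored = kept && store_every > 0 && ((k + 1) % store_every == 0);
    long row = stored ? (k + 1) / store_every - 1 : -1;

    // long-range input: column sweep over the (symmetric) connectome
    std::fill(lr.begin(), lr.end(), 0.0);
    for (int p = 0; p < N; ++p) {
      const double s = S_E[p];
      if (s == 0.0) continue;
      const double *col = cp + (size_t) p * N;
      for (int n = 0; n < N; ++n) lr[n] += col[n] * s;
    }

    for (int n = 0; n < N; ++n) {
      double I_E = ext_E + W_plus * J_NMDA * S_E[n]
                 + G * J_NMDA * lr[n] - Jp[n] * S_I[n];
      double I_I = ext_I + J_NMDA * S_E[n] - S_I[n];
      double r_E = fi_curve(I_E, g_E, Ithr_E, d_E);
      double r_I = fi_curve(I_I, g_I, Ithr_I, d_I);

      if (kept) rate_sum[n] += r_E;
      if (stored) {
        if (rsp) rsp[row + (size_t) n * n_store] = r_E;
        if (ssp) ssp[row + (size_t) n * n_store] = S_E[n];
      }

      double sE = S_E[n] + dt * (-S_E[n] / tau_N
                  + (1.0 - S_E[n]) * gamma_k * r_E)
                  + sq_noise * norm_rand();
      double sI = S_I[n] + dt * (-S_I[n] / tau_G + r_I)
                  + sq_noise * norm_rand();
      S_E[n] = sE < 0.0 ? 0.0 : (sE > 1.0 ? 1.0 : sE);
      S_I[n] = sI < 0.0 ? 0.0 : (sI > 1.0 ? 1.0 : sI);
    }

    if ((t & 1023) == 0) {
      for (int n = 0; n < N; ++n) {
        if (!std::isfinite(S_E[n]) || !std::isfinite(S_I[n]))
          stop("numerical blow-up (non-finite gating) at t = %f s; "
               "reduce the integration step dt = %f s", t * dt, dt);
      }
    }
  }

  NumericVector mean_rate(N);
  for (int n = 0; n < N; ++n) mean_rate[n] = rate_sum[n] / n_keep;

  return List::create(_["mean_rate"] = mean_rate,
                      _["r_E_series"] = r_store,
                      _["S_E_series"] = s_store,
                      _["n_kept_steps"] = n_keep,
                      _["store_every"] = store_every,
                      _["S_E_final"] = NumericVector(S_E.begin(), S_E.end()),
                      _["S_I_final"] = NumericVector(S_I.begin(), S_I.end()));
}

// Fixed-point residual of the deterministic equations at a given state:
// returns c(dS_E, dS_I) stacked, used to verify noise-free equilibria.
// [[Rcpp::export]]
NumericVector dmf_drift_cpp(NumericMatrix C, NumericVector J, List par,
                            NumericVector S_E, NumericVector S_I) {
  const int N = C.nrow();
  const double I0 = par["I0"], W_E = par["W_E"], W_I = par["W_I"];
  const double W_plus = par["W_plus"], J_NMDA = par["J_NMDA"], G = par["G"];
  const double g_E = par["g_E"], g_I = par["g_I"];
  const double Ithr_E = par["I_thr_E"], Ithr_I = par["I_thr_I"];
  const double d_E = par["d_E"], d_I = par["d_I"];
  const double tau_N = par["tau_NMDA"], tau_G = par["tau_GABA"];
  const double gamma_k = par["gamma"];
  NumericVector out(2 * N);
  for (int n = 0; n < N; ++n) {
    double lr = 0.0;
    for (int p = 0; p < N; ++p) lr += C(n, p) * S_E[p];
    double I_E = W_E * I0 + W_plus * J_NMDA * S_E[n]
               + G * J_NMDA * lr - J[n] * S_I[n];
    double I_I = W_I * I0 + J_NMDA * S_E[n] - S_I[n];
    double r_E = fi_curve(I_E, g_E, Ithr_E, d_E);
    double r_I = fi_curve(I_I, g_I, Ithr_I, d_I);
    out[n] = -S_E[n] / tau_N + (1.0 - S_E[n]) * gamma_k * r_E;
    out[N + n] = -S_I[n] / tau_G + r_I;
  }
  return out;
}

// Balloon-Windkessel hemodynamics, Euler-integrated per region at the
// neural step dt and decimated to every `sample_every`-th step.
// x: time x region neural drive (already z-scored and scaled upstream).
// [[Rcpp::export]]
NumericMatrix bw_bold_cpp(NumericMatrix x, List bw, double dt,
                          int sample_every) {
  const int T = x.nrow(), N = x.ncol();
  const double kappa  = bw["kappa"];
  const double gammaf = bw["gamma_f"];
  const double tau    = bw["tau"];
  const double alphag = bw["alpha_g"];
  const double rho    = bw["rho"];
  const double V0     = bw["V0"];
  const double k1 = 7.0 * rho, k2 = 2.0, k3 = 2.0 * rho - 0.2;
  const double inv_alpha = 1.0 / alphag;
  const double log1mrho = std::log(1.0 - rho);

  const int n_out = sample_every > 0 ? T / sample_every : 0;
  NumericMatrix out(n_out, N);

  for (int n = 0; n < N; ++n) {
    double z = 0.0, f = 1.0, v = 1.0, q = 1.0;
    for (int t = 0; t < T; ++t) {
      double fv = std::pow(v, inv_alpha);
      double E  = (1.0 - std::exp(log1mrho / f)) / rho;
      double dz = x(t, n) - kappa * z - gammaf * (f - 1.0);
      double df = z;
      double dv = (f - fv) / tau;
      double dq = (f * E - fv * q / v) / tau;
      z += dt * dz; f += dt * df; v += dt * dv; q += dt * dq;
      if (f < 1e-4) f = 1e-4;
      if (v < 1e-4) v = 1e-4;
      if ((t + 1) % sample_every == 0) {
        int row = (t + 1) / sample_every - 1;
        if (row < n_out)
          out(row, n) = V0 * (k1 * (1.0 - q) + k2 * (1.0 - q / v)
                              + k3 * (1.0 - v));
      }
      if ((t & 2047) == 0 && (!std::isfinite(q) || !std::isfinite(v)))
        stop("non-finite hemodynamic state in region %d", n + 1);
    }
  }
  return out;
}
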