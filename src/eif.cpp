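#include <Rcpp.h>
using namespace Rcpp;

// Fixed-step Euler integration of an exponential integrate-and-fire neuron
// with a spike-triggered AHP conductance and a subthreshold adaptation
// current:
//   C dV/dt = -gL (V - EL) + gL DeltaT exp((V - VT)/DeltaT)
//             + I(t) - w - gAHP (V - EK)
//   tau_w  dw/dt     = a (V - EL) - w
//   tau_ahp dgAHP/dt = -gAHP,  gAHP += b_ahp at each spike
// When V crosses v_cut a stereotyped action-potential waveform is pasted
// (so that downstream 0 mV-crossing spike detection is exercised) and V
// resumes from v_reset. Units: mV, pA, nS, pF, ms.
//
// Band-limited recording noise (OU, correlation time tau_n, stationary SD
// sigma) is generated from R's RNG and added to the returned noisy matrix;
// the clean matrix is the deterministic integration.
//
// Returns: v (noisy, samples x sweeps), v_clean (only when sigma > 0),
// spike_times (interpolated upward 0 mV crossing inside the pasted wave).

// [[Rcpp::export(name = ".eif_integrate")]]
List eif_integrate(NumericVector amps, double holding,
                   int n_pre, int n_step, int n_post, double dt,
                   List params, NumericVector ap_wave,
                   double sigma, double tau_n) {
  const double gL    = params["g_l"];
  const double C     = params["c_m"];
  const double EL    = params["e_l"];
  const double VT    = params["v_t"];
  const double DT    = params["delta_t"];
  const double Vre   = params["v_reset"];
  const double Vcut  = params["v_cut"];
  const double bAHP  = params["b_ahp"];
  const double tAHP  = params["tau_ahp"];
  const double EK    = params["e_k"];
  const double aw    = params["a_w"];
  const double tw    = params["tau_w"];

  const int n_tot = n_pre + n_step + n_post;
  const int n_sw  = amps.size();
  const int n_ap  = ap_wave.size();
  NumericMatrix V(n_tot, n_sw);
  List spikes(n_sw);

  // interpolated upward 0 mV crossing offset inside the pasted waveform
  double cross_off = NA_REAL;
  for (int k = 1; k < n_ap; ++k) {
    if (ap_wave[k - 1] < 0.0 && ap_wave[k] >= 0.0) {
      double f = (0.0 - ap_wave[k - 1]) / (ap_wave[k] - ap_wave[k - 1]);
      cross_off = (k - 1 + f) * dt;
      break;
    }
  }

  // below VT - 10 DT the exponential term is < 5e-4 pA for typical
  // parameters: skip it (keeps the subthreshold path branch-cheap)
  const double exp_guard = VT - 10.0 * DT;
  const double ahp_decay = std::exp(-dt / tAHP);
  const double dt_C = dt / C;
  const bool has_w = aw != 0.0;

  RNGScope rng;
  for (int s = 0; s < n_sw; ++s) {
    double *col = &V(0, s);
    const double amp = amps[s];
    double v = EL + holding / gL;
    double w = aw * (v - EL);
    double g = 0.0;
    std::vector<double> st;
    int i = 0;
    while (i < n_tot) {
      double I = holding + ((i >= n_pre && i < n_pre + n_step) ? amp : 0.0);
      double drive = -gL * (v - EL) + I - w - g * (v - EK);
      if (v > exp_guard) drive += gL * DT * std::exp((v - VT) / DT);
      double v_new = v + dt_C * drive;
      if (has_w) w += dt * (aw * (v - EL) - w) / tw;
      g *= ahp_decay;
      if (v_new >= Vcut) {
        // paste the stereotyped AP waveform, truncating at sweep end
        if (!ISNA(cross_off)) st.push_back(i * dt + cross_off);
        g += bAHP;
        for (int k = 0; k < n_ap && i < n_tot; ++k, ++i) {
          col[i] = ap_wave[k];
          if (has_w) w += dt * (aw * (ap_wave[k] - EL) - w) / tw;
          g *= ahp_decay;
        }
        v = Vre;
        continue;
      }
      if (!std::isfinite(v_new))
        stop("eif_integrate: state became non-finite (sweep %d)", s + 1);
      col[i] = v;
      v = v_new;
      ++i;
    }
    spikes[s] = NumericVector(st.begin(), st.end());
  }

  if (sigma <= 0.0)
    return List::create(_["v"] = V, _["v_clean"] = R_NilValue,
                        _["spike_times"] = spikes);

  // Band-limited noise: OU generated on a 4x coarser grid and linearly
  // interpolated back to dt (the OU correlation time is >> 4 dt, so the
  // interpolation leaves the spectrum essentially unchanged).
  NumericMatrix Vn(n_tot, n_sw);
  const int sub = 4;
  const double rho = std::exp(-sub * dt / tau_n);
  const double innov = sigma * std::sqrt(1.0 - rho * rho);
  for (int s = 0; s < n_sw; ++s) {
    const double *clean = &V(0, s);
    double *noisy = &Vn(0, s);
    double eta0 = sigma * norm_rand();  // stationary start, per sweep
    for (int i = 0; i < n_tot; i += sub) {
      double eta1 = rho * eta0 + innov * norm_rand();
      const int nseg = std::min(sub, n_tot - i);
      for (int k = 0; k < nseg; ++k)
        noisy[i + k] = clean[i + k] + eta0 + (eta1 - eta0) * k / sub;
      eta0 = eta1;
    }
  }
  return List::create(_["v"] = Vn, _["v_clean"] = V,
                      _["spike_times"] = spikes);
}

// Upward threshold crossings of each column, linearly interpolated; returns
// per-column fractional sample positions (0-based), i.e. time / dt.
// [[Rcpp::export(name = ".upward_crossings")]]
List upward_crossings(NumericMatrix v, double level) {
  const int n = v.nrow(), m = v.ncol();
  List out(m);
  for (int s = 0; s < m; ++s) {
    const double *col = &v(0, s);
    std::vector<double> pos;
    for (int i = 1; i < n; ++i) {
      if (col[i - 1] < level && col[i] >= level) {
        double f = (level - col[i - 1]) / (col[i] - col[i - 1]);
        pos.push_back(i - 1 + f);
      }
    }
    out[s] = NumericVector(pos.begin(), pos.end());
  }
  return out;
}

// Clements-Bekkers sliding fit: for each lag the template w (length N) is
// fitted to the trace window by least squares in scale and offset; returns
// the fitted scale and the detection criterion scale/SE(scale).
// [[Rcpp::export(name = ".cb_criterion")]]
List cb_criterion(NumericVector y, NumericVector w) {
  const int M = y.size(), N = w.size();
  const int n_lag = M - N + 1;
  if (n_lag < 1) stop("cb_criterion: trace shorter than template");
  double st = 0, stt = 0;
  for (int j = 0; j < N; ++j) { st += w[j]; stt += w[j] * w[j]; }
  const double sxt = stt - st * st / N;

  NumericVector scale(n_lag), crit(n_lag);
  double sy = 0, sy2 = 0;
  for (int j = 0; j < N; ++j) { sy += y[j]; sy2 += y[j] * y[j]; }
  const double *yp = REAL(y);
  const double *wp = REAL(w);
  for (int i = 0; i < n_lag; ++i) {
    double sty = 0;
    const double *yi = yp + i;
    for (int j = 0; j < N; ++j) sty += wp[j] * yi[j];
    double s = (sty - st * sy / N) / sxt;
    double sse = (sy2 - sy * sy / N) - s * s * sxt;
    if (sse < 0) sse = 0;
    double se = std::sqrt(sse / (N - 2) / sxt);
    scale[i] = s;
    crit[i] = (se > 0) ? s / se : 0.0;
    if (i + 1 < n_lag) {
      sy += yp[i + N] - yp[i];
      sy2 += yp[i + N] * yp[i + N] - yp[i] * yp[i];
    }
  }
  return List::create(_["scale"] = scale, _["criterion"] = crit);
}
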