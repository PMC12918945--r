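#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Two-compartment motor neuron: active soma (Na+, fast K+, slow K+
// conductances, four gating variables with threshold-switched "pulse"
// rate constants) electrotonically coupled to a passive dendrite.
//
// Integration: Rush-Larsen (exact exponential) updates for the gating
// variables -- the switched rates are piecewise constant, so the decay
// factors can be precomputed -- and a semi-implicit Euler update for the
// two membrane potentials, which is unconditionally stable.
//
// Parameter vector layout (all indices fixed, see mn_par_index() in R):
//  0 Cs (nF)    1 Cd (nF)    2 gls (uS)   3 gld (uS)   4 gc (uS)
//  5 gNa (uS)   6 gKf (uS)   7 gKs (uS)
//  8 ENa (mV)   9 EK (mV)   10 EL (mV)   11 Vgate (mV)
// 12 am 13 bm 14 ah 15 bh 16 an 17 bn 18 aq 19 bq   (ms^-1)
// 20 Vdetect (mV)  21 lockout (ms)

// [[Rcpp::export]]
List cpp_simulate_mn(NumericVector par, NumericVector input, double dt,
                     bool record_v) {
  if (par.size() < 22) stop("parameter vector too short");
  if (dt <= 0 || dt > 0.1) stop("dt must lie in (0, 0.1] ms");
  const double Cs = par[0], Cd = par[1], gls = par[2], gld = par[3],
               gc = par[4], gNa = par[5], gKf = par[6], gKs = par[7],
               ENa = par[8], EK = par[9], EL = par[10], Vgate = par[11],
               am = par[12], bm = par[13], ah = par[14], bh = par[15],
               an = par[16], bn = par[17], aq = par[18], bq = par[19],
               Vdet = par[20], lockout = par[21];
  const int n = input.size();

  // precomputed Rush-Larsen decay factors for gate above/below threshold
  const double em_on = std::exp(-dt * am), em_off = std::exp(-dt * bm);
  const double eh_on = std::exp(-dt * bh), eh_off = std::exp(-dt * ah);
  const double en_on = std::exp(-dt * an), en_off = std::exp(-dt * bn);
  const double eq_on = std::exp(-dt * aq), eq_off = std::exp(-dt * bq);

  double Vs = EL, Vd = EL, m = 0.0, h = 1.0, gn = 0.0, q = 0.0;
  const double gd_tot = gld + gc;

  std::vector<double> spikes;
  spikes.reserve(1024);
  NumericVector vtrace;
  if (record_v) vtrace = NumericVector(n);
  double last_spike = -1e18;

  for (int i = 0; i < n; ++i) {
    const bool gate = Vs > Vgate;
    // gating: exact update toward 0 or 1 at the switched rate
    if (gate) {
      m = 1.0 + (m - 1.0) * em_on;
      h *= eh_on;
      gn = 1.0 + (gn - 1.0) * en_on;
      q = 1.0 + (q - 1.0) * eq_on;
    } else {
      m *= em_off;
      h = 1.0 + (h - 1.0) * eh_off;
      gn *= en_off;
      q *= eq_off;
    }
    const double m2 = m * m;
    const double n2 = gn * gn;
    const double gna_t = gNa * m2 * m * h;
    const double gkf_t = gKf * n2 * n2;
    const double gks_t = gKs * q * q;
    const double gtot = gna_t + gkf_t + gks_t + gls + gc;
    const double num = gna_t * ENa + (gkf_t + gks_t) * EK + gls * EL +
                       gc * Vd + input[i];
    const double Vs_new = (Cs * Vs + dt * num) / (Cs + dt * gtot);
    const double Vd_new = (Cd * Vd + dt * (gld * EL + gc * Vs)) /
                          (Cd + dt * gd_tot);
    // upward crossing of the detection level, with refractory lockout
    if (Vs < Vdet && Vs_new >= Vdet) {
      const double tc = i * dt + dt * (Vdet - Vs) / (Vs_new - Vs);
      if (tc - last_spike > lockout) {
        spikes.push_back(tc);
        last_spike = tc;
      }
    }
    Vs = Vs_new;
    Vd = Vd_new;
    if (record_v) vtrace[i] = Vs;
    if ((i & 0x3FFF) == 0 && !std::isfinite(Vs))
      stop("membrane potential diverged (non-finite) at t = %f ms", i * dt);
  }
  if (!std::isfinite(Vs))
    stop("membrane potential diverged (non-finite) at end of integration");

  List out = List::create(
      _["spike_times"] = NumericVector(spikes.begin(), spikes.end()),
      _["v_end"] = Vs);
  if (record_v) out["v"] = vtrace;
  return out;
}

// Spike times only, for long pool runs where the voltage trace is not kept.
// [[Rcpp::export]]
NumericVector cpp_spike_times(NumericVector par, NumericVector input,
                              double dt) {
  List r = cpp_simulate_mn(par, input, dt, false);
  return r["spike_times"];
}

// Pool-run fast path: the injected current is a shared fine-grid base
// (mean drive + common noise + EPSC train) plus this neuron's band-limited
// independent noise, supplied on the coarse synthesis grid and linearly
// interpolated on the fly.  Avoids per-neuron fine-grid temporaries.
// [[Rcpp::export]]
NumericVector cpp_spike_times_base_noise(NumericVector par,
                                         NumericVector base,
                                         NumericVector noise_coarse,
                                         int ratio, double dt) {
  if (par.size() < 22) stop("parameter vector too short");
  if (dt <= 0 || dt > 0.1) stop("dt must lie in (0, 0.1] ms");
  const int n = base.size();
  if ((int)noise_coarse.size() < n / ratio + 2)
    stop("coarse noise trace too short for the fine grid");
  const double Cs = par[0], Cd = par[1], gls = par[2], gld = par[3],
               gc = par[4], gNa = par[5], gKf = par[6], gKs = par[7],
               ENa = par[8], EK = par[9], EL = par[10], Vgate = par[11],
               am = par[12], bm = par[13], ah = par[14], bh = par[15],
               an = par[16], bn = par[17], aq = par[18], bq = par[19],
               Vdet = par[20], lockout = par[21];
  const double em_on = std::exp(-dt * am), em_off = std::exp(-dt * bm);
  const double eh_on = std::exp(-dt * bh), eh_off = std::exp(-dt * ah);
  const double en_on = std::exp(-dt * an), en_off = std::exp(-dt * bn);
  const double eq_on = std::exp(-dt * aq), eq_off = std::exp(-dt * bq);
  const double inv_ratio = 1.0 / ratio;

  double Vs = EL, Vd = EL, m = 0.0, h = 1.0, gn = 0.0, q = 0.0;
  const double gd_tot = gld + gc;
  std::vector<double> spikes;
  spikes.reserve(1024);
  double last_spike = -1e18;

  for (int i = 0; i < n; ++i) {
    const int j = i / ratio;
    const double frac = (i - j * ratio) * inv_ratio;
    const double I = base[i] +
      noise_coarse[j] + (noise_coarse[j + 1] - noise_coarse[j]) * frac;
    const bool gate = Vs > Vgate;
    if (gate) {
      m = 1.0 + (m - 1.0) * em_on;
      h *= eh_on;
      gn = 1.0 + (gn - 1.0) * en_on;
      q = 1.0 + (q - 1.0) * eq_on;
    } else {
      m *= em_off;
      h = 1.0 + (h - 1.0) * eh_off;
      gn *= en_off;
      q *= eq_off;
    }
    const double m2 = m * m;
    const double n2 = gn * gn;
    const double gna_t = gNa * m2 * m * h;
    const double gkf_t = gKf * n2 * n2;
    const double gks_t = gKs * q * q;
    const double gtot = gna_t + gkf_t + gks_t + gls + gc;
    const double num = gna_t * ENa + (gkf_t + gks_t) * EK + gls * EL +
                       gc * Vd + I;
    const double Vs_new = (Cs * Vs + dt * num) / (Cs + dt * gtot);
    const double Vd_new = (Cd * Vd + dt * (gld * EL + gc * Vs)) /
                          (Cd + dt * gd_tot);
    if (Vs < Vdet && Vs_new >= Vdet) {
      const double tc = i * dt + dt * (Vdet - Vs) / (Vs_new - Vs);
      if (tc - last_spike > lockout) {
        spikes.push_back(tc);
        last_spike = tc;
      }
    }
    Vs = Vs_new;
    Vd = Vd_new;
    if ((i & 0x3FFF) == 0 && !std::isfinite(Vs))
      stop("membrane potential diverged (non-finite) at t = %f ms", i * dt);
  }
  if (!std::isfinite(Vs))
    stop("membrane potential diverged (non-finite) at end of integration");
  return NumericVector(spikes.begin(), spikes.end());
}
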