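// Forward-Euler inner loop of the coupled neurone-astrocyte cradle model.
// Mirrors the R-level pathway functions exactly (the test suite cross-checks
// recorded currents against their R implementations at recorded states).
#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

namespace {

struct Pars {
  // geometry
  double SA_PsC, Vol_PsC, Vol_PsECS, SA_Syn, SA_ECSL, CSA_P, l_P;
  // constants
  double R, T, F, k_B, Q, eps, RTF;
  // astrocyte
  double V_A, V_m, g_Kir, g_K, g_Na, g_ECS, g_ECS_Na, K_K, K_Na, K_Ca, phi_w;
  double PNKA_max, K_Nai, K_KE, I_bar_NCX, gamma, J0, tau;
  double K_AS, Na_AS, Ca_AS, K_GECS, Na_GECS, Ca_PsECS;
  double z_K, z_Na, z_Ca;
  // neurone
  double C_m, g_NaNeu, g_KNeu, g_LNeu, g_KBNeu, g_NaBNeu;
  double E_NaNeu, E_KNeu, E_LNeu, PNKA_maxNeu, K_NaiNeu, K_KENeu;
  double Na_Syn, K_Syn, spike_threshold, refractory;
  // options
  bool include_h, k_bg_in_psc, kir_sqrt, nernst_z, pf_z;
  double conc_floor;
};

double getd(const List& par, const char* nm) {
  return as<double>(par[nm]);
}

Pars read_pars(const List& par) {
  Pars p;
  p.SA_PsC = getd(par, "SA_PsC"); p.Vol_PsC = getd(par, "Vol_PsC");
  p.Vol_PsECS = getd(par, "Vol_PsECS"); p.SA_Syn = getd(par, "SA_Syn");
  p.SA_ECSL = getd(par, "SA_ECSL"); p.CSA_P = getd(par, "CSA_P");
  p.l_P = getd(par, "l_P");
  p.R = getd(par, "R"); p.T = getd(par, "T"); p.F = getd(par, "F");
  p.k_B = getd(par, "k_B"); p.Q = getd(par, "Q"); p.eps = getd(par, "eps");
  p.RTF = p.R * p.T / p.F;
  p.V_A = getd(par, "V_A"); p.V_m = getd(par, "V_m");
  p.g_Kir = getd(par, "g_Kir"); p.g_K = getd(par, "g_K");
  p.g_Na = getd(par, "g_Na"); p.g_ECS = getd(par, "g_ECS");
  p.g_ECS_Na = getd(par, "g_ECS_Na");
  p.K_K = getd(par, "K_K"); p.K_Na = getd(par, "K_Na");
  p.K_Ca = getd(par, "K_Ca"); p.phi_w = getd(par, "phi_w");
  p.PNKA_max = getd(par, "PNKA_max"); p.K_Nai = getd(par, "K_Nai");
  p.K_KE = getd(par, "K_KE"); p.I_bar_NCX = getd(par, "I_bar_NCX");
  p.gamma = getd(par, "gamma"); p.J0 = getd(par, "J0");
  p.tau = getd(par, "tau");
  p.K_AS = getd(par, "K_AS"); p.Na_AS = getd(par, "Na_AS");
  p.Ca_AS = getd(par, "Ca_AS"); p.K_GECS = getd(par, "K_GECS");
  p.Na_GECS = getd(par, "Na_GECS"); p.Ca_PsECS = getd(par, "Ca_PsECS");
  p.z_K = getd(par, "z_K"); p.z_Na = getd(par, "z_Na");
  p.z_Ca = getd(par, "z_Ca");
  p.C_m = getd(par, "C_m_neu"); p.g_NaNeu = getd(par, "g_NaNeu");
  p.g_KNeu = getd(par, "g_KNeu"); p.g_LNeu = getd(par, "g_LNeu");
  p.g_KBNeu = getd(par, "g_KBNeu"); p.g_NaBNeu = getd(par, "g_NaBNeu");
  p.E_NaNeu = getd(par, "E_NaNeu"); p.E_KNeu = getd(par, "E_KNeu");
  p.E_LNeu = getd(par, "E_LNeu"); p.PNKA_maxNeu = getd(par, "PNKA_maxNeu");
  p.K_NaiNeu = getd(par, "K_NaiNeu"); p.K_KENeu = getd(par, "K_KENeu");
  p.Na_Syn = getd(par, "Na_Syn"); p.K_Syn = getd(par, "K_Syn");
  p.spike_threshold = getd(par, "spike_threshold");
  p.refractory = getd(par, "refractory");
  p.include_h = as<bool>(par["include_h"]);
  p.k_bg_in_psc = as<bool>(par["k_bg_in_psc"]);
  p.kir_sqrt = as<bool>(par["kir_sqrt"]);
  p.nernst_z = as<bool>(par["nernst_z"]);
  p.pf_z = as<bool>(par["pf_z"]);
  p.conc_floor = getd(par, "conc_floor");
  return p;
}

// classic HH rates, rest-at-zero frame, 1/s; V in volts
inline void hh_rates_c(double V, double* r) {
  const double v = V * 1e3;
  double x;
  x = 25.0 - v;
  r[0] = 1e3 * 0.1 * (std::fabs(x / 10.0) < 1e-6 ? 10.0 * (1.0 - x / 20.0)
                                                 : x / (std::exp(x / 10.0) - 1.0));
  r[1] = 1e3 * 4.0 * std::exp(-v / 18.0);
  r[2] = 1e3 * 0.07 * std::exp(-v / 20.0);
  r[3] = 1e3 * 1.0 / (std::exp((30.0 - v) / 10.0) + 1.0);
  x = 10.0 - v;
  r[4] = 1e3 * 0.01 * (std::fabs(x / 10.0) < 1e-6 ? 10.0 * (1.0 - x / 20.0)
                                                  : x / (std::exp(x / 10.0) - 1.0));
  r[5] = 1e3 * 0.125 * std::exp(-v / 80.0);
}

inline double clamp01(double x) {
  return x < 0.0 ? 0.0 : (x > 1.0 ? 1.0 : x);
}

// Poole-Frenkel current, cradle -> soma positive
inline double pf_current(double conc_soma, double conc_psc, double Ki,
                         double z, const Pars& p) {
  const double zz = p.nernst_z ? z : 1.0;
  const double Vr = p.RTF / zz * std::log(conc_soma / conc_psc);
  const double dV = p.V_A - p.V_m - Vr;
  if (dV == 0.0) return 0.0;
  const double Qi = p.pf_z ? z * p.Q : p.Q;
  const double lowering = std::sqrt(Qi * std::fabs(dV) / (p.l_P * M_PI * p.eps));
  const double boltz = std::exp(-Qi * (p.phi_w - lowering) / (p.k_B * p.T));
  return Ki * (dV / p.l_P) * boltz * p.CSA_P;
}

} // namespace

// [[Rcpp::export(name = ".engine_run")]]
List engine_run(NumericVector init, List par, double dt,
                double t_settle, double t_stim, double t_post,
                std::string stim_type, double stim_rate, double stim_amplitude,
                double pulse_width, NumericVector fixture_times,
                int record_stride, double t0 = 0.0) {
  const Pars p = read_pars(par);
  if (dt <= 0) stop("engine: dt must be > 0");
  const long n_settle = (long)std::llround(t_settle / dt);
  const long n_stim = (long)std::llround(t_stim / dt);
  const long n_post = (long)std::llround(t_post / dt);
  const long N = n_settle + n_stim + n_post;
  const bool fixture = (stim_type == "fixture");
  const bool pulse = (stim_type == "pulse");

  // state
  double V = init["V_Neu"], m = init["m"], h = init["h"], n = init["n"];
  double J = init["J_NaEAAT"];
  double K_PsC = init["K_PsC"], Na_PsC = init["Na_PsC"], Ca_PsC = init["Ca_PsC"];
  double K_PsECS = init["K_PsECS"], Na_PsECS = init["Na_PsECS"];

  // NCX voltage factors are constants (V_A clamped)
  const double fvrt = p.V_A / p.RTF;
  const double ncx_e1 = std::exp(p.gamma * fvrt);
  const double ncx_e2 = std::exp((p.gamma - 1.0) * fvrt);

  // audits: cumulative boundary moles and initial system moles
  const double moles_K0 = p.Vol_PsC * K_PsC + p.Vol_PsECS * K_PsECS;
  const double moles_Na0 = p.Vol_PsC * Na_PsC + p.Vol_PsECS * Na_PsECS;
  const double moles_Ca0 = p.Vol_PsC * Ca_PsC;
  double B_K = 0.0, B_Na = 0.0, B_Ca = 0.0;

  const int ncol = 36;
  const long nrec = N / record_stride + 1;
  NumericMatrix rec(nrec, ncol);
  long irec = 0;
  std::vector<double> spikes;
  double last_spike = -1e18;
  long floor_events = 0;
  std::size_t kfix = 0;

  for (long i = 0; i < N; ++i) {
    const double t = t0 + i * dt;

    // stimulus current density (A/m^2)
    double Ist = 0.0;
    if (!fixture && i >= n_settle && i < n_settle + n_stim) {
      if (pulse) {
        const double ts = (i - n_settle) * dt;
        const double period = 1.0 / stim_rate;
        const double phase = ts - std::floor(ts / period) * period;
        if (phase < pulse_width) Ist = stim_amplitude;
      } else {
        Ist = stim_amplitude;
      }
    }

    // --- neurone currents (totals, A; positive = out of neurone) ---
    double I_NaNeu = 0, I_KNeu = 0, I_LNeu = 0, I_KBNeu = 0, I_NaBNeu = 0;
    double I_NaNKANeu = 0, I_KNKANeu = 0;
    double r[6];
    if (!fixture) {
      const double E_Kn = p.RTF * std::log(K_PsECS / p.K_Syn);
      const double E_Nan = p.RTF * std::log(Na_PsECS / p.Na_Syn);
      const double gate_na = m * m * m * (p.include_h ? h : 1.0);
      I_NaNeu = p.g_NaNeu * gate_na * (V - p.E_NaNeu) * p.SA_Syn;
      I_KNeu = p.g_KNeu * n * n * n * n * (V - p.E_KNeu) * p.SA_Syn;
      I_LNeu = p.g_LNeu * (V - p.E_LNeu) * p.SA_Syn;
      I_KBNeu = p.g_KBNeu * (V - E_Kn) * p.SA_Syn;
      I_NaBNeu = p.g_NaBNeu * (V - E_Nan) * p.SA_Syn;
      const double P = p.PNKA_maxNeu *
        std::pow(p.Na_Syn / (p.Na_Syn + p.K_NaiNeu), 3) *
        std::pow(K_PsECS / (K_PsECS + p.K_KENeu), 2);
      I_NaNKANeu = 3.0 * p.F * P * p.SA_Syn;
      I_KNKANeu = -2.0 * p.F * P * p.SA_Syn;
      hh_rates_c(V, r);
    }

    // --- neurone voltage/gate update + spike detection ---
    bool spike_now = false;
    double V_new = V, m_new = m, h_new = h, n_new = n;
    if (!fixture) {
      const double I_out = (I_NaNeu + I_KNeu + I_LNeu + I_KBNeu + I_NaBNeu +
                            I_NaNKANeu + I_KNKANeu) / p.SA_Syn;
      V_new = V + dt * (Ist - I_out) / p.C_m;
      m_new = clamp01(m + dt * (r[0] * (1.0 - m) - r[1] * m));
      h_new = clamp01(h + dt * (r[2] * (1.0 - h) - r[3] * h));
      n_new = clamp01(n + dt * (r[4] * (1.0 - n) - r[5] * n));
      if (V_new >= p.spike_threshold && V < p.spike_threshold &&
          (t - last_spike) >= p.refractory) {
        spike_now = true;
        last_spike = t;
        spikes.push_back(t);
      }
    } else {
      while (kfix < (std::size_t)fixture_times.size() &&
             fixture_times[kfix] < t + dt) {
        spike_now = true; // stacked events within one step add repeatedly
        J += p.J0;
        spikes.push_back(fixture_times[kfix]);
        ++kfix;
      }
    }
    if (!fixture && spike_now) J += p.J0; // impulse lands on the same step

    // --- astrocyte currents (totals, A) ---
    const double E_K_a = p.RTF * std::log(K_PsECS / K_PsC);
    const double E_Na_a = p.RTF * std::log(Na_PsECS / Na_PsC);
    const double g_kir_eff = p.kir_sqrt ? p.g_Kir * std::sqrt(K_PsECS / 1e-3)
                                        : p.g_Kir;
    const double I_Kir = g_kir_eff * (p.V_A - E_K_a) * p.SA_PsC;
    const double I_KB = p.g_K * (p.V_A - E_K_a) * p.SA_PsC;
    const double I_NaB = p.g_Na * (p.V_A - E_Na_a) * p.SA_PsC;
    const double Pa = p.PNKA_max *
      std::pow(Na_PsC / (Na_PsC + p.K_Nai), 3) *
      std::pow(K_PsECS / (K_PsECS + p.K_KE), 2);
    const double I_NaNKA = 3.0 * p.F * Pa * p.SA_PsC;
    const double I_KNKA = -2.0 * p.F * Pa * p.SA_PsC;
    const double I_NaEAAT = -J * p.z_Na * p.F * p.Vol_PsECS;
    const double I_KEAAT = -I_NaEAAT / 3.0;
    const double ratio_na = Na_PsC / Na_PsECS;
    const double I_NaNCX = p.I_bar_NCX *
      (ratio_na * ratio_na * ratio_na * ncx_e1 -
       (Ca_PsC / p.Ca_PsECS) * ncx_e2) * p.SA_PsC;
    const double I_CaNCX = -2.0 * I_NaNCX / 3.0;
    const double I_KPF = pf_current(p.K_AS, K_PsC, p.K_K, p.z_K, p);
    const double I_NaPF = pf_current(p.Na_AS, Na_PsC, p.K_Na, p.z_Na, p);
    const double I_CaPF = pf_current(p.Ca_AS, Ca_PsC, p.K_Ca, p.z_Ca, p);
    const double I_KECSL = p.g_ECS * (p.RTF * std::log(K_PsECS / p.K_GECS)) *
      p.SA_ECSL;
    const double I_NaECSL = p.g_ECS_Na *
      (p.RTF * std::log(Na_PsECS / p.Na_GECS)) * p.SA_ECSL;

    // --- record (state at t, currents of this step) ---
    if (i % record_stride == 0) {
      const double moles_K = p.Vol_PsC * K_PsC + p.Vol_PsECS * K_PsECS;
      const double moles_Na = p.Vol_PsC * Na_PsC + p.Vol_PsECS * Na_PsECS;
      const double moles_Ca = p.Vol_PsC * Ca_PsC;
      double* row = &rec(irec, 0);
      int c = 0;
      rec(irec, c++) = t;
      rec(irec, c++) = V; rec(irec, c++) = m; rec(irec, c++) = h;
      rec(irec, c++) = n; rec(irec, c++) = J;
      rec(irec, c++) = K_PsC; rec(irec, c++) = Na_PsC; rec(irec, c++) = Ca_PsC;
      rec(irec, c++) = K_PsECS; rec(irec, c++) = Na_PsECS;
      rec(irec, c++) = I_Kir; rec(irec, c++) = I_KNKA; rec(irec, c++) = I_KEAAT;
      rec(irec, c++) = I_KB; rec(irec, c++) = I_KPF; rec(irec, c++) = I_KECSL;
      rec(irec, c++) = I_NaB; rec(irec, c++) = I_NaNKA; rec(irec, c++) = I_NaEAAT;
      rec(irec, c++) = I_NaNCX; rec(irec, c++) = I_NaPF; rec(irec, c++) = I_NaECSL;
      rec(irec, c++) = I_CaNCX; rec(irec, c++) = I_CaPF;
      rec(irec, c++) = I_KNeu; rec(irec, c++) = I_NaNeu; rec(irec, c++) = I_LNeu;
      rec(irec, c++) = I_KBNeu; rec(irec, c++) = I_NaBNeu;
      rec(irec, c++) = I_KNKANeu; rec(irec, c++) = I_NaNKANeu;
      rec(irec, c++) = Ist;
      rec(irec, c++) = ((moles_K - moles_K0) - B_K) /
        (std::fabs(moles_K0) > 0 ? moles_K0 : 1.0);
      rec(irec, c++) = ((moles_Na - moles_Na0) - B_Na) /
        (std::fabs(moles_Na0) > 0 ? moles_Na0 : 1.0);
      rec(irec, c++) = ((moles_Ca - moles_Ca0) - B_Ca) /
        (std::fabs(moles_Ca0) > 0 ? moles_Ca0 : 1.0);
      (void)row;
      ++irec;
    }

    // --- concentration updates (volumes in L, so I / (z F Vol) is M/s) ---
    const double Fv_psc = p.F * p.Vol_PsC;
    const double Fv_ecs = p.F * p.Vol_PsECS;
    const double I_Km = I_Kir + I_KNKA + I_KEAAT + I_KB;
    const double I_Nam = I_NaB + I_NaNKA + I_NaEAAT + I_NaNCX;
    const double dK_PsC = -(I_Kir + I_KNKA + I_KEAAT +
                            (p.k_bg_in_psc ? I_KB : 0.0) + I_KPF) / Fv_psc;
    const double dNa_PsC = -(I_Nam + I_NaPF) / Fv_psc;
    const double dCa_PsC = -(I_CaNCX + I_CaPF) / (p.z_Ca * Fv_psc);
    const double I_KNeu_tot = I_KNeu + I_KBNeu + I_KNKANeu;
    const double I_NaNeu_tot = I_NaNeu + I_NaBNeu + I_NaNKANeu;
    const double dK_ECS = (I_KNeu_tot + I_Km - I_KECSL) / Fv_ecs;
    const double dNa_ECS = (I_NaNeu_tot + I_Nam - I_NaECSL) / Fv_ecs;

    K_PsC += dt * dK_PsC;
    Na_PsC += dt * dNa_PsC;
    Ca_PsC += dt * dCa_PsC;
    K_PsECS += dt * dK_ECS;
    Na_PsECS += dt * dNa_ECS;
    if (K_PsC < p.conc_floor) { K_PsC = p.conc_floor; ++floor_events; }
    if (Na_PsC < p.conc_floor) { Na_PsC = p.conc_floor; ++floor_events; }
    if (Ca_PsC < p.conc_floor) { Ca_PsC = p.conc_floor; ++floor_events; }
    if (K_PsECS < p.conc_floor) { K_PsECS = p.conc_floor; ++floor_events; }
    if (Na_PsECS < p.conc_floor) { Na_PsECS = p.conc_floor; ++floor_events; }

    // audit accumulators: boundary moles into the PsC+PsECS system
    B_K += dt * (I_KNeu_tot - I_KECSL - I_KPF) / p.F;
    B_Na += dt * (I_NaNeu_tot - I_NaECSL - I_NaPF) / p.F;
    B_Ca += dt * (-(I_CaNCX) - I_CaPF) / (p.z_Ca * p.F);

    // EAAT decay (flux used this step was the post-impulse value)
    J -= dt * J / p.tau;

    V = V_new; m = m_new; h = h_new; n = n_new;

    if (!std::isfinite(V) || !std::isfinite(K_PsC) || !std::isfinite(Na_PsC) ||
        !std::isfinite(Ca_PsC) || !std::isfinite(K_PsECS) ||
        !std::isfinite(Na_PsECS) || !std::isfinite(J)) {
      const char* vars[] = {"V_Neu", "K_PsC", "Na_PsC", "Ca_PsC",
                            "K_PsECS", "Na_PsECS", "J_NaEAAT"};
      const double vals[] = {V, K_PsC, Na_PsC, Ca_PsC, K_PsECS, Na_PsECS, J};
      for (int k = 0; k < 7; ++k) {
        if (!std::isfinite(vals[k])) {
          stop("engine: non-finite state variable %s at t = %g s", vars[k], t);
        }
      }
    }
  }

  NumericVector final_state = NumericVector::create(
    _["V_Neu"] = V, _["m"] = m, _["h"] = h, _["n"] = n, _["J_NaEAAT"] = J,
    _["K_PsC"] = K_PsC, _["Na_PsC"] = Na_PsC, _["Ca_PsC"] = Ca_PsC,
    _["K_PsECS"] = K_PsECS, _["Na_PsECS"] = Na_PsECS);

  return List::create(
    _["records"] = rec(Range(0, irec - 1), _),
    _["spike_times"] = wrap(spikes),
    _["floor_events"] = (double)floor_events,
    _["final_state"] = final_state);
}
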