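#' Hodgkin-Huxley rate constants
#'
#' Classic squid-axon voltage dependence of the six gating rate constants, in
#' the rest-at-zero frame (depolarisation positive). The removable
#' singularities of `alpha_m` (at +25 mV) and `alpha_n` (at +10 mV) are
#' evaluated by their analytic limits.
#'
#' @param V Membrane potential (V, rest-at-zero frame).
#' @return Named numeric vector `alpha_m`, `beta_m`, `alpha_h`, `beta_h`,
#'   `alpha_n`, `beta_n`, all in 1/s.
#' @examples
#' hh_rates(0)[["alpha_n"]] * 1e-3   # 0.0582 / ms
#' hh_rates(10e-3)                   # singular point handled
#' @export
hh_rates <- function(V) {
  if (!is.finite(V)) abort("hh_rates: V must be finite")
  v <- V * 1e3 # mV
  vtrap <- function(x, y) {
    # x / (exp(x / y) - 1), with the L'Hopital limit y at x = 0
    if (abs(x / y) < 1e-6) y * (1 - x / (2 * y)) else x / (exp(x / y) - 1)
  }
  c(alpha_m = 0.1 * vtrap(25 - v, 10),
    beta_m = 4 * exp(-v / 18),
    alpha_h = 0.07 * exp(-v / 20),
    beta_h = 1 / (exp((30 - v) / 10) + 1),
    alpha_n = 0.01 * vtrap(10 - v, 10),
    beta_n = 0.125 * exp(-v / 80)) * 1e3
}

#' Steady-state gating variables
#'
#' Fixed points `x_inf = alpha_x / (alpha_x + beta_x)` of the three gates at a
#' given voltage.
#'
#' @inheritParams hh_rates
#' @return Named vector `m`, `h`, `n`.
#' @export
hh_steady_gates <- function(V) {
  r <- hh_rates(V)
  c(m = r[["alpha_m"]] / (r[["alpha_m"]] + r[["beta_m"]]),
    h = r[["alpha_h"]] / (r[["alpha_h"]] + r[["beta_h"]]),
    n = r[["alpha_n"]] / (r[["alpha_n"]] + r[["beta_n"]]))
}

#' Voltage-gated neuronal sodium current
#'
#' `g_NaNeu * m^3 * h * (V - E_NaNeu) * SA_Syn`, signed so that a positive
#' current moves Na+ out of the neurone into the PsECS (at rest and during the
#' upstroke the current is negative: Na+ influx). The inactivation gate `h`
#' is included by default; `include_h_gate = FALSE` reproduces the published
#' `m^3`-only form.
#'
#' @param state Named state vector (see [baseline_state()]).
#' @param params A [psc_params()] object.
#' @return Current in amperes.
#' @export
neuron_sodium_current <- function(state, params) {
  n <- params$neuron
  gate <- state[["m"]]^3 *
    (if (isTRUE(params$options$include_h_gate)) state[["h"]] else 1)
  unname(n$g_NaNeu * gate * (state[["V_Neu"]] - n$E_NaNeu) * params$geometry$SA_Syn)
}

#' Voltage-gated neuronal potassium current
#'
#' `g_KNeu * n^4 * (V - E_KNeu) * SA_Syn`; positive = K+ efflux into the
#' PsECS (the dominant direction during repolarisation).
#'
#' @inheritParams neuron_sodium_current
#' @return Current in amperes.
#' @export
neuron_potassium_current <- function(state, params) {
  n <- params$neuron
  unname(n$g_KNeu * state[["n"]]^4 * (state[["V_Neu"]] - n$E_KNeu) *
           params$geometry$SA_Syn)
}

#' Neuronal background channel current
#'
#' Passive electrochemical current `g_iBNeu * (V_Neu - E_i) * SA_Syn` with
#' `E_i = (RT/F) ln([i]_PsECS / [i]_Syn)`; positive = efflux from the neurone.
#' The neurone's internal concentrations are held constant.
#'
#' @param ion `"K"` or `"Na"`.
#' @inheritParams neuron_sodium_current
#' @return Current in amperes.
#' @export
neuron_background_current <- function(ion, state, params) {
  ion <- match.arg(ion, c("K", "Na"))
  n <- params$neuron
  if (ion == "K") {
    E <- channel_nernst(state[["K_PsECS"]], n$K_Syn, 1, params)
    g <- n$g_KBNeu
  } else {
    E <- channel_nernst(state[["Na_PsECS"]], n$Na_Syn, 1, params)
    g <- n$g_NaBNeu
  }
  unname(g * (state[["V_Neu"]] - E) * params$geometry$SA_Syn)
}

#' Neuronal Na+/K+-ATPase flux and currents
#'
#' Saturating (Hill-type) pump rate
#' `P = P_max * ([Na+]_i / ([Na+]_i + K_Nai))^3 * ([K+]_o / ([K+]_o + K_KE))^2`
#' with the neurone's fixed internal Na+ and the dynamic PsECS K+. The pump
#' extrudes 3 Na+ per 2 K+ imported at every instant:
#' `I_Na = +3 F P SA_Syn`, `I_K = -2 F P SA_Syn`.
#'
#' @inheritParams neuron_sodium_current
#' @return Named list with `P` (mol/m^2/s), `I_Na` and `I_K` (A).
#' @export
neuron_nka_flux <- function(state, params) {
  n <- params$neuron
  if (state[["K_PsECS"]] < 0) abort("neuron_nka_flux: negative [K+]_PsECS")
  P <- n$PNKA_maxNeu *
    (n$Na_Syn / (n$Na_Syn + n$K_NaiNeu))^3 *
    (state[["K_PsECS"]] / (state[["K_PsECS"]] + n$K_KENeu))^2
  FSA <- params$constants$F * params$geometry$SA_Syn
  list(P = P, I_Na = 3 * FSA * P, I_K = -2 * FSA * P)
}

#' All neuronal membrane currents
#'
#' @inheritParams neuron_sodium_current
#' @return Named numeric vector of currents (A): `I_NaNeu`, `I_KNeu`,
#'   `I_LNeu`, `I_KBNeu`, `I_NaBNeu`, `I_NaNKANeu`, `I_KNKANeu`. Positive =
#'   efflux from the neurone into the PsECS; the leak is not ion-specific and
#'   only enters the voltage equation.
#' @export
neuron_currents <- function(state, params) {
  n <- params$neuron
  nka <- neuron_nka_flux(state, params)
  c(I_NaNeu = neuron_sodium_current(state, params),
    I_KNeu = neuron_potassium_current(state, params),
    I_LNeu = unname(n$g_LNeu * (state[["V_Neu"]] - n$E_LNeu) *
                      params$geometry$SA_Syn),
    I_KBNeu = neuron_background_current("K", state, params),
    I_NaBNeu = neuron_background_current("Na", state, params),
    I_NaNKANeu = nka$I_Na,
    I_KNKANeu = nka$I_K)
}

#' Advance the neurone one forward-Euler step
#'
#' Updates the membrane potential from the sum of all membrane currents plus
#' the stimulus, and the three gates from their first-order kinetics. Gates
#' are clamped to `[0, 1]`.
#'
#' @param state Named state vector.
#' @param stimulus Stimulus current density (A/m^2, depolarising positive).
#' @param dt Time step (s); `dt = 0` returns the state unchanged.
#' @param params A [psc_params()] object.
#' @return The updated state vector.
#' @export
neuron_step <- function(state, stimulus, dt, params) {
  if (dt < 0) abort("neuron_step: dt must be >= 0")
  if (dt == 0) return(state)
  n <- params$neuron
  cur <- neuron_currents(state, params)
  # total outward current density; positive hyperpolarises
  I_out <- sum(cur) / params$geometry$SA_Syn
  r <- hh_rates(state[["V_Neu"]])
  V_new <- state[["V_Neu"]] + dt * (stimulus - I_out) / n$C_m
  if (!is.finite(V_new)) {
    abort(paste0("neuron_step: non-finite membrane potential (V_Neu) after step"))
  }
  upd <- function(x, a, b) min(1, max(0, x + dt * (a * (1 - x) - b * x)))
  state[["V_Neu"]] <- V_new
  state[["m"]] <- upd(state[["m"]], r[["alpha_m"]], r[["beta_m"]])
  state[["h"]] <- upd(state[["h"]], r[["alpha_h"]], r[["beta_h"]])
  state[["n"]] <- upd(state[["n"]], r[["alpha_n"]], r[["beta_n"]])
  state
}

#' Detect spikes in a voltage trace
#'
#' Upward threshold crossings on a uniformly sampled trace, with a refractory
#' guard between accepted events.
#'
#' @param time Sample times (s), uniformly spaced, same length as `v`.
#' @param v Membrane potential trace (V).
#' @param threshold Crossing threshold (V); default +50 mV above rest.
#' @param refractory Minimum spacing between events (s).
#' @return Numeric vector of event times (possibly empty).
#' @examples
#' t <- seq(0, 1, by = 1e-4)
#' detect_spikes(t, sin(2 * pi * 10 * t) * 0.08)  # 10 crossings
#' @export
detect_spikes <- function(time, v, threshold = 0.05, refractory = 2e-3) {
  stopifnot(length(time) == length(v))
  if (length(v) < 2) return(numeric(0))
  up <- which(v[-1] >= threshold & v[-length(v)] < threshold) + 1
  if (length(up) == 0) return(numeric(0))
  events <- numeric(0)
  last <- -Inf
  for (i in up) {
    if (time[i] - last >= refractory) {
      events <- c(events, time[i])
      last <- time[i]
    }
  }
  events
}
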