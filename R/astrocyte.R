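#' EAAT1/2 flux state update
#'
#' The transporter flux `J_NaEAAT` (a PsECS concentration-removal rate, M/s)
#' obeys impulse-decay kinetics: between glutamate-release events it decays
#' exponentially, `dJ/dt = -J / tau`; at an event the bound glutamate
#' discharges through the pore and `J` jumps by `J0`. Successive events stack
#' additively, which is what produces the frequency-dependent Na+ load.
#'
#' @param J Current flux (M/s, >= 0).
#' @param dt Time step (s, > 0).
#' @param spike_now Logical; did a glutamate-release event occur this step?
#' @param params A [psc_params()] object.
#' @return Updated flux (M/s).
#' @examples
#' p <- psc_params()
#' eaat_update(0, 1e-5, TRUE, p)      # jumps to J0
#' @export
eaat_update <- function(J, dt, spike_now, params) {
  if (dt <= 0) abort("eaat_update: dt must be > 0")
  if (J < 0) abort("eaat_update: J must be >= 0")
  if (isTRUE(spike_now)) J <- J + params$astrocyte$J0
  J - dt * J / params$astrocyte$tau_EAAT
}

#' EAAT1/2 transporter currents
#'
#' Converts the transporter flux into total membrane currents. The flux is a
#' PsECS concentration rate, so the Na+ current is
#' `I_NaEAAT = -J * z_Na * F * Vol_PsECS` (negative: Na+ moves into the
#' cradle); the counter-transported K+ current is `I_KEAAT = -I_NaEAAT / 3`
#' by the 3 Na+ : 1 glutamate : 1 K+ stoichiometry.
#'
#' @param J Transporter flux (M/s, >= 0).
#' @param params A [psc_params()] object.
#' @return Named vector `I_NaEAAT`, `I_KEAAT` (A).
#' @export
eaat_currents <- function(J, params) {
  if (J < 0) abort("eaat_currents: J must be >= 0")
  I_Na <- -J * params$astrocyte$z_Na * params$constants$F *
    params$geometry$Vol_PsECS
  c(I_NaEAAT = I_Na, I_KEAAT = -I_Na / 3)
}

#' Na+/Ca2+ exchanger currents
#'
#' Exponential-ratio rate law of the 3:1 exchanger:
#' \deqn{I_{NaNCX} = \bar{I}_{NCX}\left[
#'   \left(\frac{[Na]_{PsC}}{[Na]_{PsECS}}\right)^3 e^{\gamma F V_A / RT}
#'   - \frac{[Ca]_{PsC}}{[Ca]_{PsECS}} e^{(\gamma - 1) F V_A / RT}
#' \right] SA_{PsC}}
#' and `I_CaNCX = -2/3 * I_NaNCX`. Positive `I_NaNCX` is reverse mode: Na+
#' leaves the cradle, Ca2+ enters. The baseline state sits at the exchanger's
#' equilibrium (`V_A = E_NCX`), so the resting current is essentially zero;
#' a Na+ microdomain pushes it positive.
#'
#' @param state Named state vector (uses `Na_PsC`, `Na_PsECS`, `Ca_PsC`; the
#'   external Ca2+ is the clamped `Ca_PsECS` parameter).
#' @param params A [psc_params()] object.
#' @return Named vector `I_NaNCX`, `I_CaNCX` (A).
#' @export
ncx_currents <- function(state, params) {
  a <- params$astrocyte
  if (state[["Na_PsECS"]] <= 0 || a$Ca_PsECS <= 0) {
    abort("ncx_currents: extracellular concentrations must be > 0")
  }
  fvrt <- a$V_A / rtf(params)
  I_Na <- a$I_bar_NCX *
    ((state[["Na_PsC"]] / state[["Na_PsECS"]])^3 * exp(a$gamma * fvrt) -
       (state[["Ca_PsC"]] / a$Ca_PsECS) * exp((a$gamma - 1) * fvrt)) *
    params$geometry$SA_PS
  c(I_NaNCX = unname(I_Na), I_CaNCX = unname(-2 * I_Na / 3))
}

#' Astrocytic Na+/K+-ATPase currents
#'
#' Same saturating pump form as the neurone's ([neuron_nka_flux()]), driven
#' by the cradle's dynamic internal Na+ and the PsECS K+:
#' `I_Na = +3 F P SA_PsC`, `I_K = -2 F P SA_PsC` (3:2 stoichiometry exact).
#'
#' @inheritParams ncx_currents
#' @return Named list `P` (mol/m^2/s), `I_Na`, `I_K` (A).
#' @export
astro_nka_currents <- function(state, params) {
  a <- params$astrocyte
  P <- a$PNKA_max *
    (state[["Na_PsC"]] / (state[["Na_PsC"]] + a$K_Nai))^3 *
    (state[["K_PsECS"]] / (state[["K_PsECS"]] + a$K_KE))^2
  FSA <- params$constants$F * params$geometry$SA_PS
  list(P = unname(P), I_Na = unname(3 * FSA * P), I_K = unname(-2 * FSA * P))
}

#' Kir channel current
#'
#' Inwardly rectifying K+ channel, linear in the driving force:
#' `I_Kir = g_Kir (V_A - E_K) SA_PsC` with
#' `E_K = (RT/F) ln([K+]_PsECS / [K+]_PsC)`. At baseline `V_A > E_K`, so the
#' channel carries a small K+ efflux; a rise in PsECS K+ lifts `E_K` above
#' `V_A` and flips it to uptake. The optional `kir_sqrt` switch scales the
#' conductance by `sqrt([K+]_PsECS / 1 mM)`.
#'
#' @inheritParams ncx_currents
#' @return Current (A); positive = K+ efflux from the cradle.
#' @export
kir_current <- function(state, params) {
  a <- params$astrocyte
  if (state[["K_PsECS"]] <= 0 || state[["K_PsC"]] <= 0) {
    abort("kir_current: K+ concentrations must be > 0")
  }
  E_K <- channel_nernst(state[["K_PsECS"]], state[["K_PsC"]], 1, params)
  g <- a$g_Kir
  if (isTRUE(params$options$kir_sqrt)) g <- g * sqrt(state[["K_PsECS"]] / 1e-3)
  unname(g * (a$V_A - E_K) * params$geometry$SA_PS)
}

#' Astrocytic background channel current
#'
#' Lumped passive transport `g_i (V_A - E_i) SA_PsC` across the cradle
#' membrane, `E_i = (RT/F) ln([i]_PsECS / [i]_PsC)`. At baseline the Na+
#' background is the cradle's main passive Na+ influx pathway; the K+
#' background carries the slow efflux that restores the K+ microdomain after
#' stimulation.
#'
#' @param ion `"K"` or `"Na"`.
#' @inheritParams ncx_currents
#' @return Current (A); positive = efflux from the cradle.
#' @export
astro_background_current <- function(ion, state, params) {
  ion <- match.arg(ion, c("K", "Na"))
  a <- params$astrocyte
  out_c <- state[[paste0(ion, "_PsECS")]]
  in_c <- state[[paste0(ion, "_PsC")]]
  if (out_c <= 0 || in_c <= 0) {
    abort("astro_background_current: concentrations must be > 0")
  }
  E <- channel_nernst(out_c, in_c, 1, params)
  g <- if (ion == "K") a$g_K else a$g_Na
  unname(g * (a$V_A - E) * params$geometry$SA_PS)
}

#' PsECS to global-ECS leak current
#'
#' Diffusive exchange between the perisynaptic and global extracellular
#' space, modelled as an electrochemical channel at zero extracellular
#' potential: `I = g_iECS * E_i * SA_PsECS_GECS` with
#' `E_i = (RT/F) ln([i]_PsECS / [i]_GECS)`. Positive = ion leaves the PsECS
#' for the global ECS. The channel law is logarithmic in concentration, so
#' the per-ion conductances are scaled with the baseline concentration to
#' give K+ and Na+ the same molar (diffusive) exchange rate: `g_KECS` is the
#' table value, `g_NaECS = g_KECS * [Na+]_GECS / [K+]_GECS`.
#'
#' @param ion `"K"` or `"Na"`.
#' @inheritParams ncx_currents
#' @return Current (A).
#' @export
ecs_leak_current <- function(ion, state, params) {
  ion <- match.arg(ion, c("K", "Na"))
  a <- params$astrocyte
  psecs <- state[[paste0(ion, "_PsECS")]]
  gecs <- if (ion == "K") a$K_GECS else a$Na_GECS
  if (psecs <= 0 || gecs <= 0) {
    abort("ecs_leak_current: concentrations must be > 0")
  }
  E <- channel_nernst(psecs, gecs, 1, params)
  g <- if (ion == "K") a$g_ECS else a$g_ECS_Na
  unname(g * E * params$geometry$SA_PsECS_GECS)
}

#' All astrocytic currents at a given state
#'
#' Evaluates every membrane, leak and process pathway of the cradle at one
#' state. Positive membrane currents leave the cradle for the PsECS; positive
#' leak currents leave the PsECS for the global ECS; positive process
#' currents leave the cradle for the soma.
#'
#' @inheritParams ncx_currents
#' @return A one-row tibble with columns `I_Kir`, `I_KNKA`, `I_KEAAT`,
#'   `I_KB`, `I_KPF`, `I_KECSL`, `I_NaB`, `I_NaNKA`, `I_NaEAAT`, `I_NaNCX`,
#'   `I_NaPF`, `I_NaECSL`, `I_CaNCX`, `I_CaPF` (all A).
#' @export
astrocyte_currents <- function(state, params) {
  nka <- astro_nka_currents(state, params)
  eaat <- eaat_currents(state[["J_NaEAAT"]], params)
  ncx <- ncx_currents(state, params)
  tibble::tibble(
    I_Kir = kir_current(state, params),
    I_KNKA = nka$I_K,
    I_KEAAT = unname(eaat[["I_KEAAT"]]),
    I_KB = astro_background_current("K", state, params),
    I_KPF = process_current("K", state, params),
    I_KECSL = ecs_leak_current("K", state, params),
    I_NaB = astro_background_current("Na", state, params),
    I_NaNKA = nka$I_Na,
    I_NaEAAT = unname(eaat[["I_NaEAAT"]]),
    I_NaNCX = unname(ncx[["I_NaNCX"]]),
    I_NaPF = process_current("Na", state, params),
    I_NaECSL = ecs_leak_current("Na", state, params),
    I_CaNCX = unname(ncx[["I_CaNCX"]]),
    I_CaPF = process_current("Ca", state, params)
  )
}
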