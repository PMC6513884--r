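#' Soma-to-cradle reversal potential
#'
#' Nernst-like reversal potential of the dynamic concentration gradient along
#' the thin process, `Vr = (RT/F) ln([i]_AS / [i]_PsC)`, valence-free for
#' every ion (the model's channel convention; set the `nernst_valence` option
#' for the `z`-divided form). Soma concentrations are held constant.
#'
#' @param conc_soma,conc_psc Concentrations in the astrocyte soma and the
#'   cradle (M); both > 0.
#' @param valence Ion valence, used only under the `nernst_valence` option.
#' @param params A [psc_params()] object.
#' @return Potential in volts. Zero when the two concentrations are equal
#'   (true for all three ions at baseline); strictly decreasing in the cradle
#'   concentration.
#' @examples
#' p <- psc_params()
#' process_reversal_potential(100e-9, 200e-9, params = p)  # about -18.5 mV
#' @export
process_reversal_potential <- function(conc_soma, conc_psc, valence = 1,
                                       params = psc_params()) {
  channel_nernst(conc_soma, conc_psc, valence, params)
}

#' Poole-Frenkel well-hopping current along the process
#'
#' Cations travelling the thin process are trapped in the potential wells of
#' fixed membrane charges and escape by field-assisted (Poole-Frenkel)
#' hopping:
#' \deqn{I = K_i \frac{\Delta V}{l}
#'   \exp\!\left[-\frac{Q(\phi_w - \sqrt{Q |\Delta V| / (l \pi \epsilon)})}{k_B T}\right]
#'   CSA_P}
#' with the driving potential `\Delta V = V_A - V_m - Vr` (here `V_A` is
#' clamped to `V_m`, so `\Delta V = -Vr`), the well depth `phi_w` (eV, hence
#' multiplied by the hop charge `Q`), and the barrier lowering using the
#' field `|\Delta V| / l` so that the exponential factor is even in the
#' driving force while its sign is carried by the prefactor. The Boltzmann
#' factor at zero lowering, `exp(-Q phi_w / k_B T)`, is about 4.5e-5 at 310 K,
#' which is what semi-isolates the cradle from the soma.
#'
#' @param ion `"K"`, `"Na"` or `"Ca"` (selects the channel constant `K_i`).
#' @param Vr Soma-to-cradle reversal potential (V), from
#'   [process_reversal_potential()].
#' @param params A [psc_params()] object.
#' @return Current in amperes; positive = flow from the cradle toward the
#'   soma. Zero at `\Delta V = 0`.
#' @export
poole_frenkel_current <- function(ion, Vr, params) {
  ion <- match.arg(ion, c("K", "Na", "Ca"))
  g <- params$geometry
  cst <- params$constants
  a <- params$astrocyte
  K_i <- a[[paste0("K_", ion)]]
  z <- a[[paste0("z_", ion)]]
  Qi <- if (isTRUE(params$options$pf_valence_charge)) z * cst$Q else cst$Q
  dV <- a$V_A - a$V_m - Vr
  if (dV == 0) return(0)
  eps <- cst$eps0 * cst$eps_r
  lowering <- sqrt(Qi * abs(dV) / (g$l_P * pi * eps)) # volts
  boltz <- exp(-Qi * (a$phi_w - lowering) / (cst$k_B * cst$T))
  unname(K_i * (dV / g$l_P) * boltz * g$CSA_P)
}

# total process current for an ion at a model state
process_current <- function(ion, state, params) {
  a <- params$astrocyte
  soma <- a[[paste0(ion, "_AS")]]
  psc <- state[[paste0(ion, "_PsC")]]
  z <- a[[paste0("z_", ion)]]
  Vr <- process_reversal_potential(soma, psc, z, params)
  poole_frenkel_current(ion, Vr, params)
}
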