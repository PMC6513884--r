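#' Nernst potential
#'
#' Equilibrium potential `(RT / zF) * ln(conc_out / conc_in)` for an ion
#' across a membrane. The cradle model's channel rate laws use the
#' valence-free form (`z = 1`) for every ion, including Ca2+; pass the true
#' valence for thermodynamically exact potentials (as `ncx_equilibrium_potential()`
#' does for Ca2+).
#'
#' @param conc_out,conc_in Concentrations on the two sides (M); both > 0.
#' @param valence Ion valence `z` (default 1, the model's channel convention).
#' @param temperature Absolute temperature (K).
#' @param R,F Gas and Faraday constants; defaults are the model's table values.
#' @return Potential in volts.
#' @examples
#' nernst_potential(0.004, 0.1)             # K+ at 310 K, about -85.9 mV
#' nernst_potential(1.5e-3, 100e-9, 2)      # Ca2+ with z = 2
#' @export
nernst_potential <- function(conc_out, conc_in, valence = 1,
                             temperature = 310, R = 8.31, F = 96485) {
  if (any(!is.finite(conc_out)) || any(!is.finite(conc_in)) ||
      any(conc_out <= 0) || any(conc_in <= 0)) {
    abort("nernst_potential: concentrations must be finite and > 0")
  }
  (R * temperature) / (valence * F) * log(conc_out / conc_in)
}

#' NCX equilibrium potential
#'
#' Membrane potential at which an n:1 Na+/Ca2+ exchanger carries zero net
#' current: `E_NCX = (n * E_Na - 2 * E_Ca) / (n - 2)`. With the astroglial
#' 3:1 stoichiometry and physiological gradients this sits near -85 to -90 mV,
#' close to the astrocyte resting potential, which is why a modest Na+ rise in
#' the cradle can flip the exchanger into reverse (Ca2+-importing) mode.
#'
#' @param E_Na,E_Ca Equilibrium potentials of Na+ and Ca2+ (V); `E_Ca` is the
#'   true divalent Nernst potential.
#' @param n Na+ stoichiometry (> 2).
#' @return Potential in volts.
#' @examples
#' E_Na <- nernst_potential(0.135, 0.015)
#' E_Ca <- nernst_potential(1.5e-3, 80e-9, valence = 2)
#' ncx_equilibrium_potential(E_Na, E_Ca)    # about -86.7 mV
#' @export
ncx_equilibrium_potential <- function(E_Na, E_Ca, n = 3) {
  if (any(n == 2)) {
    abort("ncx_equilibrium_potential: n = 2 makes the expression singular (division by zero)")
  }
  (n * E_Na - 2 * E_Ca) / (n - 2)
}

# RT/F in volts for a parameter set
rtf <- function(params) {
  params$constants$R * params$constants$T / params$constants$F
}

# channel Nernst potential under the model's convention: valence-free by
# default, true valence behind the nernst_valence option
channel_nernst <- function(conc_out, conc_in, z, params) {
  zz <- if (isTRUE(params$options$nernst_valence)) z else 1
  nernst_potential(conc_out, conc_in, zz,
                   temperature = params$constants$T,
                   R = params$constants$R, F = params$constants$F)
}
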