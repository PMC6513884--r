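#' EAAT decay constant from the per-spike uptake target
#'
#' One glutamate-release event drives a transporter flux that jumps by `J0`
#' and decays with constant `tau`; its full-decay integral is `J0 * tau`.
#' Setting `tau = target_uptake / J0` makes each event remove exactly
#' `target_uptake` of Na+ from the PsECS (3 mM by default, with 1 mM of K+
#' returned by the 3:1 stoichiometry).
#'
#' @param J0 Maximum EAAT flux rate (M/s, > 0).
#' @param target_uptake Na+ taken up per event (M, >= 0).
#' @return Decay constant in seconds.
#' @examples
#' calibrate_eaat_tau(0.06, 3e-3)   # 50 ms
#' @export
calibrate_eaat_tau <- function(J0, target_uptake = 3e-3) {
  if (!is.finite(J0) || J0 <= 0) abort("calibrate_eaat_tau: J0 must be > 0")
  if (!is.finite(target_uptake) || target_uptake < 0) {
    abort("calibrate_eaat_tau: target_uptake must be >= 0")
  }
  target_uptake / J0
}

#' Net resting transmembrane flux of each ion
#'
#' Evaluates every pathway at the baseline state and sums per ion and per
#' membrane, expressed as a concentration rate (M/s) in the receiving
#' compartment: astrocyte fluxes over the cradle volume, neuronal fluxes over
#' the PsECS volume. After `psc_calibrate()` every entry is zero to numerical
#' precision.
#'
#' @param params A [psc_params()] object.
#' @return A tibble with columns `membrane`, `ion`, `residual` (M/s).
#' @export
resting_flux_residuals <- function(params) {
  s <- baseline_state(params)
  FF <- params$constants$F
  cur <- astrocyte_currents(s, params)
  ncur <- neuron_currents(s, params)
  vol_psc <- params$geometry$Vol_PS
  vol_ecs <- params$geometry$Vol_PsECS
  tibble::tibble(
    membrane = c("astrocyte", "astrocyte", "astrocyte", "neuron", "neuron"),
    ion = c("K", "Na", "Ca", "K", "Na"),
    residual = c(
      (cur$I_Kir + cur$I_KNKA + cur$I_KEAAT + cur$I_KB) / (FF * vol_psc),
      (cur$I_NaB + cur$I_NaNKA + cur$I_NaEAAT + cur$I_NaNCX) / (FF * vol_psc),
      (cur$I_CaNCX + cur$I_CaPF) / (2 * FF * vol_psc),
      unname(ncur[["I_KNeu"]] + ncur[["I_KBNeu"]] + ncur[["I_KNKANeu"]]) /
        (FF * vol_ecs),
      unname(ncur[["I_NaNeu"]] + ncur[["I_NaBNeu"]] + ncur[["I_NaNKANeu"]]) /
        (FF * vol_ecs)
    )
  )
}

#' Calibrate background conductances and pump rates for a resting equilibrium
#'
#' Solves the per-ion zero-net-flux conditions at the baseline state, one
#' membrane at a time, so that an unstimulated simulation stays at rest.
#'
#' Astrocyte (NKA maximal pump rate kept at its table value, which sets the
#' membrane's resting Na+/K+ turnover): the Kir and K+ background
#' conductances are scaled by a common factor — preserving their printed
#' ratio, so Kir remains the dominant K+ channel — until their resting K+
#' efflux equals the pump's K+ import, and the Na+ background conductance is
#' set so passive Na+ influx balances the pump's Na+ export (the NCX rests at
#' equilibrium, see [psc_calibrate()]). Keeping the printed pump rate keeps
#' the resting turnover low enough that the EAAT flux, not the pump's
#' response to extracellular K+, dominates the stimulated Na+ balance — the
#' regime in which the Na+ microdomain forms.
#'
#' Neurone (voltage-gated channels at their rest-frame fixed point, Na+
#' background conductance kept at its table value): the NKA maximal rate is
#' set from the Na+ balance, the K+ background conductance from the K+
#' balance, and the leak reversal from the total-charge balance — with every
#' ion-specific pathway closed the leak must carry zero resting current, so
#' `E_LNeu = 0` in the rest-at-zero frame.
#'
#' @param params A [psc_params()] object.
#' @return The parameter set with updated `g_Kir`, `g_K`, `g_Na`,
#'   `PNKA_maxNeu`, `g_KBNeu`, `E_LNeu`.
#' @section Errors:
#' If any balance would require a negative conductance or pump rate, a
#' calibration error is raised reporting the residual flux that could not be
#' zeroed.
#' @export
calibrate_background_conductances <- function(params) {
  a <- params$astrocyte
  n <- params$neuron
  FF <- params$constants$F

  ## astrocyte: the pump rate stays at its table value; the K+ channel
  ## conductances (Kir + background, ratio preserved) are scaled so channel
  ## efflux equals pump import at rest, and the Na+ background conductance is
  ## set so passive influx balances the pump's Na+ export
  E_K <- channel_nernst(a$K_PsECS0, a$K_PsC0, 1, params)
  E_Na <- channel_nernst(a$Na_PsECS0, a$Na_PsC0, 1, params)
  g_kir_eff <- if (isTRUE(params$options$kir_sqrt)) {
    a$g_Kir * sqrt(a$K_PsECS0 / 1e-3)
  } else {
    a$g_Kir
  }
  occ <- (a$Na_PsC0 / (a$Na_PsC0 + a$K_Nai))^3 *
    (a$K_PsECS0 / (a$K_PsECS0 + a$K_KE))^2
  P_astro <- a$PNKA_max * occ            # resting pump rate, mol/m^2/s
  I_K_chan <- (g_kir_eff + a$g_K) * (a$V_A - E_K)   # per-area, efflux > 0
  if (I_K_chan <= 0) {
    abort(paste0("calibration: resting astrocyte K+ channel flux is not an ",
                 "efflux (", format(I_K_chan), " A/m^2); cannot balance the pump"))
  }
  scale_k <- (2 * FF * P_astro) / I_K_chan
  if (scale_k <= 0) {
    abort(paste0("calibration: astrocyte K+ balance needs a negative ",
                 "conductance scale; residual flux ", format(I_K_chan), " A/m^2"))
  }
  # the NCX rests at its joint equilibrium with the Ca2+ process current
  # (see calibrate_resting_ca); its residual Na+ current enters the balance
  ncx_density <- unname(ncx_currents(baseline_state(params),
                                     params)[["I_NaNCX"]]) /
    params$geometry$SA_PS
  g_Na_astro <- (3 * FF * P_astro + ncx_density) / (E_Na - a$V_A)
  if (g_Na_astro <= 0) {
    abort(paste0("calibration: astrocyte Na+ balance needs a negative conductance; ",
                 "residual flux ", format(3 * FF * P_astro + ncx_density),
                 " A/m^2"))
  }
  params$astrocyte$g_Kir <- a$g_Kir * scale_k
  params$astrocyte$g_K <- a$g_K * scale_k
  params$astrocyte$g_Na <- g_Na_astro

  ## neurone: Na+ balance -> pump rate; K+ balance -> background conductance
  E_Kn <- channel_nernst(a$K_PsECS0, n$K_Syn, 1, params)
  E_Nan <- channel_nernst(a$Na_PsECS0, n$Na_Syn, 1, params)
  gates <- hh_steady_gates(0)
  gate_na <- gates[["m"]]^3 *
    (if (isTRUE(params$options$include_h_gate)) gates[["h"]] else 1)
  I_Na_vg <- n$g_NaNeu * gate_na * (0 - n$E_NaNeu)
  I_K_vg <- n$g_KNeu * gates[["n"]]^4 * (0 - n$E_KNeu)
  I_Na_bg <- n$g_NaBNeu * (0 - E_Nan)
  P_neu <- -(I_Na_vg + I_Na_bg) / (3 * FF)
  if (P_neu <= 0) {
    abort(paste0("calibration: neurone Na+ balance needs a negative pump rate; ",
                 "residual flux ", format(I_Na_vg + I_Na_bg), " A/m^2"))
  }
  occ_n <- (n$Na_Syn / (n$Na_Syn + n$K_NaiNeu))^3 *
    (a$K_PsECS0 / (a$K_PsECS0 + n$K_KENeu))^2
  g_KB_neu <- (2 * FF * P_neu - I_K_vg) / (0 - E_Kn)
  if (g_KB_neu <= 0) {
    abort(paste0("calibration: neurone K+ balance needs a negative conductance ",
                 "(voltage-gated K+ efflux ", format(I_K_vg),
                 " A/m^2 exceeds the pump's K+ import ",
                 format(2 * FF * P_neu), " A/m^2); check E_KNeu"))
  }
  params$neuron$PNKA_maxNeu <- P_neu / occ_n
  params$neuron$g_KBNeu <- g_KB_neu
  params$neuron$E_LNeu <- 0
  params
}

#' Resting cradle Ca2+ at the joint NCX-process equilibrium
#'
#' The exchanger is the cradle's only Ca2+ source and the process its only
#' sink, so the resting Ca2+ solves `I_CaNCX + I_CaPF = 0`. The NCX alone
#' equilibrates at `[Ca2+]_PsC = [Ca2+]_PsECS ([Na+]_PsC / [Na+]_PsECS)^3
#' exp(F V_A / RT)` (the condition `V_A = E_NCX`), which is 100.08 nM with
#' the table baselines — the published initial value of 100 nM rounded; the
#' process pulls the joint root a fraction of a percent back toward the
#' 100 nM soma concentration.
#'
#' @param params A [psc_params()] object.
#' @return Equilibrium cradle Ca2+ concentration (M).
#' @export
calibrate_resting_ca <- function(params) {
  a <- params$astrocyte
  ca_ncx <- a$Ca_PsECS * (a$Na_PsC0 / a$Na_PsECS0)^3 * exp(a$V_A / rtf(params))
  lo <- min(ca_ncx, a$Ca_AS)
  hi <- max(ca_ncx, a$Ca_AS)
  if (lo == hi) return(lo)
  net_ca <- function(ca) {
    s <- baseline_state(params)
    s[["Ca_PsC"]] <- ca
    unname(ncx_currents(s, params)[["I_CaNCX"]]) +
      process_current("Ca", s, params)
  }
  uniroot(net_ca, c(lo, hi), tol = .Machine$double.eps * lo)$root
}

#' Full resting-state calibration
#'
#' Applies, in order: [calibrate_eaat_tau()] (EAAT decay constant from the
#' 3 mM per-spike uptake target), [calibrate_background_conductances()]
#' (pump rates and background conductances for zero per-ion resting flux),
#' and [calibrate_resting_ca()] (initial cradle Ca2+ at the NCX equilibrium).
#' Records the pre/post values and the post-calibration flux residuals in
#' `$calibration` and marks the parameter set calibrated; [run_protocol()]
#' requires this.
#'
#' @param params A [psc_params()] object.
#' @param target_uptake Na+ uptake per glutamate-release event (M).
#' @return The calibrated parameter set.
#' @examples
#' p <- psc_calibrate(psc_params())
#' p$calibration$residuals
#' @export
psc_calibrate <- function(params, target_uptake = 3e-3) {
  before <- list(
    g_Kir = params$astrocyte$g_Kir,
    g_K = params$astrocyte$g_K,
    g_Na = params$astrocyte$g_Na,
    PNKA_maxNeu = params$neuron$PNKA_maxNeu,
    g_KBNeu = params$neuron$g_KBNeu,
    E_LNeu = params$neuron$E_LNeu,
    tau_EAAT = params$astrocyte$tau_EAAT,
    Ca_PsC0 = params$astrocyte$Ca_PsC0
  )
  params$astrocyte$tau_EAAT <- calibrate_eaat_tau(params$astrocyte$J0,
                                                  target_uptake)
  params$astrocyte$Ca_PsC0 <- calibrate_resting_ca(params)
  params <- calibrate_background_conductances(params)
  params$calibrated <- TRUE
  res <- resting_flux_residuals(params)
  params$calibration <- list(
    before = before,
    after = list(
      g_Kir = params$astrocyte$g_Kir,
      g_K = params$astrocyte$g_K,
      g_Na = params$astrocyte$g_Na,
      PNKA_maxNeu = params$neuron$PNKA_maxNeu,
      g_KBNeu = params$neuron$g_KBNeu,
      E_LNeu = params$neuron$E_LNeu,
      tau_EAAT = params$astrocyte$tau_EAAT,
      Ca_PsC0 = params$astrocyte$Ca_PsC0
    ),
    target_uptake = target_uptake,
    residuals = res
  )
  params
}

#' Calibrate the stimulus amplitude for a target firing rate
#'
#' For the default pulse-train stimulus (brief suprathreshold current pulses
#' at the target rate), bisection finds the smallest amplitude that entrains
#' the neurone 1:1 over a probe run and returns twice it as a safety margin
#' (the threshold drifts slightly as the PsECS concentrations move during
#' sustained stimulation). For a constant-current stimulus, bisection searches the f-I curve
#' directly; the calibrated Hodgkin-Huxley neurone is type II (repetitive
#' firing begins near 80 Hz and depolarisation block follows), so low target
#' rates are unreachable in that mode and raise a calibration error carrying
#' the bracketing amplitudes and rates.
#'
#' @param params A calibrated [psc_params()] object.
#' @param rate Target firing rate (Hz); 0 returns amplitude 0.
#' @param type `"pulse"` (default) or `"constant"`.
#' @param tolerance Acceptable rate error (Hz).
#' @param probe_duration Length of the probe run (s).
#' @param max_amplitude Upper search bound (A/m^2).
#' @return A list with `amplitude` (A/m^2), `measured_rate` (Hz), `type`.
#' @export
calibrate_stimulus <- function(params, rate, type = c("pulse", "constant"),
                               tolerance = 0.5, probe_duration = 2,
                               max_amplitude = 50) {
  type <- match.arg(type)
  if (!isTRUE(params$calibrated)) {
    abort("calibrate_stimulus: calibrate the parameter set first (psc_calibrate)")
  }
  if (rate < 0) abort("calibrate_stimulus: rate must be >= 0")
  if (rate == 0) {
    return(list(amplitude = 0, measured_rate = 0, type = type))
  }
  probe <- function(amplitude) {
    p <- params
    p$protocol$t_settle <- 0
    p$protocol$t_stim <- probe_duration
    p$protocol$t_post <- 0
    p$protocol$record_stride <- 1000L
    p$protocol$stimulus$type <- type
    p$protocol$stimulus$rate <- rate
    p$protocol$stimulus$amplitude <- amplitude
    sim <- run_protocol(p, calibrate_amplitude = FALSE)
    measured_spike_rate(sim$spike_times, window = c(probe_duration / 4,
                                                    probe_duration))
  }
  if (type == "pulse") {
    # smallest 1:1-entraining amplitude, then a 1.5x margin
    lo <- 0
    hi <- 0.5
    while (abs(probe(hi) - rate) > tolerance && hi < max_amplitude) hi <- hi * 2
    if (abs(probe(hi) - rate) > tolerance) {
      abort(paste0("calibrate_stimulus: no pulse amplitude <= ", max_amplitude,
                   " A/m^2 entrains ", rate, " Hz"))
    }
    for (i in 1:25) {
      mid <- (lo + hi) / 2
      if (abs(probe(mid) - rate) <= tolerance) hi <- mid else lo <- mid
    }
    amp <- 2 * hi
    meas <- probe(amp)
    if (abs(meas - rate) > tolerance) {
      abort(paste0("calibrate_stimulus: entrainment at margin amplitude ",
                   format(amp), " gives ", format(meas), " Hz, not ", rate, " Hz"))
    }
    return(list(amplitude = amp, measured_rate = meas, type = type))
  }
  # constant current: true f-I bisection
  lo <- 0; f_lo <- 0
  hi <- max_amplitude; f_hi <- probe(hi)
  f_scan <- vapply(c(0.1, 0.2, 0.5, 1, 2, 5, 10, 20, max_amplitude), probe,
                   numeric(1))
  amps <- c(0.1, 0.2, 0.5, 1, 2, 5, 10, 20, max_amplitude)
  if (all(abs(f_scan - rate) > tolerance) &&
      (max(f_scan) < rate - tolerance || min(f_scan[f_scan > 0], Inf) > rate + tolerance)) {
    abort(paste0(
      "calibrate_stimulus: target ", rate, " Hz unreachable with constant ",
      "current; measured f-I bracket: ",
      paste(sprintf("%g A/m^2 -> %.1f Hz", amps, f_scan), collapse = ", ")
    ))
  }
  best <- amps[which.min(abs(f_scan - rate))]
  lo <- max(c(0, amps[amps < best])); hi <- min(c(amps[amps > best], max_amplitude))
  for (i in 1:25) {
    mid <- (lo + hi) / 2
    f <- probe(mid)
    if (abs(f - rate) <= tolerance) {
      return(list(amplitude = mid, measured_rate = f, type = type))
    }
    if (f < rate) lo <- mid else hi <- mid
  }
  abort(paste0("calibrate_stimulus: bisection failed to reach ", rate,
               " Hz with constant current (last bracket ", format(lo), " - ",
               format(hi), " A/m^2)"))
}

# firing rate from event times over a window, robust to edge truncation
measured_spike_rate <- function(spike_times, window) {
  st <- spike_times[spike_times >= window[1] & spike_times <= window[2]]
  if (length(st) < 2) return(length(st) / diff(window))
  (length(st) - 1) / (st[length(st)] - st[1])
}
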