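#' Model parameters for the perisynaptic cradle simulator
#'
#' Builds the full parameter set of the coupled neurone-astrocyte model:
#' physical constants, astrocyte membrane and transporter constants, neurone
#' (Hodgkin-Huxley) constants, Poole-Frenkel process-transport constants,
#' baseline concentrations for every compartment, model option switches and
#' the simulation protocol. All defaults are the published table values of the
#' model; see `psc_calibrate()` for the derived quantities (background
#' conductances, pump rates, EAAT decay constant, resting Ca2+) that make the
#' resting state an exact equilibrium.
#'
#' Sign convention used throughout the package: a positive transmembrane
#' current moves the ion out of its source compartment (neurone or cradle)
#' into the perisynaptic extracellular space; a positive process current moves
#' the ion from the cradle toward the soma; a positive ECS leak current moves
#' the ion from the PsECS to the global ECS.
#'
#' @param geometry A [psc_geometry()] object.
#' @param ... Named overrides for any parameter in the `constants`,
#'   `astrocyte`, `neuron`, `options` or `protocol` sections (e.g. `g_Kir =
#'   100`, `dt = 2e-5`). Unknown names are rejected with the list of valid
#'   keys.
#'
#' @return An object of class `psc_params`: a nested list with elements
#'   `geometry`, `constants`, `astrocyte`, `neuron`, `options`, `protocol`,
#'   and a logical `calibrated` flag.
#'
#' @section Key parameters:
#' * `J0` (M/s): maximum EAAT1/2 flux rate, expressed as a PsECS
#'   concentration-removal rate; each glutamate-release event adds `J0` to the
#'   decaying transporter flux.
#' * `tau_EAAT` (s): EAAT flux decay constant; `calibrate_eaat_tau()` sets it
#'   so one event integrates to 3 mM of Na+ uptake.
#' * `I_bar_NCX` (A/m^2), `gamma`: NCX exchanger conductance and partition
#'   parameter of the exponential-ratio rate law.
#' * `phi_w` (eV), `K_K`/`K_Na`/`K_Ca` (S/m): Poole-Frenkel well depth and
#'   per-ion channel constants of the process transport.
#' * `V_A` (V): astrocyte membrane potential, held fixed (isopotential cradle).
#'
#' @examples
#' p <- psc_params()
#' p$astrocyte$J0
#' psc_params(g_Kir = 100, dt = 2e-5)$protocol$dt
#' @export
psc_params <- function(geometry = psc_geometry(), ...) {
  if (!inherits(geometry, "psc_geometry")) {
    abort("psc_params: `geometry` must be a psc_geometry object")
  }
  constants <- list(
    R = 8.31,            # gas constant, J/mol/K
    T = 310,             # temperature, K
    F = 96485,           # Faraday constant, C/mol
    k_B = 1.38e-23,      # Boltzmann constant, J/K
    Q = 1.6022e-19,      # elementary charge, C
    eps0 = 8.85e-12,     # vacuum permittivity, F/m
    eps_r = 0.82         # relative permittivity of cytoplasm (dimensionless)
  )
  astrocyte <- list(
    V_A = -0.0807,       # membrane potential, V (held constant)
    V_m = -0.0807,       # resting membrane potential, V
    C_m = 0.01,          # membrane capacitance, F/m^2
    phi_w = 0.267,       # Poole-Frenkel well activation energy, eV
    g_Kir = 144,         # Kir conductance, S/m^2
    g_K = 17.9364,       # K+ background conductance, S/m^2
    g_Na = 0.9761,       # Na+ background conductance, S/m^2 (recalibrated)
    g_ECS = 3.3,         # PsECS -> GECS leak conductance (K+), S/m^2
    g_ECS_Na = 3.3 * 0.135 / 0.004, # Na+ leak conductance, S/m^2: the same
                         # molar exchange coefficient as K+ (the channel law
                         # is logarithmic, so equal diffusive exchange rates
                         # need g scaled by the baseline concentration)
    K_K = 0.018,         # Poole-Frenkel channel constant, K+, S/m
    K_Na = 0.018,        # Poole-Frenkel channel constant, Na+, S/m
    K_Ca = 0.018,        # Poole-Frenkel channel constant, Ca2+, S/m (not
                         # tabulated; defaults to the K+/Na+ value)
    PNKA_max = 1e-6,     # max NKA pump rate, mol/m^2/s (recalibrated)
    K_Nai = 10e-3,       # NKA Na+ half-saturation, M
    K_KE = 1.5e-3,       # NKA K+ half-saturation, M
    I_bar_NCX = 1,       # NCX exchanger conductance, A/m^2
    gamma = 0.5,         # NCX partition parameter
    J0 = 0.06,           # max EAAT1/2 flux rate, M/s (PsECS concentration rate)
    tau_EAAT = 0.05,     # EAAT flux decay constant, s (calibrated: 3 mM / J0)
    glu_per_spike = 1e-3,# glutamate released per spike, M (implicit; bound
                         # instantaneously, never tracked as a state)
    z_K = 1, z_Na = 1, z_Ca = 2,
    # legacy fitting parameters: parsed and stored, used by no equation
    alpha_EAAT = 0.0032, beta_EAAT = 28.8, r_g = 5e-7, s_g = 9e-6,
    # baseline / clamped concentrations, M
    K_PsC0 = 0.1, Na_PsC0 = 0.015, Ca_PsC0 = 100e-9,
    K_PsECS0 = 0.004, Na_PsECS0 = 0.135, Ca_PsECS = 1.5e-3,
    K_GECS = 0.004, Na_GECS = 0.135, Ca_GECS = 1.5e-3,
    K_AS = 0.1, Na_AS = 0.015, Ca_AS = 100e-9,
    Glu_ECS = 25e-9, Glu_PsC = 1.5e-3, H_PsC = 60e-9, H_PsECS = 40e-9
  )
  neuron <- list(
    C_m = 0.01,            # F/m^2
    g_NaNeu = 1200,        # max voltage-gated Na+ conductance, S/m^2
    g_KNeu = 360,          # max voltage-gated K+ conductance, S/m^2
    g_LNeu = 3,            # leak conductance, S/m^2
    g_KBNeu = 1.0522,      # K+ background conductance, S/m^2 (recalibrated)
    g_NaBNeu = 2.3217,     # Na+ background conductance, S/m^2
    E_NaNeu = 0.115,       # Na+ channel reversal, V (rest-at-zero frame)
    E_KNeu = -0.012,       # K+ channel reversal, V (rest-at-zero frame; the
                           # published -0.12 V is an absolute-frame value)
    E_LNeu = 0.010613,     # leak reversal, V (recalibrated)
    PNKA_maxNeu = 3.7863e-8, # max NKA pump rate magnitude, mol/m^2/s
                             # (published with a direction-encoding minus sign;
                             # recalibrated)
    K_NaiNeu = 10e-3,      # M
    K_KENeu = 1.5e-3,      # M
    Na_Syn = 0.015,        # intraneuronal Na+, M (held constant)
    K_Syn = 0.1,           # intraneuronal K+, M (held constant)
    spike_threshold = 0.05,# V above rest for spike detection
    refractory = 2e-3      # s, spike detector guard
  )
  options <- list(
    include_h_gate = TRUE,      # m^3 h kinetics (FALSE: m^3 as printed)
    k_background_in_psc = TRUE, # astro K+ background feeds the PsC K+ balance
    kir_sqrt = FALSE,           # sqrt([K+]o/1 mM) factor on Kir conductance
    nernst_valence = FALSE,     # divide channel Nernst potentials by z
    pf_valence_charge = FALSE,  # Poole-Frenkel hop charge z*e instead of e
    conc_floor = 1e-12          # M, lower guard on every concentration
  )
  protocol <- list(
    dt = 1e-5,           # s, forward-Euler step
    t_settle = 6,        # s, pre-stimulus settling (0.1 min)
    t_stim = 60,         # s, stimulation window
    t_post = 60,         # s, recovery window
    record_stride = 100, # record every n-th step (1 ms at dt = 10 us)
    seed = 1L,
    stimulus = list(
      type = "pulse",    # "pulse", "constant" or "fixture"
      rate = 10,         # Hz, target firing rate (pulse / fixture)
      amplitude = NA_real_, # A/m^2, set by calibrate_stimulus()
      pulse_width = 2e-3,   # s
      spike_times = numeric(0) # s, used when type = "fixture"
    )
  )
  p <- structure(
    list(geometry = geometry, constants = constants, astrocyte = astrocyte,
         neuron = neuron, options = options, protocol = protocol,
         calibrated = FALSE, calibration = NULL),
    class = "psc_params"
  )
  psc_params_update(p, list(...))
}

# apply a flat named list of overrides to the proper sections
psc_params_update <- function(p, overrides) {
  if (length(overrides) == 0) return(p)
  if (is.null(names(overrides)) || any(names(overrides) == "")) {
    abort("psc_params: overrides must be named")
  }
  sections <- c("constants", "astrocyte", "neuron", "options", "protocol")
  valid <- unlist(lapply(sections, function(s) names(p[[s]])))
  valid <- c(valid, names(p$protocol$stimulus))
  for (nm in names(overrides)) {
    val <- overrides[[nm]]
    hit <- FALSE
    for (s in sections) {
      if (nm %in% names(p[[s]])) {
        p[[s]][[nm]] <- val
        hit <- TRUE
        break
      }
    }
    if (!hit && nm %in% names(p$protocol$stimulus)) {
      p$protocol$stimulus[[nm]] <- val
      hit <- TRUE
    }
    if (!hit) {
      sug <- suggest_key(nm, valid)
      abort(paste0(
        "psc_params: unknown parameter `", nm, "`",
        if (!is.null(sug)) paste0(" (did you mean `", sug, "`?)") else "",
        "\nValid keys: ", paste(sort(unique(valid)), collapse = ", ")
      ))
    }
  }
  validate_params(p)
}

# nearest valid key by edit distance, for error messages
suggest_key <- function(key, valid) {
  d <- adist(key, valid, ignore.case = TRUE)
  if (min(d) <= 2) valid[which.min(d)] else NULL
}

params_problems <- function(p) {
  a <- p$astrocyte
  conc <- c(K_PsC0 = a$K_PsC0, Na_PsC0 = a$Na_PsC0, Ca_PsC0 = a$Ca_PsC0,
            K_PsECS0 = a$K_PsECS0, Na_PsECS0 = a$Na_PsECS0,
            Ca_PsECS = a$Ca_PsECS, K_GECS = a$K_GECS, Na_GECS = a$Na_GECS,
            K_AS = a$K_AS, Na_AS = a$Na_AS, Ca_AS = a$Ca_AS)
  problems <- character(0)
  if (any(conc <= 0)) {
    problems <- c(problems, paste0("non-positive concentration: ",
                                   paste(names(conc)[conc <= 0], collapse = ", ")))
  }
  if (!(a$gamma > 0 && a$gamma < 1)) {
    problems <- c(problems, "gamma must lie in (0, 1)")
  }
  if (!(a$z_K == 1 && a$z_Na == 1 && a$z_Ca == 2)) {
    problems <- c(problems, "valences must be z_K = 1, z_Na = 1, z_Ca = 2")
  }
  if (p$protocol$dt <= 0) problems <- c(problems, "dt must be > 0")
  for (nm in c("t_settle", "t_stim", "t_post")) {
    if (p$protocol[[nm]] < 0) problems <- c(problems, paste0(nm, " must be >= 0"))
  }
  if (!p$protocol$stimulus$type %in% c("pulse", "constant", "fixture")) {
    problems <- c(problems, "stimulus type must be 'pulse', 'constant' or 'fixture'")
  }
  problems
}

validate_params <- function(p) {
  problems <- params_problems(p)
  if (length(problems) > 0) {
    abort(paste0("psc_params: invalid parameters:\n  - ",
                 paste(problems, collapse = "\n  - ")))
  }
  p
}

#' @export
print.psc_params <- function(x, ...) {
  cat("<psc_params>", if (isTRUE(x$calibrated)) "(calibrated)" else "(uncalibrated)", "\n")
  cat("  geometry: cradle r_IPS =", format(x$geometry$r_IPS), "m, process l_P =",
      format(x$geometry$l_P), "m\n")
  cat("  astrocyte: V_A =", x$astrocyte$V_A, "V, J0 =", x$astrocyte$J0,
      "M/s, tau_EAAT =", x$astrocyte$tau_EAAT, "s\n")
  cat("  protocol:", x$protocol$stimulus$type, "stimulus,",
      x$protocol$stimulus$rate, "Hz, dt =", x$protocol$dt, "s\n")
  invisible(x)
}

#' @describeIn psc_params Flatten a parameter set into a long tibble
#'   (section, parameter, value) of its scalar entries.
#' @param x A `psc_params` object.
#' @param ... Unused.
#' @export
tidy.psc_params <- function(x, ...) {
  rows <- purrr::map_dfr(
    c("constants", "astrocyte", "neuron", "options", "protocol"),
    function(s) {
      vals <- x[[s]]
      vals <- vals[vapply(vals, function(v) is.numeric(v) && length(v) == 1, logical(1))]
      tibble::tibble(section = s, parameter = names(vals),
                     value = unlist(vals, use.names = FALSE))
    }
  )
  rows
}

#' Baseline state vector of the coupled model
#'
#' The dynamic state comprises the neurone membrane potential and gating
#' variables, the EAAT flux state, and the five free concentrations. The
#' neurone starts at its rest-frame fixed point (V = 0 with steady-state
#' gates); the cradle and PsECS start at their baseline concentrations
#' (after `psc_calibrate()` the resting Ca2+ is the exact NCX equilibrium).
#'
#' @param params A [psc_params()] object.
#' @return A named numeric vector with elements `V_Neu`, `m`, `h`, `n`,
#'   `J_NaEAAT`, `K_PsC`, `Na_PsC`, `Ca_PsC`, `K_PsECS`, `Na_PsECS`.
#' @examples
#' baseline_state(psc_params())
#' @export
baseline_state <- function(params) {
  stopifnot(inherits(params, "psc_params"))
  g <- hh_steady_gates(0)
  a <- params$astrocyte
  c(V_Neu = 0, m = g[["m"]], h = g[["h"]], n = g[["n"]], J_NaEAAT = 0,
    K_PsC = a$K_PsC0, Na_PsC = a$Na_PsC0, Ca_PsC = a$Ca_PsC0,
    K_PsECS = a$K_PsECS0, Na_PsECS = a$Na_PsECS0)
}
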