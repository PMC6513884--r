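psc_record_columns <- c(
  "time", "V_Neu", "m", "h", "n", "J_NaEAAT",
  "K_PsC", "Na_PsC", "Ca_PsC", "K_PsECS", "Na_PsECS",
  "I_Kir", "I_KNKA", "I_KEAAT", "I_KB", "I_KPF", "I_KECSL",
  "I_NaB", "I_NaNKA", "I_NaEAAT", "I_NaNCX", "I_NaPF", "I_NaECSL",
  "I_CaNCX", "I_CaPF",
  "I_KNeu", "I_NaNeu", "I_LNeu", "I_KBNeu", "I_NaBNeu",
  "I_KNKANeu", "I_NaNKANeu", "I_stim",
  "audit_K", "audit_Na", "audit_Ca"
)

# flatten a psc_params object into the engine's parameter list
flatten_params <- function(params) {
  g <- params$geometry
  cst <- params$constants
  a <- params$astrocyte
  n <- params$neuron
  o <- params$options
  list(
    SA_PsC = g$SA_PS, Vol_PsC = g$Vol_PS, Vol_PsECS = g$Vol_PsECS,
    SA_Syn = g$SA_Syn, SA_ECSL = g$SA_PsECS_GECS, CSA_P = g$CSA_P, l_P = g$l_P,
    R = cst$R, T = cst$T, F = cst$F, k_B = cst$k_B, Q = cst$Q,
    eps = cst$eps0 * cst$eps_r,
    V_A = a$V_A, V_m = a$V_m, g_Kir = a$g_Kir, g_K = a$g_K, g_Na = a$g_Na,
    g_ECS = a$g_ECS, g_ECS_Na = a$g_ECS_Na, K_K = a$K_K, K_Na = a$K_Na, K_Ca = a$K_Ca,
    phi_w = a$phi_w, PNKA_max = a$PNKA_max, K_Nai = a$K_Nai, K_KE = a$K_KE,
    I_bar_NCX = a$I_bar_NCX, gamma = a$gamma, J0 = a$J0, tau = a$tau_EAAT,
    K_AS = a$K_AS, Na_AS = a$Na_AS, Ca_AS = a$Ca_AS,
    K_GECS = a$K_GECS, Na_GECS = a$Na_GECS, Ca_PsECS = a$Ca_PsECS,
    z_K = a$z_K, z_Na = a$z_Na, z_Ca = a$z_Ca,
    C_m_neu = n$C_m, g_NaNeu = n$g_NaNeu, g_KNeu = n$g_KNeu,
    g_LNeu = n$g_LNeu, g_KBNeu = n$g_KBNeu, g_NaBNeu = n$g_NaBNeu,
    E_NaNeu = n$E_NaNeu, E_KNeu = n$E_KNeu, E_LNeu = n$E_LNeu,
    PNKA_maxNeu = n$PNKA_maxNeu, K_NaiNeu = n$K_NaiNeu, K_KENeu = n$K_KENeu,
    Na_Syn = n$Na_Syn, K_Syn = n$K_Syn,
    spike_threshold = n$spike_threshold, refractory = n$refractory,
    include_h = isTRUE(o$include_h_gate),
    k_bg_in_psc = isTRUE(o$k_background_in_psc),
    kir_sqrt = isTRUE(o$kir_sqrt),
    nernst_z = isTRUE(o$nernst_valence),
    pf_z = isTRUE(o$pf_valence_charge),
    conc_floor = o$conc_floor
  )
}

#' Concentration derivatives of the five free compartment concentrations
#'
#' Assembles the cradle and PsECS balance equations from a set of named
#' currents (see [astrocyte_currents()] and [neuron_currents()] for the sign
#' conventions); the global ECS and soma are clamped. Currents are converted
#' to concentration rates by `z F Vol` with compartment volumes in litres.
#'
#' @param state Named state vector (unused except for validation; the
#'   derivatives depend on the currents alone).
#' @param currents Named list, one-row tibble or named vector containing all
#'   entries of [astrocyte_currents()] plus `I_KNeu_tot` and `I_NaNeu_tot`
#'   (total neuronal K+ and Na+ currents, positive into the PsECS).
#' @param params A [psc_params()] object.
#' @return Named numeric vector of derivatives (M/s): `K_PsC`, `Na_PsC`,
#'   `Ca_PsC`, `K_PsECS`, `Na_PsECS`.
#' @export
concentration_rhs <- function(state, currents, params) {
  cur <- as.list(currents)
  need <- c("I_Kir", "I_KNKA", "I_KEAAT", "I_KB", "I_KPF", "I_KECSL",
            "I_NaB", "I_NaNKA", "I_NaEAAT", "I_NaNCX", "I_NaPF", "I_NaECSL",
            "I_CaNCX", "I_CaPF", "I_KNeu_tot", "I_NaNeu_tot")
  missing <- setdiff(need, names(cur))
  if (length(missing) > 0) {
    abort(paste0("concentration_rhs: missing currents: ",
                 paste(missing, collapse = ", ")))
  }
  FF <- params$constants$F
  vol_psc <- params$geometry$Vol_PS
  vol_ecs <- params$geometry$Vol_PsECS
  z_Ca <- params$astrocyte$z_Ca
  I_Km <- cur$I_Kir + cur$I_KNKA + cur$I_KEAAT + cur$I_KB
  I_Nam <- cur$I_NaB + cur$I_NaNKA + cur$I_NaEAAT + cur$I_NaNCX
  kb_psc <- if (isTRUE(params$options$k_background_in_psc)) cur$I_KB else 0
  c(
    K_PsC = -(cur$I_Kir + cur$I_KNKA + cur$I_KEAAT + kb_psc + cur$I_KPF) /
      (FF * vol_psc),
    Na_PsC = -(I_Nam + cur$I_NaPF) / (FF * vol_psc),
    Ca_PsC = -(cur$I_CaNCX + cur$I_CaPF) / (z_Ca * FF * vol_psc),
    K_PsECS = (cur$I_KNeu_tot + I_Km - cur$I_KECSL) / (FF * vol_ecs),
    Na_PsECS = (cur$I_NaNeu_tot + I_Nam - cur$I_NaECSL) / (FF * vol_ecs)
  )
}

#' One forward-Euler step of the full coupled model (reference implementation)
#'
#' Pure-R single step used as the readable reference for — and in the test
#' suite cross-checked against — the compiled inner loop that
#' [run_protocol()] uses. Order of operations within a step: neurone currents
#' and voltage/gate update, glutamate-release impulse onto the EAAT flux,
#' astrocytic currents at the (post-impulse) flux, concentration update,
#' EAAT decay.
#'
#' @param state Named state vector (see [baseline_state()]).
#' @param dt Time step (s); `dt = 0` returns the state unchanged.
#' @param params A [psc_params()] object.
#' @param stimulus Stimulus current density into the neurone (A/m^2).
#' @param spike_now Logical: does a glutamate-release event land on this step?
#' @return The updated state vector.
#' @export
euler_step <- function(state, dt, params, stimulus = 0, spike_now = FALSE) {
  if (dt < 0) abort("euler_step: dt must be >= 0")
  if (dt == 0) return(state)
  ncur <- neuron_currents(state, params)
  new_neuron <- neuron_step(state, stimulus, dt, params)
  if (isTRUE(spike_now)) {
    state[["J_NaEAAT"]] <- state[["J_NaEAAT"]] + params$astrocyte$J0
  }
  acur <- astrocyte_currents(state, params)
  cur <- c(as.list(acur),
           list(I_KNeu_tot = unname(ncur[["I_KNeu"]] + ncur[["I_KBNeu"]] +
                                      ncur[["I_KNKANeu"]]),
                I_NaNeu_tot = unname(ncur[["I_NaNeu"]] + ncur[["I_NaBNeu"]] +
                                       ncur[["I_NaNKANeu"]])))
  d <- concentration_rhs(state, cur, params)
  for (nm in names(d)) {
    state[[nm]] <- state[[nm]] + dt * d[[nm]]
    if (state[[nm]] < params$options$conc_floor) {
      warn(paste0("euler_step: ", nm, " floored at ",
                  format(params$options$conc_floor), " M"))
      state[[nm]] <- params$options$conc_floor
    }
  }
  state[["J_NaEAAT"]] <- state[["J_NaEAAT"]] -
    dt * state[["J_NaEAAT"]] / params$astrocyte$tau_EAAT
  state[["V_Neu"]] <- new_neuron[["V_Neu"]]
  state[["m"]] <- new_neuron[["m"]]
  state[["h"]] <- new_neuron[["h"]]
  state[["n"]] <- new_neuron[["n"]]
  bad <- names(state)[!is.finite(state)]
  if (length(bad) > 0) {
    abort(paste0("euler_step: non-finite state variable ", bad[1]))
  }
  state
}

#' Run the stimulation protocol
#'
#' Integrates the coupled neurone-astrocyte model through the three protocol
#' phases — settle (no stimulus), stimulate, recover — with the compiled
#' forward-Euler loop, recording states, all named pathway currents and the
#' mole-conservation audit at the configured stride. The default protocol
#' emulates sustained physiological firing: a pulse-train stimulus entrains
#' the neurone at the target rate, each spike releases glutamate which the
#' EAAT flux state absorbs instantaneously.
#'
#' @param params A calibrated [psc_params()] object (see [psc_calibrate()]);
#'   protocol settings live in `params$protocol`.
#' @param calibrate_amplitude Logical; if the stimulus amplitude is `NA`,
#'   derive it with [calibrate_stimulus()] before the run.
#' @return A `psc_sim` object: list with `data` (tibble, one row per recorded
#'   step, one column per state/current plus audits), `spike_times`,
#'   `floor_events`, `final_state`, `params` and `meta` (phase boundaries,
#'   calibrated constants, config hash). Deterministic: identical
#'   configurations give identical results.
#' @examples
#' \dontrun{
#' p <- psc_calibrate(psc_params(t_settle = 1, t_stim = 5, t_post = 2))
#' sim <- run_protocol(p)
#' glance(sim)
#' }
#' @export
run_protocol <- function(params, calibrate_amplitude = TRUE) {
  stopifnot(inherits(params, "psc_params"))
  if (!isTRUE(params$calibrated)) {
    abort(paste0("run_protocol: parameters are not calibrated; run ",
                 "psc_calibrate() first (background conductances, EAAT tau ",
                 "and resting Ca2+ must be consistent)"))
  }
  pr <- params$protocol
  stim <- pr$stimulus
  if (pr$t_settle + pr$t_stim + pr$t_post <= 0) {
    abort("run_protocol: protocol has zero total duration")
  }
  if (stim$type %in% c("pulse", "constant") && is.na(stim$amplitude)) {
    if (!calibrate_amplitude) {
      abort("run_protocol: stimulus amplitude is NA")
    }
    cal <- calibrate_stimulus(params, stim$rate, type = stim$type)
    stim$amplitude <- cal$amplitude
    params$protocol$stimulus$amplitude <- cal$amplitude
  }
  fixture_times <- if (stim$type == "fixture") {
    stim$spike_times + pr$t_settle
  } else {
    numeric(0)
  }
  out <- .engine_run(
    init = baseline_state(params),
    par = flatten_params(params),
    dt = pr$dt,
    t_settle = pr$t_settle, t_stim = pr$t_stim, t_post = pr$t_post,
    stim_type = stim$type, stim_rate = stim$rate %||% 0,
    stim_amplitude = stim$amplitude %||% 0,
    pulse_width = stim$pulse_width %||% 2e-3,
    fixture_times = fixture_times,
    record_stride = as.integer(pr$record_stride)
  )
  data <- tibble::as_tibble(as.data.frame(out$records))
  names(data) <- psc_record_columns
  meta <- list(
    t_settle = pr$t_settle, t_stim = pr$t_stim, t_post = pr$t_post,
    dt = pr$dt, record_stride = pr$record_stride,
    stimulus = stim,
    calibration = params$calibration$after,
    floored = out$floor_events > 0,
    config_hash = rlang::hash(params)
  )
  structure(
    list(data = data, spike_times = out$spike_times,
         floor_events = out$floor_events, final_state = out$final_state,
         params = params, meta = meta),
    class = "psc_sim"
  )
}

#' Sweep stimulation rates
#'
#' Runs the protocol at several target firing rates and binds plateau
#' summaries ([glance()]) into one tibble.
#'
#' @param params A calibrated [psc_params()] object.
#' @param rates Target firing rates (Hz).
#' @return A tibble with one row per rate (columns of [glance.psc_sim()]).
#' @export
sweep_rates <- function(params, rates = c(10, 20, 30)) {
  purrr::map_dfr(rates, function(r) {
    p <- params
    p$protocol$stimulus$rate <- r
    p$protocol$stimulus$amplitude <- NA_real_
    sim <- run_protocol(p)
    glance(sim)
  })
}

#' @export
print.psc_sim <- function(x, ...) {
  cat("<psc_sim> ", nrow(x$data), " recorded steps, ",
      length(x$spike_times), " spikes\n", sep = "")
  cat("  phases: settle ", x$meta$t_settle, " s | stimulate ", x$meta$t_stim,
      " s (", x$meta$stimulus$type, ") | recover ", x$meta$t_post, " s\n",
      sep = "")
  if (isTRUE(x$meta$floored)) {
    cat("  WARNING: concentration floor events occurred; run is non-physiological\n")
  }
  print(utils::head(x$data[, c("time", "K_PsC", "Na_PsC", "Ca_PsC",
                               "K_PsECS", "Na_PsECS")], 5))
  invisible(x)
}

# phase label for each recorded time
sim_phase <- function(sim) {
  t <- sim$data$time
  dplyr::case_when(
    t < sim$meta$t_settle ~ "settle",
    t < sim$meta$t_settle + sim$meta$t_stim ~ "stimulate",
    .default = "recover"
  )
}

#' Plateau summary of a simulation
#'
#' One-row summary: plateau concentrations (mean over the last 20% of the
#' stimulation window), their baselines, the measured firing rate, the mean
#' stimulated NCX current density, and the worst mole-conservation audit.
#'
#' @param x A `psc_sim` object.
#' @param ... Unused.
#' @return A one-row tibble.
#' @export
glance.psc_sim <- function(x, ...) {
  d <- x$data
  ph <- sim_phase(x)
  stim_end <- x$meta$t_settle + x$meta$t_stim
  plateau <- d[ph == "stimulate" &
                 d$time >= x$meta$t_settle + 0.8 * x$meta$t_stim, ]
  rest <- d[ph == "settle", ]
  if (nrow(rest) == 0) rest <- d[1, ]
  sa <- x$params$geometry$SA_PS %||% x$meta$SA_PsC
  tibble::tibble(
    rate_target = x$meta$stimulus$rate %||% NA_real_,
    rate_measured = measured_spike_rate(
      x$spike_times, c(x$meta$t_settle, stim_end)),
    K_PsC_plateau = mean(plateau$K_PsC), Na_PsC_plateau = mean(plateau$Na_PsC),
    Ca_PsC_plateau = mean(plateau$Ca_PsC),
    K_PsC_rest = mean(rest$K_PsC), Na_PsC_rest = mean(rest$Na_PsC),
    Ca_PsC_rest = mean(rest$Ca_PsC),
    I_NaNCX_stim_density = mean(plateau$I_NaNCX) / sa,
    I_NaNCX_rest_density = mean(rest$I_NaNCX) / sa,
    max_abs_audit = max(abs(c(d$audit_K, d$audit_Na, d$audit_Ca))),
    floor_events = x$floor_events,
    n_spikes = length(x$spike_times)
  )
}

#' Tidy a simulation into long format
#'
#' @param x A `psc_sim` object.
#' @param variables Which column groups to pivot: `"states"`, `"currents"`
#'   or `"all"`.
#' @param ... Unused.
#' @return A tibble with columns `time`, `phase`, `variable`, `value`.
#' @export
tidy.psc_sim <- function(x, variables = c("states", "currents", "all"), ...) {
  variables <- match.arg(variables)
  states <- c("V_Neu", "J_NaEAAT", "K_PsC", "Na_PsC", "Ca_PsC",
              "K_PsECS", "Na_PsECS")
  currents <- grep("^I_", psc_record_columns, value = TRUE)
  keep <- switch(variables,
                 states = states,
                 currents = currents,
                 all = c(states, currents))
  d <- dplyr::mutate(x$data, phase = sim_phase(x))
  tidyr::pivot_longer(d[, c("time", "phase", keep)],
                      cols = dplyr::all_of(keep),
                      names_to = "variable", values_to = "value")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
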