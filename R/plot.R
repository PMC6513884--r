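#' Plot a simulation
#'
#' Faceted ggplot2 time courses of the cradle and PsECS states (default) or
#' of the named pathway currents, with the stimulation window shaded.
#'
#' @param object A `psc_sim` object.
#' @param variables `"states"`, `"currents"` or `"all"` (see
#'   [tidy.psc_sim()]).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.psc_sim <- function(object, variables = "states", ...) {
  long <- tidy(object, variables = variables)
  stim_on <- object$meta$t_settle
  stim_off <- object$meta$t_settle + object$meta$t_stim
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time, y = .data$value)) +
    ggplot2::annotate("rect", xmin = stim_on, xmax = stim_off,
                      ymin = -Inf, ymax = Inf, alpha = 0.08, fill = "orange") +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~variable, scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = NULL,
                  title = "Perisynaptic cradle simulation",
                  subtitle = paste0(object$meta$stimulus$type, " stimulus, ",
                                    object$meta$stimulus$rate %||% 0, " Hz")) +
    ggplot2::theme_minimal(base_size = 9)
}

#' Plot cradle microdomain concentrations
#'
#' Cradle K+, Na+ and Ca2+ time courses relative to baseline — the three
#' microdomains — on free y scales.
#'
#' @param sim A `psc_sim` object.
#' @return A ggplot object.
#' @export
plot_microdomains <- function(sim) {
  d <- tidy(sim, variables = "states")
  d <- dplyr::filter(d, .data$variable %in% c("K_PsC", "Na_PsC", "Ca_PsC"))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$time, y = .data$value * 1e3)) +
    ggplot2::geom_line(linewidth = 0.3, colour = "steelblue") +
    ggplot2::facet_wrap(~variable, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = "concentration (mM)",
                  title = "Cradle ion microdomains") +
    ggplot2::theme_minimal(base_size = 9)
}
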