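#' Compartment geometry of the perisynaptic cradle model
#'
#' Derives all cross-sectional areas, surface areas and volumes of the
#' six-compartment cradle model from its primitive lengths. The cradle is a
#' half cylindrical shell that enwraps the synapse (astrocytic cradles cover
#' roughly half of a synapse's surface), so every cradle, perisynaptic-ECS and
#' synapse lateral quantity carries a factor 1/2; the astrocyte process is a
#' full cylinder. Two quantities are not derivable from the listed lengths and
#' are carried as literal constants: the synapse volume `Vol_Syn` and the
#' PsECS-to-global-ECS exchange area `SA_PsECS_GECS`.
#'
#' Lengths are metres; areas square metres; volumes litres.
#'
#' @param d_IPS Perisynaptic (cradle) internal diameter (m).
#' @param d_EPS Perisynaptic external diameter (m).
#' @param l_PS Perisynaptic length (m).
#' @param d_P Process diameter (m).
#' @param l_P Process length (m).
#' @param d_Syn Synapse diameter (m).
#' @param l_Syn Synapse length (m).
#' @param Vol_Syn Synapse volume (L), carried as a constant.
#' @param SA_PsECS_GECS Exchange area between perisynaptic and global
#'   extracellular space (m^2), carried as a constant.
#'
#' @return An object of class `psc_geometry`: a named list of lengths, radii,
#'   areas and volumes. `tidy()` turns it into a tibble.
#'
#' @examples
#' geo <- psc_geometry()
#' geo$CSA_P    # pi * (50 nm)^2
#' tidy(geo)
#' @export
psc_geometry <- function(d_IPS = 300e-9,
                         d_EPS = 500e-9,
                         l_PS = 300e-9,
                         d_P = 100e-9,
                         l_P = 25e-6,
                         d_Syn = 270e-9,
                         l_Syn = 300e-9,
                         Vol_Syn = 8.5883e-16,
                         SA_PsECS_GECS = 1.5715e-14) {
  lengths <- c(d_IPS = d_IPS, d_EPS = d_EPS, l_PS = l_PS, d_P = d_P,
               l_P = l_P, d_Syn = d_Syn, l_Syn = l_Syn,
               Vol_Syn = Vol_Syn, SA_PsECS_GECS = SA_PsECS_GECS)
  bad <- names(lengths)[!is.finite(lengths) | lengths <= 0]
  if (length(bad) > 0) {
    abort(paste0("psc_geometry: non-positive or non-finite dimensions: ",
                 paste(bad, collapse = ", ")))
  }
  r_IPS <- d_IPS / 2
  r_EPS <- d_EPS / 2
  r_P <- d_P / 2
  r_Syn <- d_Syn / 2
  if (r_EPS < r_IPS) {
    abort("psc_geometry: external radius r_EPS must be >= internal radius r_IPS")
  }
  if (r_Syn > r_IPS) {
    abort("psc_geometry: synapse radius r_Syn must fit inside the cradle (r_Syn <= r_IPS)")
  }
  m3_to_L <- 1e3
  geo <- list(
    d_IPS = d_IPS, d_EPS = d_EPS, r_IPS = r_IPS, r_EPS = r_EPS, l_PS = l_PS,
    d_P = d_P, r_P = r_P, l_P = l_P,
    d_Syn = d_Syn, r_Syn = r_Syn, l_Syn = l_Syn,
    # half-wrap cradle quantities
    CSA_PS = pi * r_IPS^2 / 2,
    SA_PS = pi * r_IPS * l_PS,            # half of 2*pi*r*l
    CSA_Syn = pi * r_Syn^2 / 2,
    SA_Syn = pi * r_Syn * l_Syn,
    # full-cylinder process
    CSA_P = pi * r_P^2,
    SA_P = 2 * pi * r_P * l_P,
    SA_PsECS_GECS = SA_PsECS_GECS,
    Vol_PS = pi * (r_EPS^2 - r_IPS^2) * l_PS / 2 * m3_to_L,
    Vol_P = pi * r_P^2 * l_P * m3_to_L,
    Vol_Syn = Vol_Syn,
    Vol_PsECS = pi * (r_IPS^2 - r_Syn^2) * l_PS / 2 * m3_to_L
  )
  structure(geo, class = "psc_geometry")
}

#' @export
print.psc_geometry <- function(x, ...) {
  cat("<psc_geometry>\n")
  print(tidy(x), n = Inf)
  invisible(x)
}

#' @describeIn psc_geometry Tidy a geometry into a tibble of quantities.
#' @param x A `psc_geometry` object.
#' @param ... Unused.
#' @export
tidy.psc_geometry <- function(x, ...) {
  unit <- function(nm) {
    if (grepl("^Vol", nm)) "L" else if (grepl("^(CSA|SA)", nm)) "m^2" else "m"
  }
  tibble::tibble(
    quantity = names(unclass(x)),
    value = unlist(unclass(x), use.names = FALSE),
    unit = vapply(names(unclass(x)), unit, character(1), USE.NAMES = FALSE)
  )
}
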