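# units for each record column, used in CSV headers and the JSON sidecar
psc_column_units <- function() {
  cols <- psc_record_columns
  units <- character(length(cols))
  units[cols == "time"] <- "s"
  units[cols == "V_Neu"] <- "V"
  units[cols %in% c("m", "h", "n")] <- "1"
  units[cols == "J_NaEAAT"] <- "M/s"
  units[cols %in% c("K_PsC", "Na_PsC", "Ca_PsC", "K_PsECS", "Na_PsECS")] <- "M"
  units[grepl("^I_", cols)] <- "A"
  units[cols == "I_stim"] <- "A/m2"
  units[grepl("^audit_", cols)] <- "1"
  stats::setNames(units, cols)
}

#' Write a simulation to CSV with a JSON sidecar
#'
#' The time series goes to `<prefix>.csv` (RFC-4180, '.' decimal, one column
#' per state/current, header `name [unit]`, 15 significant digits); run
#' metadata — config hash, calibrated constants, protocol, spike event
#' times — goes to `<prefix>.json`. [read_timeseries()] restores both.
#'
#' @param sim A `psc_sim` object.
#' @param prefix Output path prefix (directories must exist).
#' @return Invisibly, the two file paths.
#' @export
write_timeseries <- function(sim, prefix) {
  stopifnot(inherits(sim, "psc_sim"))
  csv <- paste0(prefix, ".csv")
  json <- paste0(prefix, ".json")
  dir <- dirname(csv)
  if (!dir.exists(dir)) abort(paste0("write_timeseries: no such directory: ", dir))
  units <- psc_column_units()
  d <- sim$data
  header <- paste0(names(d), " [", units[names(d)], "]")
  out <- vapply(d, function(col) sprintf("%.15g", col), character(nrow(d)))
  if (nrow(d) == 1) out <- matrix(out, nrow = 1)
  con <- file(csv, "w")
  on.exit(close(con), add = TRUE)
  writeLines(paste(header, collapse = ","), con)
  if (nrow(d) > 0) {
    writeLines(apply(out, 1, paste, collapse = ","), con)
  }
  meta <- sim$meta
  meta$SA_PsC <- sim$params$geometry$SA_PS %||% meta$SA_PsC
  jsonlite::write_json(
    list(meta = meta, spike_times = sim$spike_times,
         floor_events = sim$floor_events, final_state = as.list(sim$final_state),
         columns = as.list(units[names(d)])),
    json, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(c(csv = csv, json = json))
}

#' Read a simulation written by [write_timeseries()]
#'
#' @param prefix Path prefix used when writing.
#' @return A `psc_sim` object (without the full parameter set; plateau
#'   summaries and plots work from the sidecar metadata).
#' @export
read_timeseries <- function(prefix) {
  csv <- paste0(prefix, ".csv")
  json <- paste0(prefix, ".json")
  if (!file.exists(csv) || !file.exists(json)) {
    abort(paste0("read_timeseries: missing ", csv, " or ", json))
  }
  raw <- utils::read.csv(csv, check.names = FALSE)
  names(raw) <- sub(" \\[.*\\]$", "", names(raw))
  side <- jsonlite::read_json(json, simplifyVector = TRUE)
  meta <- side$meta
  structure(
    list(data = tibble::as_tibble(raw),
         spike_times = as.numeric(side$spike_times),
         floor_events = side$floor_events,
         final_state = unlist(side$final_state),
         params = NULL,
         meta = meta),
    class = "psc_sim"
  )
}

#' Read and validate a model configuration file
#'
#' YAML (or JSON) configuration with sections `geometry`, `constants`,
#' `astrocyte`, `neuron`, `options`, `protocol` (with nested `stimulus`).
#' Every key defaults to the published table value, so an empty file yields
#' the default model. Unknown sections or keys are rejected with the full
#' list of violations at once and a nearest-key suggestion.
#'
#' @param path Path to the configuration file.
#' @return A validated [psc_params()] object.
#' @export
read_psc_config <- function(path) {
  if (!file.exists(path)) abort(paste0("read_psc_config: no such file: ", path))
  raw <- yaml::read_yaml(path)
  validate_config(raw)
}

#' Validate a raw configuration list
#'
#' @param raw Nested list as produced by reading a config file; `NULL` or an
#'   empty list yields the full default parameter set.
#' @return A validated [psc_params()] object.
#' @export
validate_config <- function(raw) {
  if (is.null(raw) || length(raw) == 0) return(psc_params())
  defaults <- psc_params()
  geom_keys <- names(formals(psc_geometry))
  sections <- list(
    geometry = geom_keys,
    constants = names(defaults$constants),
    astrocyte = names(defaults$astrocyte),
    neuron = names(defaults$neuron),
    options = names(defaults$options),
    protocol = names(defaults$protocol)
  )
  violations <- character(0)
  bad_sections <- setdiff(names(raw), names(sections))
  for (s in bad_sections) {
    sug <- suggest_key(s, names(sections))
    violations <- c(violations, paste0(
      "unknown section `", s, "`",
      if (!is.null(sug)) paste0(" (did you mean `", sug, "`?)") else "",
      "; valid sections: ", paste(names(sections), collapse = ", ")))
  }
  for (s in intersect(names(raw), names(sections))) {
    keys <- names(raw[[s]])
    if (length(raw[[s]]) > 0 && is.null(keys)) {
      violations <- c(violations, paste0("section `", s, "` must be a mapping"))
      next
    }
    valid <- sections[[s]]
    for (k in keys) {
      if (s == "protocol" && k == "stimulus") {
        stim_keys <- names(defaults$protocol$stimulus)
        for (sk in setdiff(names(raw[[s]][[k]]), stim_keys)) {
          sug <- suggest_key(sk, stim_keys)
          violations <- c(violations, paste0(
            "unknown key `protocol.stimulus.", sk, "`",
            if (!is.null(sug)) paste0(" (did you mean `", sug, "`?)") else "",
            "; valid keys: ", paste(stim_keys, collapse = ", ")))
        }
        next
      }
      if (!k %in% valid) {
        sug <- suggest_key(k, valid)
        violations <- c(violations, paste0(
          "unknown key `", s, ".", k, "`",
          if (!is.null(sug)) paste0(" (did you mean `", sug, "`?)") else "",
          "; valid keys: ", paste(valid, collapse = ", ")))
      }
    }
  }
  # apply the recognised keys so value checks can be aggregated with the
  # schema violations and everything is reported at once
  geometry <- tryCatch(do.call(psc_geometry, raw$geometry %||% list()),
                       error = function(e) {
                         violations <<- c(violations, conditionMessage(e))
                         psc_geometry()
                       })
  p <- psc_params(geometry = geometry)
  for (s in intersect(c("constants", "astrocyte", "neuron", "options"),
                      names(raw))) {
    for (k in intersect(names(raw[[s]]), sections[[s]])) {
      p[[s]][[k]] <- raw[[s]][[k]]
    }
  }
  for (k in intersect(setdiff(names(raw$protocol), "stimulus"),
                      sections$protocol)) {
    p$protocol[[k]] <- raw$protocol[[k]]
  }
  for (k in intersect(names(raw$protocol$stimulus),
                      names(defaults$protocol$stimulus))) {
    p$protocol$stimulus[[k]] <- raw$protocol$stimulus[[k]]
  }
  violations <- c(violations, params_problems(p))
  if (length(violations) > 0) {
    abort(paste0("invalid configuration:\n  - ",
                 paste(violations, collapse = "\n  - ")))
  }
  p
}

#' Serialize a parameter set back to YAML
#'
#' Writes the configuration in the same section layout that
#' [read_psc_config()] accepts; serializing the default [psc_params()]
#' reproduces the packaged defaults file byte-for-byte
#' (`system.file("extdata", "default-config.yaml", package = "pscradle")`).
#'
#' @param params A [psc_params()] object.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_psc_config <- function(params, path) {
  geom_keys <- names(formals(psc_geometry))
  cfg <- list(
    geometry = params$geometry[geom_keys],
    constants = params$constants,
    astrocyte = params$astrocyte,
    neuron = params$neuron,
    options = params$options,
    protocol = params$protocol
  )
  yaml::write_yaml(cfg, path, precision = 15)
  invisible(path)
}
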