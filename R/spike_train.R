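#' Deterministic spike-train fixtures
#'
#' Regular (optionally jittered) spike event trains used to drive the
#' astrocyte model without the Hodgkin-Huxley neurone (stimulus type
#' `"fixture"` in [run_protocol()]), and in unit tests. Events use the
#' centred convention: at rate `r`, events sit at `(i - 1/2) / r`.
#'
#' @param rate Event rate (Hz, >= 0); 0 gives an empty train.
#' @param duration Train length (s, > 0).
#' @param jitter Uniform jitter as a fraction of the inter-event interval,
#'   in `[0, 0.5)`; the train stays strictly increasing and inside
#'   `[0, duration]`.
#' @param seed Integer seed for the jitter; the same seed always reproduces
#'   the same train. Ignored when `jitter = 0`.
#' @return A `psc_spike_train` object: list with `times` (s), `rate`,
#'   `duration`, `jitter`, `seed`.
#' @examples
#' generate_spike_train(10, 1)$times   # 0.05, 0.15, ..., 0.95
#' @export
generate_spike_train <- function(rate, duration, jitter = 0, seed = 1L) {
  if (!is.finite(rate) || rate < 0) abort("generate_spike_train: rate must be >= 0")
  if (!is.finite(duration) || duration <= 0) {
    abort("generate_spike_train: duration must be > 0")
  }
  if (!is.finite(jitter) || jitter < 0 || jitter >= 0.5) {
    abort("generate_spike_train: jitter must lie in [0, 0.5)")
  }
  times <- numeric(0)
  if (rate > 0) {
    k <- seq_len(floor(rate * duration))
    times <- (k - 0.5) / rate
    if (jitter > 0) {
      old <- if (exists(".Random.seed", globalenv())) {
        get(".Random.seed", globalenv())
      }
      on.exit({
        if (!is.null(old)) assign(".Random.seed", old, globalenv())
      }, add = TRUE)
      set.seed(as.integer(seed))
      times <- times + stats::runif(length(times), -jitter, jitter) / rate
      times <- pmin(pmax(times, 0), duration)
    }
  }
  structure(list(times = times, rate = rate, duration = duration,
                 jitter = jitter, seed = as.integer(seed)),
            class = "psc_spike_train")
}

#' @export
print.psc_spike_train <- function(x, ...) {
  cat("<psc_spike_train> ", length(x$times), " events, rate ", x$rate,
      " Hz over ", x$duration, " s (jitter ", x$jitter, ", seed ", x$seed,
      ")\n", sep = "")
  invisible(x)
}

#' @describeIn generate_spike_train Tidy the train into a tibble of events.
#' @param x A `psc_spike_train` object.
#' @param ... Unused.
#' @export
tidy.psc_spike_train <- function(x, ...) {
  tibble::tibble(event = seq_along(x$times), time = x$times)
}
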