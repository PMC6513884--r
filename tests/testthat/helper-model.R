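# shared fixtures: calibrated defaults and a short-protocol builder
calibrated_params <- local({
  p <- NULL
  function() {
    if (is.null(p)) p <<- psc_calibrate(psc_params())
    p
  }
})

# short protocol wrapper: settle/stim/post seconds, returning a fresh params
short_protocol <- function(params, t_settle = 0.5, t_stim = 2, t_post = 0,
                           type = "fixture", rate = 10,
                           spike_times = numeric(0), dt = 1e-5,
                           record_stride = 100L, amplitude = NA_real_) {
  params$protocol$t_settle <- t_settle
  params$protocol$t_stim <- t_stim
  params$protocol$t_post <- t_post
  params$protocol$dt <- dt
  params$protocol$record_stride <- record_stride
  params$protocol$stimulus$type <- type
  params$protocol$stimulus$rate <- rate
  params$protocol$stimulus$amplitude <- amplitude
  params$protocol$stimulus$spike_times <- spike_times
  params
}

rtf310 <- 8.31 * 310 / 96485
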