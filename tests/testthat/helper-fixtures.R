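# shared fixtures, all generated in code

hill_curve <- function(ca, ec50, h) 1 / (1 + (ec50 / ca)^h)

# a pure-decay calcium ramp paired with a Hill-shaped current
make_hill_ramp <- function(ec50 = 0.46, h = 2.6, imax = 500,
                           ca_top = 2.1, rest = 0.1, tau = 200,
                           dt = 1, t_max = 600) {
  tt <- seq(0, t_max, dt)
  ca <- rest + ca_top * exp(-tt / tau)
  list(ca = time_series(ca, dt, 0, "uM"),
       isk = time_series(imax * hill_curve(ca, ec50, h), dt, 0, "pA"),
       imax = imax, tt = tt)
}

# minimal hand-built sweep around a given current vector
make_sweep <- function(values, v = -10, cell = "c1", cond = "baseline",
                       cap = 100, dt = 1, onset = 10, duration = 50) {
  vc_sweep(current = time_series(values, dt, 0, "pA"),
           protocol = step_protocol(v, step_onset = onset,
                                    step_duration = duration),
           capacitance = cap, condition = cond, cell_id = cell)
}

noiseless <- function() noise_params(0, 0)
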