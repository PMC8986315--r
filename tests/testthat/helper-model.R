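# Shared fixtures: default parameters and a fast measurement protocol used
# wherever a test does not depend on long averaging windows.
PARAMS <- model_params()

fast_protocol <- function(rate_window = 3000, ...) {
  measurement_protocol(rate_window = rate_window, rate_settle = 500,
                       rheo_step = 2000, ...)
}

# Reference operating point: on the 40 spk/s range with adaptation present.
REF_BG <- conductance_set(gM = 0.5, gAHP = 1.75)

# Build a minimal sim_trace by hand (for detector/metric tests).
fake_trace <- function(V, dt = 0.1, spike_times = detect_spikes(V, dt)) {
  structure(list(time = (seq_along(V) - 1) * dt, V = V,
                 gates = matrix(0, length(V), 4,
                                dimnames = list(NULL, c("w", "n", "p", "q"))),
                 stim = rep(0, length(V)), spike_times = spike_times,
                 dt = dt, params = PARAMS, g = conductance_set()),
            class = "sim_trace")
}
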