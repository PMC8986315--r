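test_that("subthreshold models settle onto the root of the steady-state current", {
  # oracle: 1-D root find of I_ss(V) = 0 with all gates at steady state
  gs <- list(conductance_set(gNa = 1, gK = 2, gleak = 2),
             conductance_set(gK = 1, gleak = 2),
             conductance_set(gNa = 2, gK = 1, gM = 0.5, gleak = 2, gAHP = 1.75))
  for (g in gs) {
    root <- uniroot(function(v) steady_current(v, g, PARAMS),
                    c(-90, -40), tol = 1e-10)$root
    tr <- simulate_neuron(PARAMS, g, stim_constant(0),
                          sim_config(settle_duration = 500,
                                     record_duration = 500))
    expect_length(tr$spike_times, 0)
    expect_equal(unname(tr$final_state["V"]), root, tolerance = 0.1)
  }
})

test_that("rest is invariant to the initial voltage", {
  g <- conductance_set(gNa = 1, gK = 2, gleak = 2)
  ends <- vapply(c(-80, -60), function(v0) {
    tr <- simulate_neuron(PARAMS, g, stim_constant(0),
                          sim_config(settle_duration = 1000,
                                     record_duration = 100),
                          initial = channelreg:::state_at(v0, PARAMS))
    unname(tr$final_state["V"])
  }, numeric(1))
  expect_equal(ends[1], ends[2], tolerance = 0.01)
})

test_that("a dominant leak pins rest at the leak reversal", {
  st <- find_rest(PARAMS, conductance_set(gleak = 500))
  expect_equal(unname(st["V"]), PARAMS$E_leak, tolerance = 0.5)
})

test_that("a step above rheobase evokes repetitive spiking", {
  g <- conductance_set(gNa = 1.54, gleak = 2)
  tr <- simulate_neuron(PARAMS, g, stim_constant(35),
                        sim_config(record_duration = 2000))
  expect_gt(length(tr$spike_times), 10)
  expect_true(all(diff(tr$spike_times) > 0))
})

test_that("halving dt changes the spike count of a 2 s run by at most 1", {
  g <- conductance_set(gNa = 2, gK = 1, gleak = 2)
  n <- vapply(c(0.1, 0.05), function(dt) {
    tr <- simulate_neuron(PARAMS, g, stim_constant(35),
                          sim_config(dt = dt, record_duration = 2000))
    length(tr$spike_times)
  }, integer(1))
  expect_lte(abs(n[1] - n[2]), 1)
})

test_that("gating variables stay in [0, 1] without clipping", {
  g <- conductance_set(gNa = 3, gK = 1, gM = 1, gleak = 2, gAHP = 1.75)
  tr <- simulate_neuron(PARAMS, g,
                        stim_ou(mu = 60, sigma = 30, tau = 5, seed = 5),
                        sim_config(record_duration = 2000))
  expect_true(all(tr$gates >= 0 & tr$gates <= 1))
})

test_that("identical inputs give bit-identical traces", {
  g <- conductance_set(gNa = 2, gK = 1, gleak = 2)
  stim <- stim_ou(mu = 40, sigma = 10, tau = 5, seed = 2)
  t1 <- simulate_neuron(PARAMS, g, stim, sim_config(record_duration = 500))
  t2 <- simulate_neuron(PARAMS, g, stim, sim_config(record_duration = 500))
  expect_identical(t1$V, t2$V)
  expect_identical(t1$spike_times, t2$spike_times)
})

test_that("recorded currents balance the stimulus at every step", {
  # Euler-consistent bookkeeping: C dV/dt + sum(I_channel) - I_stim = 0
  g <- conductance_set(gNa = 2, gK = 1, gM = 0.5, gleak = 2, gAHP = 1.75)
  tr <- simulate_neuron(PARAMS, g,
                        stim_ou(mu = 40, sigma = 10, tau = 5, seed = 9),
                        sim_config(record_duration = 200))
  cur <- channel_currents(tr)
  n <- length(tr$V)
  cap <- PARAMS$C * diff(tr$V) / tr$dt
  resid <- cap + rowSums(cur)[-n] - tr$stim[-n]
  expect_lt(max(abs(resid)), 1e-6)
})

test_that("numerical divergence aborts with a step diagnostic", {
  p <- model_params(E_Na = 1e5) # absurd driving force
  expect_error(
    simulate_neuron(p, conductance_set(gNa = 4, gleak = 0.1),
                    stim_constant(100),
                    sim_config(settle_duration = 0, record_duration = 100),
                    initial = channelreg:::state_at(-20, p)),
    "divergence")
})

test_that("spike detection follows the crossing convention", {
  dt <- 1
  two <- c(-60, 10, -60, rep(-60, 47), -60, 10, -60)
  expect_length(detect_spikes(two, dt), 2)
  expect_length(detect_spikes(rep(-50, 100), dt), 0)
  # touching the threshold exactly is not a crossing
  touch <- c(-60, 0, -60)
  expect_length(detect_spikes(touch, dt, threshold = 0), 0)
  # refractory merges close events
  burst <- c(-60, 10, -60, 10, -60)
  expect_length(detect_spikes(burst, dt, refractory = 3), 1)
  expect_length(detect_spikes(numeric(0), dt), 0)
})

test_that("trace CSV export round-trips the voltage series", {
  g <- conductance_set(gNa = 1, gK = 1, gleak = 2)
  tr <- simulate_neuron(PARAMS, g, stim_constant(0),
                        sim_config(settle_duration = 0, record_duration = 50))
  f <- tempfile(fileext = ".csv")
  write_trace_csv(tr, f)
  df <- read.csv(f)
  expect_equal(df$V, unname(tr$V), tolerance = 1e-12)
  expect_true(all(c("I_fast", "I_leak", "stim") %in% names(df)))
})
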