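test_that("firing rate is spike count over window", {
  # 80 evenly spaced spikes in a 2000 ms window -> 40 spk/s
  tr <- fake_trace(rep(-60, 20001), dt = 0.1,
                   spike_times = seq(12.5, 2000, by = 25))
  expect_equal(firing_rate(tr), 40)
  expect_equal(firing_rate(fake_trace(rep(-60, 1001))), 0)
  expect_error(firing_rate(tr, window = 0))
  expect_error(firing_rate(tr, window = 5000))
})

test_that("CV of the interspike interval", {
  expect_equal(cv_isi(seq(0, 1000, by = 25)), 0)
  two <- cv_isi(c(1, 2))
  expect_true(is.na(two))
  expect_equal(attr(two, "flag"), "too-few-spikes")
  # i.i.d. exponential ISIs have CV 1
  set.seed(42)
  st <- cumsum(rexp(1e4, rate = 0.04))
  expect_equal(cv_isi(st), 1, tolerance = 0.05)
})

test_that("rheobase bisection is independent of the initial bracket", {
  g <- conductance_set(gNa = 1.54, gleak = 2)
  r1 <- rheobase(PARAMS, g, fast_protocol(rheo_bounds = c(0, 100)))
  r2 <- rheobase(PARAMS, g, fast_protocol(rheo_bounds = c(0, 40)))
  expect_equal(as.numeric(r1), as.numeric(r2),
               tolerance = 0.2)
})

test_that("rheobase flags non-excitable and spontaneous models", {
  G <- rbind(conductance_set(gK = 4, gleak = 8),     # cannot spike at 100
             conductance_set(gNa = 1.54, gleak = 2)) # regular
  proto <- fast_protocol(rheo_bounds = c(0, 25))
  r <- rheobase(PARAMS, G, proto)
  # the high-leak model needs far more current than even the expanded bound
  expect_true(is.na(r[1]))
  expect_equal(attr(r, "flags")[1], "non-excitable")
  expect_false(is.na(r[2]))
})

test_that("added potassium conductance raises rheobase", {
  G <- rbind(conductance_set(gNa = 4, gK = 2.95, gleak = 2),
             conductance_set(gNa = 4, gK = 0, gleak = 2))
  r <- rheobase(PARAMS, G, fast_protocol())
  expect_gt(r[1], r[2])
})

test_that("f_min separates integrator-like from coincidence-detector-like points", {
  G <- rbind(conductance_set(gNa = 3, gK = 0.5, gleak = 2),  # low gK
             conductance_set(gNa = 3, gK = 3, gleak = 2))    # high gK
  proto <- fast_protocol()
  fm <- f_min(PARAMS, G, proto)
  expect_true(all(fm >= 0))
  expect_lt(fm[1], fm[2])
})

test_that("energy rate agrees with an independent trapezoid oracle", {
  g <- conductance_set(gNa = 2, gK = 1, gM = 0.5, gleak = 2, gAHP = 1.75)
  tr <- simulate_neuron(PARAMS, g,
                        stim_ou(mu = 40, sigma = 10, tau = 5, seed = 4),
                        sim_config(settle_duration = 0, record_duration = 10))
  got <- energy_consumption_rate(tr)
  cur <- channel_currents(tr)
  ion <- attr(cur, "ion")
  q_na <- pracma::trapz(tr$time, rowSums(cur[, ion == "Na"]))
  q_k <- pracma::trapz(tr$time, rowSums(cur[, ion == "K"]))
  per <- 1e-9 / 1.602e-19
  want <- max(abs(q_na) * per / 3, abs(q_k) * per / 2) / (max(tr$time) / 1000)
  expect_equal(got, want, tolerance = 1e-6)
})

test_that("with Na currents removed the pump rate is set by potassium", {
  # gNa = 0 and a fast-conductance-free parameter set leaves only K flux
  p <- model_params(gbar_fast = 0)
  g <- conductance_set(gK = 2, gleak = 2)
  tr <- simulate_neuron(p, g, stim_constant(0),
                        sim_config(settle_duration = 0,
                                   record_duration = 10),
                        initial = channelreg:::state_at(-20, p))
  cur <- channel_currents(tr)
  ion <- attr(cur, "ion")
  expect_equal(sum(abs(cur[, ion == "Na"])), 0)
  q_k <- pracma::trapz(tr$time, rowSums(cur[, ion == "K"]))
  per <- 1e-9 / 1.602e-19
  expect_equal(energy_consumption_rate(tr),
               abs(q_k) * per / 2 / (max(tr$time) / 1000), tolerance = 1e-6)
})

test_that("energy consumption rate increases with stimulus mean", {
  g <- conductance_set(gNa = 2, gK = 1, gM = 0.5, gleak = 2, gAHP = 1.75)
  rates <- vapply(c(30, 50), function(mu) {
    proto <- fast_protocol(rate_stim = stim_ou(mu = mu, sigma = 10, tau = 5,
                                               seed = 1),
                           energy_settle = 500, energy_window = 1000)
    measure_energy_rate(PARAMS, g, proto)
  }, numeric(1))
  expect_gt(rates[2], rates[1])
})

test_that("energy efficiency matches an R-level reimplementation oracle", {
  proto <- fast_protocol()
  G <- rbind(conductance_set(gNa = 2, gK = 1, gM = 0.5, gleak = 2,
                             gAHP = 1.75),
             conductance_set(gNa = 3, gK = 2, gleak = 2))
  got <- energy_efficiency(PARAMS, G, proto)
  for (i in 1:2) {
    g <- G[i, ]
    r <- find_rest(PARAMS, g)
    st <- r; st["V"] <- proto$eff_reset_v
    tr <- simulate_neuron(PARAMS, g, stim_constant(proto$rate_stim$mu),
                          sim_config(settle_duration = 0,
                                     record_duration = proto$eff_max_window),
                          initial = st)
    v <- tr$V; n <- length(v)
    pks <- which(v[2:(n - 1)] > 0 & diff(v)[1:(n - 2)] > 0 &
                   diff(v)[2:(n - 1)] <= 0) + 1
    ipk <- pks[1]
    d <- diff(v[ipk:n])
    stopi <- which(d >= 0 | abs(d) < proto$eff_plateau_eps * tr$dt |
                     v[(ipk + 1):n] < proto$eff_reset_v)[1]
    iend <- ipk + stopi
    cur <- channel_currents(tr)
    ion <- attr(cur, "ion")
    ina <- rowSums(cur[, ion == "Na"])
    # integration stops at the sample where the stop condition is detected
    qna <- sum((ina[1:(iend - 2)] + ina[2:(iend - 1)]) / 2) * tr$dt
    want <- 100 * PARAMS$C * (v[ipk] - r["V"]) / abs(qna)
    expect_equal(as.numeric(got[i]), unname(want), tolerance = 1e-6)
  }
})

test_that("a synthetic influx of twice the capacitive minimum gives 50%", {
  # formula audit on synthetic quantities
  C <- PARAMS$C; dV <- 100
  q_na <- 2 * C * dV
  expect_equal(100 * C * dV / q_na, 50)
})

test_that("efficiency never exceeds 100% across a conductance grid", {
  gg <- as.matrix(expand.grid(gNa = seq(0.5, 4, length.out = 5),
                              gK = seq(0, 4, length.out = 4)))
  G <- cbind(gg, gM = 0.5, gleak = 2, gAHP = 1.75)
  eff <- energy_efficiency(PARAMS, G, fast_protocol())
  expect_true(all(is.na(eff) | (eff > 0 & eff <= 100)))
  expect_true(any(!is.na(eff)))
})

test_that("efficiency flags models whose reset evokes no spike", {
  proto <- fast_protocol(eff_hold = 0) # no holding current
  eff <- energy_efficiency(PARAMS, conductance_set(gK = 2, gleak = 2), proto)
  expect_true(is.na(eff))
  expect_equal(attr(eff, "flags"), "no-spike")
})

test_that("input resistance matches the small-signal linearization oracle", {
  # negligible voltage-gated conductance at rest: leak-dominated model
  g <- conductance_set(gleak = 2)
  r <- find_rest(PARAMS, g)
  h <- 1e-4
  slope <- (steady_current(r["V"] + h, g, PARAMS) -
              steady_current(r["V"] - h, g, PARAMS)) / (2 * h)
  ir <- input_resistance(PARAMS, g, fast_protocol())
  expect_equal(as.numeric(ir), unname(1 / slope), tolerance = 0.1)
})

test_that("input resistance falls with added leak and is probe-invariant", {
  G <- rbind(conductance_set(gleak = 2), conductance_set(gleak = 4))
  ir <- input_resistance(PARAMS, G, fast_protocol())
  expect_gt(ir[1], ir[2])
  g <- conductance_set(gNa = 1, gK = 1, gleak = 2)
  i1 <- input_resistance(PARAMS, g, fast_protocol(ir_probe = -1))
  i2 <- input_resistance(PARAMS, g, fast_protocol(ir_probe = -0.5))
  expect_equal(as.numeric(i1), as.numeric(i2), tolerance = 0.02)
})

test_that("firing rate is stable under dt refinement", {
  g <- conductance_set(gNa = 2, gK = 1.2, gM = 0.5, gleak = 2, gAHP = 1.75)
  r1 <- as.numeric(measure_firing_rate(PARAMS, g, fast_protocol(dt = 0.1)))
  r2 <- as.numeric(measure_firing_rate(PARAMS, g, fast_protocol(dt = 0.05)))
  expect_lt(abs(r1 - r2) / r1, 0.05)
})

test_that("measure_properties returns NA (never zero) for unmeasurable entries", {
  df <- measure_properties(PARAMS, conductance_set(gK = 2, gleak = 2),
                           fast_protocol(eff_hold = 0),
                           which = c("firing_rate", "energy_efficiency"))
  expect_true(is.na(df$energy_efficiency))
  expect_false(is.na(df$firing_rate))
})
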