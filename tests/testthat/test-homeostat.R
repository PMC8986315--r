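test_that("error computation follows the deadband and bound conventions", {
  tg <- regulation_target("firing_rate", 40, tolerance = 3)
  expect_equal(unname(compute_errors(list(firing_rate = 46), tg)), -6)
  expect_equal(unname(compute_errors(list(firing_rate = 41), tg)), 0)
  lb <- regulation_target("energy_efficiency", 27, tolerance = 0.25,
                          mode = "lower_bound")
  expect_equal(unname(compute_errors(list(energy_efficiency = 29), lb)), 0)
  expect_equal(unname(compute_errors(list(energy_efficiency = 24), lb)), 3)
  expect_error(compute_errors(list(other = 1), tg), "not measured")
})

test_that("conductance updates are scaled, summed and clamped", {
  r <- regulation_rates(firing_rate = c(gNa = 60))
  g <- conductance_set(gNa = 1)
  g2 <- update_conductances(g, c(firing_rate = 6), r)
  expect_equal(unname(g2["gNa"]), 1.1)
  # additivity of two error signals on one channel
  r2 <- regulation_rates(firing_rate = c(gNa = 60),
                         energy_efficiency = c(gNa = -10))
  g3 <- update_conductances(g, c(firing_rate = 6, energy_efficiency = 2), r2)
  expect_equal(unname(g3["gNa"]), 1 + 6 / 60 + 2 / (-10))
  # floor clamp
  g4 <- update_conductances(conductance_set(gNa = 0.05),
                            c(firing_rate = -60), r, floor = 0)
  expect_equal(unname(g4["gNa"]), 0)
  # cap clamp
  g5 <- update_conductances(conductance_set(gNa = 3.95),
                            c(firing_rate = 60), r, cap = 4)
  expect_equal(unname(g5["gNa"]), 4)
  expect_error(regulation_rates(firing_rate = c(gNa = 0)))
})

test_that("a start already on target converges in exactly the streak length", {
  proto <- fast_protocol()
  g0 <- tune_to_rate(PARAMS, proto, n = 1, seed = 3)
  reg <- run_regulation(g0, regulation_target("firing_rate", 40),
                        default_rates("firing_rate", c("gNa", "gK")),
                        regulation_config(protocol = proto), PARAMS)
  expect_equal(unname(reg$status), "converged")
  expect_equal(unname(reg$converged_at), 5)
  expect_equal(reg$final[1, ], reg$trajectory[1, 1, ])
})

test_that("regulation restores the firing rate after a perturbation", {
  proto <- fast_protocol()
  start <- channelreg:::as_g_matrix(c(gNa = 3.4, gK = 1.2), REF_BG)
  reg <- run_regulation(start, regulation_target("firing_rate", 40),
                        default_rates("firing_rate", c("gNa", "gK")),
                        regulation_config(protocol = proto), PARAMS)
  expect_equal(unname(reg$status), "converged")
  expect_lt(abs(reg$final_properties[1, "firing_rate"] - 40), 3.01)
  expect_true(reg$converged_at >= 5 && reg$converged_at <= 60)
})

test_that("the convergence contract ties status to the tolerance streak", {
  proto <- fast_protocol()
  start <- channelreg:::as_g_matrix(c(gNa = 3.2, gK = 1), REF_BG)
  tg <- regulation_target("firing_rate", 40, tolerance = 3)
  reg <- run_regulation(start, tg,
                        default_rates("firing_rate", c("gNa", "gK")),
                        regulation_config(protocol = proto), PARAMS)
  k <- reg$config$consecutive_success
  it <- reg$converged_at[1]
  vals <- reg$properties[(it - k + 1):it, 1, "firing_rate"]
  expect_true(all(abs(vals - 40) <= 3))
})

test_that("a wrong-signed regulation rate fails at the iteration cap", {
  proto <- fast_protocol()
  start <- channelreg:::as_g_matrix(c(gNa = 3.2, gK = 1.2), REF_BG)
  bad <- regulation_rates(firing_rate = c(gNa = -300)) # sign-flipped
  reg <- run_regulation(start, regulation_target("firing_rate", 40), bad,
                        regulation_config(max_iterations = 60,
                                          protocol = proto), PARAMS)
  expect_equal(unname(reg$status), "failed")
  expect_equal(reg$iterations, 60)
})

test_that("conductances stay non-negative along every trajectory", {
  proto <- fast_protocol()
  cl <- generate_cluster(cluster_spec(mean = c(gNa = 1, gK = 3), sd = 0.4,
                                      n = 4, seed = 5), REF_BG)
  reg <- run_regulation(cl, regulation_target("firing_rate", 40),
                        default_rates("firing_rate", c("gNa", "gK")),
                        regulation_config(max_iterations = 60,
                                          protocol = proto), PARAMS)
  expect_true(all(reg$trajectory >= 0, na.rm = TRUE))
})

test_that("noise application respects SD zero, the floor and the cap", {
  nc <- noise_config(sd = 0, seed = 1)
  g <- conductance_set(gNa = 2, gK = 1)
  expect_identical(apply_noise(g, nc), g)
  set.seed(1)
  nc2 <- noise_config(sd = 10, floor = 0, cap = 4)
  many <- replicate(50, apply_noise(g, nc2, c("gNa", "gK")))
  expect_true(all(many >= 0 & many <= 4))
  # a draw below zero resets to the floor exactly
  set.seed(2)
  low <- apply_noise(conductance_set(gNa = 0.001), noise_config(sd = 5),
                     "gNa")
  while (low["gNa"] > 0)
    low <- apply_noise(conductance_set(gNa = 0.001), noise_config(sd = 5),
                       "gNa")
  expect_equal(unname(low[["gNa"]]), 0)
})

test_that("noise loop: zero noise leaves the population stationary", {
  proto <- fast_protocol()
  start <- tune_to_rate(PARAMS, proto, n = 3, seed = 4)
  nl <- run_noise_loop(start, regulation_target("firing_rate", 40),
                       default_rates("firing_rate", c("gNa", "gK")),
                       regulation_config(protocol = proto),
                       noise_config(sd = 0, iterations = 4,
                                    checkpoints = c(2, 4)),
                       PARAMS)
  s1 <- nl$snapshots[["2"]]$conductances
  s2 <- nl$snapshots[["4"]]$conductances
  expect_equal(s1, s2)
  expect_equal(s1[, "gNa"], start[, "gNa"], tolerance = 1e-12)
})

test_that("noise loop: solutions disperse and updates reduce the error", {
  proto <- fast_protocol()
  # a compact population: one on-target model replicated
  one <- tune_to_rate(PARAMS, proto, n = 1, seed = 6)
  start <- one[rep(1, 16), , drop = FALSE]
  tg <- regulation_target("firing_rate", 40)
  rr <- default_rates("firing_rate", c("gNa", "gleak"))
  nl <- run_noise_loop(start, tg, rr,
                       regulation_config(protocol = proto),
                       noise_config(sd = 0.05, iterations = 40,
                                    checkpoints = c(10, 40), seed = 2,
                                    conductances = c("gNa", "gleak")),
                       PARAMS)
  spread <- function(G) sum(apply(G[, c("gNa", "gleak")], 2, var))
  v1 <- spread(nl$snapshots[["10"]]$conductances)
  v2 <- spread(nl$snapshots[["40"]]$conductances)
  expect_gt(v1, 0)   # the cluster disperses on the solution manifold
  expect_gt(v2, v1)  # and keeps spreading over early iterations
  # the homeostatic update pulls the property back toward target
  expect_lt(mean(nl$err_after_update[c(10, 40)]),
            mean(nl$err_after_noise[c(10, 40)]))
})
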