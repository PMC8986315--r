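#' Measurement protocol
#'
#' Bundles every protocol constant used to measure neuronal properties.
#' Property targets use tolerance conventions of +/-3 spk/s (firing rate),
#' +/-0.25% (energy efficiency) and +/-0.003 kOhm cm2 (input resistance);
#' the protocols below are chosen so measurement noise is comfortably inside
#' those tolerances.
#'
#' @param dt forward-Euler step (ms).
#' @param spike_threshold,spike_refractory spike detection settings (mV, ms).
#' @param rate_stim fluctuating stimulus used for firing-rate and energy
#'   measurements; an [stim_ou()] spec (default mu = 40, sigma = 10 uA/cm2,
#'   tau = 5 ms).
#' @param rate_settle,rate_window settling time and recorded window (ms) for
#'   firing-rate measurement under the fluctuating stimulus.
#' @param rheo_step constant-step duration (ms) for rheobase testing.
#' @param rheo_bounds initial bisection bracket (uA/cm2); the upper bound is
#'   doubled (up to 4x) if it does not evoke repetitive spiking.
#' @param rheo_resolution bisection resolution (uA/cm2).
#' @param rheo_min_spikes,rheo_final_frac repetitive-spiking criterion: at
#'   least \code{rheo_min_spikes} spikes with at least one spike in the final
#'   \code{rheo_final_frac} fraction of the step.
#' @param fmin_epsilon current increment above rheobase (uA/cm2) at which the
#'   minimum sustainable rate is measured (over the last half of the step).
#' @param ir_probe,ir_duration,ir_window input-resistance probe amplitude
#'   (uA/cm2, subthreshold), duration (ms) and terminal averaging window (ms).
#' @param ir_max_halvings number of probe halvings attempted if the probe
#'   evokes a spike.
#' @param eff_reset_v,eff_max_window efficiency protocol: voltage reset
#'   value (mV) and maximum spike window (ms).
#' @param eff_hold current held during the efficiency protocol (uA/cm2);
#'   \code{NULL} (default) uses the mean of \code{rate_stim}, which is
#'   suprathreshold in essentially every model so the reset reliably evokes
#'   a spike.
#' @param eff_plateau_eps voltage-slope threshold (mV/ms) below which the
#'   post-spike trajectory counts as a plateau, ending the Na-influx window.
#' @param energy_settle,energy_window settling time and integration window
#'   (ms) for the energy consumption rate under \code{rate_stim}.
#' @return A \code{measurement_protocol} object.
#' @export
measurement_protocol <- function(dt = 0.1, spike_threshold = 0,
                                 spike_refractory = 2,
                                 rate_stim = stim_ou(mu = 40, sigma = 10,
                                                     tau = 5, seed = 1L),
                                 rate_settle = 1000, rate_window = 10000,
                                 rheo_step = 2000, rheo_bounds = c(0, 100),
                                 rheo_resolution = 0.1,
                                 rheo_min_spikes = 3, rheo_final_frac = 0.25,
                                 fmin_epsilon = 0.1,
                                 ir_probe = -1, ir_duration = 1000,
                                 ir_window = 100, ir_max_halvings = 3,
                                 eff_reset_v = -40, eff_max_window = 100,
                                 eff_hold = NULL, eff_plateau_eps = 0.2,
                                 energy_settle = 1000, energy_window = 1000) {
  stopifnot(dt > 0, dt <= 0.1, rate_window > 0, rheo_resolution > 0,
            rheo_step > 0, ir_duration >= ir_window, eff_max_window > 0)
  structure(as.list(environment()), class = "measurement_protocol")
}

## Shared batch runner: returns the raw C++ accumulators for a constant or
## pre-generated stimulus applied to every row of G.
batch_run <- function(params, G, stim_vec, offsets, dt, init,
                      thresh, refract, count_from = 0, energy_from = 0,
                      vstat_from = 0, spike_times = FALSE) {
  n <- nrow(G)
  if (length(offsets) == 1) offsets <- rep(offsets, n)
  .euler_batch_cpp(unclass(params), G, stim_vec, offsets, dt, init,
                   thresh, refract, count_from, energy_from, vstat_from,
                   FALSE, spike_times)
}

## Initial-state matrix: every model at the steady state for voltage v0.
init_at <- function(params, n, v0 = -70) {
  matrix(rep(state_at(v0, params), each = n), nrow = n)
}

## Rest-state matrix per model (falls back to -70 steady state, flagged).
rest_states <- function(params, G) {
  r <- find_rest_batch(params, G)
  ok <- r$stable & !is.na(r$V)
  init <- init_at(params, nrow(G))
  if (any(ok)) {
    s <- steady_gates(r$V[ok], params)
    init[ok, ] <- cbind(r$V[ok], s$w_inf, s$n_inf, s$z_inf_AHP, s$z_inf_M)
  }
  list(init = init, stable = ok, V = r$V)
}

#' Firing rate of a recorded trace
#'
#' Spike count over the analysis window divided by the window duration.
#'
#' @param trace a \code{sim_trace}.
#' @param window analysis window (ms) ending at the end of the recorded
#'   span; defaults to the full recorded span.
#' @return Firing rate (spk/s).
#' @export
firing_rate <- function(trace, window = NULL) {
  span <- max(trace$time)
  if (is.null(window)) window <- span
  if (window <= 0) stop("window must be positive")
  if (window > span + trace$dt) stop("window exceeds the recorded span")
  n <- sum(trace$spike_times > span - window)
  1000 * n / window
}

#' Measure firing rate under the fluctuating stimulus
#'
#' Integrates every conductance set (rows of \code{g}) against one shared
#' realization of the protocol's Ornstein-Uhlenbeck stimulus (frozen seed),
#' after settling at the stimulus mean, and returns spikes per second over
#' the recorded window.
#'
#' @param params a [model_params()] object.
#' @param g a conductance set or a matrix of sets (one per row).
#' @param protocol a [measurement_protocol()].
#' @return Numeric vector of rates (spk/s); \code{NA} with attribute
#'   \code{flags} for diverging models.
#' @export
measure_firing_rate <- function(params, g, protocol = measurement_protocol()) {
  G <- as_g_matrix(g)
  dt <- protocol$dt
  n_settle <- floor(protocol$rate_settle / dt)
  ou <- ou_stimulus(protocol$rate_stim, protocol$rate_window, dt)
  stim <- c(rep(protocol$rate_stim$mu, n_settle), ou)
  res <- batch_run(params, G, stim, 0, dt, init_at(params, nrow(G)),
                   protocol$spike_threshold, protocol$spike_refractory,
                   count_from = n_settle)
  out <- 1000 * res$n_spikes / protocol$rate_window
  out[res$status != 0] <- NA_real_
  attr(out, "flags") <- ifelse(res$status != 0, "diverged", "")
  out
}

#' Rheobase by batched bisection
#'
#' Smallest constant step amplitude evoking repetitive spiking (at least
#' \code{rheo_min_spikes} spikes over a \code{rheo_step}-ms step from rest,
#' with at least one spike in the final fraction of the step), bisected to
#' \code{rheo_resolution}. All conductance sets are bisected in lock-step so
#' each bisection level is one batched integration.
#'
#' @inheritParams measure_firing_rate
#' @return Numeric vector (uA/cm2). Attribute \code{flags} marks
#'   \code{"non-excitable"} models (\code{NA}) and \code{"spontaneous"}
#'   models (rheobase reported as 0).
#' @export
rheobase <- function(params, g, protocol = measurement_protocol()) {
  G <- as_g_matrix(g)
  n <- nrow(G)
  dt <- protocol$dt
  nstep <- floor(protocol$rheo_step / dt)
  stim <- rep(0, nstep + 1)
  rs <- rest_states(params, G)

  repetitive <- function(amps, idx) {
    res <- batch_run(params, G[idx, , drop = FALSE], stim, amps, dt,
                     rs$init[idx, , drop = FALSE],
                     protocol$spike_threshold, protocol$spike_refractory,
                     spike_times = TRUE)
    t_late <- protocol$rheo_step * (1 - protocol$rheo_final_frac)
    vapply(seq_along(idx), function(i) {
      st <- res$spike_times[[i]]
      res$status[i] == 0 && length(st) >= protocol$rheo_min_spikes &&
        any(st >= t_late)
    }, logical(1))
  }

  lo <- rep(protocol$rheo_bounds[1], n)
  hi <- rep(protocol$rheo_bounds[2], n)
  flags <- rep("", n)
  all_idx <- seq_len(n)
  ## spontaneous spiking at the lower bound
  sp <- repetitive(lo, all_idx)
  flags[sp & lo <= 0] <- "spontaneous"
  ## expand upper bound where needed (up to 4x)
  act <- which(!sp)
  for (k in 1:3) {
    if (!length(act)) break
    ok <- repetitive(hi[act], act)
    grow <- act[!ok]
    if (!length(grow)) break
    hi[grow] <- hi[grow] * 2
    act <- grow
  }
  if (length(act)) {
    ok <- repetitive(hi[act], act)
    flags[act[!ok]] <- "non-excitable"
  }
  active <- which(flags == "")
  while (length(active) && max(hi[active] - lo[active]) > protocol$rheo_resolution) {
    mid <- 0.5 * (lo[active] + hi[active])
    ok <- repetitive(mid, active)
    hi[active[ok]] <- mid[ok]
    lo[active[!ok]] <- mid[!ok]
    active <- active[(hi[active] - lo[active]) > protocol$rheo_resolution]
  }
  out <- 0.5 * (lo + hi)
  out[flags == "spontaneous"] <- 0
  out[flags == "non-excitable"] <- NA_real_
  attr(out, "flags") <- flags
  out
}

#' Minimum sustainable firing rate
#'
#' Firing rate at a constant step just above rheobase
#' (\code{rheobase + fmin_epsilon}), measured over the last half of the
#' step. Near zero for class-1 (integrator) models; well above zero for
#' class-2 (coincidence-detector) models.
#'
#' @inheritParams measure_firing_rate
#' @param rheo optional precomputed rheobase vector (recomputed otherwise).
#' @return Numeric vector (spk/s) with rheobase flags propagated.
#' @export
f_min <- function(params, g, protocol = measurement_protocol(), rheo = NULL) {
  G <- as_g_matrix(g)
  if (is.null(rheo)) rheo <- rheobase(params, G, protocol)
  flags <- attr(rheo, "flags")
  dt <- protocol$dt
  nstep <- floor(protocol$rheo_step / dt)
  half <- floor(nstep / 2)
  rs <- rest_states(params, G)
  amps <- ifelse(is.na(rheo), 0, rheo + protocol$fmin_epsilon)
  res <- batch_run(params, G, rep(0, nstep + 1), amps, dt, rs$init,
                   protocol$spike_threshold, protocol$spike_refractory,
                   count_from = half)
  out <- 1000 * res$n_spikes / (protocol$rheo_step / 2)
  out[is.na(rheo) | res$status != 0] <- NA_real_
  attr(out, "flags") <- flags
  out
}

#' Coefficient of variation of the interspike interval
#'
#' @param spike_times strictly increasing spike times (ms).
#' @return \code{sd(ISI)/mean(ISI)}; \code{NA} with attribute
#'   \code{flag = "too-few-spikes"} when fewer than 3 spikes are available.
#' @export
cv_isi <- function(spike_times) {
  if (length(spike_times) < 3) {
    out <- NA_real_
    attr(out, "flag") <- "too-few-spikes"
    return(out)
  }
  isi <- diff(spike_times)
  sd(isi) / mean(isi)
}

#' Energy consumption rate from a recorded trace
#'
#' Integrates (trapezoid rule) the Na-carrying and K-carrying channel
#' currents over the recorded window, converts charge to ion counts via the
#' elementary charge 1.602e-19 C, divides by the 3:2 Na+/K+-pump
#' stoichiometry and returns the larger of the two pump demands. The
#' mixed-ion leak current is excluded by default.
#'
#' @param trace a \code{sim_trace} of at least the intended integration
#'   window (1 s under the fluctuating stimulus for reported values).
#' @param include_leak if \code{TRUE}, the leak current is split by its
#'   driving-force sign and added to the ionic totals; default \code{FALSE}
#'   restricts pump accounting to Na- and K-labelled channels.
#' @return ATP/(cm2 s).
#' @export
energy_consumption_rate <- function(trace, include_leak = FALSE) {
  cur <- channel_currents(trace)
  ion <- attr(cur, "ion")
  dt <- trace$dt
  trapz <- function(y) sum((y[-1] + y[-length(y)]) / 2) * dt
  q_na <- sum(vapply(which(ion == "Na"), function(j) trapz(cur[, j]), 0))
  q_k <- sum(vapply(which(ion == "K"), function(j) trapz(cur[, j]), 0))
  if (include_leak) {
    lk <- cur[, which(ion == "mixed"), drop = FALSE]
    q_na <- q_na + trapz(pmin(rowSums(lk), 0))
    q_k <- q_k + trapz(pmax(rowSums(lk), 0))
  }
  dur_s <- (length(trace$V) - 1) * dt / 1000
  ions_per_uAms <- 1e-9 / 1.602e-19
  n_na <- abs(q_na) * ions_per_uAms
  n_k <- abs(q_k) * ions_per_uAms
  max(n_na / 3, n_k / 2) / dur_s
}

#' Measure the energy consumption rate under the fluctuating stimulus
#'
#' Batched equivalent of [energy_consumption_rate()]: integrates each
#' conductance set for \code{energy_window} ms under the protocol stimulus
#' after settling and applies the same pump accounting.
#'
#' @inheritParams measure_firing_rate
#' @return Numeric vector, ATP/(cm2 s).
#' @export
measure_energy_rate <- function(params, g, protocol = measurement_protocol()) {
  G <- as_g_matrix(g)
  dt <- protocol$dt
  n_settle <- floor(protocol$energy_settle / dt)
  ou <- ou_stimulus(protocol$rate_stim, protocol$energy_window, dt)
  stim <- c(rep(protocol$rate_stim$mu, n_settle), ou)
  res <- batch_run(params, G, stim, 0, dt, init_at(params, nrow(G)),
                   protocol$spike_threshold, protocol$spike_refractory,
                   energy_from = n_settle)
  ions_per_uAms <- 1e-9 / 1.602e-19
  dur_s <- protocol$energy_window / 1000
  out <- pmax(abs(res$q_na) * ions_per_uAms / 3,
              abs(res$q_k) * ions_per_uAms / 2) / dur_s
  out[res$status != 0] <- NA_real_
  out
}

#' Energy efficiency per spike
#'
#' From each model's resting state the voltage is reset to
#' \code{eff_reset_v} (default -40 mV) while the stimulus is held at
#' \code{eff_hold} (default: the mean of the fluctuating energy stimulus,
#' 40 uA/cm2), which makes the reset suprathreshold in essentially every
#' model and evokes a single spike. Efficiency is the capacitive minimum
#' divided by total Na+ influx, \code{100 * C * (V_peak - V_rest) / Q_Na},
#' in percent, where \code{V_peak} is the first spike's peak and the
#' Na-influx window runs from the reset to the post-spike trough or plateau
#' (or the first return below the reset voltage), capped at
#' \code{eff_max_window} ms.
#'
#' @inheritParams measure_firing_rate
#' @return Numeric vector (percent). Models with no evoked spike or no
#'   stable rest are \code{NA}, with reasons in attribute \code{flags}.
#' @export
energy_efficiency <- function(params, g, protocol = measurement_protocol()) {
  G <- as_g_matrix(g)
  rs <- rest_states(params, G)
  hold <- if (is.null(protocol$eff_hold)) protocol$rate_stim$mu else protocol$eff_hold
  res <- .efficiency_batch_cpp(unclass(params), G, rs$init, protocol$dt,
                               protocol$eff_reset_v, hold,
                               protocol$eff_max_window,
                               protocol$spike_threshold,
                               protocol$eff_plateau_eps)
  out <- 100 * params$C * (res$v_peak - res$v_rest) / abs(res$q_na)
  flags <- rep("", nrow(G))
  flags[!rs$stable] <- "no-stable-rest"
  flags[res$n_spikes == 0] <- "no-spike"
  flags[res$status != 0] <- "diverged"
  out[flags != ""] <- NA_real_
  attr(out, "flags") <- flags
  out
}

#' Input resistance
#'
#' Steady-state voltage deflection per unit current for a small
#' hyperpolarizing probe from rest (default -1 uA/cm2 for 1 s, deflection
#' averaged over the final \code{ir_window} ms), in kOhm cm2. If the probe
#' evokes a spike its amplitude is halved and the measurement retried, up to
#' \code{ir_max_halvings} times.
#'
#' @inheritParams measure_firing_rate
#' @return Numeric vector (kOhm cm2) with attribute \code{flags}.
#' @export
input_resistance <- function(params, g, protocol = measurement_protocol()) {
  G <- as_g_matrix(g)
  n <- nrow(G)
  dt <- protocol$dt
  nstep <- floor(protocol$ir_duration / dt)
  nwin <- floor(protocol$ir_window / dt)
  rs <- rest_states(params, G)
  out <- rep(NA_real_, n)
  flags <- ifelse(rs$stable, "", "no-stable-rest")
  probe <- rep(protocol$ir_probe, n)
  active <- which(rs$stable)
  for (k in 0:protocol$ir_max_halvings) {
    if (!length(active)) break
    res <- batch_run(params, G[active, , drop = FALSE], rep(0, nstep + 1),
                     probe[active], dt, rs$init[active, , drop = FALSE],
                     protocol$spike_threshold, protocol$spike_refractory,
                     vstat_from = nstep + 1 - nwin)
    vmean <- res$v_sum / res$v_n
    ok <- res$n_spikes == 0 & res$status == 0
    out[active[ok]] <- (vmean[ok] - rs$V[active[ok]]) / probe[active[ok]]
    retry <- active[!ok]
    probe[retry] <- probe[retry] / 2
    active <- retry
  }
  flags[active] <- "probe-evoked-spike"
  attr(out, "flags") <- flags
  out
}

#' Measure a set of properties for one or more conductance sets
#'
#' Convenience wrapper running the individual measurement protocols and
#' assembling a data frame (one row per conductance set). Unmeasured or
#' failed entries are \code{NA}, never zero.
#'
#' @inheritParams measure_firing_rate
#' @param which character vector from \code{"firing_rate"},
#'   \code{"rheobase"}, \code{"f_min"}, \code{"energy_rate"},
#'   \code{"energy_efficiency"}, \code{"input_resistance"},
#'   \code{"cv_isi"}, \code{"spike_amplitude"}, \code{"mean_potential"}
#'   (the last three are read off a recorded run under the fluctuating
#'   stimulus).
#' @return Data frame with the conductance columns and one column per
#'   requested property.
#' @export
measure_properties <- function(params, g,
                               protocol = measurement_protocol(),
                               which = c("firing_rate", "rheobase",
                                         "energy_efficiency",
                                         "input_resistance")) {
  G <- as_g_matrix(g)
  out <- as.data.frame(G)
  rheo <- NULL
  trace_stats <- NULL
  need_trace <- intersect(which, c("cv_isi", "spike_amplitude",
                                   "mean_potential"))
  if (length(need_trace))
    trace_stats <- trace_statistics(params, G, protocol)
  for (w in which) {
    out[[w]] <- switch(
      w,
      firing_rate = as.numeric(measure_firing_rate(params, G, protocol)),
      rheobase = as.numeric(rheo <- rheobase(params, G, protocol)),
      f_min = as.numeric(f_min(params, G, protocol, rheo = rheo)),
      energy_rate = as.numeric(measure_energy_rate(params, G, protocol)),
      energy_efficiency = as.numeric(energy_efficiency(params, G, protocol)),
      input_resistance = as.numeric(input_resistance(params, G, protocol)),
      cv_isi = trace_stats$cv_isi,
      spike_amplitude = trace_stats$spike_amplitude,
      mean_potential = trace_stats$mean_potential,
      stop("unknown property: ", w))
  }
  out
}

## Spike-train statistics from one recorded run per model under the
## fluctuating stimulus: ISI variability, mean spike peak above the mean
## potential, and the mean potential itself.
trace_statistics <- function(params, G, protocol) {
  n <- nrow(G)
  cv <- amp <- mv <- rep(NA_real_, n)
  cfg <- sim_config(dt = protocol$dt,
                    settle_duration = protocol$rate_settle,
                    record_duration = protocol$rate_window,
                    spike_threshold = protocol$spike_threshold,
                    spike_refractory = protocol$spike_refractory)
  for (i in seq_len(n)) {
    tr <- try(simulate_neuron(params, G[i, ], protocol$rate_stim, cfg),
              silent = TRUE)
    if (inherits(tr, "try-error")) next
    mv[i] <- mean(tr$V)
    if (length(tr$spike_times) >= 3)
      cv[i] <- cv_isi(tr$spike_times)
    if (length(tr$spike_times) >= 1) {
      idx <- pmin(length(tr$V), round(tr$spike_times / tr$dt) + 1)
      peaks <- vapply(idx, function(j)
        max(tr$V[j:min(length(tr$V), j + 20)]), numeric(1))
      amp[i] <- mean(peaks) - mv[i]
    }
  }
  list(cv_isi = cv, spike_amplitude = amp, mean_potential = mv)
}
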