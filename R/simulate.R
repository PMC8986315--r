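#' Integration settings
#'
#' @param dt forward-Euler time step (ms); the model is intended for steps in
#'   0.05-0.1 ms and \code{dt} must lie in (0, 0.1].
#' @param settle_duration settling time (ms) simulated at the stimulus mean
#'   before the recorded window.
#' @param record_duration recorded window (ms).
#' @param spike_threshold voltage (mV) whose upward crossing marks a spike.
#' @param spike_refractory minimum separation between detected spikes (ms).
#' @return A \code{sim_config} object.
#' @export
sim_config <- function(dt = 0.1, settle_duration = 500,
                       record_duration = 2000,
                       spike_threshold = 0, spike_refractory = 2) {
  if (dt <= 0 || dt > 0.1) stop("dt must lie in (0, 0.1] ms")
  if (settle_duration < 0 || record_duration < 0)
    stop("durations must be >= 0")
  structure(list(dt = dt, settle_duration = settle_duration,
                 record_duration = record_duration,
                 spike_threshold = spike_threshold,
                 spike_refractory = spike_refractory),
            class = "sim_config")
}

#' Simulate the model neuron
#'
#' Integrates the membrane equation with forward Euler: capacitive current
#' balances the stimulus minus the fast, slow, generic Na/K, AHP, M and leak
#' currents. The model is settled for \code{cfg$settle_duration} ms at the
#' stimulus mean before the recorded window; spike times are reported
#' relative to the start of the recorded window.
#'
#' @param params a [model_params()] object.
#' @param g conductance densities ([conductance_set()]).
#' @param stim a stimulus specification ([stim_constant()] or [stim_ou()]).
#' @param cfg a [sim_config()] object.
#' @param initial \code{"rest"} (default; settles from the resting state) or
#'   a named state vector \code{(V, w, n, p, q)}.
#' @return A \code{sim_trace} object: list with \code{time} (ms, recorded
#'   window), \code{V}, gate matrix \code{gates} (w, n, p, q), \code{stim},
#'   \code{spike_times}, \code{dt}, the final state, and the inputs needed to
#'   recompute per-channel currents (see [channel_currents()]).
#' @export
simulate_neuron <- function(params, g, stim, cfg = sim_config(),
                            initial = "rest") {
  gmat <- as_g_matrix(g)
  if (identical(initial, "rest")) {
    init <- find_rest(params, gmat[1, ])
  } else {
    init <- initial[GSTATE]
    if (any(is.na(init))) stop("initial state must contain V, w, n, p, q")
  }
  dt <- cfg$dt
  n_settle <- floor(cfg$settle_duration / dt)
  mu <- if (stim$kind == "constant") stim$amplitude else stim$mu
  rec <- ou_stimulus(stim, cfg$record_duration, dt)
  sfull <- c(rep(mu, n_settle), rec)
  res <- .euler_batch_cpp(unclass(params), gmat, sfull,
                          0, dt, matrix(init, nrow = 1),
                          cfg$spike_threshold, cfg$spike_refractory,
                          count_from = n_settle, energy_from = n_settle,
                          vstat_from = n_settle,
                          record_trace = TRUE, want_spike_times = TRUE)
  if (res$status[1] != 0)
    stop(sprintf("numerical divergence (|V| > 500 mV) at step %d (t = %.3f ms)",
                 res$div_step[1], res$div_step[1] * dt))
  keep <- (n_settle + 1):length(sfull)
  tr <- res$trace[keep, , drop = FALSE]
  colnames(tr) <- GSTATE
  structure(list(
    time = (seq_along(keep) - 1) * dt,
    V = tr[, "V"],
    gates = tr[, c("w", "n", "p", "q"), drop = FALSE],
    stim = sfull[keep],
    spike_times = res$spike_times[[1]] - n_settle * dt,
    dt = dt,
    q_na = res$q_na[1], q_k = res$q_k[1],
    final_state = setNames(res$final_state[1, ], GSTATE),
    params = params, g = gmat[1, ], config = cfg),
    class = "sim_trace")
}

#' Per-channel membrane currents of a recorded trace
#'
#' Recomputes every channel current from the recorded voltage and gating
#' series (outward positive, uA/cm2). Columns are labelled by the carried
#' ion species via the \code{"ion"} attribute: the fast and generic Na
#' conductances carry \code{"Na"}; slow, generic K, AHP and M carry
#' \code{"K"}; leak is \code{"mixed"}.
#'
#' @param trace a \code{sim_trace}.
#' @return Matrix (time x channel) with attribute \code{ion}.
#' @export
channel_currents <- function(trace) {
  p <- trace$params; g <- trace$g
  V <- trace$V; gt <- trace$gates
  m <- 0.5 * (1 + tanh((V - p$beta_m) / p$gamma_m))
  ne <- gt[, "n"]^p$n_gate_power
  out <- cbind(
    fast = p$gbar_fast * m * (V - p$E_Na),
    Na   = g[["gNa"]] * ne * (V - p$E_Na),
    slow = p$gbar_slow * gt[, "w"] * (V - p$E_K),
    K    = g[["gK"]] * ne * (V - p$E_K),
    AHP  = g[["gAHP"]] * gt[, "p"] * (V - p$E_K),
    M    = g[["gM"]] * gt[, "q"] * (V - p$E_K),
    leak = g[["gleak"]] * (V - p$E_leak))
  attr(out, "ion") <- c(fast = "Na", Na = "Na", slow = "K", K = "K",
                        AHP = "K", M = "K", leak = "mixed")
  out
}

#' Detect spikes as threshold crossings
#'
#' One event per upward crossing of \code{threshold} (previous sample
#' strictly below, next sample strictly above; a sample exactly at threshold
#' does not count) separated by at least \code{refractory} ms.
#'
#' @param V voltage series (mV).
#' @param dt sampling step (ms).
#' @param threshold crossing threshold (mV).
#' @param refractory minimum inter-event separation (ms).
#' @return Strictly increasing spike times (ms, time of the first
#'   suprathreshold sample; empty input gives an empty vector).
#' @export
detect_spikes <- function(V, dt, threshold = 0, refractory = 2) {
  n <- length(V)
  if (n < 2) return(numeric(0))
  up <- which(V[-n] < threshold & V[-1] > threshold)
  times <- up * dt
  keep <- numeric(0)
  last <- -Inf
  for (t in times) {
    if (t - last > refractory) { keep <- c(keep, t); last <- t }
  }
  keep
}

#' @export
print.sim_trace <- function(x, ...) {
  cat(sprintf("sim_trace: %.1f ms recorded at dt = %g ms, %d spikes\n",
              max(x$time), x$dt, length(x$spike_times)))
  cat(sprintf("  V range [%.1f, %.1f] mV; g = (%s) mS/cm2\n",
              min(x$V), max(x$V),
              paste(sprintf("%s=%g", names(x$g), x$g), collapse = ", ")))
  invisible(x)
}

#' @export
plot.sim_trace <- function(x, ...) {
  graphics::plot(x$time, x$V, type = "l", xlab = "time (ms)",
                 ylab = "V (mV)", ...)
  if (length(x$spike_times))
    graphics::points(x$spike_times,
                     rep(max(x$V) + 2, length(x$spike_times)), pch = "|")
  invisible(x)
}

#' Export a trace as a wide CSV table
#'
#' Columns: time, V, gates, per-channel currents and stimulus.
#'
#' @param trace a \code{sim_trace}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_trace_csv <- function(trace, path) {
  cur <- channel_currents(trace)
  colnames(cur) <- paste0("I_", colnames(cur))
  df <- data.frame(time = trace$time, V = trace$V, trace$gates, cur,
                   stim = trace$stim, check.names = FALSE)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
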