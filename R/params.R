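#' Fixed biophysical parameters of the model neuron
#'
#' Constructs the parameter set of the single-compartment model. Spikes are
#' generated by a fast sodium-like conductance (instantaneous activation
#' \code{m}) and a slower potassium conductance (gate \code{w}), both in
#' Morris-Lecar form. A generic sodium and potassium conductance pair shares a
#' single Hodgkin-Huxley-style gate \code{n} (identical kinetics, different
#' reversal potentials), and two slow first-order gates \code{p} and \code{q}
#' drive AHP-type and M-type potassium conductances.
#'
#' Defaults: \code{C} = 2 uF/cm2, \code{E_Na} = 50 mV, \code{E_K} = -100 mV,
#' \code{E_leak} = -70 mV, \code{gbar_fast} = \code{gbar_slow} = 20 mS/cm2,
#' \code{phi_w} = 0.15, \code{beta_m} = -1.2 mV, \code{gamma_m} = 18 mV,
#' \code{beta_w} = -10 mV, \code{gamma_w} = 10 mV, shared n-gate constants
#' \code{V_ab} = -24 mV, \code{s_ab} = -17 mV, \code{k_ab} = 1 ms^-1, and
#' z-gate constants \code{tau_z} = 100 ms, \code{gamma_z} = 4 mV with
#' half-activation \code{beta_z} = 0 mV (AHP) or -35 mV (M).
#'
#' @param C membrane capacitance (uF/cm2).
#' @param E_Na,E_K,E_leak reversal potentials (mV).
#' @param gbar_fast,gbar_slow fixed spike-generating conductance densities
#'   (mS/cm2).
#' @param phi_w rate scale of the \code{w} gate (dimensionless).
#' @param beta_m,gamma_m,beta_w,gamma_w Morris-Lecar half-activation and slope
#'   parameters (mV).
#' @param V_ab,s_ab shared half-activation and slope of the generic n-gate
#'   rate functions (mV).
#' @param k_ab rate constant of the n-gate (ms^-1).
#' @param tau_z_AHP,beta_z_AHP,gamma_z_AHP AHP-gate time constant (ms),
#'   half-activation and slope (mV).
#' @param tau_z_M,beta_z_M,gamma_z_M M-gate time constant (ms),
#'   half-activation and slope (mV).
#' @param n_gate_form rate family for the shared n-gate; see
#'   [n_gate_rates()] for the four candidates and the vignette for how the
#'   default was selected against published property values.
#' @return An object of class \code{model_params} (a named list).
#' @examples
#' p <- model_params()
#' steady_gates(-70, p)
#' @export
model_params <- function(C = 2, E_Na = 50, E_K = -100, E_leak = -70,
                         gbar_fast = 20, gbar_slow = 20, phi_w = 0.15,
                         beta_m = -1.2, gamma_m = 18,
                         beta_w = -10, gamma_w = 10,
                         V_ab = -24, s_ab = -17, k_ab = 1,
                         tau_z_AHP = 100, beta_z_AHP = 0, gamma_z_AHP = 4,
                         tau_z_M = 100, beta_z_M = -35, gamma_z_M = 4,
                         n_gate_form = c("linoid_scaled", "linoid",
                                         "printed", "exp"),
                         n_gate_power = 1) {
  n_gate_form <- match.arg(n_gate_form)
  p <- list(C = C, E_Na = E_Na, E_K = E_K, E_leak = E_leak,
            gbar_fast = gbar_fast, gbar_slow = gbar_slow, phi_w = phi_w,
            beta_m = beta_m, gamma_m = gamma_m,
            beta_w = beta_w, gamma_w = gamma_w,
            V_ab = V_ab, s_ab = s_ab, k_ab = k_ab,
            tau_z_AHP = tau_z_AHP, beta_z_AHP = beta_z_AHP,
            gamma_z_AHP = gamma_z_AHP,
            tau_z_M = tau_z_M, beta_z_M = beta_z_M, gamma_z_M = gamma_z_M,
            n_gate_form = n_gate_form, n_gate_power = n_gate_power,
            n_form_code = match(n_gate_form,
                                c("linoid", "printed", "exp",
                                  "linoid_scaled")) - 1L)
  stopifnot(C > 0, gamma_m != 0, gamma_w != 0,
            gamma_z_AHP != 0, gamma_z_M != 0,
            tau_z_AHP > 0, tau_z_M > 0, s_ab != 0, k_ab > 0)
  class(p) <- "model_params"
  p
}

#' @export
print.model_params <- function(x, ...) {
  cat("Model parameters (single-compartment conductance-based neuron)\n")
  v <- unlist(x[vapply(x, is.numeric, logical(1))])
  print(v)
  invisible(x)
}

#' Adjustable maximal conductance densities
#'
#' The five channel densities that are systematically varied or adjusted by
#' the homeostat: generic sodium (\code{gNa}) and potassium (\code{gK}),
#' M-type potassium (\code{gM}), leak (\code{gleak}) and AHP-type potassium
#' (\code{gAHP}), all in mS/cm2. Returned as a named numeric vector in the
#' canonical order used by every matrix interface in the package.
#'
#' @param gNa,gK,gM,gleak,gAHP non-negative densities (mS/cm2).
#' @return Named numeric vector of length 5.
#' @examples
#' conductance_set(gNa = 1.54, gleak = 2)
#' @export
conductance_set <- function(gNa = 0, gK = 0, gM = 0, gleak = 2, gAHP = 0) {
  g <- c(gNa = gNa, gK = gK, gM = gM, gleak = gleak, gAHP = gAHP)
  if (any(!is.finite(g)) || any(g < 0))
    stop("conductance densities must be finite and >= 0")
  g
}

## Coerce a vector/matrix/data.frame of conductances to an n x 5 matrix in
## canonical column order, filling unnamed columns from `background`.
as_g_matrix <- function(g, background = conductance_set()) {
  if (is.null(dim(g))) g <- matrix(g, nrow = 1, dimnames = list(NULL, names(g)))
  g <- as.matrix(g)
  if (is.null(colnames(g))) {
    if (ncol(g) != 5) stop("unnamed conductance matrix must have 5 columns")
    colnames(g) <- GCOND
  }
  out <- matrix(rep(background[GCOND], each = nrow(g)), nrow = nrow(g),
                dimnames = list(NULL, GCOND))
  for (nm in intersect(colnames(g), GCOND)) out[, nm] <- g[, nm]
  if (any(out < 0)) stop("conductance densities must be >= 0")
  out
}

#' Steady-state gating values
#'
#' Voltage-dependent steady states of all gates and the \code{w}-gate time
#' constant: \code{m_inf} and \code{w_inf} are Morris-Lecar tanh activation
#' curves, \code{tau_w = 1/cosh((V - beta_w)/(2 gamma_w))}, \code{n_inf}
#' follows from the rate functions \code{alpha/(alpha + beta)}, and the slow
#' gates are logistic: \code{z_inf = 1/(1 + exp((beta_z - V)/gamma_z))}.
#'
#' @param V membrane potential (mV); vectorized.
#' @param params a [model_params()] object.
#' @return List with components \code{m_inf}, \code{w_inf}, \code{tau_w},
#'   \code{n_inf}, \code{z_inf_AHP}, \code{z_inf_M}.
#' @export
steady_gates <- function(V, params = model_params()) {
  r <- n_gate_rates(V, params)
  list(m_inf = 0.5 * (1 + tanh((V - params$beta_m) / params$gamma_m)),
       w_inf = 0.5 * (1 + tanh((V - params$beta_w) / params$gamma_w)),
       tau_w = 1 / cosh((V - params$beta_w) / (2 * params$gamma_w)),
       n_inf = r$alpha / (r$alpha + r$beta),
       z_inf_AHP = 1 / (1 + exp((params$beta_z_AHP - V) / params$gamma_z_AHP)),
       z_inf_M = 1 / (1 + exp((params$beta_z_M - V) / params$gamma_z_M)))
}

#' Opening and closing rates of the generic n-gate
#'
#' The closing rate is always \code{beta(V) = k exp((V - V_ab)/s_ab)}. Four
#' families are available for the opening rate (with \code{x = V - V_ab},
#' \code{u = x/s_ab} and \code{s_ab < 0}); removable singularities at
#' \code{V = V_ab} use the analytic series limit:
#' \describe{
#'   \item{\code{"linoid"}}{\code{alpha = k x / (1 - exp(u))}, positive for
#'     all V; \code{alpha(V_ab) = -k s_ab}.}
#'   \item{\code{"printed"}}{\code{alpha = k x / (exp(u) - 1)}, which is
#'     negative for every V when \code{s_ab < 0}; retained only for
#'     side-by-side comparison.}
#'   \item{\code{"exp"}}{\code{alpha = k exp(-u)}, pairing with beta to give
#'     a logistic steady state with half-activation \code{V_ab} and slope
#'     \code{|s_ab|/2}.}
#'   \item{\code{"linoid_scaled"}}{\code{alpha = k x / (|s_ab| (1 - exp(u)))},
#'     the linoid normalized by its slope so \code{alpha(V_ab) = k} and the
#'     steady state is half-activated exactly at \code{V_ab}.}
#' }
#'
#' @inheritParams steady_gates
#' @return List with vectors \code{alpha} and \code{beta} (ms^-1).
#' @export
n_gate_rates <- function(V, params = model_params()) {
  x <- V - params$V_ab
  u <- x / params$s_ab
  k <- params$k_ab
  s <- params$s_ab
  small <- abs(u) < 1e-7
  alpha <- switch(params$n_gate_form,
    printed = ifelse(small, k * s * (1 - 0.5 * u), k * x / expm1(u)),
    exp = k * exp(-u),
    linoid_scaled = ifelse(small, k * (1 - 0.5 * u),
                           k * x / (abs(s) * -expm1(u))),
    ifelse(small, -k * s * (1 - 0.5 * u), k * x / -expm1(u)))
  list(alpha = alpha, beta = k * exp(u))
}

#' Steady-state membrane current
#'
#' Total ionic current (outward positive) with every gate at its
#' voltage-dependent steady state. Roots of \code{I_ss(V) = I_stim} are the
#' fixed points of the full system under constant stimulation.
#'
#' @param V membrane potential (mV); vectorized.
#' @param g conductance densities, see [conductance_set()].
#' @inheritParams steady_gates
#' @return Current density (uA/cm2), same shape as \code{V}.
#' @export
steady_current <- function(V, g, params = model_params()) {
  s <- steady_gates(V, params)
  gm <- as_g_matrix(g)
  if (nrow(gm) != 1) stop("steady_current expects a single conductance set")
  gm <- gm[1, ]
  ne <- s$n_inf^params$n_gate_power
  (params$gbar_fast * s$m_inf + gm[["gNa"]] * ne) * (V - params$E_Na) +
    (params$gbar_slow * s$w_inf + gm[["gK"]] * ne +
       gm[["gAHP"]] * s$z_inf_AHP + gm[["gM"]] * s$z_inf_M) * (V - params$E_K) +
    gm[["gleak"]] * (V - params$E_leak)
}

## Full state (V + gates at steady state) for a given voltage.
state_at <- function(V, params) {
  s <- steady_gates(V, params)
  c(V = unname(V), w = unname(s$w_inf), n = unname(s$n_inf),
    p = unname(s$z_inf_AHP), q = unname(s$z_inf_M))
}

#' Resting state of the model
#'
#' Locates the most hyperpolarized stable fixed point at \code{I_stim = 0}
#' (root of the steady-state current with positive slope) by a coarse scan
#' over \code{[-100, 0]} mV refined with [stats::uniroot()]. If no stable
#' subthreshold fixed point exists (spontaneously active model), the state
#' reached after \code{settle} ms of simulation is returned instead, with
#' attribute \code{stable = FALSE}.
#'
#' @inheritParams steady_current
#' @param settle settling duration (ms) used for the fallback.
#' @param dt time step (ms) for the fallback simulation.
#' @return Named numeric state vector \code{(V, w, n, p, q)} with attribute
#'   \code{stable}.
#' @export
find_rest <- function(params, g, settle = 500, dt = 0.1) {
  r <- find_rest_batch(params, as_g_matrix(g))
  if (is.na(r$V[1]) || !r$stable[1]) {
    cfg <- sim_config(dt = dt, settle_duration = 0, record_duration = settle)
    tr <- simulate_neuron(params, g, stim_constant(0), cfg,
                          initial = state_at(-70, params))
    st <- tr$final_state
    attr(st, "stable") <- FALSE
    return(st)
  }
  st <- state_at(r$V[1], params)
  attr(st, "stable") <- TRUE
  st
}

## Vectorized rest finding across a conductance matrix: coarse scan for the
## first upward zero crossing of I_ss, then bisection within the bracketing
## cell. Returns V (NA where none) and a stability flag.
find_rest_batch <- function(params, G, v_lo = -100, v_hi = 0, coarse = 0.5,
                            iters = 50) {
  G <- as_g_matrix(G)
  n <- nrow(G)
  vs <- seq(v_lo, v_hi, by = coarse)
  s <- steady_gates(vs, params)
  ## I_ss for all models at all scan voltages: n x length(vs)
  dna <- (vs - params$E_Na); dk <- (vs - params$E_K); dl <- (vs - params$E_leak)
  base <- params$gbar_fast * s$m_inf * dna + params$gbar_slow * s$w_inf * dk
  ne <- s$n_inf^params$n_gate_power
  iss <- outer(G[, "gNa"], ne * dna) + outer(G[, "gK"], ne * dk) +
    outer(G[, "gAHP"], s$z_inf_AHP * dk) + outer(G[, "gM"], s$z_inf_M * dk) +
    outer(G[, "gleak"], dl) + rep(base, each = n)
  ## first index j with iss[,j] < 0 and iss[,j+1] >= 0 (upward crossing)
  up <- iss[, -ncol(iss), drop = FALSE] < 0 & iss[, -1, drop = FALSE] >= 0
  j <- apply(up, 1, function(z) if (any(z)) which(z)[1] else NA_integer_)
  lo <- vs[j]; hi <- vs[j + 1]
  ok <- !is.na(j)
  if (any(ok)) {
    lo2 <- lo[ok]; hi2 <- hi[ok]; Gok <- G[ok, , drop = FALSE]
    for (it in seq_len(iters)) {
      mid <- 0.5 * (lo2 + hi2)
      im <- iss_many(mid, Gok, params)
      neg <- im < 0
      lo2[neg] <- mid[neg]; hi2[!neg] <- mid[!neg]
    }
    lo[ok] <- 0.5 * (lo2 + hi2)
  }
  list(V = ifelse(ok, lo, NA_real_), stable = ok)
}

## I_ss evaluated at one voltage per model (vectorized over models).
iss_many <- function(V, G, params) {
  s <- steady_gates(V, params)
  ne <- s$n_inf^params$n_gate_power
  dna <- V - params$E_Na; dk <- V - params$E_K; dl <- V - params$E_leak
  (params$gbar_fast * s$m_inf + G[, "gNa"] * ne) * dna +
    (params$gbar_slow * s$w_inf + G[, "gK"] * ne +
       G[, "gAHP"] * s$z_inf_AHP + G[, "gM"] * s$z_inf_M) * dk +
    G[, "gleak"] * dl
}
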