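#' Stimulus specifications
#'
#' \code{stim_constant()} describes a constant current step;
#' \code{stim_ou()} describes a mean-reverting Ornstein-Uhlenbeck current
#' \code{dI/dt = -(I - mu)/tau + S sigma N(t)} with scaling
#' \code{S = sqrt(2/tau)} so that the stationary standard deviation equals
#' \code{sigma} regardless of \code{tau}.
#'
#' @param amplitude constant current density (uA/cm2).
#' @param mu stationary mean (uA/cm2).
#' @param sigma stationary standard deviation (uA/cm2).
#' @param tau correlation time constant (ms), must be positive.
#' @param seed integer seed making realizations reproducible.
#' @return A \code{stimulus_spec} object.
#' @examples
#' ou_stimulus(stim_ou(mu = 40, sigma = 10, tau = 5, seed = 1), 100, 0.1)
#' @export
stim_constant <- function(amplitude = 0) {
  structure(list(kind = "constant", amplitude = amplitude),
            class = "stimulus_spec")
}

#' @rdname stim_constant
#' @export
stim_ou <- function(mu = 40, sigma = 10, tau = 5, seed = 1L) {
  if (tau <= 0) stop("tau_stim must be positive")
  if (sigma < 0) stop("sigma_stim must be >= 0")
  structure(list(kind = "ou", mu = mu, sigma = sigma, tau = tau,
                 seed = as.integer(seed)),
            class = "stimulus_spec")
}

#' Generate an Ornstein-Uhlenbeck stimulus series
#'
#' Euler-Maruyama discretization of the mean-reverting process:
#' \code{I[t+1] = I[t] + dt (mu - I[t])/tau + sigma sqrt(2 dt / tau) N}. The
#' recursion is an AR(1) filter and is evaluated with [stats::filter()]. The
#' series starts at \code{mu}.
#'
#' @param spec a \code{stimulus_spec} of kind \code{"ou"} (or
#'   \code{"constant"}, which yields a constant series).
#' @param duration series duration (ms).
#' @param dt time step (ms).
#' @return Numeric vector of length \code{floor(duration/dt) + 1}.
#' @export
ou_stimulus <- function(spec, duration, dt) {
  nstep <- floor(duration / dt)
  if (spec$kind == "constant")
    return(rep(spec$amplitude, nstep + 1))
  if (duration < dt) stop("duration must be at least dt")
  if (spec$sigma == 0) return(rep(spec$mu, nstep + 1))
  a <- 1 - dt / spec$tau
  if (a <= -1) stop("dt too large relative to tau_stim")
  noise <- withr_seed(spec$seed,
                      rnorm(nstep, sd = spec$sigma * sqrt(2 * dt / spec$tau)))
  dev <- stats::filter(noise, a, method = "recursive", init = 0)
  spec$mu + c(0, as.numeric(dev))
}

## Evaluate `expr` under a temporary RNG seed, restoring the caller's RNG.
withr_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}
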