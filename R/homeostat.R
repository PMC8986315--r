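#' Regulation target
#'
#' One regulated property: either a set-point (\code{mode = "value"}) or a
#' one-sided lower bound (\code{mode = "lower_bound"}; the error is zero
#' whenever the bound is satisfied, so the constraint is inactive above it).
#'
#' @param property property name (\code{"firing_rate"},
#'   \code{"energy_efficiency"}, ...).
#' @param target target value (or bound), in the property's units.
#' @param tolerance half-width within which the property counts as on
#'   target; defaults per [default_tolerances()].
#' @param mode \code{"value"} or \code{"lower_bound"}.
#' @return A \code{regulation_target} object.
#' @export
regulation_target <- function(property, target,
                              tolerance = default_tolerances(property)[[1]],
                              mode = c("value", "lower_bound")) {
  mode <- match.arg(mode)
  stopifnot(tolerance > 0)
  structure(list(property = property, target = target,
                 tolerance = tolerance, mode = mode),
            class = "regulation_target")
}

as_target_list <- function(targets) {
  if (inherits(targets, "regulation_target")) targets <- list(targets)
  stopifnot(all(vapply(targets, inherits, logical(1), "regulation_target")))
  names(targets) <- vapply(targets, `[[`, character(1), "property")
  targets
}

#' Regulation errors
#'
#' The error for each targeted property at the end of an iteration:
#' \code{target - measured} in value mode (zero inside the tolerance band,
#' which suppresses ringing once the property is on target), and
#' \code{max(0, bound - measured)} in lower-bound mode.
#'
#' @param measured named numeric vector of measured property values.
#' @param targets a [regulation_target()] or list of them.
#' @return Named numeric vector of errors (property units).
#' @export
compute_errors <- function(measured, targets) {
  targets <- as_target_list(targets)
  out <- numeric(length(targets))
  names(out) <- names(targets)
  for (nm in names(targets)) {
    tg <- targets[[nm]]
    m <- measured[[nm]]
    if (is.null(m) || is.na(m))
      stop("property not measured: ", nm)
    e <- tg$target - m
    if (tg$mode == "lower_bound") {
      e <- max(0, e)
    } else if (abs(e) <= tg$tolerance) {
      e <- 0
    }
    out[nm] <- e
  }
  out
}

#' Signed regulation-rate matrix
#'
#' Regulation time constants tau[i, p]: the update of conductance i from
#' property p's error is \code{error_p / tau[i, p]}, and updates from all
#' regulated properties are summed. Signs are free — a conductance that
#' decreases a property needs a negative tau for that property's error to
#' move it the right way. \code{Inf} (or \code{NA}) disables a pair;
#' \code{0} is rejected.
#'
#' @param ... named arguments, one per regulated property, each a named
#'   numeric vector of tau values keyed by conductance name.
#' @return A matrix (conductance x property) of class
#'   \code{regulation_rates}.
#' @examples
#' regulation_rates(firing_rate = c(gNa = 150, gK = -200))
#' @export
regulation_rates <- function(...) {
  props <- list(...)
  stopifnot(length(props) >= 1, !is.null(names(props)))
  conds <- unique(unlist(lapply(props, names)))
  stopifnot(all(conds %in% GCOND))
  m <- matrix(Inf, nrow = length(conds), ncol = length(props),
              dimnames = list(conds, names(props)))
  for (p in names(props)) m[names(props[[p]]), p] <- props[[p]]
  if (any(m == 0, na.rm = TRUE)) stop("tau = 0 is not a valid regulation rate")
  m[is.na(m)] <- Inf
  if (any(apply(m, 2, function(col) all(!is.finite(col)))))
    stop("every regulated property needs at least one finite tau")
  class(m) <- c("regulation_rates", "matrix")
  m
}

#' Sign audit of property sensitivities
#'
#' Numerically estimates d(property)/d(conductance) at a reference point by
#' central differences and returns the signs, the basis for choosing tau
#' signs: tau[i, p] must share the sign of the sensitivity for the error
#' feedback to be negative (corrective).
#'
#' @param params a [model_params()] object.
#' @param reference a [conductance_set()] at which to linearize.
#' @param properties properties to audit.
#' @param conductances conductances to audit.
#' @param h step (mS/cm2).
#' @param protocol a [measurement_protocol()].
#' @return Matrix of sensitivities (conductance x property).
#' @export
audit_sensitivities <- function(params, reference,
                                properties = "firing_rate",
                                conductances = c("gNa", "gK"),
                                h = 0.1,
                                protocol = measurement_protocol()) {
  out <- matrix(NA_real_, length(conductances), length(properties),
                dimnames = list(conductances, properties))
  for (ci in conductances) {
    up <- reference; up[ci] <- up[ci] + h
    dn <- reference; dn[ci] <- max(0, dn[ci] - h)
    G <- rbind(up, dn)
    vals <- measure_properties(params, G, protocol, which = properties)
    for (pr in properties)
      out[ci, pr] <- (vals[[pr]][1] - vals[[pr]][2]) / (up[ci] - dn[ci])
  }
  out
}

#' Default regulation rates
#'
#' Signed tau values chosen by sign audit at a reference point on the
#' 40-spk/s operating range, with magnitudes such that single-property runs
#' converge in roughly 10-50 iterations. See the vignette for the
#' calibration.
#'
#' @param properties regulated properties (subset of \code{"firing_rate"},
#'   \code{"energy_efficiency"}).
#' @param conductances adjustable conductances.
#' @param scale multiplies all tau magnitudes (larger = slower regulation).
#' @return A [regulation_rates()] matrix.
#' @export
default_rates <- function(properties = "firing_rate",
                          conductances = c("gNa", "gK"),
                          scale = 1) {
  base <- list(
    firing_rate = c(gNa = 300, gK = -240, gM = -240, gleak = -300,
                    gAHP = -240),
    energy_efficiency = c(gNa = -10, gK = -2, gM = 1.5, gleak = -15,
                          gAHP = -2))
  args <- lapply(properties, function(p) {
    v <- base[[p]]
    if (is.null(v)) stop("no default rates for property: ", p)
    v[conductances] * scale
  })
  names(args) <- properties
  do.call(regulation_rates, args)
}

#' Regulation loop configuration
#'
#' @param max_iterations iteration cap per run (default 200).
#' @param consecutive_success iterations the targets must be held within
#'   tolerance for convergence (default 5).
#' @param floor,cap conductance bounds (mS/cm2); updates are clamped to
#'   \code{[floor, cap]} (\code{cap = NULL} disables the upper bound).
#' @param protocol a [measurement_protocol()] used for the per-iteration
#'   measurements.
#' @param fresh_stimulus if \code{TRUE}, each iteration draws a fresh
#'   stimulus realization (seed advanced per iteration); default
#'   \code{FALSE} freezes the stimulus so the error signal is deterministic
#'   given the conductances.
#' @return A \code{regulation_config} object.
#' @export
regulation_config <- function(max_iterations = 200, consecutive_success = 5,
                              floor = 0, cap = 4,
                              protocol = measurement_protocol(),
                              fresh_stimulus = FALSE) {
  stopifnot(max_iterations >= consecutive_success, consecutive_success >= 1)
  structure(list(max_iterations = max_iterations,
                 consecutive_success = consecutive_success,
                 floor = floor, cap = cap, protocol = protocol,
                 fresh_stimulus = fresh_stimulus),
            class = "regulation_config")
}

#' One conductance update
#'
#' \code{g_i <- clamp(g_i + sum_p error_p / tau[i, p], floor, cap)};
#' uncontrolled pairs (infinite tau) contribute nothing.
#'
#' @param g conductance vector or matrix (members x conductances).
#' @param errors named error vector, or matrix (members x properties).
#' @param rates a [regulation_rates()] matrix.
#' @param floor,cap clamp bounds.
#' @return Updated conductances, same shape as \code{g}.
#' @export
update_conductances <- function(g, errors, rates, floor = 0, cap = NULL) {
  single <- is.null(dim(g))
  G <- if (single) matrix(g, 1, dimnames = list(NULL, names(g))) else g
  E <- if (is.null(dim(errors)))
    matrix(errors, 1, dimnames = list(NULL, names(errors))) else errors
  for (ci in rownames(rates)) {
    inv <- 1 / rates[ci, colnames(E)]
    inv[!is.finite(inv)] <- 0
    G[, ci] <- G[, ci] + as.vector(E %*% inv)
  }
  G[G < floor] <- floor
  if (!is.null(cap)) G[G > cap] <- cap
  if (single) G[1, ] else G
}

## Measure the targeted properties for a population (members x 5 matrix).
measure_targets <- function(params, G, targets, protocol) {
  props <- names(targets)
  vals <- matrix(NA_real_, nrow(G), length(props),
                 dimnames = list(NULL, props))
  for (pr in props) {
    vals[, pr] <- switch(pr,
      firing_rate = as.numeric(measure_firing_rate(params, G, protocol)),
      energy_efficiency = as.numeric(energy_efficiency(params, G, protocol)),
      input_resistance = as.numeric(input_resistance(params, G, protocol)),
      rheobase = as.numeric(rheobase(params, G, protocol)),
      stop("no measurement routine for regulated property: ", pr))
  }
  vals
}

#' Run homeostatic regulation
#'
#' Iterates measure -> error -> update for a single conductance set or a
#' population (one run per row, all batched through the compiled
#' integrator). A run converges when every targeted property has stayed
#' within tolerance for \code{consecutive_success} consecutive iterations;
#' it fails at \code{max_iterations}. Final conductances are the mean of
#' the last \code{consecutive_success} iterations.
#'
#' @param initial a [conductance_set()] or matrix of starting points (one
#'   member per row).
#' @param targets a [regulation_target()] or list of them.
#' @param rates a [regulation_rates()] matrix.
#' @param config a [regulation_config()].
#' @param params a [model_params()] object.
#' @return A \code{regulation_run}: list with \code{trajectory}
#'   (iterations x members x conductances array), \code{properties}
#'   (iterations x members x properties), \code{errors}, \code{status}
#'   (\code{"converged"}/\code{"failed"} per member), \code{iterations}
#'   used, \code{final} conductance matrix, and the inputs.
#' @export
run_regulation <- function(initial, targets, rates,
                           config = regulation_config(),
                           params = model_params()) {
  targets <- as_target_list(targets)
  G <- as_g_matrix(initial)
  nm <- nrow(G)
  nit <- config$max_iterations
  props <- names(targets)
  traj <- array(NA_real_, c(nit, nm, 5),
                dimnames = list(NULL, NULL, GCOND))
  pvals <- array(NA_real_, c(nit, nm, length(props)),
                 dimnames = list(NULL, NULL, props))
  evals <- pvals
  streak <- integer(nm)
  done_at <- rep(NA_integer_, nm)
  active <- rep(TRUE, nm)
  proto <- config$protocol
  base_seed <- proto$rate_stim$seed
  used <- 0L
  for (it in seq_len(nit)) {
    used <- it
    if (config$fresh_stimulus)
      proto$rate_stim$seed <- base_seed + it
    traj[it, , ] <- G
    idx <- which(active)
    if (!length(idx)) { used <- it - 1L; break }
    vals <- measure_targets(params, G[idx, , drop = FALSE], targets, proto)
    pvals[it, idx, ] <- vals
    E <- matrix(0, length(idx), length(props), dimnames = list(NULL, props))
    within <- rep(TRUE, length(idx))
    for (j in seq_along(idx)) {
      m <- vals[j, ]
      if (any(is.na(m))) { # measurement failure: error undefined, keep going
        within[j] <- FALSE
        E[j, ] <- 0
        next
      }
      E[j, ] <- compute_errors(as.list(m), targets)
      for (pr in props) {
        tg <- targets[[pr]]
        ok <- if (tg$mode == "lower_bound") m[pr] >= tg$target - tg$tolerance
              else abs(m[pr] - tg$target) <= tg$tolerance
        if (!ok) within[j] <- FALSE
      }
    }
    evals[it, idx, ] <- E
    streak[idx] <- ifelse(within, streak[idx] + 1L, 0L)
    newly <- idx[streak[idx] >= config$consecutive_success & is.na(done_at[idx])]
    done_at[newly] <- it
    active[newly] <- FALSE
    upd <- which(active)
    if (length(upd)) {
      ## members measured this iteration and still active get updated
      mu <- intersect(upd, idx)
      if (length(mu)) {
        Emu <- matrix(evals[it, mu, ], length(mu), length(props),
                      dimnames = list(NULL, props))
        G[mu, ] <- update_conductances(G[mu, , drop = FALSE], Emu,
                                       rates, config$floor, config$cap)
      }
    }
    if (all(!active)) break
  }
  status <- ifelse(is.na(done_at), "failed", "converged")
  k <- config$consecutive_success
  final <- matrix(NA_real_, nm, 5, dimnames = list(NULL, GCOND))
  final_prop <- matrix(NA_real_, nm, length(props),
                       dimnames = list(NULL, props))
  for (i in seq_len(nm)) {
    last <- if (is.na(done_at[i])) used else done_at[i]
    rng <- max(1, last - k + 1):last
    final[i, ] <- apply(traj[rng, i, , drop = FALSE], 3, mean)
    final_prop[i, ] <- apply(pvals[rng, i, , drop = FALSE], 3, mean,
                             na.rm = TRUE)
  }
  structure(list(trajectory = traj[seq_len(used), , , drop = FALSE],
                 properties = pvals[seq_len(used), , , drop = FALSE],
                 errors = evals[seq_len(used), , , drop = FALSE],
                 status = status, converged_at = done_at,
                 iterations = used, final = final,
                 final_properties = final_prop,
                 targets = targets, rates = rates, config = config),
            class = "regulation_run")
}

#' @export
print.regulation_run <- function(x, ...) {
  cat(sprintf("regulation_run: %d member(s), %d iteration(s); %d converged, %d failed\n",
              dim(x$trajectory)[2], x$iterations,
              sum(x$status == "converged"), sum(x$status == "failed")))
  invisible(x)
}

#' @export
summary.regulation_run <- function(object, ...) {
  conv <- object$status == "converged"
  fp <- object$final_properties
  cat(sprintf("%d/%d runs converged (median %s iterations)\n",
              sum(conv), length(conv),
              if (any(conv)) stats::median(object$converged_at[conv]) else "-"))
  for (pr in colnames(fp))
    cat(sprintf("  final %s: mean %.3g, sd %.3g\n", pr,
                mean(fp[, pr], na.rm = TRUE), sd(fp[, pr])))
  invisible(object)
}

#' @export
plot.regulation_run <- function(x, property = NULL, ...) {
  pr <- if (is.null(property)) dimnames(x$properties)[[3]][1] else property
  v <- x$properties[, , pr, drop = FALSE][, , 1, drop = FALSE]
  graphics::matplot(v[, , 1], type = "l", lty = 1, xlab = "iteration",
                    ylab = pr, ...)
  tg <- x$targets[[pr]]
  if (!is.null(tg)) graphics::abline(h = tg$target, lty = 2)
  invisible(x)
}

#' Conductance noise configuration
#'
#' @param sd Gaussian standard deviation added independently to each noisy
#'   conductance per iteration (mS/cm2).
#' @param floor,cap bounds applied after the noise draw (a density driven
#'   negative is reset to the floor before feedback; \code{cap = NULL}
#'   disables the upper bound).
#' @param iterations noise-update iteration budget.
#' @param checkpoints iteration indices at which population snapshots are
#'   recorded.
#' @param seed RNG seed for the noise draws.
#' @param conductances which conductances receive noise (default: the ones
#'   carrying finite regulation rates).
#' @return A \code{noise_config} object.
#' @export
noise_config <- function(sd = 0.05, floor = 0, cap = 4, iterations = 3000,
                         checkpoints = c(50, 200, 1000, 3000), seed = 1L,
                         conductances = NULL) {
  stopifnot(sd >= 0, iterations >= 1)
  checkpoints <- sort(unique(pmin(checkpoints, iterations)))
  structure(list(sd = sd, floor = floor, cap = cap,
                 iterations = iterations, checkpoints = checkpoints,
                 seed = as.integer(seed), conductances = conductances),
            class = "noise_config")
}

#' Apply conductance noise
#'
#' Adds an independent zero-mean Gaussian draw to each selected conductance
#' and clamps to the bounds.
#'
#' @param g conductance vector or matrix.
#' @param noise a [noise_config()] (its seed is NOT consumed here; seed the
#'   RNG at loop level).
#' @param conductances columns to perturb.
#' @return Perturbed conductances, same shape.
#' @export
apply_noise <- function(g, noise, conductances = NULL) {
  single <- is.null(dim(g))
  G <- if (single) matrix(g, 1, dimnames = list(NULL, names(g))) else g
  cols <- if (!is.null(conductances)) conductances
          else if (!is.null(noise$conductances)) noise$conductances
          else colnames(G)
  if (noise$sd > 0) {
    draw <- matrix(rnorm(nrow(G) * length(cols), sd = noise$sd),
                   nrow(G), length(cols))
    G[, cols] <- G[, cols] + draw
  }
  G[G < noise$floor] <- noise$floor
  if (!is.null(noise$cap)) G[G > noise$cap] <- noise$cap
  if (single) G[1, ] else G
}

#' Noise-update loop
#'
#' Alternates one conductance-noise draw with one homeostatic update per
#' iteration, starting from a population already on target. Records
#' population snapshots (conductances, measured properties, pairwise
#' correlation report) at the requested checkpoints.
#'
#' @param start matrix of starting conductance sets (rows), e.g. the final
#'   members of a converged [run_regulation()].
#' @param targets,rates,params as in [run_regulation()].
#' @param config a [regulation_config()]; its floor/cap also bound the
#'   feedback update.
#' @param noise a [noise_config()].
#' @return A \code{noise_loop} object: list with \code{snapshots} (one per
#'   checkpoint: iteration, conductances, properties, correlation report),
#'   \code{error_reduction} (mean |error| after update minus after noise,
#'   per iteration), and inputs.
#' @export
run_noise_loop <- function(start, targets, rates,
                           config = regulation_config(),
                           noise = noise_config(),
                           params = model_params()) {
  targets <- as_target_list(targets)
  G <- as_g_matrix(start)
  props <- names(targets)
  noisy_cols <- if (!is.null(noise$conductances)) noise$conductances
                else rownames(rates)
  proto <- config$protocol
  snapshots <- list()
  err_after_noise <- err_after_update <- rep(NA_real_, noise$iterations)
  withr_seed(noise$seed, {
    for (it in seq_len(noise$iterations)) {
      G <- apply_noise(G, noise, noisy_cols)
      vals <- measure_targets(params, G, targets, proto)
      E <- t(apply(vals, 1, function(m) {
        if (any(is.na(m))) rep(0, length(props))
        else compute_errors(as.list(setNames(m, props)), targets)
      }))
      if (length(props) == 1) E <- matrix(E, ncol = 1,
                                          dimnames = list(NULL, props))
      err_after_noise[it] <- mean(abs(vals - rep(vapply(targets, `[[`, 0,
                                                        "target"),
                                                 each = nrow(vals))),
                                  na.rm = TRUE)
      G <- update_conductances(G, E, rates, config$floor, config$cap)
      if (it %in% noise$checkpoints) {
        v2 <- measure_targets(params, G, targets, proto)
        err_after_update[it] <- mean(abs(v2 - rep(vapply(targets, `[[`, 0,
                                                         "target"),
                                                  each = nrow(v2))),
                                     na.rm = TRUE)
        rep_cols <- G[, noisy_cols, drop = FALSE]
        snapshots[[as.character(it)]] <- list(
          iteration = it, conductances = G, properties = v2,
          correlations = if (nrow(G) >= 3) zscore_correlations(rep_cols)
                         else NULL)
      }
    }
  })
  structure(list(snapshots = snapshots,
                 err_after_noise = err_after_noise,
                 err_after_update = err_after_update,
                 targets = targets, rates = rates, noise = noise,
                 config = config),
            class = "noise_loop")
}

#' @export
print.noise_loop <- function(x, ...) {
  cat(sprintf("noise_loop: %d snapshot(s) at iterations %s\n",
              length(x$snapshots), paste(names(x$snapshots), collapse = ", ")))
  invisible(x)
}
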