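#' Synthetic initial-condition clusters
#'
#' Normally distributed starting clusters of conductance densities, used as
#' initial conditions for regulation populations (published experiments use
#' such clusters; their exact values are not available, so these are
#' generated synthetically). Draws are independent per conductance and
#' floored at 0.
#'
#' @param mean named numeric vector of cluster means (mS/cm2).
#' @param sd named numeric vector of SDs (same names; recycled if scalar).
#' @param n member count.
#' @param seed RNG seed.
#' @return A \code{cluster_spec} object.
#' @export
cluster_spec <- function(mean = c(gNa = 3, gK = 1), sd = 0.3, n = 20,
                         seed = 1L) {
  if (length(sd) == 1) sd <- setNames(rep(sd, length(mean)), names(mean))
  stopifnot(all(names(mean) %in% GCOND), all(sd >= 0), n >= 1,
            identical(names(mean), names(sd)))
  structure(list(mean = mean, sd = sd, n = as.integer(n),
                 seed = as.integer(seed)),
            class = "cluster_spec")
}

#' @rdname cluster_spec
#' @param spec a \code{cluster_spec}.
#' @param background a [conductance_set()] for the non-cluster channels.
#' @return \code{generate_cluster()}: matrix of conductance sets (members x
#'   5, canonical column order).
#' @export
generate_cluster <- function(spec, background = conductance_set()) {
  draws <- withr_seed(spec$seed, {
    vapply(names(spec$mean),
           function(nm) rnorm(spec$n, spec$mean[[nm]], spec$sd[[nm]]),
           numeric(spec$n))
  })
  draws <- matrix(draws, nrow = spec$n,
                  dimnames = list(NULL, names(spec$mean)))
  draws[draws < 0] <- 0
  as_g_matrix(draws, background)
}

#' Scan the leak density for a common triple intersection
#'
#' For each leak density, extracts the iso-property contours of firing
#' rate, energy efficiency and input resistance over a (gNa, gK) grid,
#' intersects the contours pairwise, and scores the mismatch as the minimal
#' enclosing radius of the three pairwise intersection points (choosing the
#' combination of intersection points that minimizes it). The leak density
#' minimizing the mismatch is refined by golden-section search.
#'
#' @param gleak_range length-2 numeric: scan bracket (mS/cm2).
#' @param targets named numeric vector with elements \code{firing_rate},
#'   \code{energy_efficiency} and \code{input_resistance}.
#' @param params a [model_params()] object.
#' @param axes grid axes for the (gNa, gK) sub-grid.
#' @param background background densities (its \code{gleak} entry is
#'   overridden by the scan).
#' @param protocol a [measurement_protocol()].
#' @param n_scan number of coarse scan points across the bracket.
#' @param tol golden-section resolution (mS/cm2).
#' @param field_fun optional function \code{f(gleak)} returning a named
#'   list of the three fields (matrices over the axes) — used to run the
#'   scan on analytic fields instead of the neuron model.
#' @return List with \code{gleak} (the minimizer), \code{mismatch} (its
#'   enclosing radius), \code{scan} (data frame of coarse scan values) and
#'   \code{intersections} (the three pairwise points at the optimum).
#' @export
leak_scan <- function(gleak_range = c(1.7, 2.1),
                      targets = c(firing_rate = 40, energy_efficiency = 23.5,
                                  input_resistance = 0.65),
                      params = model_params(),
                      axes = list(gNa = c(0, 4, 60), gK = c(0, 4, 60)),
                      background = conductance_set(gM = 0.5, gAHP = 1.75),
                      protocol = measurement_protocol(),
                      n_scan = 9, tol = 0.01, field_fun = NULL) {
  props <- names(targets)
  axv <- lapply(axes, function(a) seq(a[1], a[2], length.out = a[3]))

  contours_at <- function(gleak) {
    fields <- if (!is.null(field_fun)) {
      field_fun(gleak)
    } else {
      bg <- background
      bg["gleak"] <- gleak
      spec <- grid_spec(axes, background = bg, properties = props,
                        protocol = protocol)
      evaluate_grid(spec, params)$fields
    }
    lapply(props, function(pr) {
      cl <- grDevices::contourLines(axv[[1]], axv[[2]],
                                    matrix(fields[[pr]],
                                           length(axv[[1]]), length(axv[[2]])),
                                    levels = targets[[pr]])
      lapply(cl, function(s) cbind(s$x, s$y))
    })
  }

  mismatch_at <- function(gleak) {
    cs <- contours_at(gleak)
    if (any(lengths(cs) == 0)) return(list(score = Inf, pts = NULL))
    p12 <- intersect_polylines(cs[[1]], cs[[2]])
    p13 <- intersect_polylines(cs[[1]], cs[[3]])
    p23 <- intersect_polylines(cs[[2]], cs[[3]])
    if (!nrow(p12) || !nrow(p13) || !nrow(p23))
      return(list(score = Inf, pts = NULL))
    best <- Inf; bp <- NULL
    for (i in seq_len(nrow(p12))) for (j in seq_len(nrow(p13)))
      for (k in seq_len(nrow(p23))) {
        pts <- rbind(p12[i, ], p13[j, ], p23[k, ])
        r <- min_enclosing_radius(pts)
        if (r < best) { best <- r; bp <- pts }
      }
    list(score = best, pts = bp)
  }

  scan_x <- seq(gleak_range[1], gleak_range[2], length.out = n_scan)
  scan_y <- vapply(scan_x, function(gl) mismatch_at(gl)$score, numeric(1))
  if (all(!is.finite(scan_y)))
    stop("no leak density in the range yields all three contours")
  i0 <- which.min(scan_y)
  lo <- scan_x[max(1, i0 - 1)]
  hi <- scan_x[min(n_scan, i0 + 1)]
  ## golden-section refinement
  gr <- (sqrt(5) - 1) / 2
  a <- lo; b <- hi
  c1 <- b - gr * (b - a); c2 <- a + gr * (b - a)
  f1 <- mismatch_at(c1)$score; f2 <- mismatch_at(c2)$score
  while (b - a > tol) {
    if (f1 <= f2) {
      b <- c2; c2 <- c1; f2 <- f1
      c1 <- b - gr * (b - a); f1 <- mismatch_at(c1)$score
    } else {
      a <- c1; c1 <- c2; f1 <- f2
      c2 <- a + gr * (b - a); f2 <- mismatch_at(c2)$score
    }
  }
  opt <- (a + b) / 2
  res <- mismatch_at(opt)
  list(gleak = opt, mismatch = res$score, pts = res$pts,
       scan = data.frame(gleak = scan_x, mismatch = scan_y))
}

#' Turnkey scenario definitions
#'
#' Bundles the package's computational experiments into reproducible
#' scenarios: \code{"grid_maps"} (2-D property maps and iso-contours),
#' \code{"knockout"} (gK knockout and feedback compensation),
#' \code{"intersections"} (the leak scan for a common triple intersection),
#' \code{"correlations"} (cluster regulation and the
#' dimensionality-correlation pattern), \code{"rates"} (regulation-rate
#' dependence of correlations), \code{"noise"} (noise-update loop),
#' \code{"failure"} (adversarial-rate regulation failure) and
#' \code{"bounds"} (lower-bound efficiency regulation).
#'
#' @param id scenario identifier.
#' @param seed integer seed propagated to all nested specifications.
#' @param size \code{"small"} (test-scale) or \code{"full"}.
#' @return A \code{scenario} object (a list of nested specs plus an
#'   \code{expect} descriptor of the qualitative outcome).
#' @export
scenario <- function(id = c("grid_maps", "knockout", "intersections",
                            "correlations", "rates", "noise", "failure",
                            "bounds"),
                     seed = 1L, size = c("small", "full")) {
  id <- match.arg(id)
  size <- match.arg(size)
  small <- size == "small"
  proto <- measurement_protocol(
    rate_window = if (small) 4000 else 10000,
    rate_stim = stim_ou(mu = 40, sigma = 10, tau = 5, seed = seed))
  base <- list(id = id, seed = as.integer(seed), size = size,
               protocol = proto,
               params = model_params())
  extra <- switch(id,
    grid_maps = list(
      axes = list(gNa = c(0, 4, if (small) 20 else 100),
                  gK = c(0, 4, if (small) 20 else 100)),
      background = conductance_set(gM = 0.5, gAHP = 1.75),
      properties = c("firing_rate", "energy_efficiency"),
      targets = c(firing_rate = 40, energy_efficiency = 23.5)),
    knockout = list(
      n_models = if (small) 10 else 20,
      baseline_gK = 2,
      background = conductance_set(gK = 2, gM = 0.5, gAHP = 1.75),
      sample_ranges = list(gNa = c(0.5, 4), gleak = c(1, 3)),
      rate_target = regulation_target("firing_rate", 40),
      rates = list(gNa = regulation_rates(firing_rate = c(gNa = 300)),
                   gleak = regulation_rates(firing_rate = c(gleak = -300)))),
    intersections = list(
      gleak_range = c(1.7, 2.1),
      axes = list(gNa = c(0, 4, if (small) 40 else 60), gK = c(0, 4, if (small) 40 else 60)),
      targets = c(firing_rate = 40, energy_efficiency = 23.5,
                  input_resistance = 0.65),
      background = conductance_set(gM = 0.5, gAHP = 1.75)),
    correlations = list(
      cluster = cluster_spec(mean = c(gNa = 2.8, gK = 1.2), sd = 0.25,
                             n = if (small) 20 else 40, seed = seed),
      background = conductance_set(gM = 0.5, gAHP = 1.75),
      targets = regulation_target("firing_rate", 40),
      variants = list(
        n2 = c("gNa", "gK"), n3 = c("gNa", "gK", "gM"),
        n4 = c("gNa", "gK", "gM", "gleak"))),
    rates = list(
      cluster = cluster_spec(mean = c(gNa = 2.8, gK = 1.2, gM = 1), sd = 0.25,
                             n = if (small) 20 else 40, seed = seed),
      background = conductance_set(gAHP = 1.75),
      rate_sets = list(
        A = default_rates(c("firing_rate", "energy_efficiency"),
                          c("gNa", "gK", "gM")),
        ## same signs, different coadjustment ratios
        B = regulation_rates(
          firing_rate = c(gNa = 600, gK = -160, gM = -480),
          energy_efficiency = c(gNa = -20, gK = -1.5, gM = 3)))),
    noise = list(
      cluster = cluster_spec(mean = c(gNa = 2.8, gK = 1.2, gM = 1), sd = 0.25,
                             n = if (small) 12 else 20, seed = seed),
      background = conductance_set(gAHP = 1.75),
      targets = regulation_target("firing_rate", 40),
      rates = default_rates("firing_rate", c("gNa", "gK", "gM")),
      noise = noise_config(sd = 0.05, iterations = if (small) 60 else 3000,
                           checkpoints = if (small) c(20, 60)
                                         else c(50, 200, 1000, 3000),
                           seed = seed)),
    failure = list(
      cluster = cluster_spec(mean = c(gNa = 2.8, gK = 1.2, gM = 1), sd = 0.25,
                             n = if (small) 6 else 20, seed = seed),
      background = conductance_set(gAHP = 1.75),
      targets = list(regulation_target("firing_rate", 40),
                     regulation_target("energy_efficiency", 23.5)),
      rates = {
        r <- default_rates(c("firing_rate", "energy_efficiency"),
                           c("gNa", "gK", "gM"))
        r[, "energy_efficiency"] <- -r[, "energy_efficiency"] # wrong-signed
        r
      }),
    bounds = list(
      cluster = cluster_spec(mean = c(gNa = 2.8, gK = 1.2, gM = 1), sd = 0.25,
                             n = if (small) 8 else 20, seed = seed),
      background = conductance_set(gAHP = 1.75),
      bound_levels = c(22, 27, 30),
      rates = default_rates(c("firing_rate", "energy_efficiency"),
                            c("gNa", "gK", "gM"))))
  structure(c(base, extra), class = "scenario")
}

#' Run a scenario
#'
#' Executes the pipeline bound to a [scenario()] and writes its outputs
#' (CSV tables and a JSON manifest recording all parameters and seeds) to
#' \code{out_dir}. Returns a machine-checkable summary list.
#'
#' @param s a [scenario()].
#' @param out_dir output directory (created if missing); \code{NULL} skips
#'   file output.
#' @return Named list of summary numbers (counts, rates, correlations,
#'   convergence statuses) depending on the scenario.
#' @export
run_scenario <- function(s, out_dir = NULL) {
  stopifnot(inherits(s, "scenario"))
  params <- s$params
  proto <- s$protocol
  summary <- switch(s$id,
    grid_maps = {
      spec <- grid_spec(s$axes, s$background, s$properties, proto)
      pg <- evaluate_grid(spec, params)
      sets <- lapply(names(s$targets), function(nm)
        extract_solution_set(pg, s$targets[nm]))
      names(sets) <- names(s$targets)
      list(n_points = nrow(pg$G),
           members = lapply(sets, function(x) nrow(x$members)),
           geometry = lapply(sets, function(x) x$geometry$class))
    },
    knockout = {
      Gk <- tune_to_rate(params, proto, target = s$rate_target$target,
                         tolerance = s$rate_target$tolerance,
                         n = s$n_models,
                         gleak_range = s$sample_ranges$gleak,
                         gNa_range = s$sample_ranges$gNa,
                         background = s$background, seed = s$seed)
      pre <- as.numeric(measure_firing_rate(params, Gk, proto))
      Gk0 <- Gk; Gk0[, "gK"] <- 0
      post <- as.numeric(measure_firing_rate(params, Gk0, proto))
      comp <- lapply(s$rates, function(rr)
        run_regulation(Gk0, s$rate_target, rr,
                       regulation_config(protocol = proto), params))
      list(n_models = nrow(Gk),
           rate_before = mean(pre), rate_after_knockout = mean(post),
           compensation = lapply(comp, function(reg) list(
             rate_after_regulation =
               mean(reg$final_properties[, "firing_rate"]),
             n_converged = sum(reg$status == "converged"),
             mean_gNa_change = mean(reg$final[, "gNa"] - Gk0[, "gNa"]),
             mean_gleak_change = mean(reg$final[, "gleak"] -
                                        Gk0[, "gleak"]))))
    },
    intersections = {
      ls <- leak_scan(s$gleak_range, s$targets, params, s$axes,
                      s$background, proto)
      list(gleak_star = ls$gleak, mismatch = ls$mismatch)
    },
    correlations = {
      out <- list()
      for (vn in names(s$variants)) {
        conds <- s$variants[[vn]]
        rates <- default_rates("firing_rate", conds)
        start <- generate_cluster(s$cluster, s$background)
        reg <- run_regulation(start, s$targets, rates,
                              regulation_config(protocol = proto), params)
        conv <- reg$status == "converged"
        rep <- if (sum(conv) >= 3)
          zscore_correlations(reg$final[conv, conds, drop = FALSE]) else NULL
        out[[vn]] <- list(
          n_converged = sum(conv),
          mean_final_rate = mean(reg$final_properties[conv, "firing_rate"]),
          mean_abs_R = if (!is.null(rep)) mean_abs_correlation(rep) else NA)
      }
      out
    },
    rates = {
      out <- list()
      start <- generate_cluster(s$cluster, s$background)
      for (rn in names(s$rate_sets)) {
        reg <- run_regulation(start,
                              list(regulation_target("firing_rate", 40),
                                   regulation_target("energy_efficiency",
                                                     23.5)),
                              s$rate_sets[[rn]],
                              regulation_config(protocol = proto), params)
        conv <- reg$status == "converged"
        rep <- if (sum(conv) >= 3)
          zscore_correlations(reg$final[conv, c("gNa", "gK", "gM"),
                                        drop = FALSE]) else NULL
        out[[rn]] <- list(n_converged = sum(conv),
                          R = if (!is.null(rep)) rep$R else NULL)
      }
      out
    },
    noise = {
      start <- generate_cluster(s$cluster, s$background)
      reg <- run_regulation(start, s$targets, s$rates,
                            regulation_config(protocol = proto), params)
      conv <- reg$status == "converged"
      nl <- run_noise_loop(reg$final[conv, , drop = FALSE], s$targets,
                           s$rates, regulation_config(protocol = proto),
                           s$noise, params)
      spread <- vapply(nl$snapshots, function(sn)
        sum(apply(sn$conductances[, rownames(s$rates), drop = FALSE], 2,
                  stats::var)), numeric(1))
      list(n_start = sum(conv), spread_by_checkpoint = spread)
    },
    failure = {
      start <- generate_cluster(s$cluster, s$background)
      reg <- run_regulation(start, s$targets, s$rates,
                            regulation_config(protocol = proto), params)
      list(n_failed = sum(reg$status == "failed"),
           n_total = length(reg$status),
           iterations = reg$iterations)
    },
    bounds = {
      out <- list()
      start <- generate_cluster(s$cluster, s$background)
      for (b in s$bound_levels) {
        tg <- list(regulation_target("firing_rate", 40),
                   regulation_target("energy_efficiency", b,
                                     mode = "lower_bound"))
        reg <- run_regulation(start, tg, s$rates,
                              regulation_config(protocol = proto), params)
        conv <- reg$status == "converged"
        out[[paste0("bound_", b)]] <- list(
          n_converged = sum(conv),
          mean_final_rate = mean(reg$final_properties[, "firing_rate"],
                                 na.rm = TRUE),
          mean_final_eff = mean(reg$final_properties[, "energy_efficiency"],
                                na.rm = TRUE),
          frac_gK_gM_at_floor = mean(reg$final[, c("gK", "gM")] < 1e-6))
      }
      out
    })
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_manifest(file.path(out_dir, paste0(s$id, "_manifest.json")),
                   scenario = s, summary = summary)
    utils::write.csv(
      data.frame(key = names(unlist(summary)), value = unlist(summary)),
      file.path(out_dir, paste0(s$id, "_summary.csv")), row.names = FALSE)
  }
  summary
}

#' Tune conductance sets onto an iso-firing-rate contour
#'
#' Draws leak densities uniformly over a range and, for each, bisects the
#' sodium density until the firing rate under the protocol stimulus falls
#' within tolerance of the target. Points whose bracket does not straddle
#' the target are dropped and redrawn (up to 4x oversampling).
#'
#' @param params a [model_params()] object.
#' @param protocol a [measurement_protocol()].
#' @param target,tolerance target firing rate and half-width (spk/s).
#' @param n number of tuned combinations to return.
#' @param gleak_range,gNa_range sampling range for the leak density and
#'   bisection bracket for the sodium density (mS/cm2).
#' @param background fixed densities for the other channels.
#' @param seed RNG seed for the leak draws.
#' @return Conductance matrix (n x 5) on the iso-rate contour.
#' @export
tune_to_rate <- function(params, protocol = measurement_protocol(),
                         target = 40, tolerance = 3, n = 10,
                         gleak_range = c(1, 3), gNa_range = c(0.5, 4),
                         background = conductance_set(gK = 2, gM = 0.5,
                                                      gAHP = 1.75),
                         seed = 1L) {
  draws <- withr_seed(seed, runif(4 * n, gleak_range[1], gleak_range[2]))
  lo <- rep(gNa_range[1], length(draws))
  hi <- rep(gNa_range[2], length(draws))
  Gof <- function(gna, gl) {
    m <- cbind(gNa = gna, gleak = gl)
    as_g_matrix(m, background)
  }
  rlo <- as.numeric(measure_firing_rate(params, Gof(lo, draws), protocol))
  rhi <- as.numeric(measure_firing_rate(params, Gof(hi, draws), protocol))
  ok <- !is.na(rlo) & !is.na(rhi) & rlo < target & rhi > target
  draws <- draws[ok]; lo <- lo[ok]; hi <- hi[ok]
  if (length(draws) < n)
    stop("could not bracket the target rate for enough leak draws")
  for (it in 1:12) {
    mid <- (lo + hi) / 2
    rm <- as.numeric(measure_firing_rate(params, Gof(mid, draws), protocol))
    up <- !is.na(rm) & rm < target
    lo[up] <- mid[up]; hi[!up] <- mid[!up]
  }
  G <- Gof((lo + hi) / 2, draws)
  r <- as.numeric(measure_firing_rate(params, G, protocol))
  G <- G[!is.na(r) & abs(r - target) <= tolerance, , drop = FALSE]
  if (nrow(G) < n) stop("bisection failed to reach the target rate band")
  G[seq_len(n), , drop = FALSE]
}

## ---- configuration and manifest round-trip ----

#' Write and read run configuration files
#'
#' Model, stimulus and protocol parameters round-trip through a structured
#' key-value YAML file; every scenario run emits a JSON manifest recording
#' all parameters and seeds.
#'
#' @param params a [model_params()] object.
#' @param protocol a [measurement_protocol()] (optional).
#' @param path file path.
#' @return \code{read_config()} returns a list with \code{params} and
#'   (optionally) \code{protocol} reconstructed.
#' @export
write_config <- function(path, params = model_params(),
                         protocol = NULL) {
  cfg <- list(model = unclass(params)[setdiff(names(params), "n_form_code")])
  if (!is.null(protocol)) {
    pl <- unclass(protocol)
    pl$rate_stim <- unclass(pl$rate_stim)
    cfg$protocol <- pl
  }
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  out <- list(params = do.call(model_params, cfg$model))
  if (!is.null(cfg$protocol)) {
    pl <- cfg$protocol
    pl$rate_stim <- do.call(stim_ou, pl$rate_stim[c("mu", "sigma", "tau",
                                                    "seed")])
    out$protocol <- do.call(measurement_protocol, pl)
  }
  out
}

#' Write a JSON run manifest
#'
#' @param path output path.
#' @param ... named components (specifications, seeds, summaries); classed
#'   objects are unclassed recursively.
#' @return \code{path}, invisibly.
#' @export
write_manifest <- function(path, ...) {
  strip <- function(x) {
    if (is.list(x)) {
      x <- unclass(x)
      x <- x[!vapply(x, is.function, logical(1))]
      lapply(x, strip)
    } else if (is.matrix(x)) {
      list(dim = dim(x), dimnames = dimnames(x), values = as.vector(x))
    } else x
  }
  jsonlite::write_json(strip(list(...)), path, auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(path)
}

#' Export property evaluations as tidy records
#'
#' One row per (conductance set, property, value) with the protocol's
#' stimulus seed, appended to the conductance columns.
#'
#' @param df a data frame from [measure_properties()].
#' @param path output CSV path.
#' @param protocol the protocol used (for the seed column).
#' @return \code{path}, invisibly.
#' @export
write_property_csv <- function(df, path, protocol = measurement_protocol()) {
  pcols <- setdiff(names(df), GCOND)
  long <- do.call(rbind, lapply(pcols, function(pr)
    data.frame(df[GCOND], property = pr, value = df[[pr]],
               seed = protocol$rate_stim$seed)))
  utils::write.csv(long, path, row.names = FALSE)
  invisible(path)
}
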