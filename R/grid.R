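#' Conductance-density grid specification
#'
#' Describes a rectangular grid over 1-3 adjustable conductance axes, the
#' fixed background densities for the remaining channels, the properties to
#' evaluate and the measurement protocol. Published maps use 100 x 100
#' (2-D) and 30 x 30 x 30 (3-D) grids; smaller counts scale the same
#' computation down.
#'
#' @param axes named list; each element is \code{c(min, max, count)} for one
#'   of \code{gNa}, \code{gK}, \code{gM}, \code{gleak}, \code{gAHP}.
#' @param background a [conductance_set()] supplying non-axis densities.
#' @param properties character vector of properties understood by
#'   [measure_properties()].
#' @param protocol a [measurement_protocol()].
#' @param seed_policy \code{"shared"} (default): one frozen stimulus
#'   realization for every grid point, so iso-rate contours are not blurred
#'   by sampling noise; \code{"per_point"}: an independent realization per
#'   point.
#' @return A \code{grid_spec} object.
#' @examples
#' gs <- grid_spec(list(gNa = c(0, 4, 25), gK = c(0, 4, 25)),
#'                 properties = "firing_rate")
#' @export
grid_spec <- function(axes, background = conductance_set(),
                      properties = "firing_rate",
                      protocol = measurement_protocol(),
                      seed_policy = c("shared", "per_point")) {
  seed_policy <- match.arg(seed_policy)
  stopifnot(is.list(axes), length(axes) >= 1, length(axes) <= 3,
            all(names(axes) %in% GCOND))
  for (a in axes) {
    stopifnot(length(a) == 3, a[3] >= 1, a[2] >= a[1], a[1] >= 0)
  }
  structure(list(axes = axes, background = background,
                 properties = properties, protocol = protocol,
                 seed_policy = seed_policy),
            class = "grid_spec")
}

## Axis value vectors and the full conductance matrix of a grid_spec.
grid_points <- function(spec) {
  vals <- lapply(spec$axes, function(a)
    if (a[3] == 1) a[1] else seq(a[1], a[2], length.out = a[3]))
  pts <- as.matrix(expand.grid(vals, KEEP.OUT.ATTRS = FALSE))
  colnames(pts) <- names(spec$axes)
  list(values = vals, G = as_g_matrix(pts, spec$background))
}

#' Evaluate properties over a conductance grid
#'
#' Runs the requested property measurements for every grid point (batched
#' through the compiled integrator) and returns one array per property with
#' the grid's shape. Deterministic given the protocol's stimulus seed; with
#' \code{seed_policy = "per_point"} each point uses stimulus seed
#' \code{seed + point index}.
#'
#' @param spec a [grid_spec()].
#' @param params a [model_params()] object.
#' @return A \code{property_grid}: list with \code{axes} (named list of axis
#'   values), \code{fields} (named list of arrays), \code{G} (the full
#'   conductance matrix), \code{background}, \code{spec}.
#' @export
evaluate_grid <- function(spec, params = model_params()) {
  gp <- grid_points(spec)
  dims <- vapply(gp$values, length, integer(1))
  fields <- list()
  df <- if (spec$seed_policy == "shared") {
    measure_properties(params, gp$G, spec$protocol, which = spec$properties)
  } else {
    base_seed <- spec$protocol$rate_stim$seed
    rows <- lapply(seq_len(nrow(gp$G)), function(i) {
      proto <- spec$protocol
      proto$rate_stim$seed <- base_seed + i
      measure_properties(params, gp$G[i, , drop = FALSE], proto,
                         which = spec$properties)
    })
    do.call(rbind, rows)
  }
  for (w in spec$properties)
    fields[[w]] <- array(df[[w]], dim = dims)
  structure(list(axes = gp$values, fields = fields, G = gp$G,
                 background = spec$background, spec = spec),
            class = "property_grid")
}

#' @export
print.property_grid <- function(x, ...) {
  cat(sprintf("property_grid: %s over %s\n",
              paste(names(x$fields), collapse = ", "),
              paste(sprintf("%s[%d]", names(x$axes),
                            lengths(x$axes)), collapse = " x ")))
  for (nm in names(x$fields)) {
    f <- x$fields[[nm]]
    cat(sprintf("  %s: range [%.3g, %.3g], %d NA\n", nm,
                suppressWarnings(min(f, na.rm = TRUE)),
                suppressWarnings(max(f, na.rm = TRUE)), sum(is.na(f))))
  }
  invisible(x)
}

#' Extract a solution set from evaluated property fields
#'
#' Members are the grid points whose measured properties all lie within
#' tolerance of their targets (single-output sets use one property;
#' multi-output sets are the intersection of the single-output conditions).
#'
#' @param grid a \code{property_grid} from [evaluate_grid()].
#' @param targets named numeric vector of target values (names must match
#'   evaluated properties).
#' @param tolerances named numeric vector of half-widths, same names as
#'   \code{targets}. Defaults: 3 spk/s for \code{firing_rate}, 0.25 for
#'   \code{energy_efficiency}, 0.003 for \code{input_resistance}.
#' @return A \code{solution_set}: members (conductance matrix), their grid
#'   indices, free-axis coordinates, targets/tolerances, provenance
#'   \code{"grid"}, and a geometry classification (see
#'   [classify_geometry()]).
#' @export
extract_solution_set <- function(grid, targets,
                                 tolerances = default_tolerances(names(targets))) {
  stopifnot(inherits(grid, "property_grid"),
            all(names(targets) %in% names(grid$fields)),
            all(names(targets) %in% names(tolerances)))
  ok <- rep(TRUE, nrow(grid$G))
  for (nm in names(targets)) {
    f <- as.vector(grid$fields[[nm]])
    ok <- ok & !is.na(f) & abs(f - targets[[nm]]) <= tolerances[[nm]]
  }
  idx <- which(ok)
  free <- grid$G[idx, names(grid$axes), drop = FALSE]
  spacing <- vapply(grid$axes, function(v) if (length(v) > 1) diff(v[1:2]) else 0,
                    numeric(1))
  structure(list(members = grid$G[idx, , drop = FALSE],
                 indices = idx, coords = free,
                 axes = names(grid$axes), spacing = spacing,
                 targets = targets, tolerances = tolerances[names(targets)],
                 provenance = "grid",
                 geometry = classify_geometry(free, spacing)),
            class = "solution_set")
}

#' Default property tolerances
#'
#' The selection tolerances used for solution sets and regulation targets:
#' +/-3 spk/s for firing rate, +/-0.25 percentage points for energy
#' efficiency, +/-0.003 kOhm cm2 for input resistance; other properties
#' default to 1% of 1 unit.
#'
#' @param properties character vector of property names.
#' @return Named numeric vector.
#' @export
default_tolerances <- function(properties) {
  known <- c(firing_rate = 3, energy_efficiency = 0.25,
             input_resistance = 0.003, rheobase = 0.5, f_min = 3,
             energy_rate = NA)
  out <- known[properties]
  out[is.na(out)] <- 0.01
  names(out) <- properties
  out
}

#' @export
print.solution_set <- function(x, ...) {
  cat(sprintf("solution_set (%s): %d members, geometry %s\n",
              x$provenance, nrow(x$members), x$geometry$class))
  cat("  targets:", paste(sprintf("%s = %g (+/- %g)", names(x$targets),
                                  x$targets, x$tolerances), collapse = "; "), "\n")
  invisible(x)
}

#' Classify the geometry of a point set
#'
#' Heuristic used to report the intrinsic dimensionality of solution sets:
#' principal-component analysis of the member coordinates, counting
#' components whose standard deviation exceeds both the grid-resolution
#' noise floor (one grid cell) and the 98% cumulative-explained-variance
#' cutoff. Classes: \code{"empty"}, \code{"point-like"} (0),
#' \code{"curve-like"} (1), \code{"surface-like"} (2), \code{"volume-like"}
#' (3).
#'
#' @param coords numeric matrix of member coordinates (free axes only).
#' @param spacing numeric vector of grid spacings per axis.
#' @param var_cutoff cumulative explained-variance threshold.
#' @return List with \code{class}, \code{dim}, \code{n}, \code{pca_sd}.
#' @export
classify_geometry <- function(coords, spacing, var_cutoff = 0.98) {
  n <- nrow(coords)
  if (is.null(n) || n == 0)
    return(list(class = "empty", dim = NA_integer_, n = 0L, pca_sd = numeric(0)))
  floor_sd <- mean(spacing)
  if (n < 3 || all(apply(coords, 2, function(v) diff(range(v))) <= 1.5 * floor_sd))
    return(list(class = "point-like", dim = 0L, n = n, pca_sd = numeric(0)))
  pc <- prcomp(coords, center = TRUE, scale. = FALSE)
  sds <- pc$sdev
  cum <- cumsum(sds^2) / sum(sds^2)
  r_var <- which(cum >= var_cutoff)[1]
  r_floor <- sum(sds > floor_sd)
  r <- max(0L, min(r_var, r_floor))
  cls <- c("point-like", "curve-like", "surface-like", "volume-like")[r + 1]
  list(class = cls, dim = as.integer(r), n = as.integer(n), pca_sd = sds)
}

#' Iso-property manifold
#'
#' Piecewise-linear level set of one property field: contour polylines via
#' marching squares in 2-D (through [grDevices::contourLines()]) or a
#' triangulated surface via marching tetrahedra in 3-D. Vertices carry
#' interpolated conductance coordinates on the grid axes.
#'
#' @param grid a \code{property_grid} with 2 or 3 axes.
#' @param property name of the field to contour.
#' @param target level value.
#' @return For 2-D, a list of polylines (each a 2-column matrix named by the
#'   axes); for 3-D, a list with \code{vertices} (n x 3) and
#'   \code{triangles} (m x 3 vertex indices). An empty level set gives an
#'   empty list; a field constant at the target is flagged degenerate via
#'   attribute \code{degenerate}.
#' @export
iso_manifold <- function(grid, property, target) {
  f <- grid$fields[[property]]
  if (is.null(f)) stop("property not evaluated on this grid: ", property)
  nd <- length(grid$axes)
  if (all(!is.na(f) & f == target)) {
    out <- list()
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  if (nd == 2) {
    cl <- grDevices::contourLines(grid$axes[[1]], grid$axes[[2]], f,
                                  levels = target)
    lapply(cl, function(s) {
      m <- cbind(s$x, s$y)
      colnames(m) <- names(grid$axes)
      m
    })
  } else if (nd == 3) {
    marching_tetrahedra(grid$axes[[1]], grid$axes[[2]], grid$axes[[3]],
                        f, target, axis_names = names(grid$axes))
  } else {
    stop("iso_manifold requires a 2-D or 3-D grid")
  }
}

## Marching tetrahedra on a rectilinear 3-D grid. Each cell is split into 6
## tetrahedra sharing the main diagonal; each tetrahedron crossing the level
## contributes 1 or 2 triangles with vertices linearly interpolated on its
## edges. NA field values suppress the incident cells.
marching_tetrahedra <- function(x, y, z, f, level, axis_names = c("x", "y", "z")) {
  nx <- length(x); ny <- length(y); nz <- length(z)
  ## corner offsets of a cell, binary order (dx, dy, dz)
  off <- cbind(c(0,1,0,1,0,1,0,1), c(0,0,1,1,0,0,1,1), c(0,0,0,0,1,1,1,1))
  ## 6 tetrahedra along the 0-7 diagonal (corner indices 1..8)
  tets <- rbind(c(1,2,4,8), c(1,2,6,8), c(1,3,4,8),
                c(1,3,7,8), c(1,5,6,8), c(1,5,7,8))
  cells <- as.matrix(expand.grid(i = seq_len(nx - 1), j = seq_len(ny - 1),
                                 k = seq_len(nz - 1)))
  corner_val <- matrix(NA_real_, nrow(cells), 8)
  for (c8 in 1:8) {
    corner_val[, c8] <- f[cbind(cells[, 1] + off[c8, 1],
                                cells[, 2] + off[c8, 2],
                                cells[, 3] + off[c8, 3])]
  }
  keep <- rowSums(is.na(corner_val)) == 0 &
    apply(corner_val, 1, min) <= level & apply(corner_val, 1, max) >= level
  cells <- cells[keep, , drop = FALSE]
  corner_val <- corner_val[keep, , drop = FALSE]
  verts <- list(); tris <- list(); nv <- 0L
  interp <- function(p1, p2, v1, v2) {
    t <- (level - v1) / (v2 - v1)
    p1 + t * (p2 - p1)
  }
  for (r in seq_len(nrow(cells))) {
    cij <- cells[r, ]
    pos <- cbind(x[cij[1] + off[, 1]], y[cij[2] + off[, 2]], z[cij[3] + off[, 3]])
    vals <- corner_val[r, ]
    for (tt in seq_len(nrow(tets))) {
      id <- tets[tt, ]
      tv <- vals[id]
      above <- tv > level
      nab <- sum(above)
      if (nab == 0 || nab == 4) next
      tp <- pos[id, , drop = FALSE]
      if (nab == 1 || nab == 3) {
        apex <- if (nab == 1) which(above) else which(!above)
        others <- setdiff(1:4, apex)
        tri <- t(vapply(others, function(o)
          interp(tp[apex, ], tp[o, ], tv[apex], tv[o]), numeric(3)))
        verts[[length(verts) + 1L]] <- tri
        tris[[length(tris) + 1L]] <- nv + 1:3
        nv <- nv + 3L
      } else {
        hi <- which(above); lo <- which(!above)
        q <- rbind(interp(tp[hi[1], ], tp[lo[1], ], tv[hi[1]], tv[lo[1]]),
                   interp(tp[hi[1], ], tp[lo[2], ], tv[hi[1]], tv[lo[2]]),
                   interp(tp[hi[2], ], tp[lo[2], ], tv[hi[2]], tv[lo[2]]),
                   interp(tp[hi[2], ], tp[lo[1], ], tv[hi[2]], tv[lo[1]]))
        verts[[length(verts) + 1L]] <- q
        tris[[length(tris) + 1L]] <- nv + 1:3
        tris[[length(tris) + 1L]] <- nv + c(1, 3, 4)
        nv <- nv + 4L
      }
    }
  }
  if (!length(verts)) return(list(vertices = matrix(numeric(0), 0, 3),
                                  triangles = matrix(integer(0), 0, 3)))
  V <- do.call(rbind, verts)
  colnames(V) <- axis_names
  list(vertices = V, triangles = matrix(unlist(tris), ncol = 3, byrow = TRUE))
}

#' Surface area of a triangulated manifold
#'
#' @param surf list with \code{vertices} and \code{triangles} as returned by
#'   [iso_manifold()] on a 3-D grid.
#' @return Total area (axis units squared).
#' @export
manifold_area <- function(surf) {
  if (!nrow(surf$triangles)) return(0)
  a <- surf$vertices[surf$triangles[, 1], , drop = FALSE]
  b <- surf$vertices[surf$triangles[, 2], , drop = FALSE]
  cc <- surf$vertices[surf$triangles[, 3], , drop = FALSE]
  u <- b - a; v <- cc - a
  cx <- u[, 2] * v[, 3] - u[, 3] * v[, 2]
  cy <- u[, 3] * v[, 1] - u[, 1] * v[, 3]
  cz <- u[, 1] * v[, 2] - u[, 2] * v[, 1]
  sum(0.5 * sqrt(cx^2 + cy^2 + cz^2))
}

#' Intersect single-output solution sets
#'
#' Joint-tolerance membership over several property fields on one grid,
#' with a geometric summary of the multi-output set. The multi-output
#' solution set is the intersection of the single-output sets; its expected
#' dimensionality is the number of free axes minus the number of targeted
#' properties.
#'
#' @inheritParams extract_solution_set
#' @return A \code{solution_set} whose \code{geometry} classifies the
#'   intersection as empty / point-like / curve-like / surface-like.
#' @export
intersect_solution_sets <- function(grid, targets,
                                    tolerances = default_tolerances(names(targets))) {
  extract_solution_set(grid, targets, tolerances)
}

#' Pairwise ion-channel correlations of a solution set
#'
#' Centers each conductance on its mean, normalizes by its standard
#' deviation (z-scores) and reports the pairwise Pearson correlation matrix
#' and the z-scored regression slopes (equal to the correlations).
#' Zero-variance conductances are flagged and excluded.
#'
#' @param solutions a \code{solution_set}, or a numeric matrix with one
#'   conductance per column.
#' @param conductances optional subset of columns to analyse.
#' @return A \code{correlation_report}: list with \code{R} (correlation
#'   matrix), \code{slopes}, \code{n}, \code{zscores}, \code{excluded}.
#' @export
zscore_correlations <- function(solutions, conductances = NULL) {
  m <- if (inherits(solutions, "solution_set")) solutions$coords else as.matrix(solutions)
  if (!is.null(conductances)) m <- m[, conductances, drop = FALSE]
  if (nrow(m) < 3) stop("at least 3 members are required")
  sds <- apply(m, 2, sd)
  excluded <- colnames(m)[sds == 0 | is.na(sds)]
  keep <- setdiff(colnames(m), excluded)
  m <- m[, keep, drop = FALSE]
  z <- scale(m)
  R <- cor(m)
  structure(list(R = R, slopes = R, n = nrow(m), zscores = z,
                 excluded = excluded),
            class = "correlation_report")
}

#' @export
print.correlation_report <- function(x, ...) {
  cat(sprintf("correlation_report: n = %d\n", x$n))
  print(round(x$R, 3))
  if (length(x$excluded))
    cat("  excluded (zero variance):", paste(x$excluded, collapse = ", "), "\n")
  invisible(x)
}

#' Mean absolute off-diagonal correlation
#'
#' Summary statistic used to compare correlation strength across solution
#' populations of different dimensionality.
#'
#' @param report a \code{correlation_report} (or correlation matrix).
#' @return Mean of |R| over distinct pairs.
#' @export
mean_abs_correlation <- function(report) {
  R <- if (inherits(report, "correlation_report")) report$R else report
  mean(abs(R[upper.tri(R)]))
}

## ---- planar geometry helpers (used by the leak scan) ----

## Intersection points of two polyline sets (lists of 2-column matrices).
intersect_polylines <- function(A, B) {
  pts <- NULL
  for (a in A) for (b in B) {
    if (nrow(a) < 2 || nrow(b) < 2) next
    for (i in seq_len(nrow(a) - 1)) {
      p <- a[i, ]; r <- a[i + 1, ] - p
      js <- seq_len(nrow(b) - 1)
      q1 <- b[js, , drop = FALSE]; q2 <- b[js + 1, , drop = FALSE]
      s1 <- q2 - q1
      denom <- r[1] * s1[, 2] - r[2] * s1[, 1]
      qp1 <- q1[, 1] - p[1]; qp2 <- q1[, 2] - p[2]
      tt <- (qp1 * s1[, 2] - qp2 * s1[, 1]) / denom
      uu <- (qp1 * r[2] - qp2 * r[1]) / denom
      hit <- is.finite(tt) & is.finite(uu) & tt >= 0 & tt <= 1 & uu >= 0 & uu <= 1
      if (any(hit))
        pts <- rbind(pts, cbind(p[1] + tt[hit] * r[1], p[2] + tt[hit] * r[2]))
    }
  }
  if (is.null(pts)) matrix(numeric(0), 0, 2) else pts
}

## Minimal enclosing circle radius of <= 3 points.
min_enclosing_radius <- function(pts) {
  n <- nrow(pts)
  if (n <= 1) return(0)
  if (n == 2) return(0.5 * sqrt(sum((pts[1, ] - pts[2, ])^2)))
  d <- as.matrix(dist(pts))
  sides <- sort(c(d[1, 2], d[1, 3], d[2, 3]), decreasing = TRUE)
  if (sides[1]^2 >= sides[2]^2 + sides[3]^2) return(sides[1] / 2)
  area <- abs((pts[2, 1] - pts[1, 1]) * (pts[3, 2] - pts[1, 2]) -
                (pts[3, 1] - pts[1, 1]) * (pts[2, 2] - pts[1, 2])) / 2
  prod(sides) / (4 * area)
}
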