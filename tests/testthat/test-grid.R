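# Analytic-field helper: wrap precomputed matrices in a property_grid so the
# extraction/geometry machinery can be tested against closed forms.
analytic_grid <- function(axes, fields) {
  structure(list(
    axes = axes,
    fields = fields,
    G = {
      pts <- as.matrix(expand.grid(axes, KEEP.OUT.ATTRS = FALSE))
      colnames(pts) <- names(axes)
      pts
    },
    background = conductance_set()),
    class = "property_grid")
}

test_that("solution-set extraction matches an exhaustive scan on f = x + y", {
  x <- seq(0, 1, length.out = 101)
  ax <- list(gNa = x, gK = x)
  f <- outer(x, x, `+`)
  g <- analytic_grid(ax, list(firing_rate = f))
  ss <- extract_solution_set(g, c(firing_rate = 1), c(firing_rate = 0.01))
  brute <- sum(abs(as.vector(f) - 1) <= 0.01)
  expect_equal(nrow(ss$members), brute)
  expect_gt(brute, 0)
  expect_equal(ss$geometry$class, "curve-like")
})

test_that("targets outside the field range give an empty set", {
  x <- seq(0, 1, length.out = 11)
  g <- analytic_grid(list(gNa = x, gK = x),
                     list(firing_rate = outer(x, x, `+`)))
  ss <- extract_solution_set(g, c(firing_rate = 10), c(firing_rate = 0.1))
  expect_equal(nrow(ss$members), 0)
  expect_equal(ss$geometry$class, "empty")
})

test_that("widening the tolerance never removes members", {
  x <- seq(0, 1, length.out = 51)
  g <- analytic_grid(list(gNa = x, gK = x),
                     list(firing_rate = outer(x, x, `+`)))
  tols <- c(0.01, 0.05, 0.2)
  counts <- vapply(tols, function(tol)
    nrow(extract_solution_set(g, c(firing_rate = 1),
                              c(firing_rate = tol))$members), integer(1))
  expect_true(all(diff(counts) >= 0))
  idx_small <- extract_solution_set(g, c(firing_rate = 1),
                                    c(firing_rate = 0.01))$indices
  idx_big <- extract_solution_set(g, c(firing_rate = 1),
                                  c(firing_rate = 0.2))$indices
  expect_true(all(idx_small %in% idx_big))
})

test_that("a 1 x 1 grid reduces to a single property evaluation", {
  spec <- grid_spec(list(gNa = c(2, 2, 1), gK = c(1, 1, 1)),
                    background = REF_BG, properties = "firing_rate",
                    protocol = fast_protocol())
  pg <- evaluate_grid(spec, PARAMS)
  direct <- measure_firing_rate(PARAMS,
                                channelreg:::as_g_matrix(
                                  c(gNa = 2, gK = 1), REF_BG),
                                fast_protocol())
  expect_equal(as.vector(pg$fields$firing_rate), as.numeric(direct))
})

test_that("grid evaluation is reproducible under the shared seed policy", {
  spec <- grid_spec(list(gNa = c(1, 3, 3), gK = c(0, 2, 3)),
                    background = REF_BG, properties = "firing_rate",
                    protocol = fast_protocol())
  a <- evaluate_grid(spec, PARAMS)
  b <- evaluate_grid(spec, PARAMS)
  expect_identical(a$fields, b$fields)
})

test_that("contours of a linear field lie on the analytic line", {
  x <- seq(0, 1, length.out = 41)
  f <- outer(x, x, function(a, b) 2 * a + 3 * b + 0.5)
  g <- analytic_grid(list(gNa = x, gK = x), list(firing_rate = f))
  lev <- 2.5137 # avoids exact node crossings, where contouring adds fuzz
  cs <- iso_manifold(g, "firing_rate", lev)
  expect_gt(length(cs), 0)
  for (s in cs) {
    resid <- 2 * s[, 1] + 3 * s[, 2] + 0.5 - lev
    expect_lt(max(abs(resid)), 1e-6)
  }
})

test_that("marching tetrahedra recover a sphere's area within 5%", {
  x <- seq(-1.2, 1.2, length.out = 30)
  f <- array(0, c(30, 30, 30))
  for (i in 1:30) for (j in 1:30)
    f[i, j, ] <- sqrt(x[i]^2 + x[j]^2 + x^2)
  g <- analytic_grid(list(gNa = x, gK = x, gM = x), list(firing_rate = f))
  surf <- iso_manifold(g, "firing_rate", 1)
  expect_gt(nrow(surf$triangles), 0)
  expect_equal(manifold_area(surf), 4 * pi, tolerance = 0.05)
  # every vertex lies on the unit sphere up to grid interpolation error
  rad <- sqrt(rowSums(surf$vertices^2))
  expect_lt(max(abs(rad - 1)), 0.01)
})

test_that("a field constant at the target is flagged degenerate", {
  x <- seq(0, 1, length.out = 5)
  g <- analytic_grid(list(gNa = x, gK = x),
                     list(firing_rate = matrix(1, 5, 5)))
  out <- iso_manifold(g, "firing_rate", 1)
  expect_true(isTRUE(attr(out, "degenerate")))
})

test_that("two linear fields intersect where the 2 x 2 solve says", {
  x <- seq(0, 1, length.out = 101)
  f1 <- outer(x, x, function(a, b) a + b)      # = 1.0
  f2 <- outer(x, x, function(a, b) a - b)      # = 0.2
  g <- analytic_grid(list(gNa = x, gK = x),
                     list(firing_rate = f1, energy_efficiency = f2))
  ss <- intersect_solution_sets(g, c(firing_rate = 1, energy_efficiency = 0.2),
                                c(firing_rate = 0.02, energy_efficiency = 0.02))
  expect_gt(nrow(ss$members), 0)
  sol <- solve(rbind(c(1, 1), c(1, -1)), c(1, 0.2)) # (0.6, 0.4)
  expect_equal(unname(colMeans(ss$coords)), sol, tolerance = 0.02)
  expect_equal(ss$geometry$class, "point-like")
})

test_that("three generic linear constraints in 2-D have no joint solution", {
  x <- seq(0, 1, length.out = 101)
  g <- analytic_grid(list(gNa = x, gK = x),
                     list(firing_rate = outer(x, x, `+`),
                          energy_efficiency = outer(x, x, `-`),
                          input_resistance = outer(x, x,
                                                   function(a, b) 2 * a + b)))
  ss <- intersect_solution_sets(
    g, c(firing_rate = 1, energy_efficiency = 0.2, input_resistance = 0.4),
    c(firing_rate = 0.01, energy_efficiency = 0.01, input_resistance = 0.01))
  expect_equal(nrow(ss$members), 0)
})

test_that("z-scored correlations behave on known point clouds", {
  th <- seq(0, 1, length.out = 50)
  col <- cbind(gNa = th, gK = 2 - 3 * th)     # exactly collinear
  r <- zscore_correlations(col)
  expect_equal(abs(r$R["gNa", "gK"]), 1)
  set.seed(8)
  iso <- matrix(rnorm(3000), ncol = 3,
                dimnames = list(NULL, c("gNa", "gK", "gM")))
  r2 <- zscore_correlations(iso)
  expect_lt(max(abs(r2$R[upper.tri(r2$R)])), 0.1)
  expect_equal(r2$R, t(r2$R))
  expect_equal(unname(diag(r2$R)), rep(1, 3))
  # zero-variance axes are excluded, not propagated
  flat <- cbind(iso[, 1:2], gM = 1)
  colnames(flat) <- c("gNa", "gK", "gM")
  r3 <- zscore_correlations(flat)
  expect_equal(r3$excluded, "gM")
  expect_error(zscore_correlations(iso[1:2, ]))
})

test_that("set members lie within one grid cell of the extracted manifold", {
  x <- seq(0, 1, length.out = 41)
  f <- outer(x, x, function(a, b) a + 2 * b)
  g <- analytic_grid(list(gNa = x, gK = x), list(firing_rate = f))
  tol <- 0.03
  ss <- extract_solution_set(g, c(firing_rate = 1), c(firing_rate = tol))
  cs <- iso_manifold(g, "firing_rate", 1)
  verts <- do.call(rbind, cs)
  h <- diff(x[1:2])
  for (i in seq_len(nrow(ss$coords))) {
    d <- sqrt((verts[, 1] - ss$coords[i, 1])^2 +
                (verts[, 2] - ss$coords[i, 2])^2)
    expect_lt(min(d), sqrt(2) * h + tol / 2)
  }
})
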