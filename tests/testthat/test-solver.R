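# Instantaneous Rayleigh solve: equilibria, identities, tension recovery.

test_that("the undriven flat disc is a stationary state", {
  cfg <- quick_config(vb = 0, p = 0)
  fl <- fixture_shape("flat", Rb = 1, N = 100)
  sol <- solve_rates(fl, cfg)
  expect_equal(max(abs(sol$rates$vu)), 0, tolerance = 1e-12)
  expect_equal(max(abs(sol$rates$vn)), 0, tolerance = 1e-12)
  expect_equal(sol$rates$ht, 0, tolerance = 1e-12)
  expect_equal(max(abs(sol$multipliers$sigma)), 0, tolerance = 1e-12)
})

test_that("a pressurized spherical cap is held by the Laplace tension", {
  cfg <- quick_config(vb = 0, p = -1, N = 150)
  hemi <- fixture_shape("spherical_cap", R = 1, angle = pi / 2, N = 150)
  sol <- solve_rates(hemi, cfg)
  # incompressibility forbids deflation; sigma = p R / 2 balances the load
  expect_equal(sol$multipliers$sigma[75], -0.5, tolerance = 1e-3)
  expect_lt(max(abs(sol$rates$vn)), 0.01)
})

test_that("solved rates satisfy the boundary-influx area identity", {
  for (case in list(list(shape = make_initial_shape(1, 0.05, 200),
                         vb = -1, p = 0),
                    list(shape = fixture_shape("spherical_cap", R = 0.8,
                                               angle = 2.2, N = 200),
                         vb = -0.5, p = -1))) {
    cfg <- quick_config(vb = case$vb, p = case$p, N = 200)
    sol <- solve_rates(case$shape, cfg)
    g <- case$shape$grid
    dAdt <- 2 * pi * (case$shape$h * grid_integral(g, sol$rates$rt) +
                        sol$rates$ht * grid_integral(g, case$shape$r))
    expect_equal(dAdt, -2 * pi * case$shape$Rb * case$vb,
                 tolerance = 5e-3)
    # dissipation is positive and the solve is numerically stationary
    expect_gt(sol$energy$D, 0)
    expect_lt(sol$energy$stat_residual, cfg$tol_stat)
    # boundary condition
    expect_equal(sol$rates$vu[200], case$vb, tolerance = 1e-12)
    expect_equal(sol$rates$vu[1], 0, tolerance = 1e-12)
  }
})

test_that("incompressibility holds pointwise in the solver discretization", {
  cfg <- quick_config(vb = -1, p = -1, N = 150)
  shp <- fixture_shape("spherical_cap", R = 0.8, angle = 2.2, N = 150)
  sol <- solve_rates(shp, cfg)
  g <- shp$grid
  psip <- memflow:::grid_deriv(g, shp$psi)
  d1b <- (as.numeric(g$D1b %*% sol$rates$vu) + sol$rates$vn * psip) / shp$h
  d2 <- c(d1b[1], (cos(shp$psi[-1]) * sol$rates$vu[-1] +
                     sin(shp$psi[-1]) * sol$rates$vn[-1]) / shp$r[-1])
  expect_lt(max(abs(d1b + d2)), cfg$tol_inc * max(1, max(abs(d1b))))
})

test_that("compression develops near the base under strong boundary flow", {
  cfg <- quick_config(vb = -1, p = 0, N = 200)
  b <- make_initial_shape(1, 0.05, 200)
  sol <- solve_rates(b, cfg)
  expect_lt(sol$multipliers$sigma[200], 0)    # compressive at the base
})

test_that("gauge consistency: coordinate rates reconstruct from the flow", {
  cfg <- quick_config(vb = -0.5, p = -0.5, N = 150)
  shp <- fixture_shape("spherical_cap", R = 0.8, angle = 2.2, N = 150)
  sol <- solve_rates(shp, cfg)
  r <- sol$rates
  q <- gauge_velocity(shp, r)
  # Eqs for the coordinate rates in terms of (vu, vn, q)
  rt2 <- (r$vu - q) * cos(shp$psi) + r$vn * sin(shp$psi)
  zt2 <- (q - r$vu) * sin(shp$psi) + r$vn * cos(shp$psi)
  expect_equal(r$rt, rt2, tolerance = 1e-10)
  expect_equal(r$zt, zt2, tolerance = 1e-10)
  # h is a scalar: the gauge ODE ties gt' to ht pointwise
  gt <- r$vu - q
  g <- shp$grid
  res <- as.numeric(g$D1b %*% gt) +
    r$vn * memflow:::grid_deriv(g, shp$psi) - r$ht
  expect_lt(max(abs(res[2:(149)])), 1e-6 * max(1, abs(r$ht)))
})

test_that("the two solver routes agree on coarse smooth shapes", {
  # well-curved coarse shapes (the nearly flat limit is a physically
  # singular regime where both routes depend on the axis regularization)
  N <- 320
  cases <- list(
    list(shape = fixture_shape("spherical_cap", R = 1, angle = pi / 2, N = N),
         vb = -1, p = 0),
    list(shape = fixture_shape("spherical_cap", R = 0.8, angle = 2.2, N = N),
         vb = -0.5, p = -1),
    list(shape = fixture_shape("spherical_cap", R = 1.2, angle = 1.5, N = N),
         vb = -0.3, p = -2))
  for (case in cases) {
    cfg <- quick_config(vb = case$vb, p = case$p, N = N, gamma = 0.1)
    sa <- solve_rates(case$shape, cfg, method = "euler_lagrange")
    sb <- solve_rates(case$shape, cfg, method = "variational")
    win <- which(case$shape$grid$u >= 0.1 & case$shape$grid$u <= 0.9)
    relmax <- function(a, b) max(abs(a[win] - b[win])) / max(abs(b[win]))
    expect_lt(abs(sa$rates$ht - sb$rates$ht) / abs(sb$rates$ht), 0.01)
    expect_lt(relmax(sa$rates$vu, sb$rates$vu), 0.01)
    expect_lt(relmax(sa$rates$vn, sb$rates$vn), 0.01)
    expect_lt(relmax(sa$multipliers$sigma, sb$multipliers$sigma), 0.01)
  }
})
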