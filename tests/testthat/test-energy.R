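# Energies: bending, dissipation, pressure power; the three forms of the
# bending power agree with realized energy differences.

test_that("bending energy matches Helfrich closed forms", {
  hemi <- fixture_shape("spherical_cap", R = 1, angle = pi / 2, N = 200)
  expect_equal(bending_energy(hemi, kappa = 2), 2 * 4 * pi, tolerance = 1e-8)
  # near-complete sphere approaches 8 pi kappa
  sph <- fixture_shape("spherical_cap", R = 1, angle = pi - 0.05, N = 400)
  expect_equal(bending_energy(sph, 1), 8 * pi, tolerance = 0.05)
  # cylinder part contributes pi kappa L / R (cap adds 4 pi kappa)
  cc <- fixture_shape("capped_cylinder", R = 0.4, L = 2, N = 401)
  expect_equal(bending_energy(cc, 1.3), 1.3 * (4 * pi + pi * 2 / 0.4),
               tolerance = 2e-3 * 1.3 * (4 * pi + pi * 2 / 0.4))
  expect_equal(bending_energy(fixture_shape("flat", Rb = 1), 1), 0)
})

test_that("dissipation matches the inflating-sphere closed form", {
  hemi <- fixture_shape("spherical_cap", R = 1, angle = pi / 2, N = 200)
  cc <- 0.25
  infl <- rate_field(hemi, vu = rep(0, 200), rt = cc * sin(hemi$psi),
                     zt = cc * cos(hemi$psi), psit = rep(0, 200),
                     ht = cc * hemi$h)
  # full sphere: 8 pi eta c^2; hemisphere is half
  expect_equal(dissipation(hemi, infl, eta = 1.5), 1.5 * 4 * pi * cc^2,
               tolerance = 1e-8)
  zero <- rate_field(hemi, rep(0, 200), rep(0, 200), rep(0, 200),
                     rep(0, 200), 0)
  expect_equal(dissipation(hemi, zero, 1), 0)
  # friction term adds (gamma/2) int vn^2 dA
  expect_equal(dissipation(hemi, infl, eta = 0, gamma = 2),
               cc^2 * 2 * pi, tolerance = 1e-8)
})

test_that("pressure power is p times the swept-volume rate", {
  hemi <- fixture_shape("spherical_cap", R = 1, angle = pi / 2, N = 200)
  cc <- 0.25
  infl <- rate_field(hemi, vu = rep(0, 200), rt = cc * sin(hemi$psi),
                     zt = cc * cos(hemi$psi), psit = rep(0, 200),
                     ht = cc * hemi$h)
  expect_equal(pressure_power(hemi, infl, p = -0.7), -0.7 * 2 * pi * cc,
               tolerance = 1e-8)
  zero <- rate_field(hemi, rep(0, 200), rep(0, 200), rep(0, 200),
                     rep(0, 200), 0)
  expect_equal(pressure_power(hemi, zero, -1), 0)
})

test_that("parameterization, geometric and realized bending powers agree", {
  for (mk in list(
    function() make_initial_shape(1, 0.05, 200),
    function() fixture_shape("spherical_cap", R = 0.8, angle = 2.2, N = 200))) {
    shp <- mk()
    g <- shp$grid
    vn <- 0.3 * cos(pi * g$u / 2)^2
    vn <- vn - vn[g$N]
    rates <- consistent_rates(shp, vn)
    dtt <- 1e-6
    sp <- apply_rates(shp, rates, dtt, tol_geom = 1)
    realized <- (bending_energy(sp, 1) - bending_energy(shp, 1)) / dtt
    param <- bending_power(shp, rates, 1)
    ctx <- memflow:::solver_context(shp)
    fel <- memflow:::helfrich_force(ctx, 1)
    geo <- 2 * pi * shp$h *
      memflow:::grid_integral(g, fel * vn * ctx$r)
    expect_equal(param, geo, tolerance = 2e-3)
    expect_equal(realized, param, tolerance = 2e-3)
  }
  # a spherical cap is a stationary point of the bending energy: all three
  # forms vanish for arbitrary normal motion with the boundary ring fixed
  cap <- fixture_shape("spherical_cap", R = 0.8, angle = 2.2, N = 200)
  vn <- 0.2 * sin(pi * cap$grid$u)^2
  expect_lt(abs(bending_power(cap, consistent_rates(cap, vn), 1)), 1e-4)
})
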