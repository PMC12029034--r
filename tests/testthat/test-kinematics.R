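# Kinematics: gauge velocity, strain rates, shape updates.

test_that("gauge velocity recovers the Lagrangian and Eulerian limits", {
  s <- fixture_shape("spherical_cap", R = 1, angle = 2, N = 100)
  vu <- sin(pi * s$grid$u) * 0.3
  # Lagrangian: coordinates follow the material -> q = 0
  lag <- rate_field(s, vu, rt = vu * cos(s$psi), zt = -vu * sin(s$psi),
                    psit = rep(0, 100), ht = 0)
  expect_equal(max(abs(gauge_velocity(s, lag))), 0, tolerance = 1e-14)
  # static grid -> q = vu
  eul <- rate_field(s, vu, rt = rep(0, 100), zt = rep(0, 100),
                    psit = rep(0, 100), ht = 0)
  expect_equal(gauge_velocity(s, eul), vu, tolerance = 1e-14)
})

test_that("strain rates are exact on inflating spheres and rigid motions", {
  hemi <- fixture_shape("spherical_cap", R = 1, angle = pi / 2, N = 200)
  cc <- 0.3
  infl <- rate_field(hemi, vu = rep(0, 200), rt = cc * sin(hemi$psi),
                     zt = cc * cos(hemi$psi), psit = rep(0, 200),
                     ht = cc * hemi$h)
  sr <- strain_rates(hemi, infl)
  expect_equal(sr$d1, rep(cc, 200), tolerance = 1e-10)
  expect_equal(sr$d2, rep(cc, 200), tolerance = 1e-10)
  # dA/dt = 8 pi R c for the full sphere; hemisphere gives half
  expect_equal(area_rate(hemi, sr), 4 * pi * cc, tolerance = 1e-8)

  # rigid axial translation of a smooth cap: no strain
  cap <- fixture_shape("spherical_cap", R = 0.8, angle = 2.2, N = 200)
  V <- 0.7
  rig <- rate_field(cap, vu = -V * sin(cap$psi), rt = rep(0, 200),
                    zt = rep(V, 200), psit = rep(0, 200), ht = 0)
  srr <- strain_rates(cap, rig)
  expect_lt(max(abs(srr$d1)), 1e-8)
  expect_lt(max(abs(srr$d2)), 1e-8)
})

test_that("flat-disc radial flow has uniform strain", {
  fl <- fixture_shape("flat", Rb = 1, N = 200)
  k <- 0.5
  rates <- rate_field(fl, vu = k * fl$grid$u, rt = k * fl$grid$u,
                      zt = rep(0, 200), psit = rep(0, 200), ht = k)
  sr <- strain_rates(fl, rates)
  expect_equal(sr$d1, rep(k, 200), tolerance = 1e-10)
  expect_equal(sr$d2, rep(k, 200), tolerance = 1e-10)
})

test_that("apply_rates advances a uniformly inflating hemisphere exactly", {
  hemi <- fixture_shape("spherical_cap", R = 1, angle = pi / 2, N = 200)
  cc <- 0.3; dt <- 1e-3
  infl <- rate_field(hemi, vu = rep(0, 200), rt = cc * sin(hemi$psi),
                     zt = cc * cos(hemi$psi), psit = rep(0, 200),
                     ht = cc * hemi$h)
  s2 <- apply_rates(hemi, infl, dt)
  cv <- curvatures(s2)
  expect_equal(1 / cv$c2, rep(1 + cc * dt, 200), tolerance = 1e-10)
  expect_equal(s2$h, hemi$h * (1 + cc * dt), tolerance = 1e-12)
  # zero rates leave the shape unchanged
  zero <- rate_field(hemi, rep(0, 200), rep(0, 200), rep(0, 200),
                     rep(0, 200), 0)
  s3 <- apply_rates(hemi, zero, dt)
  expect_equal(s3$psi, hemi$psi)
  expect_equal(s3$h, hemi$h)
})
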