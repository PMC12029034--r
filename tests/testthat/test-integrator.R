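# Time integration: invariance, conservation, convergence, determinism.

test_that("the undriven flat disc does not move over many steps", {
  cfg <- quick_config(vb = 0, p = 0, N = 100, t_end = 0.5, dt0 = 0.05,
                      dt_max = 0.05, eps = 0)
  traj <- run_simulation(cfg)
  expect_identical(traj$termination, "t_end")
  ob <- traj$observables
  expect_equal(max(abs(ob$H)), 0, tolerance = 1e-10)
  expect_equal(ob$area[nrow(ob)], pi, tolerance = 1e-10)
})

test_that("one step grows the area by the boundary influx", {
  cfg <- quick_config(vb = -1, p = 0, N = 100, eps = 0.1)
  cfg$Rb_nd <- 1
  shape <- make_initial_shape(1, 0.1, 100)
  state <- list(shape = shape, t = 0, dt = 0.002, solution = NULL,
                area_target = surface_area(shape))
  state <- step_simulation(state, cfg)
  dA <- surface_area(state$shape) - surface_area(shape)
  expect_equal(dA, 2 * pi * state$t, tolerance = 1e-6)
})

test_that("area balance holds to much better than 0.5% over a run", {
  traj <- cached_run("run_vb1_short",
                     run_simulation(quick_config(vb = -1, p = 0, N = 100,
                                                 t_end = 4, eps = 0.1)))
  ob <- traj$observables
  drift <- (ob$area - ob$area[1]) - 2 * pi * ob$t
  expect_lt(max(abs(drift)) / max(2 * pi * ob$t), 5e-3)
  # monotone growth for vb < 0
  expect_true(all(diff(ob$area) > -1e-12))
})

test_that("height converges under time-step refinement", {
  H_end <- function(dtm) {
    traj <- run_simulation(quick_config(vb = -1, p = 0, N = 100, t_end = 2,
                                        dt_max = dtm, eps = 0.1))
    ob <- traj$observables
    ob$H[nrow(ob)]
  }
  h1 <- H_end(0.03)
  h2 <- H_end(0.015)
  expect_lt(abs(h1 - h2) / abs(h2), 0.01)
})

test_that("height converges under grid refinement", {
  H_end <- function(N) {
    traj <- run_simulation(quick_config(vb = -1, p = 0, N = N, t_end = 2,
                                        eps = 0.1))
    ob <- traj$observables
    ob$H[nrow(ob)]
  }
  expect_lt(abs(H_end(100) - H_end(150)) / abs(H_end(150)), 0.01)
})

test_that("identical configurations reproduce identical trajectories", {
  cfg <- quick_config(vb = -1, p = -1, N = 100, t_end = 1, eps = 0.05)
  t1 <- run_simulation(cfg)
  t2 <- run_simulation(cfg)
  expect_identical(t1$observables, t2$observables)
})

test_that("trajectories record snapshots and tabulate with the pipe", {
  traj <- cached_run("run_vb1_short",
                     run_simulation(quick_config(vb = -1, p = 0, N = 100,
                                                 t_end = 4, eps = 0.1)))
  expect_s3_class(as_tibble(traj), "tbl_df")
  expect_gte(length(traj$snapshots), 4)
  ts <- vapply(traj$snapshots, `[[`, numeric(1), "t")
  expect_true(all(diff(ts) > 0))
  # every stored shape passes geometry validation
  for (sn in traj$snapshots) {
    expect_lt(closure_residual(sn$shape, interior = TRUE),
              1e-4 * sn$shape$h)
  }
  gl <- glance(traj)
  expect_equal(gl$vb, -1)
  expect_s3_class(gl, "tbl_df")
})
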