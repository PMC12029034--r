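# Time integration: march the solve -> update loop with adaptive step size,
# linearly-implicit bending stabilization, and trajectory recording.

#' Advance the simulation state by one adaptive step
#'
#' One cycle of the instantaneous Rayleigh solve followed by an explicit
#' update of `(psi, h)` and exact reconstruction of `(r, z)` (see
#' [apply_rates()]).  The solve carries the linearly-implicit
#' Gauss-Newton bending stabilization (weight three times the current step),
#' which suppresses the stiff high-wavenumber bending modes; the
#' tangent-angle rate is low-pass filtered before the update and the step is
#' capped so no node turns by more than 0.05 rad.  On failure
#' (solver breakdown, loss of positivity, closure violation) the step is
#' halved and retried up to 8 times; after successes the step grows back
#' toward `dt_max`.
#'
#' @param state list with elements `shape`, `t`, `dt` (and optionally the
#'   last `solution`)
#' @param config a `memflow_config`
#' @return the advanced state; `state$solution` holds the accepted solve
#' @export
step_simulation <- function(state, config) {
  dt <- state$dt
  for (try in 1:9) {
    ok <- tryCatch({
      sol <- solve_rates(state$shape, config, method = "variational",
                         dt_stab = 3 * dt)
      # low-pass the tangent-angle rate before it is written into the shape:
      # grid-scale content is below the scheme's resolution and would
      # otherwise accumulate in psi over thousands of steps
      g <- state$shape$grid
      psit_f <- grid_filter(g, sol$rates$psit, frac = 0.5)
      psit_f[c(1, g$N)] <- 0
      rates_f <- rate_field(state$shape, sol$rates$vu, sol$rates$rt,
                            sol$rates$zt, psit_f, sol$rates$ht)
      # proactive cap: limit the per-step tangent-angle change
      dt_use <- min(dt, 0.05 / max(abs(psit_f), 1e-12))
      sol$rates <- rates_f
      shp <- apply_rates(state$shape, rates_f, dt_use,
                         tol_geom = config$tol_geom)
      dt <- dt_use
      # project the shape back onto the exact constraint manifold: base
      # radius r(1) = Rb and the area-balance identity
      # A(t) = A(0) + 2 pi Rb |vb| t (the O(dt^2) update drift is removed by
      # a Newton nudge of psi along a fixed smooth direction)
      area_target <- state$area_target + 2 * pi * config$Rb_nd *
        abs(config$vb) * dt
      shp <- project_shape(shp, config, area_target)
      list(sol = sol, shp = shp, area_target = area_target)
    }, error = function(e) e)
    if (!inherits(ok, "error")) {
      state$shape <- ok$shp
      state$solution <- ok$sol
      state$area_target <- ok$area_target
      state$t <- state$t + dt
      state$dt <- min(config$dt_max, dt * 1.2)
      return(state)
    }
    if (try == 9) {
      stop("time step failed after 8 halvings: ", conditionMessage(ok))
    }
    dt <- dt / 2
  }
}

#' Run a membrane tubulation simulation
#'
#' Starts from the nearly flat initial shape of [make_initial_shape()] and
#' integrates the boundary-flow-driven dynamics up to `t_end` (in units of
#' tau), or until self-contact of the neck (innermost radius below
#' `r_contact * Rb`) or an unrecoverable solver failure.  Scalar observables
#' are recorded at every accepted step; full shape/flow snapshots every
#' `snapshot_every` time units.
#'
#' @param config a `memflow_config`
#' @return object of class `membrane_trajectory`: list with `observables`
#'   (tibble: `t, H, Wn, W, sigma_tip, sigma_base, area, h, dt`), `snapshots`
#'   (list of per-time lists with `t`, `shape`, `rates`, `sigma`), `config`,
#'   and `termination` (one of `"t_end"`, `"contact"`, `"stalled"`,
#'   `"solver_failure"`)
#' @examples
#' \donttest{
#' traj <- run_simulation(simulation_config(vb = -1, p = 0, N = 80,
#'                                          t_end = 2, dt0 = 0.01))
#' tail(traj$observables)
#' }
#' @export
run_simulation <- function(config) {
  config$Rb_nd <- 1    # simulation units
  shape <- make_initial_shape(Rb = 1, eps = config$eps, N = config$N)
  state <- list(shape = shape, t = 0, dt = config$dt0, solution = NULL,
                area_target = surface_area(shape))
  obs <- vector("list", 0)
  snaps <- vector("list", 0)
  next_snap <- 0
  termination <- "t_end"

  record_obs <- function(state) {
    sigma <- if (is.null(state$solution)) NULL else
      state$solution$multipliers$sigma
    m <- measure(state$shape, sigma = sigma, t = state$t)
    m$dt <- state$dt
    m
  }
  record_snap <- function(state) {
    list(t = state$t, shape = state$shape,
         rates = if (is.null(state$solution)) NULL else state$solution$rates,
         sigma = if (is.null(state$solution)) NULL else
           state$solution$multipliers$sigma)
  }

  obs[[length(obs) + 1L]] <- record_obs(state)
  snaps[[length(snaps) + 1L]] <- record_snap(state)
  next_snap <- config$snapshot_every

  while (state$t < config$t_end - 1e-12) {
    state$dt <- min(state$dt, config$t_end - state$t)
    state <- tryCatch(step_simulation(state, config), error = function(e) e)
    if (inherits(state, "error")) {
      termination <- "solver_failure"
      warning("simulation aborted: ", conditionMessage(state))
      break
    }
    if (state$dt < 1e-6) {
      termination <- "stalled"
      warning("simulation stalled (time step collapsed) at t = ", state$t)
      break
    }
    # keep the arclength spacing h/(N-1) below the resolution target by
    # regridding the tangent-angle profile onto a finer grid as the membrane
    # lengthens (the neck pinches numerically once under-resolved)
    if (state$shape$h / (state$shape$grid$N - 1) > config$regrid_res &&
        state$shape$grid$N < config$N_max) {
      state$shape <- regrid_shape(state$shape,
                                  min(config$N_max,
                                      as.integer(ceiling(
                                        state$shape$h / (0.85 * config$regrid_res)) + 1L)),
                                  config)
      # restore the exact area balance perturbed by the interpolation
      state$shape <- project_shape(state$shape, config, state$area_target)
      state$solution <- NULL
    }
    obs[[length(obs) + 1L]] <- record_obs(state)
    if (state$t >= next_snap - 1e-9) {
      snaps[[length(snaps) + 1L]] <- record_snap(state)
      next_snap <- next_snap + config$snapshot_every
    }
    # self-contact: neck radius below the contact threshold
    rmin <- neck_radius(state$shape$r)
    if (!is.na(rmin) && rmin < config$r_contact) {
      termination <- "contact"
      break
    }
  }
  if (termination != "solver_failure" &&
      (length(snaps) == 0 || snaps[[length(snaps)]]$t < state$t - 1e-9)) {
    snaps[[length(snaps) + 1L]] <- record_snap(state)
  }
  structure(
    list(observables = dplyr::bind_rows(obs), snapshots = snaps,
         config = config, termination = termination),
    class = "membrane_trajectory"
  )
}

#' @export
print.membrane_trajectory <- function(x, ...) {
  ob <- x$observables
  cat(sprintf(
    paste0("<membrane_trajectory> vb/v0=%g p/p0=%g N=%d  %d steps to t=%.3g",
           " tau (%s)\n  final: H=%.3f  W=%.3f  Wn=%s  area=%.3f\n"),
    x$config$vb, x$config$p, x$config$N, nrow(ob) - 1, max(ob$t),
    x$termination, ob$H[nrow(ob)], ob$W[nrow(ob)],
    ifelse(is.na(ob$Wn[nrow(ob)]), "none", sprintf("%.3f", ob$Wn[nrow(ob)])),
    ob$area[nrow(ob)]))
  invisible(x)
}

#' Tabulate trajectory observables
#'
#' @param x a `membrane_trajectory`
#' @param ... unused
#' @return the observables tibble
#' @method as_tibble membrane_trajectory
#' @export
as_tibble.membrane_trajectory <- function(x, ...) x$observables

# Project a shape onto the constraint manifold {r(1) = Rb, area = target}:
# rescale h to pin the base radius, then nudge psi along a fixed smooth
# direction (Newton on the nudge amplitude) to restore the exact area.
project_shape <- function(shp, config, area_target) {
  g <- shp$grid
  phi <- sin(pi * g$u)
  tol <- structure(config$tol_geom, interior = TRUE)
  build <- function(psi) {
    r1 <- grid_cumint0(g, cos(psi), 0)
    h <- config$Rb_nd / r1[g$N]
    r <- h * r1
    z <- grid_cumint1(g, -h * sin(psi), 0)
    membrane_shape(g, r, z, psi, h, Rb = config$Rb_nd, tol_geom = tol)
  }
  cur <- build(shp$psi)
  alpha <- 0
  for (it in 1:3) {
    err <- surface_area(cur) - area_target
    if (abs(err) < 1e-10 * area_target) break
    dalpha <- 1e-6
    ap <- surface_area(build(shp$psi + (alpha + dalpha) * phi))
    dA <- (ap - surface_area(cur)) / dalpha
    if (!is.finite(dA) || abs(dA) < 1e-12) break
    alpha <- alpha - err / dA
    cur <- build(shp$psi + alpha * phi)
  }
  cur
}


# Interpolate the tangent-angle profile onto a finer grid and rebuild the
# shape exactly (closure by construction; base radius re-pinned).
regrid_shape <- function(shape, N_new, config) {
  g2 <- grid_cached(N_new)
  build <- function(psi2) {
    psi2[1] <- 0
    if (config$base_bc == "clamped") psi2[N_new] <- 0
    r1 <- grid_cumint0(g2, cos(psi2), 0)
    h2 <- config$Rb_nd / r1[N_new]
    r2 <- h2 * r1
    if (any(r2[-1] <= 0)) return(NULL)
    z2 <- grid_cumint1(g2, -h2 * sin(psi2), 0)
    membrane_shape(g2, r2, z2, psi2, h2, Rb = config$Rb_nd,
                   tol_geom = structure(config$tol_geom, interior = TRUE))
  }
  out <- build(stats::spline(shape$grid$u, shape$psi, xout = g2$u,
                             method = "natural")$y)
  if (is.null(out)) {
    # spline overshoot near the axis; fall back to overshoot-free linear
    # interpolation for this regrid
    out <- build(stats::approx(shape$grid$u, shape$psi, xout = g2$u)$y)
  }
  if (is.null(out)) stop("regridding failed: radial profile nonpositive")
  out
}
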