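#' Instantaneous kinematic rates on a membrane shape
#'
#' Bundles the surface flow and coordinate rates at one instant: the in-plane
#' meridional lipid velocity `vu`, the normal velocity `vn` (derived,
#' `vn = sin(psi) rt + cos(psi) zt`), the coordinate rates `rt = dr/dt`,
#' `zt = dz/dt`, `psit = dpsi/dt` on the fixed `u`-grid, and the contour-length
#' rate `ht = dh/dt` (a scalar, by the uniform-metric gauge).  The azimuthal
#' flow is identically zero under axisymmetry with no imposed azimuthal
#' boundary flow, and is not stored.
#'
#' @param shape the `membrane_shape` the rates live on
#' @param vu,rt,zt,psit numeric nodal vectors
#' @param ht scalar contour-length rate
#' @return object of class `rate_field`
#' @export
rate_field <- function(shape, vu, rt, zt, psit, ht) {
  N <- shape$grid$N
  stopifnot(length(vu) == N, length(rt) == N, length(zt) == N,
            length(psit) == N, length(ht) == 1)
  vn <- sin(shape$psi) * rt + cos(shape$psi) * zt
  structure(
    list(vu = as.numeric(vu), vn = vn, rt = as.numeric(rt),
         zt = as.numeric(zt), psit = as.numeric(psit), ht = as.numeric(ht)),
    class = "rate_field"
  )
}

#' Gauge velocity of the parameterization
#'
#' The freedom in how material points map onto the fixed parameter `u` is the
#' gauge velocity `q`; `q = 0` is the Lagrangian and `q = vu` the Eulerian
#' representation.  With `(vu, rt, zt)` as independent variables it is
#' evaluated nodewise as `q = vu - cos(psi) rt + sin(psi) zt`.
#'
#' @param shape a `membrane_shape`
#' @param rates a `rate_field` on the same grid
#' @return numeric vector `q(u)`
#' @export
gauge_velocity <- function(shape, rates) {
  rates$vu - cos(shape$psi) * rates$rt + sin(shape$psi) * rates$zt
}

#' Principal strain rates of the surface flow
#'
#' For the physical flow `(vu, vn)` on the axisymmetric surface the meridional
#' and circumferential principal rates of strain are
#' `d1 = (vu' + vn psi')/h` and `d2 = (vu cos psi + vn sin psi)/r`,
#' with the tip value of `d2` given by its regular limit `d2(0) = d1(0)`.
#' Their sum is the relative rate of change of the local area element; the
#' incompressibility multiplier drives it to zero at the solution.  Strain
#' rates are gauge-independent: they depend on `(vu, vn)` only.
#'
#' @param shape a `membrane_shape`
#' @param rates a `rate_field`
#' @return list with numeric vectors `d1`, `d2`
#' @export
strain_rates <- function(shape, rates) {
  g <- shape$grid
  d1 <- (grid_deriv(g, rates$vu) + rates$vn * grid_deriv(g, shape$psi)) /
    shape$h
  d2 <- c(d1[1],
          (cos(shape$psi[-1]) * rates$vu[-1] +
             sin(shape$psi[-1]) * rates$vn[-1]) / shape$r[-1])
  list(d1 = d1, d2 = d2)
}

#' Total area change rate
#'
#' `dA/dt = \int (d1 + d2) dA` over the surface.  For an incompressible
#' solution field this reduces to the boundary influx `-2 pi Rb vb`.
#'
#' @param shape a `membrane_shape`
#' @param sr strain rates from [strain_rates()]
#' @return scalar `dA/dt`
#' @export
area_rate <- function(shape, sr) {
  2 * pi * shape$h *
    grid_integral(shape$grid, (sr$d1 + sr$d2) * shape$r)
}

#' Advance a shape by one explicit step of the solved rates
#'
#' First-order update of the primary geometric variables `(psi, h)` followed
#' by exact reconstruction of `(r, z)` from the closure relations
#' (`r` integrates `h cos psi` from the tip, `z` integrates `-h sin psi`
#' anchored at the base), so the updated shape closes to machine precision.
#' The base radius of the returned shape is `r(1)` as produced by the rates;
#' the caller (the time integrator) renormalizes the O(dt^2) drift of `r(1)`
#' back to `Rb`.
#'
#' @param shape a `membrane_shape`
#' @param rates a `rate_field` (from the stationarity solve, or analytic)
#' @param dt positive time step
#' @param tol_geom closure tolerance passed to the constructed shape
#' @return the advanced `membrane_shape`
#' @export
apply_rates <- function(shape, rates, dt, tol_geom = 1e-4) {
  stopifnot(dt > 0)
  g <- shape$grid
  psi <- shape$psi + dt * rates$psit
  h <- shape$h + dt * rates$ht
  if (h <= 0) stop("time step drove contour length h nonpositive")
  r <- grid_cumint0(g, h * cos(psi), 0)
  if (min(r) < -1e-12 * h || any(r[-1] <= 0)) {
    stop("time step drove the radial profile nonpositive")
  }
  z <- grid_cumint1(g, -h * sin(psi), 0)
  tol <- structure(tol_geom, interior = TRUE)
  membrane_shape(g, r, z, psi, h, Rb = r[g$N], tol_geom = tol)
}

#' @export
print.rate_field <- function(x, ...) {
  cat(sprintf("<rate_field> max|vu|=%.3g max|vn|=%.3g ht=%.3g\n",
              max(abs(x$vu)), max(abs(x$vn)), x$ht))
  invisible(x)
}
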