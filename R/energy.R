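#' Helfrich bending energy
#'
#' `F = (kappa/2) \int (c1 + c2)^2 dA` with zero spontaneous curvature and no
#' Gaussian-curvature term (the topology is fixed and the rigidity constant,
#' so the Gaussian term is an additive constant).
#'
#' @param shape a `membrane_shape`
#' @param kappa bending rigidity (energy units)
#' @return scalar bending energy
#' @examples
#' bending_energy(fixture_shape("spherical_cap", R = 1, angle = pi / 2), 1)
#' # hemisphere: 4*pi*kappa
#' @export
bending_energy <- function(shape, kappa = 1) {
  cv <- curvatures(shape)
  M <- cv$c1 + cv$c2
  (kappa / 2) * 2 * pi * shape$h *
    grid_integral(shape$grid, M^2 * shape$r)
}

#' Half dissipation rate of the surface flow
#'
#' `D = eta \int (d1^2 + d2^2) dA`, half the energy dissipation rate of the
#' 2D viscous lipid flow, plus an optional external normal-friction
#' contribution `(gamma/2) \int vn^2 dA` (default `gamma = 0`: the minimal
#' model dissipates only through in-plane membrane viscosity).
#'
#' @param shape a `membrane_shape`
#' @param rates a `rate_field`
#' @param eta surface viscosity
#' @param gamma external friction coefficient (default 0)
#' @return nonnegative scalar power
#' @export
dissipation <- function(shape, rates, eta = 1, gamma = 0) {
  sr <- strain_rates(shape, rates)
  w <- 2 * pi * shape$h * shape$r
  D <- eta * grid_integral(shape$grid, (sr$d1^2 + sr$d2^2) * w)
  if (gamma != 0) {
    D <- D + (gamma / 2) * grid_integral(shape$grid, rates$vn^2 * w)
  }
  D
}

#' Power exerted by the turgor pressure
#'
#' `dWext/dt = p \int vn dA`.  The pressure is signed with `p <= 0` for turgor
#' loading: the force per unit area is `p n` with `n` the outward normal (which
#' points along the invagination direction), so negative `p` opposes
#' invagination growth — the `-dWext/dt` term of the Rayleigh functional then
#' penalizes motion along `+n`.
#'
#' @param shape a `membrane_shape`
#' @param rates a `rate_field`
#' @param p pressure (force/length^2), `p <= 0` for turgor
#' @return scalar power
#' @export
pressure_power <- function(shape, rates, p) {
  p * 2 * pi * shape$h *
    grid_integral(shape$grid, rates$vn * shape$r)
}
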