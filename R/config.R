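#' Simulation configuration
#'
#' Collects the physical parameters, driving, grid and integrator settings of
#' a run.  Physical defaults are those relevant for a clathrin-coated pit:
#' bending rigidity `kappa = 4.1e3` pN nm, surface viscosity `eta = 0.1`
#' pN s/nm, base radius `Rb = 30` nm.  The driving — boundary flow `vb` and
#' turgor pressure `p` — is given in characteristic units (`vb` in units of
#' `v0 = kappa/(eta Rb)`, `p` in units of `p0 = kappa/Rb^3`) when
#' `units = "nondim"` (the default), or in nm/s and pN/nm^2 when
#' `units = "physical"`.  Both must be nonpositive: `vb < 0` pumps lipid into
#' the patch, `p < 0` is turgor pressing against the invagination.
#'
#' The simulation itself runs in nondimensional units (`kappa = eta = Rb = 1`);
#' times are in units of `tau = eta Rb^2 / kappa`.
#'
#' @param kappa bending rigidity (pN nm)
#' @param eta surface viscosity (pN s/nm)
#' @param Rb base radius (nm)
#' @param vb boundary flow velocity, `<= 0`
#' @param p turgor pressure, `<= 0`
#' @param gamma external normal-friction coefficient in units of
#'   `kappa/(Rb^2 v0)` (default 0.01, a weak normal drag from the
#'   surroundings that regularizes the nearly flat limit)
#' @param units `"nondim"` (vb in v0, p in p0) or `"physical"` (nm/s, pN/nm^2)
#' @param N grid nodes (>= 50)
#' @param dt0 initial time step, units of tau
#' @param dt_max largest allowed adaptive step, units of tau
#' @param t_end simulation horizon, units of tau
#' @param eps initial bump amplitude (fraction of Rb)
#' @param tol_geom closure tolerance during dynamics (relative to h)
#' @param tol_stat stationarity residual tolerance of the instantaneous solve
#' @param tol_inc pointwise incompressibility tolerance
#' @param snapshot_every interval between stored snapshots, units of tau
#' @param base_bc boundary condition on the tangent angle at the base:
#'   `"clamped"` (psi(1) = 0, membrane meets the flat plasma membrane
#'   tangentially; the default) or `"free_hinge"` (no bending moment)
#' @param r_contact self-contact termination threshold (fraction of Rb)
#' @param regrid_res arclength-resolution target: the grid is refined during
#'   the run so the node spacing `h/(N-1)` stays below this (units of Rb)
#' @param N_max upper bound on the adaptively refined grid size
#' @return object of class `memflow_config` (a named list)
#' @examples
#' cfg <- simulation_config(vb = -1, p = -1, N = 100, t_end = 5)
#' @export
simulation_config <- function(kappa = 4.1e3, eta = 0.1, Rb = 30,
                              vb = -1, p = 0, gamma = 0.01,
                              units = c("nondim", "physical"),
                              N = 200L, dt0 = 1e-3, dt_max = 3e-2,
                              t_end = 60, eps = 0.02,
                              tol_geom = 1e-4, tol_stat = 1e-6,
                              tol_inc = 1e-6,
                              snapshot_every = 1, base_bc = c("clamped", "free_hinge"),
                              r_contact = 0.02, regrid_res = 0.07,
                              N_max = 600L) {
  units <- match.arg(units)
  base_bc <- match.arg(base_bc)
  stopifnot(kappa > 0, eta > 0, Rb > 0, gamma >= 0, N >= 50,
            dt0 > 0, dt_max >= dt0, t_end >= 0, eps >= 0, eps <= 0.1,
            tol_geom > 0, tol_stat > 0, tol_inc > 0, snapshot_every > 0,
            r_contact > 0, r_contact < 1)
  if (t_end > 0 && dt0 >= t_end) stop("dt0 must be smaller than t_end")
  if (vb > 0) stop("vb must be nonpositive (influx convention: vb < 0 pumps lipid in)")
  if (p > 0) stop("p must be nonpositive (turgor convention)")
  us <- derive_units(kappa, eta, Rb, p = NULL)
  if (units == "physical") {
    vb_nd <- vb / us$v0
    p_nd <- p / us$p0
  } else {
    vb_nd <- vb
    p_nd <- p
  }
  structure(
    list(kappa = kappa, eta = eta, Rb = Rb,
         vb = vb_nd, p = p_nd, gamma = gamma, units = units,
         N = as.integer(N), dt0 = dt0, dt_max = dt_max, t_end = t_end,
         eps = eps, tol_geom = tol_geom, tol_stat = tol_stat,
         tol_inc = tol_inc, snapshot_every = snapshot_every,
         base_bc = base_bc, r_contact = r_contact,
         regrid_res = regrid_res, N_max = as.integer(N_max)),
    class = "memflow_config"
  )
}

#' @export
print.memflow_config <- function(x, ...) {
  cat(sprintf(
    paste0("<memflow_config> kappa=%g pN nm, eta=%g pN s/nm, Rb=%g nm\n",
           "  vb/v0=%g  p/p0=%g  gamma=%g  N=%d  dt0=%g  t_end=%g tau\n",
           "  eps=%g  base_bc=%s\n"),
    x$kappa, x$eta, x$Rb, x$vb, x$p, x$gamma, x$N, x$dt0, x$t_end,
    x$eps, x$base_bc))
  invisible(x)
}

#' Load a simulation configuration from a file
#'
#' Accepts YAML or JSON (by extension; `.json` is parsed with jsonlite,
#' anything else with yaml).  An empty file yields the full default
#' configuration.  Unknown keys are rejected with their paths; values are
#' validated by [simulation_config()].
#'
#' @param path file path
#' @return a `memflow_config`
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  vals <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  } else {
    yaml::yaml.load_file(path)
  }
  if (is.null(vals)) vals <- list()
  if (!is.list(vals)) stop("config must be a mapping of key: value pairs")
  # YAML 1.1 reads the bare key `N` as a boolean; map it back
  names(vals)[names(vals) == "FALSE"] <- "N"
  known <- names(formals(simulation_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) {
    stop("unknown config keys: ", paste0("$", bad, collapse = ", "))
  }
  do.call(simulation_config, vals)
}

#' Serialize a configuration
#'
#' Writes the configuration as YAML or JSON (chosen by extension) such that
#' [load_config()] round-trips it identically.  Driving values are written in
#' the units the configuration was created with.
#'
#' @param config a `memflow_config`
#' @param path output path (`.yaml`/`.yml` or `.json`)
#' @return `path`, invisibly
#' @export
save_config <- function(config, path) {
  vals <- unclass(config)
  if (config$units == "physical") {
    us <- derive_units(config$kappa, config$eta, config$Rb)
    vals$vb <- config$vb * us$v0
    vals$p <- config$p * us$p0
  }
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(vals, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(vals, path)
  }
  invisible(path)
}
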