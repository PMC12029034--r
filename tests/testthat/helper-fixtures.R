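# Shared helpers: small configs and shapes used across the suite.

quick_config <- function(...) {
  defaults <- list(vb = -1, p = 0, N = 100, t_end = 2, dt0 = 1e-3,
                   dt_max = 0.03, gamma = 0.01, eps = 0.02)
  args <- utils::modifyList(defaults, list(...))
  do.call(simulation_config, args)
}

# Gauge-consistent rate field from a normal-velocity profile: ht from the
# integral compatibility of the gauge ODE, gt by exact antidifferentiation.
consistent_rates <- function(shape, vn, vu = NULL) {
  g <- shape$grid
  psip <- memflow:::grid_deriv(g, shape$psi)
  ht <- memflow:::grid_integral(g, vn * psip)
  gt <- memflow:::grid_cumint0(g, ht - vn * psip, 0)
  psit <- (-memflow:::grid_deriv(g, vn) + gt * psip) / shape$h
  if (is.null(vu)) vu <- gt
  rate_field(shape, vu = vu,
             rt = gt * cos(shape$psi) + vn * sin(shape$psi),
             zt = -gt * sin(shape$psi) + vn * cos(shape$psi),
             psit = psit, ht = ht)
}

# Cache for expensive shared simulation runs (computed once per test session).
.run_cache <- new.env(parent = emptyenv())
cached_run <- function(key, expr) {
  if (is.null(.run_cache[[key]])) .run_cache[[key]] <- force(expr)
  .run_cache[[key]]
}
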