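# Pressure sweeps and the scaling-law pipeline.

#' Run a sweep of simulations over pressures (and optionally boundary flows)
#'
#' Runs one trajectory per parameter combination with all other settings
#' shared, and returns the trajectories together with a per-run summary
#' table.
#'
#' @param pressures vector of pressures (units of `p0`, all `<= 0`)
#' @param vb boundary flow (units of `v0`); may be a vector to sweep too
#' @param ... further arguments passed to [simulation_config()]
#' @return object of class `memflow_sweep`: list with `runs` (list of
#'   trajectories) and `summary` (tibble, one row per run from
#'   [glance.membrane_trajectory()])
#' @export
run_pressure_sweep <- function(pressures, vb = -1, ...) {
  grid <- expand.grid(p = pressures, vb = vb)
  runs <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    cfg <- simulation_config(vb = grid$vb[i], p = grid$p[i], ...)
    runs[[i]] <- run_simulation(cfg)
  }
  structure(
    list(runs = runs,
         summary = dplyr::bind_rows(lapply(runs, glance))),
    class = "memflow_sweep"
  )
}

#' @export
print.memflow_sweep <- function(x, ...) {
  cat("<memflow_sweep> ", length(x$runs), " runs\n", sep = "")
  print(x$summary)
  invisible(x)
}

#' Scaling-law analysis of a pressure sweep
#'
#' From the late-time plateau values of each run, fits the power laws of the
#' tube width (`W` vs `|p|`) and of the tip-tension magnitude
#' (`|sigma(u=0)|` vs `|p|`), and quantifies the collapse of `W/Rp` and
#' `|sigma|/sigmap` across pressures (coefficient of variation).
#'
#' @param sweep a `memflow_sweep` (runs at distinct nonzero pressures)
#' @return object of class `scaling_report`: list with `width_fit` and
#'   `tension_fit` (class `scaling_fit`), `width_cv`, `tension_cv`, and the
#'   underlying `table`
#' @export
scaling_report <- function(sweep) {
  tab <- sweep$summary
  stopifnot(all(tab$p < 0), length(unique(tab$p)) >= 3)
  ap <- abs(tab$p)
  Rp <- (1 / (2 * ap))^(1 / 3)        # nondimensional kappa = 1
  sigmap <- 4^(1 / 3) * ap^(2 / 3)
  width_fit <- scaling_exponent(ap, tab$W_steady)
  tension_fit <- scaling_exponent(ap, tab$sigma_tip_steady)
  structure(
    list(width_fit = width_fit, tension_fit = tension_fit,
         width_cv = collapse_statistic(tab$W_steady, Rp),
         tension_cv = collapse_statistic(tab$sigma_tip_steady, sigmap),
         table = tibble::tibble(p = tab$p, W = tab$W_steady,
                                sigma_tip = tab$sigma_tip_steady,
                                Rp = Rp, sigmap = sigmap,
                                W_over_Rp = tab$W_steady / Rp,
                                sigma_over_sigmap =
                                  tab$sigma_tip_steady / sigmap)),
    class = "scaling_report"
  )
}

#' @export
print.scaling_report <- function(x, ...) {
  cat(sprintf(
    paste0("<scaling_report>\n  width:   exponent %+.4f (se %.4f),",
           " W/Rp CV %.4f\n  tension: exponent %+.4f (se %.4f),",
           " sigma/sigmap CV %.4f\n"),
    x$width_fit$exponent, x$width_fit$stderr, x$width_cv,
    x$tension_fit$exponent, x$tension_fit$stderr, x$tension_cv))
  invisible(x)
}

#' Write a scaling report as JSON
#'
#' @param report a `scaling_report`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_scaling_report <- function(report, path) {
  jsonlite::write_json(
    list(width = list(exponent = report$width_fit$exponent,
                      stderr = report$width_fit$stderr,
                      cv = report$width_cv),
         tension = list(exponent = report$tension_fit$exponent,
                        stderr = report$tension_fit$stderr,
                        cv = report$tension_cv),
         table = report$table),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
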