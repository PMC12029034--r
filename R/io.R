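# Plain-text input/output: shape snapshots, observable tables, run manifests.

#' Write a shape (and optional flow/tension fields) as columnar CSV
#'
#' Columns `u, r, z, psi, vu, vn, sigma`; scalar metadata (`t`, `h`, `Rb`) is
#' stored in commented header lines so the file round-trips through
#' [read_shape_csv()].  Values are in the nondimensional simulation units.
#'
#' @param shape a `membrane_shape`
#' @param path output path
#' @param rates optional `rate_field` supplying `vu`, `vn`
#' @param sigma optional tension profile
#' @param t time stamp stored in the header
#' @return `path`, invisibly
#' @export
write_shape_csv <- function(shape, path, rates = NULL, sigma = NULL,
                            t = NA_real_) {
  df <- data.frame(u = shape$grid$u, r = shape$r, z = shape$z,
                   psi = shape$psi,
                   vu = if (is.null(rates)) NA_real_ else rates$vu,
                   vn = if (is.null(rates)) NA_real_ else rates$vn,
                   sigma = if (is.null(sigma)) NA_real_ else sigma)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# t = %.17g", t), con)
  writeLines(sprintf("# h = %.17g", shape$h), con)
  writeLines(sprintf("# Rb = %.17g", shape$Rb), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Read a shape snapshot written by [write_shape_csv()]
#'
#' @param path file path
#' @return list with `shape` (a `membrane_shape`), `t`, and the `vu`, `vn`,
#'   `sigma` columns (vectors of `NA` when absent)
#' @export
read_shape_csv <- function(path) {
  hdr <- readLines(path, n = 3)
  meta <- unname(vapply(hdr, function(l) as.numeric(sub("^# \\w+ = ", "", l)),
                        numeric(1)))
  df <- utils::read.csv(path, comment.char = "#")
  shape <- membrane_shape(nrow(df), df$r, df$z, df$psi, h = meta[2],
                          Rb = meta[3], tol_geom = 1e-3)
  list(shape = shape, t = meta[1], vu = df$vu, vn = df$vn, sigma = df$sigma)
}

#' Write trajectory outputs
#'
#' Writes (a) the observables table as CSV (`t, H, Wn, W, sigma_tip,
#' sigma_base, area, h, dt`), (b) one shape CSV per stored snapshot, and
#' (c) a JSON run manifest echoing the configuration, the package version,
#' wall-clock times and the termination reason.  The manifest is written
#' last, also on partially failed runs.
#'
#' @param traj a `membrane_trajectory`
#' @param dir output directory (created if needed)
#' @param force overwrite an existing non-empty directory
#' @return `dir`, invisibly
#' @export
write_trajectory <- function(traj, dir, force = FALSE) {
  if (dir.exists(dir) && length(list.files(dir)) > 0 && !force) {
    stop("output directory ", dir, " is not empty (use force = TRUE)")
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(traj$observables, file.path(dir, "observables.csv"),
                   row.names = FALSE)
  for (sn in traj$snapshots) {
    write_shape_csv(sn$shape,
                    file.path(dir, sprintf("shape_t%08.3f.csv", sn$t)),
                    rates = sn$rates, sigma = sn$sigma, t = sn$t)
  }
  manifest <- list(
    config = unclass(traj$config),
    package_version = as.character(utils::packageVersion("memflow")),
    termination = traj$termination,
    n_steps = nrow(traj$observables) - 1L,
    t_final = max(traj$observables$t),
    written = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read a trajectory's observables table
#'
#' @param dir directory written by [write_trajectory()]
#' @return tibble of observables
#' @export
read_observables <- function(dir) {
  tibble::as_tibble(utils::read.csv(file.path(dir, "observables.csv")))
}
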