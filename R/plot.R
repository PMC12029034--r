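# ggplot2 views of shapes, trajectories and scaling fits.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a membrane profile
#'
#' Draws the meridional profile mirrored across the symmetry axis.
#'
#' @param object a `membrane_shape`
#' @param ... unused
#' @return a ggplot
#' @method autoplot membrane_shape
#' @export
autoplot.membrane_shape <- function(object, ...) {
  df <- as_tibble(object)
  df2 <- dplyr::bind_rows(df, dplyr::mutate(df, r = -.data$r))
  ggplot2::ggplot(df2, ggplot2::aes(.data$r, .data$z, group = sign(.data$r + 1e-300))) +
    ggplot2::geom_path() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "r / Rb", y = "z / Rb") +
    ggplot2::theme_minimal()
}

#' Plot trajectory observables over time
#'
#' @param object a `membrane_trajectory`
#' @param vars observable columns to draw
#' @param ... unused
#' @return a ggplot (facetted by observable)
#' @method autoplot membrane_trajectory
#' @export
autoplot.membrane_trajectory <- function(object,
                                         vars = c("H", "Wn", "W",
                                                  "sigma_tip", "sigma_base"),
                                         ...) {
  ob <- object$observables |>
    dplyr::select(dplyr::all_of(c("t", vars))) |>
    tidyr::pivot_longer(-"t", names_to = "observable")
  ggplot2::ggplot(ob, ggplot2::aes(.data$t, .data$value)) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::facet_wrap(~observable, scales = "free_y") +
    ggplot2::labs(x = "t / tau", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a power-law fit in log-log axes
#'
#' @param object a `scaling_fit`
#' @param ... unused
#' @return a ggplot
#' @method autoplot scaling_fit
#' @export
autoplot.scaling_fit <- function(object, ...) {
  ggplot2::ggplot(object$data, ggplot2::aes(.data$x, .data$value)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(
      data = tibble::tibble(
        x = object$data$x,
        value = exp(object$intercept) * object$data$x^object$exponent),
      linetype = 2) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "|p| / p0",
                  y = "value",
                  subtitle = sprintf("slope %.3f", object$exponent)) +
    ggplot2::theme_minimal()
}

#' Overlay rescaled membrane profiles
#'
#' Normalizes each snapshot profile by its contour length `h` and overlays
#' them; under pressure-free growth the rescaled shapes nearly coincide
#' (self-similarity), while pressure destroys the collapse.
#'
#' @param traj a `membrane_trajectory`
#' @param times snapshot times to draw (nearest stored snapshots are used)
#' @return a ggplot
#' @export
plot_rescaled_profiles <- function(traj, times) {
  snaps <- lapply(times, function(tt) {
    k <- which.min(abs(vapply(traj$snapshots, `[[`, numeric(1), "t") - tt))
    traj$snapshots[[k]]
  })
  df <- dplyr::bind_rows(lapply(snaps, function(sn) {
    tibble::tibble(t = sprintf("t = %.3g", sn$t),
                   r = sn$shape$r / sn$shape$h,
                   z = (sn$shape$z - sn$shape$z[length(sn$shape$z)]) /
                     sn$shape$h)
  }))
  ggplot2::ggplot(df, ggplot2::aes(.data$r, .data$z, colour = .data$t)) +
    ggplot2::geom_path() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "r / h", y = "z / h", colour = NULL) +
    ggplot2::theme_minimal()
}
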