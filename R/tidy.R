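# broom-style methods for fitted objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom tibble as_tibble
#' @export
tibble::as_tibble

#' Tidy a power-law scaling fit
#'
#' @param x a `scaling_fit`
#' @param ... unused
#' @return one row per coefficient (`exponent`, `log_prefactor`) with
#'   estimates and standard errors
#' @method tidy scaling_fit
#' @export
tidy.scaling_fit <- function(x, ...) {
  tibble::tibble(
    term = c("exponent", "log_prefactor"),
    estimate = c(x$exponent, x$intercept),
    std.error = c(x$stderr, NA_real_)
  )
}

#' One-row summary of a scaling fit
#'
#' @param x a `scaling_fit`
#' @param ... unused
#' @return tibble with `exponent`, `std.error`, `r.squared`, `n`
#' @method glance scaling_fit
#' @export
glance.scaling_fit <- function(x, ...) {
  tibble::tibble(exponent = x$exponent, std.error = x$stderr,
                 r.squared = x$r_squared, n = x$n)
}

#' One-row summary of a trajectory
#'
#' Late-time plateau values of tube width, neck width and tensions (trailing
#' 20% window means, drift-flagged by [steady_value()]).
#'
#' @param x a `membrane_trajectory`
#' @param ... unused
#' @return one-row tibble
#' @method glance membrane_trajectory
#' @export
glance.membrane_trajectory <- function(x, ...) {
  ob <- x$observables
  sv <- function(col, abs_val = FALSE) {
    v <- ob[[col]]
    keep <- !is.na(v)
    if (sum(keep) < 5) return(list(value = NA_real_, unsteady = NA))
    steady_value(ob$t[keep], if (abs_val) abs(v[keep]) else v[keep])
  }
  W <- sv("W"); Wn <- sv("Wn"); st <- sv("sigma_tip", TRUE)
  sb <- sv("sigma_base", TRUE); Hf <- ob$H[nrow(ob)]
  tibble::tibble(
    vb = x$config$vb, p = x$config$p, t_final = max(ob$t),
    termination = x$termination, H_final = Hf,
    W_steady = W$value, W_unsteady = W$unsteady,
    Wn_steady = Wn$value,
    sigma_tip_steady = st$value, sigma_base_steady = sb$value
  )
}
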