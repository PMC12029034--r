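#' Characteristic unit system
#'
#' Derives the characteristic scales of the model from the physical
#' parameters: time `tau = eta Rb^2 / kappa`, velocity `v0 = Rb/tau =
#' kappa/(eta Rb)`, tension `sigma0 = kappa/Rb^2`, pressure `p0 = kappa/Rb^3`,
#' and — when a nonzero pressure is supplied — the pressure length
#' `Rp = (kappa/(2|p|))^(1/3)` and pressure tension
#' `sigmap = (4 kappa)^(1/3) |p|^(2/3)` that collapse the late-time tube width
#' and tension across pressures.
#'
#' With kappa in pN nm, eta in pN s/nm and Rb in nm, `tau` is in seconds,
#' `v0` in nm/s, `sigma0` in pN/nm and `p0` in pN/nm^2.
#'
#' @param kappa bending rigidity (pN nm)
#' @param eta surface viscosity (pN s/nm)
#' @param Rb base radius (nm)
#' @param p pressure (pN/nm^2); optional, needed only for `Rp`/`sigmap`
#' @return a tibble-row of class `unit_system` with columns `tau`, `v0`,
#'   `sigma0`, `p0` and (if `p` given) `Rp`, `sigmap`
#' @examples
#' derive_units(4.1e3, 0.1, 30)  # tau ~ 22 ms, v0 ~ 1.37 um/s
#' @export
derive_units <- function(kappa, eta, Rb, p = NULL) {
  stopifnot(kappa > 0, eta > 0, Rb > 0)
  tau <- eta * Rb^2 / kappa
  out <- tibble::tibble(
    tau = tau,
    v0 = Rb / tau,
    sigma0 = kappa / Rb^2,
    p0 = kappa / Rb^3
  )
  if (!is.null(p)) {
    if (p == 0) stop("Rp and sigmap are undefined at p = 0")
    out$Rp <- (kappa / (2 * abs(p)))^(1 / 3)
    out$sigmap <- (4 * kappa)^(1 / 3) * abs(p)^(2 / 3)
  }
  class(out) <- c("unit_system", class(out))
  out
}

#' Scalar shape observables
#'
#' Measures, on one shape (optionally with its tension profile): the
#' invagination height `H = z(0) - z(1)`, the tube width `W = max r` (a
#' radius: the widest radial coordinate), the neck width `Wn` (the radial
#' coordinate at the deepest prominent interior local minimum of `r`;
#' `NA` before a neck exists), the tip and base tensions, the surface
#' area and the contour length.
#'
#' @param shape a `membrane_shape`
#' @param sigma optional tension profile (nodal vector)
#' @param t time stamp to record (default `NA`)
#' @return one-row tibble with columns `t`, `H`, `Wn`, `W`, `sigma_tip`,
#'   `sigma_base`, `area`, `h`
#' @export
measure <- function(shape, sigma = NULL, t = NA_real_) {
  N <- shape$grid$N
  r <- shape$r
  tibble::tibble(
    t = t,
    H = shape$z[1] - shape$z[N],
    Wn = neck_radius(r),
    W = max(r),
    sigma_tip = if (is.null(sigma)) NA_real_ else sigma[1],
    sigma_base = if (is.null(sigma)) NA_real_ else sigma[N],
    area = surface_area(shape),
    h = shape$h
  )
}

# Index of the neck: the deepest interior local minimum of r with a
# prominence of at least `prom` relative to the largest radius (screening out
# discretization-level micro-wiggles).  Developed shapes can carry a second,
# shallower collar minimum behind the head; the neck in the sense used here
# is the one the in-plane flow funnels through, i.e. the deepest minimum.
# NA when no prominent interior minimum exists.
neck_index <- function(r, prom = 0.01) {
  N <- length(r)
  if (N < 5) return(NA_integer_)
  i <- 2:(N - 1)
  cand <- i[r[i] < r[i - 1] & r[i] <= r[i + 1]]
  thr <- prom * max(r)
  keep <- cand[vapply(cand, function(k) {
    min(max(r[1:k]), max(r[k:N])) - r[k] >= thr
  }, logical(1))]
  if (!length(keep)) return(NA_integer_)
  keep[which.min(r[keep])]
}

# Radius at the innermost prominent interior local minimum of r.
neck_radius <- function(r, prom = 0.01) {
  k <- neck_index(r, prom)
  if (is.na(k)) NA_real_ else r[k]
}

#' Late-time plateau value of a time series
#'
#' Mean over the trailing 20% time window, with an `unsteady` flag raised when
#' the relative drift across that window (absolute difference between the
#' means of its first and last thirds, over the window mean) exceeds 5%.
#'
#' @param t,value numeric vectors (same length, `t` increasing)
#' @param window trailing fraction of the time axis to average (default 0.2)
#' @param drift_tol relative drift above which the series is flagged unsteady
#' @return list with `value` (the window mean), `unsteady` (logical),
#'   `drift` (the relative drift), `window` (the time interval used)
#' @export
steady_value <- function(t, value, window = 0.2, drift_tol = 0.05) {
  stopifnot(length(t) == length(value), length(t) >= 5)
  t0 <- max(t) - window * (max(t) - min(t))
  sel <- t >= t0
  if (sum(sel) < 3) stop("series too short for a trailing window")
  v <- value[sel]; tw <- t[sel]
  third <- (max(tw) - min(tw)) / 3
  v1 <- mean(v[tw <= min(tw) + third])
  v3 <- mean(v[tw >= max(tw) - third])
  m <- mean(v)
  drift <- abs(v3 - v1) / abs(m)
  list(value = m, unsteady = drift > drift_tol, drift = drift,
       window = c(t0, max(t)))
}

#' Power-law exponent by log-log least squares
#'
#' Fits `log(value) ~ log(x)` by ordinary least squares and returns the slope
#' (the power-law exponent), intercept, standard error and R^2.
#'
#' @param x,value positive numeric vectors (at least 3 points); `x` is
#'   typically the pressure magnitude `|p|`
#' @return object of class `scaling_fit`: list with `exponent`, `intercept`,
#'   `stderr`, `r_squared`, `n`, and the fitted `data`
#' @examples
#' scaling_exponent(c(0.5, 1, 2, 3), 2 * c(0.5, 1, 2, 3)^(-1 / 3))$exponent
#' @export
scaling_exponent <- function(x, value) {
  stopifnot(length(x) == length(value), length(x) >= 3)
  if (any(x <= 0) || any(value <= 0)) {
    stop("scaling_exponent requires strictly positive data")
  }
  fit <- stats::lm(log(value) ~ log(x))
  sm <- suppressWarnings(summary(fit))
  structure(
    list(exponent = unname(stats::coef(fit)[2]),
         intercept = unname(stats::coef(fit)[1]),
         stderr = sm$coefficients[2, 2],
         r_squared = sm$r.squared,
         n = length(x),
         data = tibble::tibble(x = x, value = value)),
    class = "scaling_fit"
  )
}

#' @export
print.scaling_fit <- function(x, ...) {
  cat(sprintf("<scaling_fit> exponent = %.4f (se %.4f), R^2 = %.5f, n = %d\n",
              x$exponent, x$stderr, x$r_squared, x$n))
  invisible(x)
}

#' Collapse quality of rescaled observables
#'
#' Coefficient of variation (sd/mean) of `values/scales`: zero for a perfect
#' collapse of the rescaled data onto one value.
#'
#' @param values,scales equal-length positive numeric vectors
#' @return scalar CV
#' @export
collapse_statistic <- function(values, scales) {
  stopifnot(length(values) == length(scales))
  if (any(values <= 0) || any(scales <= 0)) {
    stop("collapse_statistic requires positive values and scales")
  }
  x <- values / scales
  stats::sd(x) / mean(x)
}

#' Overlap distance between rescaled membrane profiles
#'
#' Normalizes two profiles by their contour lengths and returns the mean
#' nearest-point distance between the polylines, relative to the larger
#' normalized extent.  Pressure-free growth is self-similar (shapes at
#' different times nearly coincide after rescaling by `h`); pressure breaks
#' the property.
#'
#' @param shape_a,shape_b `membrane_shape`s
#' @return scalar relative mean distance (0 for identical rescaled shapes)
#' @export
profile_distance <- function(shape_a, shape_b) {
  norm_profile <- function(s) {
    cbind(s$r / s$h, (s$z - s$z[length(s$z)]) / s$h)
  }
  A <- norm_profile(shape_a)
  B <- norm_profile(shape_b)
  nearest <- function(P, Q) {
    vapply(seq_len(nrow(P)), function(i) {
      sqrt(min((Q[, 1] - P[i, 1])^2 + (Q[, 2] - P[i, 2])^2))
    }, numeric(1))
  }
  d <- (mean(nearest(A, B)) + mean(nearest(B, A))) / 2
  extent <- max(max(A[, 2]), max(B[, 2]), max(A[, 1]), max(B[, 1]))
  d / extent
}

#' Snapshot nearest a requested time
#'
#' @param traj a `membrane_trajectory`
#' @param t requested time
#' @return the stored snapshot list (`t`, `shape`, `rates`, `sigma`)
#' @export
snapshot_at <- function(traj, t) {
  ts <- vapply(traj$snapshots, `[[`, numeric(1), "t")
  traj$snapshots[[which.min(abs(ts - t))]]
}
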