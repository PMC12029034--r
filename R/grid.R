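#' Collocation grid on the unit interval
#'
#' The membrane profile is parameterized by `u` on a fixed interval \[0, 1\],
#' with `u = 0` at the tip and `u = 1` at the base, discretized on `N` uniform
#' nodes. The grid object carries the differentiation matrix (4th-order finite
#' differences), Gregory quadrature weights of matching order, and cumulative
#' integration operators defined as exact inverses of the differentiation
#' matrix, so that integrating a derivative (or differentiating a constructed
#' antiderivative) closes to machine precision on the grid.
#'
#' @param N integer number of collocation nodes (at least 50 for simulation
#'   grids; smaller grids are permitted internally for coarse cross-checks).
#' @param min_N smallest admissible `N` (default 50, the validated resolution
#'   floor for production shapes).
#'
#' @return An object of class `memflow_grid`: a list with elements `N`, `u`
#'   (nodes), `du` (spacing), `D1` (sparse differentiation matrix), `w`
#'   (quadrature weights), and the integration operators used internally.
#' @examples
#' g <- make_grid(101)
#' f <- sin(pi * g$u)
#' max(abs(grid_deriv(g, f) - pi * cos(pi * g$u))) # ~1e-7
#' abs(grid_integral(g, f) - 2 / pi)               # ~1e-9
#' @export
make_grid <- function(N, min_N = 50L) {
  N <- as.integer(N)
  if (length(N) != 1L || is.na(N) || N < max(6L, min_N)) {
    stop("N must be a single integer >= ", max(6L, min_N))
  }
  u <- seq(0, 1, length.out = N)
  du <- 1 / (N - 1)
  D1 <- fd_matrix_order4(N, du)
  D1b <- fd_matrix_biased(N, du)
  w <- gregory_weights(N, du)

  # Integration operators: replace one row of D1 with an anchor condition and
  # factorize once.  cum0 integrates from u=0 (x(0) anchored), cum1 from u=1.
  A0 <- D1
  A0[1, ] <- 0; A0[1, 1] <- 1
  A1 <- D1
  A1[N, ] <- 0; A1[N, N] <- 1
  lu0 <- Matrix::lu(A0)
  lu1 <- Matrix::lu(A1)

  structure(
    list(N = N, u = u, du = du, D1 = D1, D1b = D1b, w = w,
         .lu0 = lu0, .lu1 = lu1),
    class = "memflow_grid"
  )
}

# 4th-order first-derivative matrix on a uniform grid (5-point stencils,
# one-sided at the two nodes nearest each boundary).
fd_matrix_order4 <- function(N, du) {
  stopifnot(N >= 6)
  i <- integer(0); j <- integer(0); x <- numeric(0)
  add <- function(row, cols, coefs) {
    i <<- c(i, rep.int(row, length(cols)))
    j <<- c(j, cols)
    x <<- c(x, coefs / (12 * du))
  }
  add(1L, 1:5, c(-25, 48, -36, 16, -3))
  add(2L, 1:5, c(-3, -10, 18, -6, 1))
  for (k in 3:(N - 2)) add(k, (k - 2):(k + 2), c(1, -8, 0, 8, -1))
  add(N - 1L, (N - 4):N, c(-1, 6, -18, 10, 3))
  add(N, (N - 4):N, c(3, -16, 36, -48, 25))
  Matrix::sparseMatrix(i = i, j = j, x = x, dims = c(N, N))
}

# Fornberg finite-difference weights: derivative of order m at x0 from nodes x.
fd_weights <- function(x0, x, m) {
  n <- length(x)
  c1 <- 1; c4 <- x[1] - x0
  C <- matrix(0, n, m + 1)
  C[1, 1] <- 1
  for (i in 2:n) {
    mn <- min(i - 1, m)
    c2 <- 1; c5 <- c4; c4 <- x[i] - x0
    for (j in 1:(i - 1)) {
      c3 <- x[i] - x[j]
      c2 <- c2 * c3
      if (j == i - 1) {
        for (k in mn:1) {
          C[i, k + 1] <- c1 * (k * C[i - 1, k] - c5 * C[i - 1, k + 1]) / c2
        }
        C[i, 1] <- -c1 * c5 * C[i - 1, 1] / c2
      }
      for (k in mn:1) {
        C[j, k + 1] <- (c4 * C[j, k + 1] - k * C[j, k]) / c3
      }
      C[j, 1] <- c4 * C[j, 1] / c3
    }
    c1 <- c2
  }
  C[, m + 1]
}

# Biased first-derivative matrix (6-point stencils, order 5).  Unlike central
# differences its symbol does not vanish at the grid Nyquist frequency, so the
# stationarity solve built on it has no spurious checkerboard null modes.
fd_matrix_biased <- function(N, du) {
  stopifnot(N >= 6)
  i <- integer(0); j <- integer(0); x <- numeric(0)
  for (k in seq_len(N)) {
    s0 <- min(max(k - 2L, 1L), N - 5L)
    cols <- s0:(s0 + 5L)
    wts <- fd_weights(k - 1, cols - 1, 1L) / du
    i <- c(i, rep.int(k, 6L)); j <- c(j, cols); x <- c(x, wts)
  }
  Matrix::sparseMatrix(i = i, j = j, x = x, dims = c(N, N))
}

# Gregory quadrature weights with third-difference end corrections, O(du^4).
gregory_weights <- function(N, du) {
  stopifnot(N >= 6)
  w <- rep(du, N)
  ends <- c(3 / 8, 7 / 6, 23 / 24)
  w[1:3] <- ends * du
  w[N:(N - 2)] <- ends * du
  w
}

#' @rdname make_grid
#' @param grid a `memflow_grid`
#' @param f numeric vector of nodal values
#' @export
grid_deriv <- function(grid, f) as.numeric(grid$D1 %*% f)

#' @rdname make_grid
#' @export
grid_integral <- function(grid, f) sum(grid$w * f)

# Cumulative antiderivative with x(0) = x0, exact inverse of the grid
# differentiation matrix (rows 2..N of D1 %*% result equal f exactly).
grid_cumint0 <- function(grid, f, x0 = 0) {
  rhs <- f; rhs[1] <- x0
  as.numeric(Matrix::solve(grid$.lu0, rhs))
}

# Cumulative antiderivative anchored at the base: x(1) = x1.
grid_cumint1 <- function(grid, f, x1 = 0) {
  rhs <- f; rhs[grid$N] <- x1
  as.numeric(Matrix::solve(grid$.lu1, rhs))
}

# Smooth spectral low-pass filter on nodal values: discrete cosine expansion
# with a raised-cosine rolloff beginning at fraction `frac` of the spectrum.
# Removes grid-scale content below the scheme's resolution; smooth fields are
# altered only at their (negligible) high-mode amplitudes.
grid_filter_matrix <- function(grid, frac = 0.6) {
  key <- paste0("filt", grid$N, "f", frac)
  Fm <- .grid_cache[[key]]
  if (!is.null(Fm)) return(Fm)
  N <- grid$N
  u <- grid$u
  B <- sapply(0:(N - 1), function(k) cos(k * pi * u))
  damp <- vapply(0:(N - 1), function(k) {
    x <- k / (N - 1)
    if (x <= frac) 1 else 0.5 * (1 + cos(pi * (x - frac) / (1 - frac)))
  }, numeric(1))
  # least-squares analysis (B is square Vandermonde-like; solve directly)
  Fm <- B %*% (damp * solve(B))
  .grid_cache[[key]] <- Fm
  Fm
}

grid_filter <- function(grid, f, frac = 0.6) {
  as.numeric(grid_filter_matrix(grid, frac) %*% f)
}

# Shared per-N cache so repeated shape constructions reuse factorizations.
.grid_cache <- new.env(parent = emptyenv())

grid_cached <- function(N, min_N = 50L) {
  key <- paste0("N", N, "m", min_N)
  g <- .grid_cache[[key]]
  if (is.null(g)) {
    g <- make_grid(N, min_N = min_N)
    .grid_cache[[key]] <- g
  }
  g
}
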