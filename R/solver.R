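# Instantaneous force-balance solve.
#
# At a fixed shape the Rayleigh functional
#   R = D + dF/dt - dWext/dt + L
# is quadratic in the rate variables with positive-semidefinite quadratic part
# (the dissipation), so its stationary point solves a LINEAR two-point
# boundary value problem on u in [0,1] with the contour-length rate entering
# as an unknown scalar parameter.  The gauge (tangential grid) velocity
# gt = vu - q reduces both closure-rate constraints to the single gauge ODE
#   gt' = ht - vn psi',   gt(0) = gt(1) = 0,
# with psit = (-vn' + gt psi')/h, rt = gt cos psi + vn sin psi,
# zt = -gt sin psi + vn cos psi derived.  Because the dissipation and the
# energy rates depend only on the physical flow (vu, vn), the functional is
# gauge-invariant and the gauge multiplier vanishes.
#
# Two independent solvers are provided:
#
#  * "variational" (production): discretize-then-optimize.  The discretized
#    functional is minimized over (vu, vn, gt, ht) subject to pointwise
#    incompressibility and the gauge ODE; the sparse KKT saddle-point system
#    is solved directly.  The variational (Rayleigh-Ritz) structure makes the
#    scheme stable; the incompressibility multipliers are the membrane
#    tension.  Assembled with the 4th/5th-order biased derivative operator
#    (whose symbol has no zero at the grid Nyquist frequency, so no
#    checkerboard null modes) and Gregory quadrature.  The bending power
#    enters in geometric form, dF/dt = int fel vn dA with
#    fel = -kappa (lap_s M + M^3/2 - 2 M K), valid because tangential flow
#    and reparameterization leave F unchanged when the base ring is pinned
#    and clamped.
#
#  * "euler_lagrange" (independent cross-check): derive-then-discretize.  The
#    weak form of the hand-derived Euler-Lagrange equations -- continuity
#    d1 + d2 = 0, the tangential force balance, and the normal force balance
#    2 eta (d1 c2 + d2 c1) + sigma M + gamma vn + fel - p = 0 -- assembled
#    with independent second-order staggered operators (midpoint box
#    differences for d1, trapezoid quadrature) and the tension as a primary
#    unknown.  Used on coarse smooth test shapes to validate the production
#    route.

# Shape-dependent coefficients shared by the solvers and evaluators.
solver_context <- function(shape) {
  g <- shape$grid
  N <- g$N
  cv <- curvatures(shape)
  psip <- grid_deriv(g, shape$psi)
  M <- cv$c1 + cv$c2
  list(
    g = g, N = N, h = shape$h, r = shape$r, psi = shape$psi,
    c = cos(shape$psi), s = sin(shape$psi),
    psip = psip, c1 = cv$c1, c2 = cv$c2, M = M,
    Mp = grid_deriv(g, M)
  )
}

# Selection matrix picking N-block `b` of an unknown layout of width nvar.
.sel <- function(N, nvar, b) {
  Matrix::sparseMatrix(i = 1:N, j = (b - 1) * N + 1:N, x = 1,
                       dims = c(N, nvar))
}

# Geometric (shape-only) Helfrich force density conjugate to vn:
# dF/dt = int fel vn dA for motions with the base ring pinned and clamped.
helfrich_force <- function(ctx, kappa = 1) {
  g <- ctx$g; h <- ctx$h
  lapM <- as.numeric(g$D1 %*% (ctx$r * ctx$Mp / h)) / (ctx$r * h)
  lapM[1] <- 2 * as.numeric(g$D1 %*% ctx$Mp)[1] / h^2
  -kappa * (lapM + ctx$M^3 / 2 - 2 * ctx$M * (ctx$c1 * ctx$c2))
}

#' Solve the instantaneous Rayleigh stationarity problem
#'
#' Computes the stationary point of the Rayleigh functional over the rates at
#' a fixed shape, subject to pointwise incompressibility (whose multiplier is
#' the membrane tension `sigma`), the uniform-metric gauge, and the boundary
#' conditions: prescribed boundary lipid flow `vu(1) = vb`, tip regularity
#' (`vu(0) = 0`, `psit(0) = 0`), pinned base ring (`rt(1) = zt(1) = 0`), and
#' the base clamp (`psit(1) = 0`) or free hinge.
#'
#' @param shape a `membrane_shape`
#' @param config a `memflow_config` (`vb`, `p`, `gamma`, `base_bc` are used;
#'   the solve is nondimensional, `kappa = eta = 1`)
#' @param method `"variational"` (production: discretize-then-optimize KKT
#'   solve of the discretized functional) or `"euler_lagrange"` (independent
#'   cross-check: weak form of the derived force-balance equations on
#'   second-order staggered operators)
#' @param dt_stab linearly-implicit bending-stabilization weight (a time, in
#'   tau units) used by the time integrator; 0 gives the plain instantaneous
#'   solve.  Supported by the production route only.
#' @return list with components `rates` (a [rate_field()]), `multipliers`
#'   (list with `sigma`, the membrane tension profile), `energy` (list `D`,
#'   `dFdt`, `dWextdt`, `L`, `R`, `stat_residual`), and `strain` (list `d1`,
#'   `d2`)
#' @export
solve_rates <- function(shape, config,
                        method = c("variational", "euler_lagrange"),
                        dt_stab = 0) {
  method <- match.arg(method)
  sol <- switch(method,
    variational = solve_rates_variational(shape, config, dt_stab),
    euler_lagrange = solve_rates_el(shape, config, dt_stab)
  )
  rates <- rate_field(shape, sol$vu, sol$rt, sol$zt, sol$psit, sol$ht)
  if (any(!is.finite(c(rates$vu, rates$vn, rates$psit, rates$ht, sol$sigma)))) {
    stop("NaN/Inf in solved rate or multiplier fields")
  }
  sr <- strain_rates(shape, rates)
  D <- dissipation(shape, rates, eta = 1, gamma = config$gamma)
  dFdt <- bending_power(shape, rates, kappa = 1)
  dW <- pressure_power(shape, rates, config$p)
  w <- 2 * pi * shape$h * shape$r
  L <- grid_integral(shape$grid, sol$sigma * (sr$d1 + sr$d2) * w)
  list(
    rates = rates,
    multipliers = list(sigma = sol$sigma),
    energy = list(D = D, dFdt = dFdt, dWextdt = dW, L = L,
                  R = D + dFdt - dW + L,
                  stat_residual = sol$stat_residual),
    strain = sr
  )
}

# Rate of change of the bending energy under a rate field, in the
# parameterization form dF/dt = pi kappa int [2 M Mdot r h + M^2 (rt h +
# r ht)] du with Mdot = (c/r) psit - (s/r^2) rt + psit'/h - (c2/h) ht.
# Equals the geometric form int fel vn dA on gauge-consistent fields; the
# test-suite asserts the agreement of both with realized energy differences.
bending_power <- function(shape, rates, kappa = 1) {
  ctx <- solver_context(shape)
  g <- shape$grid
  psitp <- grid_deriv(g, rates$psit)
  rtp <- grid_deriv(g, rates$rt)
  rinv <- c(0, 1 / ctx$r[-1])
  Mdot <- (ctx$c * rinv) * rates$psit - (ctx$s * rinv^2) * rates$rt +
    psitp / ctx$h - (ctx$c2 / ctx$h) * rates$ht
  Mdot[1] <- 2 * psitp[1] / ctx$h - ctx$c2[1] * rtp[1] / ctx$h -
    (ctx$c2[1] / ctx$h) * rates$ht
  pi * kappa * grid_integral(g,
    2 * ctx$M * Mdot * ctx$r * ctx$h +
      ctx$M^2 * (rates$rt * ctx$h + ctx$r * rates$ht))
}

# ---- production route: variational KKT solve -------------------------------

solve_rates_variational <- function(shape, config, dt_stab = 0) {
  ctx <- solver_context(shape)
  N <- ctx$N; h <- ctx$h
  nvar <- 3 * N + 1
  D1 <- ctx$g$D1b
  eta <- 1; kappa <- 1
  w <- ctx$g$w
  wa <- w * 2 * pi * ctx$r * h
  # axis-regularized weight for the damping (quadratic) terms: flooring the
  # vanishing area measure at O(du) keeps the tip modes damped; the O(du)
  # consistency error vanishes under refinement.  Forcings and multiplier
  # recovery use the true measure.
  wa_reg <- w * 2 * pi * pmax(ctx$r, 0.5 * ctx$g$du * h) * h
  Dg <- function(v) Matrix::Diagonal(N, v)

  P_vu <- .sel(N, nvar, 1); P_vn <- .sel(N, nvar, 2); P_gt <- .sel(N, nvar, 3)
  P_ht <- Matrix::sparseMatrix(i = 1:N, j = rep(nvar, N), x = 1,
                               dims = c(N, nvar))
  rs <- function(M, v) { M@x <- M@x * v[M@i + 1L]; M }   # fast row scaling
  rinv <- c(0, 1 / ctx$r[-1])
  Od1 <- as(D1 %*% P_vu + rs(P_vn, ctx$psip), "CsparseMatrix") / h
  Od2 <- rs(as(rs(P_vu, ctx$c) + rs(P_vn, ctx$s), "CsparseMatrix"), rinv)
  Od2[1, ] <- Od1[1, ]
  Opsit <- as(rs(P_gt, ctx$psip) - D1 %*% P_vn, "CsparseMatrix") / h

  sw <- sqrt(wa_reg)
  H <- 2 * eta * (Matrix::crossprod(rs(Od1, sw)) +
                  Matrix::crossprod(rs(Od2, sw)))
  if (config$gamma != 0) {
    H <- H + config$gamma * Matrix::crossprod(rs(P_vn, sw))
  }
  OMd <- NULL
  if (dt_stab > 0) {
    Ort <- as(rs(P_gt, ctx$c) + rs(P_vn, ctx$s), "CsparseMatrix")
    OMd <- as(rs(Opsit, c(0, ctx$c[-1] * rinv[-1])) -
      rs(Ort, c(0, ctx$s[-1] * rinv[-1]^2)) +
      (D1 %*% Opsit) / h - rs(P_ht, ctx$c2 / h), "CsparseMatrix")
    OMd[1, ] <- (2 / h) * (D1 %*% Opsit)[1, ] -
      (ctx$c2[1] / h) * (D1 %*% Ort)[1, ] - (ctx$c2[1] / h) * P_ht[1, ]
    H <- H + dt_stab * kappa * Matrix::crossprod(rs(OMd, sw))
  }
  # consistent smoothness prior: undivided second differences, O(du^2)
  # residual on smooth fields, O(1) on grid-scale wiggles
  S <- smoothing_rows(N, nvar, mu = 0.5)
  H <- H + Matrix::crossprod(S)

  fel <- helfrich_force(ctx, kappa)
  gvec <- as.numeric(Matrix::t(P_vn) %*% (wa * (fel - config$p)))

  # constraints: incompressibility (N rows); gauge ODE at interior nodes plus
  # its integral compatibility row (which determines ht); tip and base
  # tangent-angle rate conditions
  Cinc <- Od1 + Od2
  Cg <- rbind(
    as(D1 %*% P_gt + rs(P_vn, ctx$psip) - P_ht,
       "CsparseMatrix")[2:(N - 1), , drop = FALSE],
    Matrix::sparseMatrix(i = rep(1L, N + 1L), j = c(N + 1:N, nvar),
                         x = c(-w * ctx$psip, 1), dims = c(1L, nvar)))
  Cbc <- Opsit[1, , drop = FALSE]
  if (config$base_bc == "clamped") {
    Cbc <- rbind(Cbc, Opsit[N, , drop = FALSE])
  }
  C <- rbind(Cinc, Cg, Cbc)
  d <- rep(0, nrow(C))
  if (config$base_bc == "free_hinge" && dt_stab > 0 && !is.null(OMd)) {
    # zero base bending moment, imposed through its rate
    C <- rbind(C, OMd[N, , drop = FALSE])
    d <- c(d, -ctx$M[N] / dt_stab)
  }

  # essential boundary values: vu(0)=0, vu(1)=vb, vn(1)=0, gt(0)=0, gt(1)=0
  fixed_idx <- c(1L, N, 2L * N, 2L * N + 1L, 3L * N)
  fixed_val <- c(0, config$vb, 0, 0, 0)
  free <- setdiff(seq_len(nvar), fixed_idx)
  y0 <- numeric(nvar); y0[fixed_idx] <- fixed_val

  Hf <- H[free, free, drop = FALSE]
  gf <- gvec[free] + as.numeric(H[free, , drop = FALSE] %*% y0)
  Cf <- C[, free, drop = FALSE]
  df <- d - as.numeric(C %*% y0)

  nfree <- length(free); ncon <- nrow(Cf)
  KKT <- rbind(cbind(Hf, Matrix::t(Cf)),
               cbind(Cf, Matrix::sparseMatrix(i = integer(0), j = integer(0),
                                              dims = c(ncon, ncon))))
  rhs <- c(-gf, df)
  if (max(abs(rhs)) == 0) {
    sol <- numeric(nfree + ncon)
  } else {
    sol <- as.numeric(Matrix::solve(KKT, rhs))
  }
  y <- y0; y[free] <- sol[1:nfree]
  lam <- sol[nfree + seq_len(ncon)]

  vu <- y[1:N]; vn <- y[N + 1:N]; gt <- y[2 * N + 1:N]; ht <- y[nvar]
  psit <- as.numeric(Opsit %*% y)
  rt <- gt * ctx$c + vn * ctx$s
  zt <- -gt * ctx$s + vn * ctx$c
  # tension = incompressibility multipliers over the quadrature-area measure;
  # the axis weight vanishes, so the tip value is extrapolated, and the last
  # few nodes (contaminated by the eliminated boundary-condition reactions)
  # are replaced by integrating the tangential force balance
  # sigma' = 2 eta [h c d2 - (r d1)'] / r through the base boundary layer
  sigma <- lam[1:N] / wa
  sigma[1] <- 3 * sigma[2] - 3 * sigma[3] + sigma[4]
  vn <- y[N + 1:N]
  d1v <- (as.numeric(ctx$g$D1 %*% y[1:N]) + vn * ctx$psip) / h
  d2v <- c(d1v[1], (ctx$c[-1] * y[2:N] + ctx$s[-1] * vn[-1]) / ctx$r[-1])
  sigp <- 2 * eta * (h * ctx$c * d2v -
                       as.numeric(ctx$g$D1 %*% (ctx$r * d1v))) / ctx$r
  k0 <- N - 12L
  for (i in (k0 + 1L):N) {
    sigma[i] <- sigma[i - 1] + 0.5 * (sigp[i] + sigp[i - 1]) * ctx$g$du
  }
  res <- as.numeric(KKT %*% sol - rhs)
  list(vu = vu, rt = rt, zt = zt, psit = psit, sigma = sigma, ht = ht,
       stat_residual = max(abs(res)) / max(1, max(abs(rhs))))
}

# Undivided second-difference rows for every full N-block of the layout.
smoothing_rows <- function(N, nvar, mu) {
  nblk <- (nvar - 1L) %/% N
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  for (b in seq_len(nblk)) {
    off <- (b - 1L) * N
    rows <- seq_len(N - 2L) + (b - 1L) * (N - 2L)
    ii <- c(ii, rows, rows, rows)
    jj <- c(jj, off + 1:(N - 2), off + 2:(N - 1), off + 3:N)
    xx <- c(xx, rep(mu, N - 2), rep(-2 * mu, N - 2), rep(mu, N - 2))
  }
  Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                       dims = c(nblk * (N - 2L), nvar))
}

# ---- cross-check route: weak Euler-Lagrange equations ----------------------

solve_rates_el <- function(shape, config, dt_stab = 0) {
  if (dt_stab > 0) {
    stop("the euler_lagrange route does not support stabilized stepping")
  }
  g <- shape$grid; N <- g$N; h <- shape$h
  du <- g$du
  psi <- shape$psi; cc <- cos(psi); ss <- sin(psi); r <- shape$r
  eta <- 1; kappa <- 1

  # independent second-order kernels
  Dc <- local({
    i <- c(1, 1, 1, rep(2:(N - 1), each = 2), N, N, N)
    j <- c(1, 2, 3, as.vector(rbind((2:(N - 1)) - 1, (2:(N - 1)) + 1)),
           N - 2, N - 1, N)
    x <- c(-3, 4, -1, rep(c(-1, 1), N - 2), 1, -4, 3) / (2 * du)
    Matrix::sparseMatrix(i = i, j = j, x = x, dims = c(N, N))
  })
  Dnm <- Matrix::sparseMatrix(i = rep(1:(N - 1), 2), j = c(1:(N - 1), 2:N),
                              x = c(rep(-1 / du, N - 1), rep(1 / du, N - 1)),
                              dims = c(N - 1, N))
  Anm <- Matrix::sparseMatrix(i = rep(1:(N - 1), 2), j = c(1:(N - 1), 2:N),
                              x = rep(0.5, 2 * (N - 1)), dims = c(N - 1, N))
  wtn <- rep(du, N); wtn[c(1, N)] <- du / 2
  psip <- as.numeric(Dc %*% psi)
  psim <- as.numeric(Dnm %*% psi)     # exact midpoint tangent-angle slope
  rm <- as.numeric(Anm %*% r)
  c2 <- psip / h
  c1 <- c(c2[1], ss[-1] / r[-1])
  M <- c1 + c2
  lapM <- as.numeric(Dc %*% (r * as.numeric(Dc %*% M) / h)) / (r * h)
  lapM[1] <- 2 * as.numeric(Dc %*% as.numeric(Dc %*% M))[1] / h^2
  fel <- -kappa * (lapM + M^3 / 2 - 2 * M * (c1 * c2))

  nv <- 3 * N
  Pvu <- .sel(N, nv, 1); Pvn <- .sel(N, nv, 2); Psg <- .sel(N, nv, 3)
  Dg <- function(v) Matrix::Diagonal(length(v), v)
  # strain operators: d1 at midpoints (box scheme), d2 pointwise at nodes
  Om1 <- (Dnm %*% Pvu + Dg(psim) %*% Anm %*% Pvn) / h
  rinv <- c(0, 1 / r[-1])
  Od2 <- Dg(rinv) %*% (Dg(cc) %*% Pvu + Dg(ss) %*% Pvn)
  Od2[1, ] <- ((Dnm %*% Pvu + Dg(psim) %*% Anm %*% Pvn) / h)[1, ]
  # same axis-regularized damping measure as the production route
  Wm <- Dg(du * 2 * pi * pmax(rm, 0.5 * du * h) * h)
  Wn <- Dg(wtn * 2 * pi * pmax(r, 0.5 * du * h) * h)

  # weak equations: variations of eta int(d1^2+d2^2) dA + (gamma/2) int vn^2
  # dA + int sigma (d1+d2) dA + int (fel - p) vn dA over (vu, vn); the
  # sigma-rows are the continuity equations tested with the same measures
  Hxx <- 2 * eta * (Matrix::t(Om1) %*% Wm %*% Om1 +
                    Matrix::t(Od2) %*% Wn %*% Od2) +
    config$gamma * Matrix::t(Pvn) %*% Wn %*% Pvn
  Csig <- Matrix::t(Om1) %*% Wm %*% Anm %*% Psg +
    Matrix::t(Od2) %*% Wn %*% Psg
  A <- as(Hxx + Csig + Matrix::t(Csig), "CsparseMatrix")
  b <- -as.numeric(Matrix::t(Pvn) %*% (wtn * 2 * pi * r * h *
                                         (fel - config$p)))

  unit <- function(col) {
    Matrix::sparseMatrix(i = 1L, j = col, x = 1, dims = c(1L, nv))
  }
  # essential rows: vu(0)=0, vu(1)=vb replace the vu-gradient rows at the
  # ends; tip regularity vn'(0)=0, pinned base vn(1)=0 and the clamp
  # vn'(1)=0 replace vn-gradient rows (the clamp and pin reactions
  # invalidate the adjacent discrete balances)
  A[1, ] <- unit(1L);               b[1] <- 0
  A[N, ] <- unit(N);                b[N] <- config$vb
  A[N + 1L, ] <- (Dc %*% Pvn)[1, ]; b[N + 1L] <- 0
  A[2L * N, ] <- unit(2L * N);      b[2L * N] <- 0
  if (config$base_bc == "clamped") {
    A[2L * N - 1L, ] <- (Dc %*% Pvn)[N, ]
    b[2L * N - 1L] <- 0
  }
  x <- as.numeric(Matrix::solve(A, b))
  vu <- x[1:N]; vn <- x[N + 1:N]; sigma <- x[2 * N + 1:N]

  ht <- sum(wtn * vn * psip)
  gt <- c(0, cumsum(as.numeric(ht - Anm %*% (vn * psip)) * du))
  psit <- (-as.numeric(Dc %*% vn) + gt * psip) / h
  list(vu = vu, rt = gt * cc + vn * ss, zt = -gt * ss + vn * cc,
       psit = psit, sigma = sigma, ht = ht,
       stat_residual = 0)
}
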