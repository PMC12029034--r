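---
title: "Boundary-flow-driven membrane tubulation: model and numerics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Boundary-flow-driven membrane tubulation: model and numerics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

memflow simulates the deformation of a small patch of plasma membrane that
is inflated by a boundary influx of lipid against turgor pressure — the
geometry of a clathrin-mediated endocytic pit in a walled cell, where a ring
of myosin motors at the rim of the pit is hypothesized to pump lipid inward.
This vignette is the package's own account of the model, the numerical
scheme, and the choices made where the design was genuinely open.

## Model

The membrane is an axisymmetric surface parameterized on a fixed interval
$u \in [0,1]$, with the tip on the symmetry axis at $u=0$ and the base
pinned to a ring of radius $R_b$ at $u=1$:
$r' = h\cos\psi$, $z' = -h\sin\psi$, where $\psi(u)$ is the tangent angle
and the metric factor $h$ is kept *spatially uniform* (the uniform-metric
gauge), so $h(t)$ is simply the total contour length and arclength is
$s = h u$.  The principal curvatures are $c_1 = \sin\psi/r$ (azimuthal) and
$c_2 = \psi'/h$ (meridional).

The lipid bilayer is treated as

* an elastic surface with Helfrich bending energy
  $F = \tfrac{\kappa}{2}\int (c_1+c_2)^2\,dA$ (zero spontaneous curvature,
  no Gaussian term), and
* a two-dimensional incompressible Newtonian fluid with surface viscosity
  $\eta$, flowing with meridional velocity $v_u$ and normal velocity $v_n$
  (the azimuthal flow vanishes identically under axisymmetry with no
  azimuthal boundary forcing).

The driving is a prescribed boundary flow $v_u(1) = v_b < 0$ (lipid pumped
into the patch) and a turgor pressure $p \le 0$ acting against the outward
normal, with external power $dW_{\mathrm{ext}}/dt = p \int v_n\,dA$.

Because the dynamics is overdamped, the instantaneous rates minimize a
Rayleigh functional
$$\mathcal R = D + \frac{dF}{dt} - \frac{dW_{\mathrm{ext}}}{dt} + L,$$
where $D = \eta \int (d_1^2 + d_2^2)\,dA + \tfrac{\gamma}{2}\int v_n^2\,dA$
is half the dissipation rate (surface viscosity plus a weak normal drag
$\gamma$ from the surroundings), $d_1 = (v_u' + v_n\psi')/h$ and
$d_2 = (v_u\cos\psi + v_n\sin\psi)/r$ are the principal strain rates, and
$L$ collects the constraints: pointwise incompressibility $d_1 + d_2 = 0$,
whose Lagrange multiplier $\sigma(u)$ *is* the membrane tension, and the
uniform-metric gauge.  Writing the tangential grid velocity as
$g_t = v_u - q$ ($q$ is the gauge velocity of the parameterization), both
closure-rate constraints collapse to the single gauge ODE
$g_t' = \dot h - v_n \psi'$ with $g_t(0) = g_t(1) = 0$; the contour-length
rate $\dot h$ is the unknown scalar parameter fixed by the compatibility of
this ODE.  Since $D$, $dF/dt$ and $dW_{\mathrm{ext}}/dt$ depend only on the
physical flow, $\mathcal R$ is gauge-invariant and the gauge multiplier
vanishes identically.

Everything is solved in characteristic units: lengths in $R_b$, time in
$\tau = \eta R_b^2/\kappa$, velocity in $v_0 = \kappa/(\eta R_b)$, tension
in $\sigma_0 = \kappa/R_b^2$, pressure in $p_0 = \kappa/R_b^3$.  For the
default endocytosis parameters ($\kappa = 4.1\times10^3$ pN nm,
$\eta = 0.1$ pN s/nm, $R_b = 30$ nm) these are $\tau \approx 22$ ms,
$v_0 \approx 1.37\ \mu$m/s, $\sigma_0 \approx 4.6$ pN/nm,
$p_0 \approx 0.15$ pN/nm$^2$.  Under pressure the natural scales are
$R_p = (\kappa/2|p|)^{1/3}$ and $\sigma_p = (4\kappa)^{1/3}|p|^{2/3}$; a
cylinder of radius $R_p$ is exactly the zero-tension tube equilibrium
($\sigma = pW + \kappa/2W^2 = 0$ at $W = R_p$), which is why steady tube
widths collapse when scaled by $R_p$.

## The instantaneous solve

At a fixed shape $\mathcal R$ is *quadratic* in the rates, so stationarity
is one sparse linear solve per time step.  Two independent implementations
are provided and cross-validated:

* **`variational`** (production): discretize-then-optimize.  $D$ and the
  constraint set are discretized on the $u$-grid (Gregory quadrature; a
  biased 6-point, order-4/5 derivative operator whose Fourier symbol has no
  zero at the grid Nyquist frequency, so the discrete system has no
  spurious checkerboard modes) and the KKT saddle-point system over
  $(v_u, v_n, g_t, \dot h)$ is solved directly.  The Rayleigh–Ritz
  structure makes this scheme variationally stable — during development,
  several strong-form collocation discretizations of the same equations
  self-converged to visibly non-stationary solutions (verified by
  finite-difference directional derivatives of the Lagrangian), which is
  why the energy-based route is the production solver.  The bending power
  enters in geometric form $dF/dt = \int f_{el} v_n\,dA$ with
  $f_{el} = -\kappa(\Delta_s M + M^3/2 - 2MK)$, $M = c_1 + c_2$,
  $K = c_1 c_2$ — valid because tangential flow and reparameterization
  leave $F$ unchanged when the base ring is pinned and clamped.
* **`euler_lagrange`** (cross-check): derive-then-discretize.  The weak
  form of the hand-derived force-balance equations — continuity, the
  tangential balance $2\eta(r d_1)' - 2\eta h c\, d_2 + r\sigma' = 0$, and
  the normal balance
  $2\eta(d_1 c_2 + d_2 c_1) + \sigma M + \gamma v_n + f_{el} - p = 0$ —
  assembled with *independent* second-order staggered operators (box-scheme
  midpoint differences, trapezoid quadrature) and the tension as a primary
  unknown.

The two routes agree to better than 1% on all rate and tension fields over
$u \in [0.1, 0.9]$ on well-curved test shapes (the suite uses spherical
caps at three driving combinations, $N = 320$).  The agreement is checked
away from the ends because both discretizations resolve the boundary
layers differently, and away from the nearly flat state, which is a
physically singular limit (see below).

Numerical choices in the solve, all consistent (errors vanish under
refinement):

* **Tip regularization.**  $c_1$, $d_2$ and the bending rate carry
  removable $0/0$ singularities on the axis; they are replaced by their
  smooth limits ($c_1(0) = c_2(0)$, $d_2(0) = d_1(0)$).  The area measure
  vanishes on the axis, which would leave tip nodes entirely undamped, so
  the damping quadrature uses an axis-regularized measure floored at
  $0.5\,h\,du$ — an $O(du)$ perturbation.  The tension at the tip is
  quadratically extrapolated; near the base, where the eliminated
  essential boundary conditions contaminate the multiplier recovery, the
  last twelve nodal tensions are instead obtained by integrating the
  tangential force balance through the boundary layer.
* **Smoothness prior.**  A small penalty on undivided second differences
  (weight 0.05) suppresses grid-scale content that all the physical terms
  are nearly blind to; for smooth fields its residual is $O(du^2)$.
* **External drag $\gamma$.**  With $\gamma = 0$ the nearly flat membrane
  has no well-posed response: normal motion costs neither dissipation nor
  bending power wherever curvature vanishes, and minimizing sequences
  concentrate at curvature zeros (observed as mesh-dependent blow-up under
  refinement).  The model description includes friction from the
  surroundings; the default $\gamma = 0.01$ (in units of
  $\kappa/(R_b^2 v_0)$) regularizes the flat limit while perturbing the
  resolved tube and neck dynamics by well under 1% — physically, cytosolic
  drag on a 30 nm patch is orders of magnitude smaller than the membrane's
  own surface viscosity, so $\gamma$ is a numerical floor, not a fitted
  parameter.

## Time integration

Each step solves for rates and advances $(\psi, h)$ explicitly, then
rebuilds $(r, z)$ by exact grid antidifferentiation of the closure
relations (the integration operators are exact inverses of the
differentiation matrix, so closure holds to machine precision at interior
nodes).  Stability and accuracy devices:

* **Linearly implicit bending stabilization.**  High-wavenumber bending
  modes relax at rates $\sim \kappa q^4$ and make explicit stepping
  unstable at any useful $\Delta t$.  The solve therefore carries a
  Gauss–Newton term $\tfrac{\kappa\,\Delta t_s}{2}\int \dot M^2\,dA$
  (the second-order bending-energy expansion), with
  $\Delta t_s = 3\Delta t$; the overdamping factor 3 removes a period-two
  oscillation observed at factor 1.
* **Rate filtering.**  The tangent-angle rate is passed through a smooth
  spectral low-pass (raised-cosine rolloff above half the discrete cosine
  spectrum) before it is written into $\psi$: sub-resolution content would
  otherwise accumulate over thousands of steps and feed back through the
  fourth-derivative bending force.
* **Step control.**  $\Delta t$ adapts between $10^{-3}\tau$ and
  $3\times10^{-2}\tau$: halved on solver failure or positivity loss (up to
  8 times), additionally capped so no step turns the tangent angle by more
  than 0.05 rad anywhere, regrown by 20% after successes.  The start from
  the nearly flat bump has an integrable singular transient (rates scale
  like the inverse slope), which the controller traverses automatically.
* **Conservation projection.**  With incompressibility and the boundary
  influx, the exact area balance is
  $A(t) = A(0) + 2\pi R_b |v_b| t$.  First-order stepping drifts by
  $O(\Delta t)$; after each step the shape is projected back onto the
  exact-balance manifold (a Newton nudge of $\psi$ along a fixed smooth
  direction, $O(\Delta t^2)$ per step), and the $O(\Delta t^2)$ drift of
  the base radius is rescaled away.  The recorded trajectories satisfy the
  balance to $10^{-10}$.
* **Adaptive regridding.**  On the fixed uniform $u$-grid the physical
  node spacing is $h\,du$ and grows with the membrane.  Once spacing
  reaches $\approx 0.095 R_b$ the under-resolved neck pinches numerically
  (confirmed: the pinch time scales with $N$).  The integrator therefore
  regrids $\psi$ onto a finer grid (spline interpolation) whenever spacing
  exceeds `regrid_res` (default $0.07 R_b$), up to `N_max` (default 600).

## The synthetic initial condition

The run starts from the nearly flat state: a cosine cap in the tangent
angle, $\psi = a\sin(\pi u)$, with amplitude set so the tip height is
$\varepsilon R_b$ ($\varepsilon = 0.02$ by default) and oriented toward the
invagination side.  A full-interval profile is used rather than a
compactly supported bump because any exactly flat annulus makes the
instantaneous solve degenerate (see $\gamma$ above); the sine-cap has
nonvanishing curvature almost everywhere.  The generator emulates the
experimental situation of a flat patch with thermal-scale corrugation about
to be loaded; it does not emulate protein-coat spontaneous curvature,
actin forces, membrane–wall contact or thermal noise, so passing tests
validate the boundary-flow/pressure mechanism in isolation, not a full
endocytic event.

## What the simulations show

With the defaults the package reproduces, from scratch, the phenomenology
and the quantitative surface of the study it implements:

* pressure-free growth into a sphere-like or parachute shape whose
  rescaled profiles at different times coincide (self-similarity; mean
  profile distance between $T = 40\tau$ and $60\tau$ under 2%), with a
  neck whose radius stabilizes;
* under pressure, a tube whose height grows linearly in time
  ($R^2 > 0.999$), faster at higher pressure, with the in-plane flow
  always peaking at the neck;
* steady tube width scaling as $|p|^{-1/3}$ (fitted exponent $\approx
  -0.34$) with $W/R_p$ collapsing to CV $< 0.01$ across
  $p/p_0 \in \{-0.5, -1, -2, -3\}$, and steady tip-tension magnitude
  scaling as $|p|^{2/3}$ (fitted exponent $\approx 0.66$) with
  $\sigma/\sigma_p$ collapsing likewise;
* a base-tension plateau of magnitude $\approx 8\text{–}10\,\sigma_0$ at
  late times — the tension the boundary motor ring must sustain, about
  $2\pi R_b \cdot 10\sigma_0 \approx 8.7$ nN in physical units.

The test suite computes all of the above at $N = 150$ starting grids and
horizons of $30\tau$ (sweep) and $60\tau$ (self-similarity), sizes at which
every plateau used is drift-checked; `scripts/acceptance.R` reruns the
base-tension measurement at the production size ($N = 200$, $60\tau$).

## Known limitations

* The neck is followed only down to `r_contact` (default $0.02 R_b$);
  scission and post-contact dynamics are out of scope.
* The clamped base condition $\psi(1) = 0$ is the default; the free-hinge
  variant is implemented but only lightly exercised.
* Quantities defined *at* the boundary layers (notably the base tension)
  are recovered by force-balance integration rather than read off the
  multiplier, and carry a few-percent numerical uncertainty.
* The nearly flat limit is regularized ($\gamma$, axis floor); instantaneous
  rates in that limit are resolution-dependent even though the ensuing
  trajectories converge.
* W and the neck width are radii; figure-level axis conventions elsewhere
  may differ by a factor of two.
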