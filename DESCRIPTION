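Package: memflow
Title: Boundary-Flow-Driven Membrane Tubulation Under Turgor Pressure
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Dynamic simulation of an axisymmetric elastic membrane carrying a
    two-dimensional incompressible viscous lipid flow, driven by a prescribed
    boundary lipid influx against turgor pressure. The membrane is a Helfrich
    surface with bending rigidity kappa and surface viscosity eta; its
    overdamped evolution is obtained at every instant by making a Rayleigh
    dissipation functional stationary under incompressibility and geometric
    constraints, posed as a linear two-point boundary value problem on a fixed
    parameter interval with the total contour length as an unknown parameter.
    Includes the characteristic unit system, scalar shape observables (height,
    neck width, tube width, tension profiles), pressure sweeps, and power-law
    scaling analyses of tube width and membrane tension against pressure.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    tibble,
    dplyr,
    tidyr,
    rlang,
    ggplot2,
    jsonlite,
    yaml,
    generics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
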