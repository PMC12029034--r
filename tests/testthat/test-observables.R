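# Unit system, observables, scaling analyses.

test_that("characteristic units match the physical parameter set", {
  us <- derive_units(4.1e3, 0.1, 30)
  expect_equal(us$tau, 0.1 * 900 / 4100)          # ~22 ms
  expect_equal(round(us$tau * 1000), 22)
  expect_equal(us$v0 / 1e3, 1.37, tolerance = 5e-3)  # um/s to printed rounding
  expect_equal(signif(us$sigma0, 2), 4.6)
  expect_equal(signif(us$p0, 2), 0.15)
  # unit identities for random positive inputs
  set.seed(42)
  for (k in 1:20) {
    kap <- runif(1, 1, 1e4); eta <- runif(1, 1e-3, 10); Rb <- runif(1, 1, 100)
    u <- derive_units(kap, eta, Rb)
    expect_equal(u$v0 * u$tau, Rb, tolerance = 1e-12 * Rb)
    expect_equal(u$sigma0 * Rb, kap / Rb, tolerance = 1e-12 * kap / Rb)
    expect_equal(u$p0 * Rb, u$sigma0, tolerance = 1e-12 * u$sigma0)
  }
  expect_equal(derive_units(2, 1, 1, p = 1)$Rp, 1)
  expect_error(derive_units(2, 1, 1, p = 0), "undefined")
})

test_that("observables identify height, widths and the neck", {
  flat <- fixture_shape("flat", Rb = 1, N = 100)
  m <- measure(flat)
  expect_equal(m$H, 0)
  expect_equal(m$W, 1)
  expect_true(is.na(m$Wn))
  cc <- fixture_shape("capped_cylinder", R = 0.4, L = 2, N = 201)
  m2 <- measure(cc)
  expect_equal(m2$W, 0.4, tolerance = 1e-10)
  expect_true(is.na(m2$Wn))
  # Omega profile: bulb of radius 1 over a neck of radius 0.3
  u <- seq(0, 1, length.out = 200)
  r <- ifelse(u < 0.7, 0.3 + 0.7 * sin(pi * u / 0.7),
              0.3 + (u - 0.7) / 0.3 * 0.4)
  expect_equal(memflow:::neck_radius(r), 0.3, tolerance = 0.02)
  expect_equal(max(r), 1, tolerance = 1e-3)
})

test_that("steady_value averages plateaus and flags drifting series", {
  t <- seq(0, 60, by = 0.5)
  sv <- steady_value(t, rep(3.5, length(t)))
  expect_equal(sv$value, 3.5)
  expect_false(sv$unsteady)
  sv2 <- steady_value(t, 1 - exp(-t / 5))
  expect_equal(sv2$value, 1, tolerance = 0.01)
  expect_false(sv2$unsteady)
  sv3 <- steady_value(t, 0.5 * t + 1)    # linear growth never plateaus
  expect_true(sv3$unsteady)
})

test_that("scaling_exponent recovers exact and noisy power laws", {
  p <- c(0.5, 1, 2, 3)
  expect_equal(scaling_exponent(p, 2.7 * p^(-1 / 3))$exponent, -1 / 3,
               tolerance = 1e-12)
  expect_equal(scaling_exponent(p, 0.4 * p^(2 / 3))$exponent, 2 / 3,
               tolerance = 1e-12)
  # 2% multiplicative noise: slope within 0.03 of truth, cross-checked
  # against a brute-force grid search on the squared log-residuals
  set.seed(7)
  y <- 1.3 * p^(-1 / 3) * exp(rnorm(4, 0, 0.02))
  fit <- scaling_exponent(p, y)
  grid_slopes <- seq(-1, 1, by = 1e-4)
  sse <- vapply(grid_slopes, function(b) {
    a <- mean(log(y) - b * log(p))
    sum((log(y) - a - b * log(p))^2)
  }, numeric(1))
  expect_lt(abs(fit$exponent - grid_slopes[which.min(sse)]), 2e-4)
  expect_lt(abs(fit$exponent - (-1 / 3)), 0.03)
  expect_error(scaling_exponent(p, c(1, 2, -3, 4)), "positive")
})

test_that("collapse_statistic is zero for perfect collapse", {
  expect_equal(collapse_statistic(c(2, 4, 6), c(1, 2, 3)), 0)
  expect_gt(collapse_statistic(c(2, 5, 6), c(1, 2, 3)), 0.1)
})

test_that("tidy and glance methods return the fit in broom shape", {
  fit <- scaling_exponent(c(0.5, 1, 2, 3), 2 * c(0.5, 1, 2, 3)^(-1 / 3))
  td <- tidy(fit)
  expect_equal(td$term, c("exponent", "log_prefactor"))
  expect_equal(td$estimate[1], -1 / 3, tolerance = 1e-10)
  gl <- glance(fit)
  expect_equal(gl$r.squared, 1, tolerance = 1e-12)
})
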