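nu <- exp(seq(log(1e-4), log(40), length.out = 400))  # THz

test_that("Debye susceptibility has its analytic maximum", {
  ## peak at omega*tau = 1 with height delta/2
  v <- chi_debye(1 / (2 * pi * 1), delta = 2, tau = 1)
  expect_equal(v, 1, tolerance = 1e-14)
  vals <- chi_debye(nu, delta = 1, tau = 3)
  expect_equal(max(vals), 0.5, tolerance = 1e-4)
  expect_equal(nu[which.max(vals)] * 2 * pi * 3, 1, tolerance = 0.05)
  ## linear onset at low frequency
  lo <- nu[1:5]
  expect_equal(chi_debye(lo, 1, 3) / (2 * pi * lo * 3), rep(1, 5),
               tolerance = 1e-5)
})

test_that("Cole-Davidson reduces to Debye at beta = 1 and has beta tail", {
  expect_equal(chi_cole_davidson(nu, 1.7, 2.2, beta = 1),
               chi_debye(nu, 1.7, 2.2), tolerance = 1e-12)
  ## high-frequency flank decays as omega^-beta (frozen slope -0.5998)
  hi <- exp(seq(log(150), log(1500), length.out = 50))
  y <- chi_cole_davidson(hi, 1, 1, beta = 0.6)
  slope <- coef(lm(log(y) ~ log(hi)))[[2]]
  expect_equal(slope, -0.6, tolerance = 0.002)
  ## peak shifts above 1/tau as beta decreases (frozen: omega*tau = 1.4966)
  wt <- 2 * pi * nu * 1
  vals06 <- chi_cole_davidson(nu, 1, 1, 0.6)
  expect_equal(wt[which.max(vals06)], 1.4966, tolerance = 0.03)
  expect_equal(max(vals06), 0.39047, tolerance = 1e-3)
  expect_error(chi_cole_davidson(nu, 1, 1, beta = 0), "beta")
  expect_error(chi_cole_davidson(nu, 1, 1, beta = 1.2), "beta")
})

test_that("damped harmonic oscillator obeys its closed forms", {
  ## chi(nu0) = delta * nu0 / gamma exactly
  expect_equal(chi_dho(5.1 , delta = 1, nu0 = 5.1, gamma = 5.1 / 2), 2,
               tolerance = 1e-14)
  ## underdamped: maximum near nu0 (frozen numeric max 5.0755 for gamma=1)
  vals <- chi_dho(nu, 1, 5.1, 1)
  expect_equal(nu[which.max(vals)], 5.0755, tolerance = 0.02)
  ## zero at origin and vanishing at infinity
  expect_equal(chi_dho(1e-12, 1, 5.1, 1), 0, tolerance = 1e-10)
  expect_lt(chi_dho(4000, 1, 5.1, 1), 1e-6)
  ## Brownian oscillator: identical response, overdamped peak below nu0
  expect_identical(chi_brownian(nu, 1, 5.1, 1), chi_dho(nu, 1, 5.1, 1))
  over <- chi_brownian(nu, 1, 0.45, 3)
  expect_equal(nu[which.max(over)], 0.06901, tolerance = 0.03)
})

test_that("power law is exact, homogeneous, and rejects zero frequency", {
  expect_equal(chi_power_law(1, 1, 0.3), 1)
  y <- chi_power_law(nu, 1, 0.3)
  expect_equal(coef(lm(log(y) ~ log(nu)))[[2]], -0.3, tolerance = 1e-10)
  expect_equal(chi_power_law(nu, 2, 0.3), 2 * y, tolerance = 1e-14)
  expect_error(chi_power_law(c(0, 1), 1, 0.3), "nu")
})

test_that("model evaluation is additive, grouped, and linear in amplitudes", {
  m <- susceptibility_model(
    model_component("debye", "SR", "rot", delta = 2, tau = 100),
    model_component("cole_davidson", "WR_bulk", "bulk",
                    delta = 1, tau = 1, beta = 0.6),
    model_component("dho", "VIB", "S", delta = 0.7, nu0 = 5.1, gamma = 2.6))
  ev <- evaluate_model(m, nu, unit = "THz")
  partials <- attr(ev, "partials")
  groups <- attr(ev, "groups")
  expect_equal(rowSums(partials), ev$value, tolerance = 1e-14)
  expect_equal(rowSums(groups), ev$value, tolerance = 1e-12)
  expect_equal(groups[, "SR"], partials[, "rot"])
  ## linearity: scaling every amplitude scales the total
  m2 <- susceptibility_model(
    model_component("debye", "SR", "rot", delta = 2 * 3, tau = 100),
    model_component("cole_davidson", "WR_bulk", "bulk",
                    delta = 1 * 3, tau = 1, beta = 0.6),
    model_component("dho", "VIB", "S", delta = 0.7 * 3, nu0 = 5.1,
                    gamma = 2.6))
  expect_equal(evaluate_model(m2, nu, unit = "THz")$value, 3 * ev$value,
               tolerance = 1e-12)
  ## single component equals its function
  m1 <- susceptibility_model(model_component("debye", "SR", "d",
                                             delta = 1, tau = 5))
  expect_equal(evaluate_model(m1, nu, unit = "THz")$value,
               chi_debye(nu, 1, 5))
  expect_error(susceptibility_model(), "no components")
})

test_that("components are non-negative on positive grids", {
  set.seed(7)
  for (i in 1:20) {
    d <- runif(1, 0, 5); tau <- runif(1, 0.1, 100); b <- runif(1, 0.05, 1)
    n0 <- runif(1, 0.1, 20); g <- runif(1, 0.1, 10)
    expect_true(all(chi_debye(nu, d, tau) >= 0))
    expect_true(all(chi_cole_davidson(nu, d, tau, b) >= 0))
    expect_true(all(chi_dho(nu, d, n0, g) >= 0))
    expect_true(all(chi_power_law(nu, d, b) >= 0))
  }
})
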