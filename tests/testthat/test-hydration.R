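test_that("composition bookkeeping gives the documented mole ratios", {
  comp <- mixture_composition(lysozyme = 0.03, trehalose = 0.40, water = 0.57)
  expect_equal(water_lysozyme_ratio(comp), 15081.8762, tolerance = 1e-6)
  ## equal molar amounts give r = 1
  eq <- mixture_composition(lysozyme = 14300 / (14300 + 18.015),
                            trehalose = 0,
                            water = 18.015 / (14300 + 18.015))
  expect_equal(water_lysozyme_ratio(eq), 1, tolerance = 1e-9)
  ## doubling the water/lysozyme weight ratio doubles r
  a <- mixture_composition(lysozyme = 0.10, trehalose = 0.50, water = 0.40)
  b <- mixture_composition(lysozyme = 0.05, trehalose = 0.55, water = 0.40)
  expect_equal(water_lysozyme_ratio(b) / water_lysozyme_ratio(a), 2,
               tolerance = 1e-9)
  ## dihydrate bookkeeping: crystal water counted only on request
  d0 <- mixture_composition(lysozyme = 0.03, trehalose = 0.40, water = 0.57,
                            trehalose_form = "dihydrate")
  d1 <- mixture_composition(lysozyme = 0.03, trehalose = 0.40, water = 0.57,
                            trehalose_form = "dihydrate",
                            include_crystal_water = TRUE)
  expect_gt(water_lysozyme_ratio(d1), water_lysozyme_ratio(d0))
  expect_error(mixture_composition(0.5, 0.2, 0.2), "sum to 1")
  expect_error(water_lysozyme_ratio(
    mixture_composition(0, 0.4, 0.6)), "lysozyme")
})

test_that("hydration count follows the amplitude-fraction formula", {
  expect_equal(n_ultraslow(15000, c(ultraslow = 0.05, hydration = 0.25,
                                    bulk = 0.70)), 750)
  expect_equal(n_ultraslow(15000, c(ultraslow = 0, hydration = 0.3,
                                    bulk = 0.7)), 0)
  ## bounds: 0 <= N <= r for random amplitude draws
  set.seed(11)
  for (i in 1:50) {
    d <- runif(3)
    N <- n_ultraslow(1000, c(ultraslow = d[1], hydration = d[2],
                             bulk = d[3]))
    expect_gte(N, 0); expect_lte(N, 1000)
    ## scale invariance of the ratio statistic
    N2 <- n_ultraslow(1000, c(ultraslow = 7 * d[1], hydration = 7 * d[2],
                              bulk = 7 * d[3]))
    expect_equal(N, N2, tolerance = 1e-12)
  }
  expect_error(n_ultraslow(100, c(ultraslow = 0, hydration = 0, bulk = 0)),
               "zero")
})

test_that("retardation factor is a plain time ratio", {
  expect_equal(retardation_factor(6, 6), 1)
  expect_equal(retardation_factor(17, 1), 17)
  expect_error(retardation_factor(-1, 1))
})

test_that("Arrhenius regression is exact on clean input and flags noise", {
  T_C <- c(3.5, 10, 14.5, 25, 35)
  R <- 8.314462618
  tau <- 2 * exp(9000 / R * (1 / (T_C + 273.15)))
  fit <- arrhenius_activation_energy(T_C, tau)
  expect_equal(fit$Ea_kJmol, 9, tolerance = 1e-10)
  expect_equal(fit$se_kJmol, 0, tolerance = 1e-8)
  ## temperature-independent times give zero activation energy
  flat <- arrhenius_activation_energy(T_C, rep(3, 5))
  expect_equal(flat$Ea_kJmol, 0, tolerance = 1e-12)
  expect_error(arrhenius_activation_energy(c(1, 2), c(1, 2)), "3 distinct")
})

test_that("hydration summary aggregates a temperature series", {
  ## cheap series: noiseless, reduced grid
  wtls <- simulate_edls_series("WTL", noise = 0, n = 400)
  wts <- simulate_edls_series("WT", noise = 0, n = 400)
  comp <- mixture_composition(lysozyme = 0.03, trehalose = 0.40,
                              water = 0.57)
  hs <- suppressWarnings(hydration_series(wtls, wts, comp))
  sm <- hs$summary
  expect_s3_class(sm, "hydration_summary")
  expect_equal(nrow(sm$table), 5)
  ## generator holds the shell size constant: SD tiny, trend flat
  expect_equal(sm$N_mean, 710, tolerance = 0.01)
  expect_lt(sm$N_sd / sm$N_mean, 0.01)
  expect_gt(sm$trend$p_value, 0.05)
  ## per-process activation energies recovered from the fitted times
  expect_equal(sm$Ea$bulk$Ea_kJmol, 8, tolerance = 0.02)
  expect_equal(sm$Ea$hydration$Ea_kJmol, 9, tolerance = 0.02)
  expect_equal(sm$Ea$ultraslow$Ea_kJmol, 10, tolerance = 0.05)
  ## columns of the summary table
  expect_true(all(c("T_C", "N_ultraslow", "xi_hydration", "xi_ultraslow")
                  %in% names(sm$table)))
})
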