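## Stage fits on noiseless generator output: the model class contains the
## truth, so recovery must be essentially exact.

test_that("binary fit recovers the generator parameters on clean data", {
  s <- simulate_edls("WT", 25, noise = 0, seed = 1, n = 400)
  fit <- fit_wt(s)
  truth <- c(rotation.delta = 3, rotation.tau = 300, bulk.delta = 0.58,
             bulk.tau = 1, hydration.delta = 0.42, hydration.rho = 6,
             bending.delta = 0.35, bending.nu0 = 1.5, bending.gamma = 1.4,
             stretching.delta = 0.70, stretching.nu0 = 5.1,
             stretching.gamma = 2.6, raman1.delta = 2, raman1.nu0 = 14,
             raman1.gamma = 2, raman2.delta = 1.6, raman2.nu0 = 20,
             raman2.gamma = 2.5)
  est <- coef(fit)[names(truth)]
  expect_lt(max(abs(est / truth - 1)), 0.01)
  ## derived retardation factor and ordering constraint
  taus <- water_taus(fit)
  expect_gte(taus[["hydration"]] / taus[["bulk"]], 2)
  expect_equal(unname(taus[["hydration"]] / taus[["bulk"]]), 6,
               tolerance = 1e-4)
})

test_that("pure-water fit recovers the Cole-Davidson shape when free", {
  s <- simulate_edls("W", 25, noise = 0, seed = 2, n = 400)
  fit <- fit_water(s, beta_free = TRUE)
  expect_equal(coef(fit)[["bulk.beta"]], 0.6, tolerance = 1e-3)
  expect_equal(coef(fit)[["bulk.tau"]], 1.0, tolerance = 1e-3)
})

test_that("fit methods are coherent", {
  s <- simulate_edls("W", 25, noise = 0.02, seed = 3, n = 300)
  fit <- fit_water(s, beta_free = FALSE)
  expect_equal(length(fitted(fit)), length(residuals(fit)))
  expect_equal(fitted(fit) + residuals(fit), fit$obs, tolerance = 1e-12)
  ## predict on the fitted grid reproduces fitted values
  expect_equal(predict(fit), fitted(fit), tolerance = 1e-12)
  ## group prediction sums to total
  tot <- predict(fit, group = "total")
  expect_equal(predict(fit, group = "SR") + predict(fit, group = "WR") +
                 predict(fit, group = "VIB"), tot, tolerance = 1e-10)
  expect_error(predict(fit, group = "nope"), "unknown group")
  ## simulate draws around the fitted curve with the residual noise scale
  sim <- simulate(fit, nsim = 3, seed = 1)
  expect_equal(dim(sim), c(length(fitted(fit)), 3L))
  expect_s3_class(summary(fit), "summary.edls_fit")
})

test_that("difference spectrum isolates the protein contribution", {
  wtl <- simulate_edls("WTL", 25, noise = 0, seed = 1, n = 400)
  wt <- simulate_edls("WT", 25, noise = 0, seed = 2, n = 400)
  ## equal inputs give the zero spectrum
  z <- difference_spectrum(wtl, wtl)
  expect_lt(max(abs(z$value)), 1e-12 * max(wtl$value))
  ds <- difference_spectrum(wtl, wt)
  protein <- model_subset(attr(wtl, "truth_model"),
                          labels = c("relaxation_pl", "ultraslow",
                                     "bo1", "bo2", "bo3"))
  scale <- attr(normalize_to_band(wtl), "band_integral")
  expect_equal(ds$value,
               evaluate_model(protein, ds$frequency, unit = "GHz")$value /
                 scale,
               tolerance = 2e-3)
  ## low-frequency flank of the DS decays roughly as nu^-0.3 (the
  ## ultraslow and oscillator onsets flatten it slightly)
  nu <- convert_frequency(ds$frequency, ds$unit, "THz")
  lo <- nu < 1.5e-3
  slope <- coef(lm(log(ds$value[lo]) ~ log(nu[lo])))[[2]]
  expect_equal(slope, -0.3, tolerance = 0.25)
})

test_that("normalization to the high-frequency band is idempotent", {
  s <- simulate_edls("WT", 25, noise = 0, n = 300)
  n1 <- normalize_to_band(s)
  n2 <- normalize_to_band(n1)
  expect_equal(n1$value, n2$value, tolerance = 1e-12)
  s2 <- s; s2$value <- 7.3 * s$value
  expect_equal(normalize_to_band(s2)$value, n1$value, tolerance = 1e-12)
})

test_that("staged ternary pipeline is exact on clean data", {
  wtl <- simulate_edls("WTL", 25, noise = 0, seed = 1, n = 400)
  wt <- simulate_edls("WT", 25, noise = 0, seed = 2, n = 400)
  pp <- suppressWarnings(ternary_pipeline(wtl, wt))
  fr <- amplitude_fractions(pp$ternary_fit)
  truth <- c(bulk = 0.58, hydration = 0.42, ultraslow = 0.0494027)
  truth <- truth / sum(truth)
  expect_lt(max(abs(fr[names(truth)] / truth - 1)), 0.01)
  taus <- water_taus(pp$ternary_fit)
  expect_equal(unname(taus[["ultraslow"]] / taus[["bulk"]]), 17,
               tolerance = 0.02)
  ## fit additivity at the optimum
  ev <- evaluate_model(pp$ternary_fit$model, pp$ternary_fit$nu_THz,
                       unit = "THz")
  expect_equal(rowSums(attr(ev, "partials")), ev$value, tolerance = 1e-12)
})

test_that("staged and direct ternary fits agree on clean data", {
  wtl <- simulate_edls("WTL", 25, noise = 0, seed = 1, n = 400)
  wt <- simulate_edls("WT", 25, noise = 0, seed = 2, n = 400)
  pp <- suppressWarnings(ternary_pipeline(wtl, wt))
  direct <- suppressWarnings(fit_wtl_direct(normalize_to_band(wtl)))
  fs <- amplitude_fractions(pp$ternary_fit)
  fd <- amplitude_fractions(direct)
  expect_lt(max(abs(fd / fs - 1)), 0.05)
})

test_that("removing the ultraslow component degrades the ternary fit only", {
  wtl <- simulate_edls("WTL", 25, noise = 0.01, seed = 4, n = 400)
  wt <- simulate_edls("WT", 25, noise = 0.01, seed = 5, n = 400)
  pp <- suppressWarnings(ternary_pipeline(wtl, wt))
  ds_fit0 <- pp$ds_fit
  ds_fit0$par[["ultraslow.delta"]] <- 1e-12
  without <- suppressWarnings(fit_ternary(normalize_to_band(wtl), pp$wt_fit,
                                          ds_fit0))
  expect_gt(deviance(without), deviance(pp$ternary_fit))
  ## the binary system needs no ultraslow term: its fit is already clean
  expect_lt(deviance(pp$wt_fit) / length(pp$wt_fit$obs), 2e-4)
})

test_that("vibrational isolation recovers the generator VIB group", {
  s <- simulate_edls("WT", 25, noise = 0, seed = 6, n = 400)
  fit <- fit_wt(s)
  vib <- isolate_vibrational(s, fit)
  truth_vib <- attr(s, "groups")[, "VIB"]
  expect_equal(vib$value, truth_vib, tolerance = 0.02 * max(truth_vib))
  ## provenance check triggers on mismatched spectra
  other <- simulate_edls("WTL", 25, noise = 0, n = 400)
  expect_error(isolate_vibrational(other, fit), "provenance")
  ## refit of the isolated profile recovers the two water modes
  fv <- suppressWarnings(
    fit_vibrational(vib, subtract_model = model_subset(fit$model,
                                                       labels = c("raman1",
                                                                  "raman2"))))
  expect_equal(coef(fv)[["bending.nu0"]], 1.5, tolerance = 0.01)
  expect_equal(coef(fv)[["stretching.nu0"]], 5.1, tolerance = 0.01)
})

test_that("master-curve distance is zero for scaled copies", {
  s <- simulate_edls("WT", 25, noise = 0, n = 300)
  fit <- fit_wt(s)
  vib <- isolate_vibrational(s, fit)
  expect_equal(master_curve_distance(vib, vib), 0, tolerance = 1e-12)
  v2 <- vib; v2$value <- 5 * vib$value
  expect_equal(master_curve_distance(vib, v2), 0, tolerance = 1e-12)
})

test_that("segment joining validates overlap and metadata", {
  seg <- simulate_edls("WT", 25, noise = 0, seed = 7, segments = TRUE)
  joined <- join_segments(seg$low, seg$high,
                          background = c(attr(seg$low, "background"),
                                         attr(seg$high, "background")))
  expect_equal(joined$meta$temperature, 25)
  ## low = c * high over the full range joins back to high
  g <- exp(seq(log(1), log(100), length.out = 80))
  base <- spectrum(g, chi_debye(g / 1000, 1, 50), unit = "GHz",
                   temperature = 10)
  low <- spectrum(g[g <= 40], 3.3 * base$value[g <= 40], unit = "GHz",
                  temperature = 10)
  high <- spectrum(g[g >= 10], base$value[g >= 10], unit = "GHz",
                   temperature = 10)
  j <- join_segments(low, high)
  ref <- approx(log(base$frequency), log(base$value),
                xout = log(j$frequency))$y
  expect_lt(max(abs(j$value / exp(ref) - 1)), 1e-6)
  expect_equal(attr(j, "scale_ratio"), 3.3, tolerance = 1e-9)
  ## disjoint segments are rejected
  expect_error(join_segments(spectrum(1:10, 1:10, unit = "GHz"),
                             spectrum(100:110, 1:11, unit = "GHz")),
               "overlap")
})
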