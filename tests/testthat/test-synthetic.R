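test_that("generator is deterministic and noiseless output equals the model", {
  a <- simulate_edls("WT", 25, noise = 0.02, seed = 42, n = 200)
  b <- simulate_edls("WT", 25, noise = 0.02, seed = 42, n = 200)
  expect_identical(a$value, b$value)
  clean <- simulate_edls("WT", 25, noise = 0, seed = 1, n = 200)
  model_vals <- evaluate_model(attr(clean, "truth_model"),
                               clean$frequency, unit = "GHz")$value
  expect_equal(clean$value, model_vals, tolerance = 1e-14)
  ## ground-truth record regenerates the noiseless spectrum
  gt <- attr(clean, "ground_truth")
  expect_true(all(c("label", "param", "value") %in% names(gt)))
})

test_that("multiplicative noise has the requested relative scale", {
  clean <- simulate_edls("WT", 25, noise = 0, n = 12000)
  noisy <- simulate_edls("WT", 25, noise = 0.02, seed = 3, n = 12000)
  rel <- noisy$value / clean$value - 1
  expect_equal(sd(rel), 0.02, tolerance = 0.1 * 0.02 / 0.02)  # within 10%
})

test_that("ternary preset is the binary preset plus the protein terms", {
  wtl <- simulate_edls("WTL", 14.5, noise = 0, n = 300)
  wt <- simulate_edls("WT", 14.5, noise = 0, n = 300)
  protein <- model_subset(attr(wtl, "truth_model"),
                          labels = c("relaxation_pl", "ultraslow",
                                     "bo1", "bo2", "bo3"))
  diff_vals <- wtl$value - wt$value
  expect_equal(diff_vals,
               evaluate_model(protein, wtl$frequency, unit = "GHz")$value,
               tolerance = 1e-12)
  ## inventory inclusion: every WT component kind appears in WTL
  wt_labels <- model_labels(attr(wt, "truth_model"))
  wtl_labels <- model_labels(attr(wtl, "truth_model"))
  expect_true(all(wt_labels %in% wtl_labels))
  ## ultraslow/bulk and hydration/bulk retardations at the reference
  ## temperature (activation energies differ, so ratios drift with T)
  tm <- preset_model(edls_preset("WTL"), 25)
  expect_equal(model_param(tm, "hydration", "tau") /
                 model_param(tm, "bulk", "tau"), 6, tolerance = 1e-12)
  rat <- model_param(tm, "ultraslow", "tau") / model_param(tm, "bulk", "tau")
  expect_gte(rat, 15); expect_lte(rat, 20)
})

test_that("two-segment mode overlaps >= half a decade and rejoins", {
  seg <- simulate_edls("WT", 25, noise = 0, seed = 5, segments = TRUE)
  overlap <- log10(max(seg$low$frequency) / min(seg$high$frequency))
  expect_gte(overlap, 0.5)
  joined <- join_segments(seg$low, seg$high,
                          background = c(attr(seg$low, "background"),
                                         attr(seg$high, "background")))
  ref <- seg$reference
  jv <- approx(log(joined$frequency), log(joined$value),
               xout = log(ref$frequency), rule = 2)$y
  ## log-grid interpolation error only
  expect_lt(max(abs(exp(jv) / ref$value - 1)), 0.06)
})

test_that("temperature series follows the preset Arrhenius law exactly", {
  preset <- edls_preset("WTL")
  temps <- preset$temperatures
  taus <- sapply(temps, function(T_C) {
    model <- preset_model(preset, T_C)
    model_param(model, "hydration", "tau")
  })
  fit <- arrhenius_activation_energy(temps, taus)
  expect_equal(fit$Ea_kJmol, 9.0, tolerance = 1e-10)
  ## ln tau vs 1/T exactly linear
  expect_lt(max(abs(residuals(fit$fit))), 1e-12)
  ## ultraslow amplitude fraction is temperature-independent
  fr <- sapply(temps, function(T_C) {
    m <- preset_model(preset, T_C)
    amplitude_fractions(m)[["ultraslow"]]
  })
  expect_equal(max(fr) - min(fr), 0, tolerance = 1e-14)
})

test_that("ternary composition yields the documented water/lysozyme ratio", {
  comp <- mixture_composition(lysozyme = 0.03, trehalose = 0.40, water = 0.57)
  expect_equal(water_lysozyme_ratio(comp), 15081.876214, tolerance = 1e-6)
})

test_that("FTIR generator builds solutions additively over their solvent", {
  wl <- simulate_ftir("WL", offset = 0)
  gt <- attr(wl, "ground_truth")
  expect_equal(wl$value,
               gt$factor * gt$solvent$value + gt$sc_true$value,
               tolerance = 1e-12)
  ## ternary solvent is the binary sugar solution
  wtl <- simulate_ftir("WTL", offset = 0)
  expect_identical(attr(wtl, "ground_truth")$solvent$meta$system, "WT")
  ## amide bands only in protein systems; trehalose fingerprint confined
  w_bands <- ftir_preset("W")$bands
  expect_false(any(grepl("amide", w_bands$assignment)))
  tre <- ftir_preset("WT")$bands
  fp <- tre[tre$assignment == "trehalose_fingerprint", ]
  expect_true(all(fp$center >= 1000 & fp$center <= 1500))
  expect_error(simulate_ftir(list(system = "x", solvent = NULL,
                                  displacement = 0,
                                  bands = band_table <- data.frame(
                                    center = 1000, hwhm = 10,
                                    amplitude = -1, assignment = "a",
                                    eta = 0.1))),
               "amplitude")
  ## determinism under a seed
  n1 <- simulate_ftir("WL", noise = 0.002, seed = 9)
  n2 <- simulate_ftir("WL", noise = 0.002, seed = 9)
  expect_identical(n1$value, n2$value)
})
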