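test_that("baseline offset removal round-trips a constant", {
  f <- make_additive_ftir()
  s <- f$solution
  shifted <- s; shifted$value <- s$value + 0.37
  corrected <- baseline_offset(shifted)
  expect_equal(corrected$value, baseline_offset(s)$value, tolerance = 1e-12)
  ## already-zero baseline over the quiet window: identity
  i <- which(s$frequency >= 1800 & s$frequency <= 2500)
  s0 <- s; s0$value <- s$value - min(s$value[i])
  expect_equal(baseline_offset(s0)$value, s0$value, tolerance = 1e-14)
  expect_error(baseline_offset(s, window = c(9000, 9500)), "window")
  ## generator offset removed exactly (noiseless, quiet window clean)
  wl <- simulate_ftir("WL", offset = 0.05)
  base <- simulate_ftir("WL", offset = 0)
  expect_equal(baseline_offset(wl)$value, baseline_offset(base)$value,
               tolerance = 1e-12)
})

test_that("rescaling factor is exact for additive constructions", {
  for (c0 in c(0.3, 0.8, 0.95)) {
    f <- make_additive_ftir(c0)
    r <- find_rescaling_factor(f$solution, f$solvent, tolerance = 0)
    expect_equal(r$factor, c0, tolerance = 2e-6)
    sc <- extract_scir(f$solution, f$solvent, factor = r$factor)
    expect_lt(max(abs(sc$sc_spectrum$value - f$sc_true$value)),
              1e-5 * max(f$sc_true$value))
  }
  ## solution == solvent: factor 1 and empty SC spectrum
  f <- make_additive_ftir()
  r <- find_rescaling_factor(f$solvent, f$solvent, tolerance = 0)
  expect_equal(r$factor, 1, tolerance = 2e-6)
  sc <- extract_scir(f$solvent, f$solvent, factor = r$factor)
  expect_lt(max(abs(sc$sc_spectrum$value)), 1e-5)
  expect_error(find_rescaling_factor(
    f$solution, spectrum(f$grid, rep(0, length(f$grid)), unit = "cm-1")),
    "empty")
})

test_that("larger tolerance never decreases the factor; minimality holds", {
  f <- make_additive_ftir(0.7)
  tols <- c(0, 1e-4, 1e-3, 1e-2)
  cs <- sapply(tols, function(tol)
    find_rescaling_factor(f$solution, f$solvent, tolerance = tol)$factor)
  expect_true(all(diff(cs) >= -1e-9))
  ## minimality certificate: a noticeably larger factor violates the
  ## negativity constraint on the search grid
  r <- find_rescaling_factor(f$solution, f$solvent, tolerance = 1e-4)
  mask <- r$mask
  bigger <- f$solution$value - (r$factor * 1.01) * f$solvent$value
  expect_lt(min(bigger[mask]), -1e-4)
})

test_that("SC extraction finds protein bands and compensates sugar", {
  wl <- baseline_offset(simulate_ftir("WL"))
  w <- baseline_offset(simulate_ftir("W"))
  sc <- extract_scir(wl, w)
  bm <- sc$band_metrics
  expect_equal(bm$peak_position[bm$window == "amide_I"], 1650, tolerance = 2)
  expect_equal(bm$peak_position[bm$window == "amide_II"], 1550, tolerance = 2)
  expect_gte(sc$negativity, -sc$tolerance - 1e-12)
  ## ternary against the binary solvent: trehalose bands cancel
  wtl <- baseline_offset(simulate_ftir("WTL"))
  wt <- baseline_offset(simulate_ftir("WT"))
  sc2 <- extract_scir(wtl, wt)
  a_sc <- band_metrics(sc2$sc_spectrum, list(w = c(1000, 1500)))$area
  a_tot <- band_metrics(wtl, list(w = c(1000, 1500)))$area
  expect_lt(a_sc / a_tot, 0.05)
  ## zero-solute control: SC below the noise floor
  w2 <- baseline_offset(simulate_ftir("W", noise = 1e-3, seed = 8))
  sc0 <- extract_scir(w2, w)
  expect_lt(max(abs(sc0$sc_spectrum$value)), 8e-3)
})

test_that("normalization modes are idempotent and scale-invariant", {
  f <- make_additive_ftir()
  s <- f$solution
  for (mode in c("max", "band_area")) {
    n1 <- normalize_spectrum(s, mode)
    expect_equal(normalize_spectrum(n1, mode)$value, n1$value,
                 tolerance = 1e-12)
    s2 <- s; s2$value <- 4.2 * s$value
    expect_equal(normalize_spectrum(s2, mode)$value, n1$value,
                 tolerance = 1e-12)
  }
  expect_equal(max(normalize_spectrum(s, "max")$value), 1)
  nb <- normalize_spectrum(s, "band_area", window = c(1480, 1720))
  i <- which(nb$frequency >= 1480 & nb$frequency <= 1720)
  x <- nb$frequency[i]; y <- nb$value[i]
  expect_equal(sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2), 1,
               tolerance = 1e-9)
  expect_error(normalize_spectrum(
    spectrum(1:10, rep(0, 10), unit = "cm-1")), "zero")
})

test_that("band metrics locate peaks and respect normalization", {
  g <- seq(1000, 2000, by = 2)
  s <- spectrum(g, exp(-log(2) * ((g - 1650) / 40)^2), unit = "cm-1")
  m <- band_metrics(s, list(amide_I = c(1600, 1700)))
  expect_equal(m$peak_position, 1650, tolerance = 2)
  ## peak positions invariant under normalization mode
  wl <- baseline_offset(simulate_ftir("WL"))
  w <- baseline_offset(simulate_ftir("W"))
  sc <- extract_scir(wl, w)
  p1 <- band_metrics(normalize_spectrum(sc$sc_spectrum, "max"))
  p2 <- band_metrics(normalize_spectrum(sc$sc_spectrum, "band_area"))
  expect_equal(p1$peak_position, p2$peak_position, tolerance = 1e-9)
  expect_error(band_metrics(s, list(x = c(5000, 6000))), "window")
})

test_that("ternary shell holds less perturbed water than the binary", {
  wl <- baseline_offset(simulate_ftir("WL"))
  w <- baseline_offset(simulate_ftir("W"))
  wtl <- baseline_offset(simulate_ftir("WTL"))
  wt <- baseline_offset(simulate_ftir("WT"))
  cmp <- compare_scir(extract_scir(wl, w), extract_scir(wtl, wt))
  expect_lt(cmp$ratio, 1)
  ## SC OH distribution shifted to lower frequency than the solvent's
  sc <- extract_scir(wl, w)
  oh_sc <- band_metrics(sc$sc_spectrum, list(OH = c(3000, 3700)))
  oh_w <- band_metrics(w, list(OH = c(3000, 3700)))
  expect_lt(oh_sc$peak_position, oh_w$peak_position)
})
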