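## Spectrum-level processing around the fits: segment joining,
## vibration-band normalization, difference spectra, vibrational
## isolation and master-curve comparison.

#' Join two overlapping instrument segments
#'
#' Subtracts a constant background per segment, computes the median
#' low/high ratio over the overlap region, rescales the low-frequency
#' segment onto the high-frequency segment's intensity scale, and merges
#' both onto a unified log-spaced grid (linear interpolation in
#' log-frequency / log-value space; a log-frequency ramp blends the two
#' segments across the overlap).
#'
#' @param low,high [spectrum()] objects with overlapping ranges (same
#'   unit), e.g. the 0.6-90 GHz interferometric and 60-36000 GHz
#'   dispersive segments.
#' @param background length-2 numeric: constant background of `low` and
#'   `high` (default none).
#' @param n size of the output grid (default combined input size).
#' @return merged spectrum on the high segment's scale; attribute
#'   `"scale_ratio"` holds the applied low/high median ratio.
#' @export
join_segments <- function(low, high, background = c(0, 0), n = NULL) {
  stopifnot(inherits(low, "spectrum"), inherits(high, "spectrum"))
  if (low$unit != high$unit) high <- convert_frequency(high, high$unit, low$unit)
  tl <- low$meta$temperature; th <- high$meta$temperature
  if (is.finite(tl) && is.finite(th) && abs(tl - th) > 1e-9)
    stop("segments were measured at different temperatures", call. = FALSE)
  low$value <- low$value - background[1]
  high$value <- high$value - background[2]
  o_lo <- max(min(low$frequency), min(high$frequency))
  o_hi <- min(max(low$frequency), max(high$frequency))
  if (!(o_hi > o_lo)) stop("segments do not overlap", call. = FALSE)
  i <- which(low$frequency >= o_lo & low$frequency <= o_hi)
  if (length(i) < 5)
    stop("overlap region has fewer than 5 points", call. = FALSE)
  hi_on_lo <- interp_spectrum(high, low$frequency[i])
  ratio <- stats::median(low$value[i] / hi_on_lo)
  if (!is.finite(ratio) || ratio <= 0)
    stop("non-positive segment intensity ratio", call. = FALSE)
  low$value <- low$value / ratio
  if (is.null(n)) n <- length(low$frequency) + length(high$frequency)
  g <- exp(seq(log(min(low$frequency)), log(max(high$frequency)),
               length.out = n))
  v <- numeric(length(g))
  in_low <- g <= o_lo
  in_high <- g >= o_hi
  mid <- !(in_low | in_high)
  v[in_low] <- interp_spectrum(low, g[in_low])
  v[in_high] <- interp_spectrum(high, g[in_high])
  if (any(mid)) {
    wgt <- (log(g[mid]) - log(o_lo)) / (log(o_hi) - log(o_lo))
    v[mid] <- (1 - wgt) * interp_spectrum(low, g[mid]) +
      wgt * interp_spectrum(high, g[mid])
  }
  out <- spectrum(g, v, unit = low$unit,
                  temperature = if (is.finite(tl)) tl else th,
                  system = high$meta$system %||% low$meta$system,
                  technique = high$meta$technique)
  attr(out, "scale_ratio") <- ratio
  out
}

#' Normalize a susceptibility spectrum to its high-frequency band
#'
#' Divides by the integrated intensity over `band` (default everything
#' above 10 THz, the solute Raman modes), so that spectra of different
#' overall intensity become comparable before subtraction.  Idempotent:
#' the band integral of the output is 1.
#'
#' @param s a [spectrum()].
#' @param band two-element band in THz.
#' @return normalized spectrum; attribute `"band_integral"` holds the
#'   divisor.
#' @export
normalize_to_band <- function(s, band = c(10, Inf)) {
  stopifnot(inherits(s, "spectrum"))
  nu <- freq_THz(s)
  st <- spectrum(nu, s$value, unit = "THz")
  z <- integrate_band(st, band[1], band[2])
  if (!is.finite(z) || z <= 0)
    stop("band integral is not positive", call. = FALSE)
  s$value <- s$value / z
  attr(s, "band_integral") <- z
  s
}

#' Difference spectrum of ternary minus binary solution
#'
#' After common normalization to the >10 THz solute Raman band, subtracts
#' the binary spectrum from the ternary one on the ternary grid, exposing
#' the protein-associated contributions (power-law structural relaxation,
#' protein vibrational modes and the ultraslow water component).  The
#' residual matching factor between the two normalized spectra is
#' determined by least squares over the band, allowing a smooth additive
#' background there: the protein structural-relaxation tail extends into
#' the normalization band, and absorbing it into the match (rather than
#' into the integral ratio) keeps the subtraction from suppressing the
#' protein contribution.  Negative excursions are retained.
#'
#' @param wtl,wt ternary and binary susceptibility [spectrum()] objects.
#' @param normalize apply [normalize_to_band()] to both inputs first.
#' @param band normalization/matching band in THz.
#' @param factor optional explicit scale applied to `wt` instead of the
#'   band match.
#' @return difference spectrum (system label `"DS"`); attribute
#'   `"provenance"` records the inputs, normalization and factor.
#' @export
difference_spectrum <- function(wtl, wt, normalize = TRUE,
                                band = c(10, Inf), factor = NULL) {
  stopifnot(inherits(wtl, "spectrum"), inherits(wt, "spectrum"))
  if (normalize) {
    wtl <- normalize_to_band(wtl, band)
    wt <- normalize_to_band(wt, band)
  }
  lo <- max(min(freq_THz(wtl)), min(freq_THz(wt)))
  hi <- min(max(freq_THz(wtl)), max(freq_THz(wt)))
  if (!(hi > lo)) stop("spectra do not overlap in frequency", call. = FALSE)
  nu <- freq_THz(wtl)
  keep <- nu >= lo & nu <= hi
  wt_on_wtl <- interp_spectrum(wt, convert_frequency(nu[keep], "THz", wt$unit))
  if (is.null(factor)) {
    ib <- which(nu[keep] >= band[1] & nu[keep] <= band[2])
    if (length(ib) >= 5) {
      X <- cbind(wt = wt_on_wtl[ib], 1, log(nu[keep][ib]))
      factor <- stats::lm.fit(X, wtl$value[keep][ib])$coefficients[["wt"]]
    } else factor <- 1
    if (!is.finite(factor) || factor <= 0) factor <- 1
  }
  out <- spectrum(wtl$frequency[keep], wtl$value[keep] - factor * wt_on_wtl,
                  unit = wtl$unit, temperature = wtl$meta$temperature,
                  system = "DS", technique = "DLS_susceptibility")
  attr(out, "provenance") <- list(minuend = wtl$meta$system,
                                  subtrahend = wt$meta$system,
                                  normalized = normalize, band = band,
                                  factor = factor)
  ## normalized parent, reused as the weight reference when fitting
  attr(out, "parent") <- spectrum(wtl$frequency[keep], wtl$value[keep],
                                  unit = wtl$unit,
                                  temperature = wtl$meta$temperature,
                                  system = wtl$meta$system,
                                  technique = "DLS_susceptibility")
  out
}

#' Isolate the vibrational part of a spectrum
#'
#' Subtracts the fitted relaxation tails (SR and WR groups) from the
#' measured spectrum, leaving the vibrational profile
#' \eqn{\chi''_{VIB}}.
#'
#' @param s the susceptibility [spectrum()] the fit was obtained from.
#' @param fit the corresponding converged `"edls_fit"`.
#' @param check verify that `s` matches the fitted data (system and
#'   temperature).
#' @return vibrational spectrum on the grid of `s`.
#' @export
isolate_vibrational <- function(s, fit, check = TRUE) {
  stopifnot(inherits(s, "spectrum"), inherits(fit, "edls_fit"))
  if (check) {
    fm <- fit$data$meta
    same <- identical(fm$system, s$meta$system) &&
      (is.na(fm$temperature) || is.na(s$meta$temperature) ||
         abs(fm$temperature - s$meta$temperature) < 1e-9)
    if (!same)
      stop("fit provenance does not match this spectrum", call. = FALSE)
  }
  relax <- predict(fit, s$frequency, unit = s$unit, group = "SR") +
    predict(fit, s$frequency, unit = s$unit, group = "WR")
  out <- s
  out$value <- s$value - relax
  out$meta$technique <- "DLS_susceptibility"
  out
}

#' Fit the two-mode vibrational profile
#'
#' Fits the isolated vibrational spectrum with two DHO bands (the H-bond
#' bending and stretching modes).  Components of `subtract_model` (e.g.
#' the fitted solute Raman bands) are removed from the data first.
#'
#' @param vib vibrational [spectrum()] from [isolate_vibrational()].
#' @param subtract_model optional [susceptibility_model()] evaluated and
#'   subtracted before fitting.
#' @param window fit window in THz.
#' @return `"edls_fit"` with components `bending` and `stretching`.
#' @export
fit_vibrational <- function(vib, subtract_model = NULL, window = c(0.4, 9)) {
  stopifnot(inherits(vib, "spectrum"))
  s <- vib
  if (!is.null(subtract_model))
    s$value <- s$value - evaluate_model(subtract_model, s$frequency,
                                        unit = s$unit)$value
  nu_all <- freq_THz(s)
  keep <- nu_all >= window[1] & nu_all <= window[2]
  ## absolute residuals scaled by the band maximum: difference data can
  ## cross zero, so relative weights are not meaningful here
  w <- rep(1 / max(abs(s$value[keep])), length(nu_all))
  d <- prep_fit_data(s, window, weights = w)
  pk_lo <- interior_peak(d$nu, d$obs, window[1], 3)
  pk_hi <- interior_peak(d$nu, d$obs, 3, window[2])
  nu_b0 <- if (is.null(pk_lo)) 1.5 else pk_lo$nu
  nu_s0 <- if (is.null(pk_hi)) 5.0 else pk_hi$nu
  pars <- rbind(
    par_table("bending.delta", max(value_at(d$nu, pmax(d$obs, 1e-9), nu_b0) *
                                     1.4 / nu_b0 * 0.6, 1e-6), 1e-6, 100),
    par_table("bending.nu0", nu_b0, 0.8, 2.8),
    par_table("bending.gamma", 1.5, 0.3, 4),
    par_table("stretching.delta",
              max(value_at(d$nu, pmax(d$obs, 1e-9), nu_s0) *
                    2.6 / nu_s0 * 0.8, 1e-6), 1e-6, 100),
    par_table("stretching.nu0", nu_s0, 3.5, 7.5),
    par_table("stretching.gamma", 2.5, 0.8, 6))
  build <- function(p) susceptibility_model(
    model_component("dho", "VIB", "bending", delta = p[["bending.delta"]],
                    nu0 = p[["bending.nu0"]], gamma = p[["bending.gamma"]]),
    model_component("dho", "VIB", "stretching",
                    delta = p[["stretching.delta"]],
                    nu0 = p[["stretching.nu0"]],
                    gamma = p[["stretching.gamma"]]))
  eng <- fit_engine(d$nu, d$obs, d$w, pars, build)
  new_edls_fit(eng, s, d$nu, d$obs, d$w, window, "vibrational", idx = d$idx)
}

#' Shape distance between two spectra after max-normalization
#'
#' Both spectra are interpolated onto a common log grid over `window`,
#' scaled to unit maximum, and compared through an area-normalized L1
#' distance; 0 means the curves coincide up to a scale factor (a
#' master curve).
#'
#' @param a,b [spectrum()] objects.
#' @param window comparison window in THz.
#' @param n comparison grid size.
#' @return dimensionless distance >= 0.
#' @export
master_curve_distance <- function(a, b, window = c(0.4, 9), n = 200) {
  lo <- max(window[1], min(freq_THz(a)), min(freq_THz(b)))
  hi <- min(window[2], max(freq_THz(a)), max(freq_THz(b)))
  if (!(hi > lo)) stop("windows do not overlap", call. = FALSE)
  g <- exp(seq(log(lo), log(hi), length.out = n))
  va <- interp_spectrum(spectrum(freq_THz(a), a$value, unit = "THz"), g,
                        log_value = FALSE)
  vb <- interp_spectrum(spectrum(freq_THz(b), b$value, unit = "THz"), g,
                        log_value = FALSE)
  va <- va / max(va); vb <- vb / max(vb)
  num <- sum(diff(g) * (abs(va - vb)[-1] + abs(va - vb)[-n]) / 2)
  den <- sum(diff(g) * (((va + vb) / 2)[-1] + ((va + vb) / 2)[-n]) / 2)
  num / den
}
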