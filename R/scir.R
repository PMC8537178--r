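## Solute-correlated infrared (SC-IR) spectrum extraction by direct
## spectral subtraction: SC = solution - c * solvent, with the rescaling
## factor c chosen as the largest value for which the difference stays
## above -tolerance everywhere.  Because the SC area is monotonically
## decreasing in c (solvent >= 0), this is exactly the non-negative
## spectrum of minimum area.

#' Baseline correction by constant-offset subtraction
#'
#' Subtracts the minimum value over a quiet window (default
#' 1800-2500 cm-1, where aqueous spectra carry almost no bands) so the
#' corrected spectrum has zero minimum over that window.
#'
#' @param s a [spectrum()] in cm-1.
#' @param window two-element window (cm-1) used to locate the baseline.
#' @return baseline-corrected spectrum.
#' @export
baseline_offset <- function(s, window = c(1800, 2500)) {
  stopifnot(inherits(s, "spectrum"))
  i <- which(s$frequency >= window[1] & s$frequency <= window[2])
  if (!length(i)) stop("baseline window outside the grid", call. = FALSE)
  s$value <- s$value - min(s$value[i])
  s
}

## robust noise scale from a quiet window: SD of first differences / sqrt(2)
estimate_noise <- function(s, window = c(1800, 2500)) {
  i <- which(s$frequency >= window[1] & s$frequency <= window[2])
  if (length(i) < 8) return(0)
  stats::mad(diff(s$value[i])) / sqrt(2)
}

#' Find the solvent rescaling factor for SC-IR subtraction
#'
#' Determines, by bisection to a relative precision of 1e-6, the largest
#' factor `c` such that `solution - c * solvent >= -tolerance` at every
#' point of the search grid: the channels where the corrected solvent
#' carries real signal (at least `support_frac` of its maximum).  On that
#' grid the feasible set is an interval and the resulting difference is
#' the non-negative spectral distribution with minimum area; channels
#' with essentially no solvent signal cannot determine the factor and
#' only carry baseline-correction residue.
#'
#' @param solution,solvent baseline-corrected [spectrum()] objects on a
#'   common grid.
#' @param support_frac fraction of the solvent maximum defining the
#'   search grid.
#' @param tolerance negativity tolerance; default 0.5 x the robust noise
#'   SD estimated from the 1800-2500 cm-1 window of the solution, plus a
#'   floor of 0.2% of the solution maximum that absorbs the band-tail
#'   mismatch left by constant-offset baseline correction.  Pass `0` for
#'   exact subtraction of additively constructed spectra.
#' @return list with `factor`, `tolerance` and the bisection interval
#'   width `precision`.
#' @export
find_rescaling_factor <- function(solution, solvent, tolerance = NULL,
                                  support_frac = 0.01) {
  stopifnot(inherits(solution, "spectrum"), inherits(solvent, "spectrum"))
  if (length(solution$frequency) != length(solvent$frequency) ||
      max(abs(solution$frequency - solvent$frequency)) > 1e-8)
    stop("solution and solvent must share one grid", call. = FALSE)
  if (all(solvent$value <= 0)) stop("solvent spectrum is empty", call. = FALSE)
  if (is.null(tolerance))
    tolerance <- max(0.5 * estimate_noise(solution),
                     0.002 * max(solution$value))
  mask <- solvent$value > support_frac * max(solvent$value)
  sv <- solvent$value[mask]; so <- solution$value[mask]
  feasible <- function(c.) all(so - c. * sv >= -tolerance)
  lo <- 0
  hi <- max(1, max(so) / max(sv)) * 2
  while (feasible(hi)) hi <- hi * 2          # bracket from above
  if (!feasible(lo)) return(list(factor = 0, tolerance = tolerance,
                                 precision = 0, mask = mask))
  repeat {
    mid <- (lo + hi) / 2
    if (feasible(mid)) lo <- mid else hi <- mid
    if ((hi - lo) <= 1e-6 * max(lo, 1e-12) || (hi - lo) < 1e-15) break
  }
  list(factor = lo, tolerance = tolerance, precision = hi - lo, mask = mask)
}

#' Extract the solute-correlated infrared spectrum
#'
#' Computes `SC = solution - c * solvent` and derives band metrics.  For a
#' ternary solution the solvent is the binary sugar-water spectrum (the
#' protein solvation medium); the sugar bands then cancel in the SC
#' spectrum.
#'
#' @inheritParams find_rescaling_factor
#' @param factor rescaling factor; defaults to [find_rescaling_factor()].
#' @param windows named list of band windows (cm-1) passed to
#'   [band_metrics()].
#' @return object of class `"scir"`: factor, SC spectrum, integrated
#'   area, most-negative value, and band metrics.
#' @export
extract_scir <- function(solution, solvent, factor = NULL, tolerance = NULL,
                         windows = scir_windows()) {
  mask <- NULL
  if (is.null(factor)) {
    f <- find_rescaling_factor(solution, solvent, tolerance)
    factor <- f$factor
    tolerance <- f$tolerance
    mask <- f$mask
  }
  if (factor <= 0) stop("rescaling factor must be > 0", call. = FALSE)
  if (is.null(mask)) mask <- solvent$value > 0.01 * max(solvent$value)
  sc <- solution
  sc$value <- solution$value - factor * solvent$value
  sc$meta$system <- paste0("SC(", solution$meta$system %||% "?", ")")
  structure(list(factor = factor,
                 tolerance = tolerance %||% 0,
                 sc_spectrum = sc,
                 area = integrate_band(sc),
                 negativity = min(sc$value[mask]),
                 band_metrics = band_metrics(sc, windows),
                 solution = solution, solvent = solvent),
            class = "scir")
}

#' Default SC-IR band windows
#'
#' Amide I (1600-1700 cm-1), amide II (1500-1600 cm-1), the combined
#' amide window (1480-1720 cm-1) and the OH-stretch region
#' (3100-3600 cm-1).
#' @export
scir_windows <- function() list(
  amide_I = c(1600, 1700), amide_II = c(1500, 1600),
  amide_total = c(1480, 1720), OH_region = c(3100, 3600))

#' Band metrics over named windows
#'
#' For each window: the peak position (maximum refined by parabolic
#' interpolation through the three points around it), peak value and
#' trapezoidal integrated area.
#'
#' @param s a [spectrum()].
#' @param windows named list of two-element windows in the spectrum unit.
#' @return data.frame with one row per window.
#' @export
band_metrics <- function(s, windows = scir_windows()) {
  stopifnot(inherits(s, "spectrum"))
  rows <- lapply(names(windows), function(nm) {
    w <- windows[[nm]]
    i <- which(s$frequency >= w[1] & s$frequency <= w[2])
    if (length(i) < 3)
      stop(sprintf("window '%s' contains fewer than 3 points", nm),
           call. = FALSE)
    x <- s$frequency[i]; y <- s$value[i]
    k <- which.max(y)
    pos <- x[k]
    if (k > 1 && k < length(y)) {       # parabolic vertex through 3 points
      d1 <- (y[k + 1] - y[k - 1]) / 2
      d2 <- y[k + 1] - 2 * y[k] + y[k - 1]
      if (d2 < 0) pos <- x[k] - d1 / d2 * (x[k + 1] - x[k])
    }
    data.frame(window = nm, lo = w[1], hi = w[2], peak_position = pos,
               peak_value = y[k],
               area = sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Normalize a spectrum
#'
#' `mode = "max"` scales the peak to 1; `mode = "band_area"` scales the
#' integral over `window` to 1 (e.g. the combined amide I+II window for
#' comparing hydration-shell OH intensity between systems).  Both modes
#' are idempotent and scale-invariant.
#'
#' @param s a [spectrum()].
#' @param mode `"max"` or `"band_area"`.
#' @param window two-element window for `"band_area"` (default the
#'   combined amide window, 1480-1720 cm-1).
#' @return normalized spectrum.
#' @export
normalize_spectrum <- function(s, mode = c("max", "band_area"),
                               window = c(1480, 1720)) {
  stopifnot(inherits(s, "spectrum"))
  mode <- match.arg(mode)
  z <- switch(mode, max = max(s$value),
              band_area = integrate_band(s, window[1], window[2]))
  if (!is.finite(z) || z == 0) stop("normalizer is zero", call. = FALSE)
  s$value <- s$value / z
  s
}

#' Compare the OH-stretch intensity of two SC-IR extractions
#'
#' Normalizes both SC spectra on the combined amide band area and returns
#' the ratio of their integrated OH-region intensities (second over
#' first); a ratio < 1 means the second system has less solute-perturbed
#' water per protein.
#'
#' @param a,b [extract_scir()] results (e.g. binary WL and ternary WTL).
#' @param oh_window,amide_window integration windows in cm-1.
#' @return list with the two normalized OH areas and their ratio.
#' @export
compare_scir <- function(a, b, oh_window = c(3100, 3600),
                         amide_window = c(1480, 1720)) {
  stopifnot(inherits(a, "scir"), inherits(b, "scir"))
  oh_area <- function(r) {
    s <- normalize_spectrum(r$sc_spectrum, "band_area", amide_window)
    integrate_band(s, oh_window[1], oh_window[2])
  }
  A <- oh_area(a); B <- oh_area(b)
  list(oh_area_a = A, oh_area_b = B, ratio = B / A)
}

#' @export
print.scir <- function(x, ...) {
  cat(sprintf("<SC-IR extraction> factor c = %.6f (tolerance %.3g)\n",
              x$factor, x$tolerance))
  cat(sprintf("  area %.4g, most negative value %.3g\n",
              x$area, x$negativity))
  print(x$band_metrics[, c("window", "peak_position", "peak_value", "area")],
        digits = 5, row.names = FALSE)
  invisible(x)
}

#' @export
plot.scir <- function(x, xlim = c(800, 4000), ...) {
  s <- x$solution; sv <- x$solvent; sc <- x$sc_spectrum
  graphics::plot(s$frequency, s$value, type = "l", xlim = xlim,
                 xlab = "wavenumber (cm-1)", ylab = "absorbance", ...)
  graphics::lines(sv$frequency, x$factor * sv$value, col = "blue")
  graphics::lines(sc$frequency, sc$value, col = "red")
  graphics::legend("topright", c("solution", "c x solvent", "SC"),
                   col = c("black", "blue", "red"), lty = 1, bty = "n")
  invisible(x)
}
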