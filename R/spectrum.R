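## Spectrum container and frequency/unit plumbing.
## Canonical frequency units handled: GHz, THz, cm-1 (wavenumber).
## 1 cm-1 = 29.9792458 GHz (speed of light in cm/ns); 1 THz = 1000 GHz.

#' Physical constants used throughout the package (CODATA 2018)
#' @keywords internal
.const <- list(
  h  = 6.62607015e-34,   # Planck constant, J s
  kB = 1.380649e-23,     # Boltzmann constant, J / K
  R  = 8.314462618,      # molar gas constant, J / (mol K)
  GHz_per_cm1 = 29.9792458
)

.units <- c("GHz", "THz", "cm-1")

#' Convert frequency values between GHz, THz and cm-1
#'
#' Conversions are exact: 1 cm-1 = 29.9792458 GHz, 1 THz = 1000 GHz, so
#' round trips return the input to machine precision.
#'
#' @param x numeric vector of frequencies, or a [spectrum()] object.
#' @param from,to source and target unit, one of `"GHz"`, `"THz"`, `"cm-1"`.
#'   For a spectrum `from` is taken from the object.
#' @return numeric vector (or spectrum) in the target unit.
#' @examples
#' convert_frequency(1200, "cm-1", "GHz")   # ~ 35975 GHz
#' convert_frequency(1.5, "THz", "cm-1")    # ~ 50.03 cm-1
#' @export
convert_frequency <- function(x, from, to) {
  if (inherits(x, "spectrum")) {
    to <- match.arg(to, .units)
    x$frequency <- convert_frequency(x$frequency, x$unit, to)
    x$unit <- to
    return(x)
  }
  from <- match.arg(from, .units)
  to <- match.arg(to, .units)
  if (from == to) return(x)
  ghz <- switch(from,
    "GHz"  = x,
    "THz"  = x * 1000,
    "cm-1" = x * .const$GHz_per_cm1)
  switch(to,
    "GHz"  = ghz,
    "THz"  = ghz / 1000,
    "cm-1" = ghz / .const$GHz_per_cm1)
}

#' Construct a spectrum
#'
#' A `spectrum` is a sampled one-dimensional spectral profile: a strictly
#' increasing, positive frequency grid plus one value per grid point, with
#' metadata (temperature, system label, technique) carried along through
#' every processing step.
#'
#' @param frequency strictly increasing, positive numeric vector.
#' @param value numeric vector, same length as `frequency`.
#' @param unit frequency unit, one of `"GHz"`, `"THz"`, `"cm-1"`.
#' @param temperature sample temperature in degrees Celsius (or `NA`).
#' @param system system label, e.g. `"W"`, `"WT"`, `"WL"`, `"WTL"`,
#'   `"lysozyme_solid"`, `"DS"`.
#' @param technique one of `"DLS_intensity"`, `"DLS_susceptibility"`,
#'   `"FTIR"` (or `NA`).
#' @param meta optional named list of additional metadata.
#' @return an object of class `"spectrum"`.
#' @export
spectrum <- function(frequency, value, unit = c("GHz", "THz", "cm-1"),
                     temperature = NA_real_, system = NA_character_,
                     technique = NA_character_, meta = list()) {
  unit <- match.arg(unit)
  frequency <- as.numeric(frequency)
  value <- as.numeric(value)
  if (length(frequency) != length(value))
    stop("`frequency` and `value` must have the same length", call. = FALSE)
  if (any(!is.finite(frequency)) || any(frequency <= 0))
    stop("frequencies must be finite and > 0", call. = FALSE)
  if (is.unsorted(frequency, strictly = TRUE))
    stop("frequencies must be strictly increasing", call. = FALSE)
  structure(
    list(frequency = frequency, value = value, unit = unit,
         meta = c(list(temperature = as.numeric(temperature),
                       system = system, technique = technique), meta)),
    class = "spectrum")
}

#' @export
print.spectrum <- function(x, ...) {
  rng <- range(x$frequency)
  cat(sprintf("<spectrum> %d points, %.4g-%.4g %s\n",
              length(x$frequency), rng[1], rng[2], x$unit))
  m <- x$meta
  cat(sprintf("  system: %s  T: %s degC  technique: %s\n",
              m$system %||% NA,
              format(m$temperature), m$technique %||% NA))
  invisible(x)
}

#' @export
plot.spectrum <- function(x, log = "xy", xlab = NULL, ylab = "value",
                          type = "l", ...) {
  if (is.null(xlab)) xlab <- sprintf("frequency (%s)", x$unit)
  ok <- if (grepl("y", log)) x$value > 0 else rep(TRUE, length(x$value))
  graphics::plot(x$frequency[ok], x$value[ok], log = log, xlab = xlab,
                 ylab = ylab, type = type, ...)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## frequency grid in THz regardless of storage unit
freq_THz <- function(s) {
  if (inherits(s, "spectrum")) convert_frequency(s$frequency, s$unit, "THz")
  else s
}

#' Bose-Einstein occupation factor
#'
#' \eqn{n_B(\nu, T) = 1 / (\exp(h\nu/k_B T) - 1)}; the mean thermal
#' occupation of a mode at frequency \eqn{\nu} and temperature \eqn{T}.
#'
#' @param nu frequency, numeric vector > 0.
#' @param T_K absolute temperature in kelvin, > 0.
#' @param unit unit of `nu`.
#' @return dimensionless occupation number, positive and monotonically
#'   decreasing in `nu`.
#' @export
bose_einstein_factor <- function(nu, T_K, unit = c("GHz", "THz", "cm-1")) {
  unit <- match.arg(unit)
  if (any(nu <= 0)) stop("`nu` must be > 0", call. = FALSE)
  if (any(T_K <= 0)) stop("`T_K` must be > 0", call. = FALSE)
  nu_hz <- convert_frequency(nu, unit, "GHz") * 1e9
  x <- .const$h * nu_hz / (.const$kB * T_K)
  1 / expm1(x)
}

#' Convert depolarized-scattering intensity to imaginary susceptibility
#'
#' The susceptibility representation removes the trivial thermal
#' population factor from the depolarized scattered intensity:
#' \eqn{\chi''(\nu) = I_{HV}(\nu) / [n_B(\nu) + 1]}, so that relaxation
#' processes appear as peaks.  `susceptibility_to_intensity()` is the exact
#' inverse.
#'
#' @param s a [spectrum()] with technique `"DLS_intensity"` (or
#'   `"DLS_susceptibility"` for the inverse).
#' @param T_K absolute temperature in kelvin; defaults to the spectrum's
#'   Celsius temperature + 273.15.
#' @return a spectrum with the converted technique tag.
#' @export
intensity_to_susceptibility <- function(s, T_K = NULL) {
  stopifnot(inherits(s, "spectrum"))
  if (is.null(T_K)) T_K <- s$meta$temperature + 273.15
  if (!is.finite(T_K)) stop("temperature unknown; supply `T_K`", call. = FALSE)
  nB <- bose_einstein_factor(s$frequency, T_K, s$unit)
  s$value <- s$value / (nB + 1)
  s$meta$technique <- "DLS_susceptibility"
  s
}

#' @rdname intensity_to_susceptibility
#' @export
susceptibility_to_intensity <- function(s, T_K = NULL) {
  stopifnot(inherits(s, "spectrum"))
  if (is.null(T_K)) T_K <- s$meta$temperature + 273.15
  if (!is.finite(T_K)) stop("temperature unknown; supply `T_K`", call. = FALSE)
  nB <- bose_einstein_factor(s$frequency, T_K, s$unit)
  s$value <- s$value * (nB + 1)
  s$meta$technique <- "DLS_intensity"
  s
}

## Interpolate spectrum values onto frequencies `nu` (same unit as s),
## linear in log-frequency and, when all values positive, log-value space.
interp_spectrum <- function(s, nu, log_value = TRUE) {
  v <- s$value
  use_log <- log_value && all(v > 0)
  y <- if (use_log) log(v) else v
  out <- stats::approx(log(s$frequency), y, xout = log(nu), rule = 2)$y
  if (use_log) exp(out) else out
}

## Trapezoidal integral of a spectrum over [lo, hi] (frequencies in the
## spectrum's own unit).
integrate_band <- function(s, lo = -Inf, hi = Inf) {
  i <- which(s$frequency >= lo & s$frequency <= hi)
  if (length(i) < 2) stop("band contains fewer than 2 grid points", call. = FALSE)
  x <- s$frequency[i]; y <- s$value[i]
  sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}
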