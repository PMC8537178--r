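## Synthetic broadband depolarized-scattering spectra with known ground
## truth.  Noise is multiplicative lognormal: photon-counting spectra have
## intensity-proportional error over the four decades of signal covered.

#' Log-spaced broadband frequency grid
#'
#' @param lo,hi grid limits in GHz (default 0.6-36000 GHz, the coverage of
#'   the interferometric + dispersive instrument pair).
#' @param n number of points.
#' @return numeric vector of frequencies in GHz.
#' @export
edls_grid <- function(lo = 0.6, hi = 36000, n = 1000)
  exp(seq(log(lo), log(hi), length.out = n))

#' Generate a synthetic susceptibility spectrum
#'
#' Evaluates the ground-truth model of a [edls_preset()] at temperature
#' `T_C` on a log-spaced grid and applies multiplicative lognormal noise.
#' With `segments = TRUE` it instead emits the two overlapping instrument
#' segments (0.6-90 GHz and 60-36000 GHz) with independent scale factors
#' and additive backgrounds, to exercise [join_segments()].
#'
#' @param system system label or a [edls_preset()] object.
#' @param T_C temperature in degrees Celsius.
#' @param noise relative noise standard deviation (default 0.02).
#' @param seed integer seed; identical seeds give identical spectra.
#' @param segments emit two overlapping instrument segments.
#' @param n grid size (total, single-segment mode).
#' @return a [spectrum()] of technique `"DLS_susceptibility"` with
#'   attributes `"ground_truth"` (parameter table), `"truth_model"` and
#'   `"preset"`; in segment mode a list with elements `low`, `high` (each
#'   carrying attributes `scale` and `background`) and `reference` (the
#'   noiseless single-segment spectrum).
#' @export
simulate_edls <- function(system = "WT", T_C = 25, noise = 0.02,
                          seed = NULL, segments = FALSE, n = 1000) {
  preset <- if (inherits(system, "system_preset")) system
            else edls_preset(system)
  if (!is.null(seed)) set.seed(seed)
  model <- preset_model(preset, T_C)
  mknoise <- function(len, sd) if (sd > 0) exp(stats::rnorm(len, 0, sd)) else 1
  if (!segments) {
    g <- edls_grid(n = n)
    clean <- evaluate_model(model, g, unit = "GHz", temperature = T_C,
                            system = preset$system)
    out <- clean
    out$value <- clean$value * mknoise(n, noise)
    attr(out, "partials") <- attr(clean, "partials")
    attr(out, "groups") <- attr(clean, "groups")
    attr(out, "ground_truth") <- preset_truth(preset, T_C)
    attr(out, "truth_model") <- model
    attr(out, "preset") <- preset
    out$meta$seed <- seed
    out$meta$noise <- noise
    return(out)
  }
  ## two-segment instrument mode: the interferometric segment reaches
  ## 90 GHz and the dispersive one starts near 1 cm-1, so the overlap
  ## (28-90 GHz) spans about half a decade
  g_lo <- exp(seq(log(0.6), log(90), length.out = 140))
  g_hi <- exp(seq(log(28), log(36000), length.out = 320))
  scale_lo <- stats::runif(1, 0.5, 2)
  scale_hi <- 1
  bg_lo <- stats::runif(1, 0, 0.02)
  bg_hi <- stats::runif(1, 0, 0.02)
  mk <- function(g, sc, bg) {
    clean <- evaluate_model(model, g, unit = "GHz", temperature = T_C,
                            system = preset$system)
    s <- clean
    s$value <- clean$value * sc * mknoise(length(g), noise) + bg
    s$meta$seed <- seed; s$meta$noise <- noise
    attr(s, "scale") <- sc
    attr(s, "background") <- bg
    s
  }
  reference <- evaluate_model(model, edls_grid(n = n), unit = "GHz",
                              temperature = T_C, system = preset$system)
  list(low = mk(g_lo, scale_lo, bg_lo), high = mk(g_hi, scale_hi, bg_hi),
       reference = reference,
       ground_truth = preset_truth(preset, T_C))
}

#' Generate a temperature series of synthetic spectra
#'
#' One spectrum per temperature of the preset grid (default 3.5, 10,
#' 14.5, 25, 35 degC), sharing the preset ground truth; relaxation times
#' follow the preset Arrhenius law and the ultraslow amplitude fraction is
#' held temperature-independent.
#'
#' @inheritParams simulate_edls
#' @param temperatures temperatures in degrees Celsius (>= 3).
#' @return named list of spectra (names = temperatures), each with its
#'   ground-truth attributes.
#' @export
simulate_edls_series <- function(system = "WTL",
                                 temperatures = NULL,
                                 noise = 0.02, seed = NULL, n = 1000) {
  preset <- if (inherits(system, "system_preset")) system
            else edls_preset(system)
  if (is.null(temperatures)) temperatures <- preset$temperatures
  if (length(temperatures) < 3)
    stop("need at least 3 temperatures", call. = FALSE)
  out <- lapply(seq_along(temperatures), function(i) {
    si <- if (is.null(seed)) NULL else seed + 1000L * (i - 1L)
    simulate_edls(preset, temperatures[i], noise = noise, seed = si, n = n)
  })
  names(out) <- format(temperatures)
  out
}
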