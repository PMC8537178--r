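## Hydration statistics: composition bookkeeping, hydration-water counting,
## retardation factors, Arrhenius analysis, temperature aggregation.

#' Mixture composition by weight
#'
#' Weight fractions of lysozyme, trehalose and water (must sum to 1).
#' Trehalose can be booked as anhydrous or dihydrate; with
#' `include_crystal_water = TRUE` the two crystal waters per dihydrate are
#' counted as solvent water when mole numbers are derived.
#'
#' @param lysozyme,trehalose,water weight fractions in [0, 1], summing to 1.
#' @param trehalose_form `"anhydrous"` (M = 342.30 g/mol) or `"dihydrate"`
#'   (M = 378.33 g/mol).
#' @param include_crystal_water count dihydrate crystal water as solvent
#'   water (only meaningful for `trehalose_form = "dihydrate"`).
#' @param M_lysozyme,M_water molar masses in g/mol.
#' @return object of class `"mixture"` with weight fractions, molar masses
#'   and mole numbers per gram of solution.
#' @export
mixture_composition <- function(lysozyme = 0, trehalose = 0, water = 1,
                                trehalose_form = c("anhydrous", "dihydrate"),
                                include_crystal_water = FALSE,
                                M_lysozyme = 14300, M_water = 18.015) {
  trehalose_form <- match.arg(trehalose_form)
  w <- c(lysozyme = lysozyme, trehalose = trehalose, water = water)
  if (any(w < 0 | w > 1)) stop("weight fractions must be in [0, 1]", call. = FALSE)
  if (abs(sum(w) - 1) > 1e-9)
    stop("weight fractions must sum to 1", call. = FALSE)
  M_treh <- if (trehalose_form == "anhydrous") 342.30 else 378.33
  n <- c(lysozyme = w[["lysozyme"]] / M_lysozyme,
         trehalose = w[["trehalose"]] / M_treh,
         water = w[["water"]] / M_water)
  if (trehalose_form == "dihydrate" && include_crystal_water)
    n[["water"]] <- n[["water"]] + 2 * n[["trehalose"]]
  structure(list(weight = w, trehalose_form = trehalose_form,
                 M = c(lysozyme = M_lysozyme, trehalose = M_treh,
                       water = M_water),
                 moles_per_g = n),
            class = "mixture")
}

#' @export
print.mixture <- function(x, ...) {
  cat("<mixture> ",
      paste(sprintf("%s %.3g wt%%", names(x$weight), 100 * x$weight),
            collapse = ", "),
      sprintf(" (trehalose %s)\n", x$trehalose_form))
  invisible(x)
}

#' Water-to-lysozyme mole ratio r
#'
#' \eqn{r = (w_{water}/M_{water}) / (w_{lys}/M_{lys})}: the number of water
#' molecules per lysozyme molecule in the mixture.  For the 3/40/57 wt%
#' ternary composition r is about 1.51e4.
#'
#' @param comp a [mixture_composition()].
#' @return dimensionless ratio.
#' @export
water_lysozyme_ratio <- function(comp) {
  stopifnot(inherits(comp, "mixture"))
  n <- comp$moles_per_g
  if (n[["lysozyme"]] <= 0) stop("lysozyme fraction must be > 0", call. = FALSE)
  n[["water"]] / n[["lysozyme"]]
}

#' Number of ultraslow hydration waters per protein
#'
#' \eqn{N_{ultraslow} = r\,\Delta_{ultraslow}/\Delta_{tot}} with
#' \eqn{\Delta_{tot} = \Delta_{ultraslow} + \Delta_{hydr} + \Delta_{bulk}}:
#' the relaxation amplitudes partition the water population under the
#' assumption that the light-scattering cross-section per water molecule is
#' the same in every environment, so the ultraslow amplitude fraction times
#' the water-per-protein ratio counts the ultraslow shell.
#'
#' @param r water-to-lysozyme mole ratio (see [water_lysozyme_ratio()]).
#' @param deltas numeric vector of the three water relaxation amplitudes,
#'   named or ordered `ultraslow`, `hydration`, `bulk`; all >= 0.
#' @return water molecules per lysozyme, in [0, r].
#' @export
n_ultraslow <- function(r, deltas) {
  if (!is.null(names(deltas))) {
    want <- c("ultraslow", "hydration", "bulk")
    if (!all(want %in% names(deltas)))
      stop("`deltas` must contain ultraslow, hydration, bulk", call. = FALSE)
    deltas <- deltas[want]
  }
  if (length(deltas) != 3 || any(deltas < 0))
    stop("`deltas` must be three non-negative amplitudes", call. = FALSE)
  tot <- sum(deltas)
  if (tot <= 0) stop("total water amplitude is zero", call. = FALSE)
  r * deltas[[1]] / tot
}

#' Retardation factor of a slow water relaxation
#'
#' \eqn{\xi = \tau_{slow}/\tau_{bulk}} on the Cole-Davidson tau
#' parameters; with a shared shape parameter beta this equals the ratio of
#' mean relaxation times \eqn{\beta\tau}.
#'
#' @param tau_slow,tau_bulk relaxation times (same unit), > 0.
#' @return dimensionless ratio.
#' @export
retardation_factor <- function(tau_slow, tau_bulk) {
  stopifnot(all(tau_slow > 0), all(tau_bulk > 0))
  tau_slow / tau_bulk
}

#' Apparent Arrhenius activation energy of a relaxation process
#'
#' Fits \eqn{\ln\tau} against \eqn{1/T} by ordinary least squares;
#' \eqn{E_a} is the slope times the gas constant, in kJ/mol, with the
#' regression standard error.
#'
#' @param T_C temperatures in degrees Celsius (>= 3 distinct values).
#' @param tau relaxation times (any fixed unit), > 0.
#' @return list with `Ea_kJmol`, `se_kJmol`, `tau0` (prefactor, same unit
#'   as `tau`) and the underlying `lm` fit.
#' @export
arrhenius_activation_energy <- function(T_C, tau) {
  if (length(T_C) < 3 || length(unique(T_C)) < 3)
    stop("need >= 3 distinct temperatures", call. = FALSE)
  if (length(tau) != length(T_C) || any(tau <= 0))
    stop("`tau` must be positive and match `T_C`", call. = FALSE)
  invT <- 1 / (T_C + 273.15)
  fit <- stats::lm(log(tau) ~ invT)
  slope <- stats::coef(fit)[["invT"]]
  se <- tryCatch(suppressWarnings(
    summary(fit)$coefficients["invT", "Std. Error"]),
    error = function(e) NA_real_)
  if (!is.finite(se)) se <- 0
  list(Ea_kJmol = slope * .const$R / 1000,
       se_kJmol = se * .const$R / 1000,
       tau0 = exp(stats::coef(fit)[[1]]),
       fit = fit)
}

#' Summarize hydration across a temperature series of ternary fits
#'
#' Assembles, per temperature, the three water relaxation amplitudes, the
#' hydration and ultraslow retardation factors and
#' \eqn{N_{ultraslow}}; aggregates the mean and SD of
#' \eqn{N_{ultraslow}} over temperature, tests for a temperature trend
#' (slope of N vs T), and derives Arrhenius activation energies for the
#' bulk, hydration and ultraslow processes.
#'
#' @param fits list of converged ternary [fit_edls()] results, one per
#'   temperature.
#' @param comp the ternary [mixture_composition()].
#' @return object of class `"hydration_summary"`: a per-temperature table
#'   plus aggregates.
#' @export
summarize_hydration <- function(fits, comp) {
  stopifnot(length(fits) >= 1, inherits(comp, "mixture"))
  r <- water_lysozyme_ratio(comp)
  rows <- lapply(fits, function(f) {
    stopifnot(inherits(f, "edls_fit"))
    d <- water_amplitudes(f)
    taus <- water_taus(f)
    data.frame(
      T_C = f$data$meta$temperature,
      delta_bulk = d[["bulk"]], delta_hydration = d[["hydration"]],
      delta_ultraslow = d[["ultraslow"]],
      tau_bulk = taus[["bulk"]], tau_hydration = taus[["hydration"]],
      tau_ultraslow = taus[["ultraslow"]],
      xi_hydration = retardation_factor(taus[["hydration"]], taus[["bulk"]]),
      xi_ultraslow = retardation_factor(taus[["ultraslow"]], taus[["bulk"]]),
      N_ultraslow = n_ultraslow(r, c(ultraslow = d[["ultraslow"]],
                                     hydration = d[["hydration"]],
                                     bulk = d[["bulk"]])))
  })
  tab <- do.call(rbind, rows)
  tab <- tab[order(tab$T_C), , drop = FALSE]
  rownames(tab) <- NULL
  trend <- if (nrow(tab) >= 3) {
    tf <- stats::lm(N_ultraslow ~ T_C, data = tab)
    list(slope = stats::coef(tf)[["T_C"]],
         p_value = summary(tf)$coefficients["T_C", "Pr(>|t|)"])
  } else list(slope = NA_real_, p_value = NA_real_)
  Ea <- if (nrow(tab) >= 3) {
    lapply(c(bulk = "tau_bulk", hydration = "tau_hydration",
             ultraslow = "tau_ultraslow"),
           function(cl) arrhenius_activation_energy(tab$T_C, tab[[cl]])[
             c("Ea_kJmol", "se_kJmol")])
  } else NULL
  structure(list(table = tab, r = r,
                 N_mean = mean(tab$N_ultraslow),
                 N_sd = stats::sd(tab$N_ultraslow),
                 trend = trend, Ea = Ea, composition = comp),
            class = "hydration_summary")
}

#' @export
print.hydration_summary <- function(x, digits = 4, ...) {
  cat("Hydration summary over", nrow(x$table), "temperatures\n")
  cat(sprintf("  water per lysozyme r = %.5g\n", x$r))
  print(x$table[, c("T_C", "N_ultraslow", "xi_hydration", "xi_ultraslow")],
        digits = digits, row.names = FALSE)
  cat(sprintf("  N_ultraslow = %.0f +/- %.0f (mean +/- SD over T)\n",
              x$N_mean, ifelse(is.na(x$N_sd), 0, x$N_sd)))
  if (!is.null(x$trend$p_value) && is.finite(x$trend$p_value))
    cat(sprintf("  temperature trend: slope %.3g /degC (p = %.2g)\n",
                x$trend$slope, x$trend$p_value))
  if (!is.null(x$Ea)) {
    for (nm in names(x$Ea))
      cat(sprintf("  E_a(%s) = %.2f +/- %.2f kJ/mol\n",
                  nm, x$Ea[[nm]]$Ea_kJmol, x$Ea[[nm]]$se_kJmol))
  }
  invisible(x)
}
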