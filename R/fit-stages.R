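## Staged decomposition of broadband susceptibility spectra.
##
## Stage 1 (binary): fit the sugar-water spectrum with
##   Debye (solute rotation) + bulk CD + hydration CD + vibrational DHOs.
## Stage 2 (difference spectrum): fit the normalized ternary-minus-binary
##   residual with power law + ultraslow CD + three Brownian oscillators.
## Stage 3 (ternary): fit the full model to the ternary spectrum with
##   shape and time parameters fixed from the earlier stages; free
##   parameters are the component amplitudes and the ultraslow time.
##
## Identifiability between the overlapping hydration and ultraslow CD
## terms is enforced by ratio parameterization: tau_hydration =
## rho_h * tau_bulk with rho_h >= 2, and tau_ultraslow = rho_u *
## tau_hydration with rho_u >= 2, mirroring the protocol of fixing
## binary-fit results in the ternary stage.

.default_beta <- 0.6

## locate up to two solute Raman bands above 10 THz for starting values
find_raman_starts <- function(nu, val) {
  i <- which(nu > 10)
  if (length(i) < 5) return(c(14, 20))
  x <- nu[i]; y <- val[i]
  pk <- which(diff(sign(diff(y))) == -2) + 1
  pk <- pk[order(y[pk], decreasing = TRUE)]
  ## greedy selection with a minimum separation so that noise wiggles on
  ## one band are not mistaken for two bands
  cen <- numeric(0)
  for (k in pk) {
    if (all(abs(log(x[k] / cen)) > log(1.25))) cen <- c(cen, x[k])
    if (length(cen) == 2) break
  }
  if (length(cen) < 2) return(c(14, 20))
  sort(cen)
}

#' Fit a pure-water relaxation spectrum
#'
#' Model: one Cole-Davidson water relaxation plus the two intermolecular
#' vibrational bands (H-bond bending and stretching DHOs).  With
#' `beta_free = TRUE` the Cole-Davidson shape parameter is a free
#' parameter; otherwise it is fixed at `beta`.
#'
#' @param s susceptibility [spectrum()] of pure water.
#' @param beta_free estimate the shape parameter.
#' @param beta fixed shape value when `beta_free = FALSE`.
#' @param window fit window in THz (default the full grid).
#' @return an object of class `"edls_fit"`.
#' @export
fit_water <- function(s, beta_free = TRUE, beta = .default_beta,
                      window = NULL) {
  d <- prep_fit_data(s, window)
  pk <- interior_peak(d$nu, d$obs, 0.02, 1.2)
  chi_rel <- if (is.null(pk)) value_at(d$nu, d$obs, 0.15) else pk$value
  tau0 <- if (is.null(pk)) 1 else 1 / (2 * pi * pk$nu) * 1.4
  pars <- rbind(
    par_table("bulk.delta", chi_rel / 0.39, 1e-4, 100),
    if (beta_free) par_table("bulk.beta", 0.8, 0.2, 1, log = FALSE),
    par_table("bulk.tau", tau0, 0.05, 50),
    par_table("bending.delta", value_at(d$nu, d$obs, 1.5) * 1.4 / 1.5 * 0.6,
              1e-4, 100),
    par_table("bending.nu0", 1.5, 0.8, 2.8),
    par_table("bending.gamma", 1.5, 0.3, 4),
    par_table("stretching.delta", value_at(d$nu, d$obs, 5.1) * 2.6 / 5.1 * 0.8,
              1e-4, 100),
    par_table("stretching.nu0", 5.0, 3.5, 7.5),
    par_table("stretching.gamma", 2.5, 0.8, 6))
  build <- function(p) susceptibility_model(
    model_component("cole_davidson", "WR_bulk", "bulk",
                    delta = p[["bulk.delta"]], tau = p[["bulk.tau"]],
                    beta = if (beta_free) p[["bulk.beta"]] else beta),
    model_component("dho", "VIB", "bending", delta = p[["bending.delta"]],
                    nu0 = p[["bending.nu0"]], gamma = p[["bending.gamma"]]),
    model_component("dho", "VIB", "stretching",
                    delta = p[["stretching.delta"]],
                    nu0 = p[["stretching.nu0"]],
                    gamma = p[["stretching.gamma"]]))
  eng <- fit_engine(d$nu, d$obs, d$w, pars, build, objective = "log")
  new_edls_fit(eng, s, d$nu, d$obs, d$w, window, "water",
               fixed = if (!beta_free) c(bulk.beta = beta), idx = d$idx)
}

#' Fit the binary sugar-water spectrum
#'
#' Model: Debye solute rotation + bulk and hydration Cole-Davidson water
#' relaxations (shared shape parameter fixed at `beta`) + H-bond bending
#' and stretching DHOs + two solute Raman bands above 10 THz.  The
#' hydration time is parameterized as `rho_h * tau_bulk`, `rho_h >= 2`, so
#' hydration water is slower than bulk by construction; `rho_h` is the
#' hydration retardation factor.
#'
#' @param s susceptibility [spectrum()] of the binary solution.
#' @param beta fixed Cole-Davidson shape parameter.
#' @param window fit window in THz (default full grid).
#' @return `"edls_fit"` object; `summary()` reports the retardation
#'   factor.
#' @export
fit_wt <- function(s, beta = .default_beta, window = NULL) {
  d <- prep_fit_data(s, window)
  ## solute rotation: low-frequency tail / peak
  pk_rot <- interior_peak(d$nu, d$obs, min(d$nu), 0.01)
  tau_rot0 <- if (is.null(pk_rot)) 200 else 1 / (2 * pi * pk_rot$nu)
  d_rot0 <- 2 * max(d$obs[d$nu < 0.003])
  ## bulk relaxation region
  chi_bulk <- value_at(d$nu, d$obs, 0.15)
  raman <- find_raman_starts(d$nu, d$obs)
  pars <- rbind(
    par_table("rotation.delta", d_rot0, 1e-3, 1e3),
    par_table("rotation.tau", tau_rot0, 10, 1e4),
    par_table("bulk.delta", chi_bulk / 0.39 * 0.8, 1e-3, 50),
    par_table("bulk.tau", 1.0, 0.2, 6),
    par_table("hydration.delta", chi_bulk / 0.39 * 0.5, 1e-4, 50),
    par_table("hydration.rho", 5, 2, 15),
    par_table("bending.delta", value_at(d$nu, d$obs, 1.5) * 1.4 / 1.5 * 0.6,
              1e-4, 100),
    par_table("bending.nu0", 1.5, 0.8, 2.8),
    par_table("bending.gamma", 1.5, 0.3, 4),
    par_table("stretching.delta", value_at(d$nu, d$obs, 5.1) * 2.6 / 5.1 * 0.8,
              1e-4, 100),
    par_table("stretching.nu0", 5.0, 3.5, 7.5),
    par_table("stretching.gamma", 2.5, 0.8, 6),
    par_table("raman1.delta", value_at(d$nu, d$obs, raman[1]) * 0.15, 1e-4, 100),
    par_table("raman1.nu0", raman[1], 11, 17),
    par_table("raman1.gamma", 2, 0.5, 5),
    par_table("raman2.delta", value_at(d$nu, d$obs, raman[2]) * 0.15, 1e-4, 100),
    par_table("raman2.nu0", raman[2], 17, 26),
    par_table("raman2.gamma", 2.5, 0.5, 6))
  build <- function(p) susceptibility_model(
    model_component("debye", "SR", "rotation", delta = p[["rotation.delta"]],
                    tau = p[["rotation.tau"]]),
    model_component("cole_davidson", "WR_bulk", "bulk",
                    delta = p[["bulk.delta"]], tau = p[["bulk.tau"]],
                    beta = beta),
    model_component("cole_davidson", "WR_hydration", "hydration",
                    delta = p[["hydration.delta"]],
                    tau = p[["hydration.rho"]] * p[["bulk.tau"]],
                    beta = beta),
    model_component("dho", "VIB", "bending", delta = p[["bending.delta"]],
                    nu0 = p[["bending.nu0"]], gamma = p[["bending.gamma"]]),
    model_component("dho", "VIB", "stretching",
                    delta = p[["stretching.delta"]],
                    nu0 = p[["stretching.nu0"]],
                    gamma = p[["stretching.gamma"]]),
    model_component("dho", "VIB", "raman1", delta = p[["raman1.delta"]],
                    nu0 = p[["raman1.nu0"]], gamma = p[["raman1.gamma"]]),
    model_component("dho", "VIB", "raman2", delta = p[["raman2.delta"]],
                    nu0 = p[["raman2.nu0"]], gamma = p[["raman2.gamma"]]))
  eng <- fit_engine(d$nu, d$obs, d$w, pars, build, objective = "log")
  new_edls_fit(eng, s, d$nu, d$obs, d$w, window, "binary",
               fixed = c(bulk.beta = beta, hydration.beta = beta),
               idx = d$idx)
}

#' Fit the difference spectrum
#'
#' Model for the protein contribution isolated by the difference-spectrum
#' method: power-law structural relaxation + ultraslow Cole-Davidson water
#' relaxation + three Brownian oscillators (protein low-frequency modes).
#' Negative excursions of the difference spectrum are retained in the
#' objective; weights follow the parent ternary spectrum magnitude, since
#' the noise of a difference scales with the spectra that were subtracted.
#'
#' The power-law exponent defaults to the literature value 0.3 for
#' protein structural relaxation; set `alpha = NULL` to estimate it (used
#' to validate the exponent on synthetic data, at the cost of a strong
#' trade-off with the ultraslow amplitude).
#'
#' @param ds difference [spectrum()] (see [difference_spectrum()]).
#' @param wt_fit optional binary-stage fit; when supplied, the ultraslow
#'   time is bounded below by twice the fitted hydration time.
#' @param weights_ref optional reference spectrum (e.g. the normalized
#'   ternary spectrum) defining the weight scale 1/reference.
#' @param beta fixed Cole-Davidson shape parameter.
#' @param alpha fixed power-law exponent, or `NULL` to fit it.
#' @param window fit window in THz.
#' @return `"edls_fit"` object.
#' @export
fit_ds <- function(ds, wt_fit = NULL, weights_ref = NULL,
                   beta = .default_beta, alpha = 0.3, window = c(0, 10)) {
  w <- NULL
  if (!is.null(weights_ref)) {
    ref <- interp_spectrum(weights_ref,
                           convert_frequency(ds$frequency, ds$unit,
                                             weights_ref$unit))
    ref <- smooth_log(ref)
    w <- 1 / pmax(ref, 1e-3 * max(ref))
  }
  d <- prep_fit_data(ds, window, weights = w)
  if (is.null(w)) {
    ## fallback: relative weights with a floor to tolerate near-zero points
    d <- prep_fit_data(ds, window,
                       weights = 1 / pmax(abs(ds$value), 0.05 * max(ds$value)))
  }
  ## power-law start from the lowest frequencies (the ultraslow and
  ## oscillator terms vanish there as omega -> 0)
  lo <- d$nu <= min(d$nu) * 4
  alpha0 <- -stats::coef(stats::lm(log(pmax(d$obs[lo], 1e-12)) ~
                                     log(d$nu[lo])))[[2]]
  alpha0 <- min(max(alpha0, 0.1), 0.7)
  A0 <- max(value_at(d$nu, pmax(d$obs, 1e-12), min(d$nu)) *
              min(d$nu)^alpha0, 1e-9)
  tau_lo <- if (!is.null(wt_fit)) 2 * water_taus(wt_fit)[["hydration"]] else 6
  alpha_free <- is.null(alpha)
  mk_pars <- function(tau_u0, bo, du0) rbind(
    par_table("relaxation_pl.amplitude", A0, 1e-9, 10),
    if (alpha_free)
      par_table("relaxation_pl.alpha", alpha0, 0.05, 0.8, log = FALSE),
    par_table("ultraslow.delta", du0 * max(d$obs), 1e-9, 10),
    par_table("ultraslow.tau", tau_u0, tau_lo, 60),
    par_table("bo1.delta", 0.05 * max(d$obs), 1e-9, 10),
    par_table("bo1.nu0", bo[1], 0.25, 0.7),
    par_table("bo1.gamma", bo[4], 0.2, 5),
    par_table("bo2.delta", 0.05 * max(d$obs), 1e-9, 10),
    par_table("bo2.nu0", bo[2], 0.7, 1.6),
    par_table("bo2.gamma", bo[5], 0.2, 5),
    par_table("bo3.delta", 0.03 * max(d$obs), 1e-9, 10),
    par_table("bo3.nu0", bo[3], 1.6, 3.2),
    par_table("bo3.gamma", bo[6], 0.2, 5))
  ## deterministic multistart: oscillator-shape sets x ultraslow-time
  ## starts; the DS objective has local optima where the power law or
  ## the lowest oscillator absorbs the slow-water bump
  starts <- list()
  for (bo in list(c(0.40, 1.00, 2.50, 1.0, 1.2, 2.0),
                  c(0.35, 0.90, 2.20, 0.6, 1.0, 1.5),
                  c(0.55, 1.15, 2.80, 1.8, 2.2, 2.8)))
    for (tau_u0 in c(max(tau_lo * 1.05, 14), 30))
      starts <- c(starts, list(mk_pars(tau_u0, bo, 0.1)))
  build <- function(p) susceptibility_model(
    model_component("power_law", "SR", "relaxation_pl",
                    amplitude = p[["relaxation_pl.amplitude"]],
                    alpha = if (alpha_free) p[["relaxation_pl.alpha"]]
                            else alpha),
    model_component("cole_davidson", "WR_ultraslow", "ultraslow",
                    delta = p[["ultraslow.delta"]],
                    tau = p[["ultraslow.tau"]], beta = beta),
    model_component("brownian_oscillator", "VIB", "bo1",
                    delta = p[["bo1.delta"]], nu0 = p[["bo1.nu0"]],
                    gamma = p[["bo1.gamma"]]),
    model_component("brownian_oscillator", "VIB", "bo2",
                    delta = p[["bo2.delta"]], nu0 = p[["bo2.nu0"]],
                    gamma = p[["bo2.gamma"]]),
    model_component("brownian_oscillator", "VIB", "bo3",
                    delta = p[["bo3.delta"]], nu0 = p[["bo3.nu0"]],
                    gamma = p[["bo3.gamma"]]))
  eng <- NULL
  for (pars in starts) {
    e <- tryCatch(suppressWarnings(fit_engine(d$nu, d$obs, d$w, pars, build)),
                  error = function(err) NULL)
    if (!is.null(e) && (is.null(eng) || e$deviance < eng$deviance)) eng <- e
  }
  if (is.null(eng))
    stop("difference-spectrum fit failed from every start", call. = FALSE)
  if (!alpha_free) eng$par <- c(eng$par, relaxation_pl.alpha = alpha)
  new_edls_fit(eng, ds, d$nu, d$obs, d$w, window, "difference",
               fixed = c(ultraslow.beta = beta,
                         if (!alpha_free) c(relaxation_pl.alpha = alpha)),
               idx = d$idx)
}

#' Constrained fit of the full ternary model
#'
#' Combines the binary-stage and difference-stage results: the full model
#' is Debye rotation + power law (SR group), bulk + hydration + ultraslow
#' Cole-Davidson relaxations (WR group), and bending/stretching DHOs, two
#' solute Raman bands and three Brownian oscillators (VIB group).  The
#' binary-derived parameters (rotation, bulk and hydration times; water
#' and solute band positions and widths) are held fixed from `wt_fit`,
#' and the protein parameters determined by the difference spectrum
#' (power-law exponent, Brownian-oscillator shapes, and the ultraslow
#' amplitude and time) from `ds_fit`; the remaining component amplitudes
#' are refit on the ternary spectrum.  The ultraslow component is fixed
#' rather than refit because on the full ternary spectrum it is nearly
#' degenerate with small errors in the larger fixed terms, whereas in the
#' difference spectrum the solvent and rotation contributions cancel and
#' the component is determined directly.
#'
#' @param s susceptibility [spectrum()] of the ternary solution (on the
#'   same normalization as the spectra behind `wt_fit` and `ds_fit`).
#' @param wt_fit converged [fit_wt()] result.
#' @param ds_fit converged [fit_ds()] result.
#' @param beta fixed Cole-Davidson shape parameter.
#' @param window fit window in THz.
#' @return `"edls_fit"` object reporting the three water amplitudes.
#' @export
fit_ternary <- function(s, wt_fit, ds_fit, beta = .default_beta,
                        window = NULL) {
  stopifnot(inherits(wt_fit, "edls_fit"), inherits(ds_fit, "edls_fit"))
  d <- prep_fit_data(s, window)
  pw <- wt_fit$par
  pd <- ds_fit$par
  tau_bulk <- pw[["bulk.tau"]]
  tau_hyd <- pw[["hydration.rho"]] * tau_bulk
  amp0 <- c(rotation = pw[["rotation.delta"]],
            relaxation_pl = pd[["relaxation_pl.amplitude"]],
            bulk = pw[["bulk.delta"]], hydration = pw[["hydration.delta"]],
            bending = pw[["bending.delta"]],
            stretching = pw[["stretching.delta"]],
            raman1 = pw[["raman1.delta"]], raman2 = pw[["raman2.delta"]],
            bo1 = pd[["bo1.delta"]], bo2 = pd[["bo2.delta"]],
            bo3 = pd[["bo3.delta"]])
  fixed <- c(rotation.tau = pw[["rotation.tau"]],
             relaxation_pl.alpha = pd[["relaxation_pl.alpha"]],
             ultraslow.delta = pd[["ultraslow.delta"]],
             ultraslow.tau = pd[["ultraslow.tau"]],
             bo1.nu0 = pd[["bo1.nu0"]], bo1.gamma = pd[["bo1.gamma"]],
             bo2.nu0 = pd[["bo2.nu0"]], bo2.gamma = pd[["bo2.gamma"]],
             bo3.nu0 = pd[["bo3.nu0"]], bo3.gamma = pd[["bo3.gamma"]],
             bulk.tau = tau_bulk, hydration.tau = tau_hyd,
             bulk.beta = beta, hydration.beta = beta, ultraslow.beta = beta,
             bending.nu0 = pw[["bending.nu0"]],
             bending.gamma = pw[["bending.gamma"]],
             stretching.nu0 = pw[["stretching.nu0"]],
             stretching.gamma = pw[["stretching.gamma"]],
             raman1.nu0 = pw[["raman1.nu0"]],
             raman1.gamma = pw[["raman1.gamma"]],
             raman2.nu0 = pw[["raman2.nu0"]],
             raman2.gamma = pw[["raman2.gamma"]])
  build <- function(p) susceptibility_model(
    model_component("debye", "SR", "rotation", delta = p[["rotation.delta"]],
                    tau = fixed[["rotation.tau"]]),
    model_component("power_law", "SR", "relaxation_pl",
                    amplitude = p[["relaxation_pl.amplitude"]],
                    alpha = fixed[["relaxation_pl.alpha"]]),
    model_component("cole_davidson", "WR_bulk", "bulk",
                    delta = p[["bulk.delta"]], tau = fixed[["bulk.tau"]],
                    beta = beta),
    model_component("cole_davidson", "WR_hydration", "hydration",
                    delta = p[["hydration.delta"]],
                    tau = fixed[["hydration.tau"]], beta = beta),
    model_component("cole_davidson", "WR_ultraslow", "ultraslow",
                    delta = fixed[["ultraslow.delta"]],
                    tau = fixed[["ultraslow.tau"]],
                    beta = beta),
    model_component("dho", "VIB", "bending", delta = p[["bending.delta"]],
                    nu0 = fixed[["bending.nu0"]],
                    gamma = fixed[["bending.gamma"]]),
    model_component("dho", "VIB", "stretching",
                    delta = p[["stretching.delta"]],
                    nu0 = fixed[["stretching.nu0"]],
                    gamma = fixed[["stretching.gamma"]]),
    model_component("dho", "VIB", "raman1", delta = p[["raman1.delta"]],
                    nu0 = fixed[["raman1.nu0"]],
                    gamma = fixed[["raman1.gamma"]]),
    model_component("dho", "VIB", "raman2", delta = p[["raman2.delta"]],
                    nu0 = fixed[["raman2.nu0"]],
                    gamma = fixed[["raman2.gamma"]]),
    model_component("brownian_oscillator", "VIB", "bo1",
                    delta = p[["bo1.delta"]], nu0 = fixed[["bo1.nu0"]],
                    gamma = fixed[["bo1.gamma"]]),
    model_component("brownian_oscillator", "VIB", "bo2",
                    delta = p[["bo2.delta"]], nu0 = fixed[["bo2.nu0"]],
                    gamma = fixed[["bo2.gamma"]]),
    model_component("brownian_oscillator", "VIB", "bo3",
                    delta = p[["bo3.delta"]], nu0 = fixed[["bo3.nu0"]],
                    gamma = fixed[["bo3.gamma"]]))
  base_pars <- do.call(rbind, lapply(names(amp0), function(nm)
    par_table(paste0(nm, ".",
                     if (nm == "relaxation_pl") "amplitude" else "delta"),
              max(amp0[[nm]], 1e-6), 1e-8, 1e4)))
  eng <- fit_engine(d$nu, d$obs, d$w, base_pars, build, objective = "log")
  new_edls_fit(eng, s, d$nu, d$obs, d$w, window, "ternary",
               fixed = fixed, idx = d$idx)
}

#' Unconstrained direct fit of the ternary model
#'
#' Fits the full ternary model with every parameter free, from generic
#' data-driven starting values; serves as an independent cross-check of
#' the staged protocol on low-noise data.
#'
#' @inheritParams fit_wt
#' @return `"edls_fit"` object.
#' @export
fit_wtl_direct <- function(s, beta = .default_beta, window = NULL) {
  d <- prep_fit_data(s, window)
  pk_rot <- interior_peak(d$nu, d$obs, min(d$nu), 0.01)
  tau_rot0 <- if (is.null(pk_rot)) 200 else 1 / (2 * pi * pk_rot$nu)
  chi_bulk <- value_at(d$nu, d$obs, 0.15)
  sc <- chi_bulk / 0.39                    # water amplitude scale
  raman <- find_raman_starts(d$nu, d$obs)
  pars <- rbind(
    par_table("rotation.delta", 2 * max(d$obs[d$nu < 0.003]), 1e-9 * sc, 1e3),
    par_table("rotation.tau", tau_rot0, 10, 1e4),
    par_table("relaxation_pl.amplitude", 0.02 * sc, 1e-9 * sc, 10),
    par_table("relaxation_pl.alpha", 0.3, 0.05, 0.8, log = FALSE),
    par_table("bulk.delta", sc * 0.8, 1e-3 * sc, 50),
    par_table("bulk.tau", 1.0, 0.2, 6),
    par_table("hydration.delta", sc * 0.5, 1e-4 * sc, 50),
    par_table("hydration.rho", 5, 2, 15),
    par_table("ultraslow.delta", 0.05 * sc, 1e-9 * sc, 10),
    par_table("ultraslow.rho", 3, 2, 5, log = FALSE),
    par_table("bending.delta", value_at(d$nu, d$obs, 1.5) * 1.4 / 1.5 * 0.6,
              1e-4, 100),
    par_table("bending.nu0", 1.5, 0.8, 2.8),
    par_table("bending.gamma", 1.5, 0.3, 4),
    par_table("stretching.delta", value_at(d$nu, d$obs, 5.1) * 2.6 / 5.1 * 0.8,
              1e-4, 100),
    par_table("stretching.nu0", 5.0, 3.5, 7.5),
    par_table("stretching.gamma", 2.5, 0.8, 6),
    par_table("raman1.delta", value_at(d$nu, d$obs, raman[1]) * 0.15, 1e-4, 100),
    par_table("raman1.nu0", raman[1], 11, 17),
    par_table("raman1.gamma", 2, 0.5, 5),
    par_table("raman2.delta", value_at(d$nu, d$obs, raman[2]) * 0.15, 1e-4, 100),
    par_table("raman2.nu0", raman[2], 17, 26),
    par_table("raman2.gamma", 2.5, 0.5, 6),
    par_table("bo1.delta", 0.1 * sc, 1e-9 * sc, 10),
    par_table("bo1.nu0", 0.4, 0.25, 0.7),
    par_table("bo1.gamma", 1.0, 0.2, 5),
    par_table("bo2.delta", 0.15 * sc, 1e-9 * sc, 10),
    par_table("bo2.nu0", 1.0, 0.7, 1.6),
    par_table("bo2.gamma", 1.2, 0.2, 5),
    par_table("bo3.delta", 0.08 * sc, 1e-9 * sc, 10),
    par_table("bo3.nu0", 2.5, 1.6, 3.2),
    par_table("bo3.gamma", 2.0, 0.2, 5))
  build <- function(p) susceptibility_model(
    model_component("debye", "SR", "rotation", delta = p[["rotation.delta"]],
                    tau = p[["rotation.tau"]]),
    model_component("power_law", "SR", "relaxation_pl",
                    amplitude = p[["relaxation_pl.amplitude"]],
                    alpha = p[["relaxation_pl.alpha"]]),
    model_component("cole_davidson", "WR_bulk", "bulk",
                    delta = p[["bulk.delta"]], tau = p[["bulk.tau"]],
                    beta = beta),
    model_component("cole_davidson", "WR_hydration", "hydration",
                    delta = p[["hydration.delta"]],
                    tau = p[["hydration.rho"]] * p[["bulk.tau"]],
                    beta = beta),
    model_component("cole_davidson", "WR_ultraslow", "ultraslow",
                    delta = p[["ultraslow.delta"]],
                    tau = p[["ultraslow.rho"]] * p[["hydration.rho"]] *
                          p[["bulk.tau"]],
                    beta = beta),
    model_component("dho", "VIB", "bending", delta = p[["bending.delta"]],
                    nu0 = p[["bending.nu0"]], gamma = p[["bending.gamma"]]),
    model_component("dho", "VIB", "stretching",
                    delta = p[["stretching.delta"]],
                    nu0 = p[["stretching.nu0"]],
                    gamma = p[["stretching.gamma"]]),
    model_component("dho", "VIB", "raman1", delta = p[["raman1.delta"]],
                    nu0 = p[["raman1.nu0"]], gamma = p[["raman1.gamma"]]),
    model_component("dho", "VIB", "raman2", delta = p[["raman2.delta"]],
                    nu0 = p[["raman2.nu0"]], gamma = p[["raman2.gamma"]]),
    model_component("brownian_oscillator", "VIB", "bo1",
                    delta = p[["bo1.delta"]], nu0 = p[["bo1.nu0"]],
                    gamma = p[["bo1.gamma"]]),
    model_component("brownian_oscillator", "VIB", "bo2",
                    delta = p[["bo2.delta"]], nu0 = p[["bo2.nu0"]],
                    gamma = p[["bo2.gamma"]]),
    model_component("brownian_oscillator", "VIB", "bo3",
                    delta = p[["bo3.delta"]], nu0 = p[["bo3.nu0"]],
                    gamma = p[["bo3.gamma"]]))
  ## the ultraslow time ratio direction is shallow; profile it
  base <- pars[pars$name != "ultraslow.rho", ]
  eng <- profile_fit(d$nu, d$obs, d$w, base, build, "ultraslow.rho",
                     c(2.2, 2.8, 3.5, 4.4), lower = 2, upper = 5,
                     log = FALSE, objective = "log")
  new_edls_fit(eng, s, d$nu, d$obs, d$w, window, "direct",
               fixed = c(bulk.beta = beta, hydration.beta = beta,
                         ultraslow.beta = beta),
               idx = d$idx)
}

#' Fit a broadband susceptibility spectrum
#'
#' Umbrella entry dispatching to the stage-specific fitters:
#' `"water"` ([fit_water()]), `"binary"` ([fit_wt()]), `"difference"`
#' ([fit_ds()]), `"ternary"` ([fit_ternary()]), `"direct"`
#' ([fit_wtl_direct()]).
#'
#' @param s susceptibility [spectrum()].
#' @param stage which model/protocol stage to fit.
#' @param ... passed to the stage fitter.
#' @return an `"edls_fit"` object.
#' @export
fit_edls <- function(s, stage = c("binary", "water", "difference",
                                  "ternary", "direct"), ...) {
  stage <- match.arg(stage)
  switch(stage,
         water = fit_water(s, ...),
         binary = fit_wt(s, ...),
         difference = fit_ds(s, ...),
         ternary = fit_ternary(s, ...),
         direct = fit_wtl_direct(s, ...))
}
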