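## Calibrated system presets used by the synthetic-spectrum generator.
##
## The presets encode the component inventory of the broadband
## susceptibility decomposition for pure water (W), water-trehalose
## (WT, 40 wt%), water-lysozyme (WL, 4 wt%) and the ternary mixture
## (WTL, 3 wt% lysozyme + 40 wt% trehalose):
##   - solute rotation: Debye (trehalose) and a nu^-0.3 power law
##     (protein structural relaxation);
##   - water relaxations: Cole-Davidson terms with beta = 0.6 -- bulk
##     (tau ~ 1 ps at 25 degC), hydration (6x slower) and, only when both
##     protein and sugar are present, an ultraslow term 17x slower than
##     bulk whose amplitude fraction corresponds to ~710 waters per
##     lysozyme;
##   - vibrations: H-bond bending (1.5 THz) and stretching (5.1 THz) DHO
##     bands of water, two solute Raman bands above 10 THz, and for
##     protein systems three Brownian oscillators in the 0.3-3 THz window
##     including a boson-peak-like band.
## Relaxation times follow an Arrhenius law with apparent activation
## energies in the 8-10 kJ/mol range; the stretching-band amplitude
## decreases weakly with temperature while the bending band and the
## protein vibrations are temperature-invariant.

.T_REF_C <- 25

cmp_def <- function(kind, role, label, Ea = NA_real_, amp_slope = 0, ...) {
  list(kind = kind, role = role, label = label, Ea = Ea,
       amp_slope = amp_slope, params = list(...))
}

#' System preset for the synthetic spectrum generator
#'
#' Returns the ground-truth component inventory, composition and
#' temperature behaviour of one of the four reference systems.
#'
#' @param system `"W"` (pure water), `"WT"` (40 wt% trehalose), `"WL"`
#'   (4 wt% lysozyme) or `"WTL"` (3 wt% lysozyme + 40 wt% trehalose).
#' @param N_ultraslow_target for `"WTL"`, the size of the ultraslow
#'   hydration shell the amplitudes are calibrated to (waters per
#'   lysozyme).
#' @return object of class `"system_preset"`.
#' @export
edls_preset <- function(system = c("WT", "WTL", "W", "WL"),
                        N_ultraslow_target = 710) {
  system <- match.arg(system)
  comp <- switch(system,
    W = mixture_composition(water = 1, lysozyme = 0, trehalose = 0),
    WT = mixture_composition(lysozyme = 0, trehalose = 0.40, water = 0.60),
    WL = mixture_composition(lysozyme = 0.04, trehalose = 0, water = 0.96),
    WTL = mixture_composition(lysozyme = 0.03, trehalose = 0.40, water = 0.57))

  water_vib <- list(
    cmp_def("dho", "VIB", "bending", delta = 0.35, nu0 = 1.5, gamma = 1.4),
    cmp_def("dho", "VIB", "stretching", amp_slope = 0.006,
            delta = 0.70, nu0 = 5.1, gamma = 2.6))
  ## strong solute Raman modes above 10 THz: the anchor of the spectrum
  ## normalization, far more intense than any protein tail reaching there
  solute_raman <- list(
    cmp_def("dho", "VIB", "raman1", delta = 2.0, nu0 = 14, gamma = 2.0),
    cmp_def("dho", "VIB", "raman2", delta = 1.6, nu0 = 20, gamma = 2.5))
  protein_vib <- list(
    cmp_def("brownian_oscillator", "VIB", "bo1",
            delta = 0.08, nu0 = 0.45, gamma = 0.90),
    cmp_def("brownian_oscillator", "VIB", "bo2",
            delta = 0.12, nu0 = 0.95, gamma = 1.20),
    cmp_def("brownian_oscillator", "VIB", "bo3",
            delta = 0.06, nu0 = 2.40, gamma = 2.00))
  bulk <- cmp_def("cole_davidson", "WR_bulk", "bulk", Ea = 8.0,
                  delta = 0.58, tau = 1.0, beta = 0.6)
  hydration <- cmp_def("cole_davidson", "WR_hydration", "hydration", Ea = 9.0,
                       delta = 0.42, tau = 6.0, beta = 0.6)
  rotation <- cmp_def("debye", "SR", "rotation", Ea = 9.5,
                      delta = 3.0, tau = 300)
  ## protein structural relaxation: amplitude set so the nu^-0.3 flank
  ## sits about a decade below the solute rotation tail at the lowest
  ## frequencies, the proportion seen in full-spectrum decompositions of
  ## dilute protein solutions
  pl <- cmp_def("power_law", "SR", "relaxation_pl", amplitude = 0.015,
                alpha = 0.3)

  comps <- switch(system,
    W = c(list(cmp_def("cole_davidson", "WR_bulk", "bulk", Ea = 8.0,
                       delta = 1.0, tau = 1.0, beta = 0.6)),
          water_vib),
    WT = c(list(rotation, bulk, hydration), water_vib, solute_raman),
    WL = c(list(pl, bulk, hydration), water_vib, protein_vib),
    WTL = {
      r <- water_lysozyme_ratio(comp)
      f <- N_ultraslow_target / r      # ultraslow amplitude fraction
      du <- f / (1 - f) * (0.58 + 0.42)
      ultra <- cmp_def("cole_davidson", "WR_ultraslow", "ultraslow",
                       Ea = 10.0, delta = du, tau = 17.0, beta = 0.6)
      c(list(rotation, pl, bulk, hydration, ultra),
        water_vib, solute_raman, protein_vib)
    })
  structure(list(system = system, composition = comp, components = comps,
                 temperatures = c(3.5, 10, 14.5, 25, 35),
                 T_ref_C = .T_REF_C,
                 N_ultraslow_target =
                   if (system == "WTL") N_ultraslow_target else NA_real_),
            class = "system_preset")
}

#' Instantiate the ground-truth model of a preset at a temperature
#'
#' Relaxation times scale as \eqn{\tau(T) = \tau_{25}\exp[E_a/R\,(1/T -
#' 1/T_{25})]}; the stretching-band amplitude decreases linearly with
#' temperature; all other amplitudes are temperature-independent, so the
#' ultraslow amplitude fraction (and hence the shell size) does not change
#' with temperature.
#'
#' @param preset a [edls_preset()].
#' @param T_C temperature in degrees Celsius.
#' @return a [susceptibility_model()] with parameters at `T_C`.
#' @export
preset_model <- function(preset, T_C) {
  stopifnot(inherits(preset, "system_preset"))
  T_K <- T_C + 273.15
  T_ref_K <- preset$T_ref_C + 273.15
  comps <- lapply(preset$components, function(d) {
    p <- d$params
    if (!is.null(p$tau) && is.finite(d$Ea))
      p$tau <- p$tau * exp(d$Ea * 1000 / .const$R * (1 / T_K - 1 / T_ref_K))
    if (d$amp_slope != 0 && !is.null(p$delta))
      p$delta <- p$delta * (1 - d$amp_slope * (T_C - preset$T_ref_C))
    do.call(model_component, c(list(kind = d$kind, role = d$role,
                                    label = d$label), p))
  })
  susceptibility_model(comps)
}

#' @export
print.system_preset <- function(x, ...) {
  cat(sprintf("<system preset> %s: %d components, T grid %s degC\n",
              x$system, length(x$components),
              paste(x$temperatures, collapse = "/")))
  print(x$composition)
  invisible(x)
}

## ground-truth parameter table at temperature T_C
preset_truth <- function(preset, T_C) {
  model <- preset_model(preset, T_C)
  do.call(rbind, lapply(model$components, function(cmp) {
    data.frame(label = cmp$label, kind = cmp$kind, role = cmp$role,
               param = names(cmp$params),
               value = unlist(cmp$params), row.names = NULL)
  }))
}
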