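## Synthetic transmission-like ATR-FTIR spectra as additive pseudo-Voigt
## band mixtures.  Solutions are built as
##   solution = (1 - displacement) * solvent + solute-correlated component
## so the subtraction logic of the SC-IR module has an exact ground truth:
## the displacement fraction is the true rescaling factor and the
## solute-correlated component the true SC spectrum.

pseudo_voigt <- function(x, center, hwhm, amplitude, eta = 0.1) {
  if (amplitude < 0) stop("band amplitude must be >= 0", call. = FALSE)
  g <- exp(-log(2) * ((x - center) / hwhm)^2)
  l <- hwhm^2 / ((x - center)^2 + hwhm^2)
  amplitude * ((1 - eta) * g + eta * l)
}

band_table <- function(center, hwhm, amplitude, assignment, eta = 0.1) {
  data.frame(center = center, hwhm = hwhm, amplitude = amplitude,
             assignment = assignment, eta = eta)
}

eval_bands <- function(x, bands) {
  v <- numeric(length(x))
  for (i in seq_len(nrow(bands)))
    v <- v + pseudo_voigt(x, bands$center[i], bands$hwhm[i],
                          bands$amplitude[i], bands$eta[i])
  v
}

## band inventories ----------------------------------------------------------

## broad OH-stretch profiles are nearly Gaussian in the wings; heavy
## Lorentzian tails would leak into the quiet baseline window
.ftir_water_bands <- function() rbind(
  band_table(600,  250, 0.35, "libration"),
  band_table(1635,  80, 0.30, "HOH_bend"),
  band_table(2120, 150, 0.03, "association"),
  band_table(3280, 220, 0.95, "OH_stretch_strong", eta = 0.03),
  band_table(3490, 160, 0.65, "OH_stretch_weak", eta = 0.03))

.ftir_trehalose_bands <- function() rbind(
  band_table(1040, 30, 0.25, "trehalose_fingerprint"),
  band_table(1100, 25, 0.18, "trehalose_fingerprint"),
  band_table(1150, 25, 0.15, "trehalose_fingerprint"),
  band_table(1360, 40, 0.08, "trehalose_fingerprint"),
  band_table(1450, 40, 0.06, "trehalose_fingerprint"),
  band_table(2920, 60, 0.10, "CH_stretch"),
  band_table(3380, 200, 0.22, "OH_stretch_strong", eta = 0.03))

## protein solute-correlated bands; the perturbed-water OH amplitude is
## smaller in the ternary preset (fewer solute-perturbed waters when the
## sugar shares the solvation shell)
.ftir_lysozyme_sc_bands <- function(oh_perturbed = 0.25) rbind(
  band_table(1650, 40, 0.30, "amide_I"),
  band_table(1550, 35, 0.20, "amide_II"),
  band_table(2900, 70, 0.08, "CH_stretch"),
  band_table(3290, 150, 0.10, "NH_stretch", eta = 0.05),
  band_table(3250, 250, oh_perturbed, "OH_perturbed", eta = 0.03))

.ftir_solid_lysozyme_bands <- function() rbind(
  band_table(1650, 40, 0.90, "amide_I"),
  band_table(1550, 35, 0.60, "amide_II"),
  band_table(2900, 70, 0.30, "CH_stretch"),
  band_table(3290, 180, 0.45, "NH_stretch", eta = 0.05))

#' FTIR band preset for a system
#'
#' @param system one of `"W"`, `"WT"`, `"WL"`, `"WTL"`,
#'   `"lysozyme_solid"`.
#' @return list with the band tables, the solvent recipe and the solute
#'   displacement fraction (the ground-truth rescaling factor of the
#'   SC-IR subtraction).
#' @export
ftir_preset <- function(system = c("W", "WT", "WL", "WTL", "lysozyme_solid")) {
  system <- match.arg(system)
  switch(system,
    W = list(system = system, solvent = NULL, displacement = 0,
             bands = .ftir_water_bands()),
    WT = list(system = system, solvent = "W", displacement = 0.28,
              bands = .ftir_trehalose_bands()),
    WL = list(system = system, solvent = "W", displacement = 0.05,
              bands = .ftir_lysozyme_sc_bands(oh_perturbed = 0.25)),
    WTL = list(system = system, solvent = "WT", displacement = 0.03,
               bands = .ftir_lysozyme_sc_bands(oh_perturbed = 0.15)),
    lysozyme_solid = list(system = system, solvent = NULL, displacement = 0,
                          bands = .ftir_solid_lysozyme_bands()))
}

#' Generate a synthetic transmission-like FTIR spectrum
#'
#' Sum-of-bands construction on a 2 cm-1 grid over 300-5000 cm-1.  For a
#' solution system the spectrum is
#' `(1 - displacement) * solvent + solute bands`, recursively: the ternary
#' system uses the binary water-trehalose spectrum as its solvent, which
#' represents the protein solvation medium.  A constant offset (to
#' exercise baseline correction) and additive Gaussian noise are applied
#' last.
#'
#' @param system system label or a [ftir_preset()].
#' @param noise additive noise standard deviation (absorbance units).
#' @param seed integer seed.
#' @param offset constant baseline offset added to the spectrum.
#' @param grid wavenumber grid in cm-1 (default `seq(300, 5000, by = 2)`).
#' @return a [spectrum()] (unit cm-1, technique `"FTIR"`) with attribute
#'   `"ground_truth"`: list with the true solvent spectrum, displacement
#'   factor, true solute-correlated spectrum, offset and band table.
#' @export
simulate_ftir <- function(system = "WL", noise = 0, seed = NULL,
                          offset = 0.02, grid = seq(300, 5000, by = 2)) {
  preset <- if (is.list(system) && !is.null(system$bands)) system
            else ftir_preset(system)
  if (any(preset$bands$amplitude < 0))
    stop("band amplitudes must be >= 0", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  solvent_clean <- if (is.null(preset$solvent)) NULL else
    simulate_ftir(preset$solvent, noise = 0, offset = 0, grid = grid)
  sc_true <- eval_bands(grid, preset$bands)
  base <- if (is.null(solvent_clean)) 0 else
    (1 - preset$displacement) * solvent_clean$value
  v <- base + sc_true + offset
  if (noise > 0) v <- v + stats::rnorm(length(grid), 0, noise)
  out <- spectrum(grid, v, unit = "cm-1", system = preset$system,
                  technique = "FTIR")
  out$meta$seed <- seed
  attr(out, "ground_truth") <- list(
    solvent = solvent_clean,
    factor = if (is.null(solvent_clean)) NA_real_ else 1 - preset$displacement,
    sc_true = spectrum(grid, sc_true, unit = "cm-1",
                       system = preset$system, technique = "FTIR"),
    offset = offset, bands = preset$bands)
  out
}
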