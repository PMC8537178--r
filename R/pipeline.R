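## The full staged protocol for one temperature, and its aggregation
## over a temperature series.

#' Run the staged ternary decomposition for one temperature
#'
#' Normalizes the ternary and binary spectra to the common solute Raman
#' band, fits the binary model, forms the difference spectrum, fits the
#' protein contribution on it, and finally fits the constrained ternary
#' model.
#'
#' @param wtl,wt ternary and binary susceptibility [spectrum()] objects at
#'   the same temperature.
#' @param beta fixed Cole-Davidson shape parameter.
#' @param band normalization band in THz.
#' @return list with elements `wt_fit`, `ds`, `ds_fit`, `ternary_fit`.
#' @export
ternary_pipeline <- function(wtl, wt, beta = 0.6, band = c(10, Inf)) {
  wtl_n <- normalize_to_band(wtl, band)
  wt_n <- normalize_to_band(wt, band)
  wt_fit <- fit_wt(wt_n, beta = beta)
  ds <- difference_spectrum(wtl_n, wt_n, normalize = FALSE)
  ds_fit <- fit_ds(ds, wt_fit = wt_fit, weights_ref = attr(ds, "parent"),
                   beta = beta)
  ternary_fit <- fit_ternary(wtl_n, wt_fit, ds_fit, beta = beta)
  list(wt_fit = wt_fit, ds = ds, ds_fit = ds_fit, ternary_fit = ternary_fit)
}

#' Staged decomposition across a temperature series
#'
#' Applies [ternary_pipeline()] at each temperature and aggregates the
#' ternary fits with [summarize_hydration()].
#'
#' @param wtl_series,wt_series named lists of spectra (one per
#'   temperature, matching order).
#' @param comp ternary [mixture_composition()].
#' @param ... passed to [ternary_pipeline()].
#' @return list with `pipelines` (per temperature) and `summary`
#'   (a `"hydration_summary"`).
#' @export
hydration_series <- function(wtl_series, wt_series, comp, ...) {
  stopifnot(length(wtl_series) == length(wt_series))
  pipes <- Map(function(wtl, wt) ternary_pipeline(wtl, wt, ...),
               wtl_series, wt_series)
  fits <- lapply(pipes, `[[`, "ternary_fit")
  list(pipelines = pipes, summary = summarize_hydration(fits, comp))
}
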