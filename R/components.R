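## Analytic susceptibility components.
##
## All component functions take ordinary frequency nu in THz.  Relaxation
## times tau are in ps, so the angular product is omega*tau =
## 2*pi*nu[THz]*tau[ps] (THz.ps = 1).  Oscillator centers nu0 and dampings
## gamma are ordinary frequencies in THz; the damped-oscillator line shape
## is invariant under the nu <-> omega rescaling, so it is evaluated in nu
## directly.

#' Debye relaxation susceptibility
#'
#' \eqn{\chi''(\nu) = \Delta\,\omega\tau / (1 + \omega^2\tau^2)} with
#' \eqn{\omega = 2\pi\nu}.  Single maximum of height \eqn{\Delta/2} at
#' \eqn{\omega\tau = 1}.
#'
#' @param nu frequency grid in THz.
#' @param delta relaxation strength (amplitude), >= 0.
#' @param tau relaxation time in ps, > 0.
#' @return susceptibility values on `nu`.
#' @export
chi_debye <- function(nu, delta, tau) {
  stopifnot(delta >= 0, tau > 0)
  wt <- 2 * pi * nu * tau
  delta * wt / (1 + wt^2)
}

#' Cole-Davidson relaxation susceptibility
#'
#' Asymmetrically broadened relaxation with shape parameter
#' \eqn{0 < \beta \le 1}:
#' \eqn{\chi''(\nu) = \Delta (\cos\varphi)^\beta \sin(\beta\varphi)},
#' \eqn{\varphi = \arctan(\omega\tau)}.  Reduces to [chi_debye()] at
#' \eqn{\beta = 1}; the high-frequency flank decays as \eqn{\omega^{-\beta}}.
#'
#' @inheritParams chi_debye
#' @param beta shape parameter in (0, 1].
#' @export
chi_cole_davidson <- function(nu, delta, tau, beta) {
  stopifnot(delta >= 0, tau > 0)
  if (beta <= 0 || beta > 1) stop("`beta` must be in (0, 1]", call. = FALSE)
  phi <- atan(2 * pi * nu * tau)
  delta * cos(phi)^beta * sin(beta * phi)
}

#' Damped harmonic oscillator susceptibility
#'
#' \eqn{\chi''(\nu) = \Delta\,\nu_0^2\Gamma\nu /
#' [(\nu_0^2 - \nu^2)^2 + \Gamma^2\nu^2]}; the value at the center is
#' exactly \eqn{\Delta\,\nu_0/\Gamma}.  Used for the intermolecular
#' H-bond bending (~1.5 THz) and stretching (~5.1 THz) bands of water and
#' for solute Raman bands.
#'
#' @inheritParams chi_debye
#' @param nu0 center frequency in THz, > 0.
#' @param gamma damping in THz, > 0.
#' @export
chi_dho <- function(nu, delta, nu0, gamma) {
  stopifnot(delta >= 0, nu0 > 0, gamma > 0)
  delta * nu0^2 * gamma * nu / ((nu0^2 - nu^2)^2 + gamma^2 * nu^2)
}

#' Brownian oscillator susceptibility
#'
#' Same response function as [chi_dho()]; kept as a distinct component
#' kind because overdamped Brownian oscillators model low-frequency
#' protein modes (side-chain librations, backbone torsions, boson peak)
#' and must stay separable from the water bands in reports.
#'
#' @inheritParams chi_dho
#' @export
chi_brownian <- function(nu, delta, nu0, gamma) chi_dho(nu, delta, nu0, gamma)

#' Power-law susceptibility
#'
#' \eqn{\chi''(\nu) = A\,\nu^{-\alpha}} (nu in THz); models the protein
#' structural relaxation flank (\eqn{\alpha \approx 0.3}).
#'
#' @param nu frequency grid in THz, all > 0.
#' @param amplitude prefactor A, >= 0.
#' @param alpha positive exponent.
#' @export
chi_power_law <- function(nu, amplitude, alpha) {
  stopifnot(amplitude >= 0, alpha > 0)
  if (any(nu <= 0)) stop("power law undefined at nu <= 0", call. = FALSE)
  amplitude * nu^(-alpha)
}

.component_kinds <- c("debye", "cole_davidson", "dho", "brownian_oscillator",
                      "power_law")
.component_roles <- c("SR", "WR_bulk", "WR_hydration", "WR_ultraslow", "VIB")

#' Define one susceptibility model component
#'
#' @param kind one of `"debye"`, `"cole_davidson"`, `"dho"`,
#'   `"brownian_oscillator"`, `"power_law"`.
#' @param role model group: `"SR"` (solute rotation / structural
#'   relaxation), `"WR_bulk"`, `"WR_hydration"`, `"WR_ultraslow"` (water
#'   relaxations), or `"VIB"` (vibrational bands).
#' @param label short unique name used in reports (e.g. `"bulk"`).
#' @param ... numeric parameters for the component kind: `delta`, `tau`
#'   (ps), `beta`, `nu0` (THz), `gamma` (THz), `amplitude`, `alpha`.
#' @return object of class `"model_component"`.
#' @export
model_component <- function(kind, role, label, ...) {
  kind <- match.arg(kind, .component_kinds)
  role <- match.arg(role, .component_roles)
  params <- list(...)
  need <- switch(kind,
    debye = c("delta", "tau"),
    cole_davidson = c("delta", "tau", "beta"),
    dho = , brownian_oscillator = c("delta", "nu0", "gamma"),
    power_law = c("amplitude", "alpha"))
  missing <- setdiff(need, names(params))
  if (length(missing))
    stop(sprintf("component '%s' (%s) missing parameter(s): %s",
                 label, kind, paste(missing, collapse = ", ")), call. = FALSE)
  structure(list(kind = kind, role = role, label = label,
                 params = params[need]),
            class = "model_component")
}

eval_component <- function(comp, nu_THz) {
  p <- comp$params
  switch(comp$kind,
    debye = chi_debye(nu_THz, p$delta, p$tau),
    cole_davidson = chi_cole_davidson(nu_THz, p$delta, p$tau, p$beta),
    dho = chi_dho(nu_THz, p$delta, p$nu0, p$gamma),
    brownian_oscillator = chi_brownian(nu_THz, p$delta, p$nu0, p$gamma),
    power_law = chi_power_law(nu_THz, p$amplitude, p$alpha))
}

#' Assemble a susceptibility model from components
#'
#' The model evaluates as the pointwise sum of its components; the SR /
#' WR / VIB roles partition the components into the three groups of the
#' phenomenological decomposition
#' \eqn{\chi'' = \chi''_{SR} + \chi''_{WR} + \chi''_{VIB}}.
#'
#' @param ... [model_component()] objects (or a single list of them).
#' @return object of class `"chi_model"`.
#' @export
susceptibility_model <- function(...) {
  comps <- list(...)
  if (length(comps) == 1 && !inherits(comps[[1]], "model_component"))
    comps <- comps[[1]]
  if (!length(comps)) stop("model has no components", call. = FALSE)
  ok <- vapply(comps, inherits, logical(1), "model_component")
  if (!all(ok)) stop("all arguments must be model_component objects", call. = FALSE)
  labels <- vapply(comps, `[[`, character(1), "label")
  if (anyDuplicated(labels))
    stop("component labels must be unique", call. = FALSE)
  names(comps) <- labels
  structure(list(components = comps), class = "chi_model")
}

#' Evaluate a susceptibility model on a frequency grid
#'
#' @param model a [susceptibility_model()].
#' @param frequency numeric grid (in `unit`), or a [spectrum()] whose grid
#'   is reused.
#' @param unit frequency unit of `frequency`.
#' @param temperature,system metadata attached to the returned spectrum.
#' @return a spectrum of technique `"DLS_susceptibility"`; attribute
#'   `"partials"` holds the per-component value matrix and `"groups"` the
#'   SR / WR / VIB partial sums.
#' @export
evaluate_model <- function(model, frequency, unit = "GHz",
                           temperature = NA_real_, system = NA_character_) {
  stopifnot(inherits(model, "chi_model"))
  if (inherits(frequency, "spectrum")) {
    unit <- frequency$unit
    temperature <- frequency$meta$temperature
    system <- frequency$meta$system
    frequency <- frequency$frequency
  }
  nu <- convert_frequency(frequency, unit, "THz")
  partials <- vapply(model$components, eval_component, numeric(length(nu)),
                     nu_THz = nu)
  partials <- matrix(partials, nrow = length(nu),
                     dimnames = list(NULL, names(model$components)))
  total <- rowSums(partials)
  roles <- vapply(model$components, `[[`, character(1), "role")
  grp <- ifelse(roles == "VIB", "VIB", substr(roles, 1, 2))  # WR_* -> WR
  groups <- sapply(c("SR", "WR", "VIB"), function(g)
    rowSums(partials[, grp == g, drop = FALSE]))
  out <- spectrum(frequency, total, unit = unit, temperature = temperature,
                  system = system, technique = "DLS_susceptibility")
  attr(out, "partials") <- partials
  attr(out, "groups") <- groups
  out
}

#' @export
print.chi_model <- function(x, ...) {
  cat(sprintf("<susceptibility model> %d components\n", length(x$components)))
  for (cmp in x$components) {
    p <- paste(sprintf("%s=%.4g", names(cmp$params), unlist(cmp$params)),
               collapse = ", ")
    cat(sprintf("  %-12s %-20s [%s]  %s\n", cmp$label, cmp$kind, cmp$role, p))
  }
  invisible(x)
}

## helpers used across modules ------------------------------------------------

model_roles <- function(model)
  vapply(model$components, `[[`, character(1), "role")

#' Component labels of a model
#' @param model a [susceptibility_model()].
#' @export
model_labels <- function(model) names(model$components)

## amplitude (delta or amplitude) of each component, named by label
model_amplitudes <- function(model) {
  vapply(model$components, function(cmp)
    cmp$params$delta %||% cmp$params$amplitude, numeric(1))
}

#' Extract one parameter of a labelled component
#' @param model a [susceptibility_model()].
#' @param label component label.
#' @param param parameter name (`"delta"`, `"tau"`, ...).
#' @return the value, or `NULL` if absent.
#' @export
model_param <- function(model, label, param)
  model$components[[label]]$params[[param]]

#' Subset a model by component label or role
#' @param model a [susceptibility_model()].
#' @param labels labels to keep (default all).
#' @param roles roles to keep (default all).
#' @return a [susceptibility_model()] with the selected components.
#' @export
model_subset <- function(model, labels = NULL, roles = NULL) {
  comps <- model$components
  keep <- rep(TRUE, length(comps))
  if (!is.null(labels)) keep <- keep & names(comps) %in% labels
  if (!is.null(roles)) keep <- keep & model_roles(model) %in% roles
  if (!any(keep)) stop("model subset is empty", call. = FALSE)
  susceptibility_model(comps[keep])
}
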