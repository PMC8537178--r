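## Methods and accessors for fitted spectral decompositions.

#' @export
coef.edls_fit <- function(object, ...) object$par

#' @export
fitted.edls_fit <- function(object, ...) object$fitted_values

#' @export
residuals.edls_fit <- function(object, weighted = FALSE, ...)
  if (weighted) object$wresiduals else object$residuals

#' @export
deviance.edls_fit <- function(object, ...) object$deviance

#' Predict model (or component group) values on a frequency grid
#'
#' @param object an `"edls_fit"`.
#' @param frequency grid to evaluate on (default the fitted grid), in
#'   `unit`.
#' @param unit frequency unit of `frequency`.
#' @param group `"total"`, `"SR"`, `"WR"`, `"VIB"`, or a component label.
#' @param ... unused.
#' @return numeric vector of susceptibility values.
#' @export
predict.edls_fit <- function(object, frequency = NULL, unit = "THz",
                             group = "total", ...) {
  if (is.null(frequency)) { frequency <- object$nu_THz; unit <- "THz" }
  ev <- evaluate_model(object$model, frequency, unit = unit)
  if (group == "total") return(ev$value)
  groups <- attr(ev, "groups")
  if (group %in% colnames(groups)) return(groups[, group])
  partials <- attr(ev, "partials")
  if (group %in% colnames(partials)) return(partials[, group])
  stop(sprintf("unknown group or component '%s'", group), call. = FALSE)
}

#' Simulate noisy replicates from a fitted model
#'
#' Draws multiplicative lognormal noise around the fitted curve, matching
#' the error model of the weighted least-squares objective.
#'
#' @param object an `"edls_fit"`.
#' @param nsim number of replicates.
#' @param seed optional integer seed.
#' @param noise relative noise SD; default the residual relative SD.
#' @param ... unused.
#' @return data.frame with one column per replicate.
#' @export
simulate.edls_fit <- function(object, nsim = 1, seed = NULL, noise = NULL,
                              ...) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(noise))
    noise <- stats::sd(object$residuals / object$fitted_values)
  n <- length(object$fitted_values)
  out <- as.data.frame(replicate(nsim, object$fitted_values *
                                   exp(stats::rnorm(n, 0, noise))))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' @export
print.edls_fit <- function(x, ...) {
  cat(sprintf("<spectral fit> stage '%s': %d free parameters, %d points\n",
              x$stage, length(x$par), length(x$obs)))
  cat(sprintf("  weighted RSS %.4g after %d iterations\n", x$deviance, x$niter))
  invisible(x)
}

#' @export
summary.edls_fit <- function(object, ...) {
  tab <- data.frame(estimate = object$par, se = object$se)
  taus <- tryCatch(water_taus(object), error = function(e) NULL)
  xi <- NULL
  if (!is.null(taus) && is.finite(taus[["hydration"]]) &&
      is.finite(taus[["bulk"]])) {
    xi <- c(hydration = unname(taus[["hydration"]] / taus[["bulk"]]))
    if (is.finite(taus[["ultraslow"]]))
      xi <- c(xi, ultraslow = unname(taus[["ultraslow"]] / taus[["bulk"]]))
  }
  structure(list(stage = object$stage, coefficients = tab,
                 deviance = object$deviance, niter = object$niter,
                 n = length(object$obs), retardation = xi,
                 fractions = tryCatch(amplitude_fractions(object),
                                      error = function(e) NULL)),
            class = "summary.edls_fit")
}

#' @export
print.summary.edls_fit <- function(x, digits = 4, ...) {
  cat(sprintf("Spectral decomposition, stage '%s' (%d points)\n", x$stage, x$n))
  print(round(x$coefficients, digits))
  cat(sprintf("weighted RSS: %.5g  iterations: %d\n", x$deviance, x$niter))
  if (!is.null(x$retardation))
    cat("retardation factors:",
        paste(sprintf("%s %.3g", names(x$retardation), x$retardation),
              collapse = ", "), "\n")
  invisible(x)
}

#' @export
plot.edls_fit <- function(x, components = TRUE, ...) {
  graphics::plot(x$nu_THz, x$obs, log = "xy", pch = 16, cex = 0.4,
                 col = "grey40", xlab = "frequency (THz)",
                 ylab = "susceptibility", ...)
  graphics::lines(x$nu_THz, x$fitted_values, col = "red", lwd = 1.5)
  if (components) {
    ev <- evaluate_model(x$model, x$nu_THz, unit = "THz")
    partials <- attr(ev, "partials")
    for (j in seq_len(ncol(partials)))
      graphics::lines(x$nu_THz, partials[, j], col = j + 1, lty = 2)
    graphics::legend("bottomleft", c("fit", colnames(partials)),
                     col = c("red", seq_len(ncol(partials)) + 1),
                     lty = c(1, rep(2, ncol(partials))), cex = 0.6,
                     bty = "n")
  }
  invisible(x)
}

## accessors -------------------------------------------------------------

#' Water relaxation amplitudes of a fitted model
#'
#' @param fit an `"edls_fit"` (or a `"chi_model"`).
#' @return named vector `bulk`, `hydration`, `ultraslow` (NA when a
#'   component is absent from the model).
#' @export
water_amplitudes <- function(fit) {
  model <- if (inherits(fit, "edls_fit")) fit$model else fit
  get1 <- function(lbl) {
    v <- model_param(model, lbl, "delta")
    if (is.null(v)) NA_real_ else v
  }
  c(bulk = get1("bulk"), hydration = get1("hydration"),
    ultraslow = get1("ultraslow"))
}

#' Water relaxation times of a fitted model (ps)
#'
#' @inheritParams water_amplitudes
#' @return named vector `bulk`, `hydration`, `ultraslow`.
#' @export
water_taus <- function(fit) {
  model <- if (inherits(fit, "edls_fit")) fit$model else fit
  get1 <- function(lbl) {
    v <- model_param(model, lbl, "tau")
    if (is.null(v)) NA_real_ else v
  }
  c(bulk = get1("bulk"), hydration = get1("hydration"),
    ultraslow = get1("ultraslow"))
}

#' Water amplitude fractions of a fitted model
#'
#' Fractions of the total water relaxation amplitude
#' \eqn{\Delta_{tot} = \Delta_{ultraslow} + \Delta_{hydr} + \Delta_{bulk}}
#' carried by each water component; scale-invariant, so unaffected by
#' spectrum normalization.
#'
#' @inheritParams water_amplitudes
#' @return named vector summing to 1 over the components present.
#' @export
amplitude_fractions <- function(fit) {
  d <- water_amplitudes(fit)
  d <- d[is.finite(d)]
  if (!length(d) || sum(d) <= 0)
    stop("no water amplitudes in this model", call. = FALSE)
  d / sum(d)
}
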