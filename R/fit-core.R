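## Nonlinear least-squares engine shared by all fit stages.
##
## Objective: weighted least squares on the log-spaced grid with weights
## proportional to 1/value (relative residuals), consistent with the
## multiplicative noise of photon-counting spectra.  Positive parameters
## are fitted on a log scale; shape parameters (beta, alpha) and ratio
## parameters stay linear within bounds.  Levenberg-Marquardt with box
## bounds via minpack.lm::nls.lm.

par_table <- function(name, start, lower, upper, log = TRUE) {
  data.frame(name = name, start = start, lower = lower, upper = upper,
             log = log, stringsAsFactors = FALSE)
}

## run a block with the caller's RNG state preserved
with_preserved_seed <- function(expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  force(expr)
}

fit_engine <- function(nu, obs, weights, pars, build_model,
                       maxfev = 10000, tol = 1e-10,
                       objective = c("wls", "log")) {
  objective <- match.arg(objective)
  stopifnot(nrow(pars) >= 1, length(nu) == length(obs),
            length(weights) == length(obs))
  tr <- function(p) ifelse(pars$log, log(p), p)
  itr <- function(pt) {
    p <- ifelse(pars$log, exp(pt), pt)
    names(p) <- pars$name
    p
  }
  ## "log": least squares on log residuals -- the maximum-likelihood
  ## objective under multiplicative lognormal noise, free of the bias
  ## that 1/observation weights inherit from the noise itself
  log_obs <- if (objective == "log") log(obs)
  resid_fn <- function(pt) {
    m <- build_model(itr(pt))
    pred <- rowSums(vapply(m$components, eval_component,
                           numeric(length(nu)), nu_THz = nu))
    if (objective == "log")
      (log(pmax(pred, 1e-300)) - log_obs) * weights
    else (pred - obs) * weights
  }
  run_lm <- function(start) minpack.lm::nls.lm(
    par = start, lower = tr(pars$lower), upper = tr(pars$upper),
    fn = resid_fn,
    control = minpack.lm::nls.lm.control(maxfev = maxfev, maxiter = 1000,
                                         ftol = tol, ptol = tol))
  res <- run_lm(tr(pars$start))
  ## restarting from the solution resets the trust region; rescues runs
  ## where the damping collapsed early in a curved valley
  for (k in 1:4) {
    res2 <- run_lm(res$par)
    if (res2$deviance <= res$deviance) {
      improved <- res$deviance - res2$deviance > 1e-6 * res$deviance
      res <- res2
      if (!improved) break
    } else break
  }
  if (!(res$info %in% 1:4))
    stop(sprintf("fit did not converge (info %d after %d evaluations): %s",
                 res$info, res$niter, res$message), call. = FALSE)
  p <- itr(res$par)
  ## standard errors: delta method back from the transformed scale
  se_t <- rep(NA_real_, length(p))
  cv <- tryCatch(stats::vcov(res), error = function(e) NULL)
  if (!is.null(cv)) se_t <- sqrt(pmax(diag(cv), 0))
  se <- ifelse(pars$log, se_t * p, se_t)
  names(se) <- pars$name
  at_bound <- (abs(res$par - tr(pars$lower)) < 1e-6 * pmax(abs(tr(pars$lower)), 1)) |
              (abs(res$par - tr(pars$upper)) < 1e-6 * pmax(abs(tr(pars$upper)), 1))
  if (any(at_bound))
    warning("parameter(s) at bound: ",
            paste(pars$name[at_bound], collapse = ", "), call. = FALSE)
  model <- build_model(p)
  pred <- rowSums(vapply(model$components, eval_component,
                         numeric(length(nu)), nu_THz = nu))
  list(par = p, se = se, model = model, fitted = pred,
       residuals = obs - pred, wresiduals = (obs - pred) * weights,
       deviance = res$deviance, niter = res$niter, info = res$info,
       message = res$message)
}

## assemble the exported fit-result object
new_edls_fit <- function(eng, data, nu, obs, weights, window, stage,
                         fixed = NULL, idx = NULL) {
  structure(list(model = eng$model, par = eng$par, se = eng$se,
                 fixed = fixed,
                 fitted_values = eng$fitted, residuals = eng$residuals,
                 wresiduals = eng$wresiduals, deviance = eng$deviance,
                 niter = eng$niter, info = eng$info,
                 nu_THz = nu, obs = obs, weights = weights, idx = idx,
                 window = window, stage = stage, data = data),
            class = "edls_fit")
}

## data prep: window in THz; positive observations with unit weights for
## the log objective, or caller-supplied linear weights
prep_fit_data <- function(s, window = NULL, weights = NULL) {
  stopifnot(inherits(s, "spectrum"))
  nu <- freq_THz(s)
  obs <- s$value
  keep <- rep(TRUE, length(nu))
  if (!is.null(window)) keep <- nu >= window[1] & nu <= window[2]
  if (is.null(weights)) {
    keep <- keep & obs > 0
    w <- rep(1, length(obs))
  } else {
    w <- weights
    keep <- keep & is.finite(w) & w > 0
  }
  idx <- which(keep)
  list(nu = nu[idx], obs = obs[idx], w = w[idx], idx = idx)
}

## running-median smooth of a positive series in log space; decouples
## weight references from the point noise of the spectrum they came from
smooth_log <- function(v, k = 9) {
  v <- pmax(v, 1e-300)
  exp(stats::runmed(log(v), k = k, endrule = "median"))
}

## interior local maximum of a spectrum restricted to [lo, hi] THz;
## NULL if the maximum sits on the window edge
interior_peak <- function(nu, val, lo, hi) {
  i <- which(nu >= lo & nu <= hi)
  if (length(i) < 3) return(NULL)
  k <- i[which.max(val[i])]
  if (k == i[1] || k == i[length(i)]) return(NULL)
  list(nu = nu[k], value = val[k])
}

## value of the spectrum near frequency f (THz), by log-log interpolation
value_at <- function(nu, val, f) {
  ok <- val > 0
  exp(stats::approx(log(nu[ok]), log(val[ok]), xout = log(f), rule = 2)$y)
}

## Deterministic profile fit: optimize all parameters in `base_pars` with
## the scalar `prof_name` held at each grid value, keep the best optimum,
## then release the profiled parameter for a final polish.  Robust where
## the objective is shallow or multimodal along one nonlinear direction.
profile_fit <- function(nu, obs, w, base_pars, build, prof_name, grid,
                        lower, upper, log = FALSE,
                        objective = "wls") {
  best <- NULL; best_v <- grid[1]
  for (v in grid) {
    bld <- local({
      vv <- stats::setNames(v, prof_name)
      function(p) build(c(p, vv))
    })
    eng <- tryCatch(suppressWarnings(fit_engine(nu, obs, w, base_pars, bld,
                                                objective = objective)),
                    error = function(e) NULL)
    if (!is.null(eng) && (is.null(best) || eng$deviance < best$deviance)) {
      best <- eng; best_v <- v
    }
  }
  if (is.null(best))
    stop(sprintf("fit failed at every profile point of %s", prof_name),
         call. = FALSE)
  final <- base_pars
  final$start <- pmin(pmax(unname(best$par[final$name]), final$lower),
                      final$upper)
  eps <- 1e-3 * (upper - lower)
  final <- rbind(final,
                 par_table(prof_name, min(max(best_v, lower + eps),
                                          upper - eps),
                           lower, upper, log = log))
  eng <- tryCatch(suppressWarnings(fit_engine(nu, obs, w, final, build,
                                              objective = objective)),
                  error = function(e) NULL)
  if (is.null(eng) || eng$deviance > best$deviance) {
    eng <- best
    eng$par <- c(best$par, stats::setNames(best_v, prof_name))
    eng$se <- c(best$se, stats::setNames(NA_real_, prof_name))
    eng$model <- build(eng$par)
  }
  eng
}

## peak height factor of a Cole-Davidson component: chi_max / delta
cd_peak_factor <- function(beta) {
  phi <- pi / (2 * (1 + beta))
  cos(phi)^beta * sin(beta * phi)
}
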