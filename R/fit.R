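#' Configuration for release-curve parameter estimation
#'
#' Controls the nonlinear least-squares estimation of the transport
#' parameters from cumulative-release profiles.  By default the diffusivity
#' D is shared across all conditions and catheter sizes (the coating is too
#' thin to alter the bulk diffusion path) while the partition coefficients
#' gamma_L and gamma_D are estimated per condition.  Fitting is performed in
#' log-parameter space, which enforces positivity and makes the optimiser
#' scale-free; linear-space fitting is available for cross-checks.
#'
#' @param share_D Share one diffusivity across all conditions (default TRUE).
#' @param log_scale Optimise over log-parameters (default TRUE).
#' @param weighting `"uniform"` (raw residuals, ug/cm^2) or `"relative"`
#'   (residuals scaled by the profile magnitude, for heteroscedastic data).
#' @param numerics `numerics_config` used for every candidate simulation.
#' @param init Optional named vector/list of positive initial guesses
#'   (`D` or `D.<condition>`, `gammaL.<condition>`, `gammaD.<condition>`);
#'   unnamed parameters default to `D = 1e-5`, `gamma = 1`.
#' @param lower,upper Positive box bounds applied to every parameter.
#' @param maxiter,ftol,ptol Levenberg-Marquardt controls.
#' @param penalty Residual value substituted when a candidate simulation
#'   fails (large but finite, keeping the optimiser alive).
#' @return An object of class `fit_config`.
#' @export
fit_config <- function(share_D = TRUE, log_scale = TRUE,
                       weighting = c("uniform", "relative"),
                       numerics = numerics_config(), init = NULL,
                       lower = 1e-10, upper = 1e8,
                       maxiter = 200, ftol = 1e-12, ptol = 1e-12,
                       penalty = 1e6) {
  weighting <- match.arg(weighting)
  if (!is.null(init)) {
    init <- unlist(init)
    if (is.null(names(init)) || any(!nzchar(names(init))))
      stop("init must be a named vector")
    if (any(!is.finite(init) | init <= 0))
      stop("every initial guess must be positive and finite")
  }
  if (lower <= 0 || upper <= lower) stop("bounds must satisfy 0 < lower < upper")
  structure(list(share_D = share_D, log_scale = log_scale,
                 weighting = weighting, numerics = numerics, init = init,
                 lower = lower, upper = upper, maxiter = as.integer(maxiter),
                 ftol = ftol, ptol = ptol, penalty = penalty),
            class = "fit_config")
}

#' Bundle one release profile with its experimental context
#'
#' @param profile Data frame with columns `time_h` (hours since delivery
#'   start, strictly increasing) and `release_ug_cm2`.
#' @param geometry The `catheter_geometry` of the sample.
#' @param protocol The `stage_protocol` the sample followed.
#' @param condition Condition label (e.g. `"control"`, `"LbL"`); parameters
#'   are shared within a condition.
#' @param base A `transport_parameters` supplying the non-fitted constants
#'   (bath concentration, reservoir volume, convective coefficients).
#' @return A list of class `fit_dataset`.
#' @export
fit_dataset <- function(profile, geometry, protocol, condition,
                        base = cfx_parameters("control")) {
  stopifnot(is.data.frame(profile),
            all(c("time_h", "release_ug_cm2") %in% names(profile)),
            inherits(geometry, "catheter_geometry"),
            inherits(protocol, "stage_protocol"),
            inherits(base, "transport_parameters"))
  tt <- profile$time_h
  if (any(diff(tt) <= 0)) stop("profile times must be strictly increasing")
  if (any(tt < 0) || any(tt > protocol$t_end - protocol$t1 + 1e-9))
    stop("profile times must lie within the protocol's delivery window")
  structure(list(profile = profile, geometry = geometry, protocol = protocol,
                 condition = as.character(condition), base = base),
            class = "fit_dataset")
}

# Names of the free parameters implied by the datasets and config.
free_param_names <- function(datasets, config) {
  conds <- unique(vapply(datasets, function(d) d$condition, character(1)))
  dn <- if (config$share_D) "D" else paste0("D.", conds)
  c(dn, paste0("gammaL.", conds), paste0("gammaD.", conds))
}

default_init <- function(par_names) {
  v <- ifelse(startsWith(par_names, "D"), 1e-5, 1)
  setNames(v, par_names)
}

params_for_condition <- function(entry, pv, config) {
  D <- if (config$share_D) pv[["D"]] else pv[[paste0("D.", entry$condition)]]
  transport_parameters(
    diffusivity = D,
    gamma_load = pv[[paste0("gammaL.", entry$condition)]],
    gamma_delivery = pv[[paste0("gammaD.", entry$condition)]],
    k_load = entry$base$k_load, k_delivery = entry$base$k_delivery,
    bath_concentration = entry$base$bath_concentration,
    reservoir_volume = entry$base$reservoir_volume)
}

#' Model-minus-data residuals for a candidate parameter set
#'
#' Simulates the full protocol of every dataset with the candidate
#' parameters (shared parameters applied across datasets) and returns the
#' concatenated residual vector of model minus observed cumulative release
#' at the observed times.  A failing candidate simulation contributes
#' large-but-finite penalty residuals so a surrounding optimiser can recover.
#'
#' @param free_params Named positive vector of candidate values (see
#'   [fit_config()] for the naming scheme).
#' @param datasets List of [fit_dataset()] objects (nonempty).
#' @param config A `fit_config`.
#' @return Numeric residual vector; attribute `n_failures` counts datasets
#'   whose simulation failed under the candidate.
#' @export
release_residuals <- function(free_params, datasets, config = fit_config()) {
  if (length(datasets) == 0) stop("datasets must be nonempty")
  datasets <- lapply(datasets, function(d) {
    if (!inherits(d, "fit_dataset")) stop("each dataset must be a fit_dataset")
    d
  })
  pv <- as.list(free_params)
  needed <- free_param_names(datasets, config)
  missing <- setdiff(needed, names(pv))
  if (length(missing))
    stop("free_params is missing: ", paste(missing, collapse = ", "))
  failures <- 0L
  res <- lapply(datasets, function(entry) {
    obs <- entry$profile
    r <- tryCatch({
      params <- params_for_condition(entry, pv, config)
      sim <- simulate_protocol(entry$geometry, params, entry$protocol,
                               config$numerics)
      prof <- cumulative_release(sim)
      model <- approx(prof$time_h, prof$release_ug_cm2, xout = obs$time_h,
                      rule = 2)$y
      model - obs$release_ug_cm2
    }, error = function(e) {
      failures <<- failures + 1L
      rep(config$penalty, nrow(obs))
    })
    if (config$weighting == "relative") {
      scale <- max(abs(obs$release_ug_cm2), 1e-12)
      r <- r / scale
    }
    r
  })
  out <- unlist(res, use.names = FALSE)
  attr(out, "n_failures") <- failures
  out
}

#' Estimate transport parameters from cumulative-release profiles
#'
#' Bound-constrained Levenberg-Marquardt least squares (numerical Jacobian)
#' over the free parameters named by [fit_config()], by default the shared
#' diffusivity plus per-condition loading and delivery partition
#' coefficients.  Non-convergence is reported through the `converged` flag
#' with best-so-far estimates, not as an error.
#'
#' @param datasets List of [fit_dataset()] objects.
#' @param config A `fit_config`.
#' @param init Optional named initial guesses, overriding `config$init`.
#' @return An object of class `release_fit`: named `estimates`, the implied
#'   per-condition `parameters` (list of `transport_parameters`),
#'   `objective` (sum of squared residuals), `n_iterations`, `converged`,
#'   curvature-based `rel_uncertainty` per parameter, and optimiser
#'   diagnostics.
#' @export
fit_release_parameters <- function(datasets, config = fit_config(),
                                   init = NULL) {
  if (length(datasets) == 0) stop("at least one dataset is required")
  par_names <- free_param_names(datasets, config)
  conds <- unique(vapply(datasets, function(d) d$condition, character(1)))
  if (config$share_D && length(conds) < 2)
    warning("shared diffusivity with a single condition is weakly identified;",
            " a joint fit across conditions is recommended", call. = FALSE)
  p0 <- default_init(par_names)
  for (src in list(config$init, unlist(init))) {
    if (!is.null(src)) {
      known <- intersect(names(src), par_names)
      p0[known] <- src[known]
    }
  }
  fn <- if (config$log_scale) {
    function(p) release_residuals(setNames(exp(p), par_names), datasets, config)
  } else {
    function(p) release_residuals(setNames(p, par_names), datasets, config)
  }
  tr <- if (config$log_scale) log else identity
  inv <- if (config$log_scale) exp else identity
  ctrl <- minpack.lm::nls.lm.control(maxiter = config$maxiter,
                                     ftol = config$ftol, ptol = config$ptol)
  fit <- tryCatch(
    minpack.lm::nls.lm(par = tr(p0), fn = fn,
                       lower = rep(tr(config$lower), length(p0)),
                       upper = rep(tr(config$upper), length(p0)),
                       control = ctrl),
    error = function(e) NULL)
  if (is.null(fit)) {
    est <- p0
    res <- release_residuals(est, datasets, config)
    out <- list(estimates = est, objective = sum(res^2), n_iterations = 0L,
                converged = FALSE, rel_uncertainty = setNames(
                  rep(NA_real_, length(p0)), par_names),
                message = "optimizer raised an error; returning initial guesses")
  } else {
    est <- setNames(inv(fit$par), par_names)
    n_obs <- sum(vapply(datasets, function(d) nrow(d$profile), integer(1)))
    s2 <- fit$deviance / max(1L, n_obs - length(est))
    relu <- tryCatch({
      covm <- chol2inv(chol(fit$hessian))
      u <- sqrt(pmax(diag(covm), 0) * s2)
      # in log space the standard error of log(p) is already relative
      if (!config$log_scale) u <- u / abs(est)
      setNames(u, par_names)
    }, error = function(e) setNames(rep(NA_real_, length(est)), par_names))
    out <- list(estimates = est, objective = fit$deviance,
                n_iterations = fit$niter,
                converged = fit$info %in% 1:4,
                rel_uncertainty = relu, message = fit$message)
  }
  out$parameters <- setNames(lapply(conds, function(cc) {
    entry <- datasets[[which(vapply(datasets, function(d) d$condition,
                                    character(1)) == cc)[1]]]
    params_for_condition(entry, as.list(out$estimates), config)
  }), conds)
  out$conditions <- conds
  out$config <- config
  structure(out, class = "release_fit")
}

#' @export
print.release_fit <- function(x, ...) {
  cat(sprintf("Release-curve fit (%s): %s after %d iterations, SSR = %.4g\n",
              if (x$config$log_scale) "log-space" else "linear-space",
              if (x$converged) "converged" else "NOT converged",
              x$n_iterations, x$objective))
  est <- format(signif(x$estimates, 6))
  for (i in seq_along(est))
    cat(sprintf("  %-16s %s  (rel. unc. %.2g)\n", names(est)[i], est[i],
                x$rel_uncertainty[i]))
  invisible(x)
}
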