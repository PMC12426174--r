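#' Cumulative release per external area
#'
#' Converts the delivery-stage reservoir trajectory into the standard
#' cumulative-release curve: release(t) = CD(t) * V_bath / (2*pi*R2*L) with
#' times re-based to the start of delivery.  In pure-sink mode the release is
#' computed from the wall-mass decrement instead (the reservoir concentration
#' is identically zero).
#'
#' @param result A `catheter_simulation`.
#' @return A data frame of class `release_profile` with columns `time_h`
#'   (hours since delivery start), `cd_ug_cm3` and `release_ug_cm2`.
#' @export
cumulative_release <- function(result) {
  stopifnot(inherits(result, "catheter_simulation"))
  d <- result$stages$delivery
  out <- data.frame(
    time_h = d$times - result$protocol$t1,
    cd_ug_cm3 = d$cd,
    release_ug_cm2 = d$release
  )
  class(out) <- c("release_profile", "data.frame")
  attr(out, "sample_id") <- "simulation"
  out
}

#' Short-time loading uptake oracle
#'
#' Closed-form absorbed mass per unit area for loading from a well-mixed bath
#' into a half-space at constant surface concentration gamma_L * C_L:
#' 2 * gamma_L * C_L * sqrt(D * t / pi).  Valid while the penetration depth
#' sqrt(D t) is small compared to the wall thickness and to R2; used as an
#' independent oracle for the early loading stage.
#'
#' @param params A `transport_parameters`.
#' @param t Time(s) since the start of loading, hours; must be positive.
#' @return Uptake per area in ug/cm^2 (vectorised over `t`).
#' @export
#' @examples
#' short_time_uptake(cfx_parameters("control"), 12)  # ~32 ug/cm^2
short_time_uptake <- function(params, t) {
  stopifnot(inherits(params, "transport_parameters"))
  if (any(!is.finite(t) | t <= 0)) stop("t must be positive and finite")
  2 * params$gamma_load * params$bath_concentration *
    sqrt(params$D * t / pi)
}

#' Long-time reservoir concentration for a finite delivery bath
#'
#' Equilibrium limit of the coupled wall/reservoir system: the wall profile
#' flattens to gamma_D * CD_inf, so mass balance gives
#' CD_inf = M(t1) / (gamma_D * V_wall + V_bath).
#'
#' @param mass_at_t1 Drug mass in the wall at the start of delivery, ug.
#' @param geometry A `catheter_geometry`.
#' @param params A `transport_parameters` (finite `reservoir_volume`).
#' @return Equilibrium reservoir concentration in ug/cm^3.
#' @export
equilibrium_reservoir <- function(mass_at_t1, geometry, params) {
  stopifnot(inherits(geometry, "catheter_geometry"),
            inherits(params, "transport_parameters"))
  if (mass_at_t1 < 0) stop("mass_at_t1 must be nonnegative")
  mass_at_t1 / (params$gamma_delivery * wall_volume(geometry) +
                  params$reservoir_volume)
}

#' Radial wall-concentration snapshots
#'
#' Extracts radial profiles C(r) at the simulation snapshots nearest to the
#' requested times, across all three stages.  Useful for inspecting the
#' surface-localised profile at the end of loading and its inward spreading
#' over the rest stage.
#'
#' @param result A `catheter_simulation`.
#' @param times Times in hours (absolute, from the start of loading); must
#'   lie within the simulated range.
#' @return A data frame with columns `time_h` (requested), `snapshot_h`
#'   (actual snapshot time used), `r_cm` and `concentration_ug_cm3`.
#' @export
wall_profile_snapshots <- function(result, times) {
  stopifnot(inherits(result, "catheter_simulation"))
  all_times <- c(result$stages$load$times, result$stages$rest$times,
                 result$stages$delivery$times)
  all_states <- rbind(result$stages$load$states, result$stages$rest$states,
                      result$stages$delivery$states)
  rng <- range(all_times)
  if (any(times < rng[1] - 1e-9 | times > rng[2] + 1e-9))
    stop(sprintf("requested time outside simulated range [%g, %g] h",
                 rng[1], rng[2]))
  out <- lapply(times, function(tt) {
    i <- which.min(abs(all_times - tt))
    data.frame(time_h = tt, snapshot_h = all_times[i], r_cm = result$grid$r,
               concentration_ug_cm3 = all_states[i, ])
  })
  do.call(rbind, out)
}

#' Loading-time / rest-time protocol sweep
#'
#' Runs one full simulation per (load duration, rest duration) pair with a
#' common delivery duration, and interpolates every release curve onto a
#' shared delivery-time grid so protocol variants are directly comparable.
#'
#' @param geometry A `catheter_geometry`.
#' @param params A `transport_parameters`.
#' @param load_durations Loading durations in hours (nonempty).
#' @param rest_durations Rest durations in hours (nonempty; 0 allowed).
#' @param delivery_duration Delivery duration in hours.
#' @param numerics A `numerics_config`.
#' @param grid_dt Spacing of the common delivery-time grid, hours.
#' @return An object of class `protocol_sweep`: list with `release` (long
#'   data frame: `load_h`, `rest_h`, `time_h`, `release_ug_cm2`) and
#'   `uptake` (data frame of wall mass per external area at the end of each
#'   loading stage, ug/cm^2).
#' @export
sweep_protocol <- function(geometry, params, load_durations, rest_durations,
                           delivery_duration, numerics = numerics_config(),
                           grid_dt = 1) {
  if (length(load_durations) == 0 || length(rest_durations) == 0)
    stop("duration lists must be nonempty")
  tgrid <- seq(0, delivery_duration, by = grid_dt)
  rel <- list(); upt <- list(); k <- 0
  for (ld in load_durations) for (rd in rest_durations) {
    k <- k + 1
    prot <- stage_protocol(ld, ld + rd, ld + rd + delivery_duration)
    sim <- tryCatch(
      simulate_protocol(geometry, params, prot, numerics),
      error = function(e) stop(sprintf(
        "sweep failed at (load = %g h, rest = %g h): %s",
        ld, rd, conditionMessage(e))))
    prof <- cumulative_release(sim)
    y <- approx(prof$time_h, prof$release_ug_cm2, xout = tgrid,
                rule = 2)$y
    rel[[k]] <- data.frame(load_h = ld, rest_h = rd, time_h = tgrid,
                           release_ug_cm2 = y)
    load_final <- sim$stages$load$states[nrow(sim$stages$load$states), ]
    upt[[k]] <- data.frame(
      load_h = ld, rest_h = rd,
      uptake_ug_cm2 = wall_mass(load_final, sim$grid) / external_area(geometry))
  }
  structure(list(release = do.call(rbind, rel), uptake = do.call(rbind, upt),
                 geometry = geometry, params = params),
            class = "protocol_sweep")
}

#' @export
print.protocol_sweep <- function(x, ...) {
  cat(sprintf("Protocol sweep: %d (load, rest) pairs, delivery grid of %d points\n",
              nrow(x$uptake), length(unique(x$release$time_h))))
  invisible(x)
}
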