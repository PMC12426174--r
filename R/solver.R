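#' Numerical configuration for the stage solver
#'
#' The wall PDE is discretised by a conservative finite-volume scheme in
#' cylindrical coordinates (flux form of (1/r) d/dr (r D dC/dr)) and advanced
#' by an implicit theta scheme.  Implicit Euler is the default because the
#' loading stage starts from a concentration jump at r = R2, where
#' Crank-Nicolson produces bounded but unphysical oscillations.  Time steps
#' are rounded down so that an integer number of steps exactly tiles each
#' stage.
#'
#' @param n_nodes Radial nodes (>= 11); default 201.
#' @param dt_load,dt_rest,dt_delivery Nominal time steps per stage, hours.
#' @param scheme `"implicit-euler"` (default) or `"crank-nicolson"`.
#' @param max_keep Maximum number of stored snapshots per stage; long runs
#'   are thinned evenly (the final step is always kept).
#' @return An object of class `numerics_config`.
#' @export
numerics_config <- function(n_nodes = 201, dt_load = 0.01, dt_rest = 0.05,
                            dt_delivery = 0.1,
                            scheme = c("implicit-euler", "crank-nicolson"),
                            max_keep = 4000) {
  scheme <- match.arg(scheme)
  n_nodes <- as.integer(n_nodes)
  if (is.na(n_nodes) || n_nodes < 11L) stop("n_nodes must be at least 11")
  for (dt in c(dt_load, dt_rest, dt_delivery))
    if (!is.numeric(dt) || length(dt) != 1L || !is.finite(dt) || dt <= 0)
      stop("all time steps must be positive finite numbers (h)")
  structure(
    list(n_nodes = n_nodes, dt_load = as.numeric(dt_load),
         dt_rest = as.numeric(dt_rest), dt_delivery = as.numeric(dt_delivery),
         scheme = scheme, max_keep = as.integer(max_keep)),
    class = "numerics_config"
  )
}

# Split a stage of the given duration into n_steps of equal actual dt and
# choose which 1-based step indices to keep (always including the last).
stage_steps <- function(duration, dt, max_keep) {
  n_steps <- max(1L, as.integer(ceiling(duration / dt - 1e-9)))
  dt_actual <- duration / n_steps
  if (n_steps <= max_keep) {
    keep <- seq_len(n_steps)
  } else {
    keep <- unique(as.integer(round(seq(1, n_steps, length.out = max_keep))))
    keep[length(keep)] <- n_steps
    keep <- unique(keep)
  }
  list(n_steps = n_steps, dt = dt_actual, keep = keep)
}

# Assemble the tridiagonal theta-scheme system for one stage.
#
# The semi-discrete system is M dC/dt = -K C + src with M the cell-volume
# (or merged reservoir) masses and K the conductance stencil built from face
# conductances g_f = 2*pi*r_f*L*D/h.  Dirichlet rows replace the equation by
# an identity row.  Returns the A/B diagonals, source, flux weights and the
# mapping needed to reconstruct the wall profile (and reservoir) from the
# unknown vector.
build_stage_system <- function(mode, grid, params, dt, theta) {
  n <- grid$n
  geom <- grid$geometry
  g <- 2 * pi * grid$face_r * geom$L * params$D / grid$h
  V <- grid$cell_volumes
  A_ext <- 2 * pi * geom$R2 * geom$L
  wm_load <- !is.finite(params$k_load)
  wm_del <- !is.finite(params$k_delivery)
  sink <- !is.finite(params$reservoir_volume)
  gD <- params$gamma_delivery

  ksub <- -g
  kdiag <- c(g[1], g[-1] + g[-(n - 1)], g[n - 1])
  ksup <- -g
  M <- V
  src <- numeric(n)
  dirichlet <- NULL
  w <- numeric(n)
  m <- n
  kind <- "wall"

  if (mode == "load") {
    if (wm_load) {
      dirichlet <- list(idx = n,
                        val = params$gamma_load * params$bath_concentration)
    } else {
      kdiag[n] <- kdiag[n] + params$k_load * A_ext
      src[n] <- params$k_load * A_ext * params$gamma_load *
        params$bath_concentration
    }
  } else if (mode == "delivery") {
    if (wm_del && !sink) {
      # merge the outer half-cell (slaved to gamma_D * CD) with the reservoir
      ksup[n - 1] <- -g[n - 1] * gD
      ksub[n - 1] <- -g[n - 1]
      kdiag[n] <- g[n - 1] * gD
      M[n] <- gD * V[n] + params$reservoir_volume
      kind <- "delivery_wm"
    } else if (wm_del && sink) {
      dirichlet <- list(idx = n, val = 0)
      w[n - 1] <- g[n - 1] * dt
      kind <- "delivery_sink"
    } else if (!wm_del && !sink) {
      m <- n + 1
      ksub <- c(ksub, -params$k_delivery * A_ext)
      ksup <- c(ksup, 0)
      ksup[n] <- -params$k_delivery * A_ext * gD
      kdiag[n] <- kdiag[n] + params$k_delivery * A_ext
      kdiag <- c(kdiag, params$k_delivery * A_ext * gD)
      M <- c(M, params$reservoir_volume)
      src <- c(src, 0)
      w <- c(w, 0)
      kind <- "delivery_robin"
    } else {
      kdiag[n] <- kdiag[n] + params$k_delivery * A_ext
      w[n] <- params$k_delivery * A_ext * dt
      kind <- "delivery_sink_robin"
    }
  } else if (mode != "rest") {
    stop("unknown stage mode: ", mode)
  }

  al <- theta * ksub
  ad <- M / dt + theta * kdiag
  au <- theta * ksup
  bl <- -(1 - theta) * ksub
  bd <- M / dt - (1 - theta) * kdiag
  bu <- -(1 - theta) * ksup
  s <- src
  if (!is.null(dirichlet)) {
    j <- dirichlet$idx
    ad[j] <- 1; bd[j] <- 0; s[j] <- dirichlet$val
    if (j > 1) { al[j - 1] <- 0; bl[j - 1] <- 0 }
    if (j < m) { au[j] <- 0; bu[j] <- 0 }
  }
  list(al = al, ad = ad, au = au, bl = bl, bd = bd, bu = bu,
       s = s, w = w, m = m, kind = kind, g = g, A_ext = A_ext)
}

numerical_error <- function(msg) {
  stop(errorCondition(msg, class = c("cathflux_numerical_error", "error")))
}

run_stage <- function(sys, x0, n_steps, keep, ref_scale) {
  out <- stage_advance_cpp(sys$al, sys$ad, sys$au, sys$bl, sys$bd, sys$bu,
                           sys$s, sys$w, x0, as.integer(n_steps),
                           as.integer(keep))
  mx <- max(abs(out$states), abs(x0), ref_scale)
  if (min(out$states) < -1e-10 * mx)
    numerical_error(paste0(
      "numerical instability: concentrations fell below -1e-10 * max; ",
      "use a smaller time step (or the implicit-euler scheme)"))
  out
}

#' Advance the wall (and reservoir) by a single time step
#'
#' One implicit step of the stage-appropriate boundary-value problem: the
#' inner surface is always zero-flux; the outer surface is the loading
#' condition (Dirichlet `gamma_L * C_L` in the well-mixed limit, Robin with
#' `k_load` otherwise), sealed (zero-flux) during rest, or coupled to the
#' delivery reservoir.  During delivery the wall unknowns and the reservoir
#' concentration are solved in one linear system, so the step conserves
#' wall + reservoir mass to rounding error.
#'
#' @param state A `wall_state` on `grid`.
#' @param reservoir A `reservoir_state`; required iff `bc_mode = "delivery"`.
#' @param bc_mode One of `"load"`, `"rest"`, `"delivery"`.
#' @param params A `transport_parameters`.
#' @param geometry The `catheter_geometry` (must match the grid's).
#' @param grid A `radial_grid`.
#' @param dt Time step in hours.
#' @param scheme `"implicit-euler"` or `"crank-nicolson"`.
#' @return A list with elements `state` (new `wall_state`) and `reservoir`
#'   (new `reservoir_state`, or `NULL` outside delivery).
#' @export
step_stage <- function(state, reservoir = NULL,
                       bc_mode = c("load", "rest", "delivery"),
                       params, geometry, grid, dt,
                       scheme = c("implicit-euler", "crank-nicolson")) {
  bc_mode <- match.arg(bc_mode)
  scheme <- match.arg(scheme)
  stopifnot(inherits(state, "wall_state"), inherits(grid, "radial_grid"),
            inherits(params, "transport_parameters"))
  if (length(state$concentration) != grid$n)
    stop("wall state length does not match the grid")
  if (bc_mode == "delivery" && is.null(reservoir))
    stop("a reservoir state is required in delivery mode")
  theta <- if (scheme == "crank-nicolson") 0.5 else 1
  sys <- build_stage_system(bc_mode, grid, params, dt, theta)
  n <- grid$n
  C <- state$concentration
  V <- grid$cell_volumes
  gD <- params$gamma_delivery
  x0 <- switch(sys$kind,
    wall = C,
    delivery_wm = c(C[-n], (V[n] * C[n] + params$reservoir_volume *
                              reservoir$CD) / (gD * V[n] +
                                                 params$reservoir_volume)),
    delivery_robin = c(C, reservoir$CD),
    delivery_sink = c(C[-n], 0),
    delivery_sink_robin = C
  )
  ref <- params$gamma_load * params$bath_concentration
  out <- run_stage(sys, x0, 1L, 1L, ref)
  x <- out$states[1L, ]
  new_res <- NULL
  newC <- switch(sys$kind,
    wall = x,
    delivery_wm = c(x[-n], gD * x[n]),
    delivery_robin = x[seq_len(n)],
    delivery_sink = x,
    delivery_sink_robin = x
  )
  if (bc_mode == "delivery") {
    cd <- switch(sys$kind,
      delivery_wm = x[n],
      delivery_robin = x[n + 1],
      0)
    new_res <- reservoir_state(state$time + dt, cd)
  }
  list(state = wall_state(state$time + dt, newC), reservoir = new_res)
}

#' Simulate the full load / rest / delivery protocol
#'
#' Runs the three consecutive diffusion stages: loading from a concentrated
#' bath on (0, t0], sealed rest on (t0, t1] and delivery into the reservoir
#' on (t1, t_end], each stage starting from the previous stage's final wall
#' profile.  The reservoir starts at CD(t1) = 0.  Stage-boundary jumps in the
#' boundary data are attached to the later stage.
#'
#' @param geometry A `catheter_geometry`.
#' @param params A `transport_parameters`.
#' @param protocol A `stage_protocol`.
#' @param numerics A `numerics_config`.
#' @return An object of class `catheter_simulation`: the generating inputs
#'   plus per-stage snapshot times, wall-state matrices (rows = times,
#'   columns = radial nodes) and, for delivery, the reservoir trajectory
#'   `cd` (ug/cm^3) and cumulative `release` per external area (ug/cm^2).
#' @export
#' @examples
#' \donttest{
#' sim <- simulate_protocol(foley_geometry("14Fr"), cfx_parameters("control"),
#'                          stage_protocol(), numerics_config(n_nodes = 61,
#'                          dt_load = 0.1, dt_rest = 0.5, dt_delivery = 1))
#' tail(sim$stages$delivery$release, 1)
#' }
simulate_protocol <- function(geometry, params, protocol,
                              numerics = numerics_config()) {
  stopifnot(inherits(geometry, "catheter_geometry"),
            inherits(params, "transport_parameters"),
            inherits(protocol, "stage_protocol"),
            inherits(numerics, "numerics_config"))
  grid <- radial_grid(geometry, numerics$n_nodes)
  theta <- if (numerics$scheme == "crank-nicolson") 0.5 else 1
  n <- grid$n
  V <- grid$cell_volumes
  ref <- params$gamma_load * params$bath_concentration
  wrap_stage <- function(expr, stage) {
    tryCatch(expr, cathflux_numerical_error = function(e)
      numerical_error(sprintf("[%s stage] %s", stage, conditionMessage(e))))
  }

  # -- load -----------------------------------------------------------------
  ss <- stage_steps(protocol$t0, numerics$dt_load, numerics$max_keep)
  sys <- build_stage_system("load", grid, params, ss$dt, theta)
  x0 <- numeric(n)
  out <- wrap_stage(run_stage(sys, x0, ss$n_steps, ss$keep, ref), "load")
  load_states <- rbind(x0, out$states, deparse.level = 0)
  load_times <- c(0, ss$keep * ss$dt)
  x_t0 <- out$states[nrow(out$states), ]

  # -- rest -----------------------------------------------------------------
  if (protocol$t1 > protocol$t0) {
    ss <- stage_steps(protocol$t1 - protocol$t0, numerics$dt_rest,
                      numerics$max_keep)
    sys <- build_stage_system("rest", grid, params, ss$dt, theta)
    out <- wrap_stage(run_stage(sys, x_t0, ss$n_steps, ss$keep, ref), "rest")
    rest_states <- rbind(x_t0, out$states, deparse.level = 0)
    rest_times <- protocol$t0 + c(0, ss$keep * ss$dt)
    x_t1 <- out$states[nrow(out$states), ]
  } else {
    rest_states <- matrix(x_t0, nrow = 1)
    rest_times <- protocol$t0
    x_t1 <- x_t0
  }

  # -- delivery -------------------------------------------------------------
  ss <- stage_steps(protocol$t_end - protocol$t1, numerics$dt_delivery,
                    numerics$max_keep)
  sys <- build_stage_system("delivery", grid, params, ss$dt, theta)
  gD <- params$gamma_delivery
  Vb <- params$reservoir_volume
  A_ext <- sys$A_ext
  x0 <- switch(sys$kind,
    delivery_wm = c(x_t1[-n], V[n] * x_t1[n] / (gD * V[n] + Vb)),
    delivery_robin = c(x_t1, 0),
    delivery_sink = c(x_t1[-n], 0),
    delivery_sink_robin = x_t1
  )
  out <- wrap_stage(run_stage(sys, x0, ss$n_steps, ss$keep, ref), "delivery")
  M_t1 <- sum(x_t1 * V)
  if (sys$kind == "delivery_wm") {
    wall <- cbind(out$states[, -n, drop = FALSE], gD * out$states[, n])
    cd <- out$states[, n]
    release <- Vb * cd / A_ext
    flux_cum <- NULL
  } else if (sys$kind == "delivery_robin") {
    wall <- out$states[, seq_len(n), drop = FALSE]
    cd <- out$states[, n + 1]
    release <- Vb * cd / A_ext
    flux_cum <- NULL
  } else {
    wall <- out$states
    cd <- numeric(nrow(out$states))
    release <- (M_t1 - as.numeric(wall %*% V)) / A_ext
    extra <- if (sys$kind == "delivery_sink") V[n] * x_t1[n] else 0
    flux_cum <- extra + out$cumw
  }
  delivery <- list(
    times = protocol$t1 + c(0, ss$keep * ss$dt),
    states = rbind(x_t1, wall, deparse.level = 0),
    cd = c(0, cd),
    release = c(0, release),
    flux_cum = if (is.null(flux_cum)) NULL else c(0, flux_cum),
    mode = sys$kind
  )

  structure(
    list(geometry = geometry, params = params, protocol = protocol,
         numerics = numerics, grid = grid,
         stages = list(
           load = list(times = load_times, states = load_states),
           rest = list(times = rest_times, states = rest_states),
           delivery = delivery)),
    class = "catheter_simulation"
  )
}

#' @export
print.catheter_simulation <- function(x, ...) {
  d <- x$stages$delivery
  cat(sprintf(
    "Catheter release simulation (%s, %d nodes)\n",
    x$numerics$scheme, x$grid$n))
  print(x$protocol)
  cat(sprintf("  final cumulative release: %.3f ug/cm^2\n",
              d$release[length(d$release)]))
  invisible(x)
}

#' Mass-conservation audit of a protocol simulation
#'
#' Checks the discrete conservation laws of the scheme: over the sealed rest
#' stage the wall mass must be constant; over the delivery stage the total
#' wall + reservoir mass must equal the wall mass at the start of delivery
#' (finite bath), or the wall-mass decrement must equal the time-integrated
#' boundary flux (pure sink).  Defects are reported relative to the wall
#' mass at the start of the audited stage.
#'
#' @param result A `catheter_simulation`.
#' @return An object of class `mass_audit`: list with `rest_defect`,
#'   `delivery_defect` and `max_defect` (all dimensionless), or `NA` values
#'   with an explanatory `note` when the wall held no mass at t1.
#' @export
mass_balance_audit <- function(result) {
  stopifnot(inherits(result, "catheter_simulation"))
  V <- result$grid$cell_volumes
  rest <- result$stages$rest
  M_rest <- as.numeric(rest$states %*% V)
  rest_defect <- if (M_rest[1] > 0)
    max(abs(M_rest - M_rest[1])) / M_rest[1] else NA_real_

  d <- result$stages$delivery
  M_del <- as.numeric(d$states %*% V)
  M_t1 <- M_del[1]
  note <- NULL
  if (M_t1 <= 0) {
    delivery_defect <- NA_real_
    note <- "wall mass at delivery start is zero; audit undefined"
  } else if (d$mode %in% c("delivery_wm", "delivery_robin")) {
    total <- M_del + result$params$reservoir_volume * d$cd
    delivery_defect <- max(abs(total - M_t1)) / M_t1
  } else {
    decrement <- M_t1 - M_del
    delivery_defect <- max(abs(decrement - d$flux_cum)) / M_t1
  }
  structure(list(rest_defect = rest_defect,
                 delivery_defect = delivery_defect,
                 max_defect = suppressWarnings(
                   max(rest_defect, delivery_defect, na.rm = TRUE)),
                 note = note),
            class = "mass_audit")
}

#' @export
print.mass_audit <- function(x, ...) {
  cat(sprintf("Mass-balance audit: rest defect %.3g, delivery defect %.3g\n",
              x$rest_defect, x$delivery_defect))
  if (!is.null(x$note)) cat("  note:", x$note, "\n")
  invisible(x)
}
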