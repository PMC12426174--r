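#' Transport parameters of the drug/wall/bath system
#'
#' Collects the kinetic constants of the stage-switched diffusion model.
#' Canonical units are cm, hours and micrograms throughout, so diffusivity is
#' cm^2/h, concentrations are ug/cm^3 and mass-transfer coefficients cm/h.
#'
#' The surface boundary conditions use an equilibrium partition coefficient
#' gamma (solid-surface concentration over adjacent liquid concentration) and
#' a convective mass-transfer coefficient k.  Setting `k_load` or
#' `k_delivery` to `Inf` (the default, the well-mixed limit k >> D) replaces
#' the Robin condition by its Dirichlet reduction C(R2) = gamma * C_bath.
#' Setting `reservoir_volume = Inf` selects pure-sink delivery (the bath
#' concentration is pinned at zero).
#'
#' @param diffusivity Drug diffusivity D in the wall, cm^2/h; positive.
#' @param gamma_load Partition coefficient between wall surface and loading
#'   bath (dimensionless, positive).
#' @param gamma_delivery Partition coefficient between wall surface and
#'   delivery bath (dimensionless, positive).
#' @param k_load Convective coefficient at the outer surface during loading,
#'   cm/h; `Inf` means well-mixed (Dirichlet) loading.
#' @param k_delivery Convective coefficient during delivery, cm/h; `Inf`
#'   means well-mixed delivery.
#' @param bath_concentration Loading-bath drug concentration C_L in ug/cm^3;
#'   nonnegative.
#' @param reservoir_volume Delivery-bath (PBS) volume V in cm^3; `Inf`
#'   selects pure-sink delivery.
#'
#' @return An object of class `transport_parameters`.
#' @export
#' @examples
#' transport_parameters(1.744e-5, 1.478, 0.7688)
transport_parameters <- function(diffusivity, gamma_load, gamma_delivery,
                                 k_load = Inf, k_delivery = Inf,
                                 bath_concentration = 1330,
                                 reservoir_volume = 250) {
  num1 <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 1L || is.na(x))
      stop(sprintf("%s must be a single number", nm))
    as.numeric(x)
  }
  D <- num1(diffusivity, "diffusivity")
  gL <- num1(gamma_load, "gamma_load")
  gD <- num1(gamma_delivery, "gamma_delivery")
  kL <- num1(k_load, "k_load")
  kD <- num1(k_delivery, "k_delivery")
  CL <- num1(bath_concentration, "bath_concentration")
  V <- num1(reservoir_volume, "reservoir_volume")
  if (!is.finite(D) || D <= 0) stop("diffusivity must be positive and finite")
  if (!is.finite(gL) || gL <= 0) stop("gamma_load must be positive and finite")
  if (!is.finite(gD) || gD <= 0) stop("gamma_delivery must be positive and finite")
  if (kL <= 0) stop("k_load must be positive (Inf for the well-mixed limit)")
  if (kD <= 0) stop("k_delivery must be positive (Inf for the well-mixed limit)")
  if (!is.finite(CL) || CL < 0) stop("bath_concentration must be nonnegative and finite")
  if (V <= 0) stop("reservoir_volume must be positive (Inf for pure-sink delivery)")
  structure(
    list(D = D, gamma_load = gL, gamma_delivery = gD,
         k_load = kL, k_delivery = kD,
         bath_concentration = CL, reservoir_volume = V),
    class = "transport_parameters"
  )
}

#' Reference kinetic parameters for ciprofloxacin in silicone catheter walls
#'
#' Parameter sets estimated for ciprofloxacin transport through silicone
#' Foley catheter walls, for the uncoated control devices and for devices
#' carrying a carboxymethylcellulose / chitosan-silver layer-by-layer (LbL)
#' coating.  The micron-thick coating is represented purely through its
#' partition coefficients: the diffusivity D = 1.744e-5 cm^2/h is shared by
#' both conditions because the coating is ~1000x thinner than the 1 mm wall.
#' The loading bath is 1.33 mg/mL ciprofloxacin (1330 ug/cm^3).
#'
#' The delivery-bath volume is not part of the reference set; the default of
#' 250 cm^3 is effectively a sink for these loadings and can be overridden
#' (or set to `Inf` for an exact sink).
#'
#' @param condition `"control"` (uncoated) or `"LbL"` (coated).
#' @param reservoir_volume Delivery-bath volume in cm^3 (`Inf` = sink).
#' @param k_load,k_delivery Convective coefficients; default well-mixed.
#' @return A `transport_parameters` object.
#' @export
#' @examples
#' cfx_parameters("control")
#' cfx_parameters("LbL", reservoir_volume = Inf)
cfx_parameters <- function(condition = c("control", "LbL"),
                           reservoir_volume = 250,
                           k_load = Inf, k_delivery = Inf) {
  condition <- match.arg(condition)
  gam <- switch(condition,
    control = c(load = 1.478, delivery = 0.7688),
    LbL = c(load = 3.928, delivery = 1.282)
  )
  transport_parameters(
    diffusivity = 1.744e-5,
    gamma_load = gam[["load"]],
    gamma_delivery = gam[["delivery"]],
    k_load = k_load, k_delivery = k_delivery,
    bath_concentration = 1330,
    reservoir_volume = reservoir_volume
  )
}

#' @export
print.transport_parameters <- function(x, ...) {
  kfmt <- function(k) if (is.finite(k)) sprintf("%.4g cm/h", k) else "well-mixed"
  vfmt <- if (is.finite(x$reservoir_volume))
    sprintf("%.4g cm^3", x$reservoir_volume) else "sink"
  cat("Transport parameters (cm/h/ug units):\n")
  cat(sprintf("  D        = %.4g cm^2/h\n", x$D))
  cat(sprintf("  gamma_L  = %.4g   gamma_D = %.4g\n",
              x$gamma_load, x$gamma_delivery))
  cat(sprintf("  k_L      = %s   k_D = %s\n", kfmt(x$k_load), kfmt(x$k_delivery)))
  cat(sprintf("  C_L      = %.4g ug/cm^3   V_bath = %s\n",
              x$bath_concentration, vfmt))
  invisible(x)
}

#' Loading / rest / delivery stage protocol
#'
#' Times are absolute hours from the start of loading: the load stage runs on
#' (0, t0], the sealed rest stage on (t0, t1] and delivery on (t1, t_end].
#' A zero-length rest stage (`rest_end == load_end`) is allowed so protocol
#' sweeps can include a no-rest arm; all other orderings are strict.
#'
#' @param load_end End of the loading stage t0 in hours.
#' @param rest_end End of the rest stage t1 in hours (>= `load_end`).
#' @param delivery_end End of the delivery stage in hours (> `rest_end`).
#' @return An object of class `stage_protocol` with fields `t0`, `t1`, `t_end`.
#' @export
#' @examples
#' stage_protocol()  # the reference 12 h load / 24 h rest / 15 day delivery
stage_protocol <- function(load_end = 12, rest_end = 36, delivery_end = 396) {
  t0 <- as.numeric(load_end); t1 <- as.numeric(rest_end)
  te <- as.numeric(delivery_end)
  if (!is.finite(t0) || t0 <= 0) stop("load_end must be a positive time (h)")
  if (!is.finite(t1) || t1 < t0) stop("rest_end must satisfy rest_end >= load_end")
  if (!is.finite(te) || te <= t1) stop("delivery_end must exceed rest_end")
  structure(list(t0 = t0, t1 = t1, t_end = te), class = "stage_protocol")
}

#' @export
print.stage_protocol <- function(x, ...) {
  cat(sprintf(
    "Stage protocol: load (0, %g] h; rest (%g, %g] h; delivery (%g, %g] h\n",
    x$t0, x$t0, x$t1, x$t1, x$t_end))
  invisible(x)
}
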