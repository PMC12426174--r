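#' Catheter wall geometry
#'
#' Defines the annular diffusion domain of a catheter wall segment: inner
#' radius `R1`, outer radius `R2` and sample length `L`, all in centimetres.
#' The transport model is strictly one-dimensional in the radial coordinate,
#' so the geometry carries no tip, balloon orifice or end-face information.
#'
#' @param inner_radius Inner wall radius R1 in cm; must satisfy 0 < R1 < R2.
#' @param outer_radius Outer wall radius R2 in cm.
#' @param sample_length Axial length L of the segment in cm; must be positive.
#'
#' @return An object of class `catheter_geometry` with fields `R1`, `R2`, `L`.
#' @seealso [foley_geometry()] for the two reference Foley sizes.
#' @export
#' @examples
#' g <- catheter_geometry(0.135, 0.235, 2.5)
#' wall_thickness(g)
catheter_geometry <- function(inner_radius, outer_radius, sample_length) {
  if (!is.numeric(inner_radius) || length(inner_radius) != 1L ||
      !is.finite(inner_radius) || inner_radius <= 0)
    stop("inner_radius must be a single positive finite number (cm)")
  if (!is.numeric(outer_radius) || length(outer_radius) != 1L ||
      !is.finite(outer_radius) || outer_radius <= inner_radius)
    stop("outer_radius must be finite and strictly greater than inner_radius")
  if (!is.numeric(sample_length) || length(sample_length) != 1L ||
      !is.finite(sample_length) || sample_length <= 0)
    stop("sample_length must be a single positive finite number (cm)")
  structure(
    list(R1 = as.numeric(inner_radius), R2 = as.numeric(outer_radius),
         L = as.numeric(sample_length)),
    class = "catheter_geometry"
  )
}

#' Reference Foley catheter geometries
#'
#' Measured cross-sections of the two silicone Foley catheter sizes used as
#' reference devices: 14Fr (outer/inner diameters 4.7/2.7 mm) and 20Fr
#' (6.7/4.7 mm), both with a 1 mm wall, cut to 2.5 cm segments.  Note these
#' are measured diameters, not the nominal 1 Fr = 1/3 mm convention; other
#' sizes must be supplied explicitly through [catheter_geometry()].
#'
#' @param size One of `"14Fr"` or `"20Fr"`.
#' @return A `catheter_geometry` in cm.
#' @export
#' @examples
#' foley_geometry("14Fr")
foley_geometry <- function(size = c("14Fr", "20Fr")) {
  size <- match.arg(size)
  switch(size,
    "14Fr" = catheter_geometry(0.135, 0.235, 2.5),
    "20Fr" = catheter_geometry(0.235, 0.335, 2.5)
  )
}

#' Wall thickness of a catheter geometry
#'
#' @param geometry A `catheter_geometry`.
#' @return R2 - R1 in cm.
#' @export
wall_thickness <- function(geometry) {
  stopifnot(inherits(geometry, "catheter_geometry"))
  geometry$R2 - geometry$R1
}

#' External lateral surface area 2*pi*R2*L of the wall segment (cm^2)
#' @param geometry A `catheter_geometry`.
#' @return Area in cm^2.
#' @export
external_area <- function(geometry) {
  stopifnot(inherits(geometry, "catheter_geometry"))
  2 * pi * geometry$R2 * geometry$L
}

#' Annulus volume pi*(R2^2 - R1^2)*L of the wall segment (cm^3)
#' @param geometry A `catheter_geometry`.
#' @return Volume in cm^3.
#' @export
wall_volume <- function(geometry) {
  stopifnot(inherits(geometry, "catheter_geometry"))
  pi * (geometry$R2^2 - geometry$R1^2) * geometry$L
}

#' @export
print.catheter_geometry <- function(x, ...) {
  cat(sprintf(
    "Catheter wall geometry: R1 = %.4g cm, R2 = %.4g cm, L = %.4g cm (wall %.4g cm)\n",
    x$R1, x$R2, x$L, x$R2 - x$R1))
  invisible(x)
}
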