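#' Finite-volume radial grid on the catheter wall annulus
#'
#' Uniform node grid from R1 to R2 with finite-volume cells bounded by the
#' midpoints between nodes (half-cells at the two walls).  Cell volumes are
#' exact annular-shell volumes, so they telescope to the full annulus volume
#' pi*(R2^2 - R1^2)*L to rounding error, which is what makes the discrete
#' mass audits meaningful.
#'
#' @param geometry A `catheter_geometry`.
#' @param n_nodes Number of radial nodes (>= 11).
#' @return An object of class `radial_grid` with fields `r` (node positions,
#'   cm), `h` (spacing), `face_r` (interior face radii), `cell_volumes`
#'   (cm^3) and the generating `geometry`.
#' @export
#' @examples
#' g <- radial_grid(foley_geometry("14Fr"), 11)
#' sum(g$cell_volumes) - wall_volume(foley_geometry("14Fr"))
radial_grid <- function(geometry, n_nodes = 201) {
  stopifnot(inherits(geometry, "catheter_geometry"))
  n_nodes <- as.integer(n_nodes)
  if (is.na(n_nodes) || n_nodes < 11L)
    stop("n_nodes must be at least 11 to resolve the wall")
  r <- seq(geometry$R1, geometry$R2, length.out = n_nodes)
  h <- (geometry$R2 - geometry$R1) / (n_nodes - 1)
  face_r <- (r[-1] + r[-n_nodes]) / 2
  edges <- c(geometry$R1, face_r, geometry$R2)
  V <- pi * (edges[-1]^2 - edges[-(n_nodes + 1)]^2) * geometry$L
  structure(
    list(r = r, h = h, face_r = face_r, cell_volumes = V,
         n = n_nodes, geometry = geometry),
    class = "radial_grid"
  )
}

#' Drug mass held in the wall
#'
#' Discrete integral of the concentration field over the annulus using the
#' finite-volume cell volumes.
#'
#' @param concentration Numeric vector of node concentrations (ug/cm^3), or a
#'   `wall_state`.
#' @param grid The `radial_grid` the state lives on.
#' @return Mass in ug.
#' @export
wall_mass <- function(concentration, grid) {
  stopifnot(inherits(grid, "radial_grid"))
  if (inherits(concentration, "wall_state"))
    concentration <- concentration$concentration
  if (length(concentration) != grid$n)
    stop("state length does not match the grid")
  sum(as.numeric(concentration) * grid$cell_volumes)
}

#' Wall concentration state at one time point
#'
#' @param time Time in hours.
#' @param concentration Node concentrations (ug/cm^3).
#' @return An object of class `wall_state`.
#' @export
wall_state <- function(time, concentration) {
  structure(list(time = as.numeric(time),
                 concentration = as.numeric(concentration)),
            class = "wall_state")
}

#' Delivery-bath (reservoir) state at one time point
#'
#' @param time Time in hours.
#' @param concentration Reservoir drug concentration CD in ug/cm^3.
#' @return An object of class `reservoir_state`.
#' @export
reservoir_state <- function(time, concentration = 0) {
  if (concentration < 0) stop("reservoir concentration must be nonnegative")
  structure(list(time = as.numeric(time), CD = as.numeric(concentration)),
            class = "reservoir_state")
}
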