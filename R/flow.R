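#' Microfluidic flow-cell geometry
#'
#' The channel is a shallow rectangular duct of height `height_h` (mm,
#' z-direction) and width `width_w` (mm); a syringe pump drives a
#' volumetric rate `flow_q` through it.  Both unit conventions that occur
#' in practice are accepted (`"uL/s"` and `"uL/min"`); 1 uL = 1 mm^3, so
#' the average speed is `u_avg = Q / (w h)` in mm/s.
#'
#' @param height_h channel height (mm).
#' @param width_w channel width (mm).
#' @param flow_q volumetric flow rate, in `q_unit`.
#' @param q_unit `"uL/s"` or `"uL/min"`.
#' @return object of class `"flow_cell"` with the geometry and derived
#'   `u_avg` (mm/s).
#' @examples
#' average_speed(flow_cell()) # 3.856 mm/s
#' shear_rate(0, flow_cell(flow_q = 50, q_unit = "uL/min")) # 192.9 / s
#' @export
flow_cell <- function(height_h = 0.12, width_w = 1.8, flow_q = 0.833,
                      q_unit = c("uL/s", "uL/min")) {
  q_unit <- match.arg(q_unit)
  stopifnot(height_h > 0, width_w > 0, flow_q >= 0)
  q_si <- if (q_unit == "uL/min") flow_q / 60 else flow_q  # uL/s = mm^3/s
  cell <- list(height_h = height_h, width_w = width_w, flow_q = flow_q,
               q_unit = q_unit, u_avg = q_si / (width_w * height_h))
  class(cell) <- "flow_cell"
  cell
}

#' @export
print.flow_cell <- function(x, ...) {
  cat(sprintf("<flow_cell> h = %g mm, w = %g mm, Q = %g %s; u_avg = %.4g mm/s\n",
              x$height_h, x$width_w, x$flow_q, x$q_unit, x$u_avg))
  invisible(x)
}

#' Average flow speed in the cell
#'
#' `u_avg = Q / (w h)`, mm/s.
#'
#' @param cell a [flow_cell()].
#' @export
average_speed <- function(cell) cell$u_avg

#' Parabolic (Poiseuille) velocity profile
#'
#' `u_x(z) = 6 u_avg (h z - z^2) / h^2`: no-slip at both walls, maximum
#' `1.5 u_avg` at mid-height, and its average over the channel equals
#' `u_avg`.
#'
#' @param z height above the lower wall (mm), `0 <= z <= h`.
#' @param cell a [flow_cell()].
#' @return speed in mm/s.
#' @export
flow_profile <- function(z, cell) {
  if (any(z < 0 | z > cell$height_h)) stop("z outside the channel [0, h]")
  6 * cell$u_avg * (cell$height_h * z - z^2) / cell$height_h^2
}

#' Local shear rate of the profile
#'
#' `gamma_dot(z) = 6 u_avg / h * (1 - 2 z / h)` (1/s): wall value at
#' `z = 0`, zero at mid-height, sign-flipped at the far wall.  Because
#' the DNA stays within ~0.2% of the channel height of the lower wall,
#' the simulations use the constant wall value.
#'
#' @inheritParams flow_profile
#' @return shear rate (1/s).
#' @export
shear_rate <- function(z, cell) {
  if (any(z < 0 | z > cell$height_h)) stop("z outside the channel [0, h]")
  6 * cell$u_avg / cell$height_h * (1 - 2 * z / cell$height_h)
}

#' Dimensionless-number mappings
#'
#' At high salt the chain's longest relaxation time is proportional to
#' the solvent viscosity, so at fixed shear rate the Weissenberg number
#' is `Wi = c' eta` with a single calibration constant `c'` (1/cP).  The
#' per-bead Peclet number used by the integrator is `Pe = Wi / tau_r`
#' where `tau_r` is the reduced relaxation time of the chain.
#'
#' @param eta viscosity (cP).
#' @param c_prime calibration constant (1/cP).
#' @param wi Weissenberg number.
#' @param pe Peclet number.
#' @param tau_r reduced relaxation time (tau0 units), default 333.
#' @return the mapped dimensionless number (or viscosity).
#' @examples
#' wi_from_pe(0.02, 333) # 6.66
#' @export
wi_from_viscosity <- function(eta, c_prime) {
  stopifnot(all(eta >= 0), c_prime > 0)
  c_prime * eta
}

#' @rdname wi_from_viscosity
#' @export
viscosity_from_wi <- function(wi, c_prime) {
  stopifnot(c_prime > 0)
  wi / c_prime
}

#' @rdname wi_from_viscosity
#' @export
pe_from_wi <- function(wi, tau_r = 333) {
  stopifnot(tau_r > 0)
  wi / tau_r
}

#' @rdname wi_from_viscosity
#' @export
wi_from_pe <- function(pe, tau_r = 333) {
  stopifnot(tau_r > 0)
  pe * tau_r
}
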