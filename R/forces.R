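#' Deterministic force field on the chain
#'
#' The chain experiences three conservative contributions, all in reduced
#' units (kBT/a):
#'
#' * **elastic**: stiff harmonic springs between neighbouring beads,
#'   `F = -spring_k (l - 1) r_hat` along each bond;
#' * **surface**: a truncated soft wall at `z = 0`,
#'   `F_z = (6 wall_eps) ((1/z)^7 - (1/z)^4)` for `0 < z <= 1` and exactly
#'   zero for `z >= 1` (continuous at `z = 1`, purely repulsive);
#' * **peg**: a pairwise crowding attraction of magnitude
#'   `(alpha * peg_pct / decay_d) exp(-r / decay_d)` pulling beads
#'   together, restricted to pairs with contour separation
#'   `1 <= |n - n'| <= neighbor_cutoff`.
#'
#' All three are computed for every bead including the tethered bead 0;
#' the integrator never applies a force to bead 0 (it is clamped), so the
#' bead-0 rows are reported for bookkeeping only.
#'
#' @param state a [chain_state()].
#' @param params a [model_params()].
#' @return a tibble with columns `bead`, `fx`, `fy`, `fz` and an
#'   `applied` column that is `FALSE` for the clamped bead 0.
#' @examples
#' p <- model_params(n_segments = 2)
#' s <- init_conformation("extended_x", p)
#' spring_forces(s, p) # all zero: every bond at its equilibrium length
#' @export
spring_forces <- function(state, params) {
  force_tibble(spring_forces_cpp(state_matrix(state), params$spring_k))
}

#' @rdname spring_forces
#' @export
surface_forces <- function(state, params) {
  if (any(state$z <= params$z_floor)) {
    stop("bead height at or below z_floor = ", params$z_floor,
         "; the wall force diverges as z -> 0 (use a smaller dt)")
  }
  force_tibble(surface_forces_cpp(state_matrix(state), params$wall_eps))
}

#' @rdname spring_forces
#' @export
peg_forces <- function(state, params) {
  force_tibble(peg_forces_cpp(state_matrix(state), params$alpha,
                              params$decay_d, params$peg_pct,
                              params$neighbor_cutoff))
}

#' @rdname spring_forces
#' @export
total_forces <- function(state, params) {
  el <- spring_forces(state, params)
  su <- surface_forces(state, params)
  pg <- peg_forces(state, params)
  out <- el
  out$fx <- el$fx + su$fx + pg$fx
  out$fy <- el$fy + su$fy + pg$fy
  out$fz <- el$fz + su$fz + pg$fz
  out
}

force_tibble <- function(m) {
  tibble::tibble(bead = 0:(nrow(m) - 1), fx = m[, 1], fy = m[, 2],
                 fz = m[, 3], applied = c(FALSE, rep(TRUE, nrow(m) - 1)))
}

#' Total potential energy of a chain conformation
#'
#' Sum of harmonic bond energies `spring_k (l - 1)^2 / 2`, wall energies
#' `wall_eps ((1/z)^6 - 2 (1/z)^3 + 1)` for `z <= 1` (the antiderivative
#' of the wall force, zero at `z = 1`), and pairwise crowding energies
#' `-alpha * peg_pct * exp(-r / decay_d)` over the included pairs.  Units
#' of kBT.  The negative gradient of this function reproduces
#' [total_forces()]; that identity is the main use of the energy.
#'
#' @inheritParams spring_forces
#' @return scalar energy (kBT).
#' @export
total_potential <- function(state, params) {
  total_potential_cpp(state_matrix(state), params$spring_k, params$wall_eps,
                      params$alpha, params$decay_d, params$peg_pct,
                      params$neighbor_cutoff)
}
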